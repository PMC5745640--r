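#' Population limit of the covariate-adjusted logistic coefficient
#'
#' The exposure coefficient of the main-effects logistic regression of the
#' outcome on (exposure, `s`) that maximizes the expected log-likelihood
#' under the exact joint distribution — the n -> infinity limit of the
#' finite-sample adjusted fit.  When the conditional log odds ratio given
#' `s` is constant across strata, the projection recovers that constant;
#' otherwise it is the KL-projection coefficient.
#'
#' Solved by Newton iteration on the population score equations, starting
#' from zero, converging when the score norm drops below 1e-10 (cap 100
#' iterations).
#'
#' @param model A [scenario_model()].
#' @param s Adjustment set (character vector excluding exposure/outcome).
#' @return The population exposure coefficient (log odds ratio).
#'
#' @examples
#' m <- build_scenario("fig1a")
#' population_adjusted_coefficient(m, c("Z", "T"))  # = log 2 (the X->Y effect)
#' @export
population_adjusted_coefficient <- function(model, s) {
  s <- sort(unique(as.character(s)))
  dag <- model$dag
  check_nodes(dag, s, "s")
  if (dag$exposure %in% s || dag$outcome %in% s)
    stop("adjustment set must not contain the exposure or outcome",
         call. = FALSE)
  jt <- joint_table(model)
  keys <- c(dag$exposure, s)
  agg <- stats::aggregate(
    cbind(w = jt$prob, wy = jt$prob * jt[[dag$outcome]]),
    by = jt[keys], FUN = sum)
  agg <- agg[agg$w > 0, , drop = FALSE]
  q <- agg$wy / agg$w
  M <- cbind(1, as.matrix(agg[keys]))
  beta <- rep(0, ncol(M))
  for (it in seq_len(100L)) {
    p <- stats::plogis(drop(M %*% beta))
    g <- crossprod(M, agg$w * (q - p))
    if (sqrt(sum(g^2)) < 1e-10)
      return(unname(beta[2L]))
    H <- crossprod(M, M * (agg$w * p * (1 - p)))
    beta <- beta + drop(solve(H, g))
  }
  stop("population score equations did not converge within 100 iterations ",
       "(score norm ", signif(sqrt(sum(g^2)), 3), ")", call. = FALSE)
}

#' Population estimand of the stabilized-IPW marginal structural model
#'
#' At the population level the stabilized-weighted pseudo-population
#' reduces to the adjustment formula, so the MSM estimand is
#' `logit(sum_s P(Y=1|X=1,s) P(s)) - logit(sum_s P(Y=1|X=0,s) P(s))`,
#' computed exactly from the joint table.  Equals the true causal effect
#' whenever `s` is G-admissible.
#'
#' @param model A [scenario_model()].
#' @param s Adjustment set; with `s = character()` this is the crude
#'   marginal log odds ratio of outcome on exposure.
#' @return The population MSM coefficient (log odds ratio).
#' @export
population_ipw_estimand <- function(model, s) {
  s <- sort(unique(as.character(s)))
  dag <- model$dag
  check_nodes(dag, s, "s")
  if (dag$exposure %in% s || dag$outcome %in% s)
    stop("adjustment set must not contain the exposure or outcome",
         call. = FALSE)
  jt <- joint_table(model)
  x <- jt[[dag$exposure]]; y <- jt[[dag$outcome]]
  std_mean <- function(xval) {
    if (!length(s)) {
      px <- sum(jt$prob[x == xval])
      if (px <= 0) stop("positivity violation: P(X=", xval, ") = 0",
                        call. = FALSE)
      return(sum(jt$prob[x == xval & y == 1L]) / px)
    }
    pat <- interaction(jt[s], drop = FALSE, sep = ",")
    ps <- tapply(jt$prob, pat, sum)                       # P(s)
    pxs <- tapply(jt$prob * (x == xval), pat, sum)        # P(X=x, s)
    pyxs <- tapply(jt$prob * (x == xval) * (y == 1L), pat, sum)
    live <- ps > 0
    if (any(pxs[live] <= 0))
      stop("positivity violation: P(X=", xval, "|s) = 0 for pattern ",
           names(which(pxs[live] <= 0))[1L], call. = FALSE)
    sum(ps[live] * pyxs[live] / pxs[live])
  }
  p1 <- std_mean(1L); p0 <- std_mean(0L)
  eps <- 1e-12
  if (p1 < eps || p1 > 1 - eps || p0 < eps || p0 > 1 - eps)
    stop("degenerate standardized outcome probability", call. = FALSE)
  stats::qlogis(p1) - stats::qlogis(p0)
}

#' Population estimand report for a list of strategies
#'
#' Tabulates, for each adjustment strategy, the population value of its
#' estimator (logistic projection or IPW-MSM estimand) and its asymptotic
#' bias against the exact causal effect.
#'
#' @param model A [scenario_model()].
#' @param strategies List of strategies as built by [strategy()] /
#'   [make_strategies()].
#' @return A `data.frame` with columns `strategy`, `method`, `members`,
#'   `true_ace`, `population_value`, `population_bias`.
#' @export
estimand_report <- function(model, strategies) {
  truth <- true_ace_log_or(model)
  rows <- lapply(strategies, function(st) {
    val <- switch(st$method,
      adjusted_logistic = population_adjusted_coefficient(model, st$members),
      ipw_msm = population_ipw_estimand(model, st$members),
      stop("unknown method: ", st$method, call. = FALSE))
    data.frame(strategy = st$label, method = st$method,
               members = paste(st$members, collapse = ","),
               true_ace = truth, population_value = val,
               population_bias = val - truth,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
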