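#' Exact joint probability table of a scenario model
#'
#' Enumerates all `2^k` binary configurations of the `k` nodes and assigns
#' each the product of its nodes' conditional probabilities (the Bayesian
#' network factorization).  Exact up to floating point; the probabilities
#' sum to 1 within 1e-12.
#'
#' @param model A [scenario_model()].
#' @return A `data.frame` with one 0/1 column per node and a `prob` column.
#'
#' @examples
#' m <- build_scenario("fig1a")
#' jt <- joint_table(m)
#' sum(jt$prob)
#' @export
joint_table <- function(model) {
  stopifnot(inherits(model, "scenario_model"))
  nodes <- model$dag$nodes
  if (length(nodes) > 20L)
    stop("joint enumeration supports at most 20 nodes", call. = FALSE)
  if ("prob" %in% nodes)
    stop("node label \"prob\" clashes with the probability column",
         call. = FALSE)
  cfg <- expand.grid(rep(list(0:1), length(nodes)), KEEP.OUT.ATTRS = FALSE)
  names(cfg) <- nodes
  cfg$prob <- config_probability(model, cfg)
  cfg
}

# Probability of each configuration row, optionally treating `fixed` nodes
# as intervened on (their conditional term dropped).  Vectorized over rows.
config_probability <- function(model, cfg, fixed = character()) {
  prob <- rep(1, nrow(cfg))
  for (v in model$dag$nodes) {
    if (v %in% fixed) next
    pars <- model$dag$parents[[v]]
    p <- if (!length(pars)) {
      model$root_prevalence[[v]]
    } else {
      eta <- rep(model$intercept[[v]], nrow(cfg))
      for (pa in pars)
        eta <- eta + model$edge_effect[[paste0(pa, "->", v)]] * cfg[[pa]]
      stats::plogis(eta)
    }
    prob <- prob * ifelse(cfg[[v]] == 1L, p, 1 - p)
  }
  prob
}

#' Interventional outcome probability under do(X = x)
#'
#' Truncated-product (g-)formula: the exposure's own conditional is dropped,
#' the exposure column is fixed at `x`, and all other nodes are marginalized
#' from the resulting joint.
#'
#' @param model A [scenario_model()].
#' @param x 0 or 1, the value the exposure is set to.
#' @return `P(Y = 1 | do(X = x))`.
#' @export
interventional_outcome_probability <- function(model, x) {
  stopifnot(x %in% c(0, 1))
  dag <- model$dag
  others <- setdiff(dag$nodes, dag$exposure)
  cfg <- expand.grid(rep(list(0:1), length(others)), KEEP.OUT.ATTRS = FALSE)
  names(cfg) <- others
  cfg[[dag$exposure]] <- x
  w <- config_probability(model, cfg, fixed = dag$exposure)
  sum(w[cfg[[dag$outcome]] == 1L])
}

#' True average causal effect on the log odds-ratio scale
#'
#' `logit P(Y=1|do(X=1)) - logit P(Y=1|do(X=0))`, computed exactly via the
#' truncated-product formula.  This is the truth against which all
#' estimator biases are measured.
#'
#' @param model A [scenario_model()].
#' @return A single real number (log odds ratio).
#'
#' @examples
#' m <- build_scenario("fig1a", overrides = list(c2 = 0))
#' true_ace_log_or(m)  # equals c3 = log 2 exactly
#' @export
true_ace_log_or <- function(model) {
  p1 <- interventional_outcome_probability(model, 1)
  p0 <- interventional_outcome_probability(model, 0)
  eps <- 1e-12
  if (p1 < eps || p1 > 1 - eps || p0 < eps || p0 > 1 - eps)
    stop("degenerate interventional distribution: P(Y=1|do(x)) = ",
         signif(p1, 4), " / ", signif(p0, 4), call. = FALSE)
  stats::qlogis(p1) - stats::qlogis(p0)
}
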