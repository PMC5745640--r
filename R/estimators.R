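#' Covariate-adjusted logistic regression estimate of the exposure effect
#'
#' Maximum-likelihood logistic regression of the outcome on the exposure
#' plus main effects of the adjustment set; returns the exposure
#' coefficient as the causal-effect estimate with its model-based standard
#' error (inverse observed information).  Complete or quasi-complete
#' separation is reported through `converged = FALSE` with a reason rather
#' than a spurious estimate; a rank-deficient design (constant column) is
#' an error.
#'
#' @param data Sample table with one 0/1 column per node.
#' @param s Adjustment set (character vector of column names).
#' @param exposure,outcome Column names of exposure and outcome.
#' @param label Optional strategy label carried into the record.
#' @return An `estimate_record`: list with `label`, `method`, `estimate`,
#'   `model_se`, `converged`, `reason`, `n_used`.
#'
#' @examples
#' d <- data.frame(X = rep(c(1, 1, 0, 0), c(30, 20, 20, 30)),
#'                 Y = rep(c(1, 0, 1, 0), c(30, 20, 20, 30)))
#' fit_adjusted_logistic(d, character())$estimate  # log(30*30/(20*20))
#' @export
fit_adjusted_logistic <- function(data, s, exposure = "X", outcome = "Y",
                                  label = NULL) {
  s <- sort(unique(as.character(s)))
  check_columns(data, c(exposure, outcome, s))
  f <- stats::reformulate(c(exposure, s), response = outcome)
  fit <- fit_logistic_guarded(f, data, weights = NULL)
  if (anyNA(stats::coef(fit$fit)))
    stop("rank-deficient design (constant or aliased column) for set {",
         paste(s, collapse = ","), "}", call. = FALSE)
  est <- unname(stats::coef(fit$fit)[exposure])
  se <- sqrt(diag(stats::vcov(fit$fit)))[[exposure]]
  new_estimate_record(label, "adjusted_logistic", est, se,
                      fit$converged, fit$reason, nrow(data))
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' `sw_i = P(X = x_i) / P(X = x_i | s-pattern_i)`, with an intercept-only
#' numerator (sample exposure proportion) and a saturated denominator: one
#' empirical exposure proportion per observed covariate pattern of `s`,
#' the nonparametric MLE of `P(X | s)` for a small set of binary
#' covariates.  Requires empirical positivity: every observed pattern must
#' contain both exposed and unexposed subjects.
#'
#' @inheritParams fit_adjusted_logistic
#' @return Numeric weight vector (one positive value per row) with
#'   attribute `"range"` (min and max weight, a positivity diagnostic).
#'
#' @examples
#' d <- data.frame(X = c(1, 1, 0, 0), Z = c(1, 0, 1, 0),
#'                 Y = c(1, 0, 1, 0))
#' compute_stabilized_weights(d, "Z")  # all exactly 1
#' @export
compute_stabilized_weights <- function(data, s, exposure = "X") {
  s <- sort(unique(as.character(s)))
  check_columns(data, c(exposure, s))
  x <- data[[exposure]]
  if (!all(x %in% c(0, 1))) stop("exposure must be 0/1", call. = FALSE)
  pat <- if (length(s)) interaction(data[s], drop = TRUE, sep = ",")
         else factor(rep("(all)", nrow(data)))
  p1_pat <- tapply(x, pat, mean)
  viol <- names(p1_pat)[p1_pat == 0 | p1_pat == 1]
  if (length(viol))
    stop("empirical positivity violation: only one exposure arm observed ",
         "for covariate pattern(s) {", paste(s, collapse = ","), "} = ",
         paste(viol, collapse = "; "), call. = FALSE)
  p1_marg <- mean(x)
  num <- ifelse(x == 1L, p1_marg, 1 - p1_marg)
  den <- ifelse(x == 1L, p1_pat[pat], 1 - p1_pat[pat])
  w <- unname(num / den)
  attr(w, "range") <- range(w)
  w
}

#' Stabilized-IPW marginal structural model estimate
#'
#' Fits the marginal structural model `logit P(Y_x = 1) = b0 + b1 x` by
#' weighted logistic regression of the outcome on the exposure alone, with
#' observation weights from [compute_stabilized_weights()].  The exposure
#' coefficient is the causal-effect estimate; its standard error is the
#' robust sandwich estimator with the weights treated as known.
#'
#' @inheritParams fit_adjusted_logistic
#' @return An `estimate_record` (see [fit_adjusted_logistic()]) with the
#'   weight range attached as `weight_range`.
#' @export
fit_ipw_msm <- function(data, s, exposure = "X", outcome = "Y",
                        label = NULL) {
  s <- sort(unique(as.character(s)))
  check_columns(data, c(exposure, outcome, s))
  w <- compute_stabilized_weights(data, s, exposure = exposure)
  f <- stats::reformulate(exposure, response = outcome)
  fit <- fit_logistic_guarded(f, data, weights = w)
  est <- unname(stats::coef(fit$fit)[exposure])
  vc <- sandwich::sandwich(fit$fit)
  se <- sqrt(vc[exposure, exposure])
  rec <- new_estimate_record(label, "ipw_msm", est, se,
                             fit$converged, fit$reason, nrow(data))
  rec$weight_range <- attr(w, "range")
  rec
}

# Quasibinomial likelihood gives the binomial ML point estimates while
# tolerating non-integer IPW weights without warnings; separation and
# non-convergence are downgraded to a flagged record.
fit_logistic_guarded <- function(formula, data, weights = NULL) {
  msgs <- character()
  env <- environment()
  fit <- withCallingHandlers(
    {
      if (is.null(weights)) {
        stats::glm(formula, family = stats::binomial(), data = data)
      } else {
        data$.sw <- weights
        stats::glm(formula, family = stats::quasibinomial(), data = data,
                   weights = .sw)
      }
    },
    warning = function(wn) {
      assign("msgs", c(msgs, conditionMessage(wn)), envir = env)
      invokeRestart("muffleWarning")
    })
  # glm may "converge" silently under separation with exploding
  # coefficients; flag via its warning or via boundary fitted probabilities
  eps <- 1e-8
  separated <- any(grepl("fitted probabilities numerically 0 or 1", msgs)) ||
    any(stats::fitted(fit) < eps | stats::fitted(fit) > 1 - eps)
  no_conv <- any(grepl("did not converge", msgs)) || !fit$converged
  converged <- !(separated || no_conv)
  reason <- if (separated) "separation"
            else if (no_conv) "no convergence" else NA_character_
  list(fit = fit, converged = converged, reason = reason)
}

new_estimate_record <- function(label, method, estimate, model_se,
                                converged, reason, n_used) {
  structure(list(label = label, method = method,
                 estimate = estimate, model_se = model_se,
                 converged = converged, reason = reason, n_used = n_used),
            class = "estimate_record")
}

#' @export
print.estimate_record <- function(x, ...) {
  cat("<estimate_record>", if (!is.null(x$label)) x$label else "",
      sprintf("[%s]", x$method), "\n")
  cat(sprintf("  estimate %.5f  (model SE %.5f)  converged: %s%s  n = %d\n",
              x$estimate, x$model_se, x$converged,
              if (!is.na(x$reason)) paste0(" (", x$reason, ")") else "",
              x$n_used))
  invisible(x)
}

check_columns <- function(data, cols) {
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(cols)
}
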