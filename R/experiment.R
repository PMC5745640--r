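#' Adjustment strategies
#'
#' A strategy pairs an adjustment set with an estimation method.
#' `make_strategies()` crosses a named list of sets with one or more
#' methods, labelling each combination `<set>_<logistic|ipw>`.
#'
#' @param label Strategy label.
#' @param members Adjustment set (character vector).
#' @param method `"adjusted_logistic"` or `"ipw_msm"`.
#' @return `strategy()` returns a single strategy; `make_strategies()` a
#'   list of them.
#' @export
strategy <- function(label, members, method) {
  method <- match.arg(method, c("adjusted_logistic", "ipw_msm"))
  structure(list(label = label, members = sort(unique(as.character(members))),
                 method = method), class = "adjustment_strategy")
}

#' @rdname strategy
#' @param sets Named list of adjustment sets.
#' @param methods Character vector of methods to cross with `sets`.
#' @export
make_strategies <- function(sets,
                            methods = c("adjusted_logistic", "ipw_msm")) {
  out <- list()
  for (m in methods) {
    tag <- if (m == "adjusted_logistic") "logistic" else "ipw"
    for (nm in names(sets))
      out[[paste(nm, tag, sep = "_")]] <-
        strategy(paste(nm, tag, sep = "_"), sets[[nm]], m)
  }
  out
}

#' Run paired Monte-Carlo replicates of all strategies on one model
#'
#' For each replicate a single sample is drawn (seed derived from the
#' master seed by [replicate_seed()]) and every strategy is applied to that
#' same table, so method comparisons are paired.  Replicates where a
#' strategy fails (separation, positivity) are excluded from that
#' strategy's aggregates and counted.
#'
#' @param model A [scenario_model()].
#' @param strategies List of strategies ([strategy()] / [make_strategies()]).
#' @param n Subjects per replicate.
#' @param reps Number of replicates.
#' @param seed Master seed.
#' @return A `replicate_result`: list with `summary` (one row per strategy:
#'   `true_ace`, `mean_estimate`, `mean_bias`, `empirical_se`,
#'   `mean_model_se`, `mc_se`, `reps_converged`, `reps_attempted`) and the
#'   per-replicate `estimates`, `model_ses` and `converged` matrices.
#'
#' @examples
#' m <- build_scenario("fig1a")
#' st <- make_strategies(scenario_strategies(m, "A"), "ipw_msm")
#' rr <- run_replicates(m, st, n = 500, reps = 20, seed = 7)
#' rr$summary[, c("strategy", "mean_bias", "empirical_se")]
#' @export
run_replicates <- function(model, strategies, n, reps, seed) {
  stopifnot(inherits(model, "scenario_model"), reps >= 1)
  truth <- true_ace_log_or(model)
  S <- length(strategies)
  labels <- vapply(strategies, `[[`, "", "label")
  est <- mse <- matrix(NA_real_, nrow = reps, ncol = S,
                       dimnames = list(NULL, labels))
  conv <- matrix(FALSE, nrow = reps, ncol = S, dimnames = list(NULL, labels))
  for (r in seq_len(reps)) {
    dat <- simulate_dataset(model, n, seed = replicate_seed(seed, r))
    for (j in seq_len(S)) {
      st <- strategies[[j]]
      rec <- tryCatch(
        switch(st$method,
               adjusted_logistic = fit_adjusted_logistic(
                 dat, st$members, label = st$label),
               ipw_msm = fit_ipw_msm(dat, st$members, label = st$label)),
        error = function(e) NULL)
      if (!is.null(rec) && isTRUE(rec$converged)) {
        est[r, j] <- rec$estimate
        mse[r, j] <- rec$model_se
        conv[r, j] <- TRUE
      }
    }
  }
  if (!any(conv))
    stop("every strategy failed on every replicate", call. = FALSE)
  summ <- do.call(rbind, lapply(seq_len(S), function(j) {
    ok <- conv[, j]
    k <- sum(ok)
    e <- est[ok, j]
    data.frame(
      strategy = labels[j], method = strategies[[j]]$method,
      members = paste(strategies[[j]]$members, collapse = ","),
      true_ace = truth,
      mean_estimate = if (k) mean(e) else NA_real_,
      mean_bias = if (k) mean(e) - truth else NA_real_,
      empirical_se = if (k > 1) stats::sd(e) else NA_real_,
      mean_model_se = if (k) mean(mse[ok, j]) else NA_real_,
      mc_se = if (k > 1) stats::sd(e) / sqrt(k) else NA_real_,
      reps_converged = k, reps_attempted = as.integer(reps),
      stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, estimates = est, model_ses = mse,
                 converged = conv, true_ace = truth, n = n, seed = seed),
            class = "replicate_result")
}

#' Specify a parameter sweep
#'
#' @param scenario Scenario name (see [build_scenario()]).
#' @param vary Edge key to sweep, e.g. `"T->Y"` (scenario-1 aliases
#'   `c0`..`c3` are accepted for `fig1a`).
#' @param grid Strictly increasing numeric vector of effect values.
#' @param strategies List of strategies applied at every grid point.
#' @param overrides Fixed parameter overrides applied at every grid point.
#' @param n Subjects per replicate (>= 10).
#' @param reps Replicates per grid point.
#' @param seed Master seed; each grid point derives its own sub-seed.
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(scenario, vary, grid, strategies, overrides = list(),
                       n = 1000, reps = 200, seed = 1L) {
  if (!length(grid) || is.unsorted(grid, strictly = TRUE))
    stop("`grid` must be non-empty and strictly increasing", call. = FALSE)
  if (n < 10) stop("`n` must be at least 10", call. = FALSE)
  if (reps < 1) stop("`reps` must be at least 1", call. = FALSE)
  build_scenario(scenario, modifyList(overrides,
                                      stats::setNames(list(grid[1L]), vary)))
  structure(list(scenario = scenario, vary = vary, grid = grid,
                 strategies = strategies, overrides = overrides,
                 n = n, reps = reps, seed = seed),
            class = "sweep_spec")
}

#' Run a parameter sweep
#'
#' For each grid value the scenario is rebuilt with the swept edge effect
#' set to that value, the exact true causal effect is recomputed (it changes
#' when outcome-side effects are swept), and [run_replicates()] is executed
#' with a grid-point-specific seed.  Grid points whose model is degenerate
#' (interventional probability at 0 or 1) are flagged and skipped with a
#' warning rather than aborting the sweep.
#'
#' @param spec A [sweep_spec()].
#' @return A `data.frame` (class `sweep_result`) with one row per
#'   (grid value x strategy): `scenario`, `swept_edge`, `value`, `strategy`,
#'   `method`, `members`, `status`, `true_ace`, `mean_estimate`,
#'   `mean_bias`, `empirical_se`, `mean_model_se`, `mc_se`,
#'   `reps_converged`, `reps_attempted`.
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- list()
  for (gi in seq_along(spec$grid)) {
    val <- spec$grid[gi]
    ov <- modifyList(spec$overrides, stats::setNames(list(val), spec$vary))
    model <- build_scenario(spec$scenario, ov)
    ok <- tryCatch({ true_ace_log_or(model); TRUE },
                   error = function(e) FALSE)
    if (!ok) {
      warning("grid point ", val, " is degenerate; skipped", call. = FALSE)
      empty <- data.frame(
        strategy = vapply(spec$strategies, `[[`, "", "label"),
        method = vapply(spec$strategies, `[[`, "", "method"),
        members = vapply(spec$strategies, function(s)
          paste(s$members, collapse = ","), ""),
        true_ace = NA_real_, mean_estimate = NA_real_, mean_bias = NA_real_,
        empirical_se = NA_real_, mean_model_se = NA_real_, mc_se = NA_real_,
        reps_converged = 0L, reps_attempted = 0L, stringsAsFactors = FALSE)
      rows[[gi]] <- cbind(scenario = spec$scenario, swept_edge = spec$vary,
                          value = val, status = "degenerate", empty)
      next
    }
    rr <- run_replicates(model, spec$strategies, spec$n, spec$reps,
                         seed = replicate_seed(spec$seed, gi))
    rows[[gi]] <- cbind(scenario = spec$scenario, swept_edge = spec$vary,
                        value = val, status = "ok", rr$summary)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  attr(out, "spec") <- spec
  out
}

#' Write a sweep result to CSV
#'
#' Deterministic: rerunning the identical [sweep_spec()] and writing again
#' produces a byte-identical file.
#'
#' @param result A `sweep_result` from [run_sweep()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  stopifnot(inherits(result, "data.frame"))
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}

#' Plot bias and precision along a sweep
#'
#' Companion figure to [run_sweep()]: Monte-Carlo mean bias and empirical
#' standard error against the swept effect value, one panel per method.
#'
#' @param result A `sweep_result`.
#' @return A named list of two ggplot objects (`bias`, `se`).
#' @export
plot_sweep <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_sweep() requires the ggplot2 package", call. = FALSE)
  d <- as.data.frame(result)
  d <- d[d$status == "ok", , drop = FALSE]
  base <- function(yvar, ylab) {
    d$.y <- d[[yvar]]
    ggplot2::ggplot(d, ggplot2::aes(x = value, y = .y, colour = strategy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = paste("effect of", d$swept_edge[1L], "(log OR)"),
                  y = ylab) +
    ggplot2::theme_bw()
  }
  list(bias = base("mean_bias", "Monte-Carlo mean bias") +
         ggplot2::geom_hline(yintercept = 0, linetype = 2),
       se = base("empirical_se", "empirical SE across replicates"))
}
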