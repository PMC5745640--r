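#' Write and read a scenario configuration as JSON
#'
#' The configuration records nodes, edges with numeric effects, intercepts,
#' root prevalences, exposure/outcome and strategy groups, and round-trips
#' losslessly through [read_scenario_json()].
#'
#' @param model A [scenario_model()].
#' @param path File path.
#' @return `write_scenario_json()` returns `path` invisibly;
#'   `read_scenario_json()` returns a [scenario_model()].
#' @export
write_scenario_json <- function(model, path) {
  stopifnot(inherits(model, "scenario_model"))
  em <- model$dag$edges
  cfg <- list(
    nodes = model$dag$nodes,
    exposure = model$dag$exposure,
    outcome = model$dag$outcome,
    edges = lapply(seq_len(nrow(em)), function(i)
      list(from = em[i, 1L], to = em[i, 2L],
           effect = unname(model$edge_effect[[edge_keys(em)[i]]]))),
    root_prevalence = as.list(model$root_prevalence),
    intercept = as.list(model$intercept),
    strategy_groups = model$strategy_groups)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario_json
#' @export
read_scenario_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  em <- do.call(rbind, lapply(cfg$edges, function(e)
    c(e$from, e$to)))
  dag <- causal_dag(unlist(cfg$nodes), em, cfg$exposure, cfg$outcome)
  eff <- stats::setNames(
    vapply(cfg$edges, function(e) as.numeric(e$effect), 0),
    vapply(cfg$edges, function(e) paste0(e$from, "->", e$to), ""))
  groups <- lapply(cfg$strategy_groups, function(g)
    lapply(g, function(mem) unlist(mem)))
  scenario_model(dag,
                 root_prevalence = unlist(cfg$root_prevalence),
                 intercept = unlist(cfg$intercept),
                 edge_effect = eff,
                 strategy_groups = groups)
}

#' Sample-table CSV round trip
#'
#' @param data A sample table as returned by [simulate_dataset()].
#' @param path File path.
#' @return `write_sample_csv()` returns `path` invisibly;
#'   `read_sample_csv()` returns a `data.frame` of 0/1 integer columns.
#' @export
write_sample_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_csv
#' @export
read_sample_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  d[] <- lapply(d, as.integer)
  d
}
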