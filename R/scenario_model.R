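#' Binary logistic structural-equation model over a causal DAG
#'
#' Every node is Bernoulli.  Parentless (root) nodes have a fixed prevalence
#' `P(V = 1) = pi_V`; each child node has success probability
#' `expit(alpha_V + sum_e c_e * parent_e)`, i.e. the parent effects are
#' additive on the log-odds scale.  Edge effects are keyed by the edge
#' string `"parent->child"` and are log odds ratios.
#'
#' @param dag A [causal_dag()].
#' @param root_prevalence Named numeric vector/list, one probability in
#'   (0,1) per parentless node.
#' @param intercept Named numeric vector/list, one log-odds intercept per
#'   node with parents.
#' @param edge_effect Named numeric vector/list, one log-odds-ratio per edge
#'   (names `"parent->child"`).
#' @param strategy_groups Optional named list of adjustment-set groups, each
#'   a named list of character vectors (used by the scenario registry).
#' @return An object of class `scenario_model`.
#' @seealso [build_scenario()] for the four benchmark diagrams.
#' @export
scenario_model <- function(dag, root_prevalence, intercept, edge_effect,
                           strategy_groups = list()) {
  stopifnot(inherits(dag, "causal_dag"))
  roots <- dag$nodes[vapply(dag$parents[dag$nodes], length, 1L) == 0L]
  kids <- setdiff(dag$nodes, roots)
  root_prevalence <- unlist(root_prevalence)
  intercept <- unlist(intercept)
  edge_effect <- unlist(edge_effect)
  if (!setequal(names(root_prevalence), roots))
    stop("root_prevalence must name exactly the parentless nodes: ",
         paste(roots, collapse = ", "), call. = FALSE)
  if (!setequal(names(intercept), kids))
    stop("intercept must name exactly the nodes with parents: ",
         paste(kids, collapse = ", "), call. = FALSE)
  ekeys <- edge_keys(dag$edges)
  if (!setequal(names(edge_effect), ekeys))
    stop("edge_effect must name exactly the edges: ",
         paste(ekeys, collapse = ", "), call. = FALSE)
  if (any(root_prevalence <= 0 | root_prevalence >= 1))
    stop("root prevalences must lie strictly inside (0, 1)", call. = FALSE)
  if (!all(is.finite(intercept)) || !all(is.finite(edge_effect)))
    stop("intercepts and edge effects must be finite", call. = FALSE)
  structure(
    list(dag = dag,
         root_prevalence = root_prevalence[sort(names(root_prevalence))],
         intercept = intercept[sort(names(intercept))],
         edge_effect = edge_effect[ekeys],
         strategy_groups = strategy_groups),
    class = "scenario_model")
}

edge_keys <- function(em) {
  if (nrow(em)) paste0(em[, 1L], "->", em[, 2L]) else character()
}

#' @export
print.scenario_model <- function(x, ...) {
  cat("<scenario_model> over", length(x$dag$nodes), "binary nodes (",
      x$dag$exposure, "->", x$dag$outcome, ")\n")
  cat("  roots:     ", paste(sprintf("P(%s=1)=%.3g", names(x$root_prevalence),
                                     x$root_prevalence), collapse = ", "),
      "\n")
  cat("  intercepts:", paste(sprintf("%s=%.3g", names(x$intercept),
                                     x$intercept), collapse = ", "), "\n")
  cat("  effects:   ", paste(sprintf("%s=%.3g", names(x$edge_effect),
                                     x$edge_effect), collapse = ", "), "\n")
  if (length(x$strategy_groups))
    cat("  strategy groups:", paste(names(x$strategy_groups),
                                    collapse = ", "), "\n")
  invisible(x)
}

# Registry of the four benchmark diagrams.  Default parameters (the
# generator's study conditions): every root prevalence 0.5, every intercept
# -1, every edge effect log 2, giving node prevalences in roughly 0.2-0.7
# and moderate odds ratios of 2.
scenario_registry <- function() {
  conf <- function(nodes, edges, groups)
    list(nodes = nodes, edges = edges, groups = groups)
  list(
    fig1a = conf(c("Z", "T", "X", "Y"),
                 c("Z->T", "Z->X", "T->Y", "X->Y"),
                 list(A = list(A1 = "Z", A2 = "T", A3 = c("Z", "T")))),
    fig1b = conf(c("Z", "T", "W", "X", "Y"),
                 c("Z->T", "Z->X", "T->Y", "W->X", "W->Y", "X->Y"),
                 list(A = list(A1 = c("Z", "W"), A2 = c("T", "W"),
                               A3 = c("Z", "T", "W")),
                      B = list(B1 = "Z", B2 = c("Z", "T")))),
    fig1c = conf(c("Z", "T", "W", "V", "X", "Y"),
                 c("Z->T", "Z->X", "T->Y", "W->X", "W->V", "V->Y", "X->Y"),
                 list(A = list(A1 = "Z", A2 = c("Z", "T")),
                      B = list(B1 = "W", B2 = c("W", "V")),
                      C = list(C1 = c("Z", "W"), C2 = c("T", "V"),
                               C3 = c("Z", "W", "T", "V")))),
    fig1d = conf(c("Z", "T", "W", "X", "Y"),
                 c("Z->X", "Z->W", "T->W", "T->Y", "W->X", "W->Y", "X->Y"),
                 list(A = list(A1 = c("Z", "W"), A2 = c("T", "W"),
                               A3 = c("Z", "T", "W")))))
}

# c0..c3 aliases are defined only for fig1a, where the benchmark fixes them.
scenario1_aliases <- c(c0 = "Z->T", c1 = "Z->X", c2 = "T->Y", c3 = "X->Y")

#' Build one of the four benchmark scenarios
#'
#' The registry holds the four diagrams used throughout: `fig1a` with the
#' single confounding path X<-Z->T->Y; `fig1b` adding the common cause W of
#' X and Y; `fig1c` with the mediated confounder chain W->V->Y; and `fig1d`
#' where W is a collider of Z and T on the back-door side.  Each scenario
#' carries its named adjustment-set groups (e.g. `A1`, `A2`, `A3`).
#'
#' Default parameters: root prevalences 0.5, intercepts -1, edge effects
#' log 2.  `overrides` may rename any of them: edge keys (`"T->Y"`), the
#' scenario-1 aliases `c0`..`c3` (for `fig1a` only), `pi_<node>` for root
#' prevalences, and `alpha_<node>` for intercepts.
#'
#' @param name One of `"fig1a"`, `"fig1b"`, `"fig1c"`, `"fig1d"`.
#' @param overrides Named list of parameter overrides (see Details).
#' @return A [scenario_model()] with attached strategy groups.
#'
#' @examples
#' m <- build_scenario("fig1a", overrides = list(c2 = log(3), c3 = log(3)))
#' m$edge_effect[["T->Y"]]
#' @export
build_scenario <- function(name, overrides = list()) {
  reg <- scenario_registry()
  if (!is.character(name) || length(name) != 1L || !name %in% names(reg))
    stop("unknown scenario: ", paste(name, collapse = ", "),
         "; expected one of ", paste(names(reg), collapse = ", "),
         call. = FALSE)
  cf <- reg[[name]]
  dag <- causal_dag(cf$nodes, cf$edges, exposure = "X", outcome = "Y")
  roots <- dag$nodes[vapply(dag$parents[dag$nodes], length, 1L) == 0L]
  kids <- setdiff(dag$nodes, roots)
  pi_ <- stats::setNames(rep(0.5, length(roots)), roots)
  alpha <- stats::setNames(rep(-1, length(kids)), kids)
  eff <- stats::setNames(rep(log(2), length(cf$edges)), cf$edges)

  for (key in names(overrides)) {
    val <- overrides[[key]]
    if (!is.numeric(val) || length(val) != 1L)
      stop("override `", key, "` must be a single number", call. = FALSE)
    if (name == "fig1a" && key %in% names(scenario1_aliases)) {
      eff[[scenario1_aliases[[key]]]] <- val
    } else if (key %in% names(eff)) {
      eff[[key]] <- val
    } else if (grepl("^pi_", key) && sub("^pi_", "", key) %in% roots) {
      pi_[[sub("^pi_", "", key)]] <- val
    } else if (grepl("^alpha_", key) && sub("^alpha_", "", key) %in% kids) {
      alpha[[sub("^alpha_", "", key)]] <- val
    } else {
      stop("override of nonexistent parameter: ", key, call. = FALSE)
    }
  }
  m <- scenario_model(dag, pi_, alpha, eff, strategy_groups = cf$groups)
  attr(m, "scenario") <- name
  m
}

#' Named adjustment-set groups of a scenario
#'
#' @param model A [scenario_model()] (typically from [build_scenario()]).
#' @param group Optional group name (`"A"`, `"B"`, `"C"`); if `NULL`, all
#'   groups are returned.
#' @return A named list of character vectors.
#' @export
scenario_strategies <- function(model, group = NULL) {
  gs <- model$strategy_groups
  if (is.null(group)) return(gs)
  if (!group %in% names(gs))
    stop("scenario has no strategy group ", group, call. = FALSE)
  gs[[group]]
}

#' Conditional success probability of one node
#'
#' For a root node, returns its prevalence (and requires `parent_values` to
#' be empty); otherwise returns
#' `expit(intercept + sum(edge_effect * parent_value))`.
#'
#' @param model A [scenario_model()].
#' @param node Node label.
#' @param parent_values Named vector/list of 0/1 values covering exactly the
#'   node's parents.
#' @return Probability in (0, 1).
#'
#' @examples
#' m <- build_scenario("fig1a")
#' conditional_probability(m, "T", c(Z = 0))  # expit(-1)
#' @export
conditional_probability <- function(model, node, parent_values = NULL) {
  check_nodes(model$dag, node, "node")
  pars <- model$dag$parents[[node]]
  pv <- unlist(parent_values)
  if (!setequal(names(pv), pars) || length(pv) != length(pars))
    stop("parent_values must cover exactly the parents of ", node,
         if (length(pars)) paste0(" (", paste(pars, collapse = ", "), ")")
         else " (none)", call. = FALSE)
  if (!length(pars)) return(unname(model$root_prevalence[[node]]))
  if (!all(pv %in% c(0, 1)))
    stop("parent values must be 0 or 1", call. = FALSE)
  eta <- model$intercept[[node]] +
    sum(model$edge_effect[paste0(pars, "->", node)] * pv[pars])
  stats::plogis(eta)
}
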