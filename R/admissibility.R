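#' Back-door (G-) admissibility of an adjustment set
#'
#' A set `s` is G-admissible for the exposure/outcome pair of `dag` when (1)
#' no element of `s` is a descendant of the exposure and (2) `s` blocks
#' every path between exposure and outcome that contains an arrow into the
#' exposure.  Blocking uses full d-separation semantics (collider rule), so
#' conditioning on a collider can open a back-door path; condition (2) is
#' evaluated as d-separation of exposure and outcome in the graph with the
#' exposure's outgoing edges removed.
#'
#' @param dag A [causal_dag()].
#' @param s Character vector of node labels; must exclude the exposure and
#'   outcome.
#' @return `TRUE` iff `s` satisfies the back-door criterion.
#'
#' @examples
#' g <- causal_dag(c("Z", "T", "X", "Y"),
#'                 c("Z->T", "Z->X", "T->Y", "X->Y"), "X", "Y")
#' is_g_admissible(g, "T")          # TRUE
#' is_g_admissible(g, character()) # FALSE: X<-Z->T->Y is open
#' @export
is_g_admissible <- function(dag, s) {
  s <- unique(as.character(s))
  check_nodes(dag, s, "s")
  if (dag$exposure %in% s || dag$outcome %in% s)
    stop("adjustment set must not contain the exposure or outcome",
         call. = FALSE)
  if (any(s %in% dag_descendants(dag, dag$exposure))) return(FALSE)
  out_edges <- dag$edges[dag$edges[, 1L] == dag$exposure, , drop = FALSE]
  g_bd <- if (nrow(out_edges)) drop_edges(dag, out_edges) else dag
  d_separated(g_bd, dag$exposure, dag$outcome, s)
}

#' Markov boundary of a set relative to the exposure
#'
#' Finds the minimal subset `S_m` of `s` such that the exposure is
#' d-separated from the rest of `s` given `S_m`.  The search is exhaustive
#' over subsets in increasing cardinality; within a cardinality, candidates
#' are visited in lexicographic order of their sorted member lists and the
#' first qualifying subset is returned.  The attribute `"multiple"` flags
#' whether more than one subset of the minimal size qualified (for DAG
#' d-separation the boundary is in fact unique, so the flag is a guard).
#'
#' @param dag A [causal_dag()].
#' @param s Character vector of node labels; must exclude the exposure.
#' @return Sorted character vector `S_m` with logical attribute `"multiple"`.
#'
#' @examples
#' g <- causal_dag(c("Z", "T", "W", "X", "Y"),
#'                 c("Z->T", "Z->X", "T->Y", "W->X", "W->Y", "X->Y"),
#'                 "X", "Y")
#' markov_boundary(g, c("Z", "T"))  # "Z"
#' @export
markov_boundary <- function(dag, s) {
  s <- sort(unique(as.character(s)))
  check_nodes(dag, s, "s")
  if (dag$exposure %in% s)
    stop("`s` must not contain the exposure", call. = FALSE)
  for (k in 0:length(s)) {
    cands <- if (k == 0L) list(character()) else
      utils::combn(s, k, simplify = FALSE)
    hits <- Filter(function(m)
      d_separated(dag, dag$exposure, setdiff(s, m), m), cands)
    if (length(hits)) {
      res <- hits[[1L]]
      attr(res, "multiple") <- length(hits) > 1L
      return(res)
    }
  }
  # unreachable: m = s always qualifies (the complement is empty)
  stop("internal error: no qualifying subset found")
}

#' Confounding-equivalence verdict for two adjustment sets
#'
#' Two sets `t` and `z` are c-equivalent (adjustment for either yields the
#' same asymptotic bias) iff at least one of two conditions holds: their
#' Markov boundaries relative to the exposure coincide, or both sets are
#' G-admissible.
#'
#' @param dag A [causal_dag()].
#' @param t,z Character vectors of node labels excluding exposure and
#'   outcome.
#' @return A `c_equivalence_verdict`: list with `equivalent`,
#'   `boundary_condition_holds`, `admissibility_condition_holds`,
#'   `boundary_of_first`, `boundary_of_second`.
#'
#' @examples
#' g <- causal_dag(c("Z", "T", "X", "Y"),
#'                 c("Z->T", "Z->X", "T->Y", "X->Y"), "X", "Y")
#' c_equivalent(g, "Z", "T")$equivalent  # TRUE (both admissible)
#' @export
c_equivalent <- function(dag, t, z) {
  bt <- markov_boundary(dag, t)
  bz <- markov_boundary(dag, z)
  boundary_ok <- setequal(bt, bz)
  admiss_ok <- is_g_admissible(dag, t) && is_g_admissible(dag, z)
  structure(
    list(equivalent = boundary_ok || admiss_ok,
         boundary_condition_holds = boundary_ok,
         admissibility_condition_holds = admiss_ok,
         boundary_of_first = as.character(bt),
         boundary_of_second = as.character(bz)),
    class = "c_equivalence_verdict")
}

#' @export
print.c_equivalence_verdict <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste0("{", paste(v, collapse = ","), "}")
                     else "{}"
  cat("<c_equivalence_verdict> equivalent:", x$equivalent, "\n")
  cat("  identical Markov boundaries:", x$boundary_condition_holds,
      sprintf(" (%s vs %s)\n", fmt(x$boundary_of_first),
              fmt(x$boundary_of_second)))
  cat("  both sets G-admissible:     ", x$admissibility_condition_holds, "\n")
  invisible(x)
}
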