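#' Construct a causal directed acyclic graph
#'
#' A `causal_dag` stores a labelled acyclic digraph together with a single
#' designated exposure and outcome node, the setting in which back-door
#' adjustment and confounding equivalence are defined.
#'
#' @param nodes Character vector of unique node labels (case-sensitive).
#' @param edges Edges as either a character vector of `"parent->child"`
#'   strings, a two-column matrix, or a list of length-2 vectors.
#' @param exposure,outcome Labels of the exposure and outcome nodes.
#'
#' @return An object of class `causal_dag` with components `nodes`, `edges`
#'   (two-column character matrix), `exposure`, `outcome`, and precomputed
#'   parent/child adjacency lists.
#'
#' @examples
#' g <- causal_dag(c("Z", "T", "X", "Y"),
#'                 c("Z->T", "Z->X", "T->Y", "X->Y"),
#'                 exposure = "X", outcome = "Y")
#' dag_parents(g, "Y")
#' @export
causal_dag <- function(nodes, edges, exposure, outcome) {
  if (!is.character(nodes) || length(nodes) < 1L || anyNA(nodes))
    stop("`nodes` must be a non-empty character vector", call. = FALSE)
  if (anyDuplicated(nodes))
    stop("duplicate node labels: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "),
         call. = FALSE)
  em <- parse_edges(edges)
  bad <- setdiff(c(em), nodes)
  if (length(bad))
    stop("edge endpoints not among nodes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (nrow(em) && any(em[, 1L] == em[, 2L]))
    stop("self-loops are not allowed", call. = FALSE)
  if (anyDuplicated(paste(em[, 1L], em[, 2L])))
    stop("duplicate edges are not allowed", call. = FALSE)
  for (lab in c(exposure, outcome))
    if (!is.character(lab) || length(lab) != 1L || !lab %in% nodes)
      stop("exposure and outcome must each be a single node label",
           call. = FALSE)
  if (identical(exposure, outcome))
    stop("exposure and outcome must be distinct nodes", call. = FALSE)

  parents  <- lapply(stats::setNames(nodes, nodes),
                     function(v) em[em[, 2L] == v, 1L])
  children <- lapply(stats::setNames(nodes, nodes),
                     function(v) em[em[, 1L] == v, 2L])
  g <- structure(
    list(nodes = nodes, edges = em, exposure = exposure, outcome = outcome,
         parents = parents, children = children),
    class = "causal_dag")
  g$topo_order <- topological_order(g)   # errors if cyclic
  g
}

# Accept "A->B" strings, a 2-column matrix/data.frame, or a list of pairs.
parse_edges <- function(edges) {
  if (is.null(edges) || (is.character(edges) && !length(edges)))
    return(matrix(character(), ncol = 2L,
                  dimnames = list(NULL, c("from", "to"))))
  if (is.character(edges) && !is.matrix(edges)) {
    parts <- strsplit(gsub("\\s+", "", edges), "->", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("edge strings must have the form \"parent->child\"", call. = FALSE)
    em <- do.call(rbind, parts)
  } else if (is.list(edges) && !is.data.frame(edges)) {
    if (any(lengths(edges) != 2L))
      stop("each edge must be a (parent, child) pair", call. = FALSE)
    em <- do.call(rbind, lapply(edges, as.character))
  } else {
    em <- as.matrix(edges)
    if (ncol(em) != 2L) stop("edge matrix must have two columns", call. = FALSE)
    storage.mode(em) <- "character"
  }
  dimnames(em) <- list(NULL, c("from", "to"))
  em
}

# Kahn's algorithm with lexicographic tie-break; errors on a cycle.
topological_order <- function(dag) {
  indeg <- vapply(dag$parents, length, integer(1L))
  out <- character(0L)
  avail <- sort(names(indeg)[indeg == 0L])
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    out <- c(out, v)
    for (ch in dag$children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) avail <- sort(c(avail, ch))
    }
  }
  if (length(out) != length(dag$nodes))
    stop("graph contains a cycle", call. = FALSE)
  out
}

check_nodes <- function(dag, labels, arg = "set") {
  bad <- setdiff(labels, dag$nodes)
  if (length(bad))
    stop("unknown node label(s) in ", arg, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(labels)
}

#' Graph neighbourhood queries
#'
#' `dag_parents()` and `dag_children()` return direct neighbours;
#' `dag_ancestors()` and `dag_descendants()` return all strict
#' ancestors/descendants of a set of nodes (the set itself excluded unless
#' reachable through a directed cycle-free path, which cannot occur in a DAG).
#'
#' @param dag A [causal_dag()].
#' @param nodes Character vector of node labels.
#' @return Character vector of node labels.
#' @export
dag_parents <- function(dag, nodes) {
  check_nodes(dag, nodes, "nodes")
  sort(unique(unlist(dag$parents[nodes], use.names = FALSE)))
}

#' @rdname dag_parents
#' @export
dag_children <- function(dag, nodes) {
  check_nodes(dag, nodes, "nodes")
  sort(unique(unlist(dag$children[nodes], use.names = FALSE)))
}

#' @rdname dag_parents
#' @export
dag_ancestors <- function(dag, nodes) {
  reach_directed(dag, nodes, dag$parents)
}

#' @rdname dag_parents
#' @export
dag_descendants <- function(dag, nodes) {
  reach_directed(dag, nodes, dag$children)
}

reach_directed <- function(dag, nodes, adj) {
  check_nodes(dag, nodes, "nodes")
  seen <- character(0L)
  frontier <- unique(unlist(adj[nodes], use.names = FALSE))
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
  }
  sort(seen)
}

#' Remove edges from a DAG
#'
#' Returns a copy of `dag` without the given edges; used internally to
#' evaluate the back-door criterion on the exposure's incoming side.
#'
#' @param dag A [causal_dag()].
#' @param edges Edges to drop, in any form accepted by [causal_dag()].
#' @return A [causal_dag()].
#' @keywords internal
drop_edges <- function(dag, edges) {
  rm_ <- parse_edges(edges)
  keep <- !(paste(dag$edges[, 1L], dag$edges[, 2L]) %in%
              paste(rm_[, 1L], rm_[, 2L]))
  causal_dag(dag$nodes, dag$edges[keep, , drop = FALSE],
             dag$exposure, dag$outcome)
}

#' @export
print.causal_dag <- function(x, ...) {
  cat("<causal_dag> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  cat("  exposure: ", x$exposure, "   outcome: ", x$outcome, "\n", sep = "")
  if (nrow(x$edges))
    cat("  edges: ", paste(x$edges[, 1L], x$edges[, 2L], sep = "->",
                           collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Export a DAG in DOT format
#'
#' @param dag A [causal_dag()].
#' @param file Optional path; if `NULL` the DOT source is returned as a
#'   character scalar.
#' @return The DOT source, invisibly when written to `file`.
#' @export
dag_to_dot <- function(dag, file = NULL) {
  lines <- c("digraph G {",
             paste0("  ", dag$nodes,
                    ifelse(dag$nodes %in% c(dag$exposure, dag$outcome),
                           " [shape=box];", ";")),
             if (nrow(dag$edges))
               paste0("  ", dag$edges[, 1L], " -> ", dag$edges[, 2L], ";"),
             "}")
  src <- paste(lines, collapse = "\n")
  if (is.null(file)) return(src)
  writeLines(src, file)
  invisible(src)
}
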