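#' Test d-separation of two node sets
#'
#' Determines whether every undirected path between `a` and `b` is blocked
#' by the conditioning set `s` under the usual collider semantics: a path is
#' blocked iff it contains a non-collider that is in `s`, or a collider none
#' of whose descendants (itself included) is in `s`.
#'
#' The implementation is the standard reachability ("Bayes-ball") scheme:
#' starting from each node of `a`, states `(node, direction)` are expanded
#' along active edge traversals and `a` and `b` are d-separated given `s`
#' iff no node of `b` is reached.  Linear in the number of edges per source
#' node, and symmetric in `a` and `b`.
#'
#' @param dag A [causal_dag()].
#' @param a,b Disjoint character vectors of node labels.
#' @param s Conditioning set, disjoint from `a` and `b` (default empty).
#' @return `TRUE` if `a` and `b` are d-separated given `s`.
#'
#' @examples
#' g <- causal_dag(c("Z", "T", "W", "X", "Y"),
#'                 c("Z->T", "Z->X", "T->Y", "W->X", "W->Y", "X->Y"),
#'                 exposure = "X", outcome = "Y")
#' d_separated(g, "X", "T", "Z")        # TRUE
#' d_separated(g, "X", "T", c("Z", "Y")) # FALSE: Y is a collider
#' @export
d_separated <- function(dag, a, b, s = character()) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  s <- unique(as.character(s))
  check_nodes(dag, a, "a"); check_nodes(dag, b, "b"); check_nodes(dag, s, "s")
  if (length(intersect(a, b)) || length(intersect(a, s)) ||
      length(intersect(b, s)))
    stop("a, b and s must be pairwise disjoint", call. = FALSE)
  if (!length(a) || !length(b)) return(TRUE)
  for (x in a) {
    if (any(b %in% reachable_given(dag, x, s))) return(FALSE)
  }
  TRUE
}

# Nodes d-connected to x given conditioning set z (x excluded from the
# result's interpretation; z-members are never reported as reachable).
# States are (node, direction): "up" = entered from a child (or the start),
# "down" = entered from a parent.
reachable_given <- function(dag, x, z) {
  anc_z <- union(z, dag_ancestors(dag, if (length(z)) z else character()))
  idx <- stats::setNames(seq_along(dag$nodes), dag$nodes)
  visited <- matrix(FALSE, nrow = length(dag$nodes), ncol = 2L)  # up, down
  reached <- logical(length(dag$nodes))
  queue <- list(c(x, "up"))
  while (length(queue)) {
    st <- queue[[1L]]; queue <- queue[-1L]
    v <- st[1L]; d <- if (st[2L] == "up") 1L else 2L
    i <- idx[[v]]
    if (visited[i, d]) next
    visited[i, d] <- TRUE
    in_z <- v %in% z
    if (!in_z) reached[i] <- TRUE
    if (d == 1L) {            # entered travelling upward
      if (!in_z) {
        for (p in dag$parents[[v]])  queue <- c(queue, list(c(p, "up")))
        for (ch in dag$children[[v]]) queue <- c(queue, list(c(ch, "down")))
      }
    } else {                  # entered travelling downward
      if (!in_z)
        for (ch in dag$children[[v]]) queue <- c(queue, list(c(ch, "down")))
      if (v %in% anc_z)       # collider (or its observed ancestorhood) opens
        for (p in dag$parents[[v]]) queue <- c(queue, list(c(p, "up")))
    }
  }
  setdiff(dag$nodes[reached], x)
}

#' Enumerate back-door paths from exposure to outcome
#'
#' Returns every acyclic undirected path from the exposure to the outcome
#' whose first edge points into the exposure, including paths that pass
#' through colliders (which are inactive unless conditioned on).  Paths are
#' returned in lexicographic order of their node sequences.
#'
#' @param dag A [causal_dag()].
#' @return A list of character vectors, each a node sequence starting at the
#'   exposure and ending at the outcome; empty if the exposure has no
#'   incoming edge.
#'
#' @examples
#' g <- causal_dag(c("Z", "T", "X", "Y"),
#'                 c("Z->T", "Z->X", "T->Y", "X->Y"), "X", "Y")
#' enumerate_backdoor_paths(g)  # list(c("X", "Z", "T", "Y"))
#' @export
enumerate_backdoor_paths <- function(dag) {
  x <- dag$exposure; y <- dag$outcome
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == y) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    nbrs <- if (length(path) == 1L) dag$parents[[v]]        # arrow into X
            else union(dag$parents[[v]], dag$children[[v]])
    for (w in setdiff(nbrs, path)) walk(c(path, w))
  }
  walk(x)
  if (length(paths) > 1L)
    paths <- paths[order(vapply(paths, paste, "", collapse = "\r"))]
  paths
}

#' Is an undirected path blocked by a conditioning set?
#'
#' Applies the collider rule to one explicit node sequence: the path is
#' blocked iff some interior node is a non-collider in `s`, or a collider
#' with no descendant (itself included) in `s`.
#'
#' @param dag A [causal_dag()].
#' @param path Character vector of adjacent node labels.
#' @param s Conditioning set.
#' @return `TRUE` if the path is blocked given `s`.
#' @export
path_blocked <- function(dag, path, s = character()) {
  check_nodes(dag, path, "path"); check_nodes(dag, s, "s")
  if (length(path) < 3L) return(FALSE)
  for (i in seq(2L, length(path) - 1L)) {
    v <- path[i]
    collider <- path[i - 1L] %in% dag$parents[[v]] &&
                path[i + 1L] %in% dag$parents[[v]]
    if (collider) {
      if (!any(c(v, dag_descendants(dag, v)) %in% s)) return(TRUE)
    } else if (v %in% s) {
      return(TRUE)
    }
  }
  FALSE
}
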