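# Independent brute-force d-separation oracle: enumerate every undirected
# simple path between two nodes and apply the collider blocking rule to
# each.  Deliberately shares no code with the package's reachability
# implementation (path_blocked is reused only where the test's subject IS
# path blocking itself; the d-separation oracle below re-derives blocking
# from scratch).

oracle_undirected_paths <- function(dag, from, to) {
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == to) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    nbrs <- union(dag$parents[[v]], dag$children[[v]])
    for (w in setdiff(nbrs, path)) walk(c(path, w))
  }
  walk(from)
  paths
}

oracle_descendants <- function(dag, v) {
  out <- character(); frontier <- dag$children[[v]]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(dag$children[frontier])), out)
  }
  out
}

oracle_path_blocked <- function(dag, path, s) {
  if (length(path) < 3L) return(FALSE)
  for (i in seq(2L, length(path) - 1L)) {
    v <- path[i]
    is_collider <- path[i - 1L] %in% dag$parents[[v]] &&
      path[i + 1L] %in% dag$parents[[v]]
    if (is_collider) {
      if (!any(c(v, oracle_descendants(dag, v)) %in% s)) return(TRUE)
    } else if (v %in% s) return(TRUE)
  }
  FALSE
}

oracle_d_separated <- function(dag, a, b, s) {
  for (x in a) for (y in b) {
    for (p in oracle_undirected_paths(dag, x, y))
      if (!oracle_path_blocked(dag, p, s)) return(FALSE)
  }
  TRUE
}

# Random DAG on k nodes: random topological order, each forward edge kept
# with probability p.
random_dag <- function(k, p = 0.4) {
  labs <- LETTERS[seq_len(k)]
  ord <- sample(labs)
  edges <- character()
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k))
    if (stats::runif(1) < p) edges <- c(edges, paste0(ord[i], "->", ord[j]))
  causal_dag(labs, edges, exposure = ord[1L], outcome = ord[k])
}

# Exhaustive comparison of d_separated() against the oracle over all
# unordered singleton pairs and all conditioning subsets of the remaining
# nodes.  Returns c(agree, total).
compare_dsep_all_queries <- function(dag) {
  agree <- 0L; total <- 0L
  nodes <- dag$nodes
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (j <= i) next
    x <- nodes[i]; y <- nodes[j]
    rest <- setdiff(nodes, c(x, y))
    paths <- oracle_undirected_paths(dag, x, y)
    subsets <- c(list(character()),
                 unlist(lapply(seq_along(rest), function(k)
                   utils::combn(rest, k, simplify = FALSE)),
                   recursive = FALSE))
    for (s in subsets) {
      want <- all(vapply(paths, oracle_path_blocked, TRUE, dag = dag, s = s))
      got <- d_separated(dag, x, y, s)
      total <- total + 1L
      if (identical(want, got)) agree <- agree + 1L
    }
  }
  c(agree = agree, total = total)
}

# Scenario DAG shorthand used across test files.
scenario_dag <- function(name) build_scenario(name)$dag
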