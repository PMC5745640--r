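test_that("causal_dag validates its invariants", {
  expect_error(causal_dag(c("A", "A", "B"), "A->B", "A", "B"), "duplicate")
  expect_error(causal_dag(c("A", "B"), "A->C", "A", "B"), "endpoints")
  expect_error(causal_dag(c("A", "B"), c("A->B", "A->B"), "A", "B"),
               "duplicate edges")
  expect_error(causal_dag(c("A", "B"), "A->A", "A", "B"), "self-loops")
  expect_error(causal_dag(c("A", "B", "C"), c("A->B", "B->C", "C->A"),
                          "A", "C"), "cycle")
  expect_error(causal_dag(c("A", "B"), "A->B", "A", "A"), "distinct")
  g <- causal_dag(c("Z", "T", "X", "Y"), c("Z->T", "Z->X", "T->Y", "X->Y"),
                  "X", "Y")
  expect_identical(g$topo_order, c("Z", "T", "X", "Y"))
  expect_identical(dag_parents(g, "Y"), c("T", "X"))
  expect_identical(dag_descendants(g, "Z"), c("T", "X", "Y"))
  expect_identical(dag_ancestors(g, "Y"), c("T", "X", "Z"))
})

test_that("d-separation matches the benchmark diagrams' stated facts", {
  gb <- scenario_dag("fig1b")
  # conditioning on Z screens T off X (the shared-boundary fact)
  expect_true(d_separated(gb, "X", "T", "Z"))
  # conditioning on the collider Y opens X -> Y <- T
  expect_false(d_separated(gb, "X", "T", c("Z", "Y")))
  # edgeless graph: everything separated
  g0 <- causal_dag(c("X", "Y"), character(), "X", "Y")
  expect_true(d_separated(g0, "X", "Y"))
  # symmetry
  expect_identical(d_separated(gb, "X", "T", "Z"),
                   d_separated(gb, "T", "X", "Z"))
  # domain errors
  expect_error(d_separated(gb, "X", "X", "Z"), "disjoint")
  expect_error(d_separated(gb, "X", "T", "Q"), "unknown")
})

test_that("d-separation agrees with the brute-force path oracle", {
  set.seed(424242)
  for (rep in seq_len(200)) {
    dag <- random_dag(sample(3:5, 1L))
    res <- compare_dsep_all_queries(dag)
    expect_identical(res[["agree"]], res[["total"]])
  }
})

test_that("back-door path enumeration matches the diagram captions", {
  expect_identical(enumerate_backdoor_paths(scenario_dag("fig1a")),
                   list(c("X", "Z", "T", "Y")))
  # three caption paths plus the collider path through Z -> W <- T
  pd <- enumerate_backdoor_paths(scenario_dag("fig1d"))
  expect_length(pd, 4L)
  has_path <- function(p) any(vapply(pd, identical, TRUE, y = p))
  expect_true(has_path(c("X", "W", "Y")))
  expect_true(has_path(c("X", "W", "T", "Y")))
  expect_true(has_path(c("X", "Z", "W", "Y")))
  expect_true(has_path(c("X", "Z", "W", "T", "Y")))
  # lexicographic ordering of node sequences
  keys <- vapply(pd, paste, "", collapse = " ")
  expect_identical(keys, sort(keys))
  g1 <- causal_dag(c("X", "Y"), "X->Y", "X", "Y")
  expect_identical(enumerate_backdoor_paths(g1), list())
})

test_that("path blocking follows the collider rule", {
  ga <- scenario_dag("fig1a")
  bd <- c("X", "Z", "T", "Y")
  expect_false(path_blocked(ga, bd, character()))
  expect_true(path_blocked(ga, bd, "Z"))
  expect_true(path_blocked(ga, bd, "T"))
  gd <- scenario_dag("fig1d")
  coll <- c("X", "Z", "W", "T", "Y")
  expect_true(path_blocked(gd, coll, character()))   # collider W closed
  expect_false(path_blocked(gd, coll, "W"))          # conditioning opens it
  expect_true(path_blocked(gd, coll, c("W", "T")))   # T re-blocks
})

test_that("G-admissibility applies both back-door conditions", {
  ga <- scenario_dag("fig1a")
  expect_true(is_g_admissible(ga, "T"))
  expect_false(is_g_admissible(ga, character()))
  gb <- scenario_dag("fig1b")
  expect_false(is_g_admissible(gb, "Z"))   # X <- W -> Y stays open
  # a child of X on the causal path violates the descendant condition
  gm <- causal_dag(c("Z", "X", "M", "Y"),
                   c("Z->X", "Z->Y", "X->M", "M->Y"), "X", "Y")
  expect_false(is_g_admissible(gm, "M"))
  expect_true(is_g_admissible(gm, "Z"))
  expect_error(is_g_admissible(ga, "X"), "exposure")
  # empty set admissible iff no open back-door path exists
  g0 <- causal_dag(c("X", "Y", "C"), c("X->Y", "X->C"), "X", "Y")
  expect_true(is_g_admissible(g0, character()))
})

test_that("markov_boundary returns the minimal separating subset", {
  gb <- scenario_dag("fig1b")
  b <- markov_boundary(gb, c("Z", "T"))
  expect_identical(as.character(b), "Z")
  expect_false(attr(b, "multiple"))
  gc <- scenario_dag("fig1c")
  expect_identical(as.character(markov_boundary(gc, c("W", "V"))), "W")
  expect_identical(as.character(markov_boundary(gc, character())),
                   character())
  expect_error(markov_boundary(gb, c("X", "Z")), "exposure")
  # defining property: boundary separates, no proper subset does
  set.seed(99)
  for (rep in seq_len(25)) {
    dag <- random_dag(5)
    s <- setdiff(dag$nodes, dag$exposure)
    m <- as.character(markov_boundary(dag, s))
    expect_true(d_separated(dag, dag$exposure, setdiff(s, m), m))
    if (length(m))
      for (drop in seq_along(m)) {
        sub <- m[-drop]
        expect_false(d_separated(dag, dag$exposure, setdiff(s, sub), sub))
      }
  }
})

test_that("c-equivalence verdict combines both conditions", {
  gc <- scenario_dag("fig1c")
  v <- c_equivalent(gc, "Z", c("Z", "T"))
  expect_true(v$equivalent)
  expect_true(v$boundary_condition_holds)
  expect_false(v$admissibility_condition_holds)
  expect_identical(v$boundary_of_first, "Z")

  ga <- scenario_dag("fig1a")
  v2 <- c_equivalent(ga, "Z", "T")
  expect_true(v2$equivalent)
  expect_true(v2$admissibility_condition_holds)
  expect_false(v2$boundary_condition_holds)

  gb <- scenario_dag("fig1b")
  v3 <- c_equivalent(gb, "Z", "W")
  expect_false(v3$equivalent)
  expect_false(v3$boundary_condition_holds)
  expect_false(v3$admissibility_condition_holds)

  # reflexivity and symmetry
  set.seed(7)
  for (rep in seq_len(20)) {
    dag <- random_dag(5)
    conf <- setdiff(dag$nodes, c(dag$exposure, dag$outcome))
    t_ <- sample(conf, sample(0:length(conf), 1L))
    z_ <- sample(conf, sample(0:length(conf), 1L))
    expect_true(c_equivalent(dag, t_, t_)$equivalent)
    expect_identical(c_equivalent(dag, t_, z_)$equivalent,
                     c_equivalent(dag, z_, t_)$equivalent)
  }
})

test_that("the four scenarios reproduce the published classifications", {
  adm <- function(sc) {
    m <- build_scenario(sc)
    Filter(function(nm) TRUE, unlist(lapply(m$strategy_groups, names)))
  }
  check_group <- function(sc, expect_admissible) {
    m <- build_scenario(sc)
    for (grp in names(m$strategy_groups))
      for (nm in names(m$strategy_groups[[grp]])) {
        s <- m$strategy_groups[[grp]][[nm]]
        expect_identical(is_g_admissible(m$dag, s),
                         nm %in% expect_admissible,
                         label = paste(sc, nm))
      }
  }
  check_group("fig1a", c("A1", "A2", "A3"))
  check_group("fig1b", c("A1", "A2", "A3"))
  check_group("fig1c", c("C1", "C2", "C3"))
  check_group("fig1d", c("A1", "A2", "A3"))

  gb <- scenario_dag("fig1b")
  expect_identical(as.character(markov_boundary(gb, "Z")), "Z")
  expect_identical(as.character(markov_boundary(gb, c("Z", "T"))), "Z")
  gc <- scenario_dag("fig1c")
  expect_identical(as.character(markov_boundary(gc, c("Z", "T"))), "Z")
  expect_identical(as.character(markov_boundary(gc, c("W", "V"))), "W")
})

test_that("DOT export names all nodes and edges", {
  src <- dag_to_dot(scenario_dag("fig1a"))
  expect_match(src, "digraph")
  expect_match(src, "Z -> T;", fixed = TRUE)
  expect_match(src, "X \\[shape=box\\];")
})
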