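test_that("the joint table is the Bayesian-network factorization", {
  m0 <- build_scenario("fig1a",
                       overrides = list(c0 = 0, c1 = 0, c2 = 0, c3 = 0,
                                        alpha_T = 0, alpha_X = 0,
                                        alpha_Y = 0))
  jt0 <- joint_table(m0)
  expect_equal(jt0$prob, rep(1 / 16, 16))

  for (sc in c("fig1a", "fig1b", "fig1c", "fig1d")) {
    jt <- joint_table(build_scenario(sc))
    expect_lt(abs(sum(jt$prob) - 1), 1e-12)
    expect_true(all(jt$prob > 0))
  }
  # each probability is the product of the conditionals in topological order
  m <- build_scenario("fig1a")
  jt <- joint_table(m)
  for (i in c(1L, 6L, 16L)) {
    row <- jt[i, m$dag$nodes]
    p <- 1
    for (v in m$dag$topo_order) {
      pv <- conditional_probability(m, v, unlist(row[m$dag$parents[[v]]]))
      p <- p * if (row[[v]] == 1) pv else 1 - pv
    }
    expect_equal(jt$prob[i], p)
  }
})

test_that("joint table marginals match a large Monte-Carlo sample", {
  m <- build_scenario("fig1b")
  jt <- joint_table(m)
  px <- sum(jt$prob[jt$X == 1])
  n <- 200000
  d <- simulate_dataset(m, n, seed = 31)
  expect_lt(abs(mean(d$X) - px), 4 * sqrt(px * (1 - px) / n))
})

test_that("the true causal effect obeys its closed-form special cases", {
  # with no T->Y effect the outcome law is logistic in X alone
  m <- build_scenario("fig1a", overrides = list(c2 = 0))
  expect_equal(true_ace_log_or(m), log(2), tolerance = 1e-12)
  m17 <- build_scenario("fig1a", overrides = list(c2 = 0, c3 = 1.7))
  expect_equal(true_ace_log_or(m17), 1.7, tolerance = 1e-12)
  # null exposure effect gives a null causal effect
  m0 <- build_scenario("fig1a", overrides = list(c3 = 0))
  expect_equal(true_ace_log_or(m0), 0, tolerance = 1e-12)
  m0b <- build_scenario("fig1b", overrides = list(`X->Y` = 0))
  expect_equal(true_ace_log_or(m0b), 0, tolerance = 1e-12)
})

test_that("truncated-product ACE equals the printed adjustment double-sum", {
  grids <- expand.grid(c2 = c(0, 0.5, 1.1), c3 = c(-0.8, 0.3, 1.2),
                       pi_Z = c(0.3, 0.6))
  for (i in seq_len(nrow(grids))) {
    m <- build_scenario("fig1a", overrides = as.list(grids[i, ]))
    expect_lt(abs(true_ace_log_or(m) - fig1a_double_sum_ace(m)), 1e-10)
  }
})

test_that("population adjusted coefficients reproduce the identity chain", {
  m <- build_scenario("fig1a")
  c3 <- m$edge_effect[["X->Y"]]
  expect_lt(abs(population_adjusted_coefficient(m, c("Z", "T")) - c3), 1e-8)
  expect_lt(abs(population_adjusted_coefficient(m, "T") - c3), 1e-8)
  # with c2 = 0 all three strategies coincide with c3
  mz <- build_scenario("fig1a", overrides = list(c2 = 0))
  for (s in list("Z", "T", c("Z", "T")))
    expect_lt(abs(population_adjusted_coefficient(mz, s) - log(2)), 1e-8)
  # with c2 != 0 and c3 > 0 the {Z}-adjusted coefficient is attenuated
  expect_lt(population_adjusted_coefficient(m, "Z"), c3 - 1e-8)
  # and the inequality reverses for c3 < 0
  mneg <- build_scenario("fig1a", overrides = list(c3 = -log(2)))
  expect_gt(population_adjusted_coefficient(mneg, "Z"), -log(2) + 1e-8)
})

test_that("population IPW estimand solves the adjustment formula", {
  m <- build_scenario("fig1a")
  ace <- true_ace_log_or(m)
  expect_lt(abs(population_ipw_estimand(m, "T") - ace), 1e-10)
  # s = {} is the crude marginal log odds ratio
  jt <- joint_table(m)
  p <- function(x, y) sum(jt$prob[jt$X == x & jt$Y == y])
  crude <- log(p(1, 1) * p(0, 0) / (p(1, 0) * p(0, 1)))
  expect_equal(population_ipw_estimand(m, character()), crude,
               tolerance = 1e-10)
  # non-admissible set in fig1b keeps the W back-door open
  mb <- build_scenario("fig1b")
  expect_gt(abs(population_ipw_estimand(mb, "Z") - true_ace_log_or(mb)),
            0.01)
  # ... unless the W path is cut on either side
  mb0 <- build_scenario("fig1b", overrides = list(`W->Y` = 0))
  expect_lt(abs(population_ipw_estimand(mb0, "Z") - true_ace_log_or(mb0)),
            1e-10)
})

test_that("IPW with any admissible set identifies the true effect", {
  grid <- c(0.2, log(2), 1.1)
  for (sc in c("fig1a", "fig1b", "fig1c", "fig1d")) {
    m0 <- build_scenario(sc)
    out_edge <- "T->Y"
    exp_edge <- grep("->X$", edge_strings(m0), value = TRUE)[1L]
    sets <- Filter(function(s) is_g_admissible(m0$dag, s),
                   unlist(scenario_strategies(m0), recursive = FALSE))
    expect_gte(length(sets), 3L)
    for (v1 in grid) for (v2 in grid) {
      ov <- stats::setNames(list(v1, v2), c(out_edge, exp_edge))
      m <- build_scenario(sc, overrides = ov)
      ace <- true_ace_log_or(m)
      for (s in sets)
        expect_lt(abs(population_ipw_estimand(m, s) - ace), 1e-8)
    }
  }
})

test_that("scenario-2 shared-boundary sets share the IPW estimand only", {
  m <- build_scenario("fig1b")
  expect_lt(abs(population_ipw_estimand(m, "Z") -
                  population_ipw_estimand(m, c("Z", "T"))), 1e-8)
  expect_gt(abs(population_adjusted_coefficient(m, "Z") -
                  population_adjusted_coefficient(m, c("Z", "T"))), 1e-3)
})

test_that("the marginal estimand attenuates relative to the conditional", {
  # odds-ratio non-collapsibility: |IPW(admissible)| <= |conditional
  # coefficient given the outcome's parents| in every scenario
  for (sc in c("fig1a", "fig1b", "fig1c", "fig1d")) {
    for (c3 in c(0.4, log(2), 1.2)) {
      m <- build_scenario(sc, overrides = list(`X->Y` = c3))
      pa_y <- setdiff(m$dag$parents[["Y"]], "X")
      cond <- population_adjusted_coefficient(m, pa_y)
      sets <- Filter(function(s) is_g_admissible(m$dag, s),
                     unlist(scenario_strategies(m), recursive = FALSE))
      for (s in sets)
        expect_lte(abs(population_ipw_estimand(m, s)), abs(cond) + 1e-10)
    }
  }
})

test_that("degenerate parameterizations are rejected, not clipped", {
  m <- build_scenario("fig1a", overrides = list(c3 = 40))
  expect_error(true_ace_log_or(m), "degenerate")
})

test_that("estimand_report tabulates values and biases coherently", {
  m <- build_scenario("fig1a")
  sts <- make_strategies(scenario_strategies(m, "A"))
  rep_ <- estimand_report(m, sts)
  expect_identical(nrow(rep_), 6L)
  expect_equal(rep_$population_bias,
               rep_$population_value - rep_$true_ace)
  ipw <- rep_[rep_$method == "ipw_msm", ]
  expect_true(all(abs(ipw$population_bias) < 1e-8))
})
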