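# A compact scenario for PSA contract tests: strategy A strictly cheaper and
# more effective than B with certainty.
forced_dominance_scenario <- function() {
  a <- make_profile("therapy_a", effect_mean = 8, effect_sd = 2,
                    per_course_cost = 1000)
  b <- make_profile("therapy_b", effect_mean = 2, effect_sd = 2,
                    per_course_cost = 3000, dropout = 0.3)
  toy_scenario(a = a, b = b, seed = 5L)
}

test_that("PSA is seed-reproducible and degenerate with fixed distributions", {
  sc <- forced_dominance_scenario()
  sc$psa_distributions <- list(
    "strategies.therapy_a.effect_mean" = dist_spec("fixed", 8, 0),
    "strategies.therapy_b.per_course_cost" = dist_spec("fixed", 3000, 0)
  )
  res <- run_psa(sc, n = 50, seed = 5)
  expect_equal(nrow(res$draws), 50)
  # all draws identical, fractions degenerate
  expect_equal(length(unique(res$draws$delta_cost)), 1L)
  expect_true(res$fraction_dominant %in% c(0, 1))
  expect_identical(res$fraction_dominant, 1)

  sc$psa_distributions <- list(
    "strategies.therapy_a.effect_mean" =
      fit_distribution(8, 1, "normal"),
    "strategies.therapy_b.per_course_cost" =
      fit_distribution(3000, 300, "gamma")
  )
  r1 <- run_psa(sc, n = 400, seed = 99)
  r2 <- run_psa(sc, n = 400, seed = 99)
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$fraction_dominant, r2$fraction_dominant)
  r3 <- run_psa(sc, n = 400, seed = 100)
  expect_false(identical(r1$draws, r3$draws))
})

test_that("PSA quadrant fractions partition the draws", {
  sc <- example_scenario("nf_vs_psychotherapy")
  res <- run_psa(sc, n = 800, seed = 1)
  tab <- table(factor(res$draws$quadrant,
                      levels = c("dominant", "dominated", "trade_off_ne",
                                 "trade_off_sw")))
  expect_identical(sum(tab), 800L)
  expect_lte(res$fraction_dominant, res$fraction_cheaper)
  expect_equal(res$fraction_dominant,
               mean(res$draws$delta_cost < 0 & res$draws$delta_qaly > 0))
  # different seeds agree within binomial error (3 sqrt(p(1-p)/n))
  res2 <- run_psa(sc, n = 800, seed = 2)
  p <- res$fraction_cheaper
  expect_lt(abs(res2$fraction_cheaper - p), 3 * sqrt(2 * p * (1 - p) / 800))
})

test_that("CEAC endpoints follow their defining probabilities exactly", {
  sc <- example_scenario("nf_vs_psychotherapy")
  res <- run_psa(sc, n = 500, seed = 7, wtp_grid = c(0, 5e4, 1e9))
  d <- res$draws
  expect_identical(res$ceac$prob_preferred[1], mean(d$delta_cost < 0))
  expect_identical(res$ceac$prob_preferred[1], res$fraction_cheaper)
  # at effectively infinite WTP the sign of the QALY difference decides
  expect_equal(res$ceac$prob_preferred[3],
               mean(1e9 * d$delta_qaly - d$delta_cost > 0))
  expect_equal(res$ceac$prob_preferred[3], mean(d$delta_qaly > 0),
               tolerance = 0.01)
})

test_that("one_way sweeps are deterministic grids with engine monotonicity", {
  sc <- example_scenario("nf_vs_psychotherapy")
  # a parameter with no influence on the incremental outcome: sweeping a
  # state cost shifts both strategies equally only if occupancy matched, so
  # use the comparison's own dropout instead and check a flat curve on wtp
  flat <- one_way(sc, "wtp_per_qaly", 0, 1000, n_points = 5)
  expect_equal(nrow(flat), 5L)
  expect_equal(diff(range(flat$delta_cost)), 0)

  # endpoints only
  two <- one_way(sc, "strategies.nf_ot.dropout_course_prob", 0.05, 0.4,
                 n_points = 2)
  expect_identical(two$value, c(0.05, 0.4))

  # sweeping a strategy's dropout upward never increases its QALYs, so the
  # incremental QALY of that strategy is non-increasing along the curve
  curve <- one_way(sc, "strategies.nf_ot.dropout_course_prob", 0.01, 0.5,
                   n_points = 9)
  expect_true(all(diff(curve$delta_qaly) <= 1e-12))

  expect_error(one_way(sc, "no.such.param", 0, 1), "unknown parameter")
  expect_error(one_way(sc, "wtp_per_qaly", 1, 0), "low < high")
})

test_that("find_threshold solves the break-even point", {
  # incremental cost is affine in a strategy's course cost, so the root has
  # a closed form from two evaluations
  sc <- example_scenario("nf_vs_psychotherapy")
  path <- "strategies.nf_ot.per_course_cost"
  pair <- c("nf_ot", "psychotherapy")
  d0 <- ptsdcea:::incremental_deltas(set_param(sc, path, 0), pair)[["delta_cost"]]
  d1 <- ptsdcea:::incremental_deltas(set_param(sc, path, 10000), pair)[["delta_cost"]]
  root <- -d0 / ((d1 - d0) / 10000)
  th <- find_threshold(sc, path, 0, 10000, tol = 1e-6)
  expect_equal(th$threshold_value, root, tolerance = 1e-6)
  expect_lt(abs(th$delta_cost_at_threshold), 1e-6)
  expect_identical(th$direction, "psychotherapy")

  # the sign of the incremental cost flips across the threshold
  eps <- 1
  below <- ptsdcea:::incremental_deltas(set_param(sc, path, root - eps), pair)
  above <- ptsdcea:::incremental_deltas(set_param(sc, path, root + eps), pair)
  expect_lt(below[["delta_cost"]], 0)
  expect_gt(above[["delta_cost"]], 0)

  expect_error(find_threshold(sc, path, 0, 100), "no threshold in range")
})

test_that("tornado sorts parameters by influence on incremental cost", {
  sc <- example_scenario("nf_vs_psychotherapy")
  single <- tornado(sc, list("strategies.nf_ot.dropout_course_prob" = c(0.05, 0.3)))
  expect_equal(nrow(single$entries), 1L)
  expect_gt(single$entries$width, 0)

  # a zero-influence parameter gives a zero-width bar sorted last
  torn <- tornado(sc, list(
    "strategies.nf_ot.dropout_course_prob" = c(0.05, 0.3),
    "wtp_per_qaly" = c(0, 50000)
  ))
  expect_identical(torn$entries$parameter[2], "wtp_per_qaly")
  expect_identical(torn$entries$width[2], 0)
  expect_true(all(diff(torn$entries$width) <= 0))

  expect_error(tornado(sc, list()), "non-empty")
})

test_that("fixture tornado ranks dropout above retreatment", {
  sc <- example_scenario("nf_vs_psychotherapy")
  torn <- tornado(sc, ptsdcea:::default_param_ranges(sc))
  e <- torn$entries
  w <- function(p) e$width[e$parameter == p]
  expect_gt(w("strategies.psychotherapy.dropout_course_prob"),
            w("strategies.psychotherapy.retreatment_prob"))
  expect_gt(w("strategies.nf_ot.dropout_course_prob"),
            w("strategies.nf_ot.retreatment_prob"))
})
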