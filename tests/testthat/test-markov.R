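test_that("per_cycle_prob matches the constant-hazard closed form", {
  expect_identical(per_cycle_prob(0, 7), 0)
  expect_equal(per_cycle_prob(0.25, 1), 0.25)
  expect_equal(per_cycle_prob(0.33, 2), 1 - sqrt(0.67), tolerance = 1e-12)
  expect_equal(per_cycle_prob(0.33, 2), 0.1815, tolerance = 1e-3)
  # inverse property: applying the per-cycle probability c times recovers p
  for (p in c(0.05, 0.33, 0.9)) {
    for (cc in c(1, 2, 4, 12)) {
      q <- per_cycle_prob(p, cc)
      expect_equal(1 - (1 - q)^cc, p, tolerance = 1e-12)
    }
  }
  expect_error(per_cycle_prob(1, 4), "\\[0, 1\\)")
})

test_that("discount_factor follows annual compounding on the cycle grid", {
  expect_identical(discount_factor(0.03, 0, 0.25), 1)
  expect_equal(discount_factor(0.03, 4, 0.25), 1 / 1.03, tolerance = 1e-12)
  expect_identical(discount_factor(0, 9, 0.25), 1)
  expect_error(discount_factor(-0.01, 1, 0.25), ">= 0")
})

test_that("band_crossing_prob agrees with quadrature and behaves at the edges", {
  expect_identical(band_crossing_prob("moderate", 0, 0), 0)
  expect_identical(band_crossing_prob("moderate", 30, 0), 1)   # exceeds width 19
  expect_error(band_crossing_prob("asymptomatic", 5, 1), "milder")
  expect_error(band_crossing_prob("mild", 5, -1), ">= 0")

  # closed form vs deterministic quadrature on the printed severe-band case
  p <- band_crossing_prob("severe", 7.01, 2.883)
  expect_equal(p, crossing_prob_quad(60, 80, 7.01, 2.883), tolerance = 1e-6)

  # monotone non-decreasing in the effect mean
  grid <- seq(0, 30, by = 0.5)
  for (b in c("severe", "moderate", "mild")) {
    ps <- vapply(grid, function(m) band_crossing_prob(b, m, 2.5), numeric(1))
    expect_true(all(diff(ps) >= -1e-12), info = b)
    expect_true(all(ps >= 0 & ps <= 1))
  }

  # negative mean with censoring at 0: crossing needs a positive reduction
  expect_equal(band_crossing_prob("mild", -5, 2),
               crossing_prob_quad(20, 39, -5, 2), tolerance = 1e-9)
})

test_that("transition matrices conserve probability and encode the event order", {
  # all event probabilities zero, no mortality: identity matrix
  sc <- toy_scenario()
  M <- build_transition_matrix(sc, "therapy_a")
  expect_equal(unclass(M), diag(ncol(M)), ignore_attr = TRUE)

  # with mortality only: diagonal 1 - p_death, rest to the dead column
  sc <- toy_scenario(mortality = list(asymptomatic = 0.01, mild = 0.02,
                                      moderate = 0.03, severe = 0.04))
  M <- build_transition_matrix(sc, "therapy_a")
  expect_equal(M["on_severe_from_severe", "dead"], 0.04)
  expect_equal(M["on_severe_from_severe", "on_severe_from_severe"], 0.96)
  expect_equal(M["dropped_mild", "dead"], 0.02)
  expect_equal(M["asymptomatic", "dead"], 0.01)
  expect_equal(M["dead", "dead"], 1)
  expect_equal(unname(rowSums(M)), rep(1, ncol(M)), tolerance = 1e-12)

  # certain dropout: surviving on-treatment mass moves entirely to the
  # dropped state at the same band
  sc <- set_param(sc, "strategies.therapy_a.dropout_course_prob", 1)
  M <- build_transition_matrix(sc, "therapy_a")
  expect_equal(M["on_moderate_from_severe", "dropped_moderate"], 0.97)
  expect_equal(M["on_moderate_from_severe", "dead"], 0.03)
  expect_equal(unname(rowSums(M)), rep(1, ncol(M)), tolerance = 1e-12)

  # fixture matrices: rows sum to one for every strategy
  for (nm in fixture_names) {
    sc <- example_scenario(nm)
    for (s in names(sc$strategies)) {
      M <- build_transition_matrix(sc, s)
      expect_equal(unname(rowSums(M)), rep(1, ncol(M)), tolerance = 1e-12)
      expect_true(all(M >= 0 & M <= 1))
      expect_equal(M["dead", "dead"], 1)
      # asymptomatic exits only to dead
      off <- setdiff(colnames(M), c("asymptomatic", "dead"))
      expect_true(all(M["asymptomatic", off] == 0))
    }
  }
})

test_that("relapse returns retreated mass to the entry band", {
  a <- make_profile("therapy_a", relapse = 0.2, retreat = 0.6)
  sc <- toy_scenario(a = a)
  M <- build_transition_matrix(sc, "therapy_a")
  # from on(mild, entry severe): relapse 0.2 splits 60/40 between
  # on(severe, severe) and dropped(severe)
  expect_equal(M["on_mild_from_severe", "on_severe_from_severe"], 0.2 * 0.6)
  expect_equal(M["on_mild_from_severe", "dropped_severe"], 0.2 * 0.4)
  expect_equal(M["on_mild_from_severe", "on_mild_from_severe"], 0.8)
})

test_that("cohort traces conserve mass and reproduce closed-form toys", {
  # identity dynamics: constant trace
  sc <- toy_scenario()
  tr <- run_cohort(sc, "therapy_a")
  expect_equal(nrow(tr), sc$horizon_cycles + 1L)
  for (t in seq_len(nrow(tr))) expect_equal(unclass(tr)[t, ], unclass(tr)[1, ])

  # uniform death probability 0.5: alive mass halves every cycle
  sc <- toy_scenario(mortality = list(asymptomatic = 0.5, mild = 0.5,
                                      moderate = 0.5, severe = 0.5))
  tr <- run_cohort(sc, "therapy_a")
  alive <- 1 - unclass(tr)[, "dead"]
  expect_equal(unname(alive), 0.5^(0:12), tolerance = 1e-12)

  # fixtures: every cycle sums to 1, dead occupancy non-decreasing
  for (nm in fixture_names) {
    sc <- example_scenario(nm)
    for (s in names(sc$strategies)) {
      tr <- run_cohort(sc, s)
      expect_equal(unname(rowSums(tr)), rep(1, nrow(tr)), tolerance = 1e-9)
      expect_true(all(diff(unclass(tr)[, "dead"]) >= -1e-12))
    }
  }
})

test_that("accrual prices states and therapy per the cost model", {
  # an all-dead trace accrues nothing
  sc <- toy_scenario()
  tr <- run_cohort(sc, "therapy_a")
  dead <- unclass(tr) * 0
  dead[, "dead"] <- 1
  attributes(dead) <- attributes(tr)
  rr <- accrue(dead, sc, "therapy_a")
  expect_identical(rr$total_cost, 0)
  expect_identical(rr$total_qaly, 0)

  # a cohort held in mild with no therapy costs exactly the quarterly care
  # cost of mild PTSD for one cycle
  sc1 <- toy_scenario(initial_distribution = list(mild = 1),
                      horizon_cycles = 1L, annual_discount_rate = 0)
  rr <- accrue(run_cohort(sc1, "therapy_a"), sc1, "therapy_a")
  expect_equal(rr$total_cost, 3450)

  # full-health cohort: discounted QALYs equal the quarterly annuity
  sc2 <- toy_scenario(regression = regression_map(intercept = 200, slope = -0.1))
  expect_equal(band_utility(sc2$regression, "severe"), 1)  # clamped at 100
  rr <- accrue(run_cohort(sc2, "therapy_a"), sc2, "therapy_a")
  expect_equal(rr$total_qaly_discounted,
               sum(0.25 * 1.03^(-0.25 * (0:11))), tolerance = 1e-12)

  # discounted never exceeds undiscounted; zero rate is an exact identity
  sc3 <- example_scenario("nf_vs_psychotherapy")
  rr <- run_strategy(sc3, "nf_ot")
  expect_true(all(rr$per_cycle$cost_discounted <= rr$per_cycle$cost + 1e-12))
  expect_true(all(diff(rr$cumulative_by_year$cost_discounted) >= 0))
  sc0 <- set_param(sc3, "annual_discount_rate", 0)
  rr0 <- run_strategy(sc0, "nf_ot")
  expect_identical(rr0$total_cost_discounted, rr0$total_cost)
  expect_identical(rr0$total_qaly_discounted, rr0$total_qaly)
})

test_that("therapy billing modes differ only by post-course course cost", {
  a <- make_profile("therapy_a", per_course_cost = 1890,
                    annual_drug_cost = 400)
  sc_once <- toy_scenario(a = a, bill_therapy_every_cycle = FALSE,
                          annual_discount_rate = 0)
  sc_every <- toy_scenario(a = a, bill_therapy_every_cycle = TRUE,
                           annual_discount_rate = 0)
  once <- run_strategy(sc_once, "therapy_a")
  every <- run_strategy(sc_every, "therapy_a")
  # no dynamics: everyone stays on treatment for 12 cycles
  expect_equal(every$total_cost - once$total_cost, 1890 * 11, tolerance = 1e-9)
  # drug cost is billed every cycle in both modes
  expect_equal(once$per_cycle$cost[5] - once$per_cycle$cost[5- 1], 0)
  expect_gt(once$per_cycle$cost[1], once$per_cycle$cost[2])  # course in cycle 0
})

test_that("half-cycle correction averages start- and end-of-cycle occupancy", {
  sc <- toy_scenario(mortality = list(asymptomatic = 0.5, mild = 0.5,
                                      moderate = 0.5, severe = 0.5),
                     annual_discount_rate = 0)
  plain <- run_strategy(sc, "therapy_a")
  sc$half_cycle_correction <- TRUE
  hc <- run_strategy(sc, "therapy_a")
  alive <- 0.5^(0:12)
  care <- (5880 + 4900 + 3450) / 3
  expect_equal(plain$per_cycle$cost, care * alive[1:12], tolerance = 1e-9)
  expect_equal(hc$per_cycle$cost,
               care * (alive[1:12] + alive[2:13]) / 2, tolerance = 1e-9)
})
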