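# Shared builders and independent oracles for the test suite.

make_profile <- function(name = "toy",
                         dropout = 0, relapse = 0, retreat = 0.5,
                         effect_mean = 0, effect_sd = 0,
                         per_course_cost = 0, annual_drug_cost = 0,
                         course_cycles = 1, relapse_cycles = 1) {
  therapy_profile(
    name = name,
    per_session_cost = 0, sessions_per_course = 0,
    per_course_cost = per_course_cost,
    annual_drug_cost = annual_drug_cost,
    dropout_course_prob = dropout, relapse_prob = relapse,
    retreatment_prob = retreat,
    effect_mean = effect_mean, effect_dispersion = effect_sd,
    effect_dispersion_kind = "sd",
    course_cycles = course_cycles, relapse_cycles = relapse_cycles
  )
}

toy_scenario <- function(a = make_profile("therapy_a"),
                         b = make_profile("therapy_b"),
                         state_costs = list(severe = 5880, moderate = 4900,
                                            mild = 3450, asymptomatic = 0),
                         mortality = list(asymptomatic = 0, mild = 0,
                                          moderate = 0, severe = 0),
                         initial_distribution = list(severe = 1 / 3,
                                                     moderate = 1 / 3,
                                                     mild = 1 / 3),
                         ...) {
  scenario(strategies = list(a, b), state_costs = state_costs,
           mortality = mortality,
           initial_distribution = initial_distribution, ...)
}

fixture_names <- c("nf_vs_psychotherapy", "nf_vs_pharmacotherapy",
                   "prism_vs_each")

# Independent quadrature oracle for the band-crossing probability:
# P(U - max(N, 0) < lo), U ~ Unif[lo, hi], N ~ Normal(mean, sd).
crossing_prob_quad <- function(lo, hi, mean, sd) {
  w <- hi - lo
  if (sd == 0) return(min(max(mean, 0) / w, 1))
  f <- function(t) 1 - stats::pnorm((t - mean) / sd)
  stats::integrate(f, 0, w, rel.tol = 1e-10, abs.tol = 1e-12)$value / w
}

# Monte Carlo oracle for the same quantity
crossing_prob_mc <- function(lo, hi, mean, sd, n = 1e6) {
  u <- stats::runif(n, lo, hi)
  r <- pmax(stats::rnorm(n, mean, sd), 0)
  mean(u - r < lo)
}

# Exhaustive grid-scan oracle for threshold finding: returns the midpoint of
# the first grid interval over which the incremental cost changes sign.
grid_threshold_oracle <- function(sc, parameter, low, high, n = 10000,
                                  comparison = NULL) {
  pair <- if (is.null(comparison)) names(sc$strategies)[1:2] else comparison
  grid <- seq(low, high, length.out = n)
  dc <- vapply(grid, function(v) {
    ptsdcea:::incremental_deltas(set_param(sc, parameter, v), pair)[["delta_cost"]]
  }, numeric(1))
  flips <- which(diff(sign(dc)) != 0)
  if (!length(flips)) return(NULL)
  list(bracket = c(grid[flips[1]], grid[flips[1] + 1L]),
       step = grid[2] - grid[1])
}
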