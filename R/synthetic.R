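#' Generate a random valid scenario
#'
#' Draws a complete scenario with the statistical structure the analysis
#' assumes -- probabilities from beta families (dropout constrained to
#' (0, 0.6)), costs from gamma families, treatment effects from normal
#' families with positive means -- for property-based testing of the engine.
#' The result always passes [validate_scenario()] and is deterministic for a
#' given seed.
#'
#' @param seed Integer seed.
#' @return A validated [scenario()] with two strategies.
#' @export
random_scenario <- function(seed) {
  set.seed(seed)
  rand_profile <- function(name) {
    per_session <- stats::rgamma(1, shape = 25, scale = 6)      # ~USD 150
    sessions <- stats::runif(1, 8, 16)
    cycles <- sample(c(1L, 2L, 4L), 1)
    therapy_profile(
      name = name,
      per_session_cost = per_session,
      sessions_per_course = sessions,
      per_course_cost = per_session * sessions,
      annual_drug_cost = if (stats::runif(1) < 0.5) stats::rgamma(1, 4, scale = 350) else 0,
      dropout_course_prob = 0.6 * stats::rbeta(1, 2, 4),
      relapse_prob = stats::rbeta(1, 2, 8),
      retreatment_prob = stats::rbeta(1, 5, 5),
      effect_mean = abs(stats::rnorm(1, 7, 3)) + 0.5,
      effect_dispersion = stats::runif(1, 0.5, 5),
      course_cycles = cycles,
      relapse_cycles = sample(c(1L, 4L), 1)
    )
  }
  base_mort <- stats::runif(1, 1e-4, 1e-3)
  mult <- cumprod(c(1, stats::runif(3, 1, 1.6)))   # asym -> severe
  init <- stats::rgamma(3, shape = 2)
  init <- init / sum(init)
  scenario(
    strategies = list(rand_profile("therapy_a"), rand_profile("therapy_b")),
    state_costs = list(severe = stats::rgamma(1, 16, scale = 350),
                       moderate = stats::rgamma(1, 16, scale = 300),
                       mild = stats::rgamma(1, 16, scale = 220),
                       asymptomatic = 0),
    mortality = list(asymptomatic = base_mort * mult[1],
                     mild = base_mort * mult[2],
                     moderate = base_mort * mult[3],
                     severe = base_mort * mult[4]),
    initial_distribution = list(severe = init[1], moderate = init[2],
                                mild = init[3]),
    regression = regression_map(intercept = stats::runif(1, 85, 98),
                                slope = -stats::runif(1, 0.3, 1.1)),
    annual_discount_rate = stats::runif(1, 0, 0.05),
    seed = seed
  )
}

#' Patient-level microsimulation (cohort-engine oracle)
#'
#' Simulates `n` individual patients through the same quarterly event
#' sequence as the cohort engine -- death, dropout, relapse (with the
#' retreatment split), band improvement -- using the identical per-cycle
#' probabilities, but realising the improvement step with continuous CAPS-5
#' scores: each cycle the patient's within-band score is drawn uniformly
#' (the within-band distribution is exchangeable across cycles, matching the
#' band-crossing probability's uniform assumption) and a Normal effect draw,
#' censored below at 0, is subtracted; the patient crosses into the next
#' milder band when the treated score falls below the band's lower bound.
#' For strategies whose course spans several cycles the per-course crossing
#' indicator is thinned to the per-cycle scale.
#'
#' Because event draws are distributionally identical to the cohort chain,
#' the mean trace converges to [run_cohort()] at the binomial rate; the
#' function exists as a brute-force cross-check of the cohort algebra.
#'
#' All randomness flows from `seed`; each cycle consumes a fixed schedule of
#' length-`n` draw vectors (death, dropout, relapse, retreatment, in-band
#' score, effect, thinning), so runs with the same seed and `n` are
#' bit-identical and paired across strategies (common random numbers).
#'
#' @param sc A validated [scenario()].
#' @param strategy Strategy name or [therapy_profile()].
#' @param n Number of simulated patients.
#' @param seed Integer seed.
#' @param init `"uniform"` (default) draws entry scores uniformly within the
#'   entry band; `"midpoint"` starts every patient at the band midpoint
#'   (affects only the recorded scores, not transitions).
#' @param keep_ledger If TRUE, also return the per-patient per-cycle ledger
#'   (columns patient, cycle, state, caps5, cost, qaly) -- intended for
#'   debugging at small `n`.
#' @return A `microsim_result`: `mean_occupancy` and `se_occupancy`
#'   (`(horizon+1) x n_states` matrices aligned with [run_cohort()]),
#'   `mean_cost`, `se_cost`, `mean_qaly`, `se_qaly` (per-cycle discounted
#'   means over patients), `total_mean_cost`, `total_mean_qaly` with
#'   standard errors, `n`, `seed`, `strategy`, optionally `ledger`.
#' @export
microsim <- function(sc, strategy, n, seed = sc$seed,
                     init = c("uniform", "midpoint"), keep_ledger = FALSE) {
  sc <- validate_scenario(sc)
  init <- match.arg(init)
  stopifnot(n >= 1)
  pr <- cycle_probs(sc, strategy)
  profile <- pr$profile
  sv <- state_values(sc, strategy)
  st <- sv$states
  H <- sc$horizon_cycles
  len <- sc$cycle_length_years

  band_tab <- validate_bands(sc$bands)          # severe..asymptomatic order
  lo <- band_tab$caps5_low
  wd <- band_tab$caps5_high - band_tab$caps5_low
  mort <- unlist(sc$mortality[.band_labels])
  care_cost <- unlist(sc$state_costs[.band_labels])
  util <- stats::setNames(band_utility(sc$regression, .band_labels, sc$bands),
                          .band_labels)
  eff_sd <- effect_sd(profile)
  p_course <- vapply(.symptomatic_bands, function(b) {
    band_crossing_prob(b, profile$effect_mean, eff_sd, sc$bands)
  }, numeric(1))
  thin <- ifelse(p_course > 0,
                 per_cycle_prob_safe(p_course, profile$course_cycles) / p_course,
                 0)

  set.seed(seed)
  # entry bands: severe=1, moderate=2, mild=3 (indices into .band_labels)
  init_p <- unlist(sc$initial_distribution[.symptomatic_bands])
  entry <- sample.int(3L, n, replace = TRUE, prob = init_p)
  band <- entry                              # current band index (4 = asym)
  status <- rep(1L, n)                       # 1 on, 2 dropped, 3 asym, 4 dead
  caps5 <- if (init == "uniform") {
    lo[entry] + wd[entry] * stats::runif(n)
  } else {
    lo[entry] + wd[entry] / 2
  }

  state_name <- function(status, band, entry) {
    ifelse(status == 4L, "dead",
    ifelse(status == 3L, "asymptomatic",
    ifelse(status == 2L, paste0("dropped_", .band_labels[band]),
           paste0("on_", .band_labels[band], "_from_", .band_labels[entry]))))
  }

  occ_count <- matrix(0, H + 1L, nrow(st), dimnames = list(0:H, st$name))
  cost_pc <- matrix(0, n, H)   # per-patient discounted cost by cycle
  qaly_pc <- matrix(0, n, H)
  ledger <- if (keep_ledger) vector("list", H) else NULL

  tab_states <- function() {
    tabulate(match(state_name(status, band, entry), st$name), nrow(st))
  }
  occ_count[1L, ] <- tab_states()

  for (t in seq_len(H)) {
    cyc <- t - 1L
    disc <- discount_factor(sc$annual_discount_rate, cyc, len)
    # accrual at start-of-cycle state; dead patients accrue nothing
    alive <- status != 4L
    ccost <- ifelse(alive, care_cost[band], 0)
    on_tr <- status == 1L
    therapy_cost <- sv$drug_cycle_cost +
      if (sc$bill_therapy_every_cycle || cyc < profile$course_cycles)
        sv$course_cycle_cost else 0
    ccost <- ccost + ifelse(on_tr, therapy_cost, 0)
    cqaly <- ifelse(alive, util[band], 0) * len
    cost_pc[, t] <- ccost * disc
    qaly_pc[, t] <- cqaly * disc
    if (keep_ledger) {
      ledger[[t]] <- data.frame(patient = seq_len(n), cycle = cyc,
                                state = state_name(status, band, entry),
                                caps5 = ifelse(alive, caps5, NA_real_),
                                cost = ccost, qaly = cqaly)
    }

    # fixed draw schedule: death, dropout, relapse, retreat, score, effect, thin
    u_death <- stats::runif(n)
    u_drop  <- stats::runif(n)
    u_rel   <- stats::runif(n)
    u_ret   <- stats::runif(n)
    u_score <- stats::runif(n)
    r_eff   <- pmax(stats::rnorm(n, profile$effect_mean, eff_sd), 0)
    u_thin  <- stats::runif(n)

    dies <- alive & u_death < mort[band]
    at_risk <- on_tr & !dies
    drops <- at_risk & u_drop < pr$p_dropout
    relapses <- at_risk & !drops & u_rel < pr$p_relapse
    retreats <- relapses & u_ret < pr$p_retreat

    can_improve <- at_risk & !drops & !relapses
    score <- lo[band] + wd[band] * u_score
    crossed <- can_improve & (score - r_eff < lo[band]) & (u_thin < thin[pmin(band, 3L)])

    status[dies] <- 4L
    status[drops] <- 2L
    band[relapses] <- entry[relapses]
    caps5[relapses] <- lo[entry[relapses]] + wd[entry[relapses]] / 2
    status[relapses & !retreats] <- 2L
    band[crossed] <- band[crossed] + 1L
    asym <- crossed & band == 4L
    status[asym] <- 3L
    caps5[can_improve] <- pmin(pmax(score[can_improve] - r_eff[can_improve], 0),
                               80)
    occ_count[t + 1L, ] <- tab_states()
  }

  mean_occ <- occ_count / n
  se_occ <- sqrt(mean_occ * (1 - mean_occ) / n)
  res <- list(
    n = n, seed = seed, strategy = profile$name,
    mean_occupancy = mean_occ,
    se_occupancy = se_occ,
    mean_cost = colMeans(cost_pc),
    se_cost = apply(cost_pc, 2, stats::sd) / sqrt(n),
    mean_qaly = colMeans(qaly_pc),
    se_qaly = apply(qaly_pc, 2, stats::sd) / sqrt(n),
    total_mean_cost = mean(rowSums(cost_pc)),
    total_se_cost = stats::sd(rowSums(cost_pc)) / sqrt(n),
    total_mean_qaly = mean(rowSums(qaly_pc)),
    total_se_qaly = stats::sd(rowSums(qaly_pc)) / sqrt(n)
  )
  if (keep_ledger) res$ledger <- do.call(rbind, ledger)
  structure(res, class = "microsim_result")
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("<microsim_result> strategy '%s', n = %d (seed %d)\n",
              x$strategy, x$n, x$seed))
  cat(sprintf("  discounted totals: cost %.0f +/- %.0f USD, QALYs %.4f +/- %.4f\n",
              x$total_mean_cost, x$total_se_cost,
              x$total_mean_qaly, x$total_se_qaly))
  invisible(x)
}
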