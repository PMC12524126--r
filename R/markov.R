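#' Convert a per-course probability to the quarterly cycle scale
#'
#' Published dropout and relapse rates refer to a whole treatment course or
#' a year, not to the model's quarterly cycle. Assuming a constant hazard
#' within the course, the per-cycle probability is
#' `1 - (1 - course_prob)^(1 / cycles_per_course)`, so that applying it for
#' `cycles_per_course` consecutive cycles recovers the course-level
#' probability exactly.
#'
#' @param course_prob Probability over the whole course, in `[0, 1)`.
#' @param cycles_per_course Number of cycles the course spans (>= 1).
#' @return Per-cycle probability.
#' @export
#' @examples
#' per_cycle_prob(0.33, 4)   # annual 33% dropout on the quarterly scale
per_cycle_prob <- function(course_prob, cycles_per_course) {
  if (any(course_prob < 0 | course_prob >= 1)) {
    stop("per_cycle_prob: course_prob must be in [0, 1) (a certain event ",
         "has no finite per-cycle hazard)", call. = FALSE)
  }
  if (any(cycles_per_course < 1)) {
    stop("per_cycle_prob: cycles_per_course must be >= 1", call. = FALSE)
  }
  1 - (1 - course_prob)^(1 / cycles_per_course)
}

# Engine-internal variant: tolerates course_prob == 1 (deterministic event
# stays deterministic on the cycle scale).
per_cycle_prob_safe <- function(course_prob, cycles_per_course) {
  ifelse(course_prob >= 1, 1, per_cycle_prob(pmin(course_prob, 1 - 1e-15),
                                             cycles_per_course))
}

#' Probability of crossing below a severity band in one course
#'
#' A patient whose CAPS-5 score is uniformly distributed within a band
#' receives a Normal(mean, sd) score reduction, censored below at 0 (scores
#' cannot worsen through treatment here). The band-crossing probability is
#' the chance the treated score falls below the band's lower bound, i.e.
#' moves the patient into the next milder band.
#'
#' Writing `w` for the band width and `t = score - caps5_low ~ U[0, w]`,
#' the crossing probability is the closed form
#' `(sd / w) * (G(mean/sd) - G((mean - w)/sd))` with
#' `G(z) = z * pnorm(z) + dnorm(z)`; for `sd = 0` it degenerates to
#' `min(max(mean, 0) / w, 1)`.
#'
#' @param band Band label (not asymptomatic).
#' @param effect_mean Mean CAPS-5 reduction per course.
#' @param effect_sd SD of the reduction (>= 0).
#' @param bands Band table, see [severity_bands()].
#' @return Crossing probability in `[0, 1]`, non-decreasing in `effect_mean`.
#' @export
band_crossing_prob <- function(band, effect_mean, effect_sd,
                               bands = severity_bands()) {
  if (band == "asymptomatic") {
    stop("band_crossing_prob: asymptomatic has no milder band", call. = FALSE)
  }
  if (effect_sd < 0) {
    stop("band_crossing_prob: effect_sd must be >= 0", call. = FALSE)
  }
  w <- band_width(band, bands)
  if (effect_sd == 0) {
    if (w == 0) return(as.numeric(effect_mean > 0))
    return(min(max(effect_mean, 0) / w, 1))
  }
  if (w == 0) {
    return(stats::pnorm(effect_mean / effect_sd))
  }
  G <- function(z) z * stats::pnorm(z) + stats::dnorm(z)
  p <- (effect_sd / w) * (G(effect_mean / effect_sd) -
                          G((effect_mean - w) / effect_sd))
  min(max(p, 0), 1)
}

#' Discount factor for a model cycle
#'
#' @param annual_rate Annual discount rate (>= 0).
#' @param cycle_index Cycle number (0-based; cycle 0 is undiscounted).
#' @param cycle_length_years Cycle length in years.
#' @return `(1 + annual_rate)^(-cycle_index * cycle_length_years)`.
#' @export
discount_factor <- function(annual_rate, cycle_index, cycle_length_years) {
  if (any(annual_rate < 0)) {
    stop("discount_factor: annual_rate must be >= 0", call. = FALSE)
  }
  (1 + annual_rate)^(-(cycle_index * cycle_length_years))
}

# ---- state space ------------------------------------------------------------

# Health states carry the current severity band, treatment status and the
# band at model entry (the state a relapse returns to):
#   on_<band>_from_<entry>  : on treatment, improvement can only move one
#                             band milder per cycle, so band <= entry
#   dropped_<band>          : out of therapy, frozen at the dropout band
#   asymptomatic            : absorbing except for background death
#   dead                    : absorbing
state_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    band <- character(0); entry <- character(0)
    for (e in .symptomatic_bands) {
      bs <- .symptomatic_bands[match(e, .symptomatic_bands):length(.symptomatic_bands)]
      band <- c(band, bs); entry <- c(entry, rep(e, length(bs)))
    }
    cache <<- data.frame(
      name = c(paste0("on_", band, "_from_", entry),
               paste0("dropped_", .symptomatic_bands), "asymptomatic", "dead"),
      status = c(rep("on_treatment", length(band)),
                 rep("dropped_out", 3L), "asymptomatic", "dead"),
      band = c(band, .symptomatic_bands, "asymptomatic", NA_character_),
      entry_band = c(entry, rep(NA_character_, 5L)),
      stringsAsFactors = FALSE
    )
    cache
  }
})

# Precomputed integer indices into the state space for the matrix builder
state_indices <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    st <- state_table()
    idx <- stats::setNames(seq_len(nrow(st)), st$name)
    on <- which(st$status == "on_treatment")
    b <- st$band[on]; e <- st$entry_band[on]
    cache <<- list(
      st = st, n = nrow(st), idx = idx,
      i_on = on,
      on_band_i = match(b, .symptomatic_bands),
      j_drop_band = idx[paste0("dropped_", b)],
      j_on_ee = idx[paste0("on_", e, "_from_", e)],
      j_drop_entry = idx[paste0("dropped_", e)],
      j_dest = ifelse(b == "mild", idx["asymptomatic"],
                      idx[paste0("on_", vapply(b, band_below, character(1)),
                                 "_from_", e)]),
      i_drop = which(st$status == "dropped_out"),
      drop_band_i = match(st$band[st$status == "dropped_out"],
                          .symptomatic_bands),
      i_asym = which(st$status == "asymptomatic"),
      i_dead = which(st$status == "dead"),
      band_of_state = match(st$band, .band_labels)
    )
    cache
  }
})

resolve_strategy <- function(sc, strategy) {
  if (inherits(strategy, "therapy_profile")) return(strategy)
  p <- sc$strategies[[strategy]]
  if (is.null(p)) {
    stop("unknown strategy '", strategy, "'; scenario has: ",
         paste(names(sc$strategies), collapse = ", "), call. = FALSE)
  }
  p
}

# Per-cycle event probabilities for one strategy
cycle_probs <- function(sc, strategy) {
  p <- resolve_strategy(sc, strategy)
  sd <- effect_sd(p)
  p_imp <- vapply(.symptomatic_bands, function(b) {
    per_cycle_prob_safe(band_crossing_prob(b, p$effect_mean, sd, sc$bands),
                        p$course_cycles)
  }, numeric(1))
  list(
    profile = p,
    p_death = unlist(sc$mortality[.band_labels]),
    p_dropout = per_cycle_prob_safe(p$dropout_course_prob, p$course_cycles),
    p_relapse = per_cycle_prob_safe(p$relapse_prob, p$relapse_cycles),
    p_retreat = p$retreatment_prob,
    p_improve = p_imp
  )
}

#' Build the per-cycle transition matrix for one strategy
#'
#' Competing risks are composed multiplicatively in a fixed order, each
#' conditional on the previous events not occurring: death (band-specific),
#' then dropout, then relapse (split between retreatment, which returns the
#' patient to therapy at their entry band, and abandonment, which moves them
#' to the dropped-out state at the entry band), then improvement by one
#' severity band. Dropped-out patients stay at their dropout band;
#' asymptomatic patients exit only to death; death is absorbing.
#'
#' @param sc A validated [scenario()].
#' @param strategy Strategy name or [therapy_profile()].
#' @return A `transition_matrix`: square matrix with state dimnames; rows
#'   sum to 1 within 1e-12.
#' @export
build_transition_matrix <- function(sc, strategy) {
  ix <- state_indices()
  pr <- cycle_probs(sc, strategy)
  n <- ix$n
  M <- matrix(0, n, n, dimnames = list(ix$st$name, ix$st$name))

  # absorbing / passive rows
  M[ix$i_dead, ix$i_dead] <- 1
  pd_drop <- pr$p_death[ix$drop_band_i]
  M[cbind(ix$i_drop, ix$i_dead)] <- pd_drop
  M[cbind(ix$i_drop, ix$i_drop)] <- 1 - pd_drop
  pd_asym <- pr$p_death[["asymptomatic"]]
  M[ix$i_asym, ix$i_dead] <- pd_asym
  M[ix$i_asym, ix$i_asym] <- 1 - pd_asym

  # on-treatment rows: death -> dropout -> relapse (retreatment split) ->
  # improvement -> remain, each conditional on prior non-occurrence.
  # Looped because several event destinations can coincide (e.g. relapse at
  # the entry band) and their masses must accumulate.
  for (k in seq_along(ix$i_on)) {
    i <- ix$i_on[k]
    pd <- pr$p_death[[ix$on_band_i[k]]]
    alive <- 1 - pd
    m_drop <- alive * pr$p_dropout
    m_rel  <- alive * (1 - pr$p_dropout) * pr$p_relapse
    m_imp  <- alive * (1 - pr$p_dropout) * (1 - pr$p_relapse) *
      pr$p_improve[[ix$on_band_i[k]]]
    M[i, ix$i_dead] <- pd
    M[i, ix$j_drop_band[k]] <- M[i, ix$j_drop_band[k]] + m_drop
    M[i, ix$j_on_ee[k]] <- M[i, ix$j_on_ee[k]] + m_rel * pr$p_retreat
    M[i, ix$j_drop_entry[k]] <- M[i, ix$j_drop_entry[k]] + m_rel * (1 - pr$p_retreat)
    M[i, ix$j_dest[k]] <- M[i, ix$j_dest[k]] + m_imp
    M[i, i] <- M[i, i] + 1 - (pd + m_drop + m_rel + m_imp)
    if (M[i, i] < -1e-12 || M[i, i] > 1 + 1e-12) {
      stop("build_transition_matrix: composed probability outside [0, 1] in ",
           "state '", ix$st$name[i], "'", call. = FALSE)
    }
  }
  structure(M, class = c("transition_matrix", "matrix", "array"),
            states = ix$st)
}

#' Run the cohort trace
#'
#' Propagates the initial cohort distribution through the strategy's
#' transition matrix for `horizon_cycles` cycles. The cohort enters on
#' treatment at its severity band (entry band equal to current band).
#'
#' @inheritParams build_transition_matrix
#' @return A `cohort_trace`: matrix `(horizon_cycles + 1) x n_states` of
#'   occupancy proportions, rows labelled by cycle `0..H`.
#' @export
run_cohort <- function(sc, strategy) {
  M <- build_transition_matrix(sc, strategy)
  st <- attr(M, "states")
  H <- sc$horizon_cycles
  occ <- matrix(0, H + 1L, nrow(st), dimnames = list(0:H, st$name))
  for (b in .symptomatic_bands) {
    occ[1L, paste0("on_", b, "_from_", b)] <- sc$initial_distribution[[b]]
  }
  for (t in seq_len(H)) {
    occ[t + 1L, ] <- occ[t, ] %*% M
  }
  structure(occ, class = c("cohort_trace", "matrix", "array"),
            states = st, strategy = resolve_strategy(sc, strategy)$name)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  df <- data.frame(
    cycle = rep(as.integer(rownames(x)), times = ncol(x)),
    state = rep(colnames(x), each = nrow(x)),
    occupancy = as.vector(unclass(x)),
    stringsAsFactors = FALSE
  )
  df[order(df$cycle, match(df$state, colnames(x))), , drop = FALSE]
}

# Per-state cost of one on-treatment cycle and utilities for QALY accrual
state_values <- function(sc, strategy) {
  ix <- state_indices()
  p <- resolve_strategy(sc, strategy)
  course_cycle_cost <- p$per_course_cost / p$course_cycles
  drug_cycle_cost <- p$annual_drug_cost * sc$cycle_length_years
  therapy_cycle_cost <- course_cycle_cost + drug_cycle_cost
  u <- band_utility(sc$regression, .band_labels, sc$bands)
  bi <- ix$band_of_state                       # NA for dead
  care <- unlist(sc$state_costs[.band_labels])[bi]
  care[is.na(care)] <- 0
  util <- u[bi]
  util[is.na(util)] <- 0
  cost <- care
  cost[ix$i_on] <- cost[ix$i_on] + therapy_cycle_cost
  list(states = ix$st, cost = cost, utility = util,
       therapy_cycle_cost = therapy_cycle_cost,
       course_cycle_cost = course_cycle_cost,
       drug_cycle_cost = drug_cycle_cost,
       care_cost = care)
}

# Undiscounted per-cycle cost and QALY streams from an occupancy matrix
# (rows: cycles 0..H). Shared by accrue() and the totals-only fast path.
cycle_streams <- function(occ, sc, strategy, sv) {
  H <- nrow(occ) - 1L
  if (isTRUE(sc$half_cycle_correction)) {
    val_occ <- (occ[seq_len(H), , drop = FALSE] +
                occ[seq_len(H) + 1L, , drop = FALSE]) / 2
  } else {
    val_occ <- occ[seq_len(H), , drop = FALSE]
  }
  if (!isTRUE(sc$bill_therapy_every_cycle)) {
    # bill the course only while the first course is running; ongoing drug
    # cost is billed every on-treatment cycle regardless
    p <- resolve_strategy(sc, strategy)
    cost <- as.vector(val_occ %*% sv$cost)
    late <- seq_len(H) - 1L >= p$course_cycles
    if (any(late)) {
      on_occ <- rowSums(val_occ[, sv$states$status == "on_treatment",
                                drop = FALSE])
      cost[late] <- cost[late] - on_occ[late] * sv$course_cycle_cost
    }
  } else {
    cost <- as.vector(val_occ %*% sv$cost)
  }
  list(cost = cost,
       qaly = as.vector(val_occ %*% sv$utility) * sc$cycle_length_years)
}

# Discounted totals only (hot path for PSA / threshold search)
run_totals <- function(sc, strategy) {
  M <- build_transition_matrix(sc, strategy)
  H <- sc$horizon_cycles
  occ <- matrix(0, H + 1L, ncol(M))
  init <- numeric(ncol(M))
  ix <- state_indices()
  for (b in .symptomatic_bands) {
    init[ix$idx[[paste0("on_", b, "_from_", b)]]] <- sc$initial_distribution[[b]]
  }
  occ[1L, ] <- init
  for (t in seq_len(H)) occ[t + 1L, ] <- occ[t, ] %*% M
  sv <- state_values(sc, strategy)
  streams <- cycle_streams(occ, sc, strategy, sv)
  disc <- discount_factor(sc$annual_discount_rate, seq_len(H) - 1L,
                          sc$cycle_length_years)
  c(cost = sum(streams$cost * disc), qaly = sum(streams$qaly * disc))
}

#' Accrue discounted costs and QALYs over a cohort trace
#'
#' Each cycle values the cohort at its start-of-cycle occupancy (or the mean
#' of start and end when half-cycle correction is on): occupancy times the
#' state's quarterly care cost, plus therapy cost for on-treatment states
#' (course cost spread uniformly over the course's cycles, plus the
#' cycle-length share of any annual drug cost), plus occupancy times band
#' utility times the cycle length in years for QALYs. Both streams are
#' returned discounted and undiscounted, with cumulative totals at each
#' whole year.
#'
#' @param trace A [run_cohort()] trace.
#' @inheritParams build_transition_matrix
#' @return A `run_result` with elements `per_cycle` (data.frame: cycle, cost,
#'   qaly, cost_discounted, qaly_discounted), `cumulative_by_year`,
#'   `total_cost_discounted`, `total_qaly_discounted`, `total_cost`,
#'   `total_qaly`, `strategy`.
#' @export
accrue <- function(trace, sc, strategy) {
  stopifnot(inherits(trace, "cohort_trace"))
  sv <- state_values(sc, strategy)
  H <- nrow(trace) - 1L
  streams <- cycle_streams(unclass(trace), sc, strategy, sv)
  cost <- streams$cost
  qaly <- streams$qaly
  cycles <- seq_len(H) - 1L
  disc <- discount_factor(sc$annual_discount_rate, cycles, sc$cycle_length_years)
  per_cycle <- data.frame(
    cycle = cycles,
    cost = cost,
    qaly = qaly,
    cost_discounted = cost * disc,
    qaly_discounted = qaly * disc
  )
  years <- seq_len(floor(H * sc$cycle_length_years + 1e-9))
  cum <- do.call(rbind, lapply(years, function(y) {
    keep <- (cycles + 1L) * sc$cycle_length_years <= y + 1e-9
    data.frame(year = y,
               cost = sum(cost[keep]),
               qaly = sum(qaly[keep]),
               cost_discounted = sum(per_cycle$cost_discounted[keep]),
               qaly_discounted = sum(per_cycle$qaly_discounted[keep]))
  }))
  structure(
    list(per_cycle = per_cycle,
         cumulative_by_year = cum,
         total_cost = sum(cost),
         total_qaly = sum(qaly),
         total_cost_discounted = sum(per_cycle$cost_discounted),
         total_qaly_discounted = sum(per_cycle$qaly_discounted),
         strategy = resolve_strategy(sc, strategy)$name),
    class = "run_result"
  )
}

#' Run one strategy end to end
#'
#' Convenience wrapper: [run_cohort()] then [accrue()].
#'
#' @inheritParams build_transition_matrix
#' @return A `run_result`.
#' @export
run_strategy <- function(sc, strategy) {
  accrue(run_cohort(sc, strategy), sc, strategy)
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> strategy '%s': discounted cost %.0f USD, QALYs %.4f\n",
              x$strategy, x$total_cost_discounted, x$total_qaly_discounted))
  invisible(x)
}

#' @export
as.data.frame.run_result <- function(x, ...) x$per_cycle
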