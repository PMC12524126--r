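# Which parameter paths are probabilities (resampled into [0,1] during PSA)
is_prob_path <- function(path) {
  grepl("\\.(dropout_course_prob|relapse_prob|retreatment_prob)$", path) |
    startsWith(path, "mortality.")
}

incremental_deltas <- function(sc, pair) {
  a <- run_totals(sc, pair[1])
  b <- run_totals(sc, pair[2])
  c(delta_cost = a[["cost"]] - b[["cost"]],
    delta_qaly = a[["qaly"]] - b[["qaly"]])
}

resolve_pair <- function(sc, comparison) {
  if (is.null(comparison)) comparison <- names(sc$strategies)[1:2]
  if (length(comparison) != 2L) {
    stop("comparison must name exactly 2 strategies", call. = FALSE)
  }
  for (nm in comparison) resolve_strategy(sc, nm)
  comparison
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: each iteration samples
#' every entry of the scenario's `psa_distributions` from its distribution,
#' runs both strategies of the comparison, and records the incremental
#' discounted cost and QALYs (first strategy minus second). Quadrant
#' fractions summarise the incremental cost-effectiveness plane, and the
#' cost-effectiveness acceptability curve (CEAC) gives the probability the
#' first strategy has positive net monetary benefit across a
#' willingness-to-pay grid.
#'
#' Sampled probabilities falling outside `[0, 1]` are resampled (counted);
#' a resample rate above 1% of probability draws aborts the analysis, since
#' it signals a badly specified distribution.
#'
#' @param sc A validated [scenario()].
#' @param n Number of Monte Carlo iterations (default 10000).
#' @param seed Random seed; identical seeds give bit-identical results.
#' @param comparison Character pair of strategy names (default: first two).
#' @param wtp_grid WTP values for the CEAC, USD/QALY.
#' @return A `psa_result`: `draws` (data.frame draw, delta_cost, delta_qaly,
#'   quadrant), `n`, `seed`, `fraction_dominant`, `fraction_cheaper`,
#'   `fraction_dominated`, `ceac` (data.frame wtp, prob_preferred),
#'   `resamples`, `comparison`.
#' @export
run_psa <- function(sc, n = 10000L, seed = sc$seed, comparison = NULL,
                    wtp_grid = seq(0, 100000, by = 10000)) {
  sc <- validate_scenario(sc)
  pair <- resolve_pair(sc, comparison)
  paths <- names(sc$psa_distributions)
  set.seed(seed)
  resamples <- 0L
  prob_draws <- 0L
  dc <- numeric(n); de <- numeric(n)
  for (i in seq_len(n)) {
    sci <- sc
    for (path in paths) {
      spec <- sc$psa_distributions[[path]]
      x <- sample_dist(spec)
      if (is_prob_path(path)) {
        prob_draws <- prob_draws + 1L
        tries <- 0L
        while (x < 0 || x > 1) {
          resamples <- resamples + 1L
          tries <- tries + 1L
          if (tries > 1000L) {
            stop("run_psa: cannot sample a probability in [0, 1] for '",
                 path, "'", call. = FALSE)
          }
          x <- sample_dist(spec)
        }
      }
      sci <- set_param(sci, path, x)
    }
    d <- incremental_deltas(sci, pair)
    dc[i] <- d[["delta_cost"]]
    de[i] <- d[["delta_qaly"]]
  }
  if (prob_draws > 0L && resamples > 0.01 * prob_draws) {
    stop("run_psa: probability resample rate ",
         sprintf("%.1f%%", 100 * resamples / prob_draws),
         " exceeds 1%; check the psa_distributions", call. = FALSE)
  }
  quadrant <- classify_plane(dc, de)
  ceac <- data.frame(
    wtp = wtp_grid,
    prob_preferred = vapply(wtp_grid, function(w) mean(w * de - dc > 0),
                            numeric(1))
  )
  structure(
    list(draws = data.frame(draw = seq_len(n), delta_cost = dc,
                            delta_qaly = de, quadrant = quadrant),
         n = n, seed = seed,
         fraction_dominant = mean(dc < 0 & de > 0),
         fraction_cheaper = mean(dc < 0),
         fraction_dominated = mean(dc > 0 & de < 0),
         ceac = ceac,
         resamples = resamples,
         comparison = pair),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %s vs %s, n = %d (seed %d)\n",
              x$comparison[1], x$comparison[2], x$n, x$seed))
  cat(sprintf("  dominant %.1f%%  cheaper %.1f%%  dominated %.1f%%\n",
              100 * x$fraction_dominant, 100 * x$fraction_cheaper,
              100 * x$fraction_dominated))
  invisible(x)
}

#' One-way deterministic sensitivity sweep
#'
#' Re-runs the base case at each of `n_points` equally spaced values of a
#' single parameter, all other parameters fixed, and records the incremental
#' discounted cost and QALYs of the comparison's first strategy over its
#' second.
#'
#' @inheritParams run_psa
#' @param parameter Dotted parameter path (see [get_param()]).
#' @param low,high Sweep bounds (`low < high`).
#' @param n_points Number of grid points (>= 2).
#' @return A data.frame with columns `value`, `delta_cost`, `delta_qaly`.
#' @export
one_way <- function(sc, parameter, low, high, n_points = 11L,
                    comparison = NULL) {
  sc <- validate_scenario(sc)
  pair <- resolve_pair(sc, comparison)
  get_param(sc, parameter)
  if (!(low < high)) stop("one_way: need low < high", call. = FALSE)
  if (n_points < 2L) stop("one_way: need n_points >= 2", call. = FALSE)
  grid <- seq(low, high, length.out = n_points)
  out <- t(vapply(grid, function(v) {
    incremental_deltas(set_param(sc, parameter, v), pair)
  }, numeric(2)))
  data.frame(value = grid, delta_cost = out[, "delta_cost"],
             delta_qaly = out[, "delta_qaly"])
}

#' Threshold (break-even) value of a parameter
#'
#' Finds the parameter value at which the incremental discounted cost
#' between the two compared strategies crosses zero, by bisection on
#' `[low, high]`. The incremental cost must change sign over the interval.
#'
#' @inheritParams one_way
#' @param tol Absolute tolerance on the incremental cost at the root, USD.
#' @return A `threshold_result`: `parameter`, `threshold_value`,
#'   `delta_cost_at_threshold`, `direction` (which strategy is the less
#'   expensive for parameter values above the threshold), `comparison`.
#' @export
find_threshold <- function(sc, parameter, low, high, tol = 0.01,
                           comparison = NULL) {
  sc <- validate_scenario(sc)
  pair <- resolve_pair(sc, comparison)
  g <- function(v) {
    incremental_deltas(set_param(sc, parameter, v), pair)[["delta_cost"]]
  }
  g_lo <- g(low); g_hi <- g(high)
  if (sign(g_lo) == sign(g_hi)) {
    stop("find_threshold: no threshold in range [", low, ", ", high,
         "]: incremental cost has the same sign (",
         sprintf("%.2f, %.2f", g_lo, g_hi), ") at both ends", call. = FALSE)
  }
  lo <- low; hi <- high
  mid <- (lo + hi) / 2; g_mid <- g(mid)
  while (abs(g_mid) > tol && (hi - lo) > max(1e-12, 1e-12 * abs(hi))) {
    if (sign(g_mid) == sign(g_lo)) {
      lo <- mid; g_lo <- g_mid
    } else {
      hi <- mid
    }
    mid <- (lo + hi) / 2; g_mid <- g(mid)
  }
  # above the threshold the sign of g_hi rules: positive incremental cost
  # means the comparison's second strategy is the cheaper one there
  structure(
    list(parameter = parameter,
         threshold_value = mid,
         delta_cost_at_threshold = g_mid,
         direction = if (g_hi > 0) pair[2] else pair[1],
         comparison = pair),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> %s = %.6g; '%s' is less expensive above it\n",
              x$parameter, x$threshold_value, x$direction))
  invisible(x)
}

#' Tornado analysis
#'
#' One-way sensitivity of the incremental discounted cost at the endpoints
#' of each parameter's plausible range, sorted by descending influence
#' (bar width).
#'
#' @inheritParams one_way
#' @param param_ranges Named list, parameter path to `c(low, high)`.
#' @return A `tornado_result` whose `entries` data.frame has columns
#'   `parameter`, `low`, `high`, `outcome_low`, `outcome_high`, `width`,
#'   sorted by descending `width`.
#' @export
tornado <- function(sc, param_ranges, comparison = NULL) {
  if (!length(param_ranges) || is.null(names(param_ranges))) {
    stop("tornado: param_ranges must be a non-empty named list", call. = FALSE)
  }
  pair <- resolve_pair(validate_scenario(sc), comparison)
  rows <- lapply(names(param_ranges), function(p) {
    r <- param_ranges[[p]]
    curve <- one_way(sc, p, r[1], r[2], n_points = 2L, comparison = pair)
    data.frame(parameter = p, low = r[1], high = r[2],
               outcome_low = curve$delta_cost[1],
               outcome_high = curve$delta_cost[2],
               stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, rows)
  entries$width <- abs(entries$outcome_high - entries$outcome_low)
  entries <- entries[order(-entries$width), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries, comparison = pair),
            class = "tornado_result")
}

#' @export
print.tornado_result <- function(x, ...) {
  cat(sprintf("<tornado_result> %s vs %s\n", x$comparison[1], x$comparison[2]))
  print(x$entries)
  invisible(x)
}
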