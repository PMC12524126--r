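#' Linear CAPS-5 to EQ-VAS map
#'
#' Health-state utilities are derived from CAPS-5 severity through a linear
#' regression onto the EuroQol Visual Analogue Scale (EQ-VAS, 0--100):
#' `EQ-VAS = intercept + slope * CAPS-5`, clamped to the instrument range.
#' Lower CAPS-5 (less severe PTSD) maps to higher EQ-VAS, so the slope must
#' be negative.
#'
#' The default coefficients (intercept 92, slope -0.68) place the
#' asymptomatic band midpoint near full health and the severe midpoint near
#' EQ-VAS 44, consistent with published PTSD utility gradients; both are
#' configurable because comparative results depend on utility differences,
#' not absolute levels.
#'
#' @param intercept EQ-VAS at CAPS-5 = 0.
#' @param slope EQ-VAS points per CAPS-5 point (negative).
#' @return A `regression_map` list.
#' @export
regression_map <- function(intercept = 92, slope = -0.68) {
  validate_regression(structure(list(intercept = intercept, slope = slope),
                                class = "regression_map"))
}

validate_regression <- function(reg) {
  if (!is.list(reg) || is.null(reg$intercept) || is.null(reg$slope)) {
    stop("regression: needs fields intercept and slope", call. = FALSE)
  }
  if (!is.numeric(reg$slope) || reg$slope >= 0) {
    stop("regression.slope: must be negative (lower CAPS-5 must map to ",
         "higher EQ-VAS)", call. = FALSE)
  }
  class(reg) <- "regression_map"
  reg
}

#' Predict EQ-VAS from a CAPS-5 score
#'
#' @param reg A [regression_map()].
#' @param caps5 CAPS-5 score(s) in `[0, 80]`.
#' @return EQ-VAS score(s), clamped to `[0, 100]`.
#' @export
#' @examples
#' caps5_to_eqvas(regression_map(), c(0, 40, 80))
caps5_to_eqvas <- function(reg, caps5) {
  reg <- validate_regression(reg)
  if (any(!is.finite(caps5)) || any(caps5 < 0 | caps5 > 80)) {
    stop("caps5 out of instrument range [0, 80]", call. = FALSE)
  }
  pmin(pmax(reg$intercept + reg$slope * caps5, 0), 100)
}

#' Utility of a severity band
#'
#' The cohort engine carries severity bands, not continuous scores, so each
#' band's utility is the EQ-VAS of its midpoint score divided by 100.
#'
#' @param reg A [regression_map()].
#' @param band Band label(s).
#' @param bands Band table, see [severity_bands()].
#' @return Utility value(s) in `[0, 1]`.
#' @export
band_utility <- function(reg, band, bands = severity_bands()) {
  mid <- vapply(band, band_midpoint, numeric(1), bands = bands)
  unname(caps5_to_eqvas(reg, mid) / 100)
}

#' Incremental comparison of two strategy runs
#'
#' Computes discounted incremental cost and QALYs of run `a` over run `b`,
#' the incremental cost-effectiveness ratio (ICER), and the
#' cost-effectiveness plane classification:
#' \describe{
#'   \item{dominant}{`a` cheaper and more effective.}
#'   \item{dominated}{`a` costlier and less effective.}
#'   \item{trade_off_ne}{costlier and at least as effective (north-east).}
#'   \item{trade_off_sw}{cheaper (or cost-equal) and at most as effective
#'     (south-west).}
#' }
#' The ICER is `NA` (undefined) when the QALY difference is zero. At the
#' willingness-to-pay threshold `wtp`, `preferred` reports whether `a` has
#' positive incremental net monetary benefit `wtp * dQALY - dCost`; at
#' `wtp = 0` this reduces to cost minimisation.
#'
#' @param a,b `run_result` objects from [accrue()] over the same horizon.
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @return An `incremental_result` list with `delta_cost`, `delta_qaly`,
#'   `icer`, `classification`, `preferred`, `wtp`.
#' @export
compare_runs <- function(a, b, wtp = 0) {
  stopifnot(inherits(a, "run_result"), inherits(b, "run_result"))
  if (length(a$per_cycle$cost) != length(b$per_cycle$cost)) {
    stop("compare_runs: runs have different horizons", call. = FALSE)
  }
  dc <- a$total_cost_discounted - b$total_cost_discounted
  de <- a$total_qaly_discounted - b$total_qaly_discounted
  structure(
    list(delta_cost = dc,
         delta_qaly = de,
         icer = if (de != 0) dc / de else NA_real_,
         classification = classify_plane(dc, de),
         preferred = (wtp * de - dc) > 0,
         wtp = wtp),
    class = "incremental_result"
  )
}

# Quadrant classification on the cost-effectiveness plane. Boundary draws
# (a zero difference) fall to the trade-off quadrants: dominance requires
# strictly lower cost AND strictly higher effect.
classify_plane <- function(delta_cost, delta_qaly) {
  ifelse(delta_cost < 0 & delta_qaly > 0, "dominant",
  ifelse(delta_cost > 0 & delta_qaly < 0, "dominated",
  ifelse(delta_cost <= 0, "trade_off_sw", "trade_off_ne")))
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("<incremental_result> dCost = %.2f USD, dQALY = %.4f (%s)\n",
              x$delta_cost, x$delta_qaly, x$classification))
  cat(sprintf("  ICER: %s   preferred at WTP %s: %s\n",
              if (is.na(x$icer)) "undefined" else sprintf("%.0f USD/QALY", x$icer),
              format(x$wtp), x$preferred))
  invisible(x)
}

#' @export
as.list.incremental_result <- function(x, ...) unclass(x)

#' Reweight a pooled treatment effect to a new subgroup mix
#'
#' Trial populations differ in composition (here: military vs. civilian
#' participants, where military PTSD responds less to treatment), so a pooled
#' CAPS-5 reduction estimated under one mix is not directly comparable to an
#' effect estimated under another. `normalize_effect` reweights subgroup
#' effects from a source mix to a target mix.
#'
#' Two usages:
#' \itemize{
#'   \item Known subgroup effects: supply `effect_by_subgroup`; the result is
#'     the target-mix weighted mean.
#'   \item Known pooled effect and subgroup effect ratio: supply `pooled`
#'     and `effect_ratio` (second subgroup relative to first); the two
#'     subgroup effects are solved from the source-mix pooling identity and
#'     then reweighted.
#' }
#'
#' @param effect_by_subgroup Named numeric vector of per-subgroup CAPS-5
#'   reductions (omit when using `pooled`).
#' @param source_mix,target_mix Named proportion vectors over the same
#'   subgroups, each summing to 1.
#' @param pooled Pooled effect under `source_mix`.
#' @param effect_ratio Ratio of the second subgroup's effect to the first's
#'   (two-subgroup case only).
#' @return The effect under `target_mix`.
#' @export
#' @examples
#' # shifting weight towards a better-responding subgroup raises the effect
#' normalize_effect(c(military = 4, civilian = 8),
#'                  source_mix = c(military = 0.5, civilian = 0.5),
#'                  target_mix = c(military = 0.2, civilian = 0.8))
normalize_effect <- function(effect_by_subgroup = NULL, source_mix, target_mix,
                             pooled = NULL, effect_ratio = NULL) {
  if (!setequal(names(source_mix), names(target_mix)) ||
      is.null(names(source_mix))) {
    stop("normalize_effect: source_mix and target_mix must be named over the ",
         "same subgroups", call. = FALSE)
  }
  target_mix <- target_mix[names(source_mix)]
  if (abs(sum(source_mix) - 1) > 1e-9 || abs(sum(target_mix) - 1) > 1e-9) {
    stop("normalize_effect: mixes must each sum to 1", call. = FALSE)
  }
  if (is.null(effect_by_subgroup)) {
    if (is.null(pooled) || is.null(effect_ratio)) {
      stop("normalize_effect: supply either effect_by_subgroup or both ",
           "pooled and effect_ratio", call. = FALSE)
    }
    if (length(source_mix) != 2L) {
      stop("normalize_effect: effect_ratio form requires exactly 2 subgroups",
           call. = FALSE)
    }
    # pooled = w1*e1 + w2*(r*e1)  =>  e1 = pooled / (w1 + w2*r)
    e1 <- pooled / (source_mix[1] + source_mix[2] * effect_ratio)
    effect_by_subgroup <- c(e1, effect_ratio * e1)
    names(effect_by_subgroup) <- names(source_mix)
  }
  if (!setequal(names(effect_by_subgroup), names(source_mix))) {
    stop("normalize_effect: effect_by_subgroup names must match the mixes",
         call. = FALSE)
  }
  unname(sum(target_mix * effect_by_subgroup[names(target_mix)]))
}
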