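# Default one-way ranges for tornado / threshold analysis: every dropout,
# relapse, retreatment, effect and cost parameter, swept around its base-case
# value (probabilities +/-25% relative, clipped away from the boundaries;
# costs +/-20%; effect means +/-25%).
default_param_ranges <- function(sc, comparison = NULL) {
  pair <- resolve_pair(sc, comparison)
  ranges <- list()
  for (nm in pair) {
    p <- sc$strategies[[nm]]
    pre <- paste0("strategies.", nm, ".")
    for (f in c("dropout_course_prob", "relapse_prob", "retreatment_prob")) {
      v <- p[[f]]
      if (v > 0) {
        ranges[[paste0(pre, f)]] <- c(max(0.75 * v, 1e-4), min(1.25 * v, 0.99))
      }
    }
    if (p$effect_mean > 0) {
      ranges[[paste0(pre, "effect_mean")]] <- c(0.75, 1.25) * p$effect_mean
    }
    if (p$per_course_cost > 0) {
      ranges[[paste0(pre, "per_course_cost")]] <- c(0.8, 1.2) * p$per_course_cost
    }
    if (p$annual_drug_cost > 0) {
      ranges[[paste0(pre, "annual_drug_cost")]] <- c(0.8, 1.2) * p$annual_drug_cost
    }
  }
  for (b in .symptomatic_bands) {
    v <- sc$state_costs[[b]]
    if (v > 0) ranges[[paste0("state_costs.", b)]] <- c(0.8, 1.2) * v
  }
  ranges
}

#' Run a full cost-effectiveness comparison
#'
#' Orchestrates the analysis surfaces for one strategy pair: the
#' deterministic base case (incremental discounted cost and QALYs, ICER,
#' dominance classification, per-year cost differences), probabilistic
#' sensitivity analysis, a tornado over the default parameter ranges, and
#' break-even thresholds on both strategies' dropout probabilities.
#'
#' @inheritParams run_psa
#' @param psa_n Monte Carlo iterations for the PSA.
#' @param scenario_id Label recorded in the report.
#' @param run_tornado,run_thresholds Toggle the deterministic analyses.
#' @return A `comparison_report`: `scenario_id`, `comparison`, `runs` (the
#'   two `run_result`s), `base` ([compare_runs()] result), `by_year`
#'   (data.frame year, delta_cost, delta_qaly, discounted), `psa`
#'   ([run_psa()] result), `tornado`, `thresholds` (data.frame), `seed`.
#' @export
run_comparison <- function(sc, comparison = NULL, psa_n = 10000L,
                           seed = sc$seed, scenario_id = "scenario",
                           run_tornado = TRUE, run_thresholds = TRUE) {
  sc <- validate_scenario(sc)
  pair <- resolve_pair(sc, comparison)
  a <- run_strategy(sc, pair[1])
  b <- run_strategy(sc, pair[2])
  base <- compare_runs(a, b, wtp = sc$wtp_per_qaly)
  by_year <- data.frame(
    year = a$cumulative_by_year$year,
    delta_cost = a$cumulative_by_year$cost_discounted -
      b$cumulative_by_year$cost_discounted,
    delta_qaly = a$cumulative_by_year$qaly_discounted -
      b$cumulative_by_year$qaly_discounted
  )
  psa <- if (psa_n > 0) run_psa(sc, n = psa_n, seed = seed, comparison = pair)
  torn <- if (run_tornado) {
    tornado(sc, default_param_ranges(sc, pair), comparison = pair)
  }
  thresholds <- NULL
  if (run_thresholds) {
    rows <- lapply(pair, function(nm) {
      path <- paste0("strategies.", nm, ".dropout_course_prob")
      th <- tryCatch(find_threshold(sc, path, 0.005, 0.6, comparison = pair),
                     error = function(e) NULL)
      if (is.null(th)) {
        data.frame(parameter = path, threshold_value = NA_real_,
                   cheaper_above = NA_character_, stringsAsFactors = FALSE)
      } else {
        data.frame(parameter = path, threshold_value = th$threshold_value,
                   cheaper_above = th$direction, stringsAsFactors = FALSE)
      }
    })
    thresholds <- do.call(rbind, rows)
  }
  structure(
    list(scenario_id = scenario_id, comparison = pair,
         runs = stats::setNames(list(a, b), pair),
         base = base, by_year = by_year, psa = psa, tornado = torn,
         thresholds = thresholds, seed = seed),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s: %s vs %s\n",
              x$scenario_id, x$comparison[1], x$comparison[2]))
  cat(sprintf("  base case: dCost %.0f USD, dQALY %.4f (%s)\n",
              x$base$delta_cost, x$base$delta_qaly, x$base$classification))
  for (i in seq_len(nrow(x$by_year))) {
    cat(sprintf("  year %d: cumulative dCost %.0f USD\n",
                x$by_year$year[i], x$by_year$delta_cost[i]))
  }
  if (!is.null(x$psa)) {
    cat(sprintf("  PSA (n = %d): dominant %.1f%%, cheaper %.1f%%\n",
                x$psa$n, 100 * x$psa$fraction_dominant,
                100 * x$psa$fraction_cheaper))
  }
  invisible(x)
}

scenario_digest <- function(sc) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(unclass(validate_scenario(sc))), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

#' Write report artifacts to a directory
#'
#' Writes the standard analysis files: `trace.csv` (tidy cohort traces for
#' both strategies), `psa_scatter.csv`, `tornado.csv`, `thresholds.csv` and
#' `report.json` (run metadata plus headline numbers). Identical inputs and
#' seed produce byte-identical outputs.
#'
#' @param report A [run_comparison()] report.
#' @param sc The scenario the report was produced from.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, sc, dir) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  traces <- do.call(rbind, lapply(report$comparison, function(nm) {
    df <- as.data.frame(run_cohort(sc, nm))
    df$strategy <- nm
    df[, c("strategy", "cycle", "state", "occupancy")]
  }))
  utils::write.csv(traces, file.path(dir, "trace.csv"), row.names = FALSE)
  if (!is.null(report$psa)) {
    utils::write.csv(report$psa$draws, file.path(dir, "psa_scatter.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$tornado)) {
    utils::write.csv(report$tornado$entries, file.path(dir, "tornado.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$thresholds)) {
    utils::write.csv(report$thresholds, file.path(dir, "thresholds.csv"),
                     row.names = FALSE)
  }
  meta <- list(
    scenario_id = report$scenario_id,
    package_version = as.character(utils::packageVersion("ptsdcea")),
    seed = report$seed,
    parameter_digest = scenario_digest(sc),
    comparison = as.list(report$comparison),
    base = list(delta_cost = report$base$delta_cost,
                delta_qaly = report$base$delta_qaly,
                icer = if (is.na(report$base$icer)) NULL else report$base$icer,
                classification = report$base$classification),
    by_year = report$by_year,
    psa = if (!is.null(report$psa)) list(
      n = report$psa$n,
      fraction_dominant = report$psa$fraction_dominant,
      fraction_cheaper = report$psa$fraction_cheaper,
      fraction_dominated = report$psa$fraction_dominated
    )
  )
  jsonlite::write_json(meta, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
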