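#' Define a treatment strategy
#'
#' A therapy profile bundles everything the engine needs about one treatment
#' arm: its course cost and schedule, its quarterly dynamics (dropout,
#' relapse, retreatment) and its effectiveness as a CAPS-5 score-reduction
#' distribution.
#'
#' Published dropout and relapse rates are typically trial-duration figures
#' spanning about one quarter (a course of ~13.5 sessions), so by default
#' they apply directly on the quarterly cycle scale
#' (`course_cycles = relapse_cycles = 1`). Rates quoted on a longer horizon
#' (e.g. an annual non-adherence figure) declare it via `course_cycles` /
#' `relapse_cycles` and the engine rescales them with [per_cycle_prob()].
#'
#' @param name Strategy identifier (lowercase letters, digits, underscore).
#' @param per_session_cost,sessions_per_course,per_course_cost Course cost
#'   structure in USD; `per_course_cost` defaults to the product (rounded to
#'   the dollar). Sessions may be fractional.
#' @param annual_drug_cost Annual medication cost in USD (0 if none).
#' @param dropout_course_prob Probability of dropping out over one course.
#' @param relapse_prob Probability of relapse over `relapse_cycles` cycles.
#' @param retreatment_prob Probability a relapsing patient re-enters therapy
#'   (otherwise they remain untreated at their entry severity).
#' @param effect_mean Mean CAPS-5 reduction per course.
#' @param effect_dispersion Dispersion of the effect distribution.
#' @param effect_dispersion_kind `"sd"` or `"ci95"` (full 95% CI width).
#' @param course_cycles Quarterly cycles spanned by one course.
#' @param relapse_cycles Quarterly cycles spanned by `relapse_prob`.
#' @return A `therapy_profile` list.
#' @export
#' @examples
#' therapy_profile("psychotherapy", per_session_cost = 147,
#'                 sessions_per_course = 13.5, per_course_cost = 1985,
#'                 dropout_course_prob = 0.206, relapse_prob = 0.14,
#'                 retreatment_prob = 0.5, effect_mean = 6.25,
#'                 effect_dispersion = 4.94)
therapy_profile <- function(name,
                            per_session_cost = 0,
                            sessions_per_course = 0,
                            per_course_cost = round(per_session_cost * sessions_per_course),
                            annual_drug_cost = 0,
                            dropout_course_prob = 0,
                            relapse_prob = 0,
                            retreatment_prob = 0.5,
                            effect_mean = 0,
                            effect_dispersion = 0,
                            effect_dispersion_kind = c("sd", "ci95"),
                            course_cycles = 1,
                            relapse_cycles = 1) {
  effect_dispersion_kind <- match.arg(effect_dispersion_kind)
  p <- structure(
    list(name = name,
         per_session_cost = per_session_cost,
         sessions_per_course = sessions_per_course,
         per_course_cost = per_course_cost,
         annual_drug_cost = annual_drug_cost,
         dropout_course_prob = dropout_course_prob,
         relapse_prob = relapse_prob,
         retreatment_prob = retreatment_prob,
         effect_mean = effect_mean,
         effect_dispersion = effect_dispersion,
         effect_dispersion_kind = effect_dispersion_kind,
         course_cycles = course_cycles,
         relapse_cycles = relapse_cycles),
    class = "therapy_profile"
  )
  validate_profile(p)
  p
}

# SD of the per-course effect distribution, honouring the dispersion kind.
effect_sd <- function(profile) {
  if (identical(profile$effect_dispersion_kind, "ci95")) {
    profile$effect_dispersion / 3.92
  } else {
    profile$effect_dispersion
  }
}

validate_profile <- function(p) {
  nm <- p$name
  if (!is.character(nm) || length(nm) != 1L || !grepl("^[a-z][a-z0-9_]*$", nm)) {
    stop("therapy profile name must match ^[a-z][a-z0-9_]*$ (got '", nm, "')",
         call. = FALSE)
  }
  for (f in c("dropout_course_prob", "relapse_prob", "retreatment_prob")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("strategy '", nm, "': ", f, " must be a probability in [0, 1] (got ",
           format(v), ")", call. = FALSE)
    }
  }
  if (p$dropout_course_prob >= 1) {
    stop("strategy '", nm, "': dropout_course_prob must be < 1", call. = FALSE)
  }
  for (f in c("per_session_cost", "sessions_per_course", "per_course_cost",
              "annual_drug_cost", "effect_dispersion")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("strategy '", nm, "': ", f, " must be >= 0 (got ", format(v), ")",
           call. = FALSE)
    }
  }
  if (p$per_session_cost > 0 && p$sessions_per_course > 0) {
    expected <- p$per_session_cost * p$sessions_per_course
    if (abs(p$per_course_cost - expected) > 0.5) {
      stop("strategy '", nm, "': per_course_cost (", p$per_course_cost,
           ") must equal per_session_cost * sessions_per_course (",
           format(expected), ") to within USD 0.5", call. = FALSE)
    }
  }
  if (!is.numeric(p$effect_mean) || is.na(p$effect_mean)) {
    stop("strategy '", nm, "': effect_mean must be numeric", call. = FALSE)
  }
  if (p$course_cycles < 1) {
    stop("strategy '", nm, "': course_cycles must be >= 1", call. = FALSE)
  }
  if (p$relapse_cycles < 1) {
    stop("strategy '", nm, "': relapse_cycles must be >= 1", call. = FALSE)
  }
  invisible(p)
}

.profile_fields <- c("name", "per_session_cost", "sessions_per_course",
                     "per_course_cost", "annual_drug_cost",
                     "dropout_course_prob", "relapse_prob",
                     "retreatment_prob", "effect_mean", "effect_dispersion",
                     "effect_dispersion_kind", "course_cycles",
                     "relapse_cycles")

#' Assemble a model scenario
#'
#' A scenario is the complete specification of one cost-effectiveness
#' comparison: the strategies, the quarterly care cost and death probability
#' for each severity band, the analysis horizon and discount rate, the
#' CAPS-5 to EQ-VAS regression used for utilities, and the parameter
#' distributions for probabilistic sensitivity analysis.
#'
#' @param strategies List of [therapy_profile()] objects (at least 2; a
#'   comparison is always between a named pair, by default the first two).
#' @param state_costs Named list, band to quarterly non-therapy care cost in
#'   USD. Asymptomatic defaults to 0.
#' @param mortality Named list, band to quarterly death probability;
#'   must be non-decreasing with severity.
#' @param bands Severity band table; see [severity_bands()].
#' @param horizon_cycles Number of quarterly cycles (default 12 = 3 years).
#' @param cycle_length_years Cycle length in years (default 0.25).
#' @param annual_discount_rate Annual discount rate applied to both costs and
#'   utilities (default 0.03).
#' @param wtp_per_qaly Willingness-to-pay threshold in USD/QALY (default 0).
#' @param initial_distribution Named list, band to starting proportion of the
#'   cohort (on treatment); must sum to 1.
#' @param regression CAPS-5 to EQ-VAS map; see [regression_map()].
#' @param psa_distributions Named list, dotted parameter path to
#'   [dist_spec()] (see [set_param()] for the path grammar).
#' @param seed Default random seed for stochastic analyses.
#' @param half_cycle_correction Value states at the mean of start- and
#'   end-of-cycle occupancy instead of start-of-cycle (default FALSE).
#' @param bill_therapy_every_cycle If TRUE (default) therapy course cost is
#'   billed every on-treatment cycle (patients repeat courses until
#'   asymptomatic); if FALSE only during the first course.
#' @return A validated `scenario` object.
#' @export
scenario <- function(strategies,
                     state_costs,
                     mortality = list(asymptomatic = 0.0005, mild = 0.00065,
                                      moderate = 0.0008, severe = 0.001),
                     bands = severity_bands(),
                     horizon_cycles = 12L,
                     cycle_length_years = 0.25,
                     annual_discount_rate = 0.03,
                     wtp_per_qaly = 0,
                     initial_distribution = list(severe = 1 / 3, moderate = 1 / 3,
                                                 mild = 1 / 3),
                     regression = regression_map(),
                     psa_distributions = list(),
                     seed = 1L,
                     half_cycle_correction = FALSE,
                     bill_therapy_every_cycle = TRUE) {
  sc <- structure(
    list(strategies = strategies,
         state_costs = state_costs,
         mortality = mortality,
         bands = bands,
         horizon_cycles = horizon_cycles,
         cycle_length_years = cycle_length_years,
         annual_discount_rate = annual_discount_rate,
         wtp_per_qaly = wtp_per_qaly,
         initial_distribution = initial_distribution,
         regression = regression,
         psa_distributions = psa_distributions,
         seed = seed,
         half_cycle_correction = half_cycle_correction,
         bill_therapy_every_cycle = bill_therapy_every_cycle),
    class = "scenario"
  )
  validate_scenario(sc)
}

#' Validate a scenario against the schema invariants
#'
#' Checks every structural invariant (probabilities in range, costs
#' non-negative, initial distribution summing to one, contiguous bands,
#' mortality non-decreasing with severity, course-cost consistency) and
#' normalises field order. Errors name the offending field and constraint.
#'
#' @param sc A `scenario`.
#' @return The normalised scenario, invisibly usable in pipelines.
#' @export
validate_scenario <- function(sc) {
  if (!inherits(sc, "scenario")) stop("not a scenario object", call. = FALSE)
  sc$bands <- validate_bands(sc$bands)

  if (!is.list(sc$strategies) || length(sc$strategies) < 2L) {
    stop("strategies: need at least 2 therapy profiles", call. = FALSE)
  }
  nms <- vapply(sc$strategies, function(p) p$name, character(1))
  if (anyDuplicated(nms)) {
    stop("strategies: duplicate strategy name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  names(sc$strategies) <- nms
  for (p in sc$strategies) validate_profile(p)

  sc$state_costs <- check_band_map(sc$state_costs, "state_costs",
                                   default_asym = 0)
  if (any(unlist(sc$state_costs) < 0)) {
    stop("state_costs: quarterly costs must be >= 0", call. = FALSE)
  }
  sc$mortality <- check_band_map(sc$mortality, "mortality")
  mort <- unlist(sc$mortality[.band_labels])
  if (any(mort < 0 | mort > 1)) {
    stop("mortality: quarterly death probabilities must be in [0, 1]",
         call. = FALSE)
  }
  # .band_labels runs severe -> asymptomatic, so severity-non-decreasing
  # mortality means the vector is non-increasing in this order
  if (any(diff(mort) > 0)) {
    stop("mortality: death probability must be non-decreasing with severity",
         call. = FALSE)
  }

  if (sc$horizon_cycles < 1 || sc$horizon_cycles != round(sc$horizon_cycles)) {
    stop("horizon_cycles: must be a positive integer", call. = FALSE)
  }
  if (sc$cycle_length_years <= 0) {
    stop("cycle_length_years: must be > 0", call. = FALSE)
  }
  if (sc$annual_discount_rate < 0) {
    stop("annual_discount_rate: must be >= 0", call. = FALSE)
  }

  init <- sc$initial_distribution
  bad <- setdiff(names(init), .band_labels)
  if (length(bad)) {
    stop("initial_distribution: unknown band(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (b in setdiff(.band_labels, names(init))) init[[b]] <- 0
  init <- init[.band_labels]
  iv <- unlist(init)
  if (any(iv < 0)) {
    stop("initial_distribution: proportions must be >= 0", call. = FALSE)
  }
  if (abs(sum(iv) - 1) > 1e-9) {
    stop("initial_distribution: proportions must sum to 1 (got ",
         format(sum(iv), digits = 12), ")", call. = FALSE)
  }
  if (init$asymptomatic > 0) {
    stop("initial_distribution: cohort must start in a symptomatic band ",
         "(asymptomatic proportion must be 0)", call. = FALSE)
  }
  sc$initial_distribution <- init

  sc$regression <- validate_regression(sc$regression)

  if (length(sc$psa_distributions)) {
    if (is.null(names(sc$psa_distributions)) ||
        any(!nzchar(names(sc$psa_distributions)))) {
      stop("psa_distributions: entries must be named by parameter path",
           call. = FALSE)
    }
    for (path in names(sc$psa_distributions)) {
      get_param(sc, path)  # errors if the path does not resolve
      if (!inherits(sc$psa_distributions[[path]], "dist_spec")) {
        stop("psa_distributions['", path, "']: not a dist_spec", call. = FALSE)
      }
    }
  }
  invisible(sc)
}

check_band_map <- function(x, field, default_asym = NULL) {
  if (!is.list(x)) x <- as.list(x)
  bad <- setdiff(names(x), .band_labels)
  if (length(bad)) {
    stop(field, ": unknown band(s) ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!("asymptomatic" %in% names(x)) && !is.null(default_asym)) {
    x$asymptomatic <- default_asym
  }
  missing <- setdiff(.band_labels, names(x))
  if (length(missing)) {
    stop(field, ": missing band(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x[.band_labels]
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", length(x$strategies), " strategies: ",
      paste(names(x$strategies), collapse = ", "), "\n", sep = "")
  cat(sprintf("  horizon: %d cycles x %.2f yr, discount %.1f%%/yr, WTP %s/QALY\n",
              x$horizon_cycles, x$cycle_length_years,
              100 * x$annual_discount_rate, format(x$wtp_per_qaly)))
  cat("  PSA parameters:", length(x$psa_distributions), "\n")
  invisible(x)
}

# ---- parameter paths --------------------------------------------------------

# Dotted parameter paths give probabilistic and deterministic sensitivity
# analysis a single namespace:
#   strategies.<name>.<field>   e.g. strategies.psychotherapy.dropout_course_prob
#   state_costs.<band>          e.g. state_costs.moderate
#   mortality.<band>
#   regression.intercept / regression.slope
#   annual_discount_rate, wtp_per_qaly (top-level scalars)

.top_scalar_params <- c("annual_discount_rate", "wtp_per_qaly",
                        "cycle_length_years")

#' Read or set a scenario parameter by dotted path
#'
#' @param sc A `scenario`.
#' @param path Dotted parameter path, e.g.
#'   `"strategies.psychotherapy.dropout_course_prob"`, `"state_costs.mild"`,
#'   `"mortality.severe"`, `"regression.slope"`.
#' @param value Replacement value (`set_param`).
#' @return `get_param`: the value. `set_param`: the modified scenario (no
#'   revalidation -- sensitivity analyses sweep parameters through ranges the
#'   base-case validator would reject piecemeal).
#' @export
get_param <- function(sc, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  err <- function() {
    stop("unknown parameter path '", path, "'; valid paths include:\n  ",
         paste(utils::head(list_params(sc), 40), collapse = "\n  "),
         call. = FALSE)
  }
  if (length(parts) == 1L) {
    if (!(parts %in% .top_scalar_params)) err()
    return(sc[[parts]])
  }
  if (parts[1] == "strategies" && length(parts) == 3L) {
    p <- sc$strategies[[parts[2]]]
    if (is.null(p) || !(parts[3] %in% .profile_fields)) err()
    return(p[[parts[3]]])
  }
  if (parts[1] %in% c("state_costs", "mortality") && length(parts) == 2L) {
    if (!(parts[2] %in% .band_labels)) err()
    return(sc[[parts[1]]][[parts[2]]])
  }
  if (parts[1] == "regression" && length(parts) == 2L &&
      parts[2] %in% c("intercept", "slope")) {
    return(sc$regression[[parts[2]]])
  }
  err()
}

#' @rdname get_param
#' @export
set_param <- function(sc, path, value) {
  get_param(sc, path)  # path check
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1L) {
    sc[[parts]] <- value
  } else if (parts[1] == "strategies") {
    sc$strategies[[parts[2]]][[parts[3]]] <- value
  } else if (parts[1] == "regression") {
    sc$regression[[parts[2]]] <- value
  } else {
    sc[[parts[1]]][[parts[2]]] <- value
  }
  sc
}

#' @rdname get_param
#' @export
list_params <- function(sc) {
  numeric_fields <- setdiff(.profile_fields,
                            c("name", "effect_dispersion_kind"))
  c(
    as.vector(t(outer(paste0("strategies.", names(sc$strategies), "."),
                      numeric_fields, paste0))),
    paste0("state_costs.", .band_labels),
    paste0("mortality.", .band_labels),
    c("regression.intercept", "regression.slope"),
    .top_scalar_params
  )
}

# ---- file I/O ---------------------------------------------------------------

.scenario_top_keys <- c("strategies", "state_costs", "mortality", "bands",
                        "horizon_cycles", "cycle_length_years",
                        "annual_discount_rate", "wtp_per_qaly",
                        "initial_distribution", "regression",
                        "psa_distributions", "seed", "half_cycle_correction",
                        "bill_therapy_every_cycle")

#' Read and write scenario files
#'
#' Scenarios are stored as YAML with a fixed schema and canonical key order,
#' so saved files diff cleanly. `load_scenario` rejects unknown keys and
#' validates every invariant; `save_scenario` writes a file that
#' `load_scenario` reads back into an identical scenario.
#'
#' @param path File path.
#' @param sc A `scenario`.
#' @return `load_scenario`: a validated `scenario`. `save_scenario`: `path`,
#'   invisibly.
#' @seealso [example_scenario()] for the shipped base cases.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) {
    stop("scenario file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  extra <- setdiff(names(raw), .scenario_top_keys)
  if (length(extra)) {
    stop("scenario file: unknown key(s) ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  need <- c("strategies", "state_costs")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("scenario file: missing required key(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  strategies <- lapply(raw$strategies, profile_from_list)
  bands <- if (is.null(raw$bands)) severity_bands() else bands_from_list(raw$bands)
  psa <- list()
  if (!is.null(raw$psa_distributions)) {
    psa <- lapply(seq_along(raw$psa_distributions), function(i) {
      dist_spec_from_list(raw$psa_distributions[[i]],
                          where = names(raw$psa_distributions)[i])
    })
    names(psa) <- names(raw$psa_distributions)
  }
  args <- list(
    strategies = strategies,
    state_costs = raw$state_costs,
    bands = bands,
    psa_distributions = psa
  )
  for (k in c("mortality", "horizon_cycles", "cycle_length_years",
              "annual_discount_rate", "wtp_per_qaly", "initial_distribution",
              "seed", "half_cycle_correction", "bill_therapy_every_cycle")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  if (!is.null(raw$regression)) {
    args$regression <- regression_map(intercept = raw$regression$intercept,
                                      slope = raw$regression$slope)
  }
  do.call(scenario, args)
}

profile_from_list <- function(x) {
  extra <- setdiff(names(x), .profile_fields)
  if (length(extra)) {
    stop("strategy '", x$name %||% "?", "': unknown field(s) ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  do.call(therapy_profile, x)
}

bands_from_list <- function(x) {
  df <- do.call(rbind, lapply(x, function(r) {
    data.frame(label = r$label, caps5_low = as.integer(r$caps5_low),
               caps5_high = as.integer(r$caps5_high), stringsAsFactors = FALSE)
  }))
  validate_bands(df)
}

#' @rdname load_scenario
#' @export
save_scenario <- function(sc, path) {
  sc <- validate_scenario(sc)
  out <- list(
    strategies = lapply(unname(sc$strategies), function(p) {
      unclass(p)[.profile_fields]
    }),
    state_costs = sc$state_costs[.band_labels],
    mortality = sc$mortality[.band_labels],
    bands = lapply(seq_len(nrow(sc$bands)), function(i) {
      list(label = sc$bands$label[i],
           caps5_low = sc$bands$caps5_low[i],
           caps5_high = sc$bands$caps5_high[i])
    }),
    horizon_cycles = as.integer(sc$horizon_cycles),
    cycle_length_years = sc$cycle_length_years,
    annual_discount_rate = sc$annual_discount_rate,
    wtp_per_qaly = sc$wtp_per_qaly,
    initial_distribution = sc$initial_distribution[.band_labels],
    regression = list(intercept = sc$regression$intercept,
                      slope = sc$regression$slope),
    psa_distributions = lapply(sc$psa_distributions, dist_spec_to_list),
    seed = as.integer(sc$seed),
    half_cycle_correction = sc$half_cycle_correction,
    bill_therapy_every_cycle = sc$bill_therapy_every_cycle
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Shipped base-case scenarios
#'
#' Three base cases are installed with the package:
#' \describe{
#'   \item{`nf_vs_psychotherapy`}{Adjunctive neurofeedback (NF + OT) vs.
#'     trauma-focused psychotherapy.}
#'   \item{`nf_vs_pharmacotherapy`}{NF + OT vs. pharmacotherapy.}
#'   \item{`prism_vs_each`}{Amygdala-EFP neurofeedback (Prism) vs. both
#'     comparators (3 strategies; compare pairwise).}
#' }
#'
#' @param name Fixture name.
#' @return A validated `scenario`.
#' @export
#' @examples
#' sc <- example_scenario("nf_vs_psychotherapy")
#' names(sc$strategies)
example_scenario <- function(name = c("nf_vs_psychotherapy",
                                      "nf_vs_pharmacotherapy",
                                      "prism_vs_each")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "ptsdcea",
                      mustWork = TRUE)
  load_scenario(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
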