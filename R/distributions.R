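#' Construct a parameter distribution by method of moments
#'
#' Builds the sampling distribution used in probabilistic sensitivity analysis
#' from a published point estimate and dispersion. Gamma distributions model
#' positive quantities (costs), beta distributions model probabilities, and
#' normal distributions model effect estimates on the CAPS-5 scale. The
#' returned parameters reproduce the requested mean and standard deviation
#' exactly (method of moments).
#'
#' Dispersions reported as a full 95% confidence-interval width are converted
#' to a standard deviation as `width / 3.92` (the normal-theory convention).
#'
#' @param mean Point estimate (the distribution mean).
#' @param dispersion Standard deviation, or full 95% CI width when
#'   `kind = "ci95"`.
#' @param family One of `"gamma"`, `"beta"`, `"normal"`, `"fixed"`.
#' @param kind How `dispersion` is expressed: `"sd"` (default) or `"ci95"`.
#' @return A `dist_spec` list with elements `family`, `param_a`, `param_b`,
#'   `derived_from`. Parameterisation: gamma (shape, scale); beta (alpha,
#'   beta); normal (mean, sd); fixed (value, 0).
#' @export
#' @examples
#' fit_distribution(0.174, 0.05, "beta")           # relapse probability
#' fit_distribution(7.01, 12.66 - 1.36, "normal", kind = "ci95")
fit_distribution <- function(mean, dispersion, family = c("gamma", "beta", "normal", "fixed"),
                             kind = c("sd", "ci95")) {
  family <- match.arg(family)
  kind <- match.arg(kind)
  if (family == "fixed") {
    return(dist_spec("fixed", mean, 0, derived_from = c(mean = mean, sd = 0)))
  }
  if (!is.finite(mean) || !is.finite(dispersion) || dispersion <= 0) {
    stop("fit_distribution: dispersion must be a positive finite number",
         call. = FALSE)
  }
  sd <- if (kind == "ci95") dispersion / 3.92 else dispersion
  spec <- switch(family,
    gamma = {
      if (mean <= 0) stop("fit_distribution: gamma requires mean > 0", call. = FALSE)
      shape <- mean^2 / sd^2
      scale <- sd^2 / mean
      dist_spec("gamma", shape, scale, derived_from = c(mean = mean, sd = sd))
    },
    beta = {
      if (mean <= 0 || mean >= 1) {
        stop("fit_distribution: beta requires mean in (0, 1)", call. = FALSE)
      }
      v <- mean * (1 - mean)
      if (v <= sd^2) {
        stop("fit_distribution: beta moments infeasible: need mean*(1-mean) > sd^2 ",
             "(got ", signif(v, 4), " <= ", signif(sd^2, 4),
             "); a beta variable on [0,1] cannot have that much variance",
             call. = FALSE)
      }
      nu <- v / sd^2 - 1
      dist_spec("beta", mean * nu, (1 - mean) * nu,
                derived_from = c(mean = mean, sd = sd))
    },
    normal = dist_spec("normal", mean, sd, derived_from = c(mean = mean, sd = sd))
  )
  spec
}

#' @rdname fit_distribution
#' @param param_a,param_b Family parameters (see `fit_distribution`).
#' @param derived_from Optional named vector `c(mean=, sd=)` recording the
#'   moments the parameters were derived from.
#' @export
dist_spec <- function(family, param_a, param_b, derived_from = NULL) {
  family <- match.arg(family, c("gamma", "beta", "normal", "fixed"))
  if (family %in% c("gamma", "beta") && (param_a <= 0 || param_b <= 0)) {
    stop("dist_spec: ", family, " parameters must be > 0", call. = FALSE)
  }
  if (family == "normal" && param_b < 0) {
    stop("dist_spec: normal sd must be >= 0", call. = FALSE)
  }
  structure(
    list(family = family, param_a = param_a, param_b = param_b,
         derived_from = derived_from),
    class = "dist_spec"
  )
}

#' Analytic moments of a `dist_spec`
#'
#' @param spec A `dist_spec`.
#' @return Named vector `c(mean=, var=)`.
#' @export
dist_moments <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  with(spec, switch(family,
    gamma  = c(mean = param_a * param_b, var = param_a * param_b^2),
    beta   = {
      s <- param_a + param_b
      c(mean = param_a / s, var = param_a * param_b / (s^2 * (s + 1)))
    },
    normal = c(mean = param_a, var = param_b^2),
    fixed  = c(mean = param_a, var = 0)
  ))
}

#' Sample from a `dist_spec`
#'
#' @param spec A `dist_spec`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "dist_spec"))
  with(spec, switch(family,
    gamma  = stats::rgamma(n, shape = param_a, scale = param_b),
    beta   = stats::rbeta(n, param_a, param_b),
    normal = stats::rnorm(n, param_a, param_b),
    fixed  = rep_len(param_a, n)
  ))
}

#' @export
print.dist_spec <- function(x, ...) {
  m <- dist_moments(x)
  cat(sprintf("<dist_spec> %s(%.6g, %.6g)  mean=%.6g sd=%.6g\n",
              x$family, x$param_a, x$param_b, m["mean"], sqrt(m["var"])))
  invisible(x)
}

dist_spec_to_list <- function(spec) {
  out <- list(family = spec$family, param_a = spec$param_a, param_b = spec$param_b)
  if (!is.null(spec$derived_from)) {
    out$derived_from <- as.list(spec$derived_from)
  }
  out
}

dist_spec_from_list <- function(x, where = "psa_distributions") {
  need <- c("family", "param_a", "param_b")
  if (!all(need %in% names(x))) {
    stop(where, ": distribution needs fields ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(x), c(need, "derived_from"))
  if (length(extra)) {
    stop(where, ": unknown distribution field(s) ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  df <- if (!is.null(x$derived_from)) unlist(x$derived_from) else NULL
  dist_spec(x$family, x$param_a, x$param_b, derived_from = df)
}
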