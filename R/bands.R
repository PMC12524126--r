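#' CAPS-5 severity bands
#'
#' The model stratifies PTSD severity into four contiguous bands of the
#' Clinician-Administered PTSD Scale for DSM-5 (CAPS-5, 0--80, lower is
#' better): severe 60--80, moderate 40--59, mild 20--39 and asymptomatic
#' 0--19. Bands are ordered from most to least severe.
#'
#' @return A data.frame with columns `label`, `caps5_low`, `caps5_high`.
#' @export
#' @examples
#' severity_bands()
severity_bands <- function() {
  data.frame(
    label      = c("severe", "moderate", "mild", "asymptomatic"),
    caps5_low  = c(60L, 40L, 20L, 0L),
    caps5_high = c(80L, 59L, 39L, 19L),
    stringsAsFactors = FALSE
  )
}

# Symptomatic bands, most to least severe
.symptomatic_bands <- c("severe", "moderate", "mild")
.band_labels <- c("severe", "moderate", "mild", "asymptomatic")

band_row <- function(band, bands = severity_bands()) {
  i <- match(band, bands$label)
  if (is.na(i)) {
    stop("unknown severity band '", band, "'; expected one of ",
         paste(bands$label, collapse = ", "), call. = FALSE)
  }
  bands[i, , drop = FALSE]
}

band_width <- function(band, bands = severity_bands()) {
  r <- band_row(band, bands)
  r$caps5_high - r$caps5_low
}

band_midpoint <- function(band, bands = severity_bands()) {
  r <- band_row(band, bands)
  (r$caps5_low + r$caps5_high) / 2
}

# The next milder band (mild -> asymptomatic); errors on asymptomatic.
band_below <- function(band) {
  i <- match(band, .band_labels)
  if (is.na(i)) stop("unknown severity band '", band, "'", call. = FALSE)
  if (band == "asymptomatic") {
    stop("asymptomatic has no milder band", call. = FALSE)
  }
  .band_labels[i + 1L]
}

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands))
  need <- c("label", "caps5_low", "caps5_high")
  if (!all(need %in% names(bands))) {
    stop("bands: missing column(s) ",
         paste(setdiff(need, names(bands)), collapse = ", "), call. = FALSE)
  }
  if (!setequal(bands$label, .band_labels)) {
    stop("bands: labels must be exactly ",
         paste(.band_labels, collapse = ", "), call. = FALSE)
  }
  bands <- bands[match(.band_labels, bands$label), ]
  if (any(bands$caps5_low > bands$caps5_high)) {
    stop("bands: caps5_low must not exceed caps5_high", call. = FALSE)
  }
  # contiguous, disjoint, decreasing severity
  for (i in seq_len(nrow(bands) - 1L)) {
    if (bands$caps5_low[i] != bands$caps5_high[i + 1L] + 1L) {
      stop("bands: '", bands$label[i], "' and '", bands$label[i + 1L],
           "' must be contiguous and disjoint", call. = FALSE)
    }
  }
  invisible(bands)
}
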