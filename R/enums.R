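#' Ordered category scales used throughout the package
#'
#' Three ordered scales structure the analysis:
#'
#' * **Acute stress categories** grade a single day's apparent temperature
#'   (CCI, degrees C) into six bands: no stress (< 25), mild (25-30), moderate
#'   (30-35), strong (35-40), extreme (40-45) and extreme danger (>= 45).
#'   Bands are half-open `[lo, hi)`, so a CCI of exactly 30 is "moderate".
#' * **Chronic risk classes** grade a location's mean Annual Thermal Load
#'   (degrees C x days) into five bands: low (< 100), moderate (100-500),
#'   high (500-1200), very high (1200-2000) and extreme (> 2000). Lower
#'   bounds are inclusive except that extreme is strictly above 2000, so an
#'   ATL of exactly 2000 is "very_high".
#' * **Discomfort intensities** are the affective-state grades of the
#'   Welfare Footprint Framework: none < annoying < hurtful < disabling <
#'   excruciating.
#'
#' @name scales
#' @keywords internal
NULL

STRESS_LEVELS <- c("no_stress", "mild", "moderate", "strong", "extreme",
                   "extreme_danger")
STRESS_BREAKS <- c(-Inf, 25, 30, 35, 40, 45, Inf)

RISK_LEVELS <- c("low", "moderate", "high", "very_high", "extreme")
RISK_BREAKS <- c(-Inf, 100, 500, 1200, 2000, Inf)

INTENSITY_LEVELS <- c("none", "annoying", "hurtful", "disabling",
                      "excruciating")

PHASE_NAMES <- c("I", "II", "III")

#' @rdname scales
#' @param x character vector of level names.
#' @export
stress_factor <- function(x) {
  bad <- setdiff(unique(as.character(x)), c(STRESS_LEVELS, NA))
  if (length(bad)) stop("unknown stress category: ", paste(bad, collapse = ", "))
  factor(as.character(x), levels = STRESS_LEVELS, ordered = TRUE)
}

#' @rdname scales
#' @export
risk_factor <- function(x) {
  bad <- setdiff(unique(as.character(x)), c(RISK_LEVELS, NA))
  if (length(bad)) stop("unknown risk class: ", paste(bad, collapse = ", "))
  factor(as.character(x), levels = RISK_LEVELS, ordered = TRUE)
}

#' @rdname scales
#' @export
intensity_factor <- function(x) {
  bad <- setdiff(unique(as.character(x)), c(INTENSITY_LEVELS, NA))
  if (length(bad)) stop("unknown intensity: ", paste(bad, collapse = ", "))
  factor(as.character(x), levels = INTENSITY_LEVELS, ordered = TRUE)
}
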