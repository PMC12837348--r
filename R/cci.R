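#' Comprehensive Climate Index (CCI) adjustment factors
#'
#' The CCI expresses environmental heat load on cattle as an apparent
#' temperature: `CCI = Ta + FRH + FWS + FRAD`, where the three additive
#' corrections account for relative humidity, convective cooling by wind, and
#' solar radiation load.
#'
#' Two factor sets are provided:
#'
#' * `"published"`: coefficients transcribed from the CCI as established for
#'   beef cattle in extensive systems (Mader, Johnson & Gaughan 2010,
#'   J. Anim. Sci. 88:2153-2165). These are single continuous correction
#'   equations in Ta, RH, WS and RAD; the humidity correction changes sign
#'   around RH 30% and the wind correction is always cooling. See
#'   [cci_published_constants()] for the transcription and its caveats.
#' * `"identity"`: all three corrections identically zero, so CCI equals raw
#'   air temperature. Used to test the additive structure and for analyses
#'   that should not depend on any particular coefficient transcription.
#'
#' Radiation here is the daily-mean downward shortwave flux in W/m2 (as
#' distributed by NASA POWER when the W/m2 unit is requested); daily means
#' are used throughout, so one CCI value is produced per day.
#'
#' @param ta_c air temperature, degrees C.
#' @param rh_pct relative humidity, percent (0-100).
#' @param ws_ms wind speed at 2 m, m/s (>= 0).
#' @param rad_wm2 downward shortwave radiation, W/m2 (>= 0).
#' @return the correction in degrees C (vectorised).
#' @references Mader TL, Johnson LJ, Gaughan JB (2010). A comprehensive index
#'   for assessing environmental stress in animals. Journal of Animal
#'   Science 88:2153-2165.
#' @name cci_factors
NULL

#' @rdname cci_factors
#' @export
humidity_adjustment <- function(ta_c, rh_pct) {
  if (any(!is.finite(ta_c)) || any(!is.finite(rh_pct))) {
    stop("humidity_adjustment: inputs must be finite")
  }
  if (any(rh_pct < 0 | rh_pct > 100)) {
    stop("humidity_adjustment: rh_pct must be within [0, 100]")
  }
  exp(0.00182 * rh_pct + 1.8e-05 * ta_c * rh_pct) *
    (0.000054 * ta_c^2 + 0.00192 * ta_c - 0.0246) * (rh_pct - 30)
}

#' @rdname cci_factors
#' @export
wind_adjustment <- function(ta_c, ws_ms) {
  if (any(!is.finite(ta_c)) || any(!is.finite(ws_ms))) {
    stop("wind_adjustment: inputs must be finite")
  }
  if (any(ws_ms < 0)) stop("wind_adjustment: ws_ms must be >= 0")
  ex <- (1 / (2.26 * ws_ms + 0.23))^(0.45 * (2.9 + 1.14e-06 * ws_ms^2.5 -
          log(2.26 * ws_ms + 0.33) / log(0.3)))
  -6.56 / exp(ex) - 0.00566 * ws_ms^2 + 3.33
}

#' @rdname cci_factors
#' @export
radiation_adjustment <- function(ta_c, rad_wm2) {
  if (any(!is.finite(ta_c)) || any(!is.finite(rad_wm2))) {
    stop("radiation_adjustment: inputs must be finite")
  }
  if (any(rad_wm2 < 0)) stop("radiation_adjustment: rad_wm2 must be >= 0")
  0.0076 * rad_wm2 - 2e-05 * rad_wm2 * ta_c + 5e-05 * ta_c^2 * sqrt(rad_wm2) +
    0.1 * ta_c - 2
}

#' Factor sets for the CCI
#'
#' A factor set is a named list of three functions (`frh(ta, rh)`,
#' `fws(ta, ws)`, `frad(ta, rad)`), each returning a correction in degrees C.
#' Custom factor sets can be supplied to [compute_cci()], e.g. to plug in an
#' alternative coefficient transcription.
#'
#' @param name `"published"` or `"identity"`.
#' @return a list with elements `frh`, `fws`, `frad` and a `name` attribute.
#' @examples
#' fs <- cci_factor_set("identity")
#' fs$frh(30, 80)  # 0
#' @export
cci_factor_set <- function(name = c("published", "identity")) {
  name <- match.arg(name)
  set <- switch(name,
    published = list(frh = humidity_adjustment,
                     fws = wind_adjustment,
                     frad = radiation_adjustment),
    identity = list(frh = function(ta_c, rh_pct) rep(0, length(ta_c)),
                    fws = function(ta_c, ws_ms) rep(0, length(ta_c)),
                    frad = function(ta_c, rad_wm2) rep(0, length(ta_c)))
  )
  attr(set, "name") <- name
  set
}

#' Documentation table for the published CCI coefficients
#'
#' Returns the transcription of the published CCI correction equations as a
#' data frame (term, equation, note), for inspection and provenance. The
#' transcription source presents each correction as one continuous equation;
#' descriptions of the index elsewhere mention separate equation branches for
#' humidity below/above 25% and wind coefficients below/above Ta 27 degrees C.
#' The continuous forms reproduce the intended qualitative behaviour on both
#' sides of those boundaries (humidity warms when humid, wind always cools,
#' radiation always warms at daytime temperatures) and are smooth across them;
#' any analysis that must not depend on this transcription should use the
#' `"identity"` factor set.
#'
#' @return a data.frame with columns `term`, `equation`, `note`.
#' @export
cci_published_constants <- function() {
  data.frame(
    term = c("FRH", "FWS", "FRAD"),
    equation = c(
      "exp(0.00182*RH + 1.8e-5*Ta*RH) * (0.000054*Ta^2 + 0.00192*Ta - 0.0246) * (RH - 30)",
      "-6.56 / exp((1/(2.26*WS + 0.23))^(0.45*(2.9 + 1.14e-6*WS^2.5 - log(2.26*WS + 0.33)/log(0.3)))) - 0.00566*WS^2 + 3.33",
      "0.0076*RAD - 0.00002*RAD*Ta + 0.00005*Ta^2*sqrt(RAD) + 0.1*Ta - 2"
    ),
    note = c(
      "sign follows (RH - 30): humid air above ~30% RH adds heat load at warm Ta",
      "monotone cooling in WS; no explicit Ta branch in the transcribed form",
      "increases with RAD at warm Ta; RAD is the daily-mean shortwave flux, W/m2"
    ),
    stringsAsFactors = FALSE
  )
}

#' Classify a CCI value into an acute heat stress category
#'
#' Categories are half-open `[lo, hi)` on the thresholds 25, 30, 35, 40 and
#' 45 degrees C, so a CCI of exactly 30.0 is "moderate" and exactly 45.0 is
#' "extreme_danger". This convention makes "stress day" counting with the
#' predicate `CCI >= 30` reproducible.
#'
#' @param cci_c numeric vector of CCI values, degrees C; must be finite.
#' @return an ordered factor with levels no_stress < mild < moderate <
#'   strong < extreme < extreme_danger.
#' @examples
#' classify_stress(c(24, 25, 29.999, 30, 41.2, 46))
#' @export
classify_stress <- function(cci_c) {
  if (any(!is.finite(cci_c))) stop("classify_stress: cci_c must be finite")
  cut(cci_c, breaks = STRESS_BREAKS, labels = STRESS_LEVELS,
      right = FALSE, ordered_result = TRUE)
}

#' Compute the daily CCI and stress category for a weather series
#'
#' @param days a data.frame with columns `date`, `ta_c`, `rh_pct`, `ws_ms`,
#'   `rad_wm2` (e.g. the `days` element of a [location_series()]), or a
#'   `location_series` object.
#' @param factors a factor set from [cci_factor_set()], or its name.
#' @return a data.frame with columns `date`, `cci_c`, `category` (ordered
#'   factor). Rows with any missing input variable get `NA` CCI and category.
#' @examples
#' d <- data.frame(date = as.Date("2021-01-01"), ta_c = 32, rh_pct = 80,
#'                 ws_ms = 2, rad_wm2 = 250)
#' compute_cci(d, "identity")
#' @export
compute_cci <- function(days, factors = "published") {
  if (inherits(days, "location_series")) days <- days$days
  if (is.character(factors)) factors <- cci_factor_set(factors)
  stopifnot(is.list(factors), all(c("frh", "fws", "frad") %in% names(factors)))
  need <- c("date", "ta_c", "rh_pct", "ws_ms", "rad_wm2")
  missing_cols <- setdiff(need, names(days))
  if (length(missing_cols)) {
    stop("compute_cci: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  ok <- stats::complete.cases(days[, c("ta_c", "rh_pct", "ws_ms", "rad_wm2")])
  cci <- rep(NA_real_, nrow(days))
  if (any(ok)) {
    ta <- days$ta_c[ok]
    cci[ok] <- ta +
      factors$frh(ta, days$rh_pct[ok]) +
      factors$fws(ta, days$ws_ms[ok]) +
      factors$frad(ta, days$rad_wm2[ok])
  }
  category <- factor(rep(NA_character_, nrow(days)), levels = STRESS_LEVELS,
                     ordered = TRUE)
  category[ok] <- classify_stress(cci[ok])
  data.frame(date = days$date, cci_c = cci, category = category)
}
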