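#' Daily excess thermal load
#'
#' The excess of a day's CCI over the comfort threshold (default 30 degrees
#' C, the onset of moderate stress): `max(0, cci - threshold)`. Days at or
#' below the threshold contribute zero.
#'
#' @param cci_c daily CCI, degrees C (vectorised).
#' @param threshold_c comfort threshold, degrees C.
#' @return excess in degrees C.
#' @examples
#' daily_excess(38, 30)  # 8
#' daily_excess(c(22, 30, 38))
#' @export
daily_excess <- function(cci_c, threshold_c = 30) {
  if (any(!is.finite(cci_c)) || !is.finite(threshold_c)) {
    stop("daily_excess: inputs must be finite")
  }
  pmax(0, cci_c - threshold_c)
}

#' Annual Thermal Load for one calendar year
#'
#' The ATL is the sum, over all days of one year, of the daily CCI excess
#' above the threshold, in degrees C x days. All days present are summed
#' (Feb 29 of a leap year counts like any other day).
#'
#' @param year_cci a data.frame with columns `date` and `cci_c`, all dates in
#'   one calendar year (e.g. one year's slice of [compute_cci()] output).
#' @param threshold_c comfort threshold, degrees C.
#' @return ATL in degrees C x days.
#' @examples
#' d <- data.frame(date = seq(as.Date("2021-01-01"), by = "day", length.out = 365),
#'                 cci_c = c(rep(35, 10), rep(20, 355)))
#' annual_thermal_load(d)  # 50
#' @export
annual_thermal_load <- function(year_cci, threshold_c = 30) {
  stopifnot(is.data.frame(year_cci), all(c("date", "cci_c") %in% names(year_cci)))
  if (nrow(year_cci) == 0L) stop("annual_thermal_load: empty year")
  yrs <- unique(format(as.Date(year_cci$date), "%Y"))
  if (length(yrs) > 1L) {
    stop("annual_thermal_load: days span multiple years: ",
         paste(yrs, collapse = ", "))
  }
  sum(daily_excess(year_cci$cci_c, threshold_c))
}

#' Summarise chronic thermal exposure over multiple years
#'
#' Computes the ATL of each calendar year, their arithmetic mean, and the
#' chronic risk class of the mean: low (< 100), moderate (100-500), high
#' (500-1200), very high (1200-2000) or extreme (>= 2000) degrees C x days,
#' half-open bands.
#'
#' @param series_cci a data.frame with columns `date`, `cci_c` spanning one
#'   or more calendar years. Rows with `NA` CCI are dropped with a warning.
#' @param threshold_c comfort threshold, degrees C.
#' @return an object of class `atl_summary`: `per_year_atl` (named numeric),
#'   `mean_atl`, `risk` (ordered factor), `threshold_c`.
#' @export
summarize_atl <- function(series_cci, threshold_c = 30) {
  stopifnot(is.data.frame(series_cci),
            all(c("date", "cci_c") %in% names(series_cci)))
  if (anyNA(series_cci$cci_c)) {
    warning("summarize_atl: dropping ", sum(is.na(series_cci$cci_c)),
            " day(s) with missing CCI")
    series_cci <- series_cci[!is.na(series_cci$cci_c), ]
  }
  if (nrow(series_cci) == 0L) stop("summarize_atl: no complete year available")
  yr <- format(as.Date(series_cci$date), "%Y")
  per_year <- vapply(split(series_cci, yr), annual_thermal_load,
                     numeric(1), threshold_c = threshold_c)
  mean_atl <- mean(per_year)
  structure(list(per_year_atl = per_year, mean_atl = mean_atl,
                 risk = classify_risk(mean_atl), threshold_c = threshold_c),
            class = "atl_summary")
}

#' @export
print.atl_summary <- function(x, ...) {
  cat(sprintf("<atl_summary> mean ATL %.1f C*days over %d year(s): %s risk\n",
              x$mean_atl, length(x$per_year_atl), as.character(x$risk)))
  invisible(x)
}

#' Classify a mean ATL into a chronic risk class
#'
#' Band bounds follow the published table: lower bounds at 100, 500 and 1200
#' are inclusive, while the extreme class is strictly above 2000 (so an ATL
#' of exactly 2000 is still very high).
#'
#' @param atl mean Annual Thermal Load, degrees C x days (vectorised).
#' @return ordered factor low < moderate < high < very_high < extreme.
#' @examples
#' classify_risk(c(50, 100, 600, 2000, 2500))
#' @export
classify_risk <- function(atl) {
  if (any(!is.finite(atl))) stop("classify_risk: atl must be finite")
  if (any(atl < 0)) stop("classify_risk: atl must be >= 0")
  idx <- 1L + (atl >= 100) + (atl >= 500) + (atl >= 1200) + (atl > 2000)
  factor(RISK_LEVELS[idx], levels = RISK_LEVELS, ordered = TRUE)
}

#' Mean days per year in each acute stress category
#'
#' Counts, per calendar year, the days in each CCI stress category and
#' averages the counts across years. Fractional means are kept unrounded.
#'
#' @param series_cci a data.frame with columns `date`, `category` (e.g.
#'   [compute_cci()] output).
#' @return an object of class `stress_day_profile`: `days_per_category`
#'   (named numeric over the six categories), `years_covered`.
#' @export
stress_day_profile <- function(series_cci) {
  stopifnot(is.data.frame(series_cci),
            all(c("date", "category") %in% names(series_cci)))
  ok <- !is.na(series_cci$category)
  series_cci <- series_cci[ok, ]
  if (nrow(series_cci) == 0L) stop("stress_day_profile: no classified days")
  yr <- format(as.Date(series_cci$date), "%Y")
  tab <- table(yr, factor(series_cci$category, levels = STRESS_LEVELS))
  means <- colMeans(tab)
  structure(list(days_per_category = means, years_covered = nrow(tab)),
            class = "stress_day_profile")
}

#' @export
print.stress_day_profile <- function(x, ...) {
  cat(sprintf("<stress_day_profile> over %d year(s):\n", x$years_covered))
  print(round(x$days_per_category, 1))
  invisible(x)
}

# The thirteen defined acute x chronic scenario cells. Cells absent from the
# grid (extreme acute at moderate chronic; extreme-danger acute at moderate
# or high chronic) do not occur in the source risk landscape and are resolved
# by clamping the chronic class upward to the nearest defined cell.
SCENARIO_TABLE <- data.frame(
  id = 1:13,
  acute = c("moderate", "moderate", "moderate", "moderate",
            "strong", "strong", "strong", "strong",
            "extreme", "extreme", "extreme",
            "extreme_danger", "extreme_danger"),
  chronic = c("moderate", "high", "very_high", "extreme",
              "moderate", "high", "very_high", "extreme",
              "high", "very_high", "extreme",
              "very_high", "extreme"),
  label = c("M-M", "M-H", "M-VH", "M-E", "S-M", "S-H", "S-VH", "S-E",
            "E-H", "E-VH", "E-E", "ED-VH", "ED-E"),
  stringsAsFactors = FALSE
)

#' The thirteen heat stress scenarios
#'
#' Returns the scenario grid combining the acute stress category of a day
#' (moderate, strong, extreme, extreme danger) with the chronic risk class
#' of the location (moderate, high, very high, extreme). Labels follow the
#' acute-chronic convention, e.g. `"S-VH"` = a strong-stress day in a
#' very-high chronic-load region.
#'
#' @return a data.frame with columns `id`, `acute`, `chronic`, `label`.
#' @export
scenario_table <- function() SCENARIO_TABLE

#' Assign a day's stress category to a scenario
#'
#' Days below moderate acute stress accrue no discomfort and map to `NA`
#' (no scenario). Chronic class `low` is not part of the scenario grid; its
#' stress days are assessed in the moderate-risk column (nearest defined
#' chronic context, conservative), with a warning. Grid cells that do not
#' occur (extreme acute at moderate chronic; extreme-danger acute at
#' moderate or high chronic) are resolved by raising the chronic class to
#' the nearest defined cell (`E-M -> E-H`; `ED-M`, `ED-H -> ED-VH`), also
#' with a warning.
#'
#' @param acute stress category (string or factor level).
#' @param chronic risk class (string or factor level).
#' @param warn emit warnings on clamping (default TRUE).
#' @return one row of [scenario_table()] (with an extra logical column
#'   `clamped`), or `NULL` for sub-moderate days.
#' @examples
#' assign_scenario("strong", "very_high")$label  # "S-VH"
#' @export
assign_scenario <- function(acute, chronic, warn = TRUE) {
  acute <- as.character(acute)
  chronic <- as.character(chronic)
  stopifnot(acute %in% STRESS_LEVELS, chronic %in% RISK_LEVELS)
  if (acute %in% c("no_stress", "mild")) return(NULL)
  clamped <- FALSE
  if (chronic == "low") {
    if (warn) warning("low-risk location: assessing ", acute,
                      " day in the moderate-risk column", call. = FALSE)
    chronic <- "moderate"
    clamped <- TRUE
  }
  hit <- SCENARIO_TABLE[SCENARIO_TABLE$acute == acute &
                        SCENARIO_TABLE$chronic == chronic, ]
  if (nrow(hit) == 0L) {
    # clamp chronic upward to the nearest defined cell, preserving acute
    cand <- SCENARIO_TABLE[SCENARIO_TABLE$acute == acute, ]
    ord <- match(cand$chronic, RISK_LEVELS)
    cand <- cand[ord > match(chronic, RISK_LEVELS), ]
    hit <- cand[which.min(match(cand$chronic, RISK_LEVELS)), ]
    if (warn) warning("undefined scenario cell (", acute, ", ", chronic,
                      "): clamped to ", hit$label, call. = FALSE)
    clamped <- TRUE
  }
  hit$clamped <- clamped
  rownames(hit) <- NULL
  hit
}

#' Mean days per year in each heat stress scenario
#'
#' Assigns every day with acute category at or above moderate to a scenario
#' (given the location's chronic risk class) and averages the per-year counts
#' across calendar years. Clamping events are recorded once per distinct
#' (acute, chronic) combination in the `warnings` attribute.
#'
#' @param series_cci a data.frame with columns `date`, `category`.
#' @param risk the location's chronic risk class (from [summarize_atl()] of
#'   the same, unshaded, series).
#' @return a named numeric vector, mean days/year per scenario label, with a
#'   `warnings` character attribute. Scenarios with zero days are omitted.
#' @export
count_scenario_days <- function(series_cci, risk) {
  stopifnot(is.data.frame(series_cci),
            all(c("date", "category") %in% names(series_cci)))
  risk <- as.character(risk)
  stopifnot(length(risk) == 1L, risk %in% RISK_LEVELS)
  ok <- !is.na(series_cci$category)
  series_cci <- series_cci[ok, ]
  acute_levels <- intersect(setdiff(STRESS_LEVELS, c("no_stress", "mild")),
                            as.character(unique(series_cci$category)))
  warnings_log <- character(0)
  label_of <- vapply(acute_levels, function(a) {
    sc <- withCallingHandlers(
      assign_scenario(a, risk, warn = TRUE),
      warning = function(w) {
        warnings_log <<- c(warnings_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    sc$label
  }, character(1))

  stress <- series_cci[series_cci$category %in% acute_levels, ]
  n_years <- length(unique(format(as.Date(series_cci$date), "%Y")))
  if (nrow(stress) == 0L) {
    out <- numeric(0)
    attr(out, "warnings") <- unique(warnings_log)
    return(out)
  }
  lab <- label_of[as.character(stress$category)]
  counts <- tapply(rep(1, nrow(stress)), lab, sum)
  out <- as.numeric(counts) / n_years
  names(out) <- names(counts)
  # order by scenario id
  out <- out[order(match(names(out), SCENARIO_TABLE$label))]
  attr(out, "warnings") <- unique(warnings_log)
  out
}
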