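# In-code fixtures: weather CSVs, constant CCI series, random CCI years.

power_csv_lines <- function(unit = "W/m^2", key = c("mdy", "doy"),
                            rows = NULL) {
  key <- match.arg(key)
  header <- c(
    "-BEGIN HEADER-",
    "NASA/POWER Source Native Resolution Daily Data",
    "Parameters:",
    "T2M MERRA-2 Temperature at 2 Meters (C) ;",
    "RH2M MERRA-2 Relative Humidity at 2 Meters (%) ;",
    "WS2M MERRA-2 Wind Speed at 2 Meters (m/s) ;",
    sprintf("ALLSKY_SFC_SW_DWN CERES All Sky Surface Shortwave Downward Irradiance (%s) ;",
            unit),
    "-END HEADER-")
  if (is.null(rows)) {
    rows <- data.frame(
      YEAR = 2021, MO = 1, DY = 1:5,
      T2M = c(25.1, 26.2, 27.3, 28.4, 29.5),
      RH2M = c(80, 81, 82, 83, 84),
      WS2M = c(2, 2.1, 2.2, 2.3, 2.4),
      ALLSKY_SFC_SW_DWN = c(240, 241, 242, 243, 244))
  }
  if (key == "doy") {
    rows$DOY <- as.integer(format(
      as.Date(sprintf("%04d-%02d-%02d", rows$YEAR, rows$MO, rows$DY)), "%j"))
    rows$MO <- rows$DY <- NULL
    rows <- rows[, c("YEAR", "DOY", "T2M", "RH2M", "WS2M",
                     "ALLSKY_SFC_SW_DWN")]
  }
  body <- c(paste(names(rows), collapse = ","),
            apply(rows, 1, function(r) paste(trimws(format(r)), collapse = ",")))
  c(header, body)
}

write_power_fixture <- function(..., file = tempfile(fileext = ".csv")) {
  writeLines(power_csv_lines(...), file)
  file
}

# a full calendar year of CCI days at the given values
constant_cci_year <- function(year, cci, n_override = NULL) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  if (!is.null(n_override)) dates <- dates[seq_len(n_override)]
  cci <- rep_len(cci, length(dates))
  data.frame(date = dates, cci_c = cci,
             category = classify_stress(cci))
}

# a year with n_hot days at cci_hot and the rest at cci_cool
mixed_cci_year <- function(year, n_hot, cci_hot, cci_cool = 20) {
  d <- constant_cci_year(year, cci_cool)
  d$cci_c[seq_len(n_hot)] <- cci_hot
  d$category <- classify_stress(d$cci_c)
  d
}

# random multi-year CCI series spanning the full category range
random_cci_series <- function(n_years = 2, start_year = 2019,
                              min_cci = 15, max_cci = 50) {
  do.call(rbind, lapply(seq_len(n_years), function(i) {
    yr <- start_year + i - 1L
    d <- constant_cci_year(yr, 0)
    d$cci_c <- stats::runif(nrow(d), min_cci, max_cci)
    d$category <- classify_stress(d$cci_c)
    d
  }))
}

# independent brute-force oracle for the annual thermal load
atl_loop_oracle <- function(cci_values, threshold = 30) {
  total <- 0
  for (x in cci_values) {
    excess <- x - threshold
    if (excess > 0) total <- total + excess
  }
  total
}

# independent brute-force oracle for daily cumulative pain: enumerate every
# (phase, intensity) cell of the track and add its contribution
cumulative_pain_oracle <- function(durations_lo, durations_hi, probs) {
  out <- list()
  for (k in colnames(probs)) {
    lo <- 0; hi <- 0
    for (ph in rownames(probs)) {
      lo <- lo + probs[ph, k] * durations_lo[[ph]]
      hi <- hi + probs[ph, k] * durations_hi[[ph]]
    }
    out[[k]] <- c(lo, hi)
  }
  out
}

# random valid pain-track probability matrix (rows sum to 1)
random_track <- function() {
  m <- matrix(stats::runif(15), nrow = 3,
              dimnames = list(c("I", "II", "III"),
                              c("none", "annoying", "hurtful", "disabling",
                                "excruciating")))
  sweep(m, 1, rowSums(m), "/")
}
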