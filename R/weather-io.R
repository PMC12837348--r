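#' Daily weather series for one location
#'
#' The basic data container: an ordered multi-year sequence of daily weather
#' records for one location. Variables follow the daily-mean convention of the
#' NASA POWER point archive: air temperature (degrees C), relative humidity
#' (percent), wind speed at 2 m (m/s) and downward shortwave radiation
#' (W/m2).
#'
#' @param location_id character identifier.
#' @param days data.frame with columns `date` (Date), `ta_c`, `rh_pct`,
#'   `ws_ms`, `rad_wm2`. Dates must be strictly increasing with no
#'   duplicates. Missing measurements are `NA`.
#' @param latitude,longitude optional coordinates in decimal degrees.
#' @return an object of class `location_series`.
#' @export
location_series <- function(location_id, days, latitude = NA_real_,
                            longitude = NA_real_) {
  stopifnot(is.character(location_id), length(location_id) == 1L,
            is.data.frame(days))
  need <- c("date", "ta_c", "rh_pct", "ws_ms", "rad_wm2")
  missing_cols <- setdiff(need, names(days))
  if (length(missing_cols)) {
    stop("location_series: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  days <- days[, need]
  days$date <- as.Date(days$date)
  if (anyNA(days$date)) stop("location_series: unparseable dates present")
  if (nrow(days) > 1L) {
    d <- diff(as.integer(days$date))
    if (any(d == 0L)) {
      stop("location_series: duplicate date(s): ",
           paste(unique(days$date[c(FALSE, d == 0L)]), collapse = ", "))
    }
    if (any(d < 0L)) stop("location_series: dates must be strictly increasing")
  }
  rng_bad <- with(days,
    (!is.na(rh_pct) & (rh_pct < 0 | rh_pct > 100)) |
    (!is.na(ws_ms) & ws_ms < 0) |
    (!is.na(rad_wm2) & rad_wm2 < 0) |
    (!is.na(ta_c) & (ta_c < -60 | ta_c > 60)))
  if (any(rng_bad)) {
    stop("location_series: ", sum(rng_bad),
         " record(s) violate physical ranges (first at ",
         days$date[which(rng_bad)[1L]], ")")
  }
  rownames(days) <- NULL
  structure(list(location_id = location_id, latitude = latitude,
                 longitude = longitude, days = days),
            class = "location_series")
}

#' @export
print.location_series <- function(x, ...) {
  cat(sprintf("<location_series> %s: %d days (%s to %s)\n", x$location_id,
              nrow(x$days), min(x$days$date), max(x$days$date)))
  invisible(x)
}

# default mapping from POWER parameter names to tidy variable names
POWER_PARAM_MAP <- c(T2M = "ta_c", RH2M = "rh_pct", WS2M = "ws_ms",
                     ALLSKY_SFC_SW_DWN = "rad_wm2")

MJ_PER_DAY_TO_WM2 <- 11.574  # 1e6 J / 86400 s

#' Read a NASA-POWER-style daily point CSV
#'
#' Accepts both the comment-prefixed export (a `-BEGIN HEADER-` ...
#' `-END HEADER-` block before the data) and a plain CSV with the same
#' columns. Rows are keyed either by `YEAR,MO,DY` or by `YEAR,DOY`. The
#' sentinel `-999` (any value <= -999) is converted to `NA`. If the header
#' block (or the `rad_unit` argument) declares the radiation unit as
#' MJ/m2/day, values are converted to W/m2 (x 11.574).
#'
#' @param path file path.
#' @param location_id identifier for the resulting series; defaults to the
#'   file name without extension.
#' @param param_map named character vector mapping POWER parameter columns to
#'   the tidy names `ta_c`, `rh_pct`, `ws_ms`, `rad_wm2`.
#' @param rad_unit `"auto"` (inspect the header), `"Wm2"` or `"MJ"`.
#' @return a [location_series()].
#' @export
read_power_csv <- function(path, location_id = NULL,
                           param_map = POWER_PARAM_MAP,
                           rad_unit = c("auto", "Wm2", "MJ")) {
  rad_unit <- match.arg(rad_unit)
  if (!file.exists(path)) stop("read_power_csv: file not found: ", path)
  if (is.null(location_id)) {
    location_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  header_lines <- character(0)
  if (length(lines) && grepl("-BEGIN HEADER-", lines[[1L]], fixed = TRUE)) {
    end <- grep("-END HEADER-", lines, fixed = TRUE)
    if (!length(end)) stop("read_power_csv: unterminated POWER header block")
    header_lines <- lines[seq_len(end[[1L]])]
    lines <- lines[-seq_len(end[[1L]])]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("read_power_csv: no data rows in ", path)
  dat <- utils::read.csv(text = paste(lines, collapse = "\n"),
                         stringsAsFactors = FALSE, check.names = TRUE)
  names(dat) <- toupper(names(dat))

  rad_col <- names(param_map)[param_map == "rad_wm2"]
  is_mj <- switch(rad_unit,
    MJ = TRUE, Wm2 = FALSE,
    auto = any(grepl("MJ", header_lines[grepl(rad_col[1L], header_lines)],
                     ignore.case = FALSE)))

  missing_params <- setdiff(names(param_map), names(dat))
  if (length(missing_params)) {
    stop("read_power_csv: missing required column(s): ",
         paste(missing_params, collapse = ", "))
  }

  if (all(c("YEAR", "MO", "DY") %in% names(dat))) {
    date <- as.Date(sprintf("%04d-%02d-%02d", dat$YEAR, dat$MO, dat$DY))
  } else if (all(c("YEAR", "DOY") %in% names(dat))) {
    date <- as.Date(dat$DOY - 1, origin = as.Date(sprintf("%04d-01-01", dat$YEAR)))
  } else {
    stop("read_power_csv: rows must be keyed by YEAR/MO/DY or YEAR/DOY")
  }
  if (anyNA(date)) {
    stop("read_power_csv: unparseable date at data row ",
         which(is.na(date))[1L])
  }

  out <- data.frame(date = date)
  for (p in names(param_map)) {
    v <- as.numeric(dat[[p]])
    v[!is.na(v) & v <= -999] <- NA_real_
    out[[param_map[[p]]]] <- v
  }
  if (is_mj) out$rad_wm2 <- out$rad_wm2 * MJ_PER_DAY_TO_WM2
  out <- out[order(out$date), ]
  location_series(location_id, out)
}

#' Read and write the tidy daily-weather CSV dialect
#'
#' The tidy dialect has exactly the columns `date` (ISO-8601), `ta_c`,
#' `rh_pct`, `ws_ms`, `rad_wm2`, one row per day. [write_series()] writes it
#' with 6 decimal places, so a read/write round-trip is lossless at that
#' precision.
#'
#' @param path file path.
#' @param location_id identifier; defaults to the file name.
#' @return [read_tidy_csv()] returns a [location_series()];
#'   [write_series()] returns `path` invisibly.
#' @export
read_tidy_csv <- function(path, location_id = NULL) {
  if (!file.exists(path)) stop("read_tidy_csv: file not found: ", path)
  if (is.null(location_id)) {
    location_id <- sub("\\.[^.]*$", "", basename(path))
  }
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "ta_c", "rh_pct", "ws_ms", "rad_wm2")
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols)) {
    stop("read_tidy_csv: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(dat) == 0L) {
    warning("read_tidy_csv: ", path, " has a header but no data rows")
    dat$date <- as.Date(character(0))
    return(location_series(location_id, dat))
  }
  date <- as.Date(dat$date)
  if (anyNA(date)) {
    stop("read_tidy_csv: unparseable date at data row ", which(is.na(date))[1L],
         " ('", dat$date[which(is.na(date))[1L]], "')")
  }
  dat$date <- date
  if (anyDuplicated(dat$date)) {
    stop("read_tidy_csv: duplicate date(s): ",
         paste(unique(dat$date[duplicated(dat$date)]), collapse = ", "))
  }
  dat <- dat[order(dat$date), ]
  for (v in need[-1]) dat[[v]] <- as.numeric(dat[[v]])
  location_series(location_id, dat)
}

#' @rdname read_tidy_csv
#' @param series a [location_series()].
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "location_series"))
  d <- series$days
  for (v in c("ta_c", "rh_pct", "ws_ms", "rad_wm2")) {
    d[[v]] <- ifelse(is.na(d[[v]]), NA, sprintf("%.6f", d[[v]]))
  }
  d$date <- format(d$date, "%Y-%m-%d")
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validate (and gap-impute) a daily weather series
#'
#' Checks per-calendar-year coverage after imputing short gaps. Gaps of at
#' most `max_gap_days` consecutive missing days (per variable; a day counts
#' as missing if any variable is `NA`, and leading/trailing absent dates are
#' gaps against the calendar year) are filled by linear interpolation between
#' the flanking observed values; longer or boundary gaps remain missing and
#' reduce coverage. A year passes when its post-imputation coverage is at
#' least `min_coverage`; the report passes when every year passes.
#'
#' Interpolated values always lie between the flanking observations (convex
#' combination), so imputation cannot create new extremes.
#'
#' @param series a [location_series()].
#' @param min_coverage minimum fraction of days per calendar year, default
#'   0.95.
#' @param max_gap_days longest imputable run of missing days, default 3.
#' @return a list of class `validation_report`: `coverage` (data.frame
#'   year/n_days/n_missing/coverage/pass), `gaps` (data.frame
#'   start/length/imputed), `out_of_range` (data.frame, always empty for a
#'   constructed series but kept for report symmetry), `pass` (flag), and
#'   `series` (the gap-imputed series).
#' @export
validate_series <- function(series, min_coverage = 0.95, max_gap_days = 3) {
  stopifnot(inherits(series, "location_series"))
  d <- series$days
  if (nrow(d) == 0L) {
    rep0 <- list(coverage = data.frame(year = integer(0), n_days = integer(0),
                                       n_missing = integer(0),
                                       coverage = numeric(0),
                                       pass = logical(0)),
                 gaps = data.frame(start = as.Date(character(0)),
                                   length = integer(0), imputed = logical(0)),
                 out_of_range = data.frame(),
                 pass = FALSE, series = series)
    class(rep0) <- "validation_report"
    return(rep0)
  }
  # expand to the full calendar span of the years present
  years <- sort(unique(as.integer(format(d$date, "%Y"))))
  full_dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
                    as.Date(sprintf("%d-12-31", max(years))), by = "day")
  full <- data.frame(date = full_dates)
  full <- merge(full, d, by = "date", all.x = TRUE, sort = TRUE)

  vars <- c("ta_c", "rh_pct", "ws_ms", "rad_wm2")
  miss <- !stats::complete.cases(full[, vars])
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gap_rows <- which(r$values)
  gaps <- data.frame(start = full$date[starts[gap_rows]],
                     length = r$lengths[gap_rows],
                     imputed = rep(FALSE, length(gap_rows)))
  for (i in seq_along(gap_rows)) {
    g <- gap_rows[i]
    if (r$lengths[g] > max_gap_days) next
    lo <- starts[g] - 1L
    hi <- ends[g] + 1L
    if (lo < 1L || hi > nrow(full)) next  # boundary gap, no flanks
    idx <- starts[g]:ends[g]
    can <- TRUE
    for (v in vars) {
      if (is.na(full[[v]][lo]) || is.na(full[[v]][hi])) { can <- FALSE; break }
    }
    if (!can) next
    for (v in vars) {
      full[[v]][idx] <- stats::approx(x = c(lo, hi),
                                      y = c(full[[v]][lo], full[[v]][hi]),
                                      xout = idx)$y
    }
    gaps$imputed[i] <- TRUE
  }

  still_missing <- !stats::complete.cases(full[, vars])
  yr <- as.integer(format(full$date, "%Y"))
  cov <- do.call(rbind, lapply(split(seq_along(yr), yr), function(ix) {
    data.frame(year = yr[ix[1L]], n_days = length(ix),
               n_missing = sum(still_missing[ix]),
               coverage = 1 - sum(still_missing[ix]) / length(ix))
  }))
  cov$pass <- cov$coverage >= min_coverage
  rownames(cov) <- NULL

  out <- list(coverage = cov,
              gaps = gaps,
              out_of_range = data.frame(),
              pass = all(cov$pass),
              series = location_series(series$location_id, full,
                                       series$latitude, series$longitude))
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s: %d year(s), %d gap(s)\n",
              if (x$pass) "PASS" else "FAIL", nrow(x$coverage), nrow(x$gaps)))
  invisible(x)
}

#' Serialise a validation report to JSON
#'
#' @param report a `validation_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  obj <- list(pass = report$pass, coverage = report$coverage,
              gaps = transform(report$gaps, start = format(start, "%Y-%m-%d")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
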