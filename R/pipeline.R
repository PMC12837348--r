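#' Run the full heat-stress welfare pipeline over one or more locations
#'
#' For each input series: validate and gap-impute, compute the daily CCI and
#' stress category, summarise chronic exposure (Annual Thermal Load and risk
#' class), build the stress-day profile and scenario day counts, evaluate
#' annual welfare without and with shade, compare them, and attach the
#' finishing-phase shade economics. A failing location is recorded as a
#' failure and does not abort the run.
#'
#' @param inputs one of: a list of [location_series()] objects; a character
#'   vector of tidy-CSV paths; or a simulation manifest - a data.frame with
#'   columns `archetype`, `years`, `seed` (one synthetic location per row).
#' @param paintracks Pain-Track configuration, default [default_paintracks()].
#' @param econ an [econ_params()] (economics are per-animal and identical
#'   across locations).
#' @param factors CCI factor set or its name, default `"published"`.
#' @param threshold_c ATL comfort threshold, degrees C.
#' @param policy a [shade_policy()].
#' @param min_coverage,max_gap_days validation settings, see
#'   [validate_series()].
#' @return a list of class `pipeline_result`: `reports` (named list of
#'   `location_report` objects), `failures` (named character), `summary`
#'   (a `cohort_summary`, NULL when no location succeeded), `config`
#'   (echo of the effective settings).
#' @export
run_pipeline <- function(inputs, paintracks = default_paintracks(),
                         econ = econ_params(), factors = "published",
                         threshold_c = 30, policy = shade_policy(),
                         min_coverage = 0.95, max_gap_days = 3) {
  if (is.character(factors)) factors <- cci_factor_set(factors)
  series_list <- resolve_inputs(inputs)
  reports <- list()
  failures <- character(0)
  for (s in series_list) {
    res <- tryCatch(
      location_report(s, paintracks = paintracks, econ = econ,
                      factors = factors, threshold_c = threshold_c,
                      policy = policy, min_coverage = min_coverage,
                      max_gap_days = max_gap_days),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[s$location_id]] <- conditionMessage(res)
    } else {
      reports[[s$location_id]] <- res
    }
  }
  summary <- if (length(reports)) render_summary(reports) else NULL
  structure(list(reports = reports, failures = failures, summary = summary,
                 config = list(factors = attr(factors, "name"),
                               threshold_c = threshold_c,
                               category_downshift = policy$category_downshift,
                               min_coverage = min_coverage,
                               max_gap_days = max_gap_days)),
            class = "pipeline_result")
}

resolve_inputs <- function(inputs) {
  if (is.data.frame(inputs)) {
    stopifnot(all(c("archetype", "years", "seed") %in% names(inputs)))
    return(lapply(seq_len(nrow(inputs)), function(i) {
      generate_location(inputs$archetype[[i]], inputs$years[[i]],
                        inputs$seed[[i]])
    }))
  }
  if (is.character(inputs)) return(lapply(inputs, read_tidy_csv))
  if (inherits(inputs, "location_series")) return(list(inputs))
  stopifnot(is.list(inputs),
            all(vapply(inputs, inherits, logical(1), "location_series")))
  inputs
}

#' Analyse a single location end to end
#'
#' @param series a [location_series()].
#' @inheritParams run_pipeline
#' @return an object of class `location_report`: `location_id`,
#'   `validation`, `atl` ([summarize_atl()]), `profile`
#'   ([stress_day_profile()]), `scenario_days`, `welfare` (unshaded
#'   [annual_welfare()]), `welfare_shaded`, `comparison`
#'   ([compare_welfare()]), `economics` ([shade_economics()]), `warnings`.
#' @export
location_report <- function(series, paintracks = default_paintracks(),
                            econ = econ_params(), factors = "published",
                            threshold_c = 30, policy = shade_policy(),
                            min_coverage = 0.95, max_gap_days = 3) {
  if (is.character(factors)) factors <- cci_factor_set(factors)
  val <- validate_series(series, min_coverage = min_coverage,
                         max_gap_days = max_gap_days)
  if (!val$pass) {
    stop("location ", series$location_id, ": validation failed (coverage ",
         paste(sprintf("%d: %.2f", val$coverage$year, val$coverage$coverage),
               collapse = ", "), ")")
  }
  cci <- compute_cci(val$series, factors)
  cci_ok <- cci[!is.na(cci$cci_c), ]
  atl <- summarize_atl(cci_ok, threshold_c = threshold_c)
  profile <- stress_day_profile(cci_ok)
  scenario_days <- count_scenario_days(cci_ok, atl$risk)
  welfare <- annual_welfare(scenario_days, paintracks)
  welfare_shaded <- shaded_welfare(cci_ok, atl$risk, paintracks, policy)
  comparison <- compare_welfare(welfare, welfare_shaded)
  structure(list(location_id = series$location_id, validation = val,
                 atl = atl, profile = profile,
                 scenario_days = scenario_days,
                 welfare = welfare, welfare_shaded = welfare_shaded,
                 comparison = comparison,
                 economics = shade_economics(econ),
                 warnings = attr(scenario_days, "warnings")),
            class = "location_report")
}

#' @export
print.location_report <- function(x, ...) {
  cat(sprintf("<location_report> %s: ATL %.0f (%s risk), %.1f stress days/yr\n",
              x$location_id, x$atl$mean_atl, as.character(x$atl$risk),
              x$welfare$days_in_stress))
  invisible(x)
}

#' Aggregate location reports into a cohort summary
#'
#' Averages, within each chronic risk class, the stress-day profile (days
#' per year per acute category), the per-stress-day daily discomfort hours
#' per intensity (interval midpoints; stress-day predicate CCI >= 30), and
#' the annual discomfort hours with and without shade. Risk classes with no
#' locations are omitted from the tables and listed in `empty_classes`.
#'
#' @param reports a non-empty list of `location_report` objects.
#' @return an object of class `cohort_summary` with data.frames
#'   `class_counts`, `days_per_category`, `daily_hours`, `annual_hours`,
#'   and `empty_classes`.
#' @export
render_summary <- function(reports) {
  stopifnot(length(reports) > 0,
            all(vapply(reports, inherits, logical(1), "location_report")))
  risk <- vapply(reports, function(r) as.character(r$atl$risk), character(1))
  classes <- RISK_LEVELS[RISK_LEVELS %in% risk]

  class_counts <- data.frame(risk = classes,
                             n_locations = vapply(classes, function(cl) {
                               sum(risk == cl)
                             }, numeric(1)))

  days_per_category <- do.call(rbind, lapply(classes, function(cl) {
    mats <- vapply(reports[risk == cl],
                   function(r) r$profile$days_per_category,
                   numeric(length(STRESS_LEVELS)))
    out <- data.frame(risk = cl, t(rowMeans(as.matrix(mats))))
    names(out) <- c("risk", STRESS_LEVELS)
    out
  }))

  intensities <- setdiff(INTENSITY_LEVELS, "none")
  daily_hours <- do.call(rbind, lapply(classes, function(cl) {
    rs <- reports[risk == cl]
    vals <- vapply(rs, function(r) {
      vapply(intensities, function(k) {
        iv_mid(r$welfare$daily_on_stress_days[[k]])
      }, numeric(1))
    }, numeric(length(intensities)))
    out <- data.frame(risk = cl, t(rowMeans(as.matrix(vals))))
    names(out) <- c("risk", intensities)
    out
  }))

  annual_hours <- do.call(rbind, lapply(classes, function(cl) {
    rs <- reports[risk == cl]
    rows <- lapply(c(without = "welfare", with_shade = "welfare_shaded"),
                   function(fld) {
      vals <- vapply(rs, function(r) {
        vapply(intensities, function(k) iv_mid(r[[fld]]$hours[[k]]),
               numeric(1))
      }, numeric(length(intensities)))
      t(rowMeans(as.matrix(vals)))
    })
    out <- data.frame(risk = cl, shading = c("without", "with_shade"),
                      rbind(rows[[1]], rows[[2]]))
    names(out) <- c("risk", "shading", intensities)
    out
  }))

  structure(list(class_counts = class_counts,
                 days_per_category = days_per_category,
                 daily_hours = daily_hours,
                 annual_hours = annual_hours,
                 empty_classes = setdiff(RISK_LEVELS, classes)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$class_counts, row.names = FALSE)
  invisible(x)
}

#' Write pipeline reports to disk
#'
#' Writes `location_<id>.json` per location, `summary.csv` (the annual-hours
#' table) and `run_log.txt` (configuration echo, failures and warnings) into
#' `out_dir`.
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_reports <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (r in result$reports) {
    obj <- list(
      location_id = r$location_id,
      mean_atl = r$atl$mean_atl,
      per_year_atl = as.list(r$atl$per_year_atl),
      risk = as.character(r$atl$risk),
      days_per_category = as.list(r$profile$days_per_category),
      scenario_days = as.list(unclass(r$scenario_days)),
      annual_hours_without = lapply(r$welfare$hours, as.numeric),
      annual_hours_with_shade = lapply(r$welfare_shaded$hours, as.numeric),
      reduction_pct = as.list(r$comparison$reduction_pct),
      warnings = r$warnings)
    jsonlite::write_json(obj, file.path(out_dir,
                                        paste0("location_", r$location_id, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(result$summary)) {
    utils::write.csv(result$summary$annual_hours,
                     file.path(out_dir, "summary.csv"), row.names = FALSE)
  }
  log_lines <- c(
    "heatfootprint run",
    paste0("config: ", paste(names(result$config), unlist(result$config),
                             sep = "=", collapse = ", ")),
    paste0("locations ok: ", length(result$reports)),
    paste0("failures: ", length(result$failures)),
    if (length(result$failures)) {
      paste0("  ", names(result$failures), ": ", result$failures)
    },
    unlist(lapply(result$reports, function(r) {
      if (length(r$warnings)) paste0(r$location_id, ": ", r$warnings)
    })))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
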