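#' Shade policy
#'
#' Effective shade is modelled conservatively as lowering each day's acute
#' stress category by one step (a strong-stress day becomes a moderate-stress
#' day), floored at no stress. The chronic (ATL) risk class of the location
#' is by default held at its unshaded baseline when scenarios are reassigned,
#' since the chronic class describes the regional thermal landscape rather
#' than the shaded microclimate; set `recompute_chronic = TRUE` to instead
#' re-derive the chronic class from a shade-adjusted CCI series (5 degrees C
#' lower per downshift step, the width of one category band).
#'
#' @param category_downshift number of categories removed by shade (>= 0,
#'   default 1).
#' @param recompute_chronic logical, default FALSE.
#' @return an object of class `shade_policy`.
#' @export
shade_policy <- function(category_downshift = 1, recompute_chronic = FALSE) {
  stopifnot(is.numeric(category_downshift), length(category_downshift) == 1L,
            category_downshift >= 0,
            category_downshift == round(category_downshift),
            is.logical(recompute_chronic))
  structure(list(category_downshift = as.integer(category_downshift),
                 recompute_chronic = recompute_chronic),
            class = "shade_policy")
}

#' Apply shade to acute stress categories
#'
#' Lowers each category by the policy's downshift, floored at no stress.
#' Monotone (never raises a category) and idempotent at the floor.
#'
#' @param category stress categories (ordered factor or character).
#' @param policy a [shade_policy()].
#' @return ordered factor of the same length.
#' @examples
#' apply_shade(stress_factor(c("strong", "mild", "no_stress")))
#' @export
apply_shade <- function(category, policy = shade_policy()) {
  stopifnot(inherits(policy, "shade_policy"))
  f <- stress_factor(as.character(category))
  idx <- pmax(1L, as.integer(f) - policy$category_downshift)
  idx[is.na(f)] <- NA_integer_
  factor(STRESS_LEVELS[idx], levels = STRESS_LEVELS, ordered = TRUE)
}

#' Annual welfare under shade
#'
#' Downshifts every day's acute category per the policy, reassigns scenarios
#' (at the unshaded baseline chronic class unless
#' `policy$recompute_chronic`), and recomputes annual welfare.
#'
#' @param series_cci data.frame with columns `date`, `category` (and
#'   `cci_c` if `recompute_chronic`), from [compute_cci()].
#' @param risk the location's chronic risk class from the unshaded series.
#' @param config Pain-Track configuration.
#' @param policy a [shade_policy()].
#' @return an [annual_welfare()] object.
#' @export
shaded_welfare <- function(series_cci, risk, config = default_paintracks(),
                           policy = shade_policy()) {
  stopifnot(inherits(policy, "shade_policy"))
  shifted <- series_cci
  shifted$category <- apply_shade(series_cci$category, policy)
  if (policy$recompute_chronic) {
    if (!"cci_c" %in% names(series_cci)) {
      stop("shaded_welfare: recompute_chronic requires a cci_c column")
    }
    # one category step spans 5 degrees C, so the shaded thermal load is
    # approximated by lowering each day's CCI accordingly
    shifted$cci_c <- series_cci$cci_c - 5 * policy$category_downshift
    risk <- summarize_atl(shifted)$risk
  }
  days <- count_scenario_days(shifted, risk)
  annual_welfare(days, config)
}

#' Compare annual welfare with and without shade
#'
#' Per-intensity reductions are reported both as hour intervals (bound-wise:
#' `lo_without - lo_with`, `hi_without - hi_with`, the jointly-attained
#' convention used throughout) and as percentages of the interval midpoint
#' (0 when the unshaded midpoint is 0).
#'
#' @param without,with_shade [annual_welfare()] objects for the same
#'   location and configuration.
#' @return an object of class `welfare_comparison`: `without`, `with_shade`,
#'   `reduction` (named list of [iv()]), `reduction_pct` (named numeric).
#' @export
compare_welfare <- function(without, with_shade) {
  stopifnot(inherits(without, "annual_welfare"),
            inherits(with_shade, "annual_welfare"))
  reduction <- list()
  pct <- numeric(0)
  for (k in INTENSITY_LEVELS) {
    a <- without$hours[[k]]
    b <- with_shade$hours[[k]]
    lo <- iv_lo(a) - iv_lo(b)
    hi <- iv_hi(a) - iv_hi(b)
    reduction[[k]] <- iv(min(lo, hi), max(lo, hi))
    m <- iv_mid(a)
    pct[[k]] <- if (m > 0) 100 * (m - iv_mid(b)) / m else 0
  }
  structure(list(without = without, with_shade = with_shade,
                 reduction = reduction, reduction_pct = pct),
            class = "welfare_comparison")
}

#' @export
print.welfare_comparison <- function(x, ...) {
  cat("<welfare_comparison> reduction in hours/year (midpoint %):\n")
  for (k in setdiff(INTENSITY_LEVELS, "none")) {
    cat(sprintf("  %-12s %s (%.1f%%)\n", k, format(x$reduction[[k]]),
                x$reduction_pct[[k]]))
  }
  invisible(x)
}

#' Economic parameters for finishing-phase shade provision
#'
#' Defaults reflect customized steel shade structures (3 m2 per animal) in
#' Brazilian finishing operations: investment US$75-93 per shaded spot
#' amortised over a 10-year lifespan at 3 finishing cycles per year (30
#' cycles), a conservative 5 kg carcass-weight differential, and 2023-2024
#' beef prices of US$45-56 per arroba (15 kg carcass) or US$3-4/kg.
#'
#' @param investment_per_spot USD interval.
#' @param lifespan_years structure lifespan, years.
#' @param cycles_per_year finishing cycles per year.
#' @param carcass_delta_kg carcass weight differential with shade, kg.
#' @param price_per_arroba USD interval per arroba.
#' @param kg_per_arroba kg per arroba (the trading unit; 15).
#' @param price_per_kg_override optional USD/kg interval used instead of
#'   arroba pricing when `pricing = "per_kg"`.
#' @param pricing which price basis to use: `"arroba"` (default) or
#'   `"per_kg"`.
#' @return an object of class `econ_params`.
#' @export
econ_params <- function(investment_per_spot = iv(75, 93),
                        lifespan_years = 10,
                        cycles_per_year = 3,
                        carcass_delta_kg = 5,
                        price_per_arroba = iv(45, 56),
                        kg_per_arroba = 15,
                        price_per_kg_override = iv(3, 4),
                        pricing = c("arroba", "per_kg")) {
  pricing <- match.arg(pricing)
  investment_per_spot <- as_iv(investment_per_spot)
  price_per_arroba <- as_iv(price_per_arroba)
  if (!is.null(price_per_kg_override)) {
    price_per_kg_override <- as_iv(price_per_kg_override)
  }
  stopifnot(lifespan_years > 0, cycles_per_year > 0, carcass_delta_kg > 0,
            kg_per_arroba == 15)
  structure(list(investment_per_spot = investment_per_spot,
                 lifespan_years = lifespan_years,
                 cycles_per_year = cycles_per_year,
                 carcass_delta_kg = carcass_delta_kg,
                 price_per_arroba = price_per_arroba,
                 kg_per_arroba = kg_per_arroba,
                 price_per_kg_override = price_per_kg_override,
                 pricing = pricing),
            class = "econ_params")
}

#' Finishing-phase economics of shade provision
#'
#' Per-cycle amortised cost is the investment divided by
#' `lifespan_years * cycles_per_year`; per-cycle revenue gain is the carcass
#' weight differential times the per-kg price (arroba price / 15, or the
#' per-kg override). Net gain is revenue minus cost under the usual
#' anti-tone interval subtraction (`net_lo = rev_lo - cost_hi`). Monetary
#' intervals are kept unrounded; round only at report rendering (e.g.
#' `round(...)` of the net interval).
#'
#' Payback is the smallest whole number of cycles whose cumulative revenue
#' gain covers the investment, reported under three documented conventions:
#' `best` (lowest investment, highest available per-cycle revenue - the
#' per-kg price ceiling when an override is supplied), `midpoint`
#' (interval midpoints on the selected pricing basis) and `worst` (highest
#' investment, lowest revenue). `payback_cycles`/`payback_months` expose the
#' best case; `payback` holds all three. Months per cycle is
#' `12 / cycles_per_year`.
#'
#' @param params an [econ_params()].
#' @return an object of class `econ_result` with elements
#'   `amortized_cost_per_cycle`, `revenue_gain_per_cycle`,
#'   `net_gain_per_cycle` (all [iv()], USD), `payback_cycles`,
#'   `payback_months`, `payback` (data.frame convention/cycles/months).
#' @examples
#' r <- shade_economics(econ_params())
#' round(c(iv_lo(r$net_gain_per_cycle), iv_hi(r$net_gain_per_cycle)))  # 12 16
#' @export
shade_economics <- function(params = econ_params()) {
  stopifnot(inherits(params, "econ_params"))
  n_cycles <- params$lifespan_years * params$cycles_per_year
  cost <- iv_scale(params$investment_per_spot, 1 / n_cycles)

  per_kg_arroba <- iv_scale(params$price_per_arroba, 1 / params$kg_per_arroba)
  per_kg <- switch(params$pricing,
                   arroba = per_kg_arroba,
                   per_kg = {
                     if (is.null(params$price_per_kg_override)) {
                       stop("shade_economics: pricing = 'per_kg' requires price_per_kg_override")
                     }
                     params$price_per_kg_override
                   })
  revenue <- iv_scale(per_kg, params$carcass_delta_kg)
  net <- iv_sub_antitone(revenue, cost)

  months_per_cycle <- 12 / params$cycles_per_year
  best_rev <- params$carcass_delta_kg * max(
    iv_hi(per_kg_arroba),
    if (!is.null(params$price_per_kg_override)) {
      iv_hi(params$price_per_kg_override)
    } else -Inf)
  conventions <- data.frame(
    convention = c("best", "midpoint", "worst"),
    investment = c(iv_lo(params$investment_per_spot),
                   iv_mid(params$investment_per_spot),
                   iv_hi(params$investment_per_spot)),
    revenue_per_cycle = c(best_rev, iv_mid(revenue), iv_lo(revenue)),
    stringsAsFactors = FALSE
  )
  conventions$cycles <- ceiling(conventions$investment /
                                conventions$revenue_per_cycle)
  conventions$months <- conventions$cycles * months_per_cycle

  structure(list(amortized_cost_per_cycle = cost,
                 revenue_gain_per_cycle = revenue,
                 net_gain_per_cycle = net,
                 payback_cycles = conventions$cycles[conventions$convention == "best"],
                 payback_months = conventions$months[conventions$convention == "best"],
                 payback = conventions,
                 params = params),
            class = "econ_result")
}

#' @export
print.econ_result <- function(x, ...) {
  cat("<econ_result> per finishing cycle (USD):\n")
  cat(sprintf("  amortised cost  %s\n", format(x$amortized_cost_per_cycle)))
  cat(sprintf("  revenue gain    %s\n", format(x$revenue_gain_per_cycle)))
  cat(sprintf("  net gain        %s  (rounds to [%d, %d])\n",
              format(x$net_gain_per_cycle),
              round(iv_lo(x$net_gain_per_cycle)),
              round(iv_hi(x$net_gain_per_cycle))))
  cat(sprintf("  payback (best case) %d cycles = %g months\n",
              x$payback_cycles, x$payback_months))
  invisible(x)
}
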