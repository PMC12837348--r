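test_that("shade lowers categories one step, floored and idempotent", {
  expect_equal(as.character(apply_shade(stress_factor("strong"))), "moderate")
  expect_equal(as.character(apply_shade(stress_factor("mild"))), "no_stress")
  expect_equal(as.character(apply_shade(stress_factor("no_stress"))),
               "no_stress")
  all_cats <- stress_factor(c("no_stress", "mild", "moderate", "strong",
                              "extreme", "extreme_danger"))
  shaded <- apply_shade(all_cats)
  expect_true(all(shaded <= all_cats))            # never raises
  expect_identical(apply_shade(all_cats, shade_policy(0)), all_cats)
  # a large downshift saturates at the floor
  expect_true(all(apply_shade(all_cats, shade_policy(10)) == "no_stress"))
})

test_that("shaded welfare recategorises days at the baseline chronic class", {
  # a location with only moderate stress days: shade removes all discomfort
  d <- mixed_cci_year(2021, 30, 32)
  aw <- shaded_welfare(d, "moderate")
  expect_equal(aw$days_in_stress, 0)
  for (k in names(aw$hours)) {
    expect_equal(as.numeric(aw$hours[[k]]), c(0, 0), ignore_attr = TRUE)
  }

  # 100 strong days at high risk shade into exactly {M-H: 100}
  d2 <- mixed_cci_year(2021, 100, 37)
  aw2 <- shaded_welfare(d2, "high")
  ref <- annual_welfare(c("M-H" = 100))
  expect_equal(aw2$days_in_stress, 100)
  for (k in names(aw2$hours)) {
    expect_equal(as.numeric(aw2$hours[[k]]), as.numeric(ref$hours[[k]]),
                 ignore_attr = TRUE)
  }

  # zero downshift reproduces the unshaded welfare
  base <- annual_welfare(count_scenario_days(d2, "high"))
  aw3 <- shaded_welfare(d2, "high", policy = shade_policy(0))
  for (k in names(aw3$hours)) {
    expect_equal(as.numeric(aw3$hours[[k]]), as.numeric(base$hours[[k]]),
                 ignore_attr = TRUE)
  }
})

test_that("welfare comparisons report reductions and midpoint percentages", {
  d <- mixed_cci_year(2021, 100, 37)
  base <- annual_welfare(count_scenario_days(d, "high"))
  cmp_same <- compare_welfare(base, base)
  for (k in names(cmp_same$reduction)) {
    expect_equal(as.numeric(cmp_same$reduction[[k]]), c(0, 0),
                 ignore_attr = TRUE)
    expect_equal(unname(cmp_same$reduction_pct[[k]]), 0)
  }

  zero <- annual_welfare(setNames(numeric(0), character(0)))
  cmp_full <- compare_welfare(base, zero)
  expect_equal(unname(cmp_full$reduction_pct[["hurtful"]]), 100)
  expect_equal(as.numeric(cmp_full$reduction$hurtful),
               as.numeric(base$hours$hurtful), ignore_attr = TRUE)
})

test_that("shade never increases severe discomfort hours on random series", {
  set.seed(31)
  for (i in 1:20) {
    series <- random_cci_series(n_years = 2)
    risk <- summarize_atl(series)$risk
    base <- annual_welfare(suppressWarnings(count_scenario_days(series, risk)))
    shaded <- suppressWarnings(shaded_welfare(series, risk))
    for (k in c("hurtful", "disabling", "excruciating")) {
      expect_lte(iv_lo(shaded$hours[[k]]), iv_lo(base$hours[[k]]) + 1e-9)
      expect_lte(iv_hi(shaded$hours[[k]]), iv_hi(base$hours[[k]]) + 1e-9)
    }
  }
})

test_that("an extreme-risk synthetic location sees a large disabling cut", {
  # regression pin: tropical_extreme preset, seed 1, default config
  rep <- location_report(generate_location("tropical_extreme", 5, 1))
  expect_equal(as.character(rep$atl$risk), "extreme")
  expect_gte(rep$comparison$reduction_pct[["disabling"]], 30)
})

test_that("shade economics reproduce the finishing-phase worked numbers", {
  r <- shade_economics(econ_params())
  expect_equal(iv_lo(r$revenue_gain_per_cycle), 15)       # 5 kg x 45/15
  expect_equal(as.numeric(r$amortized_cost_per_cycle), c(2.5, 3.1),
               ignore_attr = TRUE)
  net <- r$net_gain_per_cycle
  expect_equal(round(c(iv_lo(net), iv_hi(net))), c(12, 16))
  # best-case payback: US$75 at US$4/kg -> 20 USD/cycle -> 4 cycles, 16 months
  expect_equal(r$payback_cycles, 4)
  expect_equal(r$payback_months, 16)
  worst <- r$payback[r$payback$convention == "worst", ]
  expect_gte(worst$cycles, r$payback_cycles)
})

test_that("economics follow exact interval identities", {
  p <- econ_params()
  r <- shade_economics(p)
  # net + cost recovers revenue bound-wise by construction
  expect_equal(iv_lo(r$net_gain_per_cycle) + iv_hi(r$amortized_cost_per_cycle),
               iv_lo(r$revenue_gain_per_cycle))
  expect_equal(iv_hi(r$net_gain_per_cycle) + iv_lo(r$amortized_cost_per_cycle),
               iv_hi(r$revenue_gain_per_cycle))
  # doubling cycles per year halves the amortised cost exactly
  r2 <- shade_economics(econ_params(cycles_per_year = 6))
  expect_equal(as.numeric(r2$amortized_cost_per_cycle),
               as.numeric(r$amortized_cost_per_cycle) / 2, ignore_attr = TRUE)
  # per-kg pricing basis
  r3 <- shade_economics(econ_params(pricing = "per_kg"))
  expect_equal(as.numeric(r3$revenue_gain_per_cycle), c(15, 20),
               ignore_attr = TRUE)
  expect_error(econ_params(kg_per_arroba = 14))
})
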