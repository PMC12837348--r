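test_that("daily excess is the positive part above the threshold", {
  expect_equal(daily_excess(38, 30), 8)
  expect_equal(daily_excess(30, 30), 0)
  expect_equal(daily_excess(22, 30), 0)
  expect_equal(daily_excess(c(29, 31.5, 40)), c(0, 1.5, 10))
})

test_that("annual thermal load reproduces the worked examples exactly", {
  expect_equal(annual_thermal_load(mixed_cci_year(2021, 10, 35)), 50)
  expect_equal(annual_thermal_load(mixed_cci_year(2021, 100, 40)), 1000)
  expect_equal(annual_thermal_load(constant_cci_year(2021, 25)), 0)
})

test_that("annual thermal load rejects empty and mixed-year input", {
  expect_error(annual_thermal_load(constant_cci_year(2021, 30)[0, ]), "empty")
  two <- rbind(constant_cci_year(2021, 30), constant_cci_year(2022, 30))
  expect_error(annual_thermal_load(two), "multiple years")
})

test_that("ATL equals a brute-force loop oracle on random years", {
  set.seed(1234)
  for (i in 1:1000) {
    n <- sample(300:366, 1)
    vals <- runif(n, 10, 55)
    d <- constant_cci_year(2020, 0, n_override = n)
    d$cci_c <- vals
    expect_equal(annual_thermal_load(d), atl_loop_oracle(vals))
  }
})

test_that("ATL is additive, monotone and permutation-stable", {
  set.seed(77)
  d <- constant_cci_year(2021, 0)
  d$cci_c <- runif(nrow(d), 15, 50)
  split_at <- 180
  a <- d[1:split_at, ]; b <- d[(split_at + 1):nrow(d), ]
  expect_equal(annual_thermal_load(a) + annual_thermal_load(b),
               annual_thermal_load(d))
  # raising any single day never decreases the total
  d2 <- d; i <- sample(nrow(d), 1); d2$cci_c[i] <- d2$cci_c[i] + 3
  expect_gte(annual_thermal_load(d2), annual_thermal_load(d))
  # permutation of days within the year leaves ATL unchanged
  d3 <- d; d3$cci_c <- sample(d3$cci_c)
  expect_equal(annual_thermal_load(d3), annual_thermal_load(d))
})

test_that("multi-year summaries average arithmetically and classify per bands", {
  five <- do.call(rbind, lapply(2019:2023, function(y) {
    mixed_cci_year(y, 60, 40)  # 60 days x 10 C excess = 600 per year
  }))
  s <- summarize_atl(five)
  expect_equal(unname(s$per_year_atl), rep(600, 5))
  expect_equal(s$mean_atl, 600)
  expect_equal(as.character(s$risk), "high")

  # years {0,0,0,0,500} -> mean 100, moderate (half-open band)
  mixed <- do.call(rbind, c(lapply(2019:2022, constant_cci_year, cci = 20),
                            list(mixed_cci_year(2023, 50, 40))))
  s2 <- summarize_atl(mixed)
  expect_equal(s2$mean_atl, 100)
  expect_equal(as.character(s2$risk), "moderate")

  s3 <- summarize_atl(mixed_cci_year(2021, 250, 40))
  expect_equal(s3$mean_atl, 2500)
  expect_equal(as.character(s3$risk), "extreme")
})

test_that("risk bands are half-open at their bounds", {
  expect_equal(as.character(classify_risk(c(0, 99.99, 100, 500, 1200, 2000, 2001))),
               c("low", "low", "moderate", "high", "very_high", "very_high",
                 "extreme"))
  expect_error(classify_risk(-1), ">= 0")
})

test_that("stress-day profiles count and average by category", {
  p <- stress_day_profile(constant_cci_year(2021, 20))
  expect_equal(unname(p$days_per_category[["no_stress"]]), 365)
  expect_equal(sum(p$days_per_category), 365)

  d <- mixed_cci_year(2021, 100, 37)
  p2 <- stress_day_profile(d)
  expect_equal(unname(p2$days_per_category[["strong"]]), 100)

  two <- rbind(mixed_cci_year(2021, 100, 37), mixed_cci_year(2022, 50, 37))
  p3 <- stress_day_profile(two)
  expect_equal(unname(p3$days_per_category[["strong"]]), 75)
  expect_equal(p3$years_covered, 2)
})

test_that("scenario assignment follows the grid with clamping conventions", {
  expect_equal(assign_scenario("strong", "very_high")$id, 7)
  expect_equal(assign_scenario("strong", "very_high")$label, "S-VH")
  expect_null(assign_scenario("mild", "extreme"))
  expect_null(assign_scenario("no_stress", "moderate"))

  expect_warning(sc <- assign_scenario("extreme", "moderate"), "clamped")
  expect_equal(sc$label, "E-H")
  expect_true(sc$clamped)
  expect_warning(sc2 <- assign_scenario("extreme_danger", "moderate"))
  expect_equal(sc2$label, "ED-VH")
  expect_warning(sc3 <- assign_scenario("extreme_danger", "high"))
  expect_equal(sc3$label, "ED-VH")
  expect_warning(sc4 <- assign_scenario("moderate", "low"), "low-risk")
  expect_equal(sc4$label, "M-M")
  # defined cells are silent
  expect_silent(assign_scenario("extreme", "extreme"))
})

test_that("scenario day counts cover exactly the moderate-plus days", {
  d <- mixed_cci_year(2021, 20, 32)
  counts <- count_scenario_days(d, "moderate")
  expect_equal(unname(counts[["M-M"]]), 20)

  d2 <- constant_cci_year(2021, 20)
  d2$cci_c[1:10] <- 37; d2$cci_c[11:15] <- 42
  d2$category <- classify_stress(d2$cci_c)
  counts2 <- count_scenario_days(d2, "high")
  expect_equal(unname(counts2[["S-H"]]), 10)
  expect_equal(unname(counts2[["E-H"]]), 5)
  expect_equal(sum(counts2), sum(d2$category >= "moderate"))

  expect_length(count_scenario_days(constant_cci_year(2021, 20), "high"), 0)

  # means across years may be fractional
  two <- rbind(mixed_cci_year(2021, 3, 32), mixed_cci_year(2022, 4, 32))
  expect_equal(unname(count_scenario_days(two, "moderate")[["M-M"]]), 3.5)

  # clamping events surface in the warnings attribute
  d3 <- mixed_cci_year(2021, 5, 46)
  counts3 <- count_scenario_days(d3, "moderate")
  expect_match(attr(counts3, "warnings"), "clamped", all = FALSE)
})
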