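test_that("the packaged configuration loads, validates and pins the M-M track", {
  cfg <- default_paintracks()
  expect_setequal(names(cfg), scenario_table()$label)
  mm <- cfg[["M-M"]]
  expect_equal(unname(mm$probs["II", c("annoying", "hurtful", "disabling")]),
               c(0.10, 0.80, 0.10))
  expect_equal(as.numeric(mm$durations$I), c(1, 2), ignore_attr = TRUE)
  expect_equal(as.numeric(mm$durations$II), c(2, 3), ignore_attr = TRUE)
  # every phase row is a probability distribution
  for (scn in cfg) expect_equal(unname(rowSums(scn$probs)), rep(1, 3))
  # the known phase-sum vs declared-total mismatches are surfaced, not hidden
  expect_match(attr(cfg, "consistency"), "M-M", all = FALSE)
  w <- capture_warnings(load_paintrack_config())
  expect_match(w, "phase durations sum", all = TRUE)
  expect_length(w, 3)  # M-M, M-H and M-E totals disagree with their phase sums
})

test_that("invalid configurations fail with the scenario and phase named", {
  cfg_raw <- yaml::read_yaml(system.file("extdata", "paintracks_default.yaml",
                                         package = "heatfootprint"))
  broken <- cfg_raw
  broken$scenarios$`S-H`$phases$I$probs$hurtful <- 0.36  # sum 0.9
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(broken, f)
  expect_error(suppressWarnings(load_paintrack_config(f)), "S-H phase I")

  broken2 <- cfg_raw
  broken2$scenarios$`M-VH`$phases$II$duration <- c(-1, 2)
  yaml::write_yaml(broken2, f)
  expect_error(suppressWarnings(load_paintrack_config(f)), "M-VH phase II")

  broken3 <- cfg_raw
  broken3$scenarios$`ED-E` <- NULL
  yaml::write_yaml(broken3, f)
  expect_error(suppressWarnings(load_paintrack_config(f)), "ED-E")
})

test_that("daily cumulative pain reproduces the published M-M table", {
  daily <- daily_cumulative_pain(default_paintracks()[["M-M"]])
  expect_equal(as.numeric(daily$hurtful), c(2.0, 3.2), ignore_attr = TRUE)
  expect_equal(as.numeric(daily$disabling), c(0.2, 0.3), ignore_attr = TRUE)
  expect_equal(as.numeric(daily$annoying), c(1.4, 2.7), ignore_attr = TRUE)
  expect_equal(as.numeric(daily$excruciating), c(0, 0), ignore_attr = TRUE)
  # conservation: intensities (incl. none) sum to the phase-duration sum
  tot <- Reduce(iv_add, daily)
  expect_equal(as.numeric(tot), c(4.0, 7.0), ignore_attr = TRUE)
})

test_that("a track with all mass on none yields zero discomfort", {
  probs <- matrix(0, 3, 5, dimnames = list(c("I", "II", "III"),
                                           c("none", "annoying", "hurtful",
                                             "disabling", "excruciating")))
  probs[, "none"] <- 1
  daily <- daily_cumulative_pain(list(iv(1, 2), iv(2, 3), iv(1, 2)), probs)
  for (k in c("annoying", "hurtful", "disabling", "excruciating")) {
    expect_equal(as.numeric(daily[[k]]), c(0, 0), ignore_attr = TRUE)
  }
  expect_equal(as.numeric(daily$none), c(4, 7), ignore_attr = TRUE)
})

test_that("cumulative pain matches a brute-force enumeration on random tracks", {
  set.seed(2024)
  for (i in 1:25) {
    lo <- sort(runif(3, 0, 4)); hi <- lo + runif(3, 0, 3)
    probs <- random_track()
    daily <- daily_cumulative_pain(list(iv(lo[1], hi[1]), iv(lo[2], hi[2]),
                                        iv(lo[3], hi[3])), probs)
    names(lo) <- names(hi) <- rownames(probs)
    oracle <- cumulative_pain_oracle(lo, hi, probs)
    for (k in colnames(probs)) {
      expect_equal(as.numeric(daily[[k]]), oracle[[k]], ignore_attr = TRUE)
    }
    # conservation holds on every random config
    tot <- Reduce(iv_add, daily)
    expect_equal(as.numeric(tot), c(sum(lo), sum(hi)), ignore_attr = TRUE)
  }
})

test_that("severe default hours grow along both scenario axes", {
  cfg <- default_paintracks()
  severe_mid <- function(lab) {
    d <- daily_cumulative_pain(cfg[[lab]])
    iv_mid(d$hurtful) + iv_mid(d$disabling)
  }
  chronic_chains <- list(c("M-M", "M-H", "M-VH", "M-E"),
                         c("S-M", "S-H", "S-VH", "S-E"),
                         c("E-H", "E-VH", "E-E"),
                         c("ED-VH", "ED-E"))
  acute_chains <- list(c("M-M", "S-M"),
                       c("M-H", "S-H", "E-H"),
                       c("M-VH", "S-VH", "E-VH", "ED-VH"),
                       c("M-E", "S-E", "E-E", "ED-E"))
  for (ch in c(chronic_chains, acute_chains)) {
    vals <- vapply(ch, severe_mid, numeric(1))
    expect_true(all(diff(vals) >= -1e-9),
                info = paste(ch, collapse = " -> "))
  }
  # excruciating mass appears only in extreme-danger scenarios, capped
  for (lab in names(cfg)) {
    ex <- cfg[[lab]]$probs[, "excruciating"]
    if (grepl("^ED", lab)) expect_true(all(ex <= 0.05)) else
      expect_equal(unname(ex), rep(0, 3))
  }
})

test_that("annual welfare scales daily intervals by scenario days, linearly", {
  cfg <- default_paintracks()
  aw <- annual_welfare(c("M-M" = 20), cfg)
  expect_equal(as.numeric(aw$hours$hurtful), c(40, 64), ignore_attr = TRUE)
  expect_equal(aw$days_in_stress, 20)
  expect_equal(as.numeric(aw$daily_on_stress_days$hurtful), c(2, 3.2),
               ignore_attr = TRUE)

  empty <- annual_welfare(setNames(numeric(0), character(0)), cfg)
  expect_equal(empty$days_in_stress, 0)
  for (k in names(empty$hours)) {
    expect_equal(as.numeric(empty$hours[[k]]), c(0, 0), ignore_attr = TRUE)
  }

  both <- annual_welfare(c("M-M" = 10, "S-M" = 10), cfg)
  mm <- annual_welfare(c("M-M" = 10), cfg)
  sm <- annual_welfare(c("S-M" = 10), cfg)
  for (k in names(both$hours)) {
    expect_equal(as.numeric(both$hours[[k]]),
                 as.numeric(iv_add(mm$hours[[k]], sm$hours[[k]])),
                 ignore_attr = TRUE)
  }

  expect_error(annual_welfare(c("NOPE" = 3), cfg), "unknown scenario")
  expect_error(annual_welfare(c("M-M" = -1), cfg), "negative")
})
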