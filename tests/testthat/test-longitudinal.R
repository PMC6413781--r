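test_that("directional and absolute change follow their definitions", {
  ds <- data.frame(participant = rep(c("A", "B"), each = 2),
                   visit_month = rep(c(0, 12), 2),
                   value = c(3, 5, 4, 3))  # changes +2, -1
  s <- change_from_baseline(ds, 12)$summary
  expect_equal(s$mean_change, 0.5)
  expect_equal(s$mean_abs_change, 1.5)

  ds0 <- ds; ds0$value <- c(3, 3, 4, 4)
  s0 <- change_from_baseline(ds0, 12)$summary
  expect_equal(s0$mean_change, 0)
  expect_equal(s0$mean_abs_change, 0)
})

test_that("eye-level changes pool into OD, OS and OU summaries", {
  ds <- expand.grid(participant = c("A", "B"), eye = c("OD", "OS"),
                    visit_month = c(0, 12), stringsAsFactors = FALSE)
  ds <- ds[order(ds$participant, ds$eye, ds$visit_month), ]
  base <- 4
  changes <- c(A.OD = 1, A.OS = -1, B.OD = 1, B.OS = 3)
  ds$value <- ifelse(ds$visit_month == 0, base,
                     base + changes[paste(ds$participant, ds$eye, sep = ".")])
  s <- change_from_baseline(ds, 12)$summary
  expect_equal(s$mean_change[s$group == "OD"], 1)
  expect_equal(s$mean_change[s$group == "OS"], 1)
  expect_equal(s$mean_change[s$group == "OU"], 1)
  expect_equal(s$n[s$group == "OU"], 4L)
  # OU directional mean = mean of OD and OS means under balanced eyes
  expect_equal(s$mean_change[s$group == "OU"],
               mean(s$mean_change[s$group %in% c("OD", "OS")]))
})

test_that("absolute change dominates directional change on random data", {
  set.seed(14)
  for (i in 1:10) {
    ds <- data.frame(participant = rep(paste0("P", 1:8), each = 2),
                     visit_month = rep(c(0, 12), 8),
                     value = rnorm(16, 4, 2))
    s <- change_from_baseline(ds, 12)$summary
    expect_gte(s$mean_abs_change + 1e-12, abs(s$mean_change))
  }
})

test_that("the earliest baseline with data is used", {
  ds <- data.frame(participant = c("A", "A", "A", "B", "B"),
                   visit_month = c(0, 1, 12, 1, 12),
                   value = c(2, 4, 5, 3, 6))
  ch <- change_from_baseline(ds, 12)$changes
  expect_equal(ch$baseline_month, c(0, 1))
  expect_equal(ch$change, c(3, 3))
})

test_that("significance labels follow the 0.05 / 0.10 convention", {
  expect_equal(significance_label(0.047), "significant")
  expect_equal(significance_label(0.08), "moderately significant")
  expect_equal(significance_label(0.5), "not significant")
  expect_equal(significance_label(c(0.049999, 0.05, 0.0999, 0.1)),
               c("significant", "moderately significant",
                 "moderately significant", "not significant"))
  expect_error(significance_label(0), "\\(0, 1\\]")
  expect_error(significance_label(1.2), "\\(0, 1\\]")
})

test_that("balanced complete data reproduce raw mean changes exactly", {
  tr <- cohort_truth(n_participants = 12, sd_intercept = 0, sd_slope = 0,
                     eye_sd = 0, seed = 3)
  ds <- simulate_latent_scores(tr, resid_sd = 0.4)
  f <- fit_longitudinal(ds, random = "intercept")
  raw <- aggregate(value ~ visit_month, ds, mean)
  expect_equal(f$estimates$estimate, raw$value[-1] - raw$value[1],
               tolerance = 1e-8)
})

test_that("the fitted visit effects recover the generating truth", {
  tr <- cohort_truth(n_participants = 40, seed = 7)
  ds <- simulate_latent_scores(tr, resid_sd = 0.05)
  f <- fit_longitudinal(ds)
  expect_false(f$fallback_applied)
  est12 <- f$estimates[f$estimates$visit_month == 12, ]
  expect_equal(est12$estimate, 1.0, tolerance = 0.1)
  expect_true(est12$ci_low <= est12$estimate &&
                est12$estimate <= est12$ci_high)
  expect_true(all(f$estimates$p > 0 & f$estimates$p <= 1))
})

test_that("eyes are nested within participants when both eyes are present", {
  tr <- cohort_truth(n_participants = 20, seed = 8)
  ds <- simulate_latent_scores(tr, resid_sd = 0.2, eyes = TRUE)
  f <- fit_longitudinal(ds)
  expect_equal(f$n_units, 40L)
  expect_match(f$model_label, "nested")
  est12 <- f$estimates[f$estimates$visit_month == 12, ]
  expect_equal(est12$estimate, 1.0, tolerance = 0.15)
})

test_that("a degenerate slope variance triggers the intercept-only fallback", {
  tr <- cohort_truth(n_participants = 6, sd_slope = 0, seed = 5)
  ds <- simulate_latent_scores(tr, resid_sd = 0)
  expect_message(f <- fit_longitudinal(ds), "falling back")
  expect_true(f$fallback_applied)
  expect_match(f$model_label, "random intercept per participant")
})

test_that("the fallback agrees with the slope model when slopes are absent", {
  tr <- cohort_truth(n_participants = 30, sd_slope = 0, seed = 21)
  ds <- simulate_latent_scores(tr, resid_sd = 0.3)
  f_int <- fit_longitudinal(ds, random = "intercept")
  f_slope <- suppressMessages(fit_longitudinal(ds))
  expect_equal(f_int$estimates$estimate, f_slope$estimates$estimate,
               tolerance = 0.05)
})

test_that("unusable datasets are rejected with clear errors", {
  ds <- data.frame(participant = "A", visit_month = c(0, 12), value = 1:2)
  expect_error(fit_longitudinal(ds), "2 participants")
  ds2 <- data.frame(participant = c("A", "B"), visit_month = 0, value = 1:2)
  expect_error(fit_longitudinal(ds2), "2 visits")
  expect_error(change_from_baseline(
    data.frame(participant = "A", visit_month = 0, value = 1), 12),
    "visit month 12")
})
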