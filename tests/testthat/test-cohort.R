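test_that("truth validation names the offending field", {
  expect_error(cohort_truth(sd_intercept = -1), "sd_intercept")
  expect_error(cohort_truth(visit_months = c(0, 6, 3)), "visit_months")
  expect_error(cohort_truth(visit_months = c(3, 6)), "month 0")
  expect_error(cohort_truth(n_graders = 1), "n_graders")
  expect_error(cohort_truth(images_per_eye_visit = 0), "images_per_eye_visit")
  expect_error(cohort_truth(visit_months = c(0, 3),
                            fixed_visit_effects = c(`0` = 0)),
               "fixed_visit_effects")
})

test_that("generation is deterministic given truth and seed", {
  tr <- cohort_truth(n_participants = 2, visit_months = c(0, 12),
                     fixed_visit_effects = c(`0` = 0, `12` = 1),
                     image_size = c(121, 121),
                     image_geometry = iris_geometry(60, 60, 50, 15),
                     seed = 17)
  b1 <- generate_cohort(tr)
  b2 <- generate_cohort(tr)
  expect_identical(b1$grades, b2$grades)
  expect_identical(b1$images, b2$images)
  expect_identical(b1$spectra, b2$spectra)
  expect_identical(b1$hair, b2$hair)
  expect_identical(b1$acuity, b2$acuity)
  # a different seed changes the draw
  tr2 <- cohort_truth(n_participants = 2, visit_months = c(0, 12),
                      fixed_visit_effects = c(`0` = 0, `12` = 1),
                      image_size = c(121, 121),
                      image_geometry = iris_geometry(60, 60, 50, 15),
                      seed = 18)
  expect_false(identical(generate_cohort(tr2, "grades")$grades, b1$grades))
  # grade stream does not depend on which other streams are generated
  expect_identical(generate_cohort(tr, "grades")$grades, b1$grades)
})

test_that("noise-free grades equal the latent score rounded to one decimal", {
  tr <- cohort_truth(n_participants = 3, grader_bias_sd = 0,
                     grader_noise_sd = 0, seed = 4)
  b <- generate_cohort(tr, "grades")
  m <- merge(b$grades, b$latent[, c("participant", "eye", "visit_month",
                                    "latent")])
  expect_equal(m$grade, round(m$latent, 1))
})

test_that("noise-free renders round-trip through the scorer", {
  g <- iris_geometry(120, 120, 100, 30)
  for (s in c(0, 2.5, 4, 8)) {
    img <- render_ti_image(s, g, size = c(241, 241), noise_sd = 0)
    expect_equal(semiquant_score(img)$score, s, tolerance = 0.05,
                 info = paste("latent", s))
  }
  # extremes are exact: annulus red is identically 0 / 255
  img0 <- render_ti_image(0, g, size = c(241, 241), noise_sd = 0)
  expect_true(all(img0$pixels[, , 1][melaquant:::annulus_mask(g, c(241, 241))] == 0))
  img8 <- render_ti_image(8, g, size = c(241, 241), noise_sd = 0)
  expect_true(all(img8$pixels[, , 1][melaquant:::annulus_mask(g, c(241, 241))] == 255))
  expect_error(render_ti_image(4, g, size = c(100, 100)), "image bounds")
})

test_that("the full noise-free bundle is recovered by the image scorer", {
  tr <- cohort_truth(n_participants = 2, visit_months = c(0, 12),
                     fixed_visit_effects = c(`0` = 0, `12` = 1),
                     image_noise_sd = 0, image_size = c(161, 161),
                     image_geometry = iris_geometry(80, 80, 65, 20),
                     seed = 6)
  b <- generate_cohort(tr, "images")
  res <- score_image_set(b$images)
  m <- merge(res$eye_visit_scores,
             b$latent[, c("participant", "eye", "visit_month", "latent")])
  expect_equal(m$mean_score, m$latent, tolerance = 0.05)
})

test_that("synthetic spectra encode their target M index exactly", {
  rt <- default_reflectometry_truth()
  rt$replicate_sd <- 0; rt$participant_sd <- 0
  tr <- cohort_truth(n_participants = 1, visit_months = c(0, 12),
                     fixed_visit_effects = c(`0` = 0, `12` = 1),
                     reflectometry_truth = rt, seed = 12)
  b <- generate_cohort(tr, "spectra")
  ms <- summarize_site(b$spectra)
  expected <- merge(ms, rt, by = "site")
  expect_equal(
    expected$m_index,
    expected$baseline_m + expected$shift_12 * pmin(expected$visit_month, 12) / 12,
    tolerance = 1e-9)
})

test_that("baseline panel-mean dispersion matches the generating variances", {
  tr <- cohort_truth(n_participants = 500, visit_months = 0,
                     fixed_visit_effects = c(`0` = 0), eye_sd = 0, seed = 19)
  b <- generate_cohort(tr, "grades")
  pm <- panel_scores(b$grades)
  pm_od <- pm[pm$eye == "OD", ]
  # analytic SD of per-participant panel means: participant intercept plus
  # grader noise averaged over 18 graders x 2 images (grader bias is a
  # common offset and adds nothing across participants); one-decimal
  # rounding adds ~uniform(-0.05, 0.05) per grade
  analytic <- sqrt(tr$sd_intercept^2 +
                     (tr$grader_noise_sd^2 + 0.1^2 / 12) / (18 * 2))
  expect_equal(sd(pm_od$mean_score), analytic, tolerance = 0.1 * analytic)
})

test_that("a second baseline visit exercises the earliest-baseline rule", {
  tr <- cohort_truth(second_baseline = TRUE, seed = 2)
  expect_true(1 %in% tr$visit_months)
  expect_equal(unname(tr$fixed_visit_effects[["1"]]), 0)
  ds <- simulate_latent_scores(tr, resid_sd = 0.1)
  ch <- change_from_baseline(ds, 12)$changes
  expect_true(all(ch$baseline_month == 0))
})

test_that("bundles write to disk and read back consistently", {
  tr <- cohort_truth(n_participants = 2, visit_months = c(0, 12),
                     fixed_visit_effects = c(`0` = 0, `12` = 1),
                     images_per_eye_visit = 1,
                     image_size = c(121, 121),
                     image_geometry = iris_geometry(60, 60, 50, 15),
                     seed = 23)
  b <- generate_cohort(tr)
  dir <- tempfile("bundle")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  write_bundle(b, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "grades.csv", "spectra.csv", "hair.csv", "acuity.csv", "geometry.csv",
    "truth.yaml", "manifest.yaml")))))
  grades <- read_grades(file.path(dir, "grades.csv"))
  expect_equal(nrow(grades), nrow(b$grades))
  spectra <- read_spectra(file.path(dir, "spectra.csv"))
  expect_equal(nrow(spectra), nrow(b$spectra))
  imgs <- read_ti_images(file.path(dir, "images"),
                         file.path(dir, "geometry.csv"))
  expect_equal(length(imgs), length(b$images))
  # PNG round trip is lossless
  expect_equal(imgs[[1]]$pixels, b$images[[1]]$pixels)
})
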