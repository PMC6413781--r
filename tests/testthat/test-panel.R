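test_that("grade validation enforces the one-decimal 0-8 scale", {
  g <- grades_from_matrix(matrix(c(1, 2, 3, 4), 2))
  expect_silent(validate_grades(g))
  g$grade[1] <- 8.5
  expect_error(validate_grades(g), "\\[0, 8\\]")
  g$grade[1] <- 4.25
  expect_error(validate_grades(g), "one decimal")
  expect_error(validate_grades(g[, -6]), "missing column")
})

test_that("panel means are the two-stage grader-then-image average", {
  # all graders agree at 5.0 on both images
  g <- expand.grid(participant = "P1", eye = "OD", visit_month = 0,
                   grader_id = paste0("G", 1:18), image_index = 1:2,
                   stringsAsFactors = FALSE)
  g$grade <- 5
  expect_equal(panel_scores(g)$mean_score, 5)
  expect_equal(panel_scores(g)$n_graders_used, 18L)

  # grader A: 4 & 5 -> 4.5; grader B: 6 & 7 -> 6.5; panel mean 5.5
  g2 <- expand.grid(participant = "P1", eye = "OD", visit_month = 0,
                    grader_id = c("A", "B"), image_index = 1:2,
                    stringsAsFactors = FALSE)
  g2$grade <- c(4, 6, 5, 7)
  expect_equal(panel_scores(g2)$mean_score, 5.5)

  # permutation invariance
  shuffled <- g2[sample(nrow(g2)), ]
  expect_equal(panel_scores(shuffled), panel_scores(g2))
})

test_that("perfect agreement yields ICC 1", {
  M <- matrix(rep(c(2, 4.5, 7), 3), ncol = 3)  # distinct rows, equal columns
  r <- intergrader_icc(grades_from_matrix(M))
  expect_equal(r$icc, 1)
  expect_equal(r$icc_avg, 1)
  expect_true(r$ci_low <= r$icc && r$icc <= r$ci_high)
})

test_that("the worked 5x3 matrix matches a longhand ANOVA oracle", {
  M <- matrix(c(2, 2.5, 3, 4, 4.5, 4, 6, 5.5, 6.5, 1, 1.5, 1, 7, 7.5, 8),
              ncol = 3, byrow = TRUE)
  r <- intergrader_icc(grades_from_matrix(M))

  # independent route: two-way ANOVA mean squares via stats::aov
  d <- data.frame(y = as.vector(M),
                  row = factor(rep(1:5, 3)), col = factor(rep(1:3, each = 5)))
  ms <- summary(stats::aov(y ~ row + col, d))[[1]][, "Mean Sq"]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  n <- 5; k <- 3
  icc_oracle <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  icck_oracle <- (MSR - MSE) / (MSR + (MSC - MSE) / n)
  expect_equal(r$icc, icc_oracle, tolerance = 1e-10)
  expect_equal(r$icc_avg, icck_oracle, tolerance = 1e-10)

  # frozen values (point estimates and 95% CI cross-validated against an
  # independent two-way random-effects agreement ICC implementation)
  expect_equal(r$icc, 0.972568578554, tolerance = 1e-9)
  expect_equal(r$icc_avg, 0.990685859441, tolerance = 1e-9)
  expect_equal(r$ci_low, 0.878626441129, tolerance = 1e-6)
  expect_equal(r$ci_high, 0.996867019616, tolerance = 1e-6)
})

test_that("single-measure ICC never exceeds the average-measure ICC", {
  set.seed(31)
  for (i in 1:10) {
    M <- matrix(rnorm(8 * 4, mean = rep(rnorm(8, 4, 1.5), 4), sd = 0.4), 8)
    M <- round(pmin(pmax(M, 0), 8), 1)
    r <- tryCatch(intergrader_icc(grades_from_matrix(M)),
                  error = function(e) NULL)
    if (is.null(r)) next
    expect_lte(r$icc, r$icc_avg + 1e-12)
    expect_true(r$ci_low <= r$icc && r$icc <= r$ci_high)
  }
})

test_that("degenerate and incomplete panels are rejected", {
  M <- matrix(5, 4, 3)
  expect_error(intergrader_icc(grades_from_matrix(M)), "constant grades")
  g <- grades_from_matrix(matrix(c(1, 2, 3, 4, 5, 6), 3))
  g <- g[-1, ]  # knock out one cell
  expect_error(intergrader_icc(g), "incomplete")
  r <- intergrader_icc(g, allow_missing = TRUE)
  expect_equal(r$n_participants, 2L)
})

test_that("grader noise lowers the ICC towards zero without signal", {
  tr_lo <- cohort_truth(n_participants = 30, visit_months = 0,
                        fixed_visit_effects = c(`0` = 0),
                        grader_noise_sd = 0.2, seed = 9)
  tr_hi <- cohort_truth(n_participants = 30, visit_months = 0,
                        fixed_visit_effects = c(`0` = 0),
                        grader_noise_sd = 1.5, seed = 9)
  icc_lo <- intergrader_icc(generate_cohort(tr_lo, "grades")$grades,
                            eye = "OD", visit_month = 0)$icc
  icc_hi <- intergrader_icc(generate_cohort(tr_hi, "grades")$grades,
                            eye = "OD", visit_month = 0)$icc
  expect_gt(icc_lo, icc_hi)
})

test_that("Spearman agreement between methods uses pooled midranks", {
  panel <- data.frame(participant = paste0("P", 1:6), eye = "OD",
                      visit_month = 0,
                      mean_score = c(1, 2.5, 3, 4.5, 6, 7))
  mono <- panel; mono$mean_score <- panel$mean_score^2 / 10
  expect_equal(method_correlation(panel, mono), 1)
  anti <- panel; anti$mean_score <- rev(sort(panel$mean_score))
  expect_equal(method_correlation(panel, anti), -1)

  # worked 6-pair table with a tie, against a longhand midrank oracle
  semi <- panel
  semi$mean_score <- c(2, 2, 5, 4, 8, 9)
  midrank <- function(x) {
    vapply(x, function(v) sum(x < v) + (1 + sum(x == v)) / 2, numeric(1))
  }
  rx <- midrank(panel$mean_score); ry <- midrank(semi$mean_score)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(method_correlation(panel, semi), oracle, tolerance = 1e-12)

  expect_error(method_correlation(panel[1:2, ], semi[1:2, ]), "at least 3")
})
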