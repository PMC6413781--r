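test_that("the M index reproduces its closed forms", {
  expect_equal(m_index(flat_spectrum(100)), 0)
  expect_equal(m_index(flat_spectrum(10)), 100)
  expect_equal(m_index(flat_spectrum(50)), 100 * log10(2), tolerance = 1e-12)
  # weighted band: (60 + 40 + 0.5*50 + 0.5*30)/3 / 100 = 0.4666...
  s <- flat_spectrum(70)
  s[c("640", "650", "660", "670")] <- c(50, 60, 40, 30)
  expect_equal(m_index(s), 100 * log10(3 / 1.4), tolerance = 1e-12)
})

test_that("M is log-linear and ignores wavelengths outside 640-670 nm", {
  s <- flat_spectrum(23.7)
  expect_equal(m_index(s * 10) - m_index(s), -100, tolerance = 1e-9)
  s2 <- s
  s2[as.character(seq(400, 630, 10))] <- 99
  s2[as.character(c(680, 690, 700))] <- 1
  expect_equal(m_index(s2), m_index(s))
  # strictly decreasing in any band reflectance increase
  s3 <- s
  s3["650"] <- s3["650"] + 5
  expect_lt(m_index(s3), m_index(s))
})

test_that("invalid spectra are rejected", {
  expect_error(m_index(flat_spectrum(0)), "non-positive reflectance")
  s <- flat_spectrum(50)[-25]  # drop 640 nm
  expect_error(m_index(s), "640")
})

test_that("site summaries average replicate M indices", {
  mk <- function(m, rep) data.frame(participant = "P1", visit_month = 0,
                                    site = "inner_bicep", replicate = rep,
                                    wavelength = seq(400, 700, 10),
                                    pr = flat_spectrum(10^(2 - m / 100)))
  target <- c(20, 22, 24, 26, 28)
  sp <- do.call(rbind, Map(mk, target, 1:5))
  out <- summarize_site(sp)
  expect_equal(out$m_index, 24, tolerance = 1e-9)
  expect_equal(out$n_replicates, 5L)
  # identical replicates: site M equals single-spectrum M
  sp2 <- do.call(rbind, Map(mk, rep(33, 5), 1:5))
  expect_equal(summarize_site(sp2)$m_index, 33, tolerance = 1e-9)
  # single replicate
  expect_equal(summarize_site(mk(41, 1))$n_replicates, 1L)
  expect_equal(summarize_site(mk(41, 1))$m_index, 41, tolerance = 1e-9)
})

test_that("mean-spectrum aggregation equals mean-m only for equal replicates", {
  mk <- function(m, rep) data.frame(participant = "P1", visit_month = 0,
                                    site = "hair", replicate = rep,
                                    wavelength = seq(400, 700, 10),
                                    pr = flat_spectrum(10^(2 - m / 100)))
  sp <- rbind(mk(20, 1), mk(60, 2))
  mm <- summarize_site(sp, aggregate = "mean-m")$m_index
  ms <- summarize_site(sp, aggregate = "mean-spectrum")$m_index
  expect_equal(mm, 40, tolerance = 1e-9)
  # Jensen gap: M of the mean spectrum is below the mean M
  expect_lt(ms, mm)
  sp_eq <- rbind(mk(30, 1), mk(30, 2))
  expect_equal(summarize_site(sp_eq, aggregate = "mean-spectrum")$m_index,
               30, tolerance = 1e-9)
})

test_that("calibration references are checked against tolerance", {
  ok <- calibration_check(flat_spectrum(100), flat_spectrum(0))
  expect_true(ok$pass)
  borderline <- calibration_check(flat_spectrum(101.5), flat_spectrum(0.5))
  expect_true(borderline$pass)
  bad <- calibration_check(flat_spectrum(95), flat_spectrum(0))
  expect_false(bad$pass)
  expect_equal(nrow(bad$deviations), 31L)
  expect_true(all(bad$deviations$deviation == -5))
  expect_error(calibration_check(flat_spectrum(100)[-1], flat_spectrum(0)),
               "full 400-700")
})
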