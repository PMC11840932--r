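test_that("baseline correction removes a pure linear ramp exactly", {
  nu <- seq(250, 500, by = 1)
  sp <- ir_spectrum(nu, 0.2 + 0.003 * nu)
  out <- baseline_correct(sp, degree = 1)
  expect_lt(max(abs(out$intensity)), 1e-9)
  expect_error(baseline_correct(sp, degree = 3), "degree")
})

test_that("baseline correction preserves the band apex on a ramp and is idempotent", {
  flat <- single_band_spectrum(center = 375, amplitude = 0.8)
  ramped <- single_band_spectrum(center = 375, amplitude = 0.8,
                                 baseline = c(0.1, 5e-4))
  corr <- baseline_correct(ramped, degree = 1)
  apex_ref <- max(flat$intensity)
  apex_corr <- corr$intensity[which.max(corr$intensity)]
  expect_equal(apex_corr, apex_ref, tolerance = 0.01)
  twice <- baseline_correct(corr, degree = 1)
  expect_lt(max(abs(twice$intensity - corr$intensity)), 1e-6)
})

test_that("second derivative is zero for a line and minimal at band centers", {
  nu <- seq(250, 500, by = 1)
  line <- ir_spectrum(nu, 1 + 0.01 * nu)
  d2 <- second_derivative(line)
  expect_lt(max(abs(d2$intensity)), 1e-10)

  one <- single_band_spectrum(center = 362)
  d2b <- second_derivative(one)
  expect_equal(d2b$wavenumber[which.min(d2b$intensity)], 362, tolerance = 1)

  lib <- band_library(rbind(band(362, 15, 0.8, shape = "gaussian",
                                 species = "EndoIII"),
                            band(392, 15, 0.8, shape = "gaussian",
                                 species = "EndoIII")), "far-IR")
  two <- generate_spectrum(lib, "EndoIII",
                           sim_config(250, 500, 1, 0, seed = 1L))
  pk <- detect_peaks(second_derivative(two))
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$center, c(362, 392), tolerance = 1)

  expect_error(second_derivative(one, window_pts = 10), "odd")
  expect_error(second_derivative(one, window_pts = 501), "larger")
})

test_that("second derivative is linear in its input", {
  f <- single_band_spectrum(center = 340, amplitude = 0.5)
  g <- single_band_spectrum(center = 420, amplitude = 0.7)
  lhs <- second_derivative(ir_spectrum(f$wavenumber,
                                       2 * f$intensity + 3 * g$intensity))
  rhs <- 2 * second_derivative(f)$intensity + 3 * second_derivative(g)$intensity
  expect_lt(max(abs(lhs$intensity - rhs)), 1e-9)
})

test_that("peak detection finds the packaged Fe-S bands and nothing on flat input", {
  nu <- seq(250, 500, by = 1)
  expect_equal(nrow(detect_peaks(ir_spectrum(nu, rep(0, length(nu))))), 0L)

  lib <- default_band_library("far-IR")
  sp <- generate_spectrum(lib, "EndoIII", default_sim_config("far-IR", 3L))
  d2 <- second_derivative(baseline_correct(sp))
  pk <- detect_peaks(d2, prominence_frac = 0.1, window = c(300, 460))
  expect_equal(nrow(pk), 4L)
  expect_equal(pk$center, c(326, 362, 392, 443), tolerance = 1)
  expect_true(all(pk$center >= pk$lo & pk$center <= pk$hi))
  expect_true(all(pk$prominence > 0))
  expect_error(detect_peaks(d2, window = c(600, 700)), "empty window")
  expect_error(detect_peaks(d2, prominence_frac = 0), "prominence_frac")
})

test_that("detected peaks are invariant to a linear baseline offset", {
  lib <- default_band_library("far-IR")
  cfg0 <- default_sim_config("far-IR", 3L, baseline_coeffs = c(0, 0, 0))
  cfg1 <- default_sim_config("far-IR", 3L, baseline_coeffs = c(0.3, 2e-3, 0))
  chain <- function(cfg) {
    sp <- generate_spectrum(lib, "EndoIII", cfg)
    detect_peaks(second_derivative(baseline_correct(sp)),
                 window = c(300, 460))
  }
  expect_equal(chain(cfg0)$center, chain(cfg1)$center, tolerance = 0.2)
})

test_that("peak matching handles identity, shift, and disappearance", {
  pk <- function(centers) data.frame(center = centers,
                                     prominence = rep(1, length(centers)),
                                     lo = centers - 5, hi = centers + 5)
  same <- match_peaks(pk(c(326, 362, 392)), pk(c(326, 362, 392)))
  expect_true(all(same$status == "unchanged"))
  expect_true(all(same$delta_nu == 0))

  thio <- match_peaks(pk(362), pk(352), tol = 20)
  expect_equal(thio$delta_nu, 10)
  expect_equal(thio$status, "shifted")

  gone <- match_peaks(pk(890), pk(numeric(0)), tol = 20)
  expect_equal(gone$status, "disappeared")
  expect_true(is.na(gone$nu))

  empty <- match_peaks(pk(numeric(0)), pk(numeric(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("peak matching conserves counts on random peak sets", {
  set.seed(42)
  pk <- function(centers) data.frame(center = centers,
                                     prominence = rep(1, length(centers)),
                                     lo = centers - 5, hi = centers + 5)
  for (i in 1:20) {
    n0 <- sample(0:8, 1); n1 <- sample(0:8, 1)
    a <- pk(sort(runif(n0, 300, 500)))
    b <- pk(sort(runif(n1, 300, 500)))
    m <- match_peaks(a, b, tol = 15)
    matched <- sum(m$status %in% c("shifted", "unchanged"))
    expect_equal(matched + sum(m$status == "disappeared"), n0)
    expect_equal(matched + sum(m$status == "new"), n1)
  }
})

test_that("difference spectra subtract pointwise and localize the thiolate change", {
  sp <- single_band_spectrum()
  zero <- difference_spectrum(sp, sp)
  expect_true(all(zero$intensity == 0))

  ramped <- single_band_spectrum(baseline = c(0.1, 5e-4))
  base <- ir_spectrum(sp$wavenumber,
                      0.1 + 5e-4 * sp$wavenumber)
  pure <- difference_spectrum(ramped, base)
  expect_lt(max(abs(pure$intensity - sp$intensity)), 1e-9)

  lib <- default_band_library("far-IR")
  cfg <- default_sim_config("far-IR", 3L)
  nat <- generate_spectrum(lib, "EndoIII", cfg)
  cpx <- generate_spectrum(lib, "complex", cfg)
  d <- difference_spectrum(cpx, nat)
  peak_at <- d$wavenumber[which.max(abs(d$intensity))]
  expect_gte(peak_at, 350)
  expect_lte(peak_at, 365)

  other <- single_band_spectrum(from = 240, to = 490)
  expect_error(difference_spectrum(sp, other), "grid mismatch")
})

test_that("noise estimate recovers the simulated noise scale", {
  lib <- default_band_library("far-IR")
  cfg <- default_sim_config("far-IR", 11L, noise_sigma = 0.01)
  sp <- generate_spectrum(lib, "EndoIII", cfg)
  expect_equal(estimate_noise(sp), 0.01, tolerance = 0.3)
})
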