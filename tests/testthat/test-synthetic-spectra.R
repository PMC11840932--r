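test_that("far-IR library carries the four Fe-S modes and the thiolate downshift", {
  lib <- default_band_library("far-IR")
  endo <- lib$bands[lib$bands$species == "EndoIII", ]
  expect_equal(sort(endo$center), c(326, 362, 392, 443))
  expect_equal(nrow(endo), 4L)
  cpx <- lib$bands[lib$bands$species == "complex", ]
  expect_true(352 %in% cpx$center)
  expect_false(362 %in% cpx$center)
  expect_equal(cpx$origin[cpx$center == 352], "362")
})

test_that("mid-IR complex library drops 890/967, shifts amide-I, splits 1376", {
  lib <- default_band_library("mid-IR")
  cpx <- lib$bands[lib$bands$species == "complex", ]
  expect_false(any(cpx$center %in% c(890, 967)))
  expect_true(1650 %in% cpx$center)
  expect_equal(cpx$origin[cpx$center == 1650], "1653")
  split <- cpx[cpx$origin == "1376", ]
  expect_gte(nrow(split), 2L)
  expect_true(all(split$amplitude < 0.6))
  # every complex band traces to a native center or is flagged new
  native_centers <- lib$bands$center[lib$bands$species != "complex"]
  expect_true(all(cpx$origin == "new" |
                    as.numeric(cpx$origin) %in% native_centers))
  expect_error(default_band_library("near-IR"))
})

test_that("band and library invariants are enforced", {
  expect_error(band(362, fwhm = -1, amplitude = 1), "fwhm")
  expect_error(band(362, fwhm = 12, amplitude = -1), "amplitude")
  expect_error(band(362, 12, 1, eta = 1.5), "eta")
  dup <- rbind(band(362, 12, 1, species = "EndoIII"),
               band(362, 10, 2, species = "EndoIII"))
  expect_error(band_library(dup, "far-IR"), "share a center")
})

test_that("noiseless single-band spectrum peaks at the center with the band amplitude", {
  sp <- single_band_spectrum(center = 362, amplitude = 0.8)
  i <- which.max(sp$intensity)
  expect_equal(sp$wavenumber[i], 362)
  expect_equal(max(sp$intensity), 0.8, tolerance = 1e-12)
})

test_that("generation is deterministic and grid errors are caught", {
  lib <- default_band_library("far-IR")
  cfg <- default_sim_config("far-IR", seed = 7L)
  a <- generate_spectrum(lib, "EndoIII", cfg)
  b <- generate_spectrum(lib, "EndoIII", cfg)
  expect_identical(a$intensity, b$intensity)
  # seed isolation: package generation must not disturb the session RNG
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_spectrum(lib, "EndoIII", cfg))
  expect_identical(rnorm(1), before)
  small <- sim_config(400, 500, 1, seed = 1L)
  expect_error(generate_spectrum(lib, "EndoIII", small), "outside")
  expect_error(sim_config(250, 500, grid_step = -1), "grid_step")
  expect_error(sim_config(500, 250), "grid_start")
})

test_that("gaussian band area matches the closed-form integral", {
  A <- 0.8; w <- 12
  sp <- single_band_spectrum(center = 375, fwhm = w, amplitude = A,
                             from = 200, to = 550, step = 0.05)
  area_num <- sum(sp$intensity) * 0.05
  area_closed <- A * w / 2 * sqrt(pi / log(2))
  expect_equal(area_num, area_closed, tolerance = 1e-3)
})

test_that("two-band spectrum is the sum of single-band spectra plus one baseline/noise draw", {
  b1 <- band(340, 12, 0.5, species = "EndoIII")
  b2 <- band(420, 12, 0.7, species = "EndoIII")
  cfg <- sim_config(250, 500, 1, noise_sigma = 0.01,
                    baseline_coeffs = c(0.05, 1e-4), seed = 5L)
  lib12 <- band_library(rbind(b1, b2), "far-IR")
  lib1 <- band_library(b1, "far-IR")
  lib2 <- band_library(b2, "far-IR")
  lib0 <- band_library(band(340, 12, 0, species = "dsDNA"), "far-IR")
  both <- generate_spectrum(lib12, "EndoIII", cfg)
  s1 <- generate_spectrum(lib1, "EndoIII", cfg)
  s2 <- generate_spectrum(lib2, "EndoIII", cfg)
  base_noise <- generate_spectrum(lib0, "dsDNA", cfg)  # zero-amplitude band
  expect_equal(both$intensity,
               s1$intensity + s2$intensity - base_noise$intensity,
               tolerance = 1e-12)
})

test_that("forward model places tracked complex bands at nu0 - k/r", {
  fw <- forward_from_distances(7.0, k = 70)
  expect_equal(fw$tracked$delta_nu, 10)
  cpx <- fw$complex
  expect_equal(cpx$wavenumber[which.max(cpx$intensity)],
               fw$tracked$nu0 - 10, tolerance = 0.1)
  # infinite-distance limit: complex band at the native center
  far <- forward_from_distances(1e9, k = 70)
  expect_equal(far$tracked$delta_nu, 7e-8, tolerance = 1e-12)
  expect_error(forward_from_distances(c(7, -1), k = 70), "distances")
  expect_error(forward_from_distances(7, k = 0), "k must be")
})
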