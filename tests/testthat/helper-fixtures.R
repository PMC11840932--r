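# shared fixtures, all built in code at test time

# noiseless single-gaussian spectrum
single_band_spectrum <- function(center = 362, fwhm = 12, amplitude = 0.8,
                                 from = 250, to = 500, step = 1,
                                 baseline = c(0, 0, 0)) {
  lib <- band_library(band(center, fwhm, amplitude, shape = "gaussian",
                           species = "EndoIII"), "far-IR")
  cfg <- sim_config(from, to, step, noise_sigma = 0,
                    baseline_coeffs = baseline, seed = 1L)
  generate_spectrum(lib, "EndoIII", cfg)
}

# minimal peak_shifts table for the distance/feature modules
make_shifts <- function(nu0, nu, status = NULL) {
  d <- abs(nu - nu0)
  if (is.null(status)) status <- ifelse(d <= 1, "unchanged", "shifted")
  out <- data.frame(assignment = sprintf("band-%d", seq_along(nu0)),
                    nu0 = nu0, nu = nu, delta_nu = d,
                    intensity_change = 0, status = status,
                    intensity_confirmed = NA)
  class(out) <- c("peak_shifts", "data.frame")
  out
}

# independent ridge oracle: literal penalized normal equations with an
# unpenalized intercept, solved by qr.solve
ridge_oracle <- function(x, y, alpha) {
  X <- cbind(1, as.matrix(x))
  P <- diag(c(0, rep(alpha, ncol(x))))
  beta <- qr.solve(crossprod(X) + P, crossprod(X, y))
  list(intercept = beta[1], coefficients = beta[-1])
}

# exact noiseless feature table for the forward model (tracked bands at
# nu0, complex centers nu0 - k/r), descriptor = signed position change
forward_feature_table <- function(r, nu0, k = 70) {
  sh <- make_shifts(nu0, nu0 - k / r, status = rep("shifted", length(r)))
  build_feature_table(sh, k = k, descriptor = "change")
}
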