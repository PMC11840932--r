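#' Iterative polynomial baseline correction
#'
#' Fits a polynomial of the given degree to the spectrum, then performs
#' two rounds of peak masking (points whose residual exceeds twice the
#' robust residual scale are dropped from the fit) and subtracts the
#' final baseline. Peak-free regions end up with mean ~0.
#'
#' @param spectrum An [ir_spectrum()].
#' @param degree Polynomial degree, 0, 1 or 2.
#' @param n_mask_rounds Rounds of outlier (peak) masking.
#' @return Baseline-corrected [ir_spectrum()] on the same grid.
#' @export
baseline_correct <- function(spectrum, degree = 1, n_mask_rounds = 2) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  if (!degree %in% 0:2) stop("degree must be 0, 1 or 2")
  nu <- spectrum$wavenumber
  y <- spectrum$intensity
  if (length(nu) < degree + 2) stop("spectrum shorter than degree + 2 points")
  x <- nu - mean(nu)  # center for conditioning
  X <- stats::poly(x, degree = max(degree, 1), raw = TRUE,
                   simple = TRUE)[, seq_len(degree), drop = FALSE]
  keep <- rep(TRUE, length(nu))
  fit_baseline <- function(keep) {
    if (degree == 0) return(rep(mean(y[keep]), length(y)))
    f <- stats::lm.fit(cbind(1, X[keep, , drop = FALSE]), y[keep])
    drop(cbind(1, X) %*% f$coefficients)
  }
  base <- fit_baseline(keep)
  for (i in seq_len(n_mask_rounds)) {
    res <- y - base
    s <- stats::mad(res)
    if (s == 0) s <- stats::sd(res)
    if (is.na(s) || s == 0) break
    keep <- res < 2 * s              # mask upward excursions (bands)
    if (sum(keep) < degree + 2) break
    base <- fit_baseline(keep)
  }
  ir_spectrum(nu, y - base,
              meta = c(spectrum$meta, list(baseline_degree = degree)))
}

#' Savitzky-Golay second derivative
#'
#' Second derivative on the native grid via a Savitzky-Golay filter;
#' band centers of symmetric bands appear as local minima. Defaults
#' (11-point window, cubic) preserve ~12 cm^-1 wide bands on a 1 cm^-1
#' grid.
#'
#' @param spectrum An [ir_spectrum()].
#' @param window_pts Odd filter window length in points,
#'   `> poly_order`.
#' @param poly_order Polynomial order (>= 2).
#' @return An [ir_spectrum()] holding d2A/dnu2.
#' @export
second_derivative <- function(spectrum, window_pts = 11, poly_order = 3) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  if (window_pts %% 2 == 0) stop("window_pts must be odd")
  if (poly_order < 2) stop("poly_order must be >= 2")
  if (window_pts <= poly_order) stop("window_pts must exceed poly_order")
  n <- length(spectrum$wavenumber)
  if (window_pts > n) stop("window larger than spectrum")
  step <- spectrum$wavenumber[2] - spectrum$wavenumber[1]
  d2 <- signal::sgolayfilt(spectrum$intensity, p = poly_order,
                           n = window_pts, m = 2, ts = step)
  ir_spectrum(spectrum$wavenumber, d2,
              meta = c(spectrum$meta, list(derivative = 2L)))
}

#' Detect band positions from a second-derivative spectrum
#'
#' Bands are local minima of the second derivative. On a
#' baseline-corrected spectrum the second derivative is ~0 away from
#' bands, so a minimum's prominence is taken as its depth below zero; a
#' minimum is kept when that depth reaches `prominence_frac` times the
#' depth of the deepest minimum in the window. Centers are refined by
#' parabolic interpolation through the three points around each minimum.
#'
#' @param sd_spectrum Second-derivative [ir_spectrum()] (output of
#'   [second_derivative()]).
#' @param prominence_frac Fraction in `(0, 1]`.
#' @param window Optional `c(lo, hi)` wavenumber window to search.
#' @return A `peak_list` data frame with columns `center`, `prominence`,
#'   `lo`, `hi` (centers sorted ascending).
#' @export
detect_peaks <- function(sd_spectrum, prominence_frac = 0.1, window = NULL) {
  stopifnot(inherits(sd_spectrum, "ir_spectrum"))
  if (prominence_frac <= 0 || prominence_frac > 1)
    stop("prominence_frac must be in (0, 1]")
  nu <- sd_spectrum$wavenumber
  d2 <- sd_spectrum$intensity
  if (!is.null(window)) {
    sel <- nu >= window[1] & nu <= window[2]
    if (!any(sel)) stop("empty window")
    nu <- nu[sel]; d2 <- d2[sel]
  }
  empty <- data.frame(center = numeric(), prominence = numeric(),
                      lo = numeric(), hi = numeric())
  class(empty) <- c("peak_list", "data.frame")
  y <- -d2                                  # minima of d2 -> maxima of y
  n <- length(y)
  if (n < 3) return(empty)
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  cand <- cand[y[cand] > 0]                 # require negative d2
  if (!length(cand)) return(empty)
  prom <- y[cand]                           # depth below zero
  keep <- prom >= prominence_frac * max(y)
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty)
  step <- nu[2] - nu[1]
  center <- vapply(cand, function(i) {
    a <- y[i - 1]; b <- y[i]; cc <- y[i + 1]
    den <- a - 2 * b + cc
    off <- if (den == 0) 0 else 0.5 * (a - cc) / den
    nu[i] + off * step
  }, numeric(1))
  # half-depth crossing window around each peak
  half_window <- function(j, dir) {
    i <- cand[j]; th <- prom[j] / 2
    while (i > 1 && i < n && y[i] > th) i <- i + dir
    nu[i]
  }
  lo <- vapply(seq_along(cand), half_window, numeric(1), dir = -1L)
  hi <- vapply(seq_along(cand), half_window, numeric(1), dir = 1L)
  out <- data.frame(center = center, prominence = prom, lo = lo, hi = hi)
  out <- out[order(out$center), ]
  rownames(out) <- NULL
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Match peaks between a native and a complex spectrum
#'
#' Greedy nearest-neighbour matching of detected band centers within a
#' tolerance: candidate pairs are accepted in order of increasing
#' `|delta_nu|` (ties broken by lower native wavenumber). Unmatched
#' native peaks are reported `disappeared`, unmatched complex peaks
#' `new`; matched pairs with `|delta_nu| <= unchanged_tol` are
#' `unchanged`, the rest `shifted`.
#'
#' When the baseline-corrected spectra are supplied, the relative
#' intensity change `(I_complex(nu) - I_native(nu0)) / I_native(nu0)` is
#' attached, and disappearances are intensity-confirmed when the complex
#' intensity at `nu0` falls below 3x the complex noise estimate.
#'
#' @param native_peaks,complex_peaks `peak_list` data frames from
#'   [detect_peaks()].
#' @param tol Matching tolerance, cm^-1 (> 0).
#' @param unchanged_tol Shift magnitude at or below which a matched pair
#'   is labelled `unchanged`, cm^-1.
#' @param native_spectrum,complex_spectrum Optional baseline-corrected
#'   [ir_spectrum()]s used for intensity changes.
#' @return Data frame (class `peak_shifts`) with columns `assignment`,
#'   `nu0`, `nu`, `delta_nu`, `intensity_change`, `status`,
#'   `intensity_confirmed`.
#' @export
match_peaks <- function(native_peaks, complex_peaks, tol = 20,
                        unchanged_tol = 1,
                        native_spectrum = NULL, complex_spectrum = NULL) {
  if (tol <= 0) stop("tol must be > 0")
  n0 <- native_peaks$center
  n1 <- complex_peaks$center
  pairs <- expand.grid(i = seq_along(n0), j = seq_along(n1))
  if (nrow(pairs)) {
    pairs$d <- abs(n0[pairs$i] - n1[pairs$j])
    pairs <- pairs[pairs$d <= tol, , drop = FALSE]
    pairs <- pairs[order(pairs$d, n0[pairs$i]), , drop = FALSE]
  }
  used_i <- logical(length(n0)); used_j <- logical(length(n1))
  mi <- integer(); mj <- integer()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (!used_i[i] && !used_j[j]) {
      used_i[i] <- TRUE; used_j[j] <- TRUE
      mi <- c(mi, i); mj <- c(mj, j)
    }
  }
  interp <- function(spec, at) {
    if (is.null(spec)) return(NA_real_)
    stats::approx(spec$wavenumber, spec$intensity, xout = at)$y
  }
  rows <- list()
  for (kk in seq_along(mi)) {
    nu0 <- n0[mi[kk]]; nu <- n1[mj[kk]]
    d <- abs(nu - nu0)
    i_n <- interp(native_spectrum, nu0)
    i_c <- interp(complex_spectrum, nu)
    rows[[length(rows) + 1L]] <- data.frame(
      assignment = NA_character_, nu0 = nu0, nu = nu, delta_nu = d,
      intensity_change = if (is.na(i_n) || i_n == 0) NA_real_ else
        (i_c - i_n) / i_n,
      status = if (d <= unchanged_tol) "unchanged" else "shifted",
      intensity_confirmed = NA)
  }
  noise <- if (!is.null(complex_spectrum))
    estimate_noise(complex_spectrum) else NA_real_
  for (i in which(!used_i)) {
    nu0 <- n0[i]
    i_n <- interp(native_spectrum, nu0)
    i_c <- interp(complex_spectrum, nu0)
    rows[[length(rows) + 1L]] <- data.frame(
      assignment = NA_character_, nu0 = nu0, nu = NA_real_,
      delta_nu = NA_real_,
      intensity_change = if (is.na(i_n) || i_n == 0) NA_real_ else
        (i_c - i_n) / i_n,
      status = "disappeared",
      intensity_confirmed = if (is.na(noise) || is.na(i_c)) NA else
        i_c < 3 * noise)
  }
  for (j in which(!used_j)) {
    rows[[length(rows) + 1L]] <- data.frame(
      assignment = NA_character_, nu0 = NA_real_, nu = n1[j],
      delta_nu = NA_real_, intensity_change = NA_real_,
      status = "new", intensity_confirmed = NA)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(assignment = character(), nu0 = numeric(), nu = numeric(),
               delta_nu = numeric(), intensity_change = numeric(),
               status = character(), intensity_confirmed = logical())
  out <- out[order(is.na(out$nu0), out$nu0, out$nu), ]
  rownames(out) <- NULL
  class(out) <- c("peak_shifts", "data.frame")
  out
}

#' Annotate peak shifts with band assignments
#'
#' Labels each shift row with the assignment of the nearest native-band
#' center of the library (within `tol`); `new` rows are matched against
#' complex-species band centers instead.
#'
#' @param shifts A `peak_shifts` data frame from [match_peaks()].
#' @param library A [band_library()].
#' @param tol Maximum center-to-band distance for labelling, cm^-1.
#' @return The shifts table with `assignment` filled where identifiable.
#' @export
annotate_shifts <- function(shifts, library, tol = 10) {
  native <- library$bands[library$bands$species != "complex", , drop = FALSE]
  cpx <- library$bands[library$bands$species == "complex", , drop = FALSE]
  label <- function(x, tab) {
    if (is.na(x) || !nrow(tab)) return(NA_character_)
    d <- abs(tab$center - x)
    if (min(d) > tol) return(NA_character_)
    tab$assignment[which.min(d)]
  }
  shifts$assignment <- ifelse(
    !is.na(shifts$nu0),
    vapply(shifts$nu0, label, character(1), tab = native),
    vapply(shifts$nu, label, character(1), tab = cpx))
  shifts
}

#' Robust noise estimate of a spectrum
#'
#' Scaled median absolute deviation of the second difference of the
#' intensities; for additive white gaussian noise on a smooth signal
#' this estimates the noise standard deviation.
#'
#' @param spectrum An [ir_spectrum()].
#' @return Estimated noise standard deviation (absorbance units).
#' @export
estimate_noise <- function(spectrum) {
  d2 <- diff(spectrum$intensity, differences = 2)
  stats::mad(d2) / sqrt(6)
}

#' Pointwise difference spectrum
#'
#' @param sample,background [ir_spectrum()]s on identical grids.
#' @return `sample - background` as an [ir_spectrum()]; metadata records
#'   both parents.
#' @export
difference_spectrum <- function(sample, background) {
  stopifnot(inherits(sample, "ir_spectrum"),
            inherits(background, "ir_spectrum"))
  if (length(sample$wavenumber) != length(background$wavenumber) ||
      any(sample$wavenumber != background$wavenumber))
    stop("grid mismatch between sample and background")
  ir_spectrum(sample$wavenumber, sample$intensity - background$intensity,
              meta = list(difference_of = list(sample = sample$meta,
                                               background = background$meta)))
}

#' Write a peak-shift table to CSV
#'
#' @param shifts A `peak_shifts` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_shifts_csv <- function(shifts, path) {
  utils::write.csv(
    shifts[, c("assignment", "nu0", "nu", "delta_nu", "intensity_change",
               "status")],
    path, row.names = FALSE)
  invisible(path)
}
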