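#' Calibrate the shift-to-distance constant
#'
#' The interaction energy behind a band shift is taken proportional to
#' the shift magnitude and inversely proportional to the binding
#' distance, giving the one-parameter law `r = k / delta_nu`. The
#' constant is anchored so that the largest observed shift maps to the
#' closest-approach distance: `k = r_anchor * max(delta_nu)`.
#'
#' @param shifts Numeric vector of shift magnitudes `delta_nu` (cm^-1),
#'   or a `peak_shifts` table from [match_peaks()] (its `shifted` rows
#'   are used).
#' @param r_anchor Closest-approach anchor distance, Angstrom
#'   (default 7.0).
#' @return Calibration constant `k` in Angstrom * cm^-1.
#' @export
calibrate_k <- function(shifts, r_anchor = 7.0) {
  if (inherits(shifts, "peak_shifts"))
    shifts <- shifts$delta_nu[shifts$status == "shifted"]
  shifts <- shifts[!is.na(shifts)]
  if (!length(shifts)) stop("no shifts supplied")
  if (any(shifts < 0)) stop("negative shift magnitude")
  if (all(shifts == 0)) stop("all shifts are zero; cannot calibrate")
  if (r_anchor <= 0) stop("r_anchor must be > 0")
  r_anchor * max(shifts)
}

#' Estimate a binding distance from a band shift
#'
#' `r = min(k / delta_nu, r_max)`; a zero shift (no detectable
#' interaction) returns `r_max` with `capped = TRUE`.
#'
#' @param delta_nu Shift magnitude, cm^-1 (>= 0). Vectorized.
#' @param k Calibration constant, Angstrom * cm^-1 (> 0).
#' @param r_max Upper distance cap, Angstrom (default 16).
#' @param assignment Optional band label(s) carried through.
#' @return Data frame (class `distance_estimates`) with columns
#'   `assignment`, `delta_nu`, `energy_proxy`, `r`, `k`, `capped`.
#' @export
estimate_distance <- function(delta_nu, k, r_max = 16,
                              assignment = NA_character_) {
  if (k <= 0) stop("k must be > 0")
  if (r_max <= 0) stop("r_max must be > 0")
  if (any(delta_nu < 0, na.rm = TRUE)) stop("negative delta_nu")
  r_raw <- ifelse(delta_nu > 0, k / delta_nu, Inf)
  out <- data.frame(assignment = assignment, delta_nu = delta_nu,
                    energy_proxy = delta_nu, r = pmin(r_raw, r_max),
                    k = k, capped = r_raw > r_max)
  class(out) <- c("distance_estimates", "data.frame")
  out
}

#' Distance estimates for a shift table
#'
#' Convenience wrapper applying [estimate_distance()] to every `shifted`
#' row of a [match_peaks()] table.
#'
#' @param shifts A `peak_shifts` data frame.
#' @param k Calibration constant; `NULL` calibrates from the table via
#'   [calibrate_k()].
#' @param r_anchor,r_max Anchor and cap distances, Angstrom.
#' @return A `distance_estimates` data frame.
#' @export
estimate_distances <- function(shifts, k = NULL, r_anchor = 7.0,
                               r_max = 16) {
  stopifnot(inherits(shifts, "peak_shifts"))
  sh <- shifts[shifts$status == "shifted", , drop = FALSE]
  if (!nrow(sh)) stop("no shifted bands in table")
  if (is.null(k)) k <- calibrate_k(sh$delta_nu, r_anchor)
  estimate_distance(sh$delta_nu, k, r_max, assignment = sh$assignment)
}

#' Build a supervised feature table from matched band shifts
#'
#' One row per `shifted` band. The native feature is the native band
#' center; the complex feature depends on `descriptor`:
#' `"position"` uses the complex band center, `"change"` the signed
#' position change `nu - nu0` (the better-conditioned encoding of the
#' two "peak value changes"), and `"intensity"` the relative intensity
#' change. The regression target is the [estimate_distance()] output.
#' Both feature columns are standardized to zero mean and unit variance;
#' the centering/scaling constants are attached as attributes
#' `feature_center` / `feature_scale`.
#'
#' @param shifts A `peak_shifts` table with at least 2 shifted rows.
#' @param k Calibration constant (`NULL` to calibrate from the table).
#' @param r_anchor,r_max Anchor and cap, Angstrom.
#' @param descriptor `"position"`, `"change"` or `"intensity"`.
#' @return Data frame (class `feature_table`) with columns `assignment`,
#'   `f_native`, `f_complex` (standardized), `target_r`.
#' @export
build_feature_table <- function(shifts, k = NULL, r_anchor = 7.0,
                                r_max = 16,
                                descriptor = c("position", "change",
                                               "intensity")) {
  stopifnot(inherits(shifts, "peak_shifts"))
  descriptor <- match.arg(descriptor)
  sh <- shifts[shifts$status == "shifted", , drop = FALSE]
  if (nrow(sh) < 2)
    stop("fewer than 2 shifted bands; cannot standardize features")
  est <- estimate_distances(shifts, k = k, r_anchor = r_anchor,
                            r_max = r_max)
  f_native <- sh$nu0
  f_complex <- switch(descriptor,
                      position = sh$nu,
                      change = sh$nu - sh$nu0,
                      intensity = sh$intensity_change)
  if (any(!is.finite(f_native)) || any(!is.finite(f_complex)))
    stop("non-finite feature values")
  X <- scale(cbind(f_native, f_complex))
  out <- data.frame(assignment = sh$assignment,
                    f_native = X[, 1], f_complex = X[, 2],
                    target_r = est$r)
  attr(out, "feature_center") <- attr(X, "scaled:center")
  attr(out, "feature_scale") <- attr(X, "scaled:scale")
  attr(out, "descriptor") <- descriptor
  attr(out, "k") <- est$k[1]
  class(out) <- c("feature_table", "data.frame")
  out
}
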