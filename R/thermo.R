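#' Gibbs energy from a dissociation constant
#'
#' Evaluates `dG = -R T ln(Kd) / 1000` (kJ/mol) with
#' R = 8.314 J/(mol K). Note the sign convention: for Kd < 1 M this
#' yields a positive value (e.g. Kd = 10 uM at 298 K gives
#' +28.52 kJ/mol), which is reported as printed rather than negated;
#' the accompanying `convention_note` records this.
#'
#' @param kd Dissociation constant, molar (> 0).
#' @param temperature Temperature, K (> 0); default 298.
#' @return Gibbs energy change, kJ/mol.
#' @export
gibbs_from_kd <- function(kd, temperature = 298) {
  if (any(kd <= 0)) stop("Kd must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  -GAS_CONSTANT * temperature * log(kd) / 1000
}

GAS_CONSTANT <- 8.314  # J/(mol K)

#' Entropy change from Gibbs energy and enthalpy
#'
#' Inverts `dG = dH - T dS`: `dS = (dH - dG) * 1000 / T`, in
#' J/(mol K) with dG and dH in kJ/mol.
#'
#' @param dG Gibbs energy change, kJ/mol.
#' @param dH Enthalpy change, kJ/mol.
#' @param temperature Temperature, K (> 0).
#' @return Entropy change, J/(mol K).
#' @export
entropy_from_gibbs <- function(dG, dH, temperature = 298) {
  if (temperature <= 0) stop("temperature must be > 0")
  (dH - dG) * 1000 / temperature
}

#' Full thermodynamic characterization of the binding interaction
#'
#' Computes dG from the dissociation constant and dS from the supplied
#' enthalpy, with an internal closure check
#' `dG = dH - T dS` (to 1e-9 kJ/mol).
#'
#' @param kd Dissociation constant, molar; default 1e-5 (10 uM).
#' @param temperature Temperature, K; default 298.
#' @param dH Enthalpy change, kJ/mol; default -30.
#' @return A `thermo_result` list: `dG` (kJ/mol), `dH` (kJ/mol), `dS`
#'   (J/(mol K)), `kd`, `temperature`, `convention_note`.
#' @export
thermo_analysis <- function(kd = 1e-5, temperature = 298, dH = -30) {
  dG <- gibbs_from_kd(kd, temperature)
  dS <- entropy_from_gibbs(dG, dH, temperature)
  stopifnot(abs(dG - (dH - temperature * dS / 1000)) < 1e-9)
  structure(list(
    dG = dG, dH = dH, dS = dS, kd = kd, temperature = temperature,
    convention_note = paste(
      "dG evaluated as -RT ln(Kd); for Kd < 1 M this is positive",
      "(dissociation-oriented sign), reported as such without",
      "reinterpretation")),
    class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf(paste0("<thermo_result> Kd = %.3g M, T = %g K\n",
                     "  dG = %.2f kJ/mol, dH = %.2f kJ/mol, ",
                     "dS = %.2f J/(mol K)\n"),
              x$kd, x$temperature, x$dG, x$dH, x$dS))
  invisible(x)
}
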