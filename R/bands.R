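#' Construct a vibrational band
#'
#' @param center Band center, cm^-1.
#' @param fwhm Full width at half maximum, cm^-1 (> 0).
#' @param amplitude Peak absorbance (>= 0, arbitrary units).
#' @param shape Lineshape: `"gaussian"`, `"lorentzian"` or `"pseudo_voigt"`.
#' @param eta Lorentzian fraction for the pseudo-Voigt profile, in `[0, 1]`.
#' @param assignment Free-text vibrational assignment (e.g. `"amide-I"`).
#' @param species One of `"dsDNA"`, `"EndoIII"`, `"complex"`.
#' @param origin Native band center this band derives from (for
#'   complex-species bands), or `"new"` when it has no native parent,
#'   or `NA` for native bands.
#' @return One-row data frame describing the band.
#' @export
band <- function(center, fwhm, amplitude, shape = "pseudo_voigt",
                 eta = 0.5, assignment = "", species = "EndoIII",
                 origin = NA_real_) {
  shape <- match.arg(shape, c("gaussian", "lorentzian", "pseudo_voigt"))
  species <- match.arg(species, c("dsDNA", "EndoIII", "complex"))
  if (fwhm <= 0) stop("fwhm must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (eta < 0 || eta > 1) stop("eta must be in [0, 1]")
  data.frame(center = center, fwhm = fwhm, amplitude = amplitude,
             shape = shape, eta = eta, assignment = assignment,
             species = species,
             origin = as.character(origin),
             stringsAsFactors = FALSE)
}

#' Assemble a band library
#'
#' @param bands Data frame of bands as produced by [band()] (rows may be
#'   concatenated with `rbind`).
#' @param range_label `"mid-IR"` or `"far-IR"`.
#' @return A `band_library` object.
#' @export
band_library <- function(bands, range_label) {
  range_label <- match.arg(range_label, c("mid-IR", "far-IR"))
  key <- paste(bands$species, bands$center)
  if (anyDuplicated(key))
    stop("two bands of the same species share a center")
  bands <- bands[order(bands$species, bands$center), ]
  rownames(bands) <- NULL
  structure(list(bands = bands, range_label = range_label),
            class = "band_library")
}

#' @export
print.band_library <- function(x, ...) {
  cat(sprintf("<band_library> %s, %d bands (%s)\n", x$range_label,
              nrow(x$bands),
              paste(sprintf("%s: %d", names(table(x$bands$species)),
                            table(x$bands$species)), collapse = ", ")))
  invisible(x)
}

#' Packaged default band library
#'
#' Band inventory for dsDNA, Endonuclease III (EndoIII) and their complex.
#'
#' Mid-IR (dsDNA): CH out-of-plane bending at 720 and 780 cm^-1,
#' sugar-phosphate backbone at 782, deoxyribose ring at 890, O-P-O
#' bending at 967, phosphate backbone stretches at 1055 (also cited as
#' 1060) and 1213, C-O/C-C at 1110, CH2 wagging / N-H deformation at
#' 1281 and 1329, and C-N stretching of cytosine/guanine at 1376 cm^-1.
#' EndoIII contributes the amide-I band at 1653 cm^-1. In the complex
#' the amide-I band downshifts by 3 cm^-1 (1653 to 1650), the 890 and
#' 967 cm^-1 bands disappear, 780 and 1055 shift by small amounts
#' (defaults 2 and 3 cm^-1), and the 1376 cm^-1 band is split into two
#' half-amplitude sub-bands at 1370 and 1382 cm^-1.
#'
#' Far-IR (EndoIII): the four Fe-S stretching modes of the \[4Fe4S\]
#' cluster at 443, 392, 362 and 326 cm^-1; in the complex the Fe-S
#' thiolate mode downshifts from 362 to 352 cm^-1. (Reported elsewhere
#' in the source narrative as 363 to 353; the library follows the
#' primary 362 to 352 statement.) No distinct dsDNA far-IR bands are
#' packaged.
#'
#' @param range_label `"mid-IR"` or `"far-IR"`.
#' @param split_offsets Offsets (cm^-1) of the sub-bands replacing the
#'   1376 cm^-1 band in the complex (mid-IR only).
#' @return A [band_library()] covering all three species.
#' @export
default_band_library <- function(range_label = c("mid-IR", "far-IR"),
                                 split_offsets = c(-6, 6)) {
  range_label <- match.arg(range_label)
  if (range_label == "far-IR") {
    fw <- 12
    fe_s <- rbind(
      band(443, fw, 0.60, assignment = "Fe-S stretch", species = "EndoIII"),
      band(392, fw, 0.70, assignment = "Fe-S stretch", species = "EndoIII"),
      band(362, fw, 0.80, assignment = "Fe-S thiolate", species = "EndoIII"),
      band(326, fw, 0.50, assignment = "Fe-S stretch", species = "EndoIII"))
    cpx <- fe_s
    cpx$species <- "complex"
    cpx$origin <- as.character(fe_s$center)
    cpx$center[cpx$center == 362] <- 352   # thiolate downshift on binding
    return(band_library(rbind(fe_s, cpx), "far-IR"))
  }
  fw <- 20
  dna <- rbind(
    band(720,  fw, 0.40, assignment = "CH out-of-plane", species = "dsDNA"),
    band(780,  fw, 0.50, assignment = "CH out-of-plane", species = "dsDNA"),
    band(782,  fw, 0.45, assignment = "sugar-phosphate", species = "dsDNA"),
    band(890,  fw, 0.35, assignment = "deoxyribose ring", species = "dsDNA"),
    band(967,  fw, 0.40, assignment = "O-P-O bending", species = "dsDNA"),
    band(1055, fw, 0.90, assignment = "phosphate backbone", species = "dsDNA"),
    band(1110, fw, 0.60, assignment = "C-O/C-C stretch", species = "dsDNA"),
    band(1213, fw, 0.80, assignment = "PO2 stretch", species = "dsDNA"),
    band(1281, fw, 0.50, assignment = "CH2 wag/N-H def", species = "dsDNA"),
    band(1329, fw, 0.50, assignment = "CH2 wagging", species = "dsDNA"),
    band(1376, fw, 0.60, assignment = "C-N cytosine/guanine",
         species = "dsDNA"))
  pro <- band(1653, fw, 1.00, assignment = "amide-I", species = "EndoIII")

  shift_to <- function(b, new_center) {
    b$origin <- as.character(b$center); b$center <- new_center; b
  }
  keep <- function(b) { b$origin <- as.character(b$center); b }
  cpx_rows <- list()
  for (i in seq_len(nrow(dna))) {
    b <- dna[i, ]; b$species <- "complex"
    cpx_rows[[length(cpx_rows) + 1L]] <- switch(
      as.character(b$center),
      "780"  = shift_to(b, 778),     # small CH oop shift
      "890"  = NULL,                 # deoxyribose band vanishes on binding
      "967"  = NULL,                 # O-P-O band vanishes on binding
      "1055" = shift_to(b, 1058),    # phosphate backbone shift
      "1376" = NULL,                 # replaced by split sub-bands below
      keep(b))
  }
  split <- do.call(rbind, lapply(1376 + split_offsets, function(cc)
    band(cc, fw, 0.30, assignment = "C-N cytosine/guanine (split)",
         species = "complex", origin = 1376)))
  amide_cpx <- band(1650, fw, 1.00, assignment = "amide-I",
                    species = "complex", origin = 1653)
  cpx <- rbind(do.call(rbind, cpx_rows), split, amide_cpx)
  band_library(rbind(dna, pro, cpx), "mid-IR")
}
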