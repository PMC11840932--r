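#' IR spectrum container
#'
#' A light S3 container for a single infrared spectrum: a strictly
#' ascending wavenumber grid (cm^-1), intensities in absorbance units,
#' and free-form metadata (species, spectral range, provenance).
#'
#' @param wavenumber Numeric vector, strictly ascending, cm^-1.
#' @param intensity Numeric vector of the same length, absorbance units.
#' @param meta Named list of metadata (e.g. `species`, `range`, `seed`).
#' @return An object of class `ir_spectrum`.
#' @export
ir_spectrum <- function(wavenumber, intensity, meta = list()) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity))
    stop("wavenumber and intensity must have equal length")
  if (length(wavenumber) < 2L)
    stop("a spectrum needs at least two points")
  if (any(!is.finite(wavenumber)) || any(!is.finite(intensity)))
    stop("non-finite values in spectrum")
  if (any(diff(wavenumber) <= 0))
    stop("wavenumber grid must be strictly ascending")
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 meta = meta),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  rng <- range(x$wavenumber)
  cat(sprintf("<ir_spectrum> %d points, %.1f-%.1f cm^-1", length(x$wavenumber),
              rng[1], rng[2]))
  if (!is.null(x$meta$species))
    cat(sprintf(" [%s]", paste(x$meta$species, collapse = "+")))
  if (!is.null(x$meta$range)) cat(sprintf(" (%s)", x$meta$range))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.ir_spectrum <- function(x, ...) {
  data.frame(wavenumber = x$wavenumber, intensity = x$intensity)
}

#' Read and write two-column spectral CSV
#'
#' The on-disk format is a two-column CSV (`wavenumber`, `intensity`)
#' preceded by a single comment line
#' `# species=<s> range=<r> seed=<n>` carrying the generator metadata.
#'
#' @param spectrum An [ir_spectrum()].
#' @param path File path.
#' @return `read_spectrum_csv` returns an `ir_spectrum`;
#'   `write_spectrum_csv` returns `path` invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  m <- spectrum$meta
  hdr <- sprintf("# species=%s range=%s seed=%s",
                 paste(if (is.null(m$species)) "NA" else m$species,
                       collapse = "+"),
                 if (is.null(m$range)) "NA" else m$range,
                 if (is.null(m$seed)) "NA" else m$seed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(spectrum), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- list()
  if (startsWith(first, "#")) {
    kv <- regmatches(first, gregexpr("[a-z]+=[^ ]+", first))[[1]]
    for (p in kv) {
      k <- sub("=.*", "", p); v <- sub("^[a-z]+=", "", p)
      meta[[k]] <- if (k == "species") strsplit(v, "\\+")[[1]] else v
    }
  }
  d <- utils::read.csv(path, comment.char = "#")
  ir_spectrum(d[[1]], d[[2]], meta = meta)
}

#' Read a JCAMP-DX infrared spectrum
#'
#' Minimal reader for the fixed-increment `XYDATA=(X++(Y..Y))` dialect:
#' each data line starts with an X value followed by equally spaced Y
#' values; the grid is reconstructed from `FIRSTX`/`LASTX`/`NPOINTS`
#' (with `XFACTOR`/`YFACTOR` applied). Descending files are flipped to
#' ascending order.
#'
#' @param path Path to a `.jdx`/`.dx` file.
#' @return An [ir_spectrum()].
#' @export
read_jcampdx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(name, default = NA_real_) {
    hit <- grep(sprintf("^##%s=", name), lines, value = TRUE)
    if (!length(hit)) return(default)
    as.numeric(sub(sprintf("^##%s=\\s*", name), "", hit[1]))
  }
  xfac <- get_field("XFACTOR", 1); yfac <- get_field("YFACTOR", 1)
  firstx <- get_field("FIRSTX"); lastx <- get_field("LASTX")
  npt <- get_field("NPOINTS")
  start <- grep("^##XYDATA=\\s*\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines)
  if (!length(start))
    stop("no XYDATA=(X++(Y..Y)) block found")
  end <- grep("^##END=", lines)
  end <- if (length(end)) min(end[end > start[1]]) else length(lines) + 1L
  body <- lines[(start[1] + 1L):(end - 1L)]
  ys <- unlist(lapply(body, function(l) {
    v <- as.numeric(strsplit(trimws(l), "[ \t,]+")[[1]])
    v[-1]  # first token is the line's X value
  }))
  if (is.na(npt)) npt <- length(ys)
  if (length(ys) != npt)
    stop(sprintf("NPOINTS=%d but %d Y values read", npt, length(ys)))
  x <- seq(firstx, lastx, length.out = npt) * xfac
  y <- ys * yfac
  if (x[1] > x[length(x)]) { x <- rev(x); y <- rev(y) }
  ir_spectrum(x, y, meta = list(source = path, format = "jcamp-dx"))
}

# run fn with a local RNG state seeded by `seed`; outer RNG untouched
with_seed <- function(seed, fn) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  fn()
}
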