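## Cube input/output and reflectance calibration.

#' Dark/white reflectance calibration
#'
#' Converts a raw-counts cube to reflectance using the averaged whiteboard
#' and dark-current reference spectra:
#' \deqn{R_s = (R_{raw} - R_b) / (R_w - R_b)}
#' applied elementwise per band. Values below 0 or above 1 are retained (not
#' clipped) with a warning, since clipping would bias downstream
#' pretreatments.
#'
#' @param cube a raw \linkS4class{SpectralCube}; its stored white/dark frames
#'   are used unless overridden.
#' @param white,dark optional numeric reference spectra, one value per band.
#' @return a reflectance \linkS4class{SpectralCube}.
#' @export
calibrateReflectance <- function(cube, white = NULL, dark = NULL) {
  stopifnot(is(cube, "SpectralCube"))
  white <- white %||% cube@white
  dark <- dark %||% cube@dark
  p <- dim(cube@data)[3]
  if (length(white) != p || length(dark) != p)
    stop("white and dark frames must match the cube's band axis")
  denom <- white - dark
  bad <- which(denom == 0)
  if (length(bad))
    stop(sprintf("degenerate denominator: white = dark at band(s) %s",
                 paste(head(bad, 5), collapse = ", ")))
  out <- cube@data
  for (k in seq_len(p)) out[, , k] <- (cube@data[, , k] - dark[k]) / denom[k]
  if (any(out < 0) || any(out > 1))
    warning("reflectance outside [0, 1] retained (not clipped)")
  new("SpectralCube", data = out, wavelengths = cube@wavelengths,
      kind = "reflectance", white = numeric(), dark = numeric())
}

#' Extract the mean spectrum of the masked pixels
#'
#' Per-band arithmetic mean over the foreground pixels of a reflectance
#' cube — the sample-level spectrum used for calibration modelling.
#'
#' @param cube a reflectance \linkS4class{SpectralCube}.
#' @param mask logical height x width matrix with at least one TRUE pixel
#'   (default: all pixels).
#' @param sampleId identifier stored in the result.
#' @return a \linkS4class{MeanSpectrum}.
#' @export
extractMeanSpectrum <- function(cube, mask = NULL, sampleId = "sample") {
  stopifnot(is(cube, "SpectralCube"))
  d <- dim(cube@data)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!identical(dim(mask), d[1:2])) stop("mask dimensions must match the cube")
  npix <- sum(mask)
  if (npix < 1L) stop("mask selects no pixels")
  vals <- vapply(seq_len(d[3]), function(k) mean(cube@data[, , k][mask]),
                 numeric(1))
  new("MeanSpectrum", sampleId = sampleId, values = vals,
      wavelengths = cube@wavelengths, pixelCount = as.integer(npix))
}

checkTrim <- function(p, trimLow, trimHigh) {
  trimLow <- as.integer(trimLow); trimHigh <- as.integer(trimHigh)
  if (trimLow < 0L || trimHigh < 0L) stop("trim counts must be >= 0")
  if (trimLow + trimHigh >= p)
    stop(sprintf("cannot trim %d + %d channels from %d", trimLow, trimHigh, p))
  (1L + trimLow):(p - trimHigh)
}

#' @rdname trimBands
#' @export
setMethod("trimBands", "CalibrationSet", function(x, trimLow = 4L, trimHigh = 4L) {
  keep <- checkTrim(nrow(x), trimLow, trimHigh)
  x[keep, ]
})

#' @rdname trimBands
#' @export
setMethod("trimBands", "SpectralCube", function(x, trimLow = 4L, trimHigh = 4L) {
  keep <- checkTrim(dim(x@data)[3], trimLow, trimHigh)
  new("SpectralCube", data = x@data[, , keep, drop = FALSE],
      wavelengths = x@wavelengths[keep], kind = x@kind,
      white = if (length(x@white)) x@white[keep] else numeric(),
      dark = if (length(x@dark)) x@dark[keep] else numeric())
})

#' @rdname trimBands
#' @export
setMethod("trimBands", "MeanSpectrum", function(x, trimLow = 4L, trimHigh = 4L) {
  keep <- checkTrim(length(x@values), trimLow, trimHigh)
  new("MeanSpectrum", sampleId = x@sampleId, values = x@values[keep],
      wavelengths = x@wavelengths[keep], pixelCount = x@pixelCount)
})

#' @rdname trimBands
#' @export
setMethod("trimBands", "matrix", function(x, trimLow = 4L, trimHigh = 4L) {
  keep <- checkTrim(ncol(x), trimLow, trimHigh)
  x[, keep, drop = FALSE]
})

#' @rdname trimBands
#' @export
setMethod("trimBands", "SyntheticDataset", function(x, trimLow = 4L, trimHigh = 4L) {
  keep <- checkTrim(nrow(x@calibration), trimLow, trimHigh)
  planted <- match(intersect(x@plantedBands, keep), keep)
  new("SyntheticDataset", calibration = x@calibration[keep, ],
      plantedBands = as.integer(planted), provenance = x@provenance)
})

## ------------------------------------------------------------------ ENVI format

#' Read and write ENVI-format cubes
#'
#' Lossless reader/writer for a pinned ENVI dialect: text header
#' (\code{.hdr}) plus band-sequential (BSQ) little-endian float32 binary
#' (\code{.dat}). BIL interleave is accepted on read. The header must carry a
#' \code{wavelength} list matching the band count; a custom \code{kind} key
#' records raw vs reflectance, and companion white/dark reference spectra are
#' stored as 1-line cubes next to the data (\code{<stem>_white},
#' \code{<stem>_dark}) and re-attached on read.
#'
#' @param cube a \linkS4class{SpectralCube}.
#' @param stem path without extension; \code{<stem>.hdr} and
#'   \code{<stem>.dat} are written/read.
#' @return \code{readENVICube} returns a \linkS4class{SpectralCube};
#'   \code{writeENVICube} invisibly returns the header path.
#' @export
writeENVICube <- function(cube, stem) {
  stopifnot(is(cube, "SpectralCube"))
  d <- dim(cube@data)
  hdr <- c(
    "ENVI",
    "description = {tea hyperspectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    sprintf("kind = %s", cube@kind),
    "wavelength units = nm",
    sprintf("wavelength = {%s}",
            paste(format(cube@wavelengths, digits = 12, trim = TRUE,
                         scientific = FALSE), collapse = ", ")))
  writeLines(hdr, paste0(stem, ".hdr"))
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  # BSQ: band-major, line-major within band, sample fastest
  for (k in seq_len(d[3]))
    writeBin(as.numeric(t(cube@data[, , k])), con, size = 4L,
             endian = "little")
  for (fr in c("white", "dark")) {
    v <- slot(cube, fr)
    if (length(v)) {
      frameCube <- new("SpectralCube",
                       data = array(v, dim = c(1L, 1L, d[3])),
                       wavelengths = cube@wavelengths, kind = "raw",
                       white = numeric(), dark = numeric())
      writeENVICube(frameCube, paste0(stem, "_", fr))
    }
  }
  invisible(paste0(stem, ".hdr"))
}

parseENVIHeader <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl("^ENVI", txt)) stop("not an ENVI header: ", path)
  fields <- list()
  # key = value, where value may be a {...} list spanning lines
  pat <- gregexpr("([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)",
                  txt, perl = TRUE)
  for (m in regmatches(txt, pat)[[1]]) {
    key <- tolower(trimws(sub("=.*", "", m)))
    val <- trimws(sub("^[^=]*=", "", m))
    fields[[key]] <- val
  }
  fields
}

#' @rdname writeENVICube
#' @param attachFrames logical: look for \code{<stem>_white}/\code{_dark}
#'   companion cubes and attach them.
#' @export
readENVICube <- function(stem, attachFrames = TRUE) {
  hdrPath <- if (file.exists(paste0(stem, ".hdr"))) paste0(stem, ".hdr") else stem
  f <- parseENVIHeader(hdrPath)
  need <- c("samples", "lines", "bands", "interleave", "data type")
  miss <- setdiff(need, names(f))
  if (length(miss)) stop("header missing field(s): ", paste(miss, collapse = ", "))
  ns <- as.integer(f[["samples"]]); nl <- as.integer(f[["lines"]]); nb <- as.integer(f[["bands"]])
  interleave <- tolower(f[["interleave"]])
  if (!interleave %in% c("bsq", "bil"))
    stop("unsupported interleave: ", interleave)
  if (as.integer(f[["data type"]]) != 4L)
    stop("only data type 4 (float32) is supported")
  if (is.null(f[["wavelength"]])) stop("header missing the wavelength field")
  wl <- as.numeric(strsplit(gsub("[{}]", "", f[["wavelength"]]), ",")[[1]])
  if (length(wl) != nb)
    stop(sprintf("wavelength list length %d does not match bands = %d",
                 length(wl), nb))
  datPath <- sub("\\.hdr$", ".dat", hdrPath)
  vals <- readBin(datPath, "numeric", n = ns * nl * nb, size = 4L,
                  endian = "little")
  if (length(vals) != ns * nl * nb)
    stop("binary size does not match header dimensions")
  arr <- array(0, dim = c(nl, ns, nb))
  if (interleave == "bsq") {
    a <- array(vals, dim = c(ns, nl, nb))       # sample, line, band
    arr <- aperm(a, c(2, 1, 3))
  } else {                                      # bil: sample, band, line
    a <- array(vals, dim = c(ns, nb, nl))
    arr <- aperm(a, c(3, 1, 2))
  }
  kind <- f[["kind"]] %||% "raw"
  white <- dark <- numeric()
  if (attachFrames) {
    for (fr in c("white", "dark")) {
      cstem <- paste0(sub("\\.hdr$", "", hdrPath), "_", fr)
      if (file.exists(paste0(cstem, ".hdr"))) {
        comp <- readENVICube(cstem, attachFrames = FALSE)
        v <- as.numeric(comp@data[1, 1, ])
        if (fr == "white") white <- v else dark <- v
      }
    }
  }
  new("SpectralCube", data = arr, wavelengths = wl, kind = kind,
      white = white, dark = dark)
}
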