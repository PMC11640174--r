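## Pixel-wise concentration mapping: apply the fitted pretreatment, band
## selection and regression model to every foreground pixel of a reflectance
## cube and render the result as a pseudo-colour image.

#' Threshold-based background masking
#'
#' A pixel is foreground iff its mean reflectance over a wavelength window
#' exceeds a threshold. The default window (750--950 nm) sits on the
#' near-infrared reflectance plateau of leaf material, well above the 0.02
#' background filler, so a 0.15 threshold separates leaf from belt/background.
#' Raising the threshold never grows the foreground set.
#'
#' @param cube a reflectance \linkS4class{SpectralCube}.
#' @param windowNm numeric length-2 wavelength window in nm.
#' @param threshold reflectance threshold.
#' @return logical height x width matrix.
#' @export
maskBackground <- function(cube, windowNm = c(750, 950), threshold = 0.15) {
  stopifnot(is(cube, "SpectralCube"))
  inWin <- which(cube@wavelengths >= windowNm[1] &
                 cube@wavelengths <= windowNm[2])
  if (!length(inWin)) stop("empty wavelength window")
  d <- dim(cube@data)
  acc <- matrix(0, d[1], d[2])
  for (k in inWin) acc <- acc + cube@data[, , k]
  acc / length(inWin) > threshold
}

#' Predict a pixel-wise TFAA map
#'
#' For every foreground pixel: trim edge channels, apply the fitted
#' pretreatment chain (using its calibration-set parameters — the MSC
#' reference is the calibration reference, not a per-image one, so pixel and
#' tabular predictions agree), subset to the selected channels, and predict
#' with the fitted model. Background pixels are undefined (\code{NA}).
#'
#' @param cube a reflectance \linkS4class{SpectralCube} on the untrimmed grid.
#' @param pretreat a fitted \linkS4class{PretreatmentSpec}.
#' @param selection a \linkS4class{SelectionResult} (indices on the trimmed
#'   grid).
#' @param model a fitted \linkS4class{PLSRModel} or \linkS4class{LSSVRModel}.
#' @param mask logical foreground mask (default via
#'   \code{\link{maskBackground}}).
#' @param trimLow,trimHigh edge-channel trim applied before pretreatment.
#' @param modelLabel label stored on the map.
#' @param limits colour-scale limits; default the 2nd--98th percentile of the
#'   foreground predictions (robust to outlier pixels).
#' @return a \linkS4class{PredictionMap}.
#' @export
predictMap <- function(cube, pretreat, selection, model, mask = NULL,
                       trimLow = 4L, trimHigh = 4L, modelLabel = "model",
                       limits = NULL) {
  stopifnot(is(cube, "SpectralCube"))
  if (cube@kind != "reflectance") stop("cube must be reflectance-calibrated")
  if (is.null(mask)) mask <- maskBackground(cube)
  d <- dim(cube@data)
  vals <- matrix(NA_real_, d[1], d[2])
  idx <- which(mask)
  if (length(idx)) {
    pix <- matrix(cube@data, nrow = d[1] * d[2])[idx, , drop = FALSE]
    pix <- trimBands(pix, trimLow, trimHigh)
    pix <- applyPretreatment(pretreat, pix)
    pix <- pix[, selection@bands, drop = FALSE]
    if (ncol(pix) != length(model@xMeans))
      stop("channel count mismatch between cube and model chain")
    vals[idx] <- predict(model, pix)
  }
  if (is.null(limits)) {
    limits <- if (length(idx))
      as.numeric(stats::quantile(vals[idx], c(0.02, 0.98), names = FALSE))
    else c(0, 1)
    if (limits[1] == limits[2]) limits <- limits + c(-0.5, 0.5)
  }
  new("PredictionMap", values = vals, mask = mask, modelLabel = modelLabel,
      limits = limits)
}

#' Render a prediction map as a pseudo-colour PNG
#'
#' Maps foreground values linearly onto the palette between the scale
#' limits (values outside are clamped); background pixels are rendered
#' neutral grey. Output bytes are deterministic for a fixed map, palette and
#' limits.
#'
#' @param map a \linkS4class{PredictionMap}.
#' @param path output PNG path.
#' @param palette character vector of colours (default 64-step viridis).
#' @param limits optional override of the map's colour-scale limits.
#' @param background background colour (default grey).
#' @return invisibly, the path.
#' @export
renderPseudocolor <- function(map, path,
                              palette = grDevices::hcl.colors(64, "viridis"),
                              limits = NULL, background = "grey85") {
  stopifnot(is(map, "PredictionMap"))
  limits <- limits %||% map@limits
  if (limits[1] > limits[2]) stop("reversed colour-scale limits")
  h <- nrow(map@values); w <- ncol(map@values)
  rgbPal <- grDevices::col2rgb(palette) / 255
  rgbBg <- grDevices::col2rgb(background) / 255
  img <- array(0, dim = c(h, w, 3))
  span <- limits[2] - limits[1]
  u <- if (span > 0) (map@values - limits[1]) / span else map@values * 0 + 0.5
  u <- pmin(pmax(u, 0), 1)
  ci <- 1L + as.integer(round(u * (length(palette) - 1L)))
  for (ch in 1:3) {
    plane <- matrix(rgbBg[ch], h, w)
    plane[map@mask] <- rgbPal[ch, ci[map@mask]]
    img[, , ch] <- plane
  }
  png::writePNG(img, target = path)
  invisible(path)
}
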