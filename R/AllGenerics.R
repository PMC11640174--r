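#' Accessor generics
#'
#' Small accessor layer over the S4 containers: \code{wavelengths} returns the
#' wavelength axis in nm, \code{spectraMatrix} the samples x channels
#' reflectance matrix, \code{tfaa} the reference chemistry vector,
#' \code{processStep} the per-sample processing-step labels,
#' \code{plantedBands} the generator's ground-truth channel indices,
#' \code{selectedBands} a selector's chosen channel indices, and
#' \code{trimBands} drops unstable edge channels.
#'
#' @param x,object an object of one of the package's classes.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' @rdname accessors
#' @export
setGeneric("tfaa", function(x) standardGeneric("tfaa"))

#' @rdname accessors
#' @export
setGeneric("processStep", function(x) standardGeneric("processStep"))

#' @rdname accessors
#' @export
setGeneric("plantedBands", function(x) standardGeneric("plantedBands"))

#' @rdname accessors
#' @export
setGeneric("selectedBands", function(x) standardGeneric("selectedBands"))

#' Trim unstable edge channels
#'
#' Drops \code{trimLow} channels at the short-wavelength end and
#' \code{trimHigh} at the long-wavelength end, keeping the wavelength axis in
#' step. The defaults (4 + 4) reduce a 951-channel grid to the 943 stable
#' channels used for modelling; edge channels are where sensor noise
#' concentrates.
#'
#' @param x a \linkS4class{CalibrationSet}, \linkS4class{SpectralCube},
#'   \linkS4class{MeanSpectrum} or plain matrix (samples x channels).
#' @param trimLow,trimHigh non-negative integer channel counts to drop.
#' @return an object of the same class with fewer channels.
#' @examples
#' d <- studyDesign(batches = 1, replicates = 1)
#' ds <- simulateTeaSpectra(d, seed = 1)
#' nrow(trimBands(calibration(ds)))  # 943
#' @export
setGeneric("trimBands", function(x, trimLow = 4L, trimHigh = 4L)
  standardGeneric("trimBands"))

#' @rdname accessors
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))
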