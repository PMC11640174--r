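#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @importFrom stats coef cor lm predict rnorm sd var
#' @importFrom utils head tail read.csv write.csv
#' @importFrom withr with_seed
#' @importFrom signal sgolayfilt
#' @importFrom jsonlite write_json read_json
#' @importFrom yaml read_yaml
#' @importFrom png writePNG
#' @importFrom tools md5sum
#' @importFrom grDevices col2rgb hcl.colors
NULL

## ---------------------------------------------------------------- study design

#' Study design for a tea-processing hyperspectral experiment
#'
#' Holds the sampling roster (processing step x batch x replicate) and the
#' wavelength grid of the spectrometer. The default mirrors a production-line
#' experiment: three processing steps (fresh-leaf spreading FLS, steaming
#' fixation SF, hot-air drying HD), 30 batches per step, 3 replicates, and a
#' 951-channel grid spanning 400--1000 nm.
#'
#' @slot steps ordered character vector of processing-step labels.
#' @slot batches integer, batches per step.
#' @slot replicates integer, replicate samplings per batch.
#' @slot roster data.frame with columns \code{sample_id}, \code{step},
#'   \code{batch}, \code{replicate}; one row per sample.
#' @slot wavelengths numeric, strictly increasing uniform grid in nm.
#' @exportClass StudyDesign
setClass("StudyDesign",
  representation(
    steps = "character",
    batches = "integer",
    replicates = "integer",
    roster = "data.frame",
    wavelengths = "numeric"
  )
)

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (length(object@steps) < 1L) msg <- c(msg, "at least one processing step required")
  if (object@batches < 1L) msg <- c(msg, "batches must be >= 1")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  wl <- object@wavelengths
  if (length(wl) < 2L) msg <- c(msg, "wavelength grid needs >= 2 channels")
  if (any(diff(wl) <= 0)) msg <- c(msg, "wavelengths must be strictly increasing")
  if (length(wl) > 2L && diff(range(diff(wl))) > 1e-8 * mean(diff(wl)))
    msg <- c(msg, "wavelengths must be uniformly spaced")
  n_expect <- length(object@steps) * object@batches * object@replicates
  if (nrow(object@roster) != n_expect)
    msg <- c(msg, sprintf("roster has %d rows, expected %d", nrow(object@roster), n_expect))
  if (anyDuplicated(object@roster$sample_id))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

## -------------------------------------------------------------- component library

#' Spectral component library
#'
#' Unit-normalised (max = 1) absorption profiles on a common wavelength grid,
#' each built as a sum of Gaussian bands. The default library contains an
#' analyte profile (free amino acids: O-H first-overtone band near 947 nm and
#' an N-H stretch band near 1000 nm), a chlorophyll-like pigment profile
#' (strong red 620--780 nm and blue absorption, weak green 490--560 nm
#' absorption), and a water/background profile (band near 970 nm).
#'
#' @slot wavelengths numeric grid in nm.
#' @slot profiles numeric matrix, channels x components, column names are
#'   component names; non-negative, each column max-normalised to 1.
#' @exportClass ComponentLibrary
setClass("ComponentLibrary",
  representation(wavelengths = "numeric", profiles = "matrix")
)

setValidity("ComponentLibrary", function(object) {
  msg <- character()
  if (nrow(object@profiles) != length(object@wavelengths))
    msg <- c(msg, "profiles rows must match wavelength grid length")
  if (any(object@profiles < 0)) msg <- c(msg, "profiles must be non-negative")
  if (is.null(colnames(object@profiles))) msg <- c(msg, "components must be named")
  if (!"analyte" %in% colnames(object@profiles)) msg <- c(msg, "an 'analyte' component is required")
  if (length(msg)) msg else TRUE
})

## -------------------------------------------------------------- simulation params

#' Simulation parameters for the spectra generator
#'
#' All standard deviations are >= 0. TFAA step means are in percent dry mass;
#' the defaults encode a level of approximately 4 with a slight dip at the
#' middle processing step. Scatter, baseline and noise parameters control the
#' instrument artifacts added on top of the Beer-Lambert mixing model.
#'
#' @slot tfaaMeanByStep numeric, one mean (% dry mass) per processing step.
#' @slot tfaaSd numeric, within-step TFAA standard deviation (%).
#' @slot scatterSlopeSd,scatterOffsetSd numeric, multiplicative/additive
#'   scatter magnitudes per sample.
#' @slot baselineDegree integer, polynomial degree of the baseline drift.
#' @slot baselineCoefSd numeric, sd of each baseline polynomial coefficient.
#' @slot noiseSd numeric, additive per-channel reflectance noise sd.
#' @slot componentJitterSd numeric, relative between-sample variation of the
#'   nuisance (pigment, water) component coefficients.
#' @slot analyteCoefPerPct numeric, absorbance contribution of the analyte
#'   profile per percent TFAA.
#' @slot pigmentCoef,waterCoef numeric, mean absorbance coefficients of the
#'   nuisance components.
#' @slot stepPigmentFactor numeric, per-step multiplier on the pigment
#'   coefficient (leaf colour deepens along the processing line).
#' @slot baseReflectance numeric in (0, 1], envelope reflectance before
#'   absorption.
#' @slot seed integer RNG seed.
#' @exportClass SimulationParams
setClass("SimulationParams",
  representation(
    tfaaMeanByStep = "numeric", tfaaSd = "numeric",
    scatterSlopeSd = "numeric", scatterOffsetSd = "numeric",
    baselineDegree = "integer", baselineCoefSd = "numeric",
    noiseSd = "numeric", componentJitterSd = "numeric",
    analyteCoefPerPct = "numeric", pigmentCoef = "numeric",
    waterCoef = "numeric", stepPigmentFactor = "numeric",
    baseReflectance = "numeric", seed = "integer"
  )
)

setValidity("SimulationParams", function(object) {
  msg <- character()
  sds <- c(object@tfaaSd, object@scatterSlopeSd, object@scatterOffsetSd,
           object@baselineCoefSd, object@noiseSd, object@componentJitterSd)
  if (any(sds < 0)) msg <- c(msg, "all standard deviations must be >= 0")
  if (any(object@tfaaMeanByStep <= 0)) msg <- c(msg, "TFAA step means must be > 0")
  if (object@baseReflectance <= 0 || object@baseReflectance > 1)
    msg <- c(msg, "baseReflectance must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

## -------------------------------------------------------------- calibration set

#' Samples-by-bands calibration container
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"spectra"}
#' stores reflectance with rows = spectral channels and columns = samples;
#' \code{rowData} carries \code{wavelength_nm}, \code{colData} carries
#' \code{sample_id}, \code{step}, \code{batch}, \code{replicate} and the
#' reference chemistry \code{tfaa_percent}. Subsetting rows trims bands,
#' subsetting columns selects samples, and all metadata stay aligned.
#'
#' @exportClass CalibrationSet
setClass("CalibrationSet", contains = "SummarizedExperiment")

setValidity("CalibrationSet", function(object) {
  msg <- character()
  if (!"spectra" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'spectra' is required")
  if (!"wavelength_nm" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData column 'wavelength_nm' is required")
  wl <- SummarizedExperiment::rowData(object)$wavelength_nm
  if (length(wl) > 1L && any(diff(wl) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (!"tfaa_percent" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData column 'tfaa_percent' is required")
  if (length(msg)) msg else TRUE
})

## -------------------------------------------------------------- synthetic dataset

#' Synthetic dataset with planted ground truth
#'
#' Bundles the simulated \linkS4class{CalibrationSet} with the indices of the
#' planted analyte-informative channels (those where the analyte absorption
#' profile reaches at least half of its maximum) and a provenance record
#' (seed, parameter echo, clip-event count). The planted indices are the
#' ground truth against which wavelength selectors are validated.
#'
#' @slot calibration a \linkS4class{CalibrationSet}.
#' @slot plantedBands integer indices into the channel axis.
#' @slot provenance list with at least \code{seed} and \code{params}.
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
  representation(calibration = "CalibrationSet", plantedBands = "integer",
                 provenance = "list")
)

setValidity("SyntheticDataset", function(object) {
  msg <- character()
  p <- nrow(object@calibration)
  if (length(object@plantedBands) < 1L) msg <- c(msg, "plantedBands must be non-empty")
  if (any(object@plantedBands < 1L) || any(object@plantedBands > p))
    msg <- c(msg, "plantedBands out of channel range")
  if (length(msg)) msg else TRUE
})

## ------------------------------------------------------------------ spectral cube

#' Hyperspectral cube with companion reference frames
#'
#' A height x width x bands array of raw counts or reflectance together with
#' its wavelength axis and (optionally) the per-band averaged whiteboard and
#' dark-current reference spectra used for reflectance calibration.
#'
#' @slot data numeric array, height x width x bands.
#' @slot wavelengths numeric, strictly increasing, length = bands.
#' @slot kind either \code{"raw"} or \code{"reflectance"}.
#' @slot white,dark numeric vectors of length bands (or length 0 if absent).
#' @exportClass SpectralCube
setClass("SpectralCube",
  representation(data = "array", wavelengths = "numeric", kind = "character",
                 white = "numeric", dark = "numeric")
)

setValidity("SpectralCube", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-D array")
  else {
    if (d[3] != length(object@wavelengths))
      msg <- c(msg, "band axis must match wavelength vector")
    for (fr in c("white", "dark")) {
      v <- slot(object, fr)
      if (length(v) && length(v) != d[3])
        msg <- c(msg, sprintf("%s frame band count mismatch", fr))
    }
  }
  if (any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (!object@kind %in% c("raw", "reflectance"))
    msg <- c(msg, "kind must be 'raw' or 'reflectance'")
  if (object@kind == "reflectance" && !all(is.finite(object@data)))
    msg <- c(msg, "reflectance cube must be finite")
  if (length(msg)) msg else TRUE
})

## ------------------------------------------------------------------ mean spectrum

#' Per-sample mean reflectance spectrum
#'
#' @slot sampleId character scalar.
#' @slot values numeric reflectance, one per channel.
#' @slot wavelengths numeric grid in nm.
#' @slot pixelCount integer, number of foreground pixels averaged.
#' @exportClass MeanSpectrum
setClass("MeanSpectrum",
  representation(sampleId = "character", values = "numeric",
                 wavelengths = "numeric", pixelCount = "integer")
)

setValidity("MeanSpectrum", function(object) {
  msg <- character()
  if (object@pixelCount < 1L) msg <- c(msg, "pixelCount must be >= 1")
  if (length(object@values) != length(object@wavelengths))
    msg <- c(msg, "values length must match wavelength grid")
  if (length(msg)) msg else TRUE
})

## ----------------------------------------------------------------- standard curve

#' Ninhydrin-assay standard curve
#'
#' Ordinary least-squares line mapping absorbance at 570 nm to analyte mass
#' (mg). A valid assay has positive slope.
#'
#' @slot slope,intercept numeric coefficients (mass = slope * A + intercept).
#' @slot r2 numeric coefficient of determination of the fit.
#' @slot n integer number of standards.
#' @exportClass StandardCurve
setClass("StandardCurve",
  representation(slope = "numeric", intercept = "numeric", r2 = "numeric",
                 n = "integer")
)

setValidity("StandardCurve", function(object) {
  if (object@n < 2L) return("a standard curve needs >= 2 points")
  TRUE
})

## -------------------------------------------------------------- pretreatment spec

#' Fitted, ordered pretreatment chain
#'
#' An ordered chain of spectral pretreatments from \{MSC, CT, D1, SG\}. The
#' chain is fitted on calibration rows only (\code{\link{fitPretreatment}})
#' and then applied unchanged to calibration rows, prediction rows and map
#' pixels (\code{\link{applyPretreatment}}), which rules out information
#' leakage from the prediction set.
#'
#' @slot methods character vector, ordered subset of MSC, CT, D1, SG.
#' @slot options list of per-step options (SG/D1 window, polyorder, spacing).
#' @slot params list of fitted parameters (MSC reference, CT column means),
#'   empty until fitted.
#' @slot fitted logical scalar.
#' @exportClass PretreatmentSpec
setClass("PretreatmentSpec",
  representation(methods = "character", options = "list", params = "list",
                 fitted = "logical")
)

setValidity("PretreatmentSpec", function(object) {
  msg <- character()
  bad <- setdiff(object@methods, c("MSC", "CT", "D1", "SG", "none"))
  if (length(bad)) msg <- c(msg, paste("unknown pretreatment:", paste(bad, collapse = ", ")))
  if (object@fitted && length(object@params) != length(object@methods))
    msg <- c(msg, "fitted spec must carry one parameter set per step")
  if (length(msg)) msg else TRUE
})

## ------------------------------------------------------------------- split result

#' SPXY calibration/prediction split
#'
#' @slot train,test integer row indices, disjoint and exhaustive.
#' @slot selectionOrder integer, train indices in the order selected by the
#'   max-min procedure.
#' @slot fraction numeric, requested train fraction.
#' @exportClass SplitResult
setClass("SplitResult",
  representation(train = "integer", test = "integer",
                 selectionOrder = "integer", fraction = "numeric")
)

setValidity("SplitResult", function(object) {
  msg <- character()
  if (length(intersect(object@train, object@test)))
    msg <- c(msg, "train and test must be disjoint")
  if (!setequal(object@selectionOrder, object@train))
    msg <- c(msg, "selectionOrder must enumerate the train set")
  if (length(msg)) msg else TRUE
})

## --------------------------------------------------------------- selection result

#' Wavelength-selection result
#'
#' Output of \code{\link{carsSelect}} or \code{\link{vissaSelect}}: the
#' selected channel indices, the RMSECV trajectory over iterations, the
#' best (minimum-RMSECV) iteration, and an echo of the settings and seed.
#'
#' @slot method \code{"CARS"}, \code{"VISSA"} or \code{"none"}.
#' @slot bands sorted unique integer channel indices, non-empty.
#' @slot trace numeric RMSECV per iteration.
#' @slot bestIteration integer, the iteration whose channels were returned
#'   (the argmin of the trace, or the sparsest statistically tied iteration
#'   under the one-standard-error rule).
#' @slot settings list echoing the call settings (includes \code{p}, the
#'   total channel count).
#' @slot seed integer.
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(method = "character", bands = "integer", trace = "numeric",
                 bestIteration = "integer", settings = "list", seed = "integer")
)

setValidity("SelectionResult", function(object) {
  msg <- character()
  b <- object@bands
  if (length(b) < 1L) msg <- c(msg, "selected set must be non-empty")
  if (is.unsorted(b, strictly = TRUE)) msg <- c(msg, "bands must be sorted and unique")
  p <- object@settings$p
  if (!is.null(p) && length(b) && (min(b) < 1L || max(b) > p))
    msg <- c(msg, "bands out of range")
  if (length(object@bestIteration) == 1L && length(object@trace) &&
      (object@bestIteration < 1L || object@bestIteration > length(object@trace)))
    msg <- c(msg, "bestIteration out of trace range")
  if (length(msg)) msg else TRUE
})

## ------------------------------------------------------------------- PLSR model

#' Partial least squares regression model (SIMPLS)
#'
#' @slot nlv integer, number of latent variables.
#' @slot xMeans,yMean centring parameters learned from the training rows.
#' @slot coefficients numeric regression vector (one per channel); predictions
#'   are \code{(X - xMeans) \%*\% coefficients + yMean}.
#' @slot cvTable data.frame mapping candidate nLVs to RMSECV (may be empty).
#' @exportClass PLSRModel
setClass("PLSRModel",
  representation(nlv = "integer", xMeans = "numeric", yMean = "numeric",
                 coefficients = "numeric", cvTable = "data.frame")
)

setValidity("PLSRModel", function(object) {
  if (object@nlv < 1L) return("nlv must be >= 1")
  if (length(object@coefficients) != length(object@xMeans))
    return("coefficient length must match channel count")
  TRUE
})

## ------------------------------------------------------------------ LS-SVR model

#' Least squares support vector regression model
#'
#' Kernel ridge-style regression solving the single linear KKT system
#' \code{[[0, 1'], [1, K + I/C]] [b; alpha] = [0; y]} with an RBF kernel
#' \code{K_ij = exp(-gamma * ||x_i - x_j||^2)} (a linear kernel is available
#' as an oracle mode for testing).
#'
#' @slot gamma,cost positive hyperparameters (RBF width, regularisation C).
#' @slot alpha numeric support coefficients, one per training row.
#' @slot b numeric bias.
#' @slot X training matrix (centred), stored for kernel evaluation.
#' @slot xMeans numeric centring vector applied to new data.
#' @slot kernel \code{"rbf"} or \code{"linear"}.
#' @exportClass LSSVRModel
setClass("LSSVRModel",
  representation(gamma = "numeric", cost = "numeric", alpha = "numeric",
                 b = "numeric", X = "matrix", xMeans = "numeric",
                 kernel = "character")
)

setValidity("LSSVRModel", function(object) {
  msg <- character()
  if (object@cost <= 0) msg <- c(msg, "C must be > 0")
  if (object@kernel == "rbf" && object@gamma <= 0) msg <- c(msg, "gamma must be > 0")
  if (length(object@alpha) != nrow(object@X))
    msg <- c(msg, "one alpha per training row required")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------- prediction map

#' Pixel-wise TFAA prediction map
#'
#' @slot values numeric matrix (height x width) of predicted TFAA (% dry
#'   mass); \code{NA} outside the foreground mask.
#' @slot mask logical matrix, TRUE = foreground.
#' @slot modelLabel character, e.g. \code{"CT-CARS-PLSR"}.
#' @slot limits numeric length-2 colour-scale limits.
#' @exportClass PredictionMap
setClass("PredictionMap",
  representation(values = "matrix", mask = "matrix", modelLabel = "character",
                 limits = "numeric")
)

setValidity("PredictionMap", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "values and mask dimensions must agree")
  if (any(!is.na(object@values[!object@mask])))
    msg <- c(msg, "values must be NA outside the mask")
  if (length(object@limits) == 2L &&
      (any(!is.finite(object@limits)) || object@limits[1] > object@limits[2]))
    msg <- c(msg, "limits must be finite and ordered")
  if (length(msg)) msg else TRUE
})

## ----------------------------------------------------------------- show methods

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf("StudyDesign: %d steps (%s) x %d batches x %d replicates = %d samples\n",
              length(object@steps), paste(object@steps, collapse = ", "),
              object@batches, object@replicates, nrow(object@roster)))
  wl <- object@wavelengths
  cat(sprintf("  grid: %d channels, %.1f-%.1f nm (spacing %.4g nm)\n",
              length(wl), min(wl), max(wl), wl[2] - wl[1]))
})

setMethod("show", "SpectralCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("SpectralCube [%s]: %d x %d pixels, %d bands (%.1f-%.1f nm)%s\n",
              object@kind, d[1], d[2], d[3],
              min(object@wavelengths), max(object@wavelengths),
              if (length(object@white)) ", white/dark frames attached" else ""))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset: %d samples x %d channels, %d planted analyte bands (seed %d)\n",
              ncol(object@calibration), nrow(object@calibration),
              length(object@plantedBands), object@provenance$seed))
})

setMethod("show", "PretreatmentSpec", function(object) {
  cat(sprintf("PretreatmentSpec: %s [%s]\n",
              paste(object@methods, collapse = " -> "),
              if (object@fitted) "fitted" else "unfitted"))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult [%s]: %d bands of %s, best iteration %d (RMSECV %.4g)\n",
              object@method, length(object@bands),
              as.character(object@settings$p %||% "?"),
              object@bestIteration, min(object@trace)))
})

setMethod("show", "PLSRModel", function(object) {
  cat(sprintf("PLSRModel: %d latent variables over %d channels\n",
              object@nlv, length(object@coefficients)))
})

setMethod("show", "LSSVRModel", function(object) {
  cat(sprintf("LSSVRModel [%s kernel]: gamma = %.4g, C = %.4g, %d support points\n",
              object@kernel, object@gamma, object@cost, length(object@alpha)))
})

setMethod("show", "SplitResult", function(object) {
  cat(sprintf("SplitResult: %d train / %d test (fraction %.3f)\n",
              length(object@train), length(object@test), object@fraction))
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf("StandardCurve: mass = %.4g * A + %.4g (R2 = %.4f, n = %d)\n",
              object@slope, object@intercept, object@r2, object@n))
})

setMethod("show", "PredictionMap", function(object) {
  cat(sprintf("PredictionMap [%s]: %d x %d, %d foreground pixels, scale [%.3g, %.3g]\n",
              object@modelLabel, nrow(object@values), ncol(object@values),
              sum(object@mask), object@limits[1], object@limits[2]))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
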