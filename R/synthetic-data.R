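## Synthetic-data generator: study-shaped fixtures with planted ground truth.
## The mixing model is Beer-Lambert-style exponential attenuation mapped to
## reflectance, with multiplicative scatter, polynomial baseline drift and
## additive noise layered on top, so that the pretreatments have realistic
## work to do while a linear model remains a good local approximation.

#' Build a study design
#'
#' Materialises the sampling roster and wavelength grid of a tea-processing
#' hyperspectral experiment. The default reproduces a production-line layout:
#' 3 processing steps (FLS, SF, HD) x 30 batches x 3 replicates = 270 samples
#' on a 951-channel grid spanning 400--1000 nm.
#'
#' @param steps ordered character vector of processing-step labels.
#' @param batches integer >= 1, sampling batches per step.
#' @param replicates integer >= 1, replicate samplings per batch.
#' @param wavelengthStart,wavelengthEnd grid endpoints in nm (inclusive).
#' @param nChannels integer >= 2, number of spectral channels.
#' @return a \linkS4class{StudyDesign}.
#' @examples
#' d <- studyDesign()
#' nrow(designRoster(d))  # 270
#' @export
studyDesign <- function(steps = c("FLS", "SF", "HD"), batches = 30L,
                        replicates = 3L, wavelengthStart = 400,
                        wavelengthEnd = 1000, nChannels = 951L) {
  batches <- as.integer(batches); replicates <- as.integer(replicates)
  nChannels <- as.integer(nChannels)
  if (length(steps) < 1L || batches < 1L || replicates < 1L)
    stop("steps, batches and replicates must all be >= 1")
  if (wavelengthEnd <= wavelengthStart)
    stop("wavelengthEnd must exceed wavelengthStart")
  if (nChannels < 2L) stop("nChannels must be >= 2")
  roster <- expand.grid(replicate = seq_len(replicates),
                        batch = seq_len(batches),
                        step = steps, stringsAsFactors = FALSE)
  roster <- roster[, c("step", "batch", "replicate")]
  roster$sample_id <- sprintf("%s_b%02d_r%d", roster$step, roster$batch,
                              roster$replicate)
  wl <- seq(wavelengthStart, wavelengthEnd, length.out = nChannels)
  new("StudyDesign", steps = steps, batches = batches,
      replicates = replicates, roster = roster, wavelengths = wl)
}

#' @rdname accessors
#' @export
designRoster <- function(x) x@roster

#' @describeIn studyDesign wavelength accessor for a design.
#' @param x a \linkS4class{StudyDesign}.
#' @export
setMethod("wavelengths", "StudyDesign", function(x) x@wavelengths)

## Gaussian band profile over a grid; bands = matrix with columns
## center_nm, sigma_nm, amplitude.
gaussianProfile <- function(wavelengths, bands) {
  bands <- rbind(bands)
  prof <- rep(0, length(wavelengths))
  for (i in seq_len(nrow(bands))) {
    prof <- prof + bands[i, 3] *
      exp(-(wavelengths - bands[i, 1])^2 / (2 * bands[i, 2]^2))
  }
  prof
}

#' Spectral component library
#'
#' Builds unit-normalised (max = 1) absorption profiles on a wavelength grid,
#' each a sum of Gaussian bands given as rows of \code{c(center_nm, sigma_nm,
#' amplitude)}. The defaults encode: an analyte (free amino acid) profile
#' with an O-H first-overtone band at 947 nm and an N-H band at 1000 nm; a
#' chlorophyll-like pigment absorbing strongly in the blue and red
#' (620--780 nm) and weakly in the green (490--560 nm), which carves the
#' familiar dual reflectance peaks at 500--600 nm and 750--950 nm out of leaf
#' spectra; and a water/background profile with a band near 970 nm. Custom
#' band tables (e.g. a single isolated analyte band for selector-validation
#' studies) may be supplied.
#'
#' @param wavelengths numeric grid in nm.
#' @param analyteBands,pigmentBands,waterBands Gaussian band tables; set
#'   \code{pigmentBands}/\code{waterBands} to \code{NULL} to omit the
#'   component.
#' @return a \linkS4class{ComponentLibrary}.
#' @export
componentLibrary <- function(wavelengths,
                             analyteBands = rbind(c(947, 15, 1.0),
                                                  c(1000, 20, 0.8)),
                             pigmentBands = rbind(c(440, 25, 1.0),
                                                  c(670, 30, 1.0),
                                                  c(525, 30, 0.15)),
                             waterBands = rbind(c(970, 25, 1.0))) {
  comp <- list(analyte = analyteBands, pigment = pigmentBands,
               water = waterBands)
  comp <- comp[!vapply(comp, is.null, logical(1))]
  prof <- vapply(comp, function(b) {
    v <- gaussianProfile(wavelengths, b)
    v / max(v)
  }, numeric(length(wavelengths)))
  new("ComponentLibrary", wavelengths = wavelengths, profiles = prof)
}

#' @describeIn componentLibrary wavelength accessor.
#' @param x a \linkS4class{ComponentLibrary}.
#' @export
setMethod("wavelengths", "ComponentLibrary", function(x) x@wavelengths)

#' @describeIn componentLibrary channels x components profile matrix.
#' @param object a \linkS4class{ComponentLibrary}.
#' @export
componentProfiles <- function(object) object@profiles

#' Simulation parameters
#'
#' Constructor with the generator's default study conditions: TFAA
#' concentrated around 4\% dry mass with a slight dip (3.8\%) at the middle
#' processing step, within-step sd 0.5\%, mild multiplicative scatter,
#' quadratic baseline drift and additive reflectance noise. Setting every sd
#' to zero yields a fully deterministic function of TFAA.
#'
#' @param tfaaMeanByStep numeric, \% dry mass per processing step.
#' @param tfaaSd within-step TFAA sd (\%).
#' @param scatterSlopeSd,scatterOffsetSd per-sample multiplicative slope /
#'   additive offset scatter sds.
#' @param baselineDegree polynomial degree of the baseline drift.
#' @param baselineCoefSd sd of each baseline polynomial coefficient.
#' @param noiseSd additive per-channel reflectance noise sd.
#' @param componentJitterSd relative between-sample variation of the pigment
#'   and water coefficients (composition variability, distinct from sensor
#'   noise).
#' @param analyteCoefPerPct absorbance per percent TFAA on the analyte
#'   profile; small enough that reflectance stays locally linear in TFAA.
#' @param pigmentCoef,waterCoef mean absorbance coefficients of the nuisance
#'   components.
#' @param stepPigmentFactor per-step pigment multiplier (colour deepens along
#'   the line).
#' @param baseReflectance envelope reflectance before absorption.
#' @param seed integer RNG seed.
#' @return a \linkS4class{SimulationParams}.
#' @export
simulationParams <- function(tfaaMeanByStep = c(4.0, 3.8, 4.0), tfaaSd = 0.5,
                             scatterSlopeSd = 0.03, scatterOffsetSd = 0.01,
                             baselineDegree = 2L, baselineCoefSd = 0.005,
                             noiseSd = 0.002, componentJitterSd = 0.05,
                             analyteCoefPerPct = 0.05, pigmentCoef = 1.5,
                             waterCoef = 0.8,
                             stepPigmentFactor = c(1.0, 1.05, 1.15),
                             baseReflectance = 0.75, seed = 42L) {
  new("SimulationParams",
      tfaaMeanByStep = tfaaMeanByStep, tfaaSd = tfaaSd,
      scatterSlopeSd = scatterSlopeSd, scatterOffsetSd = scatterOffsetSd,
      baselineDegree = as.integer(baselineDegree),
      baselineCoefSd = baselineCoefSd, noiseSd = noiseSd,
      componentJitterSd = componentJitterSd,
      analyteCoefPerPct = analyteCoefPerPct, pigmentCoef = pigmentCoef,
      waterCoef = waterCoef, stepPigmentFactor = stepPigmentFactor,
      baseReflectance = baseReflectance, seed = as.integer(seed))
}

#' Construct a CalibrationSet
#'
#' @param spectra samples x channels reflectance matrix.
#' @param wavelengths numeric grid in nm, one per channel.
#' @param tfaa numeric reference TFAA (\% dry mass), one per sample.
#' @param step,batch,replicate optional per-sample metadata.
#' @param sampleId optional sample identifiers (defaults to row names or
#'   \code{sample_1, ...}).
#' @return a \linkS4class{CalibrationSet}.
#' @export
calibrationSet <- function(spectra, wavelengths, tfaa, step = NULL,
                           batch = NULL, replicate = NULL, sampleId = NULL) {
  spectra <- as.matrix(spectra)
  n <- nrow(spectra)
  if (ncol(spectra) != length(wavelengths))
    stop("spectra columns must match wavelength grid")
  if (length(tfaa) != n) stop("one TFAA value per sample required")
  if (is.null(sampleId))
    sampleId <- rownames(spectra) %||% sprintf("sample_%03d", seq_len(n))
  cd <- S4Vectors::DataFrame(
    sample_id = sampleId,
    step = step %||% rep(NA_character_, n),
    batch = batch %||% rep(NA_integer_, n),
    replicate = replicate %||% rep(NA_integer_, n),
    tfaa_percent = tfaa)
  rownames(cd) <- sampleId
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(spectra = t(unname(spectra))),
    rowData = S4Vectors::DataFrame(wavelength_nm = wavelengths),
    colData = cd)
  new("CalibrationSet", se)
}

#' @rdname accessors
#' @export
setMethod("wavelengths", "CalibrationSet", function(x)
  SummarizedExperiment::rowData(x)$wavelength_nm)

#' @rdname accessors
#' @export
setMethod("spectraMatrix", "CalibrationSet", function(x) {
  m <- t(SummarizedExperiment::assay(x, "spectra"))
  rownames(m) <- SummarizedExperiment::colData(x)$sample_id
  m
})

#' @rdname accessors
#' @export
setMethod("tfaa", "CalibrationSet", function(x)
  SummarizedExperiment::colData(x)$tfaa_percent)

#' @rdname accessors
#' @export
setMethod("processStep", "CalibrationSet", function(x)
  SummarizedExperiment::colData(x)$step)

#' @rdname accessors
#' @export
setMethod("calibration", "SyntheticDataset", function(x) x@calibration)

#' @rdname accessors
#' @export
setMethod("plantedBands", "SyntheticDataset", function(x) x@plantedBands)

#' @rdname accessors
#' @export
setMethod("wavelengths", "SyntheticDataset", function(x)
  wavelengths(x@calibration))

#' @rdname accessors
#' @export
setMethod("wavelengths", "SpectralCube", function(x) x@wavelengths)

#' @rdname accessors
#' @export
setMethod("wavelengths", "MeanSpectrum", function(x) x@wavelengths)

#' Simulate sample spectra for a study design
#'
#' Draws per-sample TFAA values from the configured per-step normals (clipped
#' to be positive), then generates reflectance as
#' \deqn{r(\lambda) = \mathrm{clip}_{(0,1]}\{[a\,e^{-\sum_k c_k\,
#'   \mathrm{profile}_k(\lambda)} + \mathrm{baseline}(\lambda)]
#'   (1 + \mathrm{slope}) + \mathrm{offset} + \mathrm{noise}\}}
#' with the analyte coefficient proportional to the sample's TFAA and the
#' pigment/water coefficients jittered between samples. Identical seeds give
#' bit-identical output.
#'
#' The planted ground truth is the set of channels where the analyte profile
#' reaches at least \code{plantedThreshold} of its maximum; with every
#' stochastic term switched off, regressing TFAA on the absorbance
#' \eqn{-\log r} at any planted channel is exactly linear.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param library a \linkS4class{ComponentLibrary} on the design's grid
#'   (default built by \code{\link{componentLibrary}}).
#' @param params a \linkS4class{SimulationParams}.
#' @param seed integer seed (defaults to \code{params@seed}).
#' @param plantedThreshold fraction of the analyte-profile maximum defining
#'   the planted channels (default 0.5).
#' @return a \linkS4class{SyntheticDataset}.
#' @examples
#' ds <- simulateTeaSpectra(studyDesign(batches = 2), seed = 7)
#' dim(spectraMatrix(calibration(ds)))
#' @export
simulateTeaSpectra <- function(design, library = NULL,
                               params = simulationParams(), seed = NULL,
                               plantedThreshold = 0.5) {
  if (is.null(library)) library <- componentLibrary(design@wavelengths)
  if (!isTRUE(all.equal(library@wavelengths, design@wavelengths)))
    stop("component library is not defined on the design's wavelength grid")
  seed <- as.integer(seed %||% params@seed)
  roster <- design@roster
  n <- nrow(roster)
  wl <- design@wavelengths
  p <- length(wl)
  stepIdx <- match(roster$step, design@steps)
  stepMeans <- rep_len(params@tfaaMeanByStep, length(design@steps))
  pigFac <- rep_len(params@stepPigmentFactor, length(design@steps))

  out <- withr::with_seed(seed, {
    y <- rnorm(n, mean = stepMeans[stepIdx], sd = params@tfaaSd)
    y <- pmax(y, 1e-3)  # physical: concentrations stay positive
    jp <- rnorm(n, 0, params@componentJitterSd)
    jw <- rnorm(n, 0, params@componentJitterSd)
    slope <- rnorm(n, 0, params@scatterSlopeSd)
    offset <- rnorm(n, 0, params@scatterOffsetSd)
    bcoef <- matrix(rnorm(n * (params@baselineDegree + 1L), 0,
                          params@baselineCoefSd), nrow = n)
    noise <- matrix(rnorm(n * p, 0, params@noiseSd), nrow = n)
    list(y = y, jp = jp, jw = jw, slope = slope, offset = offset,
         bcoef = bcoef, noise = noise)
  })

  prof <- library@profiles
  absorb <- (params@analyteCoefPerPct * out$y) %o% prof[, "analyte"]
  if ("pigment" %in% colnames(prof))
    absorb <- absorb + (params@pigmentCoef * pigFac[stepIdx] * (1 + out$jp)) %o%
      prof[, "pigment"]
  if ("water" %in% colnames(prof))
    absorb <- absorb + (params@waterCoef * (1 + out$jw)) %o% prof[, "water"]
  r0 <- params@baseReflectance * exp(-absorb)

  u <- 2 * (wl - min(wl)) / (max(wl) - min(wl)) - 1  # scaled to [-1, 1]
  vander <- outer(u, 0:params@baselineDegree, `^`)
  baseline <- out$bcoef %*% t(vander)

  r <- (r0 + baseline) * (1 + out$slope) + out$offset + out$noise
  nclip <- sum(r <= 0 | r > 1)
  r <- pmin(pmax(r, 1e-6), 1)
  rownames(r) <- roster$sample_id

  cal <- calibrationSet(r, wl, out$y, step = roster$step,
                        batch = roster$batch, replicate = roster$replicate,
                        sampleId = roster$sample_id)
  planted <- which(prof[, "analyte"] >= plantedThreshold * max(prof[, "analyte"]))
  new("SyntheticDataset", calibration = cal,
      plantedBands = as.integer(planted),
      provenance = list(seed = seed, params = params,
                        plantedThreshold = plantedThreshold,
                        clipEvents = nclip))
}

#' Simulate a hyperspectral cube around one sample spectrum
#'
#' Builds a reflectance cube whose foreground pixels equal the supplied
#' spectrum plus iid pixel noise and whose background pixels are a
#' low-reflectance filler (0.02), together with the companion whiteboard
#' (~1) and dark-current (~0) frames and a raw-counts cube constructed so
#' that \code{\link{calibrateReflectance}} recovers the stored reflectance.
#' The foreground region is a deterministic central blob sized so that
#' \code{backgroundFraction} of the pixels are background.
#'
#' @param spectrum numeric reflectance spectrum or \linkS4class{MeanSpectrum}.
#' @param wavelengths grid in nm (taken from the \code{MeanSpectrum} if one
#'   is given).
#' @param height,width positive image dimensions in pixels.
#' @param backgroundFraction fraction of pixels that are background filler.
#' @param backgroundReflectance filler reflectance level.
#' @param pixelNoiseSd iid per-pixel reflectance noise sd.
#' @param sensorNoiseSd per-band noise on the white/dark reference frames.
#' @param darkLevel mean dark-current level in raw-count units.
#' @param seed integer RNG seed.
#' @return list with elements \code{raw} (a raw-counts
#'   \linkS4class{SpectralCube} carrying white/dark frames),
#'   \code{reflectance} (the reflectance \linkS4class{SpectralCube}),
#'   \code{foreground} (logical height x width ground-truth mask) and
#'   \code{spectrum} (the input spectrum).
#' @export
simulateCube <- function(spectrum, wavelengths = NULL, height = 40L,
                         width = 40L, backgroundFraction = 0.3,
                         backgroundReflectance = 0.02, pixelNoiseSd = 0.002,
                         sensorNoiseSd = 0, darkLevel = 0.05, seed = 1L) {
  if (is(spectrum, "MeanSpectrum")) {
    wavelengths <- spectrum@wavelengths
    spectrum <- spectrum@values
  }
  if (is.null(wavelengths)) stop("wavelengths required for a bare spectrum")
  if (length(spectrum) != length(wavelengths))
    stop("spectrum length must match wavelength grid")
  height <- as.integer(height); width <- as.integer(width)
  if (height < 1L || width < 1L) stop("image dimensions must be positive")
  p <- length(wavelengths)
  npix <- height * width

  # deterministic central blob: background = pixels farthest from centre
  ri <- matrix(seq_len(height), height, width)
  ci <- matrix(seq_len(width), height, width, byrow = TRUE)
  d2 <- ((ri - (height + 1) / 2) / height)^2 + ((ci - (width + 1) / 2) / width)^2
  nbg <- round(backgroundFraction * npix)
  ord <- order(d2, decreasing = TRUE)
  fg <- matrix(TRUE, height, width)
  if (nbg > 0) fg[ord[seq_len(min(nbg, npix))]] <- FALSE

  refl <- withr::with_seed(as.integer(seed), {
    arr <- array(0, dim = c(height, width, p))
    noise <- array(rnorm(npix * p, 0, pixelNoiseSd), dim = c(height, width, p))
    base <- array(rep(backgroundReflectance, npix * p), dim = c(height, width, p))
    fgarr <- array(rep(fg, p), dim = c(height, width, p))
    spec <- aperm(array(spectrum, dim = c(p, height, width)), c(2, 3, 1))
    arr <- ifelse(fgarr, spec, base) + noise
    white <- 1 + rnorm(p, 0, sensorNoiseSd)
    dark <- darkLevel + rnorm(p, 0, sensorNoiseSd)
    list(arr = pmin(pmax(arr, 1e-6), 1), white = white, dark = dark)
  })

  whiteCounts <- refl$dark + refl$white
  darkCounts <- refl$dark
  raw <- array(0, dim = c(height, width, p))
  span <- whiteCounts - darkCounts
  for (k in seq_len(p))
    raw[, , k] <- darkCounts[k] + span[k] * refl$arr[, , k]

  list(
    raw = new("SpectralCube", data = raw, wavelengths = wavelengths,
              kind = "raw", white = whiteCounts, dark = darkCounts),
    reflectance = new("SpectralCube", data = refl$arr,
                      wavelengths = wavelengths, kind = "reflectance",
                      white = numeric(), dark = numeric()),
    foreground = fg, spectrum = spectrum)
}

#' Simulate a selector-validation fixture with planted bands
#'
#' A compact fixture for validating wavelength selectors against known
#' ground truth. TFAA is modelled as the total over \code{nPlanted}
#' amino-acid-like sub-components, each with its own narrow absorption band
#' (one channel wide at half maximum) and its own independently drawn
#' concentration; the response is the total. Because no single channel
#' determines the total, every planted channel is individually necessary for
#' an exact fit — the property a selector must exploit. Broad pigment and
#' water nuisance components with between-sample coefficient jitter provide
#' realistic interfering variance; sensor noise, scatter and baseline are off
#' by default ("noiseless" means no measurement noise, not no composition
#' variability).
#'
#' @param nSamples number of samples.
#' @param nChannels number of spectral channels over 400--1000 nm.
#' @param nPlanted number of planted analyte channels.
#' @param seed integer RNG seed.
#' @param tfaaMean,tfaaSd mean and sd of total TFAA (\% dry mass); each
#'   sub-component draws mean/nPlanted and sd/sqrt(nPlanted).
#' @param jitterSd relative sd of the nuisance-component coefficients.
#' @param noiseSd additive reflectance noise sd; the default 1e-3 is a
#'   sensor-noise floor that keeps the spectral matrix full rank (a strictly
#'   zero-noise matrix is rank-deficient and coefficient-based selector
#'   weights become non-identifiable).
#' @param analyteCoefPerPct absorbance per percent on each sub-band.
#' @return a \linkS4class{SyntheticDataset}; \code{plantedBands} are the
#'   \code{nPlanted} channel indices.
#' @export
simulateSelectorFixture <- function(nSamples = 80L, nChannels = 100L,
                                    nPlanted = 5L, seed = 1L, tfaaMean = 4,
                                    tfaaSd = 0.5, jitterSd = 0.05,
                                    noiseSd = 1e-3, analyteCoefPerPct = 0.05) {
  nSamples <- as.integer(nSamples); nChannels <- as.integer(nChannels)
  nPlanted <- as.integer(nPlanted)
  if (nPlanted < 1L || nPlanted > nChannels %/% 4L)
    stop("nPlanted must be between 1 and nChannels/4")
  wl <- seq(400, 1000, length.out = nChannels)
  spacing <- wl[2] - wl[1]
  # planted channels sit in the nuisance-quiet 580-840 nm window so each is
  # an essentially pure recorder of its own sub-component
  planted <- round(seq(which.min(abs(wl - 580)), which.min(abs(wl - 840)),
                       length.out = nPlanted))
  # single-channel sub-bands: each sub-component is recorded by exactly one
  # channel, so zero-noise collinear proxies cannot arise at neighbours
  subProf <- vapply(planted, function(j)
    as.numeric(abs(wl - wl[j]) < spacing / 2), numeric(nChannels))
  pigment <- exp(-(wl - 500)^2 / (2 * 30^2))
  water <- exp(-(wl - 900)^2 / (2 * 30^2))

  out <- withr::with_seed(as.integer(seed), {
    tk <- matrix(rnorm(nSamples * nPlanted, tfaaMean / nPlanted,
                       tfaaSd / sqrt(nPlanted)), nrow = nSamples)
    tk <- pmax(tk, 1e-3)
    list(tk = tk,
         jp = rnorm(nSamples, 0, jitterSd),
         jw = rnorm(nSamples, 0, jitterSd),
         noise = matrix(rnorm(nSamples * nChannels, 0, noiseSd),
                        nrow = nSamples))
  })
  y <- rowSums(out$tk)
  absorb <- (analyteCoefPerPct * nPlanted * out$tk) %*% t(subProf) +
    (1.5 * (1 + out$jp)) %o% pigment + (0.8 * (1 + out$jw)) %o% water
  r <- pmin(pmax(0.75 * exp(-absorb) + out$noise, 1e-6), 1)
  rownames(r) <- sprintf("sample_%03d", seq_len(nSamples))
  cal <- calibrationSet(r, wl, y)
  new("SyntheticDataset", calibration = cal,
      plantedBands = as.integer(sort(planted)),
      provenance = list(seed = as.integer(seed),
                        params = simulationParams(
                          tfaaMeanByStep = tfaaMean, tfaaSd = tfaaSd,
                          noiseSd = noiseSd, componentJitterSd = jitterSd,
                          analyteCoefPerPct = analyteCoefPerPct, seed = seed),
                        plantedThreshold = 0.5, clipEvents = 0L))
}

#' Write a synthetic dataset to disk
#'
#' Emits the chemistry table as CSV (\code{sample_id, step, batch, replicate,
#' tfaa_percent}), a JSON sidecar with seed, parameter echo and planted-band
#' indices, and optionally one ENVI cube (plus white/dark reference cubes)
#' per requested sample.
#'
#' @param dataset a \linkS4class{SyntheticDataset}.
#' @param dir output directory (created if needed).
#' @param cubeSamples character vector of sample ids for which to simulate
#'   and write ENVI cubes (default none).
#' @param height,width cube dimensions.
#' @param seed seed for the cube pixel noise.
#' @return invisibly, the paths written.
#' @export
writeSyntheticDataset <- function(dataset, dir, cubeSamples = character(),
                                  height = 40L, width = 40L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cal <- dataset@calibration
  cd <- as.data.frame(SummarizedExperiment::colData(cal))
  chem <- cd[, c("sample_id", "step", "batch", "replicate", "tfaa_percent")]
  chemPath <- file.path(dir, "chemistry.csv")
  write.csv(chem, chemPath, row.names = FALSE)

  prm <- dataset@provenance$params
  sidecar <- list(
    seed = dataset@provenance$seed,
    planted_bands = dataset@plantedBands,
    planted_threshold = dataset@provenance$plantedThreshold,
    clip_events = dataset@provenance$clipEvents,
    params = lapply(slotNames(prm), function(s) slot(prm, s)) |>
      stats::setNames(slotNames(prm)))
  jsonPath <- file.path(dir, "provenance.json")
  jsonlite::write_json(sidecar, jsonPath, auto_unbox = TRUE, digits = NA)

  paths <- c(chemPath, jsonPath)
  X <- spectraMatrix(cal)
  for (sid in cubeSamples) {
    i <- match(sid, cd$sample_id)
    if (is.na(i)) stop("unknown sample id: ", sid)
    cube <- simulateCube(X[i, ], wavelengths(cal), height = height,
                         width = width, seed = seed)
    stem <- file.path(dir, sid)
    writeENVICube(cube$raw, stem)
    paths <- c(paths, paste0(stem, c(".hdr", ".dat")))
  }
  invisible(paths)
}
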