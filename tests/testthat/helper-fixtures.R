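# Shared fixtures, built once per test run. Small sizes keep the default
# suite fast; the acceptance tests use the full study-scale fixture.

smallDesign <- function() studyDesign(batches = 4L, replicates = 2L,
                                      nChannels = 120L)

# fully deterministic generator settings: spectra are an exact function of
# (TFAA, step); used by exact-solvability and determinism tests
quietParams <- function(...) simulationParams(
  scatterSlopeSd = 0, scatterOffsetSd = 0, baselineCoefSd = 0,
  noiseSd = 0, componentJitterSd = 0, ...)

.cache <- new.env(parent = emptyenv())

smallDataset <- function() {
  if (is.null(.cache$small))
    .cache$small <- simulateTeaSpectra(smallDesign(), seed = 7L)
  .cache$small
}

fullDataset <- function() {
  if (is.null(.cache$full))
    .cache$full <- simulateTeaSpectra(studyDesign(), seed = 11L)
  .cache$full
}

randomCube <- function(h = 4L, w = 5L, p = 6L, seed = 3L) {
  withr::with_seed(seed, {
    new("SpectralCube",
        data = array(runif(h * w * p, 0.1, 0.9), dim = c(h, w, p)),
        wavelengths = seq(400, 1000, length.out = p), kind = "reflectance",
        white = numeric(), dark = numeric())
  })
}
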