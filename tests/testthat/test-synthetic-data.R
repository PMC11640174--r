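test_that("study design materialises the roster and wavelength grid", {
  d <- studyDesign()
  expect_equal(nrow(designRoster(d)), 270L)
  expect_equal(length(wavelengths(d)), 951L)
  expect_equal(wavelengths(d)[1], 400)
  expect_equal(tail(wavelengths(d), 1), 1000)
  expect_equal(diff(wavelengths(d))[1], 600 / 950, tolerance = 1e-12)

  d1 <- studyDesign(steps = "FLS", batches = 1, replicates = 1)
  expect_equal(nrow(designRoster(d1)), 1L)

  expect_error(studyDesign(batches = 0), "must all be >= 1")
  expect_error(studyDesign(wavelengthStart = 1000, wavelengthEnd = 400),
               "must exceed")
})

test_that("component library profiles honour the band placement", {
  wl <- seq(400, 1000, length.out = 951)
  lib <- componentLibrary(wl)
  prof <- componentProfiles(lib)
  expect_true(all(prof >= 0))
  expect_equal(unname(apply(prof, 2, max)), rep(1, 3))
  # analyte bands at 947 and 1000 nm
  a <- prof[, "analyte"]
  expect_equal(wl[which.max(a)], 947, tolerance = 1)
  expect_gt(a[length(wl)], 0.5)          # N-H band at the 1000 nm edge
  # pigment: strong red absorption, weak green
  pig <- prof[, "pigment"]
  red <- mean(pig[wl >= 620 & wl <= 780])
  green <- mean(pig[wl >= 490 & wl <= 560])
  expect_gt(red, green)
  expect_lt(green, 0.4)
})

test_that("simulated mean spectrum shows the dual reflectance peaks", {
  ds <- smallDataset()
  cal <- calibration(ds)
  mu <- colMeans(spectraMatrix(cal))
  wl <- wavelengths(cal)
  at <- function(nm) mu[which.min(abs(wl - nm))]
  w1 <- wl >= 500 & wl <= 600
  w2 <- wl >= 750 & wl <= 950
  # local maxima inside each window, above the window edges and the red trough
  expect_gt(max(mu[w1]), at(500))
  expect_gt(max(mu[w1]), at(670))
  expect_gt(max(mu[w2]), at(670))
  expect_gt(max(mu[w2]), at(990))
})

test_that("generator is seed-deterministic and clips to (0, 1]", {
  d <- smallDesign()
  a <- simulateTeaSpectra(d, seed = 5)
  b <- simulateTeaSpectra(d, seed = 5)
  expect_identical(spectraMatrix(calibration(a)), spectraMatrix(calibration(b)))
  expect_identical(tfaa(calibration(a)), tfaa(calibration(b)))
  c1 <- simulateTeaSpectra(d, seed = 6)
  expect_false(identical(spectraMatrix(calibration(a)),
                         spectraMatrix(calibration(c1))))
  X <- spectraMatrix(calibration(a))
  expect_true(all(X > 0 & X <= 1))
})

test_that("noise-free spectra are a deterministic function of TFAA", {
  d <- smallDesign()
  prm <- quietParams(tfaaSd = 0, tfaaMeanByStep = c(4, 4, 4),
                     stepPigmentFactor = 1)
  X <- spectraMatrix(calibration(simulateTeaSpectra(d, params = prm, seed = 1)))
  # all samples share TFAA = 4 and every stochastic term is off
  expect_equal(max(abs(sweep(X, 2, X[1, ]))), 0)
})

test_that("planted bands admit an exact linear fit on the absorbance scale", {
  d <- smallDesign()
  ds <- simulateTeaSpectra(d, params = quietParams(), seed = 3)
  X <- spectraMatrix(calibration(ds))
  y <- tfaa(calibration(ds))
  pb <- plantedBands(ds)
  expect_gt(length(pb), 0)
  expect_true(all(pb >= 1 & pb <= ncol(X)))
  # Beer-Lambert: -log r is exactly linear in TFAA at any planted channel
  fit <- lm(y ~ I(-log(X[, pb[1]])))
  expect_equal(1 - sum(residuals(fit)^2) / sum((y - mean(y))^2), 1,
               tolerance = 1e-10)
  # local linearity on the reflectance scale
  fitR <- lm(y ~ X[, pb])
  expect_gt(summary(fitR)$r.squared, 0.999)
})

test_that("analyte absorption at 947 nm decreases reflectance monotonically", {
  d <- smallDesign()
  ds <- simulateTeaSpectra(d, params = quietParams(stepPigmentFactor = 1),
                           seed = 9)
  cal <- calibration(ds)
  X <- spectraMatrix(cal); y <- tfaa(cal)
  i947 <- which.min(abs(wavelengths(cal) - 947))
  o <- order(y)
  expect_true(all(diff(X[o, i947]) < 0))
})

test_that("per-step TFAA means match the configured study conditions", {
  ds <- fullDataset()
  cal <- calibration(ds)
  y <- tfaa(cal); st <- processStep(cal)
  means <- c(FLS = 4.0, SF = 3.8, HD = 4.0)
  for (s in names(means)) {
    n <- sum(st == s)
    expect_lt(abs(mean(y[st == s]) - means[[s]]), 3 * 0.5 / sqrt(n))
  }
})

test_that("selector fixture plants individually necessary channels", {
  ds <- simulateSelectorFixture(seed = 2)
  X <- spectraMatrix(calibration(ds)); y <- tfaa(calibration(ds))
  pb <- plantedBands(ds)
  expect_length(pb, 5L)
  # all planted channels together give an essentially exact fit ...
  expect_gt(summary(lm(y ~ X[, pb]))$r.squared, 0.99)
  # ... but no single channel does (sub-components are semi-independent)
  single <- max(vapply(pb, function(j)
    summary(lm(y ~ X[, j]))$r.squared, numeric(1)))
  expect_lt(single, 0.6)
  expect_identical(simulateSelectorFixture(seed = 2)@plantedBands, pb)
})

test_that("simulated cubes honour the background fraction and round-trip", {
  spec <- colMeans(spectraMatrix(calibration(smallDataset())))
  wl <- wavelengths(smallDataset())
  cube <- simulateCube(spec, wl, height = 12, width = 10,
                       pixelNoiseSd = 0, seed = 4)
  expect_equal(sum(!cube$foreground), round(0.3 * 120))
  # zero pixel noise: every foreground pixel equals the input spectrum
  idx <- which(cube$foreground, arr.ind = TRUE)[1, ]
  expect_equal(as.numeric(cube$reflectance@data[idx[1], idx[2], ]), spec)
  # raw cube + frames recover the stored reflectance exactly
  rc <- calibrateReflectance(cube$raw)
  expect_equal(rc@data, cube$reflectance@data, tolerance = 1e-12)
  # degenerate: everything background
  allbg <- simulateCube(spec, wl, height = 5, width = 5,
                        backgroundFraction = 1, seed = 1)
  expect_equal(sum(allbg$foreground), 0L)
  expect_error(simulateCube(spec, wl, height = 0), "positive")
})

test_that("synthetic datasets serialise with chemistry and provenance", {
  ds <- smallDataset()
  dir <- withr::local_tempdir()
  writeSyntheticDataset(ds, dir, cubeSamples = designRoster(smallDesign())$sample_id[1],
                        height = 6, width = 6)
  chem <- read.csv(file.path(dir, "chemistry.csv"))
  expect_equal(nrow(chem), ncol(calibration(ds)))
  expect_named(chem, c("sample_id", "step", "batch", "replicate",
                       "tfaa_percent"))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  expect_equal(prov$seed, 7L)
  expect_equal(prov$planted_bands, plantedBands(ds))
  expect_true(file.exists(file.path(dir, paste0(chem$sample_id[1], ".hdr"))))
})
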