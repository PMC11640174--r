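test_that("reflectance calibration satisfies the defining identities", {
  p <- 6L
  wl <- seq(400, 1000, length.out = p)
  white <- runif(p, 0.8, 1.2); dark <- runif(p, 0, 0.1)
  mk <- function(vals) new("SpectralCube",
    data = aperm(array(vals, dim = c(p, 3, 4)), c(2, 3, 1)),
    wavelengths = wl, kind = "raw", white = white, dark = dark)
  expect_equal(unique(as.numeric(calibrateReflectance(mk(white))@data)), 1)
  expect_equal(unique(as.numeric(calibrateReflectance(mk(dark))@data)), 0)
  mid <- calibrateReflectance(mk((white + dark) / 2))@data
  expect_equal(range(mid), c(0.5, 0.5), tolerance = 1e-12)
  # affine invariance: shifting raw, white and dark by the same per-band
  # offset leaves the reflectance unchanged
  off <- runif(p, -0.3, 0.3)
  base <- mk((white + dark) / 2)
  shifted <- new("SpectralCube", data = base@data +
                   aperm(array(off, dim = c(p, 3, 4)), c(2, 3, 1)),
                 wavelengths = wl, kind = "raw",
                 white = white + off, dark = dark + off)
  expect_equal(calibrateReflectance(shifted)@data,
               calibrateReflectance(base)@data, tolerance = 1e-12)
  # degenerate denominator names the band
  bad <- mk(white); bad@white <- bad@dark
  expect_error(calibrateReflectance(bad), "white = dark at band")
})

test_that("mean-spectrum extraction averages masked pixels", {
  cube <- randomCube()
  d <- dim(cube@data)
  uni <- cube; uni@data[] <- 0.42
  ms <- extractMeanSpectrum(uni, sampleId = "u")
  expect_equal(ms@values, rep(0.42, d[3]))
  expect_equal(ms@pixelCount, d[1] * d[2])
  # two pixels: (a + b) / 2
  mask <- matrix(FALSE, d[1], d[2]); mask[1, 1] <- TRUE; mask[2, 2] <- TRUE
  ms2 <- extractMeanSpectrum(cube, mask)
  expect_equal(ms2@values, (cube@data[1, 1, ] + cube@data[2, 2, ]) / 2)
  # permutation invariance over pixels
  perm <- cube
  perm@data <- cube@data[d[1]:1, d[2]:1, , drop = FALSE]
  expect_equal(extractMeanSpectrum(perm)@values, extractMeanSpectrum(cube)@values)
  expect_error(extractMeanSpectrum(cube, matrix(FALSE, d[1], d[2])),
               "no pixels")
})

test_that("mean spectrum of a noisy cube concentrates around the truth", {
  spec <- colMeans(spectraMatrix(calibration(smallDataset())))
  wl <- wavelengths(smallDataset())
  sig <- 0.01
  cube <- simulateCube(spec, wl, height = 20, width = 20,
                       backgroundFraction = 0, pixelNoiseSd = sig, seed = 8)
  ms <- extractMeanSpectrum(cube$reflectance)
  expect_true(all(abs(ms@values - spec) < 4 * sig / sqrt(400)))
})

test_that("band trimming drops edge channels and composes", {
  ds <- fullDataset()
  cal <- calibration(ds)
  expect_equal(nrow(trimBands(cal)), 943L)          # 951 - 4 - 4
  expect_equal(nrow(trimBands(cal, 0, 0)), 951L)
  t1 <- trimBands(cal, 3, 3)
  expect_equal(wavelengths(t1), wavelengths(cal)[4:948])
  # composition: (a, b) then (c, d) == (a + c, b + d)
  expect_equal(wavelengths(trimBands(t1, 1, 1)),
               wavelengths(trimBands(cal, 4, 4)))
  expect_error(trimBands(calibrationSet(matrix(1:10, 1), 1:10, 1), 5, 5),
               "cannot trim")
  # matrix and cube methods stay aligned
  X <- spectraMatrix(cal)
  expect_equal(trimBands(X, 4, 4), spectraMatrix(trimBands(cal)))
  cube <- randomCube(p = 10)
  expect_equal(dim(trimBands(cube, 2, 3)@data)[3], 5L)
})

test_that("ENVI cubes round-trip losslessly in the pinned dialect", {
  cube <- randomCube()
  stem <- withr::local_tempfile()
  writeENVICube(cube, stem)
  r1 <- readENVICube(stem)
  # float32 storage: first read quantises, second round trip is bit-exact
  expect_equal(r1@data, cube@data, tolerance = 1e-6)
  expect_identical(r1@wavelengths, cube@wavelengths)
  stem2 <- withr::local_tempfile()
  writeENVICube(r1, stem2)
  expect_identical(readENVICube(stem2)@data, r1@data)
  expect_identical(r1@kind, "reflectance")
})

test_that("ENVI companions and validation behave", {
  spec <- runif(6, 0.2, 0.8)
  cube <- simulateCube(spec, seq(400, 1000, length.out = 6),
                       height = 3, width = 3, seed = 1)
  stem <- withr::local_tempfile()
  writeENVICube(cube$raw, stem)
  r <- readENVICube(stem)
  expect_identical(r@kind, "raw")
  expect_equal(r@white, cube$raw@white, tolerance = 1e-6)
  expect_equal(r@dark, cube$raw@dark, tolerance = 1e-6)
  # header with a wavelength list shorter than the band count errors
  hdr <- readLines(paste0(stem, ".hdr"))
  wlLine <- grep("^wavelength =", hdr)
  hdr[wlLine] <- "wavelength = {400, 500, 600, 700, 800}"
  writeLines(hdr, paste0(stem, ".hdr"))
  expect_error(readENVICube(stem), "does not match bands")
  hdr[wlLine] <- sub("wavelength = .*", "", hdr[wlLine])
  writeLines(hdr[nzchar(hdr)], paste0(stem, ".hdr"))
  expect_error(readENVICube(stem), "wavelength")
})

test_that("BIL interleave is accepted on read", {
  cube <- randomCube(h = 3, w = 4, p = 5)
  stem <- withr::local_tempfile()
  writeENVICube(cube, stem)
  # rewrite the binary as BIL (line, band, sample) and patch the header
  q <- readENVICube(stem)@data   # float32-quantised values
  con <- file(paste0(stem, ".dat"), "wb")
  for (l in 1:3) for (k in 1:5)
    writeBin(as.numeric(q[l, , k]), con, size = 4L, endian = "little")
  close(con)
  hdr <- readLines(paste0(stem, ".hdr"))
  writeLines(sub("interleave = bsq", "interleave = bil", hdr),
             paste0(stem, ".hdr"))
  expect_identical(readENVICube(stem)@data, q)
})
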