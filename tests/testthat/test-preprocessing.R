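specMat <- function(n = 8, p = 60, seed = 4) {
  withr::with_seed(seed, {
    wl <- seq_len(p)
    base <- 0.5 + 0.2 * sin(wl / 7)
    t(vapply(seq_len(n), function(i)
      base * runif(1, 0.8, 1.2) + runif(1, -0.05, 0.05) +
        rnorm(p, 0, 0.005), numeric(p)))
  })
}

test_that("MSC removes per-row affine scatter against the reference", {
  X <- specMat()
  pm <- fitMSC(X)
  ref <- pm$reference
  # a row equal to the reference is returned unchanged
  expect_equal(as.numeric(applyMSC(rbind(ref), pm)), ref, tolerance = 1e-12)
  # exact affine rows collapse onto the reference
  expect_equal(as.numeric(applyMSC(rbind(2 * ref + 3), pm)), ref,
               tolerance = 1e-10)
  # after correction, per-row OLS against the reference is (1, 0)
  Xc <- applyMSC(X, pm)
  for (i in seq_len(nrow(Xc))) {
    f <- lm(Xc[i, ] ~ ref)
    expect_equal(unname(coef(f)), c(0, 1), tolerance = 1e-10)
  }
  # idempotent under the same fitted reference
  expect_equal(applyMSC(Xc, pm), Xc, tolerance = 1e-10)
  expect_error(applyMSC(rbind(rep(1, ncol(X))), pm), "constant spectrum")
  expect_error(fitMSC(X[1, , drop = FALSE]), ">= 2 calibration rows")
})

test_that("mean centring learns from calibration rows only", {
  X <- specMat()
  pm <- fitCenter(X)
  expect_equal(unname(colMeans(applyCenter(X, pm))), rep(0, ncol(X)))
  expect_equal(as.numeric(applyCenter(rbind(pm$means), pm)), rep(0, ncol(X)))
  # single calibration row maps itself to zero
  p1 <- fitCenter(X[1, , drop = FALSE])
  expect_equal(as.numeric(applyCenter(X[1, , drop = FALSE], p1)),
               rep(0, ncol(X)))
  expect_error(applyCenter(X[, 1:5], pm), "mismatch")
})

test_that("SG smoothing reproduces polynomials and the windowed-OLS oracle", {
  p <- 60; wl <- seq_len(p)
  poly <- rbind(5 * wl^2 - 3 * wl + 1)
  expect_equal(sgSmooth(poly, 11, 2), poly, tolerance = 1e-8)
  # polyorder = window - 1 is the identity
  x <- specMat(n = 1)
  expect_equal(sgSmooth(x, 5, 4), x, tolerance = 1e-8)
  # brute-force per-window least-squares refit at interior channels
  w <- 11L; half <- 5L
  sm <- sgSmooth(x, w, 2)
  for (j in seq(half + 1L, p - half, by = 7L)) {
    win <- (j - half):(j + half)
    fit <- lm(x[1, win] ~ poly(win, 2, raw = TRUE))
    expect_equal(sm[1, j], unname(predict(fit))[half + 1L], tolerance = 1e-8)
  }
  # commutes with adding a constant
  expect_equal(sgSmooth(x + 3, 11, 2), sgSmooth(x, 11, 2) + 3,
               tolerance = 1e-10)
  expect_error(sgSmooth(x, 10, 2), "odd")
  expect_error(sgSmooth(x, 11, 11), "exceed")
  expect_error(sgSmooth(x, 61, 2), "exceeds the number of channels")
})

test_that("SG derivative returns analytic derivatives in units per nm", {
  h <- 0.63
  wl <- seq(400, by = h, length.out = 80)
  lin <- rbind(3 * wl + 2)
  d <- sgDerivative(lin, 7, 2, spacing = h)
  expect_equal(d[1, 4:77], rep(3, 74), tolerance = 1e-8)
  # constants are annihilated
  expect_equal(sgDerivative(rbind(rep(5, 80)), 7, 2, spacing = h),
               rbind(rep(0, 80)), tolerance = 1e-10)
  # quadratic a*x^2 -> 2 a x at interior channels
  quad <- rbind(0.01 * wl^2)
  dq <- sgDerivative(quad, 7, 2, spacing = h)
  expect_equal(dq[1, 4:77], 0.02 * wl[4:77], tolerance = 1e-8)
})

test_that("pretreatment chains fit on calibration rows and apply anywhere", {
  X <- specMat(n = 10)
  train <- X[1:6, ]; test <- X[7:10, ]
  ct <- fitPretreatment(pretreatment("CT"), train)
  expect_equal(unname(colMeans(applyPretreatment(ct, train))),
               rep(0, ncol(X)))
  # test rows use the TRAIN means: their column means are not zero
  expect_gt(max(abs(colMeans(applyPretreatment(ct, test)))), 1e-6)
  expect_equal(applyPretreatment(ct, test),
               sweep(test, 2, colMeans(train)), tolerance = 1e-12)
  # no leakage: applying to new data never mutates fitted parameters
  before <- ct@params
  invisible(applyPretreatment(ct, test))
  expect_identical(ct@params, before)
  # shape preservation
  d1 <- fitPretreatment(pretreatment("D1"), train)
  expect_equal(dim(applyPretreatment(d1, test)), dim(test))
  # chain [SG, CT] equals SG then CT fitted on SG-transformed rows
  ch <- fitPretreatment(pretreatment(c("SG", "CT")), train)
  sgTrain <- sgSmooth(train, 11, 2)
  manual <- sweep(sgSmooth(test, 11, 2), 2, colMeans(sgTrain))
  expect_equal(applyPretreatment(ch, test), manual, tolerance = 1e-10)
  expect_error(applyPretreatment(pretreatment("CT"), test), "fitted")
  expect_error(pretreatment("SNV"))
})
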