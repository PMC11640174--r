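test_that("the exponential schedule honours its boundary conditions", {
  r <- edfSchedule(65, 943)
  expect_equal(r[1], 1, tolerance = 1e-12)
  expect_equal(r[65], 2 / 943, tolerance = 1e-12)
  expect_true(all(diff(r) < 0))
  r2 <- edfSchedule(50, 100)
  expect_equal(c(r2[1], r2[50]), c(1, 0.02), tolerance = 1e-12)
  expect_error(edfSchedule(1, 100), ">= 2")
})

test_that("selection summaries report count and percentage", {
  mk <- function(n, p) new("SelectionResult", method = "CARS",
                           bands = seq_len(n), trace = 1, bestIteration = 1L,
                           settings = list(p = p), seed = 1L)
  expect_equal(selectionSummary(mk(67, 943))$percent, 7.1)
  expect_equal(selectionSummary(mk(41, 943))$percent, 4.3)
  expect_equal(selectionSummary(mk(943, 943))$percent, 100.0)
  expect_equal(selectionSummary(mk(32, 943))$percent, 3.4)
})

test_that("CARS is seed-deterministic with a monotone retention schedule", {
  ds <- simulateSelectorFixture(seed = 21)
  X <- spectraMatrix(calibration(ds)); y <- tfaa(calibration(ds))
  s1 <- carsSelect(X, y, N = 30, folds = 5, seed = 4)
  s2 <- carsSelect(X, y, N = 30, folds = 5, seed = 4)
  expect_identical(s1@bands, s2@bands)
  expect_identical(s1@trace, s2@trace)
  cnt <- s1@settings$countPerIter
  expect_true(all(diff(cnt) <= 0))
  expect_gte(min(cnt), 2L)
  # min of the trace beats the full-channel model on the same folds (the
  # first iteration evaluates exactly that baseline)
  folds <- cvFolds(nrow(X), 5, seed = 4)
  full <- min(tenchaHSI:::plsrRMSECV(X, y, seq_len(s1@settings$nlv0), folds))
  expect_lte(min(s1@trace), full * (1 + 1e-9))
  expect_equal(s1@trace[1], full, tolerance = 1e-12)
  expect_true(all(s1@bands %in% seq_len(ncol(X))))
})

test_that("CARS recovers planted channels from semi-independent signal", {
  stats <- sapply(1:5, function(s) {
    ds <- simulateSelectorFixture(seed = 200 + s)
    X <- spectraMatrix(calibration(ds)); y <- tfaa(calibration(ds))
    pb <- plantedBands(ds)
    sel <- carsSelect(X, y, N = 50, folds = 5, seed = s)
    hits <- length(intersect(selectedBands(sel), pb))
    c(recall = hits / length(pb), precision = hits / length(selectedBands(sel)))
  })
  expect_gte(mean(stats["recall", ]), 0.8)
  expect_gte(mean(stats["precision", ]), 0.5)
})

test_that("the strict argmin rule is available and reports its iteration", {
  ds <- simulateSelectorFixture(seed = 31)
  X <- spectraMatrix(calibration(ds)); y <- tfaa(calibration(ds))
  s <- carsSelect(X, y, N = 20, folds = 5, seed = 2, rule = "min")
  expect_equal(s@bestIteration, which.min(s@trace))
  sse <- carsSelect(X, y, N = 20, folds = 5, seed = 2, rule = "oneSE")
  expect_gte(sse@bestIteration, s@settings$argminIteration)
})

test_that("VISSA weights stay in [0, 1] and converge on planted channels", {
  stats <- sapply(1:5, function(s) {
    ds <- simulateSelectorFixture(seed = 300 + s)
    X <- spectraMatrix(calibration(ds)); y <- tfaa(calibration(ds))
    pb <- plantedBands(ds)
    sel <- vissaSelect(X, y, nSubmodels = 200, folds = 5, seed = s,
                       maxIters = 15)
    w <- sel@settings$weights
    expect_true(all(w >= 0 & w <= 1))
    # the reported iteration is the trajectory minimum
    expect_equal(sel@bestIteration, which.min(sel@trace))
    c(minPlanted = min(w[pb]), meanOther = mean(w[-pb]))
  })
  # every planted channel reaches weight 1; junk stays clearly separated
  expect_true(all(stats["minPlanted", ] >= 0.999))
  expect_true(all(stats["meanOther", ] < stats["minPlanted", ] - 0.3))
})

test_that("VISSA is seed-deterministic", {
  ds <- simulateSelectorFixture(nSamples = 50, seed = 41)
  X <- spectraMatrix(calibration(ds)); y <- tfaa(calibration(ds))
  a <- vissaSelect(X, y, nSubmodels = 100, folds = 5, seed = 3, maxIters = 5)
  b <- vissaSelect(X, y, nSubmodels = 100, folds = 5, seed = 3, maxIters = 5)
  expect_identical(a@bands, b@bands)
  expect_identical(a@settings$weights, b@settings$weights)
})

test_that("selected channels do not degrade prediction materially", {
  ds <- simulateSelectorFixture(nSamples = 100, seed = 51)
  X <- spectraMatrix(calibration(ds)); y <- tfaa(calibration(ds))
  tr <- 1:75; te <- 76:100
  sel <- carsSelect(X[tr, ], y[tr], N = 50, folds = 5, seed = 6)
  mSel <- fitPLSR(X[tr, selectedBands(sel)], y[tr],
                  selectNLVs(X[tr, selectedBands(sel)], y[tr], k = 5)$nlv)
  mFull <- fitPLSR(X[tr, ], y[tr], selectNLVs(X[tr, ], y[tr], k = 5)$nlv)
  rmsepSel <- rmse(y[te], predict(mSel, X[te, selectedBands(sel)]))
  rmsepFull <- rmse(y[te], predict(mFull, X[te, ]))
  expect_lte(rmsepSel, rmsepFull * 1.2)
})
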