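test_that("PLSR recovers exact linear relationships", {
  withr::with_seed(1, {
    X <- matrix(rnorm(20 * 5), 20)
    b <- rnorm(5)
  })
  y <- as.numeric(X %*% b) + 2
  m <- fitPLSR(X, y, nlv = 5)
  expect_equal(predict(m, X), y, tolerance = 1e-8)
  # at full rank the regression vector equals the OLS solution
  ols <- unname(coef(lm(y ~ X))[-1])
  expect_equal(m@coefficients, ols, tolerance = 1e-8)
  # centring correctness: constant shifts of y shift predictions equally
  m2 <- fitPLSR(X, y + 10, nlv = 5)
  expect_equal(predict(m2, X), predict(m, X) + 10, tolerance = 1e-8)
  expect_warning(fitPLSR(X[1:4, ], y[1:4], nlv = 5), "truncated")
})

test_that("SIMPLS agrees with an independent PLS implementation", {
  withr::with_seed(3, {
    X <- matrix(rnorm(40 * 8), 40)
    y <- as.numeric(X %*% rnorm(8) + rnorm(40, 0, 0.3))
  })
  colnames(X) <- paste0("b", 1:8)
  m <- fitPLSR(X, y, nlv = 4)
  mo <- mixOmics::pls(X, y, ncomp = 4, scale = FALSE, mode = "regression")
  expect_equal(predict(m, X),
               unname(predict(mo, X)$predict[, , 4]), tolerance = 1e-10)
})

test_that("a single latent variable tracks the informative column", {
  withr::with_seed(2, {
    t <- rnorm(40)
    X <- cbind(t, matrix(rnorm(40 * 6, 0, 1), 40))
  })
  y <- 2 * t
  m <- fitPLSR(X, y, nlv = 1)
  expect_equal(which.max(abs(m@coefficients)), 1L)
})

test_that("latent-variable selection is seeded and rank-aware", {
  withr::with_seed(4, {
    S <- matrix(rnorm(30 * 3), 30)
    X <- S %*% matrix(rnorm(3 * 12), 3)
    beta <- rnorm(12)
  })
  y <- as.numeric(X %*% beta)
  sel <- selectNLVs(X, y, maxNlv = 8, k = 10, seed = 5)
  expect_lte(sel$nlv, 3L)                 # rank-3 construction
  expect_lt(min(sel$cvTable$rmsecv), 1e-6)
  # same seed, same folds, same choice
  expect_identical(selectNLVs(X, y, maxNlv = 8, k = 10, seed = 5), sel)
  expect_identical(cvFolds(30, 10, seed = 5), cvFolds(30, 10, seed = 5))
  # leave-one-out boundary: every fold has size 1
  expect_equal(sort(unique(table(cvFolds(12, 12, seed = 1)))), 1L)
  expect_error(cvFolds(5, 1), ">= 2")
})

test_that("LS-SVR solves its KKT system and approaches known limits", {
  withr::with_seed(6, {
    X <- matrix(rnorm(20 * 3), 20)
    y <- rnorm(20)
  })
  m <- fitLSSVR(X, y, gamma = 1, C = 10)
  expect_lt(lssvrKKTResidual(m, y), 1e-8)
  # interpolation limit: C -> Inf drives training residuals to zero
  mi <- fitLSSVR(X, y, gamma = 1, C = 1e8)
  expect_lt(max(abs(predict(mi, X) - y)), 1e-5)
  # linear kernel with large C matches OLS predictions
  ml <- fitLSSVR(X, y, C = 1e8, kernel = "linear")
  expect_equal(predict(ml, X), unname(fitted(lm(y ~ X))), tolerance = 1e-6)
  # gamma -> 0 flattens the kernel: predictions approach mean(y)
  mg <- fitLSSVR(X, y, gamma = 1e-12, C = 10)
  expect_lt(max(abs(predict(mg, X) - mean(y))), 1e-3)
  expect_error(fitLSSVR(X, y, gamma = -1, C = 1), "gamma")
  expect_error(fitLSSVR(X, y, gamma = 1, C = 0), "C must be")
})

test_that("LS-SVR grid search is exhaustive with deterministic tie-breaks", {
  withr::with_seed(7, {
    X <- matrix(rnorm(30 * 3), 30)
    y <- sin(X[, 1]) + 0.1 * rnorm(30)
  })
  gg <- 2^c(-4, -2, 0); cc <- 2^c(0, 2)
  gs <- gridSearchLSSVR(X, y, gammaGrid = gg, cGrid = cc, k = 5, seed = 2)
  expect_equal(nrow(gs$cvSurface), 6L)
  # the reported pair re-evaluates to the surface minimum
  folds <- cvFolds(30, 5, seed = 2)
  re <- sapply(seq_len(nrow(gs$cvSurface)), function(i) {
    press <- 0
    for (f in 1:5) {
      tr <- folds != f
      mm <- fitLSSVR(X[tr, ], y[tr], gamma = gs$cvSurface$gamma[i],
                     C = gs$cvSurface$C[i])
      press <- press + sum((y[!tr] - predict(mm, X[!tr, , drop = FALSE]))^2)
    }
    sqrt(press / 30)
  })
  expect_equal(gs$cvSurface$rmsecv, re, tolerance = 1e-10)
  best <- gs$cvSurface[gs$cvSurface$rmsecv == min(gs$cvSurface$rmsecv), ]
  expect_equal(gs$C, min(best$C))
  # grid of size one returns that pair
  g1 <- gridSearchLSSVR(X, y, gammaGrid = 0.5, cGrid = 4, k = 5, seed = 2)
  expect_equal(c(g1$gamma, g1$C), c(0.5, 4))
})
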