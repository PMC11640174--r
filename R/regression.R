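## Calibration models: PLSR (SIMPLS) with k-fold CV selection of the number
## of latent variables, and LS-SVR (RBF kernel) with grid-searched
## hyperparameters. Both centre X (and PLSR centres y) on the training rows.

#' Cross-validation fold assignment
#'
#' Contiguous fold assignment after a seeded shuffle: rows are permuted once
#' with the given seed and the permuted order is cut into \code{k} nearly
#' equal contiguous blocks. Sharing one assignment across model comparisons
#' makes differences reflect methods, not folds.
#'
#' @param n number of rows.
#' @param k number of folds (2..n; \code{k = n} is leave-one-out).
#' @param seed integer seed.
#' @return integer vector of fold labels in 1..k, one per row.
#' @export
cvFolds <- function(n, k, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("need n >= k")
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  folds <- integer(n)
  folds[perm] <- rep(seq_len(k), times = sizes)
  folds
}

## SIMPLS for a univariate response on centred data; returns the regression
## vector for each number of components 1..ncomp (p x ncomp matrix).
simplsCoef <- function(Xc, yc, ncomp) {
  n <- nrow(Xc); p <- ncol(Xc)
  ncomp <- min(ncomp, n - 1L, p)
  S <- crossprod(Xc, yc)
  R <- matrix(0, p, ncomp); Q <- numeric(ncomp); V <- matrix(0, p, ncomp)
  B <- matrix(0, p, ncomp)
  a <- 0L
  while (a < ncomp) {
    r <- S
    t <- Xc %*% r
    normt <- sqrt(sum(t^2))
    if (normt < 1e-12) break  # residual X-y covariance exhausted (rank)
    a <- a + 1L
    t <- t / normt; r <- r / normt
    pl <- crossprod(Xc, t)
    Q[a] <- sum(yc * t)
    v <- pl
    if (a > 1L)
      v <- v - V[, 1:(a - 1L), drop = FALSE] %*%
        crossprod(V[, 1:(a - 1L), drop = FALSE], pl)
    v <- v / sqrt(sum(v^2))
    V[, a] <- v
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r
    B[, a] <- R[, 1:a, drop = FALSE] %*% Q[1:a]
  }
  if (a == 0L) stop("X has no covariance with y after centring")
  B[, 1:a, drop = FALSE]
}

#' Fit a PLSR model
#'
#' SIMPLS fit of a univariate partial least squares regression: X and y are
#' centred on the training rows and latent variables are extracted by
#' successive deflation of the X-y cross-covariance. Deterministic; if
#' \code{nlv} exceeds the effective rank it is truncated with a warning.
#'
#' @param X training samples x channels matrix.
#' @param y numeric response.
#' @param nlv number of latent variables (1..min(n-1, p)).
#' @param cvTable optional data.frame (nlv, rmsecv) recorded by
#'   \code{\link{selectNLVs}}.
#' @return a \linkS4class{PLSRModel}.
#' @examples
#' X <- matrix(rnorm(100), 20); b <- rnorm(5)
#' m <- fitPLSR(X, X %*% b, nlv = 5)
#' max(abs(predict(m, X) - X %*% b)) < 1e-8
#' @export
fitPLSR <- function(X, y, nlv, cvTable = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  nlv <- as.integer(nlv)
  if (nlv < 1L) stop("nlv must be >= 1")
  cap <- min(n - 1L, p)
  if (nlv > cap) {
    warning(sprintf("nlv truncated from %d to %d", nlv, cap))
    nlv <- cap
  }
  xm <- colMeans(X); ym <- mean(y)
  B <- simplsCoef(sweep(X, 2, xm), y - ym, nlv)
  if (ncol(B) < nlv)
    warning(sprintf("nlv truncated to rank %d", ncol(B)))
  new("PLSRModel", nlv = ncol(B), xMeans = xm, yMean = ym,
      coefficients = as.numeric(B[, ncol(B)]),
      cvTable = cvTable %||% data.frame())
}

#' @describeIn fitPLSR predict from a fitted PLSR model.
#' @param object a \linkS4class{PLSRModel}.
#' @param newdata samples x channels matrix.
#' @param ... ignored.
#' @export
setMethod("predict", "PLSRModel", function(object, newdata, ...) {
  newdata <- rbind(as.matrix(newdata))
  if (ncol(newdata) != length(object@xMeans)) stop("channel count mismatch")
  as.numeric(sweep(newdata, 2, object@xMeans) %*% object@coefficients +
               object@yMean)
})

## k-fold RMSECV of PLSR for each candidate nlv (vector result), given a
## fixed fold assignment. Used by selectNLVs and both selectors.
## plsrRMSECVse additionally returns the fold-to-fold standard error of each
## RMSECV estimate (delta method on the per-fold MSEs).
plsrRMSECV <- function(X, y, nlvs, folds) {
  plsrRMSECVse(X, y, nlvs, folds)$rmsecv
}

plsrRMSECVse <- function(X, y, nlvs, folds) {
  X <- as.matrix(X)
  lev <- sort(unique(folds))
  k <- length(lev)
  foldMSE <- matrix(0, k, length(nlvs))
  foldN <- integer(k)
  maxlv <- max(nlvs)
  for (fi in seq_len(k)) {
    tr <- folds != lev[fi]
    Xtr <- X[tr, , drop = FALSE]
    xm <- colMeans(Xtr); ym <- mean(y[tr])
    cap <- min(sum(tr) - 1L, ncol(X))
    B <- simplsCoef(sweep(Xtr, 2, xm), y[tr] - ym, min(maxlv, cap))
    Xte <- sweep(X[!tr, , drop = FALSE], 2, xm)
    foldN[fi] <- sum(!tr)
    for (j in seq_along(nlvs)) {
      a <- min(nlvs[j], ncol(B))
      pred <- Xte %*% B[, a] + ym
      foldMSE[fi, j] <- mean((y[!tr] - pred)^2)
    }
  }
  mse <- colSums(foldMSE * foldN) / sum(foldN)
  seMSE <- apply(foldMSE, 2, sd) / sqrt(k)
  rmsecv <- sqrt(mse)
  list(rmsecv = rmsecv, se = seMSE / (2 * pmax(rmsecv, 1e-12)))
}

#' Select the number of latent variables by k-fold CV
#'
#' Evaluates RMSECV for 1..\code{maxNlv} latent variables under a seeded
#' contiguous-fold assignment (see \code{\link{cvFolds}}) and returns the
#' argmin, taking the smallest nlv on ties.
#'
#' @param X samples x channels matrix.
#' @param y numeric response.
#' @param maxNlv largest candidate (capped at min(n - ceiling(n/k) - 1, p)).
#' @param k folds (default 10).
#' @param seed fold-assignment seed.
#' @param folds optional explicit fold assignment overriding \code{k}/
#'   \code{seed}.
#' @return list with \code{nlv} and the \code{cvTable} data.frame.
#' @export
selectNLVs <- function(X, y, maxNlv = 10L, k = 10L, seed = 1L, folds = NULL) {
  X <- as.matrix(X)
  if (maxNlv < 1L) stop("maxNlv must be >= 1")
  if (is.null(folds)) folds <- cvFolds(nrow(X), k, seed)
  largestTrain <- nrow(X) - max(table(folds))
  cap <- max(1L, min(as.integer(maxNlv), largestTrain - 1L, ncol(X)))
  nlvs <- seq_len(cap)
  rmsecv <- plsrRMSECV(X, y, nlvs, folds)
  list(nlv = nlvs[which.min(rmsecv)],
       cvTable = data.frame(nlv = nlvs, rmsecv = rmsecv))
}

## ------------------------------------------------------------------- LS-SVR

rbfKernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Fit an LS-SVR model
#'
#' Least squares support vector regression: solves the single linear KKT
#' system \code{[[0, 1'], [1, K + I/C]] [b; alpha] = [0; y]} with
#' \code{K_ij = exp(-gamma ||x_i - x_j||^2)} (RBF). X is centred on the
#' training rows. A \code{"linear"} kernel (\code{K = X X'}) is provided as
#' an oracle mode: with large C it reproduces ordinary least squares. A
#' singular system receives a 1e-12 ridge jitter with a warning.
#'
#' @param X training samples x channels matrix.
#' @param y numeric response.
#' @param gamma RBF width (> 0; ignored for the linear kernel).
#' @param C regularisation (> 0).
#' @param kernel \code{"rbf"} (default) or \code{"linear"}.
#' @return an \linkS4class{LSSVRModel}.
#' @export
fitLSSVR <- function(X, y, gamma = 1, C = 10, kernel = c("rbf", "linear")) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  n <- nrow(X)
  if (C <= 0) stop("C must be > 0")
  if (kernel == "rbf" && gamma <= 0) stop("gamma must be > 0")
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  K <- if (kernel == "rbf") rbfKernel(Xc, Xc, gamma) else tcrossprod(Xc)
  M <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / C))
  rhs <- c(0, y)
  sol <- tryCatch(solve(M, rhs), error = function(e) {
    warning("singular KKT system: adding 1e-12 ridge jitter")
    solve(M + diag(n + 1L) * 1e-12, rhs)
  })
  new("LSSVRModel", gamma = if (kernel == "rbf") gamma else 0,
      cost = C, alpha = sol[-1], b = sol[1], X = Xc, xMeans = xm,
      kernel = kernel)
}

#' @describeIn fitLSSVR predict from a fitted LS-SVR model.
#' @param object an \linkS4class{LSSVRModel}.
#' @param newdata samples x channels matrix.
#' @param ... ignored.
#' @export
setMethod("predict", "LSSVRModel", function(object, newdata, ...) {
  newdata <- rbind(as.matrix(newdata))
  if (ncol(newdata) != length(object@xMeans)) stop("channel count mismatch")
  Xc <- sweep(newdata, 2, object@xMeans)
  K <- if (object@kernel == "rbf") rbfKernel(Xc, object@X, object@gamma)
       else tcrossprod(Xc, object@X)
  as.numeric(K %*% object@alpha + object@b)
})

#' KKT residual of a fitted LS-SVR model
#'
#' Maximum absolute residual of the solved linear system; a correct solve is
#' at machine-precision level.
#'
#' @param model an \linkS4class{LSSVRModel}.
#' @param y the training response used in the fit.
#' @return numeric scalar.
#' @export
lssvrKKTResidual <- function(model, y) {
  n <- length(model@alpha)
  K <- if (model@kernel == "rbf") rbfKernel(model@X, model@X, model@gamma)
       else tcrossprod(model@X)
  r1 <- sum(model@alpha)
  r2 <- model@b + (K + diag(n) / model@cost) %*% model@alpha - y
  max(abs(c(r1, r2)))
}

#' Grid search for LS-SVR hyperparameters
#'
#' Exhaustive k-fold RMSECV over a (gamma, C) grid; ties are broken by
#' smaller C, then smaller gamma. The default grids follow the customary
#' powers-of-two search ranges (gamma 2^-15..2^3, C 2^-5..2^15, step 2^2).
#'
#' @param X samples x channels matrix.
#' @param y numeric response.
#' @param gammaGrid,cGrid numeric candidate vectors.
#' @param k folds (default 10).
#' @param seed fold-assignment seed.
#' @param folds optional explicit fold assignment.
#' @return list with \code{gamma}, \code{C}, and the full \code{cvSurface}
#'   data.frame (one row per grid pair).
#' @export
gridSearchLSSVR <- function(X, y, gammaGrid = 2^seq(-15, 3, by = 2),
                            cGrid = 2^seq(-5, 15, by = 2), k = 10L,
                            seed = 1L, folds = NULL) {
  X <- as.matrix(X)
  if (!length(gammaGrid) || !length(cGrid)) stop("grids must be non-empty")
  if (is.null(folds)) folds <- cvFolds(nrow(X), k, seed)
  grid <- expand.grid(gamma = sort(gammaGrid), C = sort(cGrid))
  grid <- grid[order(grid$C, grid$gamma), ]  # tie-break order: C then gamma
  rmsecv <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    press <- 0
    for (f in sort(unique(folds))) {
      tr <- folds != f
      m <- fitLSSVR(X[tr, , drop = FALSE], y[tr], gamma = grid$gamma[i],
                    C = grid$C[i])
      pred <- predict(m, X[!tr, , drop = FALSE])
      press <- press + sum((y[!tr] - pred)^2)
    }
    rmsecv[i] <- sqrt(press / length(y))
  }
  best <- which.min(rmsecv)  # first minimum in (C, gamma) order
  list(gamma = grid$gamma[best], C = grid$C[best],
       cvSurface = data.frame(gamma = grid$gamma, C = grid$C,
                              rmsecv = rmsecv))
}
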