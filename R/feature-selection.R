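## Wavelength selection: CARS (Monte-Carlo PLS-coefficient reweighted band
## elimination under an exponentially decreasing retention schedule) and
## VISSA (weighted binary matrix sampling with iterative space shrinkage).
## Both are seed-deterministic end to end and report RMSECV trajectories.

#' Exponentially decreasing retention schedule
#'
#' Per-iteration retention ratios \eqn{r_i = a e^{-k i}} with \eqn{a, k}
#' fixed by the boundary conditions \eqn{r_1 = 1} and \eqn{r_N = 2/p}: the
#' first iteration keeps every channel, the last keeps only two.
#'
#' @param N total iterations (>= 2).
#' @param p total channel count (>= 2).
#' @return numeric vector of length N, strictly decreasing from 1 to 2/p.
#' @export
edfSchedule <- function(N, p) {
  if (N < 2L || p < 2L) stop("need N >= 2 and p >= 2")
  k <- log(p / 2) / (N - 1)
  a <- exp(k)
  a * exp(-k * seq_len(N))
}

#' CARS wavelength selection
#'
#' Competitive adaptive reweighted sampling. Per iteration \eqn{i}: a
#' Monte-Carlo subset of the rows (default 80\%) is drawn; a PLSR is fitted
#' on the currently retained channels and its absolute regression
#' coefficients become the channel weights; an enforced exponentially
#' decreasing schedule (\code{\link{edfSchedule}}) keeps the top
#' \eqn{\lceil r_i p\rceil} channels; adaptive reweighted sampling (a
#' weighted draw with replacement, a channel surviving if drawn at least
#' once) further thins them; and the k-fold RMSECV of a PLSR on the retained
#' set is recorded. The channels of the minimum-RMSECV iteration (first on
#' ties) are returned. The retained count never increases and never falls
#' below 2.
#'
#' @param X samples x channels matrix.
#' @param y numeric response.
#' @param N Monte-Carlo iterations (default 65).
#' @param folds cross-validation folds for the RMSECV trace (default 5).
#' @param seed integer seed (drives subset draws, ARS draws and CV folds).
#' @param mcFraction Monte-Carlo row fraction (default 0.8).
#' @param maxNlv PLSR latent-variable cap inside the selector (default 10);
#'   the working component count is chosen once by CV under this cap.
#' @param rule iteration choice: \code{"oneSE"} (default) returns the
#'   sparsest (latest) iteration whose RMSECV lies within one fold-to-fold
#'   standard error of the minimum — the customary parsimony rule when the
#'   trace is flat within CV noise; \code{"min"} returns the strict first
#'   argmin.
#' @return a \linkS4class{SelectionResult}.
#' @export
carsSelect <- function(X, y, N = 65L, folds = 5L, seed = 1L,
                       mcFraction = 0.8, maxNlv = 10L,
                       rule = c("oneSE", "min")) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  N <- as.integer(N)
  if (N < 2L) stop("N must be >= 2")
  if (p < 2L) stop("need at least 2 channels")
  if (n <= folds || folds < 2L) stop("need n > folds >= 2")
  ratios <- edfSchedule(N, p)
  cvAssign <- cvFolds(n, folds, seed = seed)
  nsub <- max(2L, round(mcFraction * n))
  # component count fixed once by CV on the full channel set (capped), so
  # surplus latent variables do not inject noise into the coefficient weights
  nlv0 <- selectNLVs(X, y, maxNlv = maxNlv, folds = cvAssign)$nlv

  withr::with_seed(as.integer(seed), {
    retained <- seq_len(p)
    trace <- numeric(N)
    seTrace <- numeric(N)
    bandsPerIter <- vector("list", N)
    countPerIter <- integer(N)
    for (i in seq_len(N)) {
      rows <- sort(sample.int(n, nsub))
      nlv <- max(1L, min(nlv0, length(retained), nsub - 1L))
      fit <- suppressWarnings(  # collinear subsets routinely truncate rank
        fitPLSR(X[rows, retained, drop = FALSE], y[rows], nlv = nlv))
      w <- abs(fit@coefficients)
      keep <- min(ceiling(ratios[i] * p), length(retained))
      keep <- max(keep, 2L)
      top <- order(w, decreasing = TRUE)[seq_len(keep)]  # stable: index order on ties
      retained <- retained[sort(top)]
      w <- w[sort(top)]
      # adaptive reweighted sampling among the survivors: p draws with
      # replacement, so only negligible-weight channels fail to be drawn and
      # the exponential schedule governs the retention trajectory; the first
      # iteration (retention ratio 1) evaluates the full-channel baseline
      if (ratios[i] < 1 && length(retained) > 2L && sum(w) > 0) {
        drawn <- unique(sample(seq_along(retained), size = p,
                               replace = TRUE, prob = w))
        if (length(drawn) >= 2L) retained <- retained[sort(drawn)]
      }
      bandsPerIter[[i]] <- retained
      countPerIter[i] <- length(retained)
      nlvCV <- max(1L, min(nlv0, length(retained)))
      cv <- plsrRMSECVse(X[, retained, drop = FALSE], y,
                         seq_len(nlvCV), cvAssign)
      j <- which.min(cv$rmsecv)
      trace[i] <- cv$rmsecv[j]
      seTrace[i] <- cv$se[j]
    }
    argmin <- which.min(trace)
    best <- if (rule == "oneSE") {
      # parsimony under CV noise: the latest (sparsest) iteration whose
      # RMSECV is statistically indistinguishable from the minimum
      max(which(trace <= trace[argmin] + seTrace[argmin]))
    } else argmin
    new("SelectionResult", method = "CARS",
        bands = as.integer(bandsPerIter[[best]]), trace = trace,
        bestIteration = as.integer(best),
        settings = list(p = p, N = N, folds = as.integer(folds),
                        mcFraction = mcFraction, maxNlv = as.integer(maxNlv),
                        nlv0 = nlv0, rule = rule, argminIteration = argmin,
                        seTrace = seTrace, countPerIter = countPerIter),
        seed = as.integer(seed))
  })
}

#' VISSA wavelength selection
#'
#' Variable iterative space shrinkage approach. Per-channel inclusion
#' weights start at 0.5. Each iteration draws \code{nSubmodels} binary
#' inclusion vectors by weighted binary matrix sampling — column \eqn{j}
#' contains exactly \code{round(w_j nSubmodels)} ones, independently
#' row-shuffled — fits a PLSR with k-fold RMSECV per sub-model, and updates
#' each weight to the inclusion frequency of its channel among the best
#' \code{topFraction} sub-models (ties broken by sub-model index), shrinking
#' the variable space. The best-sub-model RMSECV is recorded per iteration;
#' the trajectory typically falls to a minimum and rises again once relevant
#' channels start being discarded, so iteration stops when the running
#' minimum has not improved for \code{patience} iterations (or when every
#' weight has converged to 0 or 1). The channel combination of the
#' minimum-RMSECV iteration is returned: the channels whose weights reached
#' 1 (>= 0.999) at that iteration, falling back to weight > 0.5 with a
#' warning if none converged.
#'
#' @param X samples x channels matrix.
#' @param y numeric response.
#' @param nSubmodels sub-models per iteration (>= 100; default 1000).
#' @param topFraction fraction of best sub-models used for the weight update
#'   (default 0.05).
#' @param folds cross-validation folds (default 5).
#' @param maxIters iteration cap (default 50).
#' @param seed integer seed.
#' @param maxNlv PLSR latent-variable cap inside the selector.
#' @param patience iterations without a new running minimum tolerated before
#'   stopping.
#' @return a \linkS4class{SelectionResult}; \code{settings$weights} holds the
#'   inclusion weights at the returned (minimum-RMSECV) iteration.
#' @export
vissaSelect <- function(X, y, nSubmodels = 1000L, topFraction = 0.05,
                        folds = 5L, maxIters = 50L, seed = 1L, maxNlv = 10L,
                        patience = 5L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  nSubmodels <- as.integer(nSubmodels)
  if (nSubmodels < 100L) stop("nSubmodels must be >= 100")
  if (topFraction <= 0 || topFraction >= 1) stop("topFraction must lie in (0, 1)")
  cvAssign <- cvFolds(n, folds, seed = seed)
  ntop <- max(1L, ceiling(topFraction * nSubmodels))

  withr::with_seed(as.integer(seed), {
    w <- rep(0.5, p)
    trace <- numeric(0)
    wPerIter <- list()
    sinceMin <- 0L
    for (iter in seq_len(maxIters)) {
      B <- matrix(0L, nSubmodels, p)
      for (j in seq_len(p)) {
        ones <- round(w[j] * nSubmodels)
        if (ones > 0) B[sample.int(nSubmodels, ones), j] <- 1L
      }
      rmse <- rep(Inf, nSubmodels)
      for (s in seq_len(nSubmodels)) {
        cols <- which(B[s, ] == 1L)
        if (length(cols) < 1L) next
        nlv <- max(1L, min(maxNlv, length(cols)))
        rmse[s] <- min(plsrRMSECV(X[, cols, drop = FALSE], y,
                                  seq_len(nlv), cvAssign))
      }
      ord <- order(rmse)                       # stable: ties by sub-model index
      trace <- c(trace, rmse[ord[1]])
      w <- colMeans(B[ord[seq_len(ntop)], , drop = FALSE])
      wPerIter[[iter]] <- w
      # the trajectory typically decreases to a minimum and rises again as
      # relevant channels start being discarded; stop once the minimum has
      # not improved for `patience` iterations
      sinceMin <- if (which.min(trace) == iter) 0L else sinceMin + 1L
      if (sinceMin >= patience) break
      if (all(w <= 1e-9 | w >= 1 - 1e-9)) break
    }
    best <- which.min(trace)
    wBest <- wPerIter[[best]]
    bands <- which(wBest >= 0.999)
    if (!length(bands)) {
      warning("no channel reached weight 1; returning channels with weight > 0.5")
      bands <- which(wBest > 0.5)
    }
    if (!length(bands)) bands <- which.max(wBest)
    new("SelectionResult", method = "VISSA", bands = as.integer(bands),
        trace = trace, bestIteration = as.integer(best),
        settings = list(p = p, nSubmodels = nSubmodels,
                        topFraction = topFraction, folds = as.integer(folds),
                        maxIters = as.integer(maxIters),
                        maxNlv = as.integer(maxNlv), patience = patience,
                        weights = wBest, finalWeights = w),
        seed = as.integer(seed))
  })
}

#' Identity selection (all channels)
#'
#' The "no selector" arm of the experimental matrix.
#'
#' @param p total channel count.
#' @return a \linkS4class{SelectionResult} selecting every channel.
#' @export
noSelection <- function(p) {
  new("SelectionResult", method = "none", bands = seq_len(as.integer(p)),
      trace = NA_real_, bestIteration = 1L, settings = list(p = as.integer(p)),
      seed = 0L)
}

#' @rdname accessors
#' @export
setMethod("selectedBands", "SelectionResult", function(x) x@bands)

#' Summarise a selection
#'
#' One report-table row: channel count and its percentage of the total
#' (rounded to one decimal), e.g. 67 of 943 channels is 7.1\%.
#'
#' @param result a \linkS4class{SelectionResult}.
#' @param totalBands total channel count (defaults to the result's setting).
#' @return data.frame with \code{method}, \code{n_selected},
#'   \code{total}, \code{percent}.
#' @export
selectionSummary <- function(result, totalBands = NULL) {
  stopifnot(is(result, "SelectionResult"))
  totalBands <- as.integer(totalBands %||% result@settings$p)
  cnt <- length(result@bands)
  data.frame(method = result@method, n_selected = cnt, total = totalBands,
             percent = round(100 * cnt / totalBands, 1))
}
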