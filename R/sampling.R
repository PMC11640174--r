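## SPXY calibration/prediction splitting: Kennard-Stone greedy max-min
## selection under joint X-Y distances.

#' Joint X-Y distance matrix
#'
#' Pairwise distances \eqn{d_{ij} = \|x_i - x_j\|_2 / \max d_X +
#' |y_i - y_j| / \max d_y}, where the normalisers are the maximum pairwise
#' spectral and response distances over the dataset. If all samples coincide
#' in X (or in y) that term is dropped with a warning.
#'
#' @param X samples x channels matrix.
#' @param y numeric response vector.
#' @return symmetric n x n distance matrix (the pair realising both maxima
#'   has distance 2).
#' @export
jointDistance <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("y length must match the number of rows")
  dx <- as.matrix(stats::dist(X))
  dy <- abs(outer(y, y, `-`))
  mx <- max(dx); my <- max(dy)
  out <- matrix(0, n, n)
  if (mx > 0) out <- out + dx / mx
  else warning("all samples identical in X: spectral term dropped")
  if (my > 0) out <- out + dy / my
  else warning("all samples identical in y: response term dropped")
  out
}

#' SPXY calibration/prediction split
#'
#' Deterministic Kennard-Stone-style greedy max-min selection under the joint
#' X-Y distance: seed with the maximum-distance pair, then repeatedly add the
#' sample whose minimum distance to the already-selected set is largest,
#' until \eqn{\lceil \mathrm{fraction} \cdot n \rceil} samples are selected
#' as the calibration (train) set; the remainder form the prediction (test)
#' set. Ties are broken by lowest original row index, making the split fully
#' deterministic. With \code{strata} given, the split runs independently
#' within each stratum (e.g. one per processing step) and the index sets are
#' unioned — the comprehensive-process layout where each step contributes
#' proportionally.
#'
#' @param X samples x channels matrix.
#' @param y numeric response vector.
#' @param fraction train fraction in (0, 1); the default 0.75 is the 3:1
#'   calibration:prediction ratio.
#' @param strata optional factor of per-sample stratum labels.
#' @return a \linkS4class{SplitResult}.
#' @examples
#' X <- matrix(rnorm(40), 8); y <- rnorm(8)
#' spxySplit(X, y)  # 6 train / 2 test
#' @export
spxySplit <- function(X, y, fraction = 0.75, strata = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  if (!is.null(strata)) {
    if (length(strata) != n) stop("strata length must match rows")
    parts <- split(seq_len(n), strata)
    train <- integer(); ord <- integer()
    for (idx in parts) {
      sub <- spxySplit(X[idx, , drop = FALSE], y[idx], fraction)
      train <- c(train, idx[sub@train])
      ord <- c(ord, idx[sub@selectionOrder])
    }
    return(new("SplitResult", train = sort(train),
               test = setdiff(seq_len(n), train),
               selectionOrder = ord, fraction = fraction))
  }
  if (n < 4L) stop("need at least 4 samples to split")
  ntrain <- ceiling(fraction * n)
  D <- jointDistance(X, y)
  # seed pair: argmax distance, ties by lowest (i, j)
  best <- which(D == max(D), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  sel <- sort(as.integer(best[1, ]))
  remaining <- setdiff(seq_len(n), sel)
  minDist <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < ntrain) {
    cand <- remaining[which.max(minDist[remaining])]  # which.max: first = lowest index
    sel <- c(sel, cand)
    remaining <- setdiff(remaining, cand)
    minDist <- pmin(minDist, D[, cand])
  }
  new("SplitResult", train = sort(sel), test = sort(remaining),
      selectionOrder = as.integer(sel), fraction = fraction)
}

#' @rdname accessors
#' @export
trainIndices <- function(x) x@train

#' @rdname accessors
#' @export
testIndices <- function(x) x@test
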