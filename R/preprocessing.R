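## Spectral pretreatments as fit-on-calibration / apply-anywhere transforms.
## MSC and CT learn parameters from the calibration rows; SG and D1 are
## parameter-free row-wise filters. Chains apply steps in order, each step's
## parameters fitted on the output of the previous steps.

#' Multiplicative scatter correction
#'
#' \code{fitMSC} stores the calibration-mean reference spectrum;
#' \code{applyMSC} regresses each row on the reference (\eqn{x = a\,ref + b})
#' and returns \eqn{(x - b)/a}, removing per-sample multiplicative and
#' additive scatter.
#'
#' @param X samples x channels matrix (>= 2 rows for a meaningful reference).
#' @param params list with element \code{reference}.
#' @return \code{fitMSC}: the parameter list; \code{applyMSC}: the corrected
#'   matrix.
#' @export
fitMSC <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L)
    stop("MSC needs >= 2 calibration rows for a meaningful reference")
  list(reference = colMeans(X))
}

#' @rdname fitMSC
#' @export
applyMSC <- function(X, params) {
  X <- as.matrix(X)
  ref <- params$reference
  if (ncol(X) != length(ref)) stop("channel count mismatch with MSC reference")
  refc <- ref - mean(ref)
  denom <- sum(refc^2)
  out <- X
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    a <- sum((x - mean(x)) * refc) / denom
    if (abs(a) < 1e-12)
      stop(sprintf("MSC slope ~ 0 for row %d (constant spectrum?)", i))
    b <- mean(x) - a * mean(ref)
    out[i, ] <- (x - b) / a
  }
  out
}

#' Mean centring
#'
#' \code{fitCenter} stores the per-channel calibration means; \code{applyCenter}
#' subtracts them from any matrix (prediction rows use the training means).
#'
#' @param X samples x channels matrix.
#' @param params list with element \code{means}.
#' @export
fitCenter <- function(X) list(means = colMeans(as.matrix(X)))

#' @rdname fitCenter
#' @export
applyCenter <- function(X, params) {
  X <- as.matrix(X)
  if (ncol(X) != length(params$means)) stop("channel count mismatch")
  sweep(X, 2, params$means)
}

checkSGArgs <- function(window, polyorder, p) {
  if (window %% 2 == 0) stop("SG window must be odd")
  if (window <= polyorder) stop("SG window must exceed the polynomial order")
  if (window > p) stop("SG window exceeds the number of channels")
}

#' Savitzky-Golay smoothing and derivative
#'
#' Row-wise sliding-window local polynomial filters. \code{sgSmooth} replaces
#' each channel by the centre value of a least-squares polynomial fit over
#' the window; \code{sgDerivative} returns the fitted first (or higher)
#' derivative scaled by the channel spacing, in units per nm. Edge channels
#' are handled by polynomial fits of the terminal windows.
#'
#' @param X samples x channels matrix (or a single spectrum).
#' @param window odd window length, larger than \code{polyorder}.
#' @param polyorder polynomial order (>= 1 for derivatives).
#' @param spacing channel spacing in nm (sets the derivative units).
#' @param deriv derivative order (default 1).
#' @return matrix of the same shape.
#' @export
sgSmooth <- function(X, window = 11L, polyorder = 2L) {
  X <- rbind(as.matrix(X))
  checkSGArgs(window, polyorder, ncol(X))
  t(apply(X, 1, function(x)
    signal::sgolayfilt(x, p = polyorder, n = window)))
}

#' @rdname sgSmooth
#' @export
sgDerivative <- function(X, window = 7L, polyorder = 2L, spacing = 1,
                         deriv = 1L) {
  X <- rbind(as.matrix(X))
  checkSGArgs(window, polyorder, ncol(X))
  if (polyorder < deriv) stop("polyorder must be >= the derivative order")
  t(apply(X, 1, function(x)
    signal::sgolayfilt(x, p = polyorder, n = window, m = deriv, ts = spacing)))
}

#' Build a pretreatment chain
#'
#' Constructs an (unfitted) ordered chain of pretreatments from \{MSC, CT,
#' D1, SG\} (or \code{"none"} for the identity). \code{\link{fitPretreatment}}
#' learns the data-dependent parameters (MSC reference, CT means) from the
#' calibration rows only; \code{\link{applyPretreatment}} then transforms any
#' matrix — calibration rows, prediction rows or map pixels — identically and
#' deterministically. Chains of length 1 mirror routine chemometrics
#' practice; longer chains are fitted left to right, each step on the output
#' of the previous ones.
#'
#' @param methods character vector, ordered subset of \code{"MSC"},
#'   \code{"CT"}, \code{"D1"}, \code{"SG"}, or \code{"none"}.
#' @param sgWindow,sgPolyorder window/order for SG smoothing.
#' @param d1Window,d1Polyorder window/order for the D1 derivative filter.
#' @param spacing channel spacing in nm used by D1 (default 1).
#' @return an unfitted \linkS4class{PretreatmentSpec}.
#' @examples
#' sp <- pretreatment("CT")
#' X <- matrix(rnorm(60), 6)
#' sp <- fitPretreatment(sp, X)
#' colMeans(applyPretreatment(sp, X))  # ~0
#' @export
pretreatment <- function(methods = "CT", sgWindow = 11L, sgPolyorder = 2L,
                         d1Window = 7L, d1Polyorder = 2L, spacing = 1) {
  methods <- toupper(methods)
  methods[methods == "NONE"] <- "none"
  new("PretreatmentSpec", methods = methods,
      options = list(sgWindow = as.integer(sgWindow),
                     sgPolyorder = as.integer(sgPolyorder),
                     d1Window = as.integer(d1Window),
                     d1Polyorder = as.integer(d1Polyorder),
                     spacing = spacing),
      params = list(), fitted = FALSE)
}

#' @rdname pretreatment
#' @param spec a \linkS4class{PretreatmentSpec}.
#' @param X calibration samples x channels matrix.
#' @export
fitPretreatment <- function(spec, X) {
  stopifnot(is(spec, "PretreatmentSpec"))
  X <- as.matrix(X)
  params <- vector("list", length(spec@methods))
  for (i in seq_along(spec@methods)) {
    m <- spec@methods[i]
    params[[i]] <- switch(m,
      MSC = fitMSC(X),
      CT = fitCenter(X),
      D1 = list(), SG = list(), none = list())
    X <- applyStep(m, X, params[[i]], spec@options)
  }
  new("PretreatmentSpec", methods = spec@methods, options = spec@options,
      params = params, fitted = TRUE)
}

applyStep <- function(method, X, params, options) {
  switch(method,
    MSC = applyMSC(X, params),
    CT = applyCenter(X, params),
    SG = sgSmooth(X, options$sgWindow, options$sgPolyorder),
    D1 = sgDerivative(X, options$d1Window, options$d1Polyorder,
                      options$spacing),
    none = X,
    stop("unknown pretreatment: ", method))
}

#' @rdname pretreatment
#' @export
applyPretreatment <- function(spec, X) {
  stopifnot(is(spec, "PretreatmentSpec"))
  if (!spec@fitted) stop("pretreatment must be fitted before it is applied")
  X <- rbind(as.matrix(X))
  for (i in seq_along(spec@methods))
    X <- applyStep(spec@methods[i], X, spec@params[[i]], spec@options)
  X
}
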