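## Model evaluation: R2, RMSE, RPD with credibility classes, and assembly of
## the report tables (one row per process type x pretreatment x selector x
## regressor, best row per process type flagged).

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum_i(\hat y_i - y_i)^2 / \sum_i(y_i - \bar y)^2}.
#'
#' @param y reference values (not constant, n >= 2).
#' @param yhat predictions.
#' @return numeric scalar.
#' @export
rSquared <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 2L) stop("need n >= 2")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("R2 undefined for constant reference values")
  1 - sum((yhat - y)^2) / sst
}

#' Root mean square error
#'
#' \eqn{\sqrt{\frac{1}{N}\sum_i (y_i - \hat y_i)^2}}, in the units of y.
#'
#' @param y reference values.
#' @param yhat predictions.
#' @return numeric scalar >= 0.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  sqrt(mean((y - yhat)^2))
}

#' Relative percent deviation (ratio of performance to deviation)
#'
#' Default (\code{method = "sd"}): the standard chemometrics definition
#' \eqn{RPD = SD(y_{test}) / RMSEP} with the n-1 denominator in the SD. The
#' \code{"printed"} variant \eqn{\sqrt{\sum_i(\hat y_i - \bar y)^2 /
#' \sum_i(\hat y_i - \bar y^*)^2}} (with \eqn{\bar y^*} the mean prediction)
#' is retained for comparison. A perfect fit (RMSEP = 0) returns \code{Inf}.
#'
#' @param y prediction-set reference values (n >= 2).
#' @param yhat predictions.
#' @param method \code{"sd"} (default) or \code{"printed"}.
#' @return numeric scalar.
#' @export
rpd <- function(y, yhat, method = c("sd", "printed")) {
  method <- match.arg(method)
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 2L) stop("need n >= 2")
  if (method == "sd") {
    e <- rmse(y, yhat)
    if (e == 0) return(Inf)
    sd(y) / e
  } else {
    den <- sum((yhat - mean(yhat))^2)
    if (den == 0) return(Inf)
    sqrt(sum((yhat - mean(y))^2) / den)
  }
}

#' RPD credibility class
#'
#' Below 1.4 a model is unreliable; between 1.4 and 2.0 (boundaries
#' inclusive) it is credible; above 2.0 it is highly credible.
#'
#' @param x numeric RPD values (>= 0).
#' @return character vector.
#' @examples
#' rpdClass(c(1.2, 1.7, 4.8))
#' @export
rpdClass <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("RPD must be non-negative")
  ifelse(x < 1.4, "unreliable",
         ifelse(x <= 2.0, "credible", "highly credible"))
}

#' Evaluate a fitted model on calibration and prediction sets
#'
#' @param yCal,yCalHat calibration-set reference values and predictions.
#' @param yPred,yPredHat prediction-set reference values and predictions.
#' @param model model label, e.g. \code{"CT-CARS-PLSR"}.
#' @param process process type (\code{CP}, \code{FLS}, \code{SF}, \code{HD}).
#' @param pretreatmentLabel,selector,regressor component labels.
#' @param nBands number of channels used.
#' @return one-row data.frame: Rc2, RMSEC, Rp2, RMSEP, RPD, credibility.
#' @export
evaluateModel <- function(yCal, yCalHat, yPred, yPredHat, model = "",
                          process = "", pretreatmentLabel = "", selector = "",
                          regressor = "", nBands = NA_integer_) {
  r <- rpd(yPred, yPredHat)
  data.frame(
    model = model, process = process, pretreatment = pretreatmentLabel,
    selector = selector, regressor = regressor, n_bands = nBands,
    Rc2 = rSquared(yCal, yCalHat), RMSEC = rmse(yCal, yCalHat),
    Rp2 = rSquared(yPred, yPredHat), RMSEP = rmse(yPred, yPredHat),
    RPD = r, credibility = rpdClass(r), stringsAsFactors = FALSE)
}

## the paper-style tables sometimes label steaming fixation "ST"
normalizeProcessLabel <- function(x) {
  x <- toupper(x)
  x[x == "ST"] <- "SF"
  x
}

#' Assemble the evaluation report table
#'
#' Binds per-model evaluation rows into one table, normalises the
#' steaming-fixation label (ST is an alias of SF), checks for duplicate
#' (process, pretreatment, selector, regressor) keys, and flags the best row
#' per process type (maximum prediction-set R2, ties broken by RPD). The
#' result serialises to CSV byte-identically for identical inputs.
#'
#' @param rows list of one-row data.frames from \code{\link{evaluateModel}}
#'   (or an already-bound data.frame).
#' @return data.frame with an added logical \code{best} column.
#' @export
buildReport <- function(rows) {
  if (is.data.frame(rows)) tab <- rows
  else if (!length(rows)) {
    return(data.frame(model = character(), process = character(),
                      pretreatment = character(), selector = character(),
                      regressor = character(), n_bands = integer(),
                      Rc2 = numeric(), RMSEC = numeric(), Rp2 = numeric(),
                      RMSEP = numeric(), RPD = numeric(),
                      credibility = character(), best = logical()))
  } else tab <- do.call(rbind, rows)
  tab$process <- normalizeProcessLabel(tab$process)
  key <- paste(tab$process, tab$pretreatment, tab$selector, tab$regressor)
  if (anyDuplicated(key))
    stop("duplicate report rows: ", paste(unique(key[duplicated(key)]),
                                          collapse = "; "))
  tab$best <- FALSE
  for (pr in unique(tab$process)) {
    i <- which(tab$process == pr)
    o <- i[order(-tab$Rp2[i], -tab$RPD[i])]
    tab$best[o[1]] <- TRUE
  }
  rownames(tab) <- NULL
  tab
}
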