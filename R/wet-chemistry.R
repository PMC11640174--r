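## Ninhydrin-assay reference chemistry: standard curve and TFAA computation.

#' Fit a ninhydrin standard curve
#'
#' Ordinary least-squares line relating analyte mass (mg) to absorbance at
#' 570 nm over a dilution series of standards.
#'
#' @param absorbance numeric absorbances at 570 nm (>= 2 distinct values).
#' @param massMg numeric analyte masses (mg), same length.
#' @return a \linkS4class{StandardCurve}.
#' @examples
#' fitStandardCurve(c(0, 1), c(0, 10))  # slope 10, intercept 0
#' @export
fitStandardCurve <- function(absorbance, massMg) {
  if (length(absorbance) != length(massMg))
    stop("absorbance and mass vectors must have equal length")
  if (length(absorbance) < 2L) stop("at least 2 standards required")
  if (diff(range(absorbance)) == 0)
    stop("all absorbances identical: cannot fit a standard curve")
  fit <- lm(massMg ~ absorbance)
  sst <- sum((massMg - mean(massMg))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(residuals(fit)^2) / sst
  new("StandardCurve", slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]), r2 = r2,
      n = length(absorbance))
}

#' Evaluate a standard curve
#'
#' @param curve a \linkS4class{StandardCurve}.
#' @param absorbance numeric absorbances at 570 nm.
#' @return predicted analyte mass (mg).
#' @export
predictMass <- function(curve, absorbance) {
  stopifnot(is(curve, "StandardCurve"))
  curve@slope * absorbance + curve@intercept
}

#' Compute TFAA content from assay records
#'
#' Total free amino acid content as percent of dry mass:
#' \deqn{TFAA = \frac{10^{-3} \cdot C_0 \cdot V_1}{M \cdot (m/100) \cdot V_2}
#'   \times 100\%}
#' where \eqn{C_0} is the analyte mass (mg) read off the standard curve from
#' the measured absorbance, \eqn{V_1} the total test-solution volume (mL),
#' \eqn{V_2} the volume used for the determination (mL), \eqn{M} the specimen
#' mass (g) and \eqn{m} the dry-matter content in percent (entering as the
#' fraction \eqn{m/100}).
#'
#' @param records data.frame with columns \code{A570}, \code{V1_ml},
#'   \code{V2_ml}, \code{M_g}, \code{dry_matter_pct} (and optionally
#'   \code{sample_id}), or a single-row list with those names.
#' @param curve a \linkS4class{StandardCurve}.
#' @return numeric TFAA (\% dry mass), one value per record.
#' @examples
#' cv <- fitStandardCurve(c(0, 1), c(0, 10))
#' rec <- data.frame(A570 = 1, V1_ml = 1, V2_ml = 1, M_g = 0.25,
#'                   dry_matter_pct = 95)
#' computeTFAA(rec, cv)  # ~4.211
#' @export
computeTFAA <- function(records, curve) {
  records <- as.data.frame(records)
  need <- c("A570", "V1_ml", "V2_ml", "M_g", "dry_matter_pct")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  with(records, {
    if (any(V1_ml <= 0) || any(V2_ml <= 0) || any(M_g <= 0))
      stop("volumes and specimen mass must be positive")
    if (any(dry_matter_pct <= 0) || any(dry_matter_pct > 100))
      stop("dry matter content must lie in (0, 100] percent")
    c0 <- predictMass(curve, A570)
    if (any(c0 < 0))
      stop("absorbance below the assay range: negative mass from the curve")
    1e-3 * c0 * V1_ml / (M_g * (dry_matter_pct / 100) * V2_ml) * 100
  })
}

#' Read / write assay chemistry CSVs
#'
#' \code{readChemistryCSV} expects columns \code{sample_id, A570, V1_ml,
#' V2_ml, M_g, dry_matter_pct}; \code{chemistryToCSV} writes the computed
#' \code{sample_id, tfaa_percent} table.
#'
#' @param path CSV path.
#' @param curve a \linkS4class{StandardCurve}.
#' @return \code{readChemistryCSV}: the assay data.frame;
#'   \code{chemistryToCSV}: invisibly, the output data.frame.
#' @export
readChemistryCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "A570", "V1_ml", "V2_ml", "M_g", "dry_matter_pct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname readChemistryCSV
#' @param records assay data.frame as returned by \code{readChemistryCSV}.
#' @export
chemistryToCSV <- function(records, curve, path) {
  out <- data.frame(sample_id = records$sample_id,
                    tfaa_percent = computeTFAA(records, curve))
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
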