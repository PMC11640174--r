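## Config-driven orchestration of the full experimental matrix:
## process types (CP + per-step) x pretreatments x selectors x regressors,
## with seeding, provenance and report emission.

pipelineDefaults <- function() list(
  simulate = list(steps = c("FLS", "SF", "HD"), batches = 30L,
                  replicates = 3L, wavelengthStart = 400,
                  wavelengthEnd = 1000, nChannels = 951L),
  inputDir = NULL,
  seed = 42L,
  trimLow = 4L, trimHigh = 4L,
  trainFraction = 0.75,
  processes = c("CP", "FLS", "SF", "HD"),
  pretreatments = c("MSC", "CT", "D1", "SG"),
  selectors = c("none", "CARS"),
  regressors = "PLSR",
  cars = list(N = 65L, folds = 5L, mcFraction = 0.8, maxNlv = 10L),
  vissa = list(nSubmodels = 1000L, topFraction = 0.05, folds = 5L,
               maxIters = 50L, maxNlv = 10L),
  modelFolds = 10L,
  maxNlv = 10L,
  lssvr = list(gammaGrid = 2^seq(-15, 3, by = 2),
               cGrid = 2^seq(-5, 15, by = 2)),
  map = FALSE,
  outputDir = NULL)

mergeConfig <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste0(path, unknown, collapse = ", ")))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(user[[k]]))
      defaults[[k]] <- mergeConfig(defaults[[k]], user[[k]],
                                   paste0(path, k, "$"))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Validate and normalise a pipeline configuration
#'
#' Accepts a named list or a YAML/JSON file path, fills every documented
#' default, and rejects unknown keys (naming them) and invalid values before
#' any compute. The normalised config is serialised into every output for
#' provenance.
#'
#' @param config named list, or path to a \code{.yaml}/\code{.yml}/
#'   \code{.json} file.
#' @return the normalised config list, with a \code{hash} attribute.
#' @examples
#' cfg <- validateConfig(list(seed = 7))
#' cfg$trainFraction
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- mergeConfig(pipelineDefaults(), config)
  if (cfg$trainFraction <= 0 || cfg$trainFraction >= 1)
    stop("trainFraction must lie strictly in (0, 1): a 1.0 split leaves no prediction set")
  if (cfg$trimLow < 0 || cfg$trimHigh < 0) stop("trim counts must be >= 0")
  badSel <- setdiff(cfg$selectors, c("none", "CARS", "VISSA"))
  if (length(badSel)) stop("unknown selector(s): ", paste(badSel, collapse = ", "))
  badReg <- setdiff(cfg$regressors, c("PLSR", "LSSVR"))
  if (length(badReg)) stop("unknown regressor(s): ", paste(badReg, collapse = ", "))
  badPre <- setdiff(toupper(cfg$pretreatments), c("MSC", "CT", "D1", "SG", "NONE"))
  if (length(badPre)) stop("unknown pretreatment(s): ", paste(badPre, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed)
  attr(cfg, "hash") <- configHash(cfg)
  cfg
}

configHash <- function(cfg) {
  attr(cfg, "hash") <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

## Load mean spectra from an input directory: chemistry.csv plus one ENVI
## cube per sample id; raw cubes are reflectance-calibrated and masked.
loadSampleSpectra <- function(dir) {
  chem <- read.csv(file.path(dir, "chemistry.csv"), stringsAsFactors = FALSE)
  need <- c("sample_id", "step", "tfaa_percent")
  miss <- setdiff(need, names(chem))
  if (length(miss)) stop("chemistry.csv missing: ", paste(miss, collapse = ", "))
  specs <- NULL
  wl <- NULL
  for (sid in chem$sample_id) {
    cube <- readENVICube(file.path(dir, sid))
    if (cube@kind == "raw") cube <- calibrateReflectance(cube)
    ms <- extractMeanSpectrum(cube, maskBackground(cube), sampleId = sid)
    wl <- ms@wavelengths
    specs <- rbind(specs, ms@values)
  }
  rownames(specs) <- chem$sample_id
  calibrationSet(specs, wl, chem$tfaa_percent, step = chem$step,
                 batch = chem$batch, replicate = chem$replicate,
                 sampleId = chem$sample_id)
}

runSelector <- function(name, X, y, cfg, seed) {
  switch(name,
    none = noSelection(ncol(X)),
    CARS = carsSelect(X, y, N = cfg$cars$N, folds = cfg$cars$folds,
                      seed = seed, mcFraction = cfg$cars$mcFraction,
                      maxNlv = cfg$cars$maxNlv),
    VISSA = vissaSelect(X, y, nSubmodels = cfg$vissa$nSubmodels,
                        topFraction = cfg$vissa$topFraction,
                        folds = cfg$vissa$folds,
                        maxIters = cfg$vissa$maxIters, seed = seed,
                        maxNlv = cfg$vissa$maxNlv))
}

#' Run the full experimental matrix
#'
#' For every configured process type, splits the samples by SPXY (the
#' comprehensive-process CP model stratified per step so each step
#' contributes proportionally), then trains and evaluates every
#' pretreatment x selector x regressor combination: pretreatments are fitted
#' on calibration rows only, selectors run on the pretreated calibration
#' rows, PLSR latent variables are chosen by k-fold CV and LS-SVR
#' hyperparameters by grid search under one shared fold assignment per
#' process, and each model is scored on the held-out prediction set. Emits a
#' report table (CSV), selection RMSECV traces, optional best-model
#' pseudo-colour maps on a simulated cube, and a provenance sidecar with the
#' config hash and seeds. Identical config + seed give byte-identical
#' reports.
#'
#' @param config a config list or file path (see \code{\link{validateConfig}}).
#' @return invisibly, a list with \code{report} (data.frame),
#'   \code{selections}, \code{models}, \code{config} and the written
#'   \code{paths}.
#' @export
runMatrix <- function(config = list()) {
  cfg <- validateConfig(config)
  paths <- character()

  if (!is.null(cfg$inputDir)) {
    cal <- loadSampleSpectra(cfg$inputDir)
  } else {
    design <- studyDesign(steps = cfg$simulate$steps,
                          batches = cfg$simulate$batches,
                          replicates = cfg$simulate$replicates,
                          wavelengthStart = cfg$simulate$wavelengthStart,
                          wavelengthEnd = cfg$simulate$wavelengthEnd,
                          nChannels = cfg$simulate$nChannels)
    cal <- calibration(simulateTeaSpectra(design, seed = cfg$seed))
  }
  calFull <- cal
  cal <- trimBands(cal, cfg$trimLow, cfg$trimHigh)
  X <- spectraMatrix(cal)
  y <- tfaa(cal)
  steps <- processStep(cal)

  rows <- list(); selections <- list(); models <- list()
  for (ip in seq_along(cfg$processes)) {
    proc <- cfg$processes[ip]
    if (proc == "CP") {
      rowsIdx <- seq_len(nrow(X))
      split <- spxySplit(X, y, cfg$trainFraction, strata = steps)
    } else {
      rowsIdx <- which(normalizeProcessLabel(steps) ==
                       normalizeProcessLabel(proc))
      if (!length(rowsIdx)) stop("no samples for process ", proc)
      split <- spxySplit(X[rowsIdx, , drop = FALSE], y[rowsIdx],
                         cfg$trainFraction)
    }
    tr <- rowsIdx[split@train]; te <- rowsIdx[split@test]
    foldSeed <- cfg$seed + 97L * ip
    folds <- cvFolds(length(tr), min(cfg$modelFolds, length(tr)),
                     seed = foldSeed)

    for (ie in seq_along(cfg$pretreatments)) {
      preName <- toupper(cfg$pretreatments[ie])
      spec <- fitPretreatment(pretreatment(preName,
                                           spacing = diff(wavelengths(cal))[1]),
                              X[tr, , drop = FALSE])
      Xtr <- applyPretreatment(spec, X[tr, , drop = FALSE])
      Xte <- applyPretreatment(spec, X[te, , drop = FALSE])

      for (isel in seq_along(cfg$selectors)) {
        selName <- cfg$selectors[isel]
        selSeed <- cfg$seed + 10000L * ip + 100L * ie + isel
        sel <- runSelector(selName, Xtr, y[tr], cfg, selSeed)
        selections[[paste(proc, preName, selName, sep = "-")]] <- sel
        Xtrs <- Xtr[, sel@bands, drop = FALSE]
        Xtes <- Xte[, sel@bands, drop = FALSE]

        for (reg in cfg$regressors) {
          label <- paste(preName, selName, reg, sep = "-")
          if (reg == "PLSR") {
            ch <- selectNLVs(Xtrs, y[tr], maxNlv = cfg$maxNlv,
                             folds = folds)
            model <- fitPLSR(Xtrs, y[tr], nlv = ch$nlv, cvTable = ch$cvTable)
          } else {
            gs <- gridSearchLSSVR(Xtrs, y[tr], gammaGrid = cfg$lssvr$gammaGrid,
                                  cGrid = cfg$lssvr$cGrid, folds = folds)
            model <- fitLSSVR(Xtrs, y[tr], gamma = gs$gamma, C = gs$C)
          }
          models[[paste(proc, label, sep = "-")]] <-
            list(model = model, pretreat = spec, selection = sel,
                 train = tr, test = te)
          rows[[length(rows) + 1L]] <- evaluateModel(
            y[tr], predict(model, Xtrs), y[te], predict(model, Xtes),
            model = label, process = proc, pretreatmentLabel = preName,
            selector = selName, regressor = reg,
            nBands = length(sel@bands))
        }
      }
    }
  }
  report <- buildReport(rows)

  if (!is.null(cfg$outputDir)) {
    dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
    rp <- file.path(cfg$outputDir, "report.csv")
    write.csv(report, rp, row.names = FALSE)
    paths <- c(paths, rp)
    for (nm in names(selections)) {
      sel <- selections[[nm]]
      if (sel@method == "none") next
      tp <- file.path(cfg$outputDir, paste0("selection_", nm, ".csv"))
      write.csv(data.frame(iteration = seq_along(sel@trace),
                           rmsecv = sel@trace), tp, row.names = FALSE)
      paths <- c(paths, tp)
    }
    if (isTRUE(cfg$map) && is.null(cfg$inputDir)) {
      XF <- spectraMatrix(calFull)
      for (proc in unique(report$process)) {
        bestRow <- report[report$process == proc & report$best, ][1, ]
        entry <- models[[paste(proc, bestRow$model, sep = "-")]]
        sid <- entry$test[1]
        cube <- simulateCube(XF[sid, ], wavelengths(calFull),
                             seed = cfg$seed + 7L)
        pm <- predictMap(cube$reflectance, entry$pretreat, entry$selection,
                         entry$model, mask = cube$foreground,
                         trimLow = cfg$trimLow, trimHigh = cfg$trimHigh,
                         modelLabel = paste(proc, bestRow$model, sep = "-"))
        mp <- file.path(cfg$outputDir, paste0("map_", proc, ".png"))
        renderPseudocolor(pm, mp)
        paths <- c(paths, mp)
      }
    }
    prov <- list(config = cfg[setdiff(names(cfg), "lssvr")],
                 config_hash = attr(cfg, "hash"), seed = cfg$seed,
                 n_samples = nrow(X), n_bands = ncol(X))
    pp <- file.path(cfg$outputDir, "provenance.json")
    jsonlite::write_json(prov, pp, auto_unbox = TRUE, digits = NA,
                         null = "null")
    paths <- c(paths, pp)
  }
  invisible(list(report = report, selections = selections, models = models,
                 config = cfg, paths = paths))
}
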