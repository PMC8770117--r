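#' Pipeline run configuration
#'
#' Collects every stage parameter with its default: 10 CV folds, BH alphas
#' 0.05 (screening/confirmation) and 0.01 (discovery), the 3-s.d. outlier
#' rule, 1,000 bootstrap replicates and the 75 percent sensitivity
#' operating point. A single global seed expands deterministically into
#' per-stage seeds by fixed offsets, so one integer reproduces a whole run.
#'
#' @param seed global integer seed.
#' @param sim a [simConfig()] describing the synthetic study (its own seed
#'   is overridden by the derived stage seed).
#' @param folds CV folds for the gestational-age clock.
#' @param outlierK s.d. multiplier for QC outlier flagging.
#' @param screenAlpha BH-adjusted threshold for the pre-eclampsia screen.
#' @param trendAlpha BH-adjusted discovery threshold for set trends.
#' @param confirmAlpha per-cohort confirmation threshold.
#' @param bootstrapB bootstrap replicates.
#' @param sensTarget operating sensitivity.
#' @param trainFraction gestational-age clock train fraction.
#' @return list of class `"RunConfig"`.
#' @export
runConfig <- function(seed = 1, sim = simConfig(), folds = 10,
                      outlierK = 3, screenAlpha = 0.05, trendAlpha = 0.01,
                      confirmAlpha = 0.05, bootstrapB = 1000,
                      sensTarget = 0.75, trainFraction = 0.8) {
  cfg <- list(seed = as.integer(seed), sim = sim, folds = folds,
              outlierK = outlierK, screenAlpha = screenAlpha,
              trendAlpha = trendAlpha, confirmAlpha = confirmAlpha,
              bootstrapB = bootstrapB, sensTarget = sensTarget,
              trainFraction = trainFraction)
  class(cfg) <- "RunConfig"
  cfg
}

stageSeed <- function(cfg, stage) {
  offsets <- c(sim = 101L, split = 202L, clock = 303L, trends = 404L,
               pe = 505L, bootstrap = 606L)
  cfg$seed + offsets[[stage]]
}

#' Normalise, QC-filter and cohort-correct an experiment
#'
#' Convenience wrapper running the standard preprocessing chain: CPM,
#' log2(CPM+1), QC outlier removal, then depth and cohort correction
#' learned on the designated training samples and applied to all samples.
#'
#' @param ce a [CfrnaExperiment-class].
#' @param trainIds sample ids to learn the correction on (default: all).
#' @param voiColumn colData column holding the variable of interest.
#' @param outlierK s.d. multiplier for the QC rule; `NULL` skips flagging.
#' @param qcMetrics colData columns treated as QC metrics.
#' @return the experiment, outliers removed, with `cpm`, `log2cpm1` and
#'   `corrected` assays and the model in `metadata(ce)$correctionModel`.
#' @export
preprocessExperiment <- function(ce, trainIds = colnames(ce),
                                 voiColumn = "ga_collect_weeks",
                                 outlierK = 3,
                                 qcMetrics = c("qc_total_reads",
                                               "qc_dup_rate",
                                               "qc_actb_ct")) {
  if (!is.null(outlierK)) {
    qcCols <- intersect(qcMetrics, colnames(colData(ce)))
    if (length(qcCols)) {
      fl <- flagOutliers(as.data.frame(colData(ce)[qcCols]), k = outlierK)
      if (any(fl$flag)) {
        message(sum(fl$flag), " of ", ncol(ce),
                " samples flagged as QC outliers and removed")
        ce <- ce[, !fl$flag]
        trainIds <- intersect(trainIds, colnames(ce))
      }
    }
  }
  ce <- logTransform(computeCPM(ce))
  tr <- colnames(ce) %in% trainIds
  logm <- assay(ce, "log2cpm1")
  totals <- colSums(assay(ce, "counts"))
  model <- fitCorrectionModel(logm[, tr, drop = FALSE],
                              voi = colData(ce)[[voiColumn]][tr],
                              cohort = colData(ce)$cohort[tr],
                              totals = totals[tr])
  ce <- applyCorrection(model, ce)
  metadata(ce)$correctionModel <- model
  ce
}

#' Run the full analysis pipeline end to end
#'
#' Simulates a multi-cohort study, preprocesses and corrects it, fits and
#' evaluates the gestational-age clock with its ANOVA decomposition, runs
#' the gene-set trend and monotonicity analysis on a longitudinal
#' simulation, and fits the pre-eclampsia classifier with bootstrap CIs.
#' Everything is driven by the config's global seed; identical configs give
#' identical metrics. Results are returned as a list and, when `outDir` is
#' given, written out as JSON/TSV with a plain-text log recording the
#' before/after counts of every filter.
#'
#' @param config a [runConfig()].
#' @param outDir optional output directory.
#' @return list with elements `gaClock`, `trends`, `peRisk` and `log`.
#' @export
runPipeline <- function(config = runConfig(), outDir = NULL) {
  logLines <- character()
  note <- function(...) {
    line <- paste0(...)
    logLines <<- c(logLines, line)
    message(line)
  }

  ## --- simulate + preprocess -------------------------------------------
  simCfg <- config$sim
  simCfg$seed <- stageSeed(config, "sim")
  sim <- simulateCohorts(simCfg)
  ce <- sim$experiment
  note("simulated ", ncol(ce), " samples x ", nrow(ce), " genes in ",
       simCfg$n_cohorts, " cohorts")
  healthy <- colData(ce)$outcome == "control"
  sp <- splitStratified(colData(ce)$ga_collect_weeks[healthy],
                        ids = colnames(ce)[healthy],
                        trainFraction = config$trainFraction,
                        seed = stageSeed(config, "split"))
  nBefore <- ncol(ce)
  ce <- preprocessExperiment(ce, trainIds = sp$train,
                             outlierK = config$outlierK)
  note("preprocessing kept ", ncol(ce), " of ", nBefore, " samples")
  sp$train <- intersect(sp$train, colnames(ce))
  sp$test <- intersect(sp$test, colnames(ce))

  ## --- gestational-age clock -------------------------------------------
  corrected <- assay(ce, "corrected")
  feats <- filterFeatures(corrected[, sp$train, drop = FALSE],
                          as.data.frame(rowData(ce)))
  note("feature filter kept ", length(feats), " of ", nrow(ce), " genes")
  Xtr <- t(corrected[feats, sp$train, drop = FALSE])
  Xte <- t(corrected[feats, sp$test, drop = FALSE])
  ytr <- colData(ce)[sp$train, "ga_collect_weeks"]
  yte <- colData(ce)[sp$test, "ga_collect_weeks"]
  curve <- fitLassoCv(Xtr, ytr, folds = config$folds,
                      seed = stageSeed(config, "clock"))
  lam <- selectOneSE(curve)
  clock <- fitFinal(Xtr, ytr, lam,
                    featureProvenance = "protein_coding, median > 0")
  pred <- predict(clock, Xte)
  mae <- evaluateMae(pred, yte)
  note("GA clock: ", nFeatures(clock), " features, held-out MAE ",
       round(mae, 2), " days")
  vd <- anovaVariance(yte, pred,
                      as.data.frame(colData(ce)[sp$test,
                        c("bmi", "maternal_age", "race")]))
  gaRes <- list(model = clock, penalty = lam, maeDays = mae,
                predictions = data.frame(sample_id = sp$test,
                                         truth = yte, predicted = pred),
                variance = vd, cvCurve = curve)

  ## --- gene-set trends (longitudinal) ----------------------------------
  longCfg <- simCfg
  longCfg$n_cohorts <- 4L
  longCfg$samples_per_cohort <- rep(0L, 4)
  longCfg$ga_window_per_cohort <- replicate(4, c(11, 35), simplify = FALSE)
  if (is.null(longCfg$longitudinal_cohort))
    longCfg$longitudinal_cohort <- longitudinalDesign()
  longCfg$seed <- stageSeed(config, "trends")
  lsim <- simulateLongitudinal(longCfg)
  lce <- logTransform(computeCPM(lsim$experiment))
  scores <- partitionScores(assay(lce, "cpm"), lsim$geneSets,
                            as.data.frame(colData(lce)))
  fits <- fitTrendsByCohort(scores)
  confirmed <- confirmAcrossCohorts(fits, discovery = "H",
                                    alpha = config$confirmAlpha,
                                    discoveryAlpha = config$trendAlpha)
  note(nrow(confirmed), " of ", length(lsim$geneSets),
       " gene sets confirmed across cohorts")
  discScores <- scores[scores$cohort == "H", , drop = FALSE]
  mono <- lapply(split(discScores, discScores$set), monotonicityTest)
  trendRes <- list(scores = scores, fits = fits, confirmed = confirmed,
                   monotonicity = mono,
                   trueDirection = simTruth(lce)$setDirection)

  ## --- pre-eclampsia classifier ----------------------------------------
  peCohorts <- colData(ce)$cohort %in% c("A", "E")
  Xpe <- t(assay(ce, "corrected")[, peCohorts, drop = FALSE])
  ype <- as.numeric(colData(ce)$outcome[peCohorts] == "PE")
  note("PE design: ", sum(ype), " cases, ", sum(ype == 0), " non-cases")
  peRep <- loocvFit(Xpe, ype, alpha = config$screenAlpha,
                    sensTarget = config$sensTarget)
  aucCi <- bootstrapCi(function(p, y) rocAuc(p, y)$auc,
                       peRep@probabilities, peRep@labels,
                       B = config$bootstrapB,
                       seed = stageSeed(config, "bootstrap"))
  peRep@aucCi <- c(aucCi$ciLow, aucCi$ciHigh)
  note("PE classifier: AUC ", round(peRep@auc, 3), ", PPV ",
       round(100 * peRep@ppv, 1), "% at ",
       round(100 * peRep@sensitivity), "% sensitivity")
  km <- kmLogrank(colData(ce)$ga_delivery_weeks[peCohorts],
                  peRep@probabilities >= peRep@threshold)
  peRes <- list(report = peRep, aucCi = aucCi, km = km,
                panel = simTruth(ce)$pePanel$gene_id)

  out <- list(gaClock = gaRes, trends = trendRes, peRisk = peRes,
              log = logLines)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    metrics <- list(
      ga_mae_days = mae,
      ga_n_features = nFeatures(clock),
      ga_covariate_variance = sum(vd$fraction[vd$term %in%
        c("bmi", "maternal_age", "race")]),
      n_sets_confirmed = nrow(confirmed),
      pe_auc = peRep@auc, pe_auc_ci = peRep@aucCi,
      pe_ppv = peRep@ppv, pe_sensitivity = peRep@sensitivity,
      pe_specificity = peRep@specificity,
      pe_prevalence = peRep@prevalence,
      km_logrank_p = km$p)
    jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.table(fits, file.path(outDir, "trend_fits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(confirmed, file.path(outDir, "confirmed_sets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeModelJson(clock, file.path(outDir, "ga_model.json"))
    writeLines(logLines, file.path(outDir, "run.log"))
  }
  out
}
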