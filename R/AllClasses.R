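#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames assay<- colData rowData
NULL

#' CfrnaExperiment: a container for plasma cfRNA count data
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with the sample and
#' gene annotation vocabulary used throughout the pipeline. The `"counts"`
#' assay holds raw integer counts (genes x samples); normalisation and
#' correction steps add `"cpm"`, `"log2cpm1"` and `"corrected"` assays so
#' that every expression space travels with the object and space mismatches
#' are caught at dispatch time.
#'
#' Column data is expected to carry (subsets are fine for partial analyses):
#' `sample_id`, `subject_id`, `cohort`, `draw_index`, `ga_collect_weeks`,
#' `ga_delivery_weeks`, `outcome`, `bmi`, `maternal_age`, `race`,
#' `qc_total_reads`, `qc_dup_rate`, `qc_actb_ct`. Row data carries `gene_id`
#' and `biotype` (one of `"protein_coding"`, `"pseudogene"`, `"non_coding"`).
#'
#' @slot truth optional list of generating-model ground truth when the object
#'   was simulated (see [simulateCohorts()]); empty for user data.
#'
#' @export
setClass("CfrnaExperiment",
  contains = "SummarizedExperiment",
  slots = c(truth = "list"),
  prototype = prototype(truth = list())
)

setValidity("CfrnaExperiment", function(object) {
  msg <- character()
  if (!("counts" %in% assayNames(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- assay(object, "counts")
    if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(abs(cnt - round(cnt)) > 1e-8))
      msg <- c(msg, "counts must be integers")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a CfrnaExperiment
#'
#' @param counts gene x sample matrix of raw integer counts with rownames
#'   (gene ids) and colnames (sample ids).
#' @param sampleData data.frame of per-sample annotation, one row per sample,
#'   in column order of `counts`.
#' @param geneData data.frame of per-gene annotation (`gene_id`, `biotype`),
#'   one row per gene.
#' @param truth optional list of simulation ground truth.
#' @return A [CfrnaExperiment-class] object.
#' @examples
#' cnt <- matrix(rpois(20, 10), 4, 5,
#'   dimnames = list(paste0("G", 1:4), paste0("S", 1:5)))
#' ce <- CfrnaExperiment(cnt)
#' ce
#' @export
CfrnaExperiment <- function(counts, sampleData = NULL, geneData = NULL,
                            truth = list()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("G", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  cd <- if (is.null(sampleData)) DataFrame(row.names = colnames(counts))
        else DataFrame(sampleData, row.names = colnames(counts))
  rd <- if (is.null(geneData)) DataFrame(row.names = rownames(counts))
        else DataFrame(geneData, row.names = rownames(counts))
  se <- SummarizedExperiment(assays = list(counts = counts),
                             colData = cd, rowData = rd)
  new("CfrnaExperiment", se, truth = truth)
}

#' @describeIn CfrnaExperiment access simulation ground truth (empty list for
#'   user-supplied data).
#' @param x,object a `CfrnaExperiment`.
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))

#' @rdname CfrnaExperiment
#' @export
setMethod("simTruth", "CfrnaExperiment", function(x) x@truth)

setMethod("show", "CfrnaExperiment", function(object) {
  callNextMethod()
  cat("expression spaces:", paste(assayNames(object), collapse = ", "), "\n")
  if (length(object@truth))
    cat("simulated: yes (ground truth in simTruth())\n")
})

#' CorrectionModel: learned depth and cohort correction
#'
#' Holds per-gene linear coefficients of log2(CPM+1) expression on total
#' counts (depth correction), the training-only variable-of-interest
#' coefficients used to orthogonalise the cohort effect, and per-(gene,
#' cohort) offsets. Applying the model ([applyCorrection()]) never consumes
#' the variable of interest of the target samples, so information leakage
#' from held-out covariates is impossible by construction.
#'
#' @slot genes character vector of gene ids the model covers.
#' @slot depthIntercept,depthSlope per-gene coefficients of expression on
#'   per-sample total counts.
#' @slot geneMean per-gene training mean, re-added after residualisation so
#'   corrected values stay on the log2-CPM scale.
#' @slot voiIntercept,voiSlope per-gene training-only coefficients of the
#'   depth-corrected expression on the variable of interest (e.g.
#'   gestational age); retained only to define orthogonality.
#' @slot offsets genes x cohorts matrix of cohort offsets (log2-CPM units).
#' @slot cohorts training cohort labels (column order of `offsets`).
#' @slot fittedSpace expression space the model was fitted in
#'   (`"log2cpm1"`).
#' @export
setClass("CorrectionModel", slots = c(
  genes = "character",
  depthIntercept = "numeric",
  depthSlope = "numeric",
  geneMean = "numeric",
  voiIntercept = "numeric",
  voiSlope = "numeric",
  offsets = "matrix",
  cohorts = "character",
  fittedSpace = "character"
))

setValidity("CorrectionModel", function(object) {
  msg <- character()
  n <- length(object@genes)
  for (s in c("depthIntercept", "depthSlope", "geneMean"))
    if (length(slot(object, s)) != n)
      msg <- c(msg, sprintf("slot '%s' must have one value per gene", s))
  if (nrow(object@offsets) != n)
    msg <- c(msg, "offsets must have one row per gene")
  if (!identical(colnames(object@offsets), object@cohorts))
    msg <- c(msg, "offsets columns must match training cohorts")
  if (!identical(object@fittedSpace, "log2cpm1"))
    msg <- c(msg, "fittedSpace must be 'log2cpm1'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CorrectionModel", function(object) {
  cat("CorrectionModel:", length(object@genes), "genes,",
      length(object@cohorts), "training cohorts\n")
  cat("  cohorts:", paste(object@cohorts, collapse = ", "), "\n")
  cat("  fitted in:", object@fittedSpace, "\n")
})

#' GaClock: a penalised linear gestational-age model
#'
#' Result of [fitFinal()]: the selected L1 penalty, the intercept and the
#' nonzero gene coefficients of a lasso regression of gestational age
#' (weeks) on standardised log2(CPM+1) expression.
#'
#' @slot penalty selected penalty (lambda).
#' @slot intercept model intercept (weeks).
#' @slot coef named numeric vector of nonzero gene coefficients
#'   (original, unstandardised scale).
#' @slot featureProvenance how the feature universe was filtered.
#' @slot trainSd per-feature training standard deviations, used to rank
#'   features on the standardised scale for [refitTopK()].
#' @export
setClass("GaClock", slots = c(
  penalty = "numeric",
  intercept = "numeric",
  coef = "numeric",
  featureProvenance = "character",
  trainSd = "numeric"
))

setValidity("GaClock", function(object) {
  if (length(object@coef) && is.null(names(object@coef)))
    "coefficients must be named by gene id" else TRUE
})

setMethod("show", "GaClock", function(object) {
  cat("GaClock: lasso gestational-age model\n")
  cat("  penalty (lambda):", format(object@penalty, digits = 4), "\n")
  cat("  nonzero gene features:", length(object@coef), "\n")
  cat("  feature filter:", object@featureProvenance, "\n")
})

#' @describeIn GaClock number of nonzero gene features.
#' @param object a `GaClock`.
#' @export
setGeneric("nFeatures", function(object) standardGeneric("nFeatures"))

#' @rdname GaClock
#' @export
setMethod("nFeatures", "GaClock", function(object) length(object@coef))

#' ClassifierReport: cross-validated pre-eclampsia classifier results
#'
#' @slot probabilities per-sample out-of-fold probability of pre-eclampsia.
#' @slot labels observed 0/1 labels, same order.
#' @slot foldFeatures list of per-fold retained gene ids.
#' @slot consensusFeatures genes retained in every fold.
#' @slot roc data.frame of ROC points (fpr, tpr, threshold).
#' @slot auc area under the ROC curve.
#' @slot aucCi bootstrap 95 percent CI for the AUC (length 2), NA until
#'   [bootstrapCi()] has been run.
#' @slot threshold,sensitivity,specificity,ppv operating-point metrics at
#'   the chosen sensitivity target.
#' @slot prevalence case fraction used in the PPV arithmetic.
#' @export
setClass("ClassifierReport", slots = c(
  probabilities = "numeric",
  labels = "numeric",
  foldFeatures = "list",
  consensusFeatures = "character",
  roc = "data.frame",
  auc = "numeric",
  aucCi = "numeric",
  threshold = "numeric",
  sensitivity = "numeric",
  specificity = "numeric",
  ppv = "numeric",
  prevalence = "numeric"
))

setValidity("ClassifierReport", function(object) {
  msg <- character()
  p <- object@probabilities
  if (length(p) && (any(p < 0) || any(p > 1)))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (length(object@labels) != length(p))
    msg <- c(msg, "labels and probabilities must have equal length")
  if (length(object@consensusFeatures) && length(object@foldFeatures) &&
      !all(vapply(object@foldFeatures,
                  function(f) all(object@consensusFeatures %in% f),
                  logical(1))))
    msg <- c(msg, "consensus features must appear in every fold")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClassifierReport", function(object) {
  cat("ClassifierReport:", length(object@probabilities), "samples,",
      sum(object@labels == 1), "cases\n")
  cat("  AUC:", format(object@auc, digits = 3))
  if (!anyNA(object@aucCi))
    cat(" (95% CI", paste(format(object@aucCi, digits = 3), collapse = "-"),
        ")")
  cat("\n")
  if (!anyNA(object@sensitivity))
    cat(sprintf("  operating point: sens %.3f, spec %.3f, PPV %.3f @ prev %.3f\n",
                object@sensitivity, object@specificity, object@ppv,
                object@prevalence))
  cat("  consensus features:",
      if (length(object@consensusFeatures))
        paste(object@consensusFeatures, collapse = ", ") else "(none)", "\n")
})
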