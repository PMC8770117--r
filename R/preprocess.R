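#' Convert raw counts to counts per million
#'
#' Scales every sample (column) so its values sum to one million. Zero
#' counts map to zero; a sample with no nonzero count is degenerate and
#' raises an error naming it.
#'
#' @param x gene x sample matrix of raw counts, or a
#'   [CfrnaExperiment-class] (the `"cpm"` assay is added).
#' @param ... unused.
#' @return matrix of CPM values, or the experiment with a `"cpm"` assay.
#' @examples
#' computeCPM(matrix(c(1, 1, 2), 3, 1))
#' @export
#' @rdname computeCPM
setMethod("computeCPM", "matrix", function(x, ...) {
  tot <- colSums(x)
  if (any(tot == 0)) {
    bad <- colnames(x)[tot == 0]
    if (is.null(bad)) bad <- which(tot == 0)
    stop("degenerate sample(s) with all-zero counts: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sweep(x, 2, tot, "/") * 1e6
})

#' @rdname computeCPM
#' @export
setMethod("computeCPM", "CfrnaExperiment", function(x, ...) {
  assay(x, "cpm") <- computeCPM(assay(x, "counts"))
  x
})

#' Transform CPM values to log2(CPM + 1)
#'
#' @param x matrix of CPM values, or a [CfrnaExperiment-class] carrying a
#'   `"cpm"` assay (space mismatch otherwise).
#' @param ... unused.
#' @return matrix, or the experiment with a `"log2cpm1"` assay.
#' @export
#' @rdname logTransform
setMethod("logTransform", "matrix", function(x, ...) {
  if (any(x < 0)) stop("negative values: input is not a CPM matrix",
                       call. = FALSE)
  log2(x + 1)
})

#' @rdname logTransform
#' @export
setMethod("logTransform", "CfrnaExperiment", function(x, ...) {
  if (!("cpm" %in% assayNames(x)))
    stop("space mismatch: run computeCPM() first ('cpm' assay missing)",
         call. = FALSE)
  assay(x, "log2cpm1") <- logTransform(assay(x, "cpm"))
  x
})

#' Flag QC outlier samples by the k-standard-deviation rule
#'
#' A sample is flagged when any monitored metric deviates more than `k`
#' standard deviations from that metric's mean across samples (default
#' `k = 3`, the conventional outlier rule for sequencing QC panels such as
#' total reads, duplication rate and ACTB qPCR Ct). Zero-variance metrics
#' are skipped with a warning.
#'
#' @param qc data.frame of numeric per-sample metrics (rows = samples).
#' @param k standard-deviation multiplier.
#' @return list with `flag` (logical per sample), `z` (samples x metrics
#'   z-score matrix), `metrics` used, and `fractionFlagged`.
#' @examples
#' flagOutliers(data.frame(reads = c(0, 0, 0, 0, 100)))$flag
#' @export
flagOutliers <- function(qc, k = 3) {
  qc <- as.data.frame(qc)
  num <- vapply(qc, is.numeric, logical(1))
  qc <- qc[num]
  if (nrow(qc) < 3) stop("need at least 3 samples to flag outliers",
                         call. = FALSE)
  if (!ncol(qc)) stop("no numeric QC metrics supplied", call. = FALSE)
  keep <- vapply(qc, function(v) stats::sd(v) > 0, logical(1))
  if (any(!keep))
    warning("skipping zero-variance metric(s): ",
            paste(names(qc)[!keep], collapse = ", "), call. = FALSE)
  qc <- qc[keep]
  if (!ncol(qc))
    return(list(flag = rep(FALSE, nrow(qc)), z = NULL,
                metrics = character(), fractionFlagged = 0))
  z <- vapply(qc, function(v) (v - mean(v)) / stats::sd(v),
              numeric(nrow(qc)))
  z <- matrix(z, nrow = nrow(qc), dimnames = list(rownames(qc), names(qc)))
  flag <- apply(abs(z) > k, 1, any)
  list(flag = unname(flag), z = z, metrics = names(qc),
       fractionFlagged = mean(flag))
}

# Closed-form per-gene simple regression of each row of y on x.
# Returns intercept a and slope b minimising sum((y - a - b x)^2) per gene.
rowSimpleLm <- function(y, x) {
  xc <- x - mean(x)
  vx <- sum(xc^2)
  if (vx == 0) {
    b <- rep(0, nrow(y))
  } else {
    b <- as.vector(y %*% xc) / vx
  }
  a <- rowMeans(y) - b * mean(x)
  list(intercept = a, slope = b)
}

#' Fit the sequencing-depth correction
#'
#' For each gene, measures the linear relationship of log2(CPM+1)
#' expression to per-sample total counts on the training samples; the
#' correction replaces expression by the residual of that fit plus the
#' gene's training mean (so values stay on the log2-CPM scale).
#'
#' @param train genes x samples matrix in log2(CPM+1) space (training
#'   samples only).
#' @param totals per-sample total raw counts, same order as columns.
#' @return list with per-gene `intercept`, `slope`, `geneMean`; consumed by
#'   [fitCorrectionModel()].
#' @export
fitDepthCorrection <- function(train, totals) {
  if (ncol(train) < 3)
    stop("insufficient data: need at least 3 training samples", call. = FALSE)
  if (length(totals) != ncol(train))
    stop("totals must have one value per training sample", call. = FALSE)
  fit <- rowSimpleLm(train, totals)
  list(intercept = fit$intercept, slope = fit$slope,
       geneMean = rowMeans(train))
}

applyDepth <- function(depth, m, totals) {
  pred <- outer(depth$slope, totals) + depth$intercept
  m - pred + depth$geneMean
}

#' Learn the orthogonal cohort correction
#'
#' Implements the three-step linear correction: (1) on the training data,
#' remove the effect of the variable of interest (e.g. gestational age)
#' per gene via linear-model residuals; (2) estimate each cohort's mean of
#' those residuals — the cohort offsets; (3) applying the model subtracts
#' the offsets from (depth-corrected) data. Because the offsets are means
#' of variable-of-interest residuals, only the cohort effect orthogonal to
#' the variable of interest is corrected: a cohort that differs merely
#' because it samples a different gestational-age window is left alone,
#' while a genuine batch shift is removed. The variable-of-interest fit is
#' retained in the model only to define that orthogonality; it is never
#' applied to new data, so applying the model requires no covariates of the
#' target samples.
#'
#' @param train genes x samples matrix in log2(CPM+1) space.
#' @param voi numeric variable of interest per training sample (GA weeks).
#' @param cohort cohort label per training sample.
#' @param totals per-sample total raw counts (depth correction is fitted
#'   first and the cohort offsets are learned on depth-corrected data).
#' @return a [CorrectionModel-class].
#' @export
fitCorrectionModel <- function(train, voi, cohort, totals) {
  if (length(unique(cohort)) < 2)
    stop("need at least 2 cohorts in training", call. = FALSE)
  if (anyNA(voi))
    stop("variable of interest missing for some training samples",
         call. = FALSE)
  depth <- fitDepthCorrection(train, totals)
  dcorr <- applyDepth(depth, train, totals)
  vfit <- rowSimpleLm(dcorr, voi)
  resid <- dcorr - (outer(vfit$slope, voi) + vfit$intercept)
  cohorts <- sort(unique(cohort))
  offsets <- matrix(0, nrow(train), length(cohorts),
                    dimnames = list(rownames(train), cohorts))
  for (co in cohorts) {
    idx <- cohort == co
    if (sum(idx) < 2) {
      warning("cohort '", co, "' has fewer than 2 training samples; ",
              "offset set to 0", call. = FALSE)
    } else {
      offsets[, co] <- rowMeans(resid[, idx, drop = FALSE])
    }
  }
  gn <- rownames(train)
  if (is.null(gn)) gn <- paste0("G", seq_len(nrow(train)))
  new("CorrectionModel", genes = gn,
      depthIntercept = unname(depth$intercept),
      depthSlope = unname(depth$slope),
      geneMean = unname(depth$geneMean),
      voiIntercept = unname(vfit$intercept),
      voiSlope = unname(vfit$slope),
      offsets = offsets, cohorts = cohorts, fittedSpace = "log2cpm1")
}

#' Apply a learned correction to new samples
#'
#' Depth-corrects with the stored per-gene coefficients and subtracts the
#' stored cohort offset. The signature deliberately contains no
#' variable-of-interest argument: held-out gestational ages cannot leak
#' into the corrected data. Samples from cohorts unseen in training are
#' depth-corrected only (offset 0, with a warning).
#'
#' @param model a [CorrectionModel-class].
#' @param x genes x samples matrix in log2(CPM+1) space, or a
#'   [CfrnaExperiment-class] carrying a `"log2cpm1"` assay.
#' @param cohort cohort label per sample (taken from `colData` for an
#'   experiment).
#' @param totals per-sample total raw counts (recomputed from the
#'   `"counts"` assay for an experiment).
#' @param ... unused.
#' @return corrected matrix, or the experiment with a `"corrected"` assay.
#' @export
#' @rdname applyCorrection
setMethod("applyCorrection", signature("CorrectionModel", "matrix"),
  function(model, x, cohort, totals, ...) {
    if (nrow(x) != length(model@genes))
      stop("dimension mismatch: model covers ", length(model@genes),
           " genes, data has ", nrow(x), call. = FALSE)
    if (length(cohort) != ncol(x) || length(totals) != ncol(x))
      stop("cohort and totals must have one value per sample", call. = FALSE)
    depth <- list(intercept = model@depthIntercept,
                  slope = model@depthSlope, geneMean = model@geneMean)
    out <- applyDepth(depth, x, totals)
    unseen <- setdiff(unique(cohort), model@cohorts)
    if (length(unseen))
      warning("cohort(s) unseen in training, left depth-corrected only: ",
              paste(unseen, collapse = ", "), call. = FALSE)
    known <- cohort %in% model@cohorts
    if (any(known))
      out[, known] <- out[, known] - model@offsets[, cohort[known],
                                                   drop = FALSE]
    out
  })

#' @rdname applyCorrection
#' @export
setMethod("applyCorrection", signature("CorrectionModel", "CfrnaExperiment"),
  function(model, x, ...) {
    if (!("log2cpm1" %in% assayNames(x)))
      stop("space mismatch: run computeCPM() and logTransform() first",
           call. = FALSE)
    assay(x, "corrected") <- applyCorrection(
      model, assay(x, "log2cpm1"),
      cohort = colData(x)$cohort,
      totals = colSums(assay(x, "counts")))
    x
  })
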