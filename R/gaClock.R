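#' Filter the feature universe for the gestational-age clock
#'
#' Retains protein-coding genes (pseudogenes and non-coding genes are
#' excluded) whose median expression across the supplied (training) samples
#' is greater than zero.
#'
#' @param m genes x samples expression matrix (counts, CPM or log2 space —
#'   the positive-median criterion is equivalent in all of them).
#' @param geneData data.frame with `gene_id` and `biotype` covering every
#'   row of `m`.
#' @return character vector of retained gene ids.
#' @export
filterFeatures <- function(m, geneData) {
  if (!all(rownames(m) %in% geneData$gene_id))
    stop("gene annotation does not cover all genes in the matrix",
         call. = FALSE)
  bt <- geneData$biotype[match(rownames(m), geneData$gene_id)]
  med <- apply(m, 1, stats::median)
  keep <- bt == "protein_coding" & med > 0
  if (!any(keep))
    stop("no features pass the filter; review the biotype annotation and ",
         "expression threshold", call. = FALSE)
  rownames(m)[keep]
}

#' Stratified train/test split by gestational age
#'
#' Splits samples into train and test sets so that every gestational-age
#' stratum (equal-width bins over the observed range, 8 by default) is
#' represented proportionally on both sides. The per-stratum test count is
#' the rounded global test fraction; strata of size one go to training with
#' a warning, strata of size >= 2 contribute at least one sample to each
#' side.
#'
#' @param ga gestational age (weeks) per sample.
#' @param ids sample ids (defaults to names of `ga` or indices).
#' @param trainFraction fraction assigned to training (default 0.8).
#' @param nBins number of equal-width strata.
#' @param seed integer seed; equal seeds give equal splits.
#' @return `list(train =, test =)` of sample ids (disjoint, exhaustive).
#' @export
splitStratified <- function(ga, ids = NULL, trainFraction = 0.8, nBins = 8,
                            seed = 1) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie in (0, 1)", call. = FALSE)
  if (is.null(ids)) ids <- if (!is.null(names(ga))) names(ga)
                           else as.character(seq_along(ga))
  set.seed(seed)
  br <- seq(min(ga), max(ga), length.out = nBins + 1)
  stratum <- cut(ga, breaks = br, include.lowest = TRUE)
  test <- character()
  for (s in levels(stratum)) {
    member <- ids[stratum == s]
    ns <- length(member)
    if (ns == 0) next
    if (ns == 1) {
      warning("stratum ", s, " has a single sample; assigned to training",
              call. = FALSE)
      next
    }
    nTest <- round(ns * (1 - trainFraction))
    nTest <- min(max(nTest, 1), ns - 1)
    test <- c(test, sample(member, nTest))
  }
  list(train = setdiff(ids, test), test = test)
}

#' Cross-validated lasso path for gestational age
#'
#' Fits an L1-penalised linear model of gestational age (weeks) on
#' expression with k-fold cross-validation, mean absolute error as the loss,
#' over a log-spaced penalty grid auto-scaled from the data. Features are
#' centred and scaled internally using training statistics. Errors are
#' reported in days.
#'
#' @param X samples x genes matrix (training set).
#' @param y gestational age in weeks.
#' @param folds number of CV folds (default 10).
#' @param seed seed for fold assignment.
#' @param nPenalties length of the penalty grid.
#' @return object of class `"CvCurve"`: `penalty` (strictly decreasing),
#'   `cvError` and `cvSe` (mean absolute error, days), `folds`.
#' @export
fitLassoCv <- function(X, y, folds = 10, seed = 1, nPenalties = 100) {
  if (folds > nrow(X))
    stop("folds exceeds the number of training samples", call. = FALSE)
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = nrow(X)))
  fit <- glmnet::cv.glmnet(X, y, type.measure = "mae", foldid = foldid,
                           nlambda = nPenalties, standardize = TRUE)
  structure(list(penalty = fit$lambda,
                 cvError = fit$cvm * 7,
                 cvSe = fit$cvsd * 7,
                 folds = folds),
            class = "CvCurve")
}

#' @export
print.CvCurve <- function(x, ...) {
  cat("CvCurve:", length(x$penalty), "penalties,", x$folds, "folds\n")
  i <- which.min(x$cvError)
  cat(sprintf("  min CV MAE %.2f days at lambda %.4g\n", x$cvError[i],
              x$penalty[i]))
  invisible(x)
}

#' Select the penalty by the one-standard-error rule
#'
#' Returns the largest penalty whose mean cross-validation error does not
#' exceed the minimum error plus one standard error at the minimiser — the
#' most regularised model statistically indistinguishable from the best one
#' (Breiman's rule).
#'
#' @param curve a `"CvCurve"` from [fitLassoCv()], or any list with
#'   `penalty`, `cvError`, `cvSe`.
#' @return the selected penalty.
#' @export
selectOneSE <- function(curve) {
  if (!length(curve$penalty)) stop("empty CV curve", call. = FALSE)
  i <- which.min(curve$cvError)
  thr <- curve$cvError[i] + curve$cvSe[i]
  max(curve$penalty[curve$cvError <= thr])
}

#' Fit the final gestational-age model at a chosen penalty
#'
#' @param X samples x genes training matrix.
#' @param y gestational age (weeks).
#' @param penalty lasso penalty, normally from [selectOneSE()].
#' @param featureProvenance free-text note on how features were filtered.
#' @return a [GaClock-class].
#' @export
fitFinal <- function(X, y, penalty, featureProvenance = "unfiltered") {
  fit <- glmnet::glmnet(X, y, standardize = TRUE)
  cf <- as.matrix(stats::coef(fit, s = penalty))[, 1]
  nz <- cf[-1][cf[-1] != 0]
  new("GaClock", penalty = penalty, intercept = unname(cf[1]),
      coef = nz, featureProvenance = featureProvenance,
      trainSd = apply(X, 2, stats::sd))
}

#' Predict gestational age from a fitted clock
#'
#' @param object a [GaClock-class].
#' @param newdata samples x genes matrix containing every model gene.
#' @return predicted gestational age in weeks.
#' @export
setMethod("predict", "GaClock", function(object, newdata) {
  genes <- names(object@coef)
  missing <- setdiff(genes, colnames(newdata))
  if (length(missing))
    stop("newdata is missing model gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!length(genes)) return(rep(object@intercept, nrow(newdata)))
  as.vector(newdata[, genes, drop = FALSE] %*% object@coef) +
    object@intercept
})

#' Mean absolute error of gestational-age predictions, in days
#'
#' @param pred,truth gestational ages in weeks.
#' @return MAE in days (weeks x 7).
#' @export
evaluateMae <- function(pred, truth) mean(abs(pred - truth)) * 7

#' Refit the clock on its k most informative features
#'
#' Ranks features by absolute standardised weight (coefficient times
#' training s.d.), keeps the top `k`, and retrains the lasso on the reduced
#' feature set with the same cross-validation/one-SE procedure.
#'
#' @param model a fitted [GaClock-class].
#' @param X,y training data used for the refit.
#' @param k number of features to keep (default 50).
#' @param folds,seed passed to [fitLassoCv()].
#' @return a refitted [GaClock-class].
#' @export
refitTopK <- function(model, X, y, k = 50, folds = 10, seed = 1) {
  w <- abs(model@coef * model@trainSd[names(model@coef)])
  if (length(w) < k) {
    warning("model has fewer than ", k, " nonzero features; keeping all",
            call. = FALSE)
    k <- length(w)
  }
  keep <- names(sort(w, decreasing = TRUE))[seq_len(k)]
  Xk <- X[, keep, drop = FALSE]
  if (ncol(Xk) < 2)           # the lasso solver needs >= 2 columns
    Xk <- cbind(Xk, `.pad` = 0)
  curve <- fitLassoCv(Xk, y, folds = folds, seed = seed)
  out <- fitFinal(Xk, y, selectOneSE(curve),
                  featureProvenance = paste0("top-", k, " refit of: ",
                                             model@featureProvenance))
  out@coef <- out@coef[names(out@coef) != ".pad"]
  out@trainSd <- out@trainSd[names(out@trainSd) != ".pad"]
  out
}

#' Learning curve of the gestational-age clock
#'
#' Repeats the full split/CV/one-SE/refit/evaluate procedure at decreasing
#' training fractions with different random splits, quantifying how test
#' error depends on training-set size.
#'
#' @param X samples x genes matrix (all samples).
#' @param y gestational age (weeks).
#' @param fractions training fractions to evaluate.
#' @param repeats random splits per fraction (>= 2).
#' @param folds CV folds inside each training set.
#' @param seed base seed; split r at fraction f uses a deterministic
#'   derived seed.
#' @return data.frame with `fraction`, `trainSize`, `maeMean`, `maeSd`
#'   (days).
#' @export
learningCurve <- function(X, y, fractions = c(0.6, 0.7, 0.8), repeats = 3,
                          folds = 10, seed = 1) {
  if (repeats < 2) stop("repeats must be >= 2", call. = FALSE)
  rows <- list()
  for (f in fractions) {
    if (floor(f * nrow(X)) < folds) {
      warning("fraction ", f, " leaves fewer training samples than folds; ",
              "skipped", call. = FALSE)
      next
    }
    mae <- numeric(repeats); nTr <- integer(repeats)
    for (r in seq_len(repeats)) {
      sp <- splitStratified(y, ids = as.character(seq_along(y)),
                            trainFraction = f,
                            seed = seed + 1000 * r + round(100 * f))
      tr <- as.integer(sp$train); te <- as.integer(sp$test)
      curve <- fitLassoCv(X[tr, , drop = FALSE], y[tr], folds = folds,
                          seed = seed + r)
      mod <- fitFinal(X[tr, , drop = FALSE], y[tr], selectOneSE(curve))
      mae[r] <- evaluateMae(predict(mod, X[te, , drop = FALSE]), y[te])
      nTr[r] <- length(tr)
    }
    rows[[length(rows) + 1]] <- data.frame(
      fraction = f, trainSize = round(mean(nTr)),
      maeMean = mean(mae), maeSd = stats::sd(mae))
  }
  do.call(rbind, rows)
}

#' Sequential ANOVA variance decomposition of gestational age
#'
#' Decomposes the variance of true gestational age over the cfRNA
#' prediction (entered first) and the clinical covariates BMI, maternal age
#' and race (type-I sequential sums of squares), quantifying how much of
#' the signal is transcriptomic versus clinical. Fractions are non-negative
#' and sum to one (residual included). When covariates are orthogonal to
#' the prediction, the first fraction equals the squared correlation
#' between prediction and truth.
#'
#' @param truth observed gestational age (weeks).
#' @param prediction cfRNA-predicted gestational age (weeks).
#' @param covariates data.frame with `bmi`, `maternal_age`, `race`.
#' @param order term order; by default the prediction is entered first
#'   (order sensitivity can be probed by reordering).
#' @return object of class `"VarianceDecomposition"`: data.frame of `term`,
#'   `fraction`, with the residual as the last row.
#' @export
anovaVariance <- function(truth, prediction,
                          covariates = NULL,
                          order = c("prediction", "bmi", "maternal_age",
                                    "race")) {
  df <- data.frame(truth = truth, prediction = prediction)
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    if ("race" %in% names(cv)) {
      r <- factor(cv$race)
      cv$race <- stats::relevel(r, ref = names(which.max(table(r))))
    }
    df <- cbind(df, cv)
  }
  terms <- intersect(order, names(df))
  dropped <- character()
  for (t in terms) {
    v <- df[[t]]
    if ((is.numeric(v) && stats::sd(v) == 0) ||
        (is.factor(v) && nlevels(droplevels(v)) < 2)) {
      warning("covariate '", t, "' is constant; assigned fraction 0",
              call. = FALSE)
      dropped <- c(dropped, t)
    }
  }
  used <- setdiff(terms, dropped)
  fml <- stats::reformulate(used, response = "truth")
  av <- stats::anova(stats::lm(fml, data = df))
  ss <- av[["Sum Sq"]]
  frac <- ss / sum(ss)
  names(frac) <- rownames(av)
  out <- data.frame(term = c(terms, "residual"),
                    fraction = c(vapply(terms, function(t)
                      if (t %in% names(frac)) frac[[t]] else 0,
                      numeric(1)),
                      frac[["Residuals"]]),
                    row.names = NULL)
  class(out) <- c("VarianceDecomposition", "data.frame")
  out
}

#' @export
print.VarianceDecomposition <- function(x, ...) {
  cat("Variance explained (sequential ANOVA):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-14s %6.2f%%\n", x$term[i], 100 * x$fraction[i]))
  invisible(x)
}

#' Paired bootstrap comparison of two prediction vectors
#'
#' Tests whether adding covariates (or any model change) improves mean
#' absolute error, by bootstrapping the per-sample difference of absolute
#' errors.
#'
#' @param pred1,pred2 predictions to compare (weeks).
#' @param truth observed values (weeks).
#' @param B bootstrap replicates.
#' @param seed seed.
#' @return list with `maeDiffDays` (MAE1 - MAE2, days), percentile `ci`,
#'   and two-sided bootstrap `p`.
#' @export
compareModels <- function(pred1, pred2, truth, B = 1000, seed = 1) {
  set.seed(seed)
  d <- (abs(pred1 - truth) - abs(pred2 - truth)) * 7
  boot <- vapply(seq_len(B), function(b) mean(d[sample(length(d),
                                                       replace = TRUE)]),
                 numeric(1))
  p <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  list(maeDiffDays = mean(d),
       ci = unname(stats::quantile(boot, c(0.025, 0.975))),
       p = min(p, 1))
}
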