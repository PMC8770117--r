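#' Spearman screening of genes against case status
#'
#' For each gene, computes the average-rank Spearman correlation with the
#' 0/1 case label, a two-sided p-value via the t-approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))`, and Benjamini-Hochberg adjustment
#' across genes. Genes with adjusted p below `alpha` are retained. Constant
#' genes have undefined correlation and are skipped.
#'
#' @param X samples x genes matrix (cohort-corrected expression).
#' @param y 0/1 case labels.
#' @param alpha adjusted-p threshold (default 0.05); set `adjust = FALSE`
#'   to threshold raw p-values instead (used for the hypertension-subtype
#'   contrasts).
#' @param adjust apply BH adjustment (default TRUE).
#' @return data.frame with `gene`, `rho`, `p`, `adjP`, `retained`.
#' @export
spearmanScreen <- function(X, y, alpha = 0.05, adjust = TRUE) {
  if (min(table(y)) < 2)
    stop("need at least 2 samples per class", call. = FALSE)
  n <- nrow(X)
  const <- apply(X, 2, function(v) length(unique(v)) == 1)
  if (any(const))
    message(sum(const), " constant gene(s) skipped in the Spearman screen")
  Xr <- apply(X[, !const, drop = FALSE], 2, rank)
  yr <- rank(y)
  rho <- suppressWarnings(stats::cor(Xr, yr))[, 1]
  rho <- pmin(pmax(rho, -1), 1)
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  adjP <- if (adjust) stats::p.adjust(p, method = "BH") else p
  data.frame(gene = colnames(X)[!const], rho = rho, p = p, adjP = adjP,
             retained = adjP < alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

# standardize columns on training stats; zero-sd columns pass through.
scaleBy <- function(X, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(X, 2, center), 2, scale, "/")
}

# screen on the training part, fit unpenalised logistic regression on the
# retained genes (standardised on training statistics), return a predictor.
fitFoldClassifier <- function(Xtr, ytr, alpha) {
  scr <- spearmanScreen(Xtr, ytr, alpha = alpha)
  genes <- scr$gene[scr$retained]
  if (!length(genes)) {
    # no information: emit a fold-independent uninformative probability.
    # (The fold-training prevalence would anti-correlate with the held-out
    # label across LOOCV folds and bias null AUC below 0.5.)
    return(list(genes = character(),
                predict = function(Xnew) rep(0.5, nrow(Xnew))))
  }
  Xs <- Xtr[, genes, drop = FALSE]
  ctr <- colMeans(Xs); scl <- apply(Xs, 2, stats::sd)
  df <- as.data.frame(scaleBy(Xs, ctr, scl))
  names(df) <- make.names(genes)
  df$y <- ytr
  fit <- suppressWarnings(stats::glm(y ~ ., data = df,
                                     family = stats::binomial()))
  list(genes = genes, predict = function(Xnew) {
    nd <- as.data.frame(scaleBy(Xnew[, genes, drop = FALSE], ctr, scl))
    names(nd) <- make.names(genes)
    as.vector(suppressWarnings(stats::predict(fit, nd, type = "response")))
  })
}

#' Leave-one-out cross-validated pre-eclampsia classifier
#'
#' For every held-out sample: the Spearman screen runs on the remaining
#' n-1 samples only, an unpenalised logistic regression is fitted on the
#' retained genes (standardised on fold-training statistics), and the
#' held-out probability is recorded. Feature selection therefore never sees
#' the held-out label — the nested design that keeps out-of-fold
#' probabilities honest. Consensus features are the genes retained in every
#' fold.
#'
#' @param X samples x genes matrix (cohort-corrected expression).
#' @param y 0/1 case labels (n >= 10, both classes in every fold's
#'   training part).
#' @param alpha screening threshold.
#' @param sensTarget operating sensitivity for the threshold metrics.
#' @param prevalence prevalence used in the PPV arithmetic (defaults to the
#'   empirical case fraction).
#' @return a [ClassifierReport-class].
#' @export
loocvFit <- function(X, y, alpha = 0.05, sensTarget = 0.75,
                     prevalence = mean(y)) {
  n <- nrow(X)
  if (n < 10) stop("need at least 10 samples", call. = FALSE)
  probs <- numeric(n)
  foldFeatures <- vector("list", n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2)
      stop("fold ", i, " training part contains a single class",
           call. = FALSE)
    cl <- fitFoldClassifier(X[-i, , drop = FALSE], ytr, alpha)
    foldFeatures[[i]] <- cl$genes
    probs[i] <- cl$predict(X[i, , drop = FALSE])
  }
  probs <- pmin(pmax(probs, 0), 1)
  consensus <- Reduce(intersect, foldFeatures)
  roc <- rocAuc(probs, y)
  op <- thresholdAtSensitivity(probs, y, target = sensTarget)
  new("ClassifierReport",
      probabilities = probs, labels = as.numeric(y),
      foldFeatures = foldFeatures,
      consensusFeatures = as.character(consensus),
      roc = roc$curve, auc = roc$auc, aucCi = c(NA_real_, NA_real_),
      threshold = op$threshold, sensitivity = op$sensitivity,
      specificity = op$specificity,
      ppv = ppv(op$sensitivity, op$specificity, prevalence),
      prevalence = prevalence)
}

#' ROC curve and AUC
#'
#' AUC is computed as the normalised Mann-Whitney U statistic (ties count
#' one half); the curve enumerates all distinct probability thresholds.
#'
#' @param probs predicted probabilities.
#' @param y 0/1 labels (both classes present).
#' @return list with `curve` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
rocAuc <- function(probs, y) {
  y <- as.numeric(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(probs)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(probs), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(probs[y == 0] >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(probs[y == 1] >= t), numeric(1)))
  list(curve = curve, auc = auc)
}

#' Operating threshold at a target sensitivity
#'
#' Chooses the largest probability threshold achieving at least the target
#' sensitivity on out-of-fold probabilities (samples with probability at or
#' above the threshold test positive) and reports the realised sensitivity
#' and specificity.
#'
#' @param probs out-of-fold probabilities.
#' @param y 0/1 labels.
#' @param target sensitivity target (default 0.75).
#' @return list with `threshold`, `sensitivity`, `specificity`.
#' @export
thresholdAtSensitivity <- function(probs, y, target = 0.75) {
  y <- as.numeric(y)
  if (!any(y == 1) || !any(y == 0))
    stop("both classes must be present", call. = FALSE)
  cand <- sort(unique(probs), decreasing = TRUE)
  for (t in cand) {
    sens <- mean(probs[y == 1] >= t)
    if (sens >= target)
      return(list(threshold = t, sensitivity = sens,
                  specificity = mean(probs[y == 0] < t)))
  }
  warning("sensitivity target unreachable; threshold set at the minimum ",
          "probability", call. = FALSE)
  t <- min(probs)
  list(threshold = t, sensitivity = mean(probs[y == 1] >= t),
       specificity = mean(probs[y == 0] < t))
}

#' Positive predictive value from sensitivity, specificity and prevalence
#'
#' `PPV = (sens * prev) / ((sens * prev) + ((1 - spec) * (1 - prev)))`.
#' When sensitivity, specificity and prevalence are measured on one sample,
#' this equals TP / (TP + FP) exactly.
#'
#' @param sensitivity,specificity,prevalence values in `[0, 1]`.
#' @return the positive predictive value.
#' @examples
#' ppv(0.75, 0.9, 0.137)
#' @export
ppv <- function(sensitivity, specificity, prevalence) {
  args <- c(sensitivity = sensitivity, specificity = specificity,
            prevalence = prevalence)
  if (any(args < 0 | args > 1))
    stop("all arguments must lie in [0, 1]", call. = FALSE)
  denom <- sensitivity * prevalence +
    (1 - specificity) * (1 - prevalence)
  if (denom == 0)
    stop("PPV undefined: no positive test results (sensitivity 0 and ",
         "specificity 1)", call. = FALSE)
  sensitivity * prevalence / denom
}

#' Stratified bootstrap confidence interval for a performance metric
#'
#' Resamples (probs, y) within each class `B` times and reports the
#' percentile 95 percent interval and standard deviation of the metric.
#'
#' @param metric function of `(probs, y)` returning a scalar (e.g.
#'   `function(p, y) rocAuc(p, y)$auc`).
#' @param probs,y out-of-fold probabilities and 0/1 labels.
#' @param B bootstrap replicates (>= 100).
#' @param seed seed.
#' @return list with `point`, `ciLow`, `ciHigh`, `sd`.
#' @export
bootstrapCi <- function(metric, probs, y, B = 1000, seed = 1) {
  if (B < 100) stop("B must be >= 100", call. = FALSE)
  set.seed(seed)
  i1 <- which(y == 1); i0 <- which(y == 0)
  vals <- vapply(seq_len(B), function(b) {
    idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
    metric(probs[idx], y[idx])
  }, numeric(1))
  q <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
  list(point = metric(probs, y), ciLow = q[1], ciHigh = q[2],
       sd = stats::sd(vals))
}

# stratified k-fold assignment
stratifiedFolds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' Learning curve over cross-validation fold counts
#'
#' Runs the identical screen-then-logistic pipeline at 2- to 9-fold
#' stratified cross-validation (training-set size grows with k) and appends
#' leave-one-out as the terminal point, reporting the out-of-fold AUC per
#' configuration.
#'
#' @param X,y as in [loocvFit()].
#' @param ks fold counts (default 2:9).
#' @param alpha screening threshold.
#' @param seed seed for fold assignment.
#' @param includeLoocv append the LOOCV point (default TRUE).
#' @return data.frame with `k` (NA for LOOCV) and `auc`.
#' @export
learningCurveKfold <- function(X, y, ks = 2:9, alpha = 0.05, seed = 1,
                               includeLoocv = TRUE) {
  if (any(ks > nrow(X) / 2))
    stop("fold count exceeds n/2", call. = FALSE)
  rows <- lapply(ks, function(k) {
    fold <- stratifiedFolds(y, k, seed + k)
    probs <- numeric(length(y))
    for (f in seq_len(k)) {
      tr <- fold != f
      cl <- fitFoldClassifier(X[tr, , drop = FALSE], y[tr], alpha)
      probs[!tr] <- cl$predict(X[!tr, , drop = FALSE])
    }
    data.frame(k = k, auc = rocAuc(pmin(pmax(probs, 0), 1), y)$auc)
  })
  out <- do.call(rbind, rows)
  if (includeLoocv) {
    lo <- loocvFit(X, y, alpha = alpha)
    out <- rbind(out, data.frame(k = NA, auc = lo@auc))
  }
  out
}

#' Kaplan-Meier comparison of delivery timing between test groups
#'
#' Product-limit curves of gestational age at delivery for test-positive
#' versus test-negative samples with a two-group log-rank test. All
#' deliveries are observed events by default (no censoring). Spontaneous
#' preterm deliveries can be excluded.
#'
#' @param deliveryGa gestational age at delivery (weeks).
#' @param group logical or factor test-positive indicator.
#' @param exclude optional logical; samples to drop (e.g. sPTB flag).
#' @param event optional 0/1 event indicator (default all observed).
#' @return list with `fit` (a [survival::survfit] object), `chisq`, `p`,
#'   `n`.
#' @export
kmLogrank <- function(deliveryGa, group, exclude = NULL, event = NULL) {
  if (!is.null(exclude)) {
    deliveryGa <- deliveryGa[!exclude]
    group <- group[!exclude]
    if (!is.null(event)) event <- event[!exclude]
  }
  if (is.null(event)) event <- rep(1, length(deliveryGa))
  group <- factor(group)
  if (any(table(group) < 2))
    stop("need at least 2 samples per group", call. = FALSE)
  df <- data.frame(time = deliveryGa, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  list(fit = fit, chisq = sd$chisq, p = p, n = nrow(df))
}

#' Hypertension-subtype specificity of the pre-eclampsia signature
#'
#' Screens chronic-hypertension and gestational-hypertension controls
#' against normotensive controls (two-sided Spearman, raw p < 0.05) and
#' reports the overlap of those gene lists with the pre-eclampsia retained
#' genes — an empty overlap indicates the signature is specific to
#' placentally driven hypertension rather than hypertension per se.
#'
#' @param X samples x genes matrix over the non-case samples.
#' @param substrata character per sample: `"normotensive"`,
#'   `"chronic_htn"`, `"gestational_htn"` (others ignored).
#' @param peGenes character vector of pre-eclampsia retained genes.
#' @param alpha raw-p threshold for the subtype contrasts.
#' @param minN minimum substratum size; smaller contrasts are skipped with
#'   a warning.
#' @return list with per-contrast gene lists and `overlap`; `applicable`
#'   is FALSE when no substrata were usable.
#' @export
subtypeSpecificity <- function(X, substrata, peGenes, alpha = 0.05,
                               minN = 5) {
  contrasts <- list(chronic_htn = "chronic_htn",
                    gestational_htn = "gestational_htn")
  norm <- substrata == "normotensive"
  out <- list(applicable = FALSE, contrasts = list(),
              overlap = character())
  if (sum(norm) < minN) {
    warning("fewer than ", minN, " normotensive samples; not applicable",
            call. = FALSE)
    return(out)
  }
  hits <- character()
  for (nm in names(contrasts)) {
    grp <- substrata == contrasts[[nm]]
    if (sum(grp) < minN) {
      warning("substratum '", nm, "' has fewer than ", minN,
              " samples; contrast skipped", call. = FALSE)
      next
    }
    sel <- norm | grp
    scr <- spearmanScreen(X[sel, , drop = FALSE], as.numeric(grp[sel]),
                          alpha = alpha, adjust = FALSE)
    out$contrasts[[nm]] <- scr$gene[scr$retained]
    hits <- union(hits, scr$gene[scr$retained])
    out$applicable <- TRUE
  }
  out$overlap <- intersect(hits, peGenes)
  out
}

#' Robustness of the classifier to excluding spontaneous preterm births
#'
#' Re-runs the full leave-one-out pipeline after removing sPTB-flagged
#' non-cases and reports the AUC beside the full-cohort value.
#'
#' @param X,y as in [loocvFit()].
#' @param sptb logical per sample; flagged non-cases are removed (flagged
#'   cases are retained).
#' @param ... passed to [loocvFit()].
#' @return list with `fullAuc`, `reducedAuc`, `reducedReport`, `nRemoved`.
#' @export
robustnessExcludeSptb <- function(X, y, sptb, ...) {
  full <- loocvFit(X, y, ...)
  drop <- sptb & y == 0
  if (!any(y[!drop] == 0))
    stop("excluding sPTB samples empties the non-case set", call. = FALSE)
  red <- if (any(drop)) loocvFit(X[!drop, , drop = FALSE], y[!drop], ...)
         else full
  list(fullAuc = full@auc, reducedAuc = red@auc, reducedReport = red,
       nRemoved = sum(drop))
}

#' Quantile-quantile table of screening p-values
#'
#' Ranked observed Spearman p-values against uniform order-statistic
#' expectations, the reporting utility behind p-value QQ displays.
#'
#' @param p vector of p-values.
#' @return data.frame with `expected` and `observed` (both ascending).
#' @export
qqPvalues <- function(p) {
  n <- length(p)
  data.frame(expected = (seq_len(n) - 0.5) / n, observed = sort(p))
}
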