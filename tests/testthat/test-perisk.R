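test_that("Spearman screen matches rank arithmetic and cor.test", {
  scr <- spearmanScreen(cbind(g = c(1, 2, 3, 4), noise = c(2, 1, 2, 1)),
                        y = c(0, 0, 1, 1), alpha = 0.05)
  expect_equal(scr$rho[scr$gene == "g"], 0.894, tolerance = 1e-3)
  # perfect separator
  y <- rep(c(0, 1), each = 10)
  X <- cbind(sep = y, junk = rnorm(20))
  scr2 <- spearmanScreen(X, y)
  expect_equal(abs(scr2$rho[scr2$gene == "sep"]), 1)
  expect_true(scr2$retained[scr2$gene == "sep"])
  # agreement with cor.test's rho and t-approximation p
  set.seed(21)
  X3 <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("g", 1:5)))
  y3 <- rep(0:1, 15)
  scr3 <- spearmanScreen(X3, y3)
  for (g in colnames(X3)) {
    ct <- suppressWarnings(cor.test(X3[, g], y3, method = "spearman"))
    expect_equal(scr3$rho[scr3$gene == g], unname(ct$estimate),
                 tolerance = 1e-10)
  }
  # constant genes are skipped
  expect_message(scr4 <- spearmanScreen(cbind(c = rep(1, 20), ok = rnorm(20)),
                                        y), "constant")
  expect_false("c" %in% scr4$gene)
})

test_that("null genes survive BH screening only rarely", {
  set.seed(22)
  X <- matrix(rnorm(40 * 1000), 40, 1000,
              dimnames = list(NULL, paste0("g", 1:1000)))
  y <- rep(0:1, 20)
  scr <- spearmanScreen(X, y)
  expect_lte(sum(scr$retained), 5)
})

test_that("AUC equals the normalised Mann-Whitney statistic", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(rocAuc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))$auc, 0)
  expect_equal(rocAuc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))$auc, 0.75)
  expect_error(rocAuc(c(0.1, 0.2), c(1, 1)), "both classes")
  curve <- rocAuc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))$curve
  expect_equal(curve$tpr[1], 0)
  expect_equal(curve$tpr[nrow(curve)], 1)
  expect_true(all(diff(curve$fpr) >= 0) && all(diff(curve$tpr) >= 0))
})

test_that("operating threshold reaches the sensitivity target", {
  probs <- c(0.9, 0.8, 0.7, 0.1, 0.5, 0.4, 0.3, 0.2)
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  op <- thresholdAtSensitivity(probs, y, target = 0.75)
  expect_gte(op$sensitivity, 0.75)
  expect_gte(sum(probs[y == 1] >= op$threshold), 3)
  all_in <- thresholdAtSensitivity(probs, y, target = 1)
  expect_lte(all_in$threshold, min(probs[y == 1]))
  expect_equal(all_in$sensitivity, 1)
  expect_warning(thresholdAtSensitivity(rep(0.5, 8), y, target = 0.75),
                 NA)  # ties still reach the target at the unique threshold
})

test_that("PPV follows the closed formula and the confusion-matrix identity", {
  expect_equal(ppv(1, 1, 0.5), 1)
  expect_equal(ppv(0.75, 0.9, 0.137), 0.10275 / 0.18905)
  expect_error(ppv(0, 1, 0.3), "undefined")
  expect_error(ppv(1.2, 0.5, 0.5), "\\[0, 1\\]")
  set.seed(23)
  for (i in 1:25) {
    tp <- sample(1:50, 1); fn <- sample(1:50, 1)
    fp <- sample(1:50, 1); tn <- sample(1:50, 1)
    n <- tp + fn + fp + tn
    expect_equal(ppv(tp / (tp + fn), tn / (tn + fp), (tp + fn) / n),
                 tp / (tp + fp), tolerance = 1e-12)
  }
})

test_that("bootstrap CIs are deterministic and degenerate when the metric is", {
  probs <- c(0.9, 0.95, 0.85, 0.1, 0.2, 0.15)
  y <- c(1, 1, 1, 0, 0, 0)
  auc <- function(p, yy) rocAuc(p, yy)$auc
  ci <- bootstrapCi(auc, probs, y, B = 200, seed = 1)
  expect_equal(ci$point, 1)
  expect_equal(c(ci$ciLow, ci$ciHigh), c(1, 1))
  expect_equal(ci$sd, 0)
  ci2 <- bootstrapCi(auc, probs, y, B = 200, seed = 1)
  expect_identical(ci, ci2)
  expect_error(bootstrapCi(auc, probs, y, B = 10), "100")
})

test_that("LOOCV probabilities equal a hand-built single-fold refit", {
  set.seed(24)
  n <- 30
  y <- rep(c(0, 1), c(22, 8))
  X <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("g", 1:20)))
  X[y == 1, 1:2] <- X[y == 1, 1:2] + 2.5
  rep <- loocvFit(X, y, alpha = 0.05)
  i <- 5
  scr <- spearmanScreen(X[-i, ], y[-i], alpha = 0.05)
  genes <- scr$gene[scr$retained]
  expect_identical(rep@foldFeatures[[i]], genes)
  Xs <- X[-i, genes, drop = FALSE]
  ctr <- colMeans(Xs); scl <- apply(Xs, 2, sd)
  df <- as.data.frame(scale(Xs, ctr, scl)); names(df) <- make.names(genes)
  df$y <- y[-i]
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  nd <- as.data.frame(matrix((X[i, genes] - ctr) / scl, 1,
                             dimnames = list(NULL, make.names(genes))))
  manual <- unname(predict(fit, nd, type = "response"))
  expect_equal(rep@probabilities[i], manual, tolerance = 1e-10)
  expect_true(all(rep@consensusFeatures %in% genes))
})

test_that("a strong injected effect yields the panel as consensus features", {
  cfg <- smallConfig(nc = 2, n = 60, genes = 200, seed = 25,
                     pe_prevalence = 0.2, pe_effect = 1.2,
                     cohort_offset_sd = 0.3)
  sim <- simulateCohorts(cfg)
  ce <- preprocessExperiment(sim$experiment, outlierK = NULL)
  X <- t(assay(ce, "corrected"))
  y <- as.numeric(colData(ce)$outcome == "PE")
  rep <- loocvFit(X, y)
  panel <- simTruth(ce)$pePanel$gene_id
  expect_gte(length(intersect(rep@consensusFeatures, panel)), 6)
  expect_gt(rep@auc, 0.8)
})

test_that("k-fold learning curve ends at the LOOCV point", {
  set.seed(26)
  n <- 40
  y <- rep(c(0, 1), c(28, 12))
  X <- matrix(rnorm(n * 30), n, 30, dimnames = list(NULL, paste0("g", 1:30)))
  X[y == 1, 1] <- X[y == 1, 1] + 3
  lc <- learningCurveKfold(X, y, ks = c(2, 5), seed = 2)
  expect_equal(nrow(lc), 3)
  expect_true(is.na(lc$k[3]))
  expect_equal(lc$auc[3], loocvFit(X, y)@auc)
  expect_gt(lc$auc[3], 0.8)
  expect_error(learningCurveKfold(X, y, ks = 30), "n/2")
})

test_that("log-rank comparison detects earlier delivery in test positives", {
  set.seed(27)
  times <- rnorm(30, 39, 1)
  same <- kmLogrank(c(times, times), rep(c(TRUE, FALSE), each = 30))
  expect_gt(same$p, 0.99)   # literally identical groups: curves coincide
  shifted <- kmLogrank(c(rnorm(200, 36, 1.5), rnorm(200, 39, 1.5)),
                       rep(c("pos", "neg"), each = 200))
  expect_lt(shifted$p, 0.01)
  single <- kmLogrank(c(rep(38, 3), rep(40, 3)), rep(c("a", "b"), each = 3))
  expect_equal(length(unique(summary(single$fit)$time)), 2)
  expect_error(kmLogrank(1:5, c("a", "a", "a", "a", "b")), "per group")
  # exclusion drops flagged samples from both the curves and the test
  ex <- kmLogrank(c(rnorm(50, 39, 1), rnorm(50, 39, 1), rep(30, 10)),
                  c(rep(c(TRUE, FALSE), each = 50), rep(FALSE, 10)),
                  exclude = c(rep(FALSE, 100), rep(TRUE, 10)))
  expect_equal(ex$n, 100)
})

test_that("hypertension subtypes do not share the pre-eclampsia signature", {
  set.seed(28)
  n <- 90
  strata <- rep(c("normotensive", "chronic_htn", "gestational_htn"),
                each = 30)
  X <- matrix(rnorm(n * 50), n, 50, dimnames = list(NULL, paste0("g", 1:50)))
  peGenes <- c("g1", "g2")
  out <- subtypeSpecificity(X, strata, peGenes)
  expect_true(out$applicable)
  expect_length(out$overlap, 0)
  # a gene shifted in chronic HTN that is also in the PE list must overlap
  X2 <- X
  X2[strata == "chronic_htn", 1] <- X2[strata == "chronic_htn", 1] + 4
  out2 <- subtypeSpecificity(X2, strata, peGenes)
  expect_true("g1" %in% out2$overlap)
  expect_warning(out3 <- subtypeSpecificity(X, rep("other", n), peGenes),
                 "not applicable")
  expect_false(out3$applicable)
})

test_that("excluding spontaneous preterm births leaves a null exclusion unchanged", {
  set.seed(29)
  n <- 40
  y <- rep(c(0, 1), c(30, 10))
  X <- matrix(rnorm(n * 25), n, 25, dimnames = list(NULL, paste0("g", 1:25)))
  X[y == 1, 1] <- X[y == 1, 1] + 3
  none <- robustnessExcludeSptb(X, y, sptb = rep(FALSE, n))
  expect_equal(none$fullAuc, none$reducedAuc)
  expect_equal(none$nRemoved, 0)
  some <- robustnessExcludeSptb(X, y, sptb = c(rep(TRUE, 5), rep(FALSE, 35)))
  expect_equal(some$nRemoved, 5)
  expect_lt(abs(some$reducedAuc - some$fullAuc), 0.15)
  expect_error(robustnessExcludeSptb(X, y, sptb = y == 0), "empties")
})

test_that("QQ table pairs sorted p-values with uniform order statistics", {
  q <- qqPvalues(c(0.5, 0.1, 0.9))
  expect_equal(q$observed, c(0.1, 0.5, 0.9))
  expect_equal(q$expected, (1:3 - 0.5) / 3)
})
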