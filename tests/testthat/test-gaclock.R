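test_that("feature filter keeps positive-median protein-coding genes", {
  m <- rbind(a = c(0, 0, 1), b = c(0, 1, 2), c = c(2, 2, 2))
  ann <- data.frame(gene_id = c("a", "b", "c"),
                    biotype = c("protein_coding", "protein_coding",
                                "protein_coding"))
  expect_setequal(filterFeatures(m, ann), c("b", "c"))
  annPseudo <- transform(ann, biotype = "pseudogene")
  expect_error(filterFeatures(m, annPseudo), "no features")
  # brute-force recount on simulated data
  sim <- simulateCohorts(smallConfig(nc = 2, n = 20, genes = 200, seed = 4))
  mm <- log2cpm(sim$experiment)
  ann2 <- as.data.frame(rowData(sim$experiment))
  got <- filterFeatures(mm, ann2)
  manual <- character()
  for (g in rownames(mm))
    if (ann2$biotype[ann2$gene_id == g] == "protein_coding" &&
        median(mm[g, ]) > 0) manual <- c(manual, g)
  expect_setequal(got, manual)
})

test_that("stratified splits are proportional, disjoint and reproducible", {
  ga <- rep(seq(10.5, 29.5, by = 2), each = 10)  # 100 samples, 10 strata
  sp <- splitStratified(ga, ids = as.character(1:100),
                        trainFraction = 0.8, nBins = 10, seed = 1)
  expect_length(sp$train, 80)
  expect_length(sp$test, 20)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), as.character(1:100))
  perStratum <- table(cut(ga[as.integer(sp$test)], 10))
  expect_true(all(perStratum == 2))
  sp2 <- splitStratified(ga, ids = as.character(1:100),
                         trainFraction = 0.8, nBins = 10, seed = 1)
  expect_identical(sp, sp2)
  # skewed strata {50, 5, 45} at 0.8 give test counts {10, 1, 9}
  ga3 <- c(rep(10, 50), rep(20, 5), rep(30, 45))
  sp3 <- splitStratified(ga3, ids = as.character(1:100),
                         trainFraction = 0.8, nBins = 3, seed = 2)
  tcount <- table(ga3[as.integer(sp3$test)])
  expect_equal(unname(c(tcount)), c(10, 1, 9))
})

test_that("one-SE rule picks the largest penalty within one SE of the best", {
  curve <- list(penalty = c(1, 0.1, 0.01),
                cvError = c(8.4, 8.0, 8.2),
                cvSe = c(0.3, 0.5, 0.4))
  expect_equal(selectOneSE(curve), 1)
  incr <- list(penalty = c(1, 0.1, 0.01), cvError = c(9, 8.5, 8),
               cvSe = c(0.1, 0.1, 0.1))
  expect_equal(selectOneSE(incr), 0.01)  # only the minimum qualifies
  flat <- list(penalty = c(1, 0.1, 0.01), cvError = rep(5, 3),
               cvSe = rep(0.2, 3))
  expect_equal(selectOneSE(flat), 1)
  expect_error(selectOneSE(list(penalty = numeric(), cvError = numeric(),
                                cvSe = numeric())), "empty")
})

test_that("the clock interpolates noiseless signal and degrades gracefully", {
  set.seed(11)
  n <- 80
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("g", 1:5)))
  y <- 20 + 2 * X[, 1]
  curve <- fitLassoCv(X, y, folds = 5, seed = 1)
  expect_lt(min(curve$cvError), 0.5)  # near-zero MAE at small penalties
  mod <- fitFinal(X, y, min(curve$penalty))
  expect_lt(evaluateMae(predict(mod, X), y), 0.5)
  # intercept-only model: MAE equals mean absolute deviation from the mean
  big <- fitFinal(X, y, max(curve$penalty) * 10)
  expect_equal(nFeatures(big), 0)
  expect_equal(evaluateMae(predict(big, X), y),
               mean(abs(y - mean(y))) * 7)
  expect_error(predict(mod, X[, 2:5, drop = FALSE]), "g1")
  expect_error(fitLassoCv(X, y, folds = 200), "folds")
})

test_that("predictions ignore gene order and all-zero padding genes", {
  set.seed(12)
  X <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("g", 1:8)))
  y <- 15 + X %*% c(3, -2, 1, 0, 0, 0, 0, 0) + rnorm(60, 0, 0.1)
  mod <- fitFinal(X, as.vector(y), 0.01)
  p1 <- predict(mod, X)
  shuffled <- X[, sample(ncol(X))]
  expect_equal(predict(mod, shuffled), p1)
  padded <- cbind(X, z1 = 0, z2 = 0)
  expect_equal(predict(mod, padded), p1)
})

test_that("top-k refit keeps the largest standardised weights", {
  set.seed(13)
  X <- matrix(rnorm(100 * 6), 100, 6,
              dimnames = list(NULL, paste0("g", 1:6)))
  y <- 10 + 2 * X[, 1] + 0.1 * X[, 2] + rnorm(100, 0, 0.05)
  mod <- fitFinal(X, y, 0.01)
  one <- refitTopK(mod, X, y, k = 1, folds = 5, seed = 2)
  expect_true("g1" %in% names(one@coef) || nFeatures(one) == 0)
  expect_false("g2" %in% names(one@coef))
  expect_warning(all6 <- refitTopK(mod, X, y, k = 50, folds = 5, seed = 2),
                 "fewer than")
  expect_true(all(names(all6@coef) %in% names(mod@coef)))
})

test_that("learning curves are deterministic and improve with training size", {
  set.seed(14)
  n <- 120
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("g", 1:10)))
  y <- 20 + 3 * X[, 1] - 2 * X[, 2]      # zero-noise signal
  lc <- learningCurve(X, y, fractions = c(0.5, 0.65, 0.8), repeats = 2,
                      folds = 5, seed = 3)
  lc2 <- learningCurve(X, y, fractions = c(0.5, 0.65, 0.8), repeats = 2,
                       folds = 5, seed = 3)
  expect_identical(lc, lc2)
  expect_true(all(diff(lc$maeMean) <= 0.5))  # non-increasing within MC error
  # pure noise stays at the baseline error regardless of fraction
  set.seed(15)
  yn <- runif(n, 10, 40)
  lcn <- learningCurve(X, yn, fractions = c(0.5, 0.8), repeats = 2,
                       folds = 5, seed = 4)
  base <- mean(abs(yn - mean(yn))) * 7
  expect_true(all(abs(lcn$maeMean - base) < 0.35 * base))
})

test_that("variance decomposition attributes signal to the right terms", {
  set.seed(16)
  n <- 200
  truth <- runif(n, 10, 35)
  cov <- data.frame(bmi = rnorm(n, 27, 5), maternal_age = rnorm(n, 30, 5),
                    race = sample(c("a", "b", "c"), n, TRUE))
  vd <- anovaVariance(truth, truth, cov)
  expect_equal(vd$fraction[vd$term == "prediction"], 1, tolerance = 1e-6)
  expect_true(all(vd$fraction >= -1e-12))
  expect_equal(sum(vd$fraction), 1, tolerance = 1e-12)
  # race fully determines truth, prediction is random
  race <- sample(c("a", "b", "c"), n, TRUE)
  truth2 <- c(a = 12, b = 22, c = 32)[race] + rnorm(n, 0, 0.1)
  vd2 <- anovaVariance(truth2, rnorm(n),
                       data.frame(bmi = rnorm(n), maternal_age = rnorm(n),
                                  race = race))
  expect_gt(vd2$fraction[vd2$term == "race"], 0.9)
  # orthogonal covariates: first fraction equals squared correlation
  pred <- truth + rnorm(n, 0, 3)
  vd3 <- anovaVariance(truth, pred, NULL, order = "prediction")
  expect_equal(vd3$fraction[vd3$term == "prediction"],
               cor(pred, truth)^2, tolerance = 1e-10)
  expect_warning(anovaVariance(truth, pred,
                               data.frame(bmi = rep(1, n))), "constant")
})

test_that("paired bootstrap comparison is deterministic and calibrated on equal models", {
  set.seed(17)
  truth <- runif(100, 10, 35)
  p1 <- truth + rnorm(100, 0, 2)
  p2 <- truth + rnorm(100, 0, 2)
  a <- compareModels(p1, p2, truth, B = 500, seed = 5)
  b <- compareModels(p1, p2, truth, B = 500, seed = 5)
  expect_identical(a, b)
  expect_gt(a$p, 0.01)  # no systematic difference between the two
})
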