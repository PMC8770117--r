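test_that("GMT files parse, reject duplicates, and round-trip", {
  path <- tempfile(fileext = ".gmt")
  writeLines("S1\tdesc\tG1\tG2", path)
  gs <- readGmt(path)
  expect_equal(gs[["S1"]], c("G1", "G2"))
  expect_equal(attr(gs, "description")[["S1"]], "desc")
  writeLines(c("S1\td\tG1\tG2", "S1\td\tG3"), path)
  expect_error(readGmt(path), "duplicate")
  writeLines("S1\tonly-two-fields", path)
  expect_error(readGmt(path), "malformed")
  # round-trip 20 random sets
  set.seed(3)
  sets <- lapply(1:20, function(i)
    paste0("G", sample(1000, sample(3:30, 1))))
  names(sets) <- paste0("RS", 1:20)
  coll <- newGeneSetCollection(sets, paste("set", 1:20))
  writeGmt(coll, path)
  back <- readGmt(path)
  expect_identical(unclass(back), unclass(coll))
})

test_that("partition scores are member-gene CPM sums", {
  set.seed(4)
  cpm <- computeCPM(matrix(rpois(50 * 6, 30), 50, 6,
                           dimnames = list(paste0("G", 1:50),
                                           paste0("S", 1:6))))
  all <- newGeneSetCollection(list(ALL = rownames(cpm)))
  sc <- partitionScores(cpm, all)
  expect_equal(sc$score, rep(1e6, 6))
  single <- newGeneSetCollection(list(ONE = "G7"))
  expect_equal(partitionScores(cpm, single)$score, unname(cpm["G7", ]))
  # explicit-loop oracle on random sets
  sets <- newGeneSetCollection(lapply(
    setNames(1:5, paste0("R", 1:5)),
    function(i) paste0("G", sample(50, 8))))
  sc2 <- partitionScores(cpm, sets)
  for (r in sample(nrow(sc2), 10)) {
    want <- 0
    for (g in sets[[sc2$set[r]]]) want <- want + cpm[g, sc2$sample_id[r]]
    expect_equal(sc2$score[r], want)
  }
  # partition of the universe sums to 1e6 per sample
  idx <- split(rownames(cpm), rep(1:5, each = 10))
  part <- newGeneSetCollection(setNames(idx, paste0("P", 1:5)))
  sc3 <- partitionScores(cpm, part)
  tot <- tapply(sc3$score, sc3$sample_id, sum)
  expect_equal(unname(c(tot)), rep(1e6, 6))
  # unresolvable members contribute zero, empty sets are dropped
  expect_warning(
    sc4 <- partitionScores(cpm, newGeneSetCollection(
      list(OK = c("G1", "NOPE"), GONE = "MISSING"))),
    "no resolvable")
  expect_equal(unique(sc4$set), "OK")
  expect_equal(sc4$score, unname(cpm["G1", ]))
})

test_that("trend fits recover exact slopes and are scale-equivariant", {
  ga <- seq(10, 30, length.out = 20)
  score <- 1000 + 250 * ga
  f <- fitTrend(score, ga)
  expect_equal(f$slope, 250)
  expect_lt(f$p, 1e-12)
  f2 <- fitTrend(2 * score, ga)
  expect_equal(f2$slope, 500)
  expect_error(fitTrend(score, rep(20, 20)), "distinct")
})

test_that("slope p-values are uniform under the null", {
  set.seed(6)
  ga <- runif(30, 10, 34)
  p <- replicate(1000, fitTrend(rnorm(30, 5e4, 1e3), ga)$p)
  hits <- sum(p < 0.05)
  # binomial(1000, 0.05) band
  expect_gt(hits, qbinom(0.001, 1000, 0.05))
  expect_lt(hits, qbinom(0.999, 1000, 0.05))
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.001)
})

test_that("BH selection of trending sets matches hand computation", {
  fits <- data.frame(set = c("s1", "s2"), slope = c(3, -1),
                     p = c(0.001, 0.5))
  sel <- selectTrending(fits, alpha = 0.01)
  expect_equal(sel$set, "s1")
  expect_equal(sel$adjP, 0.002)   # 0.001 * 2 / 1
  expect_equal(sel$direction, 1)
  none <- selectTrending(data.frame(set = c("a", "b"), slope = c(1, 1),
                                    p = c(1, 1)))
  expect_equal(nrow(none), 0)
  one <- selectTrending(data.frame(set = "a", slope = -2, p = 0.004))
  expect_equal(one$adjP, 0.004)   # BH is the identity for m = 1
  expect_equal(nrow(selectTrending(fits[0, ])), 0)
})

test_that("scrambling the temporal structure yields calibrated permutation p", {
  set.seed(7)
  ga <- runif(40, 10, 34)
  strong <- data.frame(sample_id = 1:40, set = "S",
                       score = 1e4 + 600 * ga, ga_collect_weeks = ga)
  sc <- scrambleControl(strong, nPerm = 199, seed = 1)
  expect_equal(sc$permP, 1 / 200)       # observed slope is extremal
  nullsc <- data.frame(sample_id = 1:40, set = "S",
                       score = rnorm(40, 1e4, 500), ga_collect_weeks = ga)
  p <- scrambleControl(nullsc, nPerm = 199, seed = 2)$permP
  expect_gte(p, 1 / 200)                # add-one lower bound
  expect_error(scrambleControl(strong, nPerm = 50), "99")
})

test_that("cross-cohort confirmation needs significance and matching sign", {
  mk <- function(cohort, slope, p)
    data.frame(set = "S", cohort = cohort, slope = slope, intercept = 0,
               p = p, ciLow = NA, ciHigh = NA, n = 50)
  everywhere <- rbind(mk("H", 5, 1e-6), mk("A", 4, 0.01), mk("B", 6, 0.02),
                      mk("G", 5, 0.03))
  conf <- confirmAcrossCohorts(everywhere, "H")
  expect_equal(conf$nCohortsSignificant, 4)
  onlyH <- rbind(mk("H", 5, 1e-6), mk("A", 1, 0.8), mk("B", 0.5, 0.9),
                 mk("G", 0.2, 0.95))
  expect_equal(nrow(confirmAcrossCohorts(onlyH, "H")), 0)
  flipped <- rbind(mk("H", 5, 1e-6), mk("A", -4, 0.01), mk("B", -6, 0.02),
                   mk("G", -5, 0.03))
  expect_equal(nrow(confirmAcrossCohorts(flipped, "H")), 0)
  expect_error(confirmAcrossCohorts(everywhere, "X"), "discovery")
})

test_that("exactly one of 24 draw orderings is monotone in each direction", {
  en <- enumerateDrawOrderings()
  expect_equal(nrow(en$orderings), 24)
  expect_equal(en$nMonotoneUp, 1)
  expect_equal(en$nMonotoneDown, 1)
})

test_that("monotonicity test classifies subjects and matches the 1/24 null", {
  mk <- function(subject, scores)
    data.frame(subject_id = subject, draw_index = 1:4, score = scores,
               set = "S")
  up <- mk("s1", c(1, 2, 3, 4))
  down <- mk("s2", c(9, 7, 4, 1))
  tied <- mk("s3", c(1, 1, 2, 3))
  mixed <- mk("s4", c(2, 1, 3, 4))
  res <- suppressMessages(monotonicityTest(rbind(up, down, tied, mixed)))
  expect_equal(res$nMonotoneUp, 1)
  expect_equal(res$nMonotoneDown, 1)
  expect_equal(res$nTies, 1)
  expect_equal(res$expected, 4 / 24)
  expect_warning(monotonicityTest(rbind(up, down, mk("s5", 1:4)[1:3, ])),
                 "excluded")
})

test_that("sets with injected slopes are selected with the correct sign", {
  sim <- simulateLongitudinal(smallLongitudinalConfig(
    nSubjects = 60, genes = 400, seed = 19, trend_frac = 0.15))
  lce <- logTransform(computeCPM(sim$experiment))
  sc <- partitionScores(assay(lce, "cpm"), sim$geneSets,
                        as.data.frame(colData(lce)))
  fits <- fitTrendsByCohort(sc)
  sel <- selectTrending(fits, alpha = 0.01)
  dir <- simTruth(sim$experiment)$setDirection
  trending <- names(dir)[dir != 0]
  hit <- sum(trending %in% sel$set &
             dir[trending] == sel$direction[match(trending, sel$set)],
             na.rm = TRUE)
  expect_gt(hit / length(trending), 0.9)
})
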