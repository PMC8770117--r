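#' Gene-set collections
#'
#' A `GeneSetCollection` is a named list of character vectors of gene ids
#' with a parallel `description` attribute — the in-memory form of a GMT
#' file.
#'
#' @param sets named list of character vectors (unique, non-empty).
#' @param description character vector of set descriptions (recycled empty).
#' @return object of class `"GeneSetCollection"`.
#' @export
newGeneSetCollection <- function(sets, description = NULL) {
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "),
         call. = FALSE)
  if (length(sets) && any(!lengths(sets)))
    stop("gene sets must be non-empty", call. = FALSE)
  if (is.null(description)) description <- rep("", length(sets))
  names(description) <- names(sets)
  structure(sets, description = description, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat("GeneSetCollection:", length(x), "sets, sizes",
      if (length(x)) paste0(min(lengths(x)), "-", max(lengths(x))) else "-",
      "\n")
  invisible(x)
}

#' Read or write gene sets in GMT format
#'
#' Standard tab-separated GMT: set name, description, then member gene ids.
#' `readGmt()` and `writeGmt()` round-trip exactly.
#'
#' @param path file path.
#' @return `readGmt()` a [newGeneSetCollection()] collection; `writeGmt()`
#'   the path, invisibly.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields",
           call. = FALSE)
    if (f[1] %in% names(sets))
      stop("duplicate gene-set name '", f[1], "' at line ", i, call. = FALSE)
    sets[[f[1]]] <- f[-(1:2)]
    desc[f[1]] <- f[2]
  }
  newGeneSetCollection(sets, desc)
}

#' @rdname readGmt
#' @param collection a `GeneSetCollection`.
#' @export
writeGmt <- function(collection, path) {
  desc <- attr(collection, "description")
  lines <- vapply(names(collection), function(nm)
    paste(c(nm, desc[[nm]], collection[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Cumulative-CPM partition scores
#'
#' Views the plasma transcriptome as partitioned into characteristic gene
#' sets: for every sample and set, sums the CPM of the member genes. The
#' cumulative CPM score is a relative abundance measure of the set in the
#' overall transcriptome (a partition of the gene universe sums to 1e6 per
#' sample). Member genes absent from the matrix contribute zero and are
#' reported; sets with no resolvable member are dropped with a warning.
#'
#' @param cpm genes x samples CPM matrix.
#' @param sets a `GeneSetCollection`.
#' @param sampleData optional data.frame (rows = samples) whose columns
#'   `ga_collect_weeks`, `subject_id`, `cohort`, `draw_index` are carried
#'   into the result when present.
#' @return data.frame with `sample_id`, `set`, `score` plus carried
#'   annotation columns.
#' @export
partitionScores <- function(cpm, sets, sampleData = NULL) {
  keep <- vapply(sets, function(g) any(g %in% rownames(cpm)), logical(1))
  if (any(!keep))
    warning("dropping set(s) with no resolvable member gene: ",
            paste(names(sets)[!keep], collapse = ", "), call. = FALSE)
  sets <- sets[keep]
  missing <- unique(unlist(lapply(sets, setdiff, rownames(cpm))))
  if (length(missing))
    message(length(missing),
            " member gene id(s) not in the matrix contribute 0")
  score <- vapply(sets, function(g)
    colSums(cpm[intersect(g, rownames(cpm)), , drop = FALSE]),
    numeric(ncol(cpm)))
  score <- matrix(score, nrow = ncol(cpm),
                  dimnames = list(colnames(cpm), names(sets)))
  out <- data.frame(
    sample_id = rep(rownames(score), times = ncol(score)),
    set = rep(colnames(score), each = nrow(score)),
    score = as.vector(score), stringsAsFactors = FALSE)
  if (!is.null(sampleData)) {
    carry <- intersect(c("ga_collect_weeks", "subject_id", "cohort",
                         "draw_index"), colnames(sampleData))
    idx <- match(out$sample_id, rownames(sampleData))
    for (cc in carry) out[[cc]] <- sampleData[[cc]][idx]
  }
  out
}

#' Linear trend of a partition score over gestational age
#'
#' Ordinary least squares of cumulative CPM on gestational age (weeks): the
#' slope is the average change of the set's expression in CPM per week, with
#' a two-sided slope p-value and 95 percent confidence band.
#'
#' @param score cumulative CPM per sample.
#' @param ga gestational age (weeks), at least 3 distinct values.
#' @return one-row data.frame: `slope`, `intercept`, `p`, `ciLow`, `ciHigh`,
#'   `n`.
#' @export
fitTrend <- function(score, ga) {
  if (length(unique(ga)) < 3)
    stop("need at least 3 distinct gestational ages", call. = FALSE)
  fit <- stats::lm(score ~ ga)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)["ga", ]
  data.frame(slope = sm["ga", "Estimate"],
             intercept = sm["(Intercept)", "Estimate"],
             p = sm["ga", "Pr(>|t|)"],
             ciLow = ci[[1]], ciHigh = ci[[2]], n = length(score))
}

#' Fit trends for every (set, cohort) combination
#'
#' @param scores a [partitionScores()] table with `ga_collect_weeks` and
#'   `cohort` columns.
#' @return data.frame of per-(set, cohort) [fitTrend()] rows.
#' @export
fitTrendsByCohort <- function(scores) {
  parts <- split(scores, list(scores$set, scores$cohort), drop = TRUE)
  rows <- lapply(parts, function(d)
    cbind(set = d$set[1], cohort = d$cohort[1],
          fitTrend(d$score, d$ga_collect_weeks)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select significantly trending gene sets in a discovery cohort
#'
#' Benjamini-Hochberg adjusts the slope p-values across sets within the
#' discovery cohort and retains sets with adjusted p below `alpha`
#' (default 0.01), recording the trend direction.
#'
#' @param fits per-set trend fits for one cohort (data.frame with `set`,
#'   `slope`, `p`).
#' @param alpha adjusted-p threshold.
#' @return data.frame of selected sets with `adjP` and `direction` (+1/-1).
#' @export
selectTrending <- function(fits, alpha = 0.01) {
  if (!nrow(fits))
    return(data.frame(set = character(), slope = numeric(),
                      p = numeric(), adjP = numeric(),
                      direction = numeric()))
  fits$adjP <- stats::p.adjust(fits$p, method = "BH")
  sel <- fits[fits$adjP < alpha, , drop = FALSE]
  sel$direction <- sign(sel$slope)
  rownames(sel) <- NULL
  sel
}

#' Permutation scrambling control for set trends
#'
#' Scrambles the temporal structure (permutes the gestational-age labels)
#' and recomputes the trend slope; the permutation p-value is the
#' add-one-corrected fraction of permutations with absolute slope at least
#' as large as observed.
#'
#' @param scores a [partitionScores()] table with `ga_collect_weeks`.
#' @param nPerm number of permutations (>= 99).
#' @param seed seed.
#' @return data.frame with `set`, `observedSlope`, `permP`.
#' @export
scrambleControl <- function(scores, nPerm = 999, seed = 1) {
  if (nPerm < 99) stop("nPerm must be >= 99", call. = FALSE)
  set.seed(seed)
  out <- lapply(split(scores, scores$set), function(d) {
    obs <- abs(fitTrend(d$score, d$ga_collect_weeks)$slope)
    hits <- 0L
    for (b in seq_len(nPerm)) {
      gp <- sample(d$ga_collect_weeks)
      if (abs(fitTrend(d$score, gp)$slope) >= obs) hits <- hits + 1L
    }
    data.frame(set = d$set[1], observedSlope = obs,
               permP = (hits + 1) / (nPerm + 1))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Confirm discovery-cohort trends in independent cohorts
#'
#' A set discovered in the discovery cohort (see [selectTrending()]) is
#' confirmed when its slope is significant (unadjusted p below `alpha`)
#' with matching sign in at least `minOther` non-discovery cohorts.
#' Reports the number of cohorts with significant signal including the
#' discovery cohort.
#'
#' @param fits per-(set, cohort) fits from [fitTrendsByCohort()].
#' @param discovery discovery cohort label.
#' @param alpha per-cohort significance level (default 0.05).
#' @param minOther minimum number of confirming non-discovery cohorts.
#' @param discoveryAlpha BH-adjusted threshold within the discovery cohort.
#' @return data.frame of confirmed sets with `direction` and
#'   `nCohortsSignificant` (including discovery).
#' @export
confirmAcrossCohorts <- function(fits, discovery, alpha = 0.05,
                                 minOther = 2, discoveryAlpha = 0.01) {
  if (!discovery %in% fits$cohort)
    stop("discovery cohort '", discovery, "' absent from fits",
         call. = FALSE)
  disc <- selectTrending(fits[fits$cohort == discovery, , drop = FALSE],
                         alpha = discoveryAlpha)
  other <- fits[fits$cohort != discovery, , drop = FALSE]
  rows <- lapply(seq_len(nrow(disc)), function(i) {
    s <- disc$set[i]; dr <- disc$direction[i]
    o <- other[other$set == s, , drop = FALSE]
    ok <- o$p < alpha & sign(o$slope) == dr
    if (sum(ok) >= minOther)
      data.frame(set = s, direction = dr, slope = disc$slope[i],
                 adjP = disc$adjP[i],
                 nCohortsSignificant = sum(ok) + 1L)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set = character(), direction = numeric(),
                      slope = numeric(), adjP = numeric(),
                      nCohortsSignificant = integer())
  out
}

#' Enumerate orderings of four draws
#'
#' Exposes the exact combinatorial null of the monotonicity test: all 24
#' permutations of four collection times, of which exactly one is strictly
#' increasing and one strictly decreasing.
#'
#' @return list with `orderings` (24 x 4 matrix), `nMonotoneUp`,
#'   `nMonotoneDown`.
#' @export
enumerateDrawOrderings <- function() {
  perms <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ,
                 drop = FALSE]
  dimnames(perms) <- NULL
  up <- sum(apply(perms, 1, function(p) all(diff(p) > 0)))
  down <- sum(apply(perms, 1, function(p) all(diff(p) < 0)))
  list(orderings = perms, nMonotoneUp = up, nMonotoneDown = down)
}

#' Exact-null monotonicity test over four ordered draws
#'
#' For each subject with exactly four draws, the cumulative CPM scores are
#' ordered by draw time and classified as monotone-up (strictly increasing),
#' monotone-down (strictly decreasing) or neither; ties count as
#' non-monotone and are reported. Under the null that scores are
#' exchangeable over the four collection times, each direction has
#' probability 1/24, so the observed monotone count is compared to the
#' Binomial(n, 1/24) expectation with a one-degree-of-freedom chi-squared
#' goodness-of-fit test per direction (an exact binomial p is reported
#' alongside).
#'
#' @param scores a [partitionScores()] table for one set in a longitudinal
#'   cohort, with `subject_id`, `draw_index` and `score`; subjects without
#'   exactly 4 draws are excluded with a warning.
#' @return object of class `"MonotonicityResult"`: `nSubjects`,
#'   `nMonotoneUp`, `nMonotoneDown`, `expected` (n/24), `chisqUp`, `pUp`,
#'   `chisqDown`, `pDown`, `binomPUp`, `binomPDown`, `nTies`.
#' @export
monotonicityTest <- function(scores) {
  subj <- split(scores, scores$subject_id)
  bad <- names(subj)[vapply(subj, nrow, integer(1)) != 4]
  if (length(bad)) {
    warning(length(bad), " subject(s) without exactly 4 draws excluded",
            call. = FALSE)
    subj <- subj[setdiff(names(subj), bad)]
  }
  n <- length(subj)
  if (!n) stop("no subjects with 4 draws", call. = FALSE)
  up <- 0L; down <- 0L; ties <- 0L
  for (d in subj) {
    s <- d$score[order(d$draw_index)]
    dd <- diff(s)
    if (any(dd == 0)) ties <- ties + 1L
    else if (all(dd > 0)) up <- up + 1L
    else if (all(dd < 0)) down <- down + 1L
  }
  if (ties) message(ties, " subject(s) with tied adjacent scores counted ",
                    "as non-monotone")
  e <- n / 24
  gof <- function(o) {
    stat <- (o - e)^2 / e + ((n - o) - (n - e))^2 / (n - e)
    list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  gu <- gof(up); gd <- gof(down)
  structure(list(nSubjects = n, nMonotoneUp = up, nMonotoneDown = down,
                 expected = e,
                 chisqUp = gu$stat, pUp = gu$p,
                 chisqDown = gd$stat, pDown = gd$p,
                 binomPUp = stats::binom.test(up, n, 1 / 24)$p.value,
                 binomPDown = stats::binom.test(down, n, 1 / 24)$p.value,
                 nTies = ties),
            class = "MonotonicityResult")
}

#' @export
print.MonotonicityResult <- function(x, ...) {
  cat(sprintf("Monotonicity over 4 draws: n = %d subjects\n", x$nSubjects))
  cat(sprintf("  monotone-up %d, monotone-down %d (expected %.3f each ",
              x$nMonotoneUp, x$nMonotoneDown, x$expected))
  cat("under the 1/24 null)\n")
  cat(sprintf("  chi-squared up: %.2f (p = %.3g); down: %.2f (p = %.3g)\n",
              x$chisqUp, x$pUp, x$chisqDown, x$pDown))
  invisible(x)
}

#' Per-window summary of partition scores
#'
#' Mean cumulative CPM per draw window with a 95 percent confidence
#' interval of the mean (mean +/- 1.96 standard errors), the summary behind
#' per-window trend displays.
#'
#' @param scores a [partitionScores()] table with `draw_index`.
#' @return data.frame with `set`, `draw_index`, `mean`, `ciLow`, `ciHigh`,
#'   `n`.
#' @export
summariseByWindow <- function(scores) {
  parts <- split(scores, list(scores$set, scores$draw_index), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(d) {
    se <- stats::sd(d$score) / sqrt(nrow(d))
    data.frame(set = d$set[1], draw_index = d$draw_index[1],
               mean = mean(d$score), ciLow = mean(d$score) - 1.96 * se,
               ciHigh = mean(d$score) + 1.96 * se, n = nrow(d))
  }))
  rownames(out) <- NULL
  out[order(out$set, out$draw_index), ]
}
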