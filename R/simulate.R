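#' Simulation configuration for multi-cohort plasma cfRNA counts
#'
#' Builds and validates the parameter set of the synthetic data generator.
#' Defaults emulate an eight-cohort prospective pregnancy study: each cohort
#' samples a distinct gestational-age window (so cohort effects are partially
#' confounded with gestational age — exactly the confound the correction
#' algorithm must untangle), counts are negative-binomial around a
#' CPM-space signal scaled by lognormal library sizes, a fraction of genes
#' carries a linear gestational-age trend in log2-CPM space, and a small
#' coding-gene panel is perturbed in pre-eclampsia cases at 13.7 percent
#' prevalence.
#'
#' @param n_cohorts number of cross-sectional cohorts.
#' @param samples_per_cohort integer vector, one entry per cohort.
#' @param ga_window_per_cohort list of `c(min_weeks, max_weeks)` windows,
#'   one per cohort; all within (4, 42) weeks.
#' @param n_genes number of genes.
#' @param frac_coding fraction of genes annotated protein_coding.
#' @param trend_frac fraction of genes with a nonzero gestational-age slope.
#' @param slope_scale s.d. of the per-gene slope (log2-CPM units per week).
#' @param cohort_offset_sd s.d. of per-(gene, cohort) offsets (log2-CPM).
#' @param libsize_meanlog,libsize_sdlog lognormal parameters of per-sample
#'   total counts.
#' @param nb_dispersion negative-binomial dispersion (> 0); variance is
#'   `mu + dispersion * mu^2`.
#' @param pe_prevalence fraction of pregnancies developing pre-eclampsia.
#' @param pe_panel_size number of coding genes perturbed in cases.
#' @param pe_effect absolute log2-CPM shift of panel genes in cases (each
#'   panel gene receives a random sign).
#' @param n_gene_sets,set_size_range number and size range of constructed
#'   gene sets with known aggregate trend direction.
#' @param longitudinal_cohort optional `list(n_subjects=, draw_windows=)`
#'   where `draw_windows` is a list of four strictly increasing,
#'   non-overlapping `c(min, max)` windows; required by
#'   [simulateLongitudinal()].
#' @param confounded_covariates if `TRUE`, BMI is made to co-vary with
#'   gestational age (stress-test mode); by default clinical covariates are
#'   independent of the transcriptomic signal.
#' @param seed integer seed; identical configurations give byte-identical
#'   simulations.
#' @return A validated list of class `"SimConfig"`.
#' @export
simConfig <- function(n_cohorts = 8,
                      samples_per_cohort = rep(150L, n_cohorts),
                      ga_window_per_cohort = defaultGaWindows(n_cohorts),
                      n_genes = 2000,
                      frac_coding = 0.7,
                      trend_frac = 0.1,
                      slope_scale = 0.05,
                      cohort_offset_sd = 0.5,
                      libsize_meanlog = log(3e6),
                      libsize_sdlog = 0.4,
                      nb_dispersion = 0.2,
                      pe_prevalence = 0.137,
                      pe_panel_size = 7,
                      pe_effect = 1.0,
                      n_gene_sets = 20,
                      set_size_range = c(10, 50),
                      longitudinal_cohort = NULL,
                      confounded_covariates = FALSE,
                      seed = 1L) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              samples_per_cohort = as.integer(samples_per_cohort),
              ga_window_per_cohort = ga_window_per_cohort,
              n_genes = as.integer(n_genes), frac_coding = frac_coding,
              trend_frac = trend_frac, slope_scale = slope_scale,
              cohort_offset_sd = cohort_offset_sd,
              libsize_meanlog = libsize_meanlog,
              libsize_sdlog = libsize_sdlog,
              nb_dispersion = nb_dispersion,
              pe_prevalence = pe_prevalence,
              pe_panel_size = as.integer(pe_panel_size),
              pe_effect = pe_effect,
              n_gene_sets = as.integer(n_gene_sets),
              set_size_range = as.integer(set_size_range),
              longitudinal_cohort = longitudinal_cohort,
              confounded_covariates = isTRUE(confounded_covariates),
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

# Table-1-style gestational-age windows: eight cohorts covering distinct but
# overlapping spans of pregnancy, first-trimester-heavy to near-term.
defaultGaWindows <- function(n) {
  base <- list(c(12.0, 27.9), c(5.6, 38.2), c(8.9, 28.1), c(12.2, 23.8),
               c(16.9, 26.8), c(4.9, 40.2), c(8.0, 38.7), c(11.4, 34.8))
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, replicate(n - length(base), c(8, 36), simplify = FALSE))
}

validateSimConfig <- function(cfg) {
  stopIf <- function(cond, field, what) {
    if (cond) stop(sprintf("invalid SimConfig field '%s': %s", field, what),
                   call. = FALSE)
  }
  stopIf(cfg$n_cohorts < 1, "n_cohorts", "must be >= 1")
  stopIf(length(cfg$samples_per_cohort) != cfg$n_cohorts,
         "samples_per_cohort", "length must equal n_cohorts")
  stopIf(length(cfg$ga_window_per_cohort) != cfg$n_cohorts,
         "ga_window_per_cohort", "length must equal n_cohorts")
  for (w in cfg$ga_window_per_cohort) {
    stopIf(length(w) != 2 || w[1] >= w[2], "ga_window_per_cohort",
           "each window must be c(min, max) with min < max")
    if (w[1] <= 4 || w[2] >= 42)
      stop("gestational-age window outside the plausible range (4, 42) weeks",
           call. = FALSE)
  }
  stopIf(cfg$frac_coding < 0 || cfg$frac_coding > 1, "frac_coding",
         "must lie in [0, 1]")
  stopIf(cfg$trend_frac < 0 || cfg$trend_frac > 1, "trend_frac",
         "must lie in [0, 1]")
  stopIf(cfg$nb_dispersion <= 0, "nb_dispersion", "must be > 0")
  stopIf(cfg$pe_prevalence < 0 || cfg$pe_prevalence > 1, "pe_prevalence",
         "must lie in [0, 1]")
  stopIf(cfg$pe_panel_size < 0, "pe_panel_size", "must be >= 0")
  if (!is.null(cfg$longitudinal_cohort)) {
    lc <- cfg$longitudinal_cohort
    stopIf(is.null(lc$n_subjects) || is.null(lc$draw_windows),
           "longitudinal_cohort", "needs n_subjects and draw_windows")
    dw <- lc$draw_windows
    stopIf(length(dw) != 4, "longitudinal_cohort", "needs 4 draw windows")
    for (w in dw)
      if (w[1] <= 4 || w[2] >= 42)
        stop("draw window outside the plausible range (4, 42) weeks",
             call. = FALSE)
    lo <- vapply(dw, `[`, numeric(1), 1)
    hi <- vapply(dw, `[`, numeric(1), 2)
    stopIf(any(lo >= hi) || any(diff(lo) <= 0) || any(hi[-4] > lo[-1]),
           "longitudinal_cohort",
           "draw windows must be strictly increasing and non-overlapping")
  }
  invisible(cfg)
}

# sample() without the length-1 surprise
safeSample <- function(x, n) x[sample.int(length(x), n)]

# Gene-level generating model shared by both simulators: baseline abundance,
# sparse GA slopes, cohort offsets, PE panel, gene sets with known direction.
simGeneModel <- function(cfg, cohorts) {
  n <- cfg$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))
  n_cod <- round(cfg$frac_coding * n)
  n_rest <- n - n_cod
  biotype <- c(rep("protein_coding", n_cod),
               rep(c("pseudogene", "non_coding"), length.out = n_rest))
  biotype <- sample(biotype)
  baseline <- stats::rnorm(n, mean = 3, sd = 2)
  slope <- numeric(n)
  n_trend <- round(cfg$trend_frac * n)
  trending <- safeSample(seq_len(n), n_trend)
  if (n_trend)
    slope[trending] <- stats::rnorm(n_trend, 0, cfg$slope_scale)
  offsets <- matrix(0, n, length(cohorts),
                    dimnames = list(gene_id, cohorts))
  if (cfg$cohort_offset_sd > 0)
    offsets[] <- stats::rnorm(n * length(cohorts), 0, cfg$cohort_offset_sd)
  coding <- which(biotype == "protein_coding")
  panel <- sort(safeSample(coding, min(cfg$pe_panel_size, length(coding))))
  panel_effect <- cfg$pe_effect * sample(c(-1, 1), length(panel),
                                         replace = TRUE)
  sets <- constructGeneSets(cfg, gene_id, slope)
  list(gene_id = gene_id, biotype = biotype, baseline = baseline,
       slope = slope, offsets = offsets,
       panel = data.frame(gene_id = gene_id[panel], effect = panel_effect,
                          stringsAsFactors = FALSE),
       geneSets = sets)
}

# Sets are sampled so their aggregate trend direction is known a priori:
# trending sets take 60% of members from genes whose slope sign matches the
# set direction, null sets only from flat genes.
constructGeneSets <- function(cfg, gene_id, slope) {
  ns <- cfg$n_gene_sets
  if (ns == 0) return(newGeneSetCollection(list(), character()))
  n_up <- ceiling(0.35 * ns); n_dn <- ceiling(0.35 * ns)
  dirs <- c(rep(1, n_up), rep(-1, n_dn), rep(0, ns - n_up - n_dn))
  up <- which(slope > 0); dn <- which(slope < 0); flat <- which(slope == 0)
  sets <- vector("list", ns)
  names(sets) <- sprintf("SET_%02d", seq_len(ns))
  for (j in seq_len(ns)) {
    size <- sample(seq(cfg$set_size_range[1], cfg$set_size_range[2]), 1)
    if (dirs[j] == 0) {
      idx <- safeSample(flat, min(size, length(flat)))
    } else {
      pool <- if (dirs[j] > 0) up else dn
      n_sig <- min(round(0.6 * size), length(pool))
      idx <- c(safeSample(pool, n_sig),
               safeSample(flat, min(size - n_sig, length(flat))))
    }
    sets[[j]] <- gene_id[sort(idx)]
  }
  desc <- sprintf("synthetic set, true direction %+d", dirs)
  names(desc) <- names(sets)
  out <- newGeneSetCollection(sets, desc)
  attr(out, "trueDirection") <- stats::setNames(dirs, names(sets))
  out
}

# Draw NB counts for one block of samples given per-sample GA, cohort and
# case status. Signal is log2 relative abundance; CPM normalisation of the
# counts recovers it up to a per-sample compositional constant.
simCounts <- function(cfg, model, ga, cohort, is_case) {
  ns <- length(ga)
  sig <- model$baseline + outer(model$slope, ga) +
    model$offsets[, cohort, drop = FALSE]
  if (nrow(model$panel) && any(is_case)) {
    pi <- match(model$panel$gene_id, model$gene_id)
    sig[pi, is_case] <- sig[pi, is_case] + model$panel$effect
  }
  rel <- 2^sig
  rel <- sweep(rel, 2, colSums(rel), "/")
  lib <- stats::rlnorm(ns, cfg$libsize_meanlog, cfg$libsize_sdlog)
  mu <- sweep(rel, 2, lib, "*")
  cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                               size = 1 / cfg$nb_dispersion),
                nrow = nrow(mu))
  dimnames(cnt) <- list(model$gene_id, NULL)
  list(counts = cnt, libsize = lib)
}

simCovariates <- function(n, ga, confounded) {
  bmi <- stats::rnorm(n, 27.5, 6.5)
  if (confounded) bmi <- bmi + 0.4 * (ga - mean(ga))
  data.frame(
    bmi = pmin(pmax(bmi, 15), 60),
    maternal_age = pmin(pmax(stats::rnorm(n, 30, 5.5), 16), 50),
    race = sample(c("White", "Black", "Hispanic", "Asian", "Other"), n,
                  replace = TRUE, prob = c(0.5, 0.2, 0.12, 0.08, 0.10)),
    stringsAsFactors = FALSE)
}

simDeliveryGa <- function(is_case) {
  n <- length(is_case)
  d <- 40 - stats::rexp(n, rate = 1 / 1.5)
  d[is_case] <- 37 - stats::rexp(sum(is_case), rate = 1 / 2)
  pmin(pmax(d, 24), 42)
}

#' Simulate a multi-cohort cross-sectional cfRNA study
#'
#' Generates negative-binomial counts for `n_cohorts` cohorts, each sampling
#' gestational ages uniformly within its own window, with per-(gene, cohort)
#' offsets, per-gene gestational-age trends, lognormal library sizes, a
#' perturbed pre-eclampsia gene panel, clinical covariates independent of the
#' transcriptome (by default), QC metrics and constructed gene sets. The
#' complete generating truth is attached to the returned experiment.
#'
#' @param config a [simConfig()] object.
#' @return `list(experiment = CfrnaExperiment, geneSets =
#'   GeneSetCollection)`; ground truth is available via
#'   [simTruth()] on the experiment.
#' @examples
#' sim <- simulateCohorts(simConfig(n_cohorts = 2,
#'   samples_per_cohort = c(20, 20), n_genes = 100, seed = 1))
#' sim$experiment
#' @export
simulateCohorts <- function(config) {
  validateSimConfig(config)
  set.seed(config$seed)
  cohorts <- LETTERS[seq_len(config$n_cohorts)]
  model <- simGeneModel(config, cohorts)
  ann <- list(); blocks <- list(); lib <- numeric()
  for (k in seq_len(config$n_cohorts)) {
    nk <- config$samples_per_cohort[k]
    w <- config$ga_window_per_cohort[[k]]
    ga <- stats::runif(nk, w[1], w[2])
    is_case <- stats::runif(nk) < config$pe_prevalence
    blk <- simCounts(config, model, ga, rep(cohorts[k], nk), is_case)
    cov <- simCovariates(nk, ga, config$confounded_covariates)
    ann[[k]] <- data.frame(
      sample_id = sprintf("%s_%03d", cohorts[k], seq_len(nk)),
      subject_id = sprintf("%s_subj%03d", cohorts[k], seq_len(nk)),
      cohort = cohorts[k], draw_index = 1L,
      ga_collect_weeks = ga,
      ga_delivery_weeks = simDeliveryGa(is_case),
      outcome = ifelse(is_case, "PE", "control"),
      cov,
      qc_total_reads = colSums(blk$counts),
      qc_dup_rate = stats::rbeta(nk, 5, 20),
      qc_actb_ct = stats::rnorm(nk, 25, 1),
      stringsAsFactors = FALSE)
    blocks[[k]] <- blk$counts
    lib <- c(lib, blk$libsize)
  }
  ann <- do.call(rbind, ann)
  counts <- do.call(cbind, blocks)
  colnames(counts) <- ann$sample_id
  truth <- list(
    gene = data.frame(gene_id = model$gene_id, biotype = model$biotype,
                      baseline = model$baseline, slope = model$slope,
                      stringsAsFactors = FALSE),
    cohortOffsets = model$offsets,
    pePanel = model$panel,
    librarySize = stats::setNames(lib, ann$sample_id),
    setDirection = attr(model$geneSets, "trueDirection"),
    config = config)
  exp <- CfrnaExperiment(counts,
    sampleData = ann[-1],
    geneData = data.frame(gene_id = model$gene_id, biotype = model$biotype,
                          stringsAsFactors = FALSE),
    truth = truth)
  list(experiment = exp, geneSets = model$geneSets)
}

#' Simulate a longitudinal cfRNA cohort with four ordered draws per subject
#'
#' Each subject is sampled once per draw window (windows strictly increasing,
#' so per-subject gestational ages are strictly increasing). With
#' `n_cohorts > 1`, that many longitudinal cohorts are generated (labelled
#' `H`, `A`, `B`, `G`, ...), each with its own cohort offsets, supporting
#' multi-cohort confirmation analyses; the first label (`H`) is the
#' conventional discovery cohort.
#'
#' @param config a [simConfig()] with `longitudinal_cohort` set.
#' @return same structure as [simulateCohorts()].
#' @examples
#' cfg <- simConfig(n_cohorts = 1, samples_per_cohort = 0,
#'   ga_window_per_cohort = list(c(11, 35)), n_genes = 100,
#'   longitudinal_cohort = list(n_subjects = 5,
#'     draw_windows = list(c(11.4, 14), c(18, 21), c(22.8, 27.8),
#'                         c(29.2, 34.8))), seed = 1)
#' sim <- simulateLongitudinal(cfg)
#' ncol(sim$experiment)  # 5 subjects x 4 draws
#' @export
simulateLongitudinal <- function(config) {
  validateSimConfig(config)
  if (is.null(config$longitudinal_cohort))
    stop("configuration error: 'longitudinal_cohort' must be set for ",
         "simulateLongitudinal()", call. = FALSE)
  set.seed(config$seed)
  lc <- config$longitudinal_cohort
  labs <- c("H", "A", "B", "G", sprintf("L%d", seq_len(config$n_cohorts)))
  cohorts <- labs[seq_len(config$n_cohorts)]
  model <- simGeneModel(config, cohorts)
  ann <- list(); blocks <- list(); lib <- numeric()
  for (k in seq_along(cohorts)) {
    nsub <- lc$n_subjects
    ga <- unlist(lapply(seq_len(nsub), function(s)
      vapply(lc$draw_windows, function(w) stats::runif(1, w[1], w[2]),
             numeric(1))))
    subj <- rep(seq_len(nsub), each = 4)
    draw <- rep(1:4, nsub)
    blk <- simCounts(config, model, ga, rep(cohorts[k], length(ga)),
                     rep(FALSE, length(ga)))
    cov1 <- simCovariates(nsub, tapply(ga, subj, mean),
                          config$confounded_covariates)
    cov <- cov1[subj, , drop = FALSE]
    ann[[k]] <- data.frame(
      sample_id = sprintf("%s_s%03d_d%d", cohorts[k], subj, draw),
      subject_id = sprintf("%s_subj%03d", cohorts[k], subj),
      cohort = cohorts[k], draw_index = draw,
      ga_collect_weeks = ga,
      ga_delivery_weeks = simDeliveryGa(rep(FALSE, length(ga))),
      outcome = "control", cov,
      qc_total_reads = colSums(blk$counts),
      qc_dup_rate = stats::rbeta(length(ga), 5, 20),
      qc_actb_ct = stats::rnorm(length(ga), 25, 1),
      row.names = NULL, stringsAsFactors = FALSE)
    blocks[[k]] <- blk$counts
    lib <- c(lib, blk$libsize)
  }
  ann <- do.call(rbind, ann)
  counts <- do.call(cbind, blocks)
  colnames(counts) <- ann$sample_id
  truth <- list(
    gene = data.frame(gene_id = model$gene_id, biotype = model$biotype,
                      baseline = model$baseline, slope = model$slope,
                      stringsAsFactors = FALSE),
    cohortOffsets = model$offsets,
    pePanel = model$panel,
    librarySize = stats::setNames(lib, ann$sample_id),
    setDirection = attr(model$geneSets, "trueDirection"),
    config = config)
  exp <- CfrnaExperiment(counts,
    sampleData = ann[-1],
    geneData = data.frame(gene_id = model$gene_id, biotype = model$biotype,
                          stringsAsFactors = FALSE),
    truth = truth)
  list(experiment = exp, geneSets = model$geneSets)
}

#' The four draw windows of the reference longitudinal design
#'
#' Convenience constructor for a longitudinal configuration with the four
#' canonical collection windows 11.4-14, 18-21, 22.8-27.8 and 29.2-34.8
#' weeks and 93 subjects per cohort.
#'
#' @param n_subjects subjects per cohort.
#' @return a list suitable for `simConfig(longitudinal_cohort = ...)`.
#' @export
longitudinalDesign <- function(n_subjects = 93) {
  list(n_subjects = as.integer(n_subjects),
       draw_windows = list(c(11.4, 14), c(18, 21), c(22.8, 27.8),
                           c(29.2, 34.8)))
}
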