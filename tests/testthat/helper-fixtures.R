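# Shared small fixtures, built in code at test time.

suppressMessages({
  library(SummarizedExperiment)
})

# small cross-sectional design: nc cohorts, n per cohort
smallConfig <- function(nc = 3, n = 40, genes = 300, seed = 1, ...) {
  win <- list(c(8, 20), c(14, 28), c(20, 34), c(10, 30), c(16.9, 26.8),
              c(6, 36), c(9, 33), c(12, 30))[seq_len(nc)]
  simConfig(n_cohorts = nc, samples_per_cohort = rep(n, nc),
            ga_window_per_cohort = win, n_genes = genes, seed = seed, ...)
}

smallLongitudinalConfig <- function(nCohorts = 1, nSubjects = 15,
                                    genes = 200, seed = 1, ...) {
  simConfig(n_cohorts = nCohorts, samples_per_cohort = rep(0L, nCohorts),
            ga_window_per_cohort = replicate(nCohorts, c(11, 35),
                                             simplify = FALSE),
            n_genes = genes,
            longitudinal_cohort = longitudinalDesign(nSubjects),
            seed = seed, ...)
}

# mean log2(CPM+1) matrix from a raw experiment
log2cpm <- function(ce) logTransform(computeCPM(assay(ce, "counts")))

# per-gene OLS slope of log2-CPM on GA, the independent trend oracle
olsSlopes <- function(m, ga) {
  apply(m, 1, function(v) stats::coef(stats::lm(v ~ ga))[[2]])
}
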