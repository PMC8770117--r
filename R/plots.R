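#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_errorbar
#'   geom_abline labs theme_bw
NULL

#' Plot a learning curve
#'
#' @param lc data.frame from [learningCurve()] (`trainSize`, `maeMean`,
#'   `maeSd`) or [learningCurveKfold()] (`k`, `auc`).
#' @return a ggplot object.
#' @export
plotLearningCurve <- function(lc) {
  if ("maeMean" %in% names(lc)) {
    ggplot(lc, aes(x = .data$trainSize, y = .data$maeMean)) +
      geom_errorbar(aes(ymin = .data$maeMean - .data$maeSd,
                        ymax = .data$maeMean + .data$maeSd), width = 0) +
      geom_line() + geom_point() +
      labs(x = "training samples", y = "held-out MAE (days)") +
      theme_bw()
  } else {
    lc$k[is.na(lc$k)] <- max(lc$k, na.rm = TRUE) + 1
    ggplot(lc, aes(x = .data$k, y = .data$auc)) +
      geom_line() + geom_point() +
      labs(x = "CV folds (terminal point = LOOCV)", y = "AUC") +
      theme_bw()
  }
}

#' Plot an ROC curve
#'
#' @param report a [ClassifierReport-class].
#' @return a ggplot object.
#' @export
plotRoc <- function(report) {
  ggplot(report@roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey") +
    geom_line() +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("AUC = %.2f", report@auc)) +
    theme_bw()
}

#' Quantile-quantile plot of screening p-values
#'
#' @param p vector of p-values (e.g. from [spearmanScreen()]).
#' @return a ggplot object of -log10 observed vs expected quantiles.
#' @export
plotQqPvalues <- function(p) {
  qq <- qqPvalues(p)
  ggplot(qq, aes(x = -log10(.data$expected), y = -log10(.data$observed))) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey") +
    geom_point(size = 0.8) +
    labs(x = expression(-log[10] ~ "expected p"),
         y = expression(-log[10] ~ "observed p")) +
    theme_bw()
}
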