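#' Read and write expression matrices
#'
#' Counts travel either as gene x sample TSV (header row of sample ids,
#' first column of gene ids) or as MatrixMarket triplets with companion
#' row/column id files (`<stem>.mtx`, `<stem>.rownames`, `<stem>.colnames`).
#'
#' @param path TSV path, or MatrixMarket stem for `format = "mtx"`.
#' @param format `"tsv"` or `"mtx"`.
#' @return `readCounts()` a genes x samples matrix; `writeCounts()` the
#'   path, invisibly.
#' @export
readCounts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(df[-1])
    rownames(m) <- df[[1]]
    m
  } else {
    m <- as.matrix(Matrix::readMM(paste0(path, ".mtx")))
    rownames(m) <- readLines(paste0(path, ".rownames"))
    colnames(m) <- readLines(paste0(path, ".colnames"))
    m
  }
}

#' @rdname readCounts
#' @param m genes x samples matrix.
#' @export
writeCounts <- function(m, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), paste0(path, ".mtx"))
    writeLines(rownames(m), paste0(path, ".rownames"))
    writeLines(colnames(m), paste0(path, ".colnames"))
  }
  invisible(path)
}

#' Write a simulation to standard on-disk formats
#'
#' Counts as TSV (or MatrixMarket), sample and gene annotation as TSV with
#' the pipeline's fixed column vocabulary, gene sets as GMT and the
#' generating truth as JSON.
#'
#' @param sim result of [simulateCohorts()] or [simulateLongitudinal()].
#' @param dir output directory (created if needed).
#' @param format counts format, `"tsv"` or `"mtx"`.
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ce <- sim$experiment
  writeCounts(assay(ce, "counts"),
              file.path(dir, if (format == "tsv") "counts.tsv" else "counts"),
              format = format)
  ann <- as.data.frame(colData(ce))
  ann <- cbind(sample_id = rownames(ann), ann)
  utils::write.table(ann, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(rowData(ce)),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeGmt(sim$geneSets, file.path(dir, "gene_sets.gmt"))
  truth <- simTruth(ce)
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a cfRNA experiment from on-disk tables
#'
#' @param countsPath counts TSV (or MatrixMarket stem).
#' @param samplesPath sample-annotation TSV with a `sample_id` column.
#' @param genesPath gene-annotation TSV with a `gene_id` column.
#' @param format counts format.
#' @return a [CfrnaExperiment-class].
#' @export
readCfrnaExperiment <- function(countsPath, samplesPath, genesPath,
                                format = c("tsv", "mtx")) {
  m <- readCounts(countsPath, format = match.arg(format))
  ann <- utils::read.delim(samplesPath, stringsAsFactors = FALSE)
  gd <- utils::read.delim(genesPath, stringsAsFactors = FALSE)
  ann <- ann[match(colnames(m), ann$sample_id), , drop = FALSE]
  gd <- gd[match(rownames(m), gd$gene_id), , drop = FALSE]
  CfrnaExperiment(m, sampleData = ann[-1], geneData = gd)
}

#' Serialise a correction model or gestational-age clock to JSON
#'
#' @param object a [CorrectionModel-class] or [GaClock-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeModelJson <- function(object, path) {
  x <- if (is(object, "CorrectionModel")) {
    list(type = "CorrectionModel", genes = object@genes,
         depthIntercept = object@depthIntercept,
         depthSlope = object@depthSlope, geneMean = object@geneMean,
         offsets = as.data.frame(object@offsets),
         cohorts = object@cohorts, fittedSpace = object@fittedSpace)
  } else if (is(object, "GaClock")) {
    list(type = "GaClock", penalty = object@penalty,
         intercept = object@intercept, coef = as.list(object@coef),
         featureProvenance = object@featureProvenance)
  } else stop("unsupported object class: ", class(object), call. = FALSE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
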