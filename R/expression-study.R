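#' Construct an ExpressionStudy
#'
#' The package's expression container: a gene x sample matrix of log2
#' intensities together with the per-sample condition (UC = ulcerative
#' colitis, the benign class; CRC = colorectal carcinoma) and the per-sample
#' batch (study of origin).
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param condition character/factor of length `ncol(values)`, values in
#'   `c("UC", "CRC")`.
#' @param batch character of length `ncol(values)`; study/batch label.
#' @return an object of class `ExpressionStudy`.
#' @export
expression_study <- function(values, condition, batch) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicated gene ids in expression matrix: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))])[1:3],
                collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stopf("duplicated sample ids in expression matrix")
  condition <- as.character(condition)
  batch <- as.character(batch)
  if (length(condition) != ncol(values) || length(batch) != ncol(values))
    stopf("condition/batch length must equal the number of samples")
  bad <- setdiff(unique(condition), CONDITION_LEVELS)
  if (length(bad))
    stopf("unknown condition label(s): %s", paste(bad, collapse = ", "))
  structure(
    list(values = values, condition = condition, batch = batch),
    class = "ExpressionStudy"
  )
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat(sprintf("ExpressionStudy: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("  conditions:",
      paste(sprintf("%s=%d", names(table(x$condition)), table(x$condition)),
            collapse = ", "), "\n")
  cat("  batches:   ",
      paste(sprintf("%s=%d", names(table(x$batch)), table(x$batch)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionStudy <- function(x) dim(x$values)

gene_ids <- function(study) rownames(study$values)

sample_ids <- function(study) colnames(study$values)

#' Subset an ExpressionStudy by sample ids
#'
#' @param study an `ExpressionStudy`.
#' @param samples character vector of sample ids to keep (order preserved).
#' @return an `ExpressionStudy` restricted to `samples`.
#' @export
subset_samples <- function(study, samples) {
  missing <- setdiff(samples, sample_ids(study))
  if (length(missing))
    stopf("sample id(s) not in study: %s", paste(missing, collapse = ", "))
  idx <- match(samples, sample_ids(study))
  expression_study(study$values[, idx, drop = FALSE],
                   study$condition[idx], study$batch[idx])
}
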