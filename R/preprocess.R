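#' Quantile (rank) normalization of one study
#'
#' Forces every sample (column) onto the same empirical distribution: each
#' column's sorted values are replaced by the across-sample mean of the
#' order statistics; ties receive the mean of their tied reference values.
#' Idempotent. Delegates to limma's quantile normalizer.
#'
#' @param study an [expression_study()].
#' @return the normalized `ExpressionStudy`.
#' @export
rank_normalize <- function(study) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (ncol(study$values) < 2) stopf("rank_normalize needs >= 2 samples")
  if (anyNA(study$values)) stopf("missing values in expression matrix")
  norm <- limma::normalizeQuantiles(study$values, ties = TRUE)
  dimnames(norm) <- dimnames(study$values)
  expression_study(norm, study$condition, study$batch)
}

#' Merge studies into one cross-study cohort
#'
#' Restricts to the gene intersection (default) or the union (private genes
#' padded as NA, for inspection only) and concatenates samples, preserving
#' per-sample batch labels. Reports common/unique gene counts per study.
#'
#' @param studies list of [expression_study()] objects (>= 2).
#' @param scope `"common"` (intersection; default) or `"union"`.
#' @return list with `merged` (ExpressionStudy) and `report` (list:
#'   `n_common`, `n_unique` named by batch, `n_union`).
#' @export
merge_studies <- function(studies, scope = c("common", "union")) {
  scope <- match.arg(scope)
  if (length(studies) < 2) stopf("need at least two studies to merge")
  gene_sets <- lapply(studies, gene_ids)
  common <- Reduce(intersect, gene_sets)
  union_g <- Reduce(union, gene_sets)
  if (length(common) == 0) stopf("empty gene intersection across studies")
  batch_of <- vapply(studies, function(s) s$batch[1], "")
  n_unique <- stats::setNames(
    vapply(seq_along(studies), function(i) {
      length(setdiff(gene_sets[[i]], unlist(gene_sets[-i])))
    }, integer(1)),
    batch_of)
  report <- list(n_common = length(common), n_unique = n_unique,
                 n_union = length(union_g))
  keep <- if (scope == "common") common else union_g
  mats <- lapply(studies, function(s) {
    m <- matrix(NA_real_, length(keep), ncol(s$values),
                dimnames = list(keep, sample_ids(s)))
    present <- intersect(keep, gene_ids(s))
    m[present, ] <- s$values[present, , drop = FALSE]
    m
  })
  merged <- expression_study(do.call(cbind, mats),
                             unlist(lapply(studies, `[[`, "condition")),
                             unlist(lapply(studies, `[[`, "batch")))
  list(merged = merged, report = report)
}
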