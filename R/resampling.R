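#' Draw random virtual cohorts (RDS designs) from the pooled cohort
#'
#' Each RDS (random microarray data set) is a seeded subset of the merged
#' cross-study cohort: samples are drawn uniformly without replacement
#' within each condition, ignoring study of origin, so virtual cohorts mix
#' both studies. `"auto"` takes `ceiling(min_total/2)` per group, capped by
#' availability and topped up from the larger group to reach `min_total`.
#'
#' @param metadata data.frame with `sample_id`, `condition`, `batch`.
#' @param n_rds number of virtual cohorts to draw.
#' @param min_total minimum samples per cohort (default 12).
#' @param per_group `"auto"` or a named count vector `c(UC=, CRC=)`.
#' @param seed integer seed.
#' @return list of `rds_design` lists (`rds_id`, `uc_samples`,
#'   `crc_samples`, `seed`).
#' @export
draw_rds <- function(metadata, n_rds = 8L, min_total = 12L,
                     per_group = "auto", seed = 1L) {
  uc_all <- metadata$sample_id[metadata$condition == "UC"]
  crc_all <- metadata$sample_id[metadata$condition == "CRC"]
  if (identical(per_group, "auto")) {
    half <- ceiling(min_total / 2)
    n_uc <- min(half, length(uc_all))
    n_crc <- min(max(half, min_total - n_uc), length(crc_all))
    if (n_uc + n_crc < min_total)
      n_uc <- min(min_total - n_crc, length(uc_all))
  } else {
    n_uc <- per_group[["UC"]]
    n_crc <- per_group[["CRC"]]
  }
  if (n_uc > length(uc_all) || n_crc > length(crc_all))
    stopf("infeasible RDS request: need UC=%d of %d, CRC=%d of %d",
          n_uc, length(uc_all), n_crc, length(crc_all))
  if (n_uc + n_crc < min_total)
    stopf("pooled cohort too small for min_total = %d", min_total)
  if (n_uc < 2 || n_crc < 2)
    stopf("each RDS group needs >= 2 samples")
  with_seed(seed, {
    lapply(seq_len(n_rds), function(r) {
      structure(list(rds_id = r,
                     uc_samples = sort(sample(uc_all, n_uc)),
                     crc_samples = sort(sample(crc_all, n_crc)),
                     seed = as.integer(seed) + r),
                class = "rds_design")
    })
  })
}

#' Run the SAM screen on every virtual cohort
#'
#' One DETable per RDS, produced by [sam_de()] on the design's subset of
#' the merged matrix. Per-RDS failures are caught and reported without
#' aborting the batch.
#'
#' @param merged merged [expression_study()].
#' @param designs list from [draw_rds()].
#' @param params a [sam_params()]; the permutation seed is offset by each
#'   design's own seed so cohorts are independently reproducible.
#' @return list with `tables` (list of DETables, `NULL` where failed) and
#'   `failures` (named character of error messages).
#' @export
run_rds_screen <- function(merged, designs, params = sam_params()) {
  failures <- character(0)
  tables <- lapply(designs, function(des) {
    tryCatch({
      sub <- subset_samples(merged, c(des$uc_samples, des$crc_samples))
      p <- params
      p$seed <- des$seed
      sam_de(sub$values, sub$condition, p)
    }, error = function(e) {
      failures[[as.character(des$rds_id)]] <<- conditionMessage(e)
      NULL
    })
  })
  if (length(failures))
    warnf("%d RDS screen(s) failed: %s", length(failures),
          paste(names(failures), collapse = ", "))
  list(tables = tables, failures = failures)
}

#' Tabulate recurrent driver genes and robust modules across cohorts
#'
#' A driver gene is one called differential in at least one virtual
#' cohort and mapping into a detected network module. A module is flagged
#' robust when at least one of its member genes is called in at least
#' `min_recurrence` distinct cohorts.
#'
#' @param de_tables list of DETables (from [run_rds_screen()]).
#' @param modules named integer vector: gene -> module id (genes absent
#'   are outside every module).
#' @param min_recurrence distinct-cohort threshold for robustness.
#' @return a `robustness` list with `genes` (gene, n_rds_called,
#'   modules_hit) and `modules` (module, n_rds_hit, robust, driver_genes).
#' @export
robust_drivers <- function(de_tables, modules, min_recurrence = 3L) {
  de_tables <- Filter(Negate(is.null), de_tables)
  all_genes <- sort(unique(unlist(lapply(de_tables, `[[`, "gene"))))
  call_mat <- vapply(de_tables, function(tab) {
    called <- tab$gene[tab$called]
    all_genes %in% called
  }, logical(length(all_genes)))
  call_mat <- matrix(call_mat, nrow = length(all_genes))
  n_called <- rowSums(call_mat)
  mod_of <- modules[all_genes]
  genes <- data.frame(
    gene = all_genes,
    n_rds_called = n_called,
    module = unname(mod_of),
    stringsAsFactors = FALSE
  )
  mod_ids <- sort(unique(modules))
  mod_rows <- lapply(mod_ids, function(m) {
    members <- names(modules)[modules == m]
    in_mod <- all_genes %in% members
    # distinct RDSs in which any member gene was called
    rds_hit <- which(colSums(call_mat[in_mod, , drop = FALSE]) > 0)
    drivers <- all_genes[in_mod & n_called > 0]
    data.frame(module = m, n_rds_hit = length(rds_hit),
               robust = length(rds_hit) >= min_recurrence,
               driver_genes = paste(drivers, collapse = ","),
               stringsAsFactors = FALSE)
  })
  structure(list(genes = genes, modules = do.call(rbind, mod_rows),
                 min_recurrence = min_recurrence),
            class = "robustness")
}
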