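#' Pipeline configuration
#'
#' Collects input paths and every stage's parameters. Accepts a YAML file
#' path or an R list; all referenced paths are validated before any stage
#' runs.
#'
#' @param expression character vector of expression TSV paths (one per
#'   study).
#' @param metadata path to the sample metadata TSV.
#' @param network path to the SIF/edge-list interaction file.
#' @param localization path to the gene localization TSV.
#' @param genesets path to the GMT collection.
#' @param outdir output directory.
#' @param seed global seed; stages use `seed + stage index`.
#' @param eb_mode `"parametric"` or `"nonparametric"`.
#' @param merge_scope `"common"` or `"union"`.
#' @param n_rds,min_total virtual-cohort design (see [draw_rds()]).
#' @param min_recurrence robustness threshold (see [robust_drivers()]).
#' @param sam a [sam_params()].
#' @param mcode an [mcode_params()].
#' @param enrichment_fdr BH-FDR cutoff for enrichment cells.
#' @param ease EASE count deflation flag.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(expression, metadata, network, localization,
                            genesets, outdir, seed = 1L,
                            eb_mode = "parametric",
                            merge_scope = "common", n_rds = 8L,
                            min_total = 12L, min_recurrence = 3L,
                            sam = sam_params(), mcode = mcode_params(),
                            enrichment_fdr = 0.01, ease = FALSE) {
  cfg <- list(expression = expression, metadata = metadata,
              network = network, localization = localization,
              genesets = genesets, outdir = outdir, seed = as.integer(seed),
              eb_mode = eb_mode, merge_scope = merge_scope,
              n_rds = as.integer(n_rds), min_total = as.integer(min_total),
              min_recurrence = as.integer(min_recurrence), sam = sam,
              mcode = mcode, enrichment_fdr = enrichment_fdr, ease = ease)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()]; `sam` and
#'   `mcode` sub-maps are passed to their constructors.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$sam <- do.call(sam_params, y$sam %||% list())
  y$mcode <- do.call(mcode_params, y$mcode %||% list())
  do.call(pipeline_config, y)
}

validate_config <- function(config) {
  paths <- c(config$expression, config$metadata, config$network,
             config$localization, config$genesets)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stopf("missing input file(s): %s", paste(missing, collapse = ", "))
  invisible(TRUE)
}

run_stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full integration and layered-network pipeline
#'
#' Stages, in order: per-study quantile normalization; cross-study merge;
#' empirical-Bayes batch adjustment; virtual-cohort (RDS) SAM screen;
#' network load, largest component, MCODE module detection; driver
#' mapping and robustness; layer assignment and layered layout;
#' (module x layer) hypergeometric enrichment; clustered heatmap matrix.
#' Every stage writes its table under `outdir` and the manifest records
#' inputs (hashed), parameters, seeds, and per-stage outputs sufficient to
#' re-run bit-identically.
#'
#' @param config a [pipeline_config()] or path to its YAML.
#' @return the run manifest (list), invisibly-written to
#'   `outdir/manifest.yaml`; key results are attached under `$results`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  md <- read_metadata_tsv(config$metadata)
  studies <- run_stage("normalize", {
    lapply(config$expression, function(p) {
      m <- read_expression_tsv(p)
      idx <- match(colnames(m), md$sample_id)
      if (anyNA(idx)) stopf("%s: sample ids missing from metadata", p)
      rank_normalize(expression_study(m, md$condition[idx], md$batch[idx]))
    })
  })

  merged_res <- run_stage("integrate", {
    mg <- merge_studies(studies, scope = config$merge_scope)
    adj <- eb_batch_adjust(mg$merged, mode = config$eb_mode)
    list(report = mg$report, adjusted = adj$adjusted, model = adj$model)
  })
  merged <- merged_res$adjusted
  write_expression_tsv(merged$values,
                       file.path(config$outdir, "integrated.tsv"))

  screen <- run_stage("rds_sam", {
    designs <- draw_rds(md, n_rds = config$n_rds,
                        min_total = config$min_total,
                        seed = stage_seed(seed, 3))
    res <- run_rds_screen(merged, designs, config$sam)
    for (i in seq_along(res$tables))
      if (!is.null(res$tables[[i]]))
        write_detable_tsv(res$tables[[i]],
                          file.path(config$outdir,
                                    sprintf("detable_rds%d.tsv", i)))
    c(res, list(designs = designs))
  })

  network_res <- run_stage("network_mcode", {
    net <- load_network(config$network)
    net <- largest_component(net)
    cxs <- mcode_complexes(net, config$mcode)
    write_tsv_schema(complexes_table(cxs),
                     file.path(config$outdir, "complexes.tsv"),
                     "complexes")
    list(net = net, complexes = cxs,
         membership = complex_membership(cxs))
  })

  robustness <- run_stage("drivers", {
    rb <- robust_drivers(screen$tables, network_res$membership,
                         min_recurrence = config$min_recurrence)
    write_tsv_schema(rb$genes,
                     file.path(config$outdir, "robustness_genes.tsv"),
                     "robustness")
    write_tsv_schema(rb$modules,
                     file.path(config$outdir, "robustness_modules.tsv"),
                     "robustness")
    rb
  })
  mapped <- run_stage("map_drivers", {
    map_drivers(network_res$net, network_res$membership, robustness)
  })

  layers_res <- run_stage("layers", {
    loc <- read_localization_tsv(config$localization)
    asg <- assign_layers(mapped$graph, loc)
    write_tsv_schema(asg, file.path(config$outdir, "layers.tsv"), "layers")
    layout <- layered_layout(mapped$graph, asg)
    write_tsv_schema(layout, file.path(config$outdir, "layout.tsv"),
                     "layout")
    write_graphml(mapped$graph,
                  file.path(config$outdir, "network_annotated.graphml"))
    list(assignment = asg, layout = layout)
  })

  enr <- run_stage("enrichment", {
    sets <- read_gmt(config$genesets)
    universe <- intersect(gene_ids(merged), igraph::V(mapped$graph)$name)
    cells <- enrich_module_layers(network_res$membership,
                                  layers_res$assignment, sets, universe,
                                  fdr_cutoff = config$enrichment_fdr,
                                  ease = config$ease)
    write_tsv_schema(cells, file.path(config$outdir, "enrichment.tsv"),
                     "enrichment")
    hm <- build_heatmap(cells, cutoff = config$enrichment_fdr)
    if (!hm$empty)
      write_tsv_schema(
        data.frame(row = rownames(hm$matrix), hm$matrix,
                   check.names = FALSE),
        file.path(config$outdir, "heatmap_matrix.tsv"), "heatmap")
    list(cells = cells, heatmap = hm)
  })

  manifest <- list(
    seed = seed,
    inputs = lapply(
      stats::setNames(as.list(c(config$expression, config$metadata,
                                config$network, config$localization,
                                config$genesets)),
                      basename(c(config$expression, config$metadata,
                                 config$network, config$localization,
                                 config$genesets))),
      function(p) unname(tools::md5sum(p))),
    parameters = list(eb_mode = config$eb_mode,
                      merge_scope = config$merge_scope,
                      n_rds = config$n_rds, min_total = config$min_total,
                      min_recurrence = config$min_recurrence,
                      sam = unclass(config$sam),
                      mcode = unclass(config$mcode),
                      enrichment_fdr = config$enrichment_fdr,
                      ease = config$ease),
    versions = list(layernet = as.character(utils::packageVersion("layernet")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    merge_report = merged_res$report,
    counts = list(
      network_nodes = igraph::vcount(network_res$net),
      network_edges = igraph::ecount(network_res$net),
      n_complexes = length(network_res$complexes),
      n_robust_modules = sum(robustness$modules$robust %||% FALSE),
      n_driver_genes = sum(robustness$genes$n_rds_called > 0),
      n_significant_cells = sum(enr$cells$significant)
    ),
    outputs = sort(unique(c(list.files(config$outdir), "manifest.yaml")))
  )
  yaml::write_yaml(manifest, file.path(config$outdir, "manifest.yaml"))
  manifest$results <- list(merged = merged, model = merged_res$model,
                           screen = screen, network = network_res,
                           robustness = robustness, mapped = mapped,
                           layers = layers_res, enrichment = enr)
  invisible(manifest)
}
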