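#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions the generator emulates: two microarray
#' cohorts on partially overlapping platforms, per-gene additive and
#' multiplicative batch effects following the empirical-Bayes location/scale
#' generative model, a planted fraction of differentially expressed (DE)
#' genes between ulcerative colitis (UC) and colorectal carcinoma (CRC), a
#' planted-partition interaction network whose dense modules overlap the
#' expression gene universe, partially missing subcellular localization
#' labels, and gene-set collections with planted enrichment.
#'
#' @param n_genes total genes in the union universe.
#' @param n_common genes shared by both platforms; the remainder is split
#'   evenly into platform-private genes.
#' @param samples_per_group_per_study samples per condition in each study
#'   (must be >= 2; per-gene variances are undefined downstream otherwise).
#' @param de_fraction proportion of common genes with a planted condition
#'   effect.
#' @param de_effect absolute log2 mean shift of planted DE genes (sign is
#'   randomized per gene: up- or down-regulation in CRC).
#' @param batch_gamma_sd standard deviation of the per-gene additive batch
#'   effects (gamma ~ Normal(0, batch_gamma_sd^2)).
#' @param batch_delta_shape shape of the inverse-gamma-like positive
#'   distribution of multiplicative batch effects; delta = 1/Gamma(shape,
#'   rate = shape - 1) so E[delta] = 1 and spread shrinks as shape grows.
#'   Must be > 2 so the variance exists.
#' @param noise_sd residual standard deviation on the log2 scale.
#' @param module_sizes integer vector of planted network module sizes
#'   (each >= 3).
#' @param background_edge_prob edge probability outside modules.
#' @param within_module_edge_prob edge probability inside a module; must
#'   exceed `background_edge_prob`.
#' @param localization_missing_rate proportion of localization labels masked
#'   to `unknown`.
#' @param n_background_nodes network nodes outside the planted modules,
#'   drawn from the non-DE expression universe.
#' @param n_driver_modules how many planted modules are seeded with DE genes
#'   (the "driver" modules a robust screen should recover; default 3,
#'   matching the three recurrent signaling clusters the method is built to
#'   find).
#' @param seed integer seed; all generation is bit-reproducible given it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       n_common = 1800,
                       samples_per_group_per_study = 8,
                       de_fraction = 0.10,
                       de_effect = 2.0,
                       batch_gamma_sd = 0.5,
                       batch_delta_shape = 4,
                       noise_sd = 0.5,
                       module_sizes = c(12, 10, 8, 8, 6, 6, 5, 5),
                       background_edge_prob = 0.01,
                       within_module_edge_prob = 0.8,
                       localization_missing_rate = 0.3,
                       n_background_nodes = 240,
                       n_driver_modules = 3,
                       seed = 1L) {
  cfg <- list(n_genes = n_genes, n_common = n_common,
              samples_per_group_per_study = samples_per_group_per_study,
              de_fraction = de_fraction, de_effect = de_effect,
              batch_gamma_sd = batch_gamma_sd,
              batch_delta_shape = batch_delta_shape, noise_sd = noise_sd,
              module_sizes = as.integer(module_sizes),
              background_edge_prob = background_edge_prob,
              within_module_edge_prob = within_module_edge_prob,
              localization_missing_rate = localization_missing_rate,
              n_background_nodes = n_background_nodes,
              n_driver_modules = n_driver_modules,
              seed = as.integer(seed))
  props <- c("de_fraction", "background_edge_prob",
             "within_module_edge_prob", "localization_missing_rate")
  for (p in props)
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stopf("`%s` must lie in [0, 1]", p)
  if (cfg$n_common > cfg$n_genes) stopf("n_common must be <= n_genes")
  if (sum(cfg$module_sizes) > cfg$n_genes)
    stopf("module sizes must sum to <= n_genes")
  if (any(cfg$module_sizes < 3)) stopf("every module size must be >= 3")
  if (cfg$within_module_edge_prob <= cfg$background_edge_prob)
    stopf("within_module_edge_prob must exceed background_edge_prob")
  if (cfg$samples_per_group_per_study < 2)
    stopf("samples_per_group_per_study must be >= 2")
  if (cfg$batch_delta_shape <= 2)
    stopf("batch_delta_shape must be > 2")
  if (cfg$n_driver_modules > length(cfg$module_sizes))
    stopf("n_driver_modules exceeds the number of planted modules")
  class(cfg) <- "sim_config"
  cfg
}

# inverse-gamma draw scaled to mean 1; degenerate at 1 as shape -> Inf
rinvgamma1 <- function(n, shape) {
  if (!is.finite(shape)) return(rep(1, n))
  (shape - 1) / stats::rgamma(n, shape = shape, rate = 1)
}

#' Generate two synthetic expression cohorts with known ground truth
#'
#' Expression for gene g, sample j in batch i is
#' `alpha_g + x_j * beta_g + gamma_ig + delta_ig * eps_gj` with
#' `eps ~ Normal(0, noise_sd^2)`, `x_j = 1` for CRC samples,
#' `beta_g = +/- de_effect` for planted DE genes (0 otherwise),
#' `gamma_ig ~ Normal(0, batch_gamma_sd^2)` and `delta_ig` positive with
#' spread set by `batch_delta_shape`. Values are on the log2 scale.
#' Platform-private genes appear in only one study.
#'
#' @param config a [sim_config()].
#' @return list with `studies` (list of two [expression_study()] objects)
#'   and `truth` (ground-truth list: `de_genes`, `de_sign`, `beta`,
#'   `gamma`, `delta` matrices gene x batch, `alpha`).
#' @export
gen_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    n_priv <- config$n_genes - config$n_common
    common <- genes[seq_len(config$n_common)]
    priv <- setdiff(genes, common)
    priv1 <- priv[seq_len(ceiling(n_priv / 2))]
    priv2 <- setdiff(priv, priv1)

    n_de <- round(config$de_fraction * config$n_common)
    de_genes <- if (n_de > 0) sort(sample(common, n_de)) else character(0)
    de_sign <- stats::setNames(sample(c(-1, 1), n_de, replace = TRUE),
                               de_genes)
    beta <- stats::setNames(numeric(config$n_genes), genes)
    beta[de_genes] <- config$de_effect * de_sign

    alpha <- stats::setNames(stats::rnorm(config$n_genes, mean = 7, sd = 1),
                             genes)
    gamma <- matrix(stats::rnorm(2 * config$n_genes, 0,
                                 config$batch_gamma_sd),
                    nrow = config$n_genes, ncol = 2,
                    dimnames = list(genes, c("study1", "study2")))
    delta <- matrix(rinvgamma1(2 * config$n_genes, config$batch_delta_shape),
                    nrow = config$n_genes, ncol = 2,
                    dimnames = list(genes, c("study1", "study2")))
    if (config$batch_gamma_sd == 0) gamma[] <- 0

    nspg <- config$samples_per_group_per_study
    make_study <- function(study_genes, batch_idx, batch_name) {
      ns <- 2 * nspg
      cond <- rep(CONDITION_LEVELS, each = nspg)
      sids <- sprintf("%s_%s%02d", batch_name,
                      ifelse(cond == "UC", "UC", "CRC"),
                      c(seq_len(nspg), seq_len(nspg)))
      g <- length(study_genes)
      eps <- matrix(stats::rnorm(g * ns, 0, config$noise_sd), g, ns)
      x <- as.numeric(cond == "CRC")
      vals <- alpha[study_genes] +
        outer(beta[study_genes], x) +
        gamma[study_genes, batch_idx] +
        delta[study_genes, batch_idx] * eps
      dimnames(vals) <- list(study_genes, sids)
      expression_study(vals, cond, rep(batch_name, ns))
    }
    studies <- list(
      study1 = make_study(c(common, priv1), 1, "study1"),
      study2 = make_study(c(common, priv2), 2, "study2")
    )
    truth <- list(de_genes = de_genes, de_sign = de_sign, beta = beta,
                  alpha = alpha, gamma = gamma, delta = delta,
                  common_genes = common,
                  private_genes = list(study1 = priv1, study2 = priv2))
    list(studies = studies, truth = truth)
  })
}

#' Generate a planted-partition interaction network with layer labels
#'
#' Draws a planted-partition graph over a subset of the expression gene
#' universe: edges inside each planted module with
#' `within_module_edge_prob`, background edges with `background_edge_prob`.
#' The first `n_driver_modules` modules are composed of planted DE genes
#' (the driver modules), the remaining modules and all background nodes of
#' non-DE genes. Each module is assigned a dominant subcellular layer
#' (cycled through the four layers) whose labels are unanimous within the
#' module; background nodes get random layers; labels are then masked to
#' `unknown` at `localization_missing_rate`. Planted modules are checked
#' for connectedness and redrawn (up to 50 attempts) if disconnected.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [gen_expression()].
#' @return list with `graph` (igraph), `localization` (data.frame gene,
#'   layer as observed, i.e. possibly masked) and `truth` extended with
#'   `module_membership`, `true_layers`, `driver_modules`.
#' @export
gen_network <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    sizes <- config$module_sizes
    k <- length(sizes)
    n_drv <- config$n_driver_modules
    need_de <- sum(sizes[seq_len(n_drv)])
    if (length(truth$de_genes) < need_de)
      stopf("not enough planted DE genes (%d) to fill %d driver modules (%d needed)",
            length(truth$de_genes), n_drv, need_de)
    de_pool <- sample(truth$de_genes)
    nonde_pool <- sample(setdiff(truth$common_genes, truth$de_genes))

    membership <- character(0)
    taken_de <- 0; taken_bg <- 0
    module_nodes <- vector("list", k)
    for (m in seq_len(k)) {
      if (m <= n_drv) {
        nodes <- de_pool[taken_de + seq_len(sizes[m])]
        taken_de <- taken_de + sizes[m]
      } else {
        nodes <- nonde_pool[taken_bg + seq_len(sizes[m])]
        taken_bg <- taken_bg + sizes[m]
      }
      module_nodes[[m]] <- nodes
    }
    background <- nonde_pool[taken_bg + seq_len(min(config$n_background_nodes,
                                                    length(nonde_pool) - taken_bg))]
    nodes <- c(unlist(module_nodes), background)
    membership <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
    for (m in seq_len(k)) membership[module_nodes[[m]]] <- m

    n <- length(nodes)
    # background edges across the whole graph
    draw_edges <- function() {
      pairs <- utils::combn(nodes, 2)
      m1 <- membership[pairs[1, ]]
      m2 <- membership[pairs[2, ]]
      same <- !is.na(m1) & !is.na(m2) & m1 == m2
      p <- ifelse(same, config$within_module_edge_prob,
                  config$background_edge_prob)
      keep <- stats::runif(ncol(pairs)) < p
      pairs[, keep, drop = FALSE]
    }
    ok <- FALSE
    for (attempt in seq_len(50)) {
      el <- draw_edges()
      g <- igraph::graph_from_edgelist(t(el), directed = FALSE)
      g <- igraph::add_vertices(g, length(setdiff(nodes, igraph::V(g)$name)),
                                name = setdiff(nodes, igraph::V(g)$name))
      connected <- vapply(module_nodes, function(mn) {
        sub <- igraph::induced_subgraph(g, mn)
        igraph::is_connected(sub)
      }, logical(1))
      if (all(connected)) { ok <- TRUE; break }
    }
    if (!ok) stopf("failed to generate connected planted modules in 50 draws")

    # unanimous module layers, cycled; random layers for background
    module_layer <- LAYER_LEVELS[((seq_len(k) - 1) %% 4) + 1]
    true_layers <- stats::setNames(rep(NA_character_, n), nodes)
    for (m in seq_len(k)) true_layers[module_nodes[[m]]] <- module_layer[m]
    true_layers[background] <- sample(LAYER_LEVELS, length(background),
                                      replace = TRUE)
    observed <- true_layers
    masked <- stats::runif(n) < config$localization_missing_rate
    observed[masked] <- "unknown"

    truth$module_membership <- membership
    truth$true_layers <- true_layers
    truth$driver_modules <- seq_len(n_drv)
    truth$module_nodes <- module_nodes
    list(graph = g,
         localization = data.frame(gene = nodes, layer = unname(observed),
                                   stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Generate a gene-set collection with planted enriched terms
#'
#' Emits one planted term per planted module (the module's gene list plus a
#' few random extras, so overlap is far above chance) and a stated number of
#' random background terms drawn uniformly from the gene universe.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [gen_network()].
#' @param n_random number of random background terms.
#' @param random_size_range size range of random terms.
#' @return named list of character vectors (GMT-ready); planted terms are
#'   named `PLANTED_M<module>`.
#' @export
gen_genesets <- function(config, truth, n_random = 30,
                         random_size_range = c(10, 40)) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth$module_nodes))
    stopf("truth lacks module membership; run gen_network() first")
  with_seed(config$seed + 2L, {
    universe <- names(truth$beta)
    sets <- list()
    for (m in seq_along(truth$module_nodes)) {
      extra <- sample(setdiff(universe, truth$module_nodes[[m]]), 3)
      s <- c(truth$module_nodes[[m]], extra)
      attr(s, "description") <- sprintf("planted term for module %d", m)
      sets[[sprintf("PLANTED_M%d", m)]] <- s
    }
    for (r in seq_len(n_random)) {
      sz <- sample(random_size_range[1]:random_size_range[2], 1)
      s <- sample(universe, sz)
      attr(s, "description") <- "random background term"
      sets[[sprintf("RANDOM_%02d", r)]] <- s
    }
    sets
  })
}

#' Generate and write a complete synthetic input bundle
#'
#' Writes the expression TSVs, metadata TSV, SIF edge list, localization
#' TSV and GMT collection for a full pipeline run, plus the ground truth
#' as JSON-free plain TSVs where meaningful.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with `paths`, `truth` and the in-memory
#'   objects.
#' @export
simulate_bundle <- function(config = sim_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  expr <- gen_expression(config)
  net <- gen_network(config, expr$truth)
  sets <- gen_genesets(config, net$truth)
  paths <- list(
    expression = file.path(outdir,
                           sprintf("expression_%s.tsv",
                                   names(expr$studies))),
    metadata = file.path(outdir, "metadata.tsv"),
    network = file.path(outdir, "network.sif"),
    localization = file.path(outdir, "localization.tsv"),
    genesets = file.path(outdir, "genesets.gmt")
  )
  md <- do.call(rbind, lapply(expr$studies, function(s)
    data.frame(sample_id = sample_ids(s), condition = s$condition,
               batch = s$batch, stringsAsFactors = FALSE)))
  rownames(md) <- NULL
  for (i in seq_along(expr$studies))
    write_expression_tsv(expr$studies[[i]]$values, paths$expression[i])
  write_metadata_tsv(md, paths$metadata)
  write_sif(net$graph, paths$network)
  write_localization_tsv(net$localization, paths$localization)
  write_gmt(sets, paths$genesets)
  invisible(list(paths = paths, truth = net$truth, studies = expr$studies,
                 graph = net$graph, localization = net$localization,
                 genesets = sets, config = config))
}
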