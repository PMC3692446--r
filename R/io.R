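#' @name io
#' @title Readers and writers for the pipeline's plain-text formats
#'
#' @description
#' All tables are tab-separated with a header row and a leading
#' schema-version comment line (`# layernet <table> v1`); readers skip
#' comment lines, tolerate Windows line endings, and report the file and
#' rule violated on malformed input. Every writer's output round-trips
#' through the matching reader unchanged.
NULL

SCHEMA <- function(kind) sprintf("# layernet %s v1", kind)

read_tsv_checked <- function(path, required_cols, kind) {
  if (!file.exists(path)) stopf("%s: file not found", path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, colnames(df))
  if (length(missing))
    stopf("%s: %s table is missing column(s): %s",
          path, kind, paste(missing, collapse = ", "))
  df
}

write_tsv_schema <- function(df, path, kind) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(SCHEMA(kind), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an expression matrix TSV
#'
#' Rows are genes (first column `gene`), remaining columns are samples.
#' Duplicated gene ids are a hard error on read.
#'
#' @param values gene x sample numeric matrix with dimnames.
#' @param path file path.
#' @return `read_expression_tsv` returns the matrix; writers return the path.
#' @export
write_expression_tsv <- function(values, path) {
  df <- data.frame(gene = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_schema(df, path, "expression")
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv_checked(path, "gene", "expression")
  if (anyDuplicated(df$gene))
    stopf("%s: duplicated gene id '%s'", path, df$gene[duplicated(df$gene)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stopf("%s: non-numeric expression values", path)
  rownames(m) <- df$gene
  m
}

#' Write / read the sample metadata TSV
#'
#' Columns: `sample_id`, `condition` (UC/CRC), `batch`.
#'
#' @param metadata data.frame with the three columns above.
#' @param path file path.
#' @export
write_metadata_tsv <- function(metadata, path) {
  write_tsv_schema(metadata[, c("sample_id", "condition", "batch")], path,
                   "metadata")
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "condition", "batch"),
                         "metadata")
  bad <- setdiff(unique(df$condition), CONDITION_LEVELS)
  if (length(bad))
    stopf("%s: unknown condition label(s): %s", path,
          paste(bad, collapse = ", "))
  df
}

#' Write / read a SIF / edge-list interaction file
#'
#' Three-column SIF (`nodeA<TAB>relation<TAB>nodeB`) or a plain two-column
#' edge list. Windows line endings are tolerated. Malformed lines are
#' reported with their line numbers.
#'
#' @param graph an igraph object (for writing).
#' @param path file path.
#' @param relation interaction type string written in column 2.
#' @return `read_sif` returns a data.frame of edges (`from`, `to`);
#'   use [load_network()] to get a cleaned igraph.
#' @export
write_sif <- function(graph, path, relation = "pp") {
  el <- igraph::as_edgelist(graph)
  lines <- sprintf("%s\t%s\t%s", el[, 1], relation, el[, 2])
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sif
#' @export
read_sif <- function(path) {
  if (!file.exists(path)) stopf("%s: file not found", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- idx[!(nfield %in% c(2L, 3L))]
  if (length(bad))
    stopf("%s: malformed line(s) (need 2 or 3 tab-separated fields): %s",
          path, paste(utils::head(bad, 5), collapse = ", "))
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, function(p) p[[length(p)]], "")
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' Write / read a GMT gene-set collection
#'
#' One set per line: `term<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param sets named list of character vectors (names are term ids); an
#'   optional `description` attribute per element is written in column 2.
#' @param path file path.
#' @return `read_gmt` returns a named list of character vectors with a
#'   `description` attribute on each element.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description") %||% "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("%s: file not found", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stopf("%s: GMT line(s) with fewer than 3 fields: %s", path,
          paste(utils::head(short, 5), collapse = ", "))
  sets <- lapply(parts, function(p) {
    genes <- p[-(1:2)]
    attr(genes, "description") <- p[[2]]
    genes
  })
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stopf("%s: duplicated term id '%s'", path,
          names(sets)[duplicated(names(sets))][1])
  sets
}

#' Write / read a gene localization TSV
#'
#' Columns `gene`, `layer`; `layer` is one of extracellular, membrane,
#' cytoplasm, nucleus, or `unknown`.
#'
#' @param table data.frame with columns `gene`, `layer`.
#' @param path file path.
#' @export
write_localization_tsv <- function(table, path) {
  write_tsv_schema(table[, c("gene", "layer")], path, "localization")
}

#' @rdname write_localization_tsv
#' @export
read_localization_tsv <- function(path) {
  df <- read_tsv_checked(path, c("gene", "layer"), "localization")
  bad <- setdiff(unique(df$layer), c(LAYER_LEVELS, "unknown"))
  if (length(bad))
    stopf("%s: unknown layer label(s): %s", path, paste(bad, collapse = ", "))
  df
}

#' Write / read a differential-expression (DETable) TSV
#'
#' Per-gene SAM results: statistic `d`, pooled standard error `s`,
#' `fold_change` (anti-logged CRC/UC ratio), estimated FDR `q`, `called`
#' flag, and `direction`.
#'
#' @param detable data.frame as returned by [sam_de()].
#' @param path file path.
#' @export
write_detable_tsv <- function(detable, path) {
  write_tsv_schema(detable, path, "detable")
}

#' @rdname write_detable_tsv
#' @export
read_detable_tsv <- function(path) {
  df <- read_tsv_checked(path, c("gene", "d", "s", "fold_change", "q",
                                 "called", "direction"), "detable")
  df$called <- as.logical(df$called)
  df
}

#' Write an annotated network as GraphML
#'
#' @param graph igraph object (node attributes are carried along).
#' @param path file path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
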