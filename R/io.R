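#' Read an omics contrast table from TSV
#'
#' Reads a tab-separated table with a header and maps its columns onto the
#' common analyte-statistic schema (`gene_name`, `difference`,
#' `significant`; phospho tables add `residue`). A p-value column can stand
#' in for the significance flag (`significant = p < 0.05`). Type-coercion
#' failures are reported with row addresses.
#'
#' @param path TSV file path
#' @param mapping named list mapping schema names to file column names,
#'   e.g. `list(gene_name = "Gene", difference = "logFC", p_value = "adj.P")`
#' @param p_threshold significance threshold when a p-value column is mapped
#' @return a validated tibble
#' @export
read_omics_table <- function(path, mapping = list(), p_threshold = 0.05) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (schema_col in names(mapping)) {
    file_col <- mapping[[schema_col]]
    if (!file_col %in% names(tbl)) {
      abort(sprintf("read_omics_table: mapped column '%s' not found in %s", file_col, path))
    }
    names(tbl)[names(tbl) == file_col] <- schema_col
  }
  require_columns(tbl, c("gene_name", "difference"), path)
  diffs <- suppressWarnings(as.numeric(tbl$difference))
  bad <- which(is.na(diffs) & !is.na(tbl$difference))
  if (length(bad)) {
    abort(sprintf("read_omics_table: non-numeric 'difference' at row(s) %s of %s",
                  paste(head(bad, 5), collapse = ", "), path))
  }
  tbl$difference <- diffs
  if (!"significant" %in% names(tbl) && "p_value" %in% names(tbl)) {
    tbl$significant <- tbl$p_value < p_threshold
  }
  if ("significant" %in% names(tbl)) tbl$significant <- as.logical(tbl$significant)
  tbl
}

#' Write a PKN as SIF plus attribute tables
#'
#' The SIF dialect encodes edge signs as relation tokens: `activates` for
#' +1 and `inhibits` for -1. Edge attributes (direct, mechanism, residue,
#' source_db) and node attributes go to companion TSVs.
#'
#' @param pkn a [pkn] object
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return invisibly, the paths written
#' @export
write_pkn <- function(pkn, dir, prefix = "pkn") {
  stopifnot(inherits(pkn, "pkn"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sif <- file.path(dir, paste0(prefix, ".sif"))
  writeLines(paste(pkn$edges$source,
                   ifelse(pkn$edges$sign > 0, "activates", "inhibits"),
                   pkn$edges$target, sep = "\t"), sif)
  epath <- file.path(dir, paste0(prefix, "_edges.tsv"))
  readr::write_tsv(pkn$edges, epath, progress = FALSE)
  npath <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  readr::write_tsv(pkn$nodes, npath, progress = FALSE)
  invisible(c(sif, epath, npath))
}

#' Read a PKN from the attribute tables written by [write_pkn()]
#' @param dir directory containing `<prefix>_edges.tsv` / `<prefix>_nodes.tsv`
#' @param prefix file-name prefix
#' @return a [pkn] object
#' @export
read_pkn <- function(dir, prefix = "pkn") {
  edges <- readr::read_tsv(file.path(dir, paste0(prefix, "_edges.tsv")),
                           show_col_types = FALSE, progress = FALSE)
  nodes <- readr::read_tsv(file.path(dir, paste0(prefix, "_nodes.tsv")),
                           show_col_types = FALSE, progress = FALSE)
  pkn(edges, nodes)
}

#' Export a signaling model as SIF, attribute TSVs and GraphML
#'
#' @param model a `signaling_model`
#' @param dir output directory
#' @param prefix file-name prefix
#' @return invisibly, the paths written
#' @export
write_model <- function(model, dir, prefix = "model") {
  stopifnot(inherits(model, "signaling_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sif <- file.path(dir, paste0(prefix, ".sif"))
  writeLines(paste(model$edges$source,
                   ifelse(model$edges$sign > 0, "activates", "inhibits"),
                   model$edges$target, sep = "\t"), sif)
  npath <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  readr::write_tsv(model$nodes, npath, progress = FALSE)
  epath <- file.path(dir, paste0(prefix, "_edges.tsv"))
  readr::write_tsv(model$edges, epath, progress = FALSE)
  gpath <- file.path(dir, paste0(prefix, ".graphml"))
  g <- model_graph(model)
  # GraphML cannot hold NA attribute values
  for (a in igraph::edge_attr_names(g)) {
    v <- igraph::edge_attr(g, a)
    if (is.character(v)) v[is.na(v)] <- ""
    if (is.logical(v)) v <- as.integer(v)
    v[is.na(v)] <- if (is.numeric(v)) -1 else v[is.na(v)]
    igraph::edge_attr(g, a) <- v
  }
  for (a in igraph::vertex_attr_names(g)) {
    v <- igraph::vertex_attr(g, a)
    if (is.character(v)) v[is.na(v)] <- ""
    if (is.logical(v)) v <- as.integer(v)
    v[is.na(v)] <- if (is.numeric(v)) -1 else v[is.na(v)]
    igraph::vertex_attr(g, a) <- v
  }
  igraph::write_graph(g, gpath, format = "graphml")
  invisible(c(sif, npath, epath, gpath))
}

#' Write a fixture input bundle to a directory as TSV files
#'
#' @param bundle output of [make_fixture_bundle()]
#' @param dir output directory
#' @return invisibly, the directory
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pkn(bundle$pkn, dir)
  readr::write_tsv(bundle$regulons, file.path(dir, "regulons.tsv"), progress = FALSE)
  readr::write_tsv(bundle$regulatory_sites, file.path(dir, "regulatory_sites.tsv"), progress = FALSE)
  readr::write_tsv(bundle$omics$transcriptomics, file.path(dir, "transcriptomics.tsv"), progress = FALSE)
  readr::write_tsv(bundle$omics$phosphoproteomics, file.path(dir, "phosphoproteomics.tsv"), progress = FALSE)
  readr::write_tsv(bundle$omics$proteomics, file.path(dir, "proteomics.tsv"), progress = FALSE)
  readr::write_tsv(bundle$phenotype_edges, file.path(dir, "phenotype_edges.tsv"), progress = FALSE)
  readr::write_tsv(bundle$gold, file.path(dir, "gold_standard.tsv"), progress = FALSE)
  readr::write_tsv(bundle$annotation, file.path(dir, "annotation.tsv"), progress = FALSE)
  readr::write_tsv(tibble(gene = names(bundle$sources), sign = as.integer(bundle$sources)),
                   file.path(dir, "sources.tsv"), progress = FALSE)
  invisible(dir)
}

#' Read a fixture input bundle written by [write_fixture_bundle()]
#' @param dir directory
#' @return list mirroring [make_fixture_bundle()] output (minus the truth)
#' @export
read_fixture_bundle <- function(dir) {
  rd <- function(f) readr::read_tsv(file.path(dir, f), show_col_types = FALSE, progress = FALSE)
  src <- rd("sources.tsv")
  list(
    pkn = read_pkn(dir),
    sources = setNames(as.integer(src$sign), src$gene),
    regulons = rd("regulons.tsv"),
    regulatory_sites = rd("regulatory_sites.tsv"),
    omics = list(transcriptomics = rd("transcriptomics.tsv"),
                 phosphoproteomics = rd("phosphoproteomics.tsv"),
                 proteomics = rd("proteomics.tsv")),
    phenotype_edges = rd("phenotype_edges.tsv"),
    gold = rd("gold_standard.tsv"),
    annotation = rd("annotation.tsv")
  )
}
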