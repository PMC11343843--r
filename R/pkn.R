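#' Prior-knowledge network (PKN) container
#'
#' A PKN is a directed, signed causal graph following the activity-flow model:
#' every interaction has a regulator (source), a target, and a sign encoding
#' up- (+1) or down- (-1) regulation. Edges carry mechanism metadata
#' (e.g. phosphorylation with the modified residue) and nodes carry a
#' molecular-function label (TF, KIN, PP or OTHER) and an entity type
#' (protein, complex, metabolite, fusion).
#'
#' @param edges tibble with columns `source`, `target`, `sign` (in {-1,+1}),
#'   `direct` (logical), `mechanism`, `residue` (site token such as "S473" or
#'   NA), `source_db`.
#' @param nodes optional tibble with columns `gene`, `mol_function`
#'   (TF/KIN/PP/OTHER) and `entity_type`; missing nodes are filled in as
#'   OTHER/protein.
#' @return an object of class `pkn`
#' @export
pkn <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  defaults <- tibble(sign = 1L, direct = TRUE, mechanism = NA_character_,
                     residue = NA_character_, source_db = NA_character_)
  for (col in names(defaults)) {
    if (!col %in% names(edges)) edges[[col]] <- defaults[[col]]
  }
  require_columns(edges, c("source", "target"), "PKN edge table")
  edges$sign <- as.integer(edges$sign)
  if (any(is.na(edges$sign)) || any(!edges$sign %in% c(-1L, 1L))) {
    abort("PKN edge signs must be -1 or +1 (no unsigned edges after assembly)")
  }
  genes <- union(edges$source, edges$target)
  base <- tibble(gene = genes, mol_function = "OTHER", entity_type = "protein")
  if (!is.null(nodes)) {
    nodes <- as_tibble(nodes)
    require_columns(nodes, "gene", "PKN node table")
    if (!"mol_function" %in% names(nodes)) nodes$mol_function <- "OTHER"
    if (!"entity_type" %in% names(nodes)) nodes$entity_type <- "protein"
    keep <- base[!base$gene %in% nodes$gene, ]
    base <- bind_rows(nodes[, c("gene", "mol_function", "entity_type")], keep)
  }
  structure(list(edges = edges, nodes = base), class = "pkn")
}

#' @export
print.pkn <- function(x, ...) {
  cat(sprintf("<pkn> %d nodes, %d edges (%d +, %d -); %d direct\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign > 0), sum(x$edges$sign < 0),
              sum(x$edges$direct)))
  invisible(x)
}

#' Convert a PKN to an igraph object
#'
#' @param pkn a [pkn] object
#' @return a directed igraph with edge attributes `sign`, `direct`,
#'   `mechanism`, `residue`, `source_db` and node attributes `mol_function`,
#'   `entity_type`.
#' @export
pkn_graph <- function(pkn) {
  stopifnot(inherits(pkn, "pkn"))
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(pkn$edges),
    directed = TRUE,
    vertices = as.data.frame(pkn$nodes)
  )
  igraph::simplify(g, remove.multiple = FALSE, remove.loops = TRUE)
}

signor_effect_sign <- function(effect) {
  eff <- tolower(trimws(effect))
  out <- rep(NA_integer_, length(eff))
  out[startsWith(eff, "up-regulates")] <- 1L
  out[startsWith(eff, "down-regulates")] <- -1L
  out[eff == "form complex"] <- 1L
  out
}

#' Parse a SIGNOR-like causal-interaction table
#'
#' Maps effect labels to signs ('up-regulates*' and 'form complex' to +1,
#' 'down-regulates*' to -1), drops rows involving 'protein family' entities,
#' and drops rows with unrecognized effect labels (count reported).
#'
#' @param table tibble with columns `source`, `target`, `effect` and entity
#'   types `type_source`, `type_target`; optional `mechanism`, `residue`,
#'   `direct` columns are carried through.
#' @param source_db provenance label stored on every edge
#' @return tibble of causal edges
#' @export
parse_signor_like <- function(table, source_db = "signor") {
  table <- as_tibble(table)
  require_columns(table, c("source", "target", "effect", "type_source", "type_target"),
                  "SIGNOR-like table")
  if (nrow(table) == 0) {
    return(empty_edges())
  }
  fam <- tolower(table$type_source) == "protein family" |
    tolower(table$type_target) == "protein family"
  table <- table[!fam, , drop = FALSE]
  sgn <- signor_effect_sign(table$effect)
  n_bad <- sum(is.na(sgn))
  if (n_bad > 0) {
    inform(sprintf("parse_signor_like: dropped %d row(s) with unrecognized effect labels", n_bad))
  }
  keep <- !is.na(sgn)
  tibble(
    source = table$source[keep],
    target = table$target[keep],
    sign = sgn[keep],
    direct = if ("direct" %in% names(table)) as.logical(table$direct[keep]) else
      !grepl("transcriptional", tolower(table$effect[keep])),
    mechanism = if ("mechanism" %in% names(table)) as.character(table$mechanism[keep]) else NA_character_,
    residue = if ("residue" %in% names(table)) as.character(table$residue[keep]) else NA_character_,
    source_db = source_db
  )
}

empty_edges <- function() {
  tibble(source = character(), target = character(), sign = integer(),
         direct = logical(), mechanism = character(), residue = character(),
         source_db = character())
}

# regulatory-role text -> {+1, -1, 0}; e.g. "activity, induced" -> +1
regulatory_role_sign <- function(role) {
  role <- tolower(role)
  out <- integer(length(role))
  out[grepl("induced|increase|activat", role)] <- 1L
  out[grepl("inhibited|decrease|inhibit", role)] <- -1L
  out
}

#' Join kinase-site interactions with phosphosite regulatory roles
#'
#' Inner join of a kinase-substrate table and a regulatory-role table on
#' (substrate protein, modified residue). The regulatory-role text is mapped
#' to {+1, -1, 0}; only edges with a defined regulatory effect (-1 or +1)
#' are retained.
#'
#' @param kinase_site_table tibble with columns `kinase`, `substrate`,
#'   `residue` (site token, e.g. "S473")
#' @param regulatory_role_table tibble with columns `gene_name`, `residue`,
#'   `role` (free text, e.g. "activity, induced")
#' @param source_db provenance label
#' @return tibble of causal kinase -> substrate edges with phosphorylation
#'   mechanism and the modified residue
#' @export
parse_regulatory_sites <- function(kinase_site_table, regulatory_role_table,
                                   source_db = "psp") {
  kinase_site_table <- as_tibble(kinase_site_table)
  regulatory_role_table <- as_tibble(regulatory_role_table)
  require_columns(kinase_site_table, c("kinase", "substrate", "residue"),
                  "kinase-site table")
  require_columns(regulatory_role_table, c("gene_name", "residue", "role"),
                  "regulatory-role table")
  joined <- inner_join(
    kinase_site_table,
    regulatory_role_table,
    by = c(substrate = "gene_name", residue = "residue")
  )
  sgn <- regulatory_role_sign(joined$role)
  keep <- sgn != 0L
  tibble(
    source = joined$kinase[keep],
    target = joined$substrate[keep],
    sign = sgn[keep],
    direct = TRUE,
    mechanism = "phosphorylation",
    residue = joined$residue[keep],
    source_db = source_db
  )
}

# linear map of percentile from [threshold, 100] onto [0.5, 0.9]
atlas_weight <- function(percentile, threshold) {
  0.5 + 0.4 * (percentile - threshold) / (100 - threshold)
}

#' Parse a kinome-atlas-like kinase-substrate percentile table
#'
#' Relations above the regulon threshold become regulon entries, weighted by
#' a linear map of the percentile from [threshold, 100] onto [0.5, 0.9].
#' Relations above the (stricter) PKN threshold are joined to the
#' regulatory-role table on the phosphosite to inherit a causal sign and
#' become PKN edges. Both thresholds are strict (percentile > threshold).
#'
#' @param relations tibble with columns `kinase`, `gene_name`, `residue`,
#'   `percentile` (in [0, 100])
#' @param regulatory_role_table as in [parse_regulatory_sites()]
#' @param regulon_threshold percentile above which relations enter regulons
#' @param pkn_threshold percentile above which relations may enter the PKN
#' @return list with `regulons` (tibble regulator/target/mode/weight, target
#'   keyed gene_residue) and `pkn_edges` (causal-edge tibble)
#' @export
parse_kinome_atlas <- function(relations, regulatory_role_table,
                               regulon_threshold = 88, pkn_threshold = 99) {
  relations <- as_tibble(relations)
  require_columns(relations, c("kinase", "gene_name", "residue", "percentile"),
                  "atlas relation table")
  thr <- c(regulon_threshold, pkn_threshold)
  if (any(thr < 0 | thr > 100)) abort("atlas thresholds must lie in [0, 100]")
  if (any(relations$percentile < 0 | relations$percentile > 100)) {
    abort("atlas percentiles must lie in [0, 100]")
  }
  reg <- relations[relations$percentile > regulon_threshold, , drop = FALSE]
  regulons <- tibble(
    regulator = reg$kinase,
    target = site_key(reg$gene_name, reg$residue),
    mode = 1,
    weight = atlas_weight(reg$percentile, regulon_threshold)
  )
  pkn_rel <- relations[relations$percentile > pkn_threshold, , drop = FALSE]
  joined <- inner_join(pkn_rel, as_tibble(regulatory_role_table),
                       by = c("gene_name", "residue"))
  sgn <- regulatory_role_sign(joined$role)
  keep <- sgn != 0L
  pkn_edges <- tibble(
    source = joined$kinase[keep],
    target = joined$gene_name[keep],
    sign = sgn[keep],
    direct = TRUE,
    mechanism = "phosphorylation",
    residue = joined$residue[keep],
    source_db = "atlas"
  )
  list(regulons = regulons, pkn_edges = pkn_edges)
}

#' Assemble a prior-knowledge network from causal-edge sets
#'
#' Takes the union of one or more causal-edge tables and applies increasingly
#' exclusive filters, either via a numbered preset or via explicit flags.
#' Presets: 1 = direct interactions only; 2 = no filtering; 3 = direct,
#' proteins only, no atlas edges; 4 = no atlas edges; 5 and 6 mirror presets
#' 1 and 2 for a second organism.
#'
#' Duplicate (source, target, residue) pairs with conflicting signs are
#' resolved in favor of the manually-curated record (`curated_db`); if the
#' conflict is within the same provenance both records are dropped (count
#' reported). Exact duplicates are collapsed to one record.
#'
#' @param edge_sets a causal-edge tibble or list of them
#' @param preset integer 1..6 or NULL to use explicit flags
#' @param direct_only drop transcriptional/indirect edges
#' @param include_atlas keep atlas-derived edges
#' @param proteins_only drop edges touching non-protein entities
#' @param nodes optional node-attribute tibble (gene, mol_function, entity_type)
#' @param curated_db provenance label treated as manually curated for
#'   sign-conflict resolution
#' @return a [pkn] object
#' @export
assemble_pkn <- function(edge_sets, preset = NULL, direct_only = FALSE,
                         include_atlas = TRUE, proteins_only = FALSE,
                         nodes = NULL, curated_db = "signor") {
  if (is.data.frame(edge_sets)) edge_sets <- list(edge_sets)
  edges <- bind_rows(lapply(edge_sets, as_tibble))
  if (nrow(edges) == 0) edges <- empty_edges()
  defaults <- list(direct = TRUE, mechanism = NA_character_,
                   residue = NA_character_, source_db = NA_character_)
  for (col in names(defaults)) {
    if (!col %in% names(edges)) edges[[col]] <- defaults[[col]]
  }
  if (!is.null(preset)) {
    stopifnot(preset %in% 1:6)
    direct_only <- preset %in% c(1L, 3L, 5L)
    include_atlas <- !(preset %in% c(3L, 4L))
    proteins_only <- preset == 3L
  }
  if (nrow(edges) > 0) {
    if (direct_only) edges <- edges[edges$direct %in% TRUE, , drop = FALSE]
    if (!include_atlas) edges <- edges[!(edges$source_db %in% "atlas"), , drop = FALSE]
    if (proteins_only && !is.null(nodes)) {
      prot <- nodes$gene[nodes$entity_type == "protein"]
      known <- nodes$gene
      ok <- (!edges$source %in% known | edges$source %in% prot) &
        (!edges$target %in% known | edges$target %in% prot)
      edges <- edges[ok, , drop = FALSE]
    }
  }
  edges <- collapse_duplicate_edges(edges, curated_db)
  if (nrow(edges) == 0) warn("assemble_pkn: all edges removed by filtering; returning empty PKN")
  pkn(edges, nodes = nodes)
}

collapse_duplicate_edges <- function(edges, curated_db) {
  if (nrow(edges) == 0) return(edges)
  key <- paste(edges$source, edges$target, edges$residue %||% NA, sep = "\r")
  # collapse exact duplicates first (same key and sign): keep first record,
  # concatenating provenance
  out <- edges |>
    mutate(.key = key) |>
    group_by(.data$.key, .data$sign) |>
    summarise(
      source = .data$source[1], target = .data$target[1],
      direct = any(.data$direct), mechanism = .data$mechanism[1],
      residue = .data$residue[1],
      source_db = paste(sort(unique(.data$source_db)), collapse = ";"),
      .groups = "drop_last"
    ) |>
    ungroup()
  conflicted <- out$.key[duplicated(out$.key)]
  if (length(conflicted)) {
    resolved <- lapply(unique(conflicted), function(k) {
      grp <- out[out$.key == k, , drop = FALSE]
      cur <- grepl(curated_db, grp$source_db, fixed = TRUE)
      if (sum(cur) == 1) grp[cur, , drop = FALSE] else grp[0, , drop = FALSE]
    })
    n_dropped <- sum(vapply(resolved, nrow, 1L) == 0)
    if (n_dropped > 0) {
      inform(sprintf("assemble_pkn: dropped %d edge pair(s) with unresolvable sign conflicts", n_dropped))
    }
    out <- bind_rows(out[!out$.key %in% conflicted, , drop = FALSE],
                     bind_rows(resolved))
  }
  out$.key <- NULL
  out[, c("source", "target", "sign", "direct", "mechanism", "residue", "source_db")]
}

#' Restrict a PKN to analytes quantified in the experiment
#'
#' Removes edges whose either protein endpoint was not quantified. Non-protein
#' entities (complexes, metabolites, fusions) and phenotype nodes are exempt
#' from the filter.
#'
#' @param pkn a [pkn] object
#' @param quantified_analytes character vector of quantified gene symbols
#' @return a filtered [pkn]
#' @export
preprocess_pkn <- function(pkn, quantified_analytes) {
  stopifnot(inherits(pkn, "pkn"))
  exempt <- pkn$nodes$gene[pkn$nodes$entity_type != "protein"]
  ok_node <- function(g) g %in% quantified_analytes | g %in% exempt
  keep <- ok_node(pkn$edges$source) & ok_node(pkn$edges$target)
  edges <- pkn$edges[keep, , drop = FALSE]
  nodes <- pkn$nodes[pkn$nodes$gene %in% union(edges$source, edges$target), , drop = FALSE]
  structure(list(edges = edges, nodes = nodes), class = "pkn")
}
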