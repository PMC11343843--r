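#' Normalize phosphoproteomics over proteomics
#'
#' Corrects each phosphosite fold-change by subtracting the fold-change of
#' its parent protein, so that sites modulated together with protein
#' abundance are down-weighted and sites moving against it are emphasized.
#' A z-score is then computed over the corrected fold-change distribution
#' (its mean and sample standard deviation) and a site is significant iff
#' |z| strictly exceeds `z_threshold` (1.96, i.e. p < 0.05).
#'
#' Sites whose parent protein was not quantified pass through unchanged and
#' are flagged (`parent_quantified = FALSE`); they still participate in the
#' corrected distribution.
#'
#' @param phospho_table tibble with columns `gene_name`, `residue`,
#'   `difference` (fold-change or contrast statistic) and optionally
#'   `significant`
#' @param proteomics_table tibble with columns `gene_name`, `difference`
#' @param z_threshold strict two-sided significance threshold on |z|
#' @return the phospho table with `difference` replaced by the corrected
#'   statistic and columns `z`, `significant`, `parent_quantified` added
#' @export
normalize_phospho <- function(phospho_table, proteomics_table, z_threshold = 1.96) {
  phospho_table <- as_tibble(phospho_table)
  proteomics_table <- as_tibble(proteomics_table)
  require_columns(phospho_table, c("gene_name", "difference"), "phospho table")
  require_columns(proteomics_table, c("gene_name", "difference"), "proteomics table")
  prot <- proteomics_table |>
    group_by(.data$gene_name) |>
    summarise(prot_difference = mean(.data$difference), .groups = "drop")
  out <- left_join(phospho_table, prot, by = "gene_name")
  out$parent_quantified <- !is.na(out$prot_difference)
  corrected <- ifelse(out$parent_quantified,
                      out$difference - out$prot_difference,
                      out$difference)
  s <- sd(corrected)
  if (!is.finite(s) || s == 0) {
    abort(paste0("normalize_phospho: corrected fold-change distribution has zero ",
                 "variance; z-scores are undefined. Check that the phospho table ",
                 "contains more than one distinct corrected value."))
  }
  out$difference <- corrected
  out$z <- (corrected - mean(corrected)) / s
  out$significant <- abs(out$z) > z_threshold
  out$prot_difference <- NULL
  out
}

# symmetric normal-quantile scores of the signature statistics
signature_quantiles <- function(statistic) {
  n <- length(statistic)
  qnorm(rank(statistic, ties.method = "average") / (n + 1))
}

#' Footprint enrichment of regulator activity
#'
#' Infers a signed activity for each regulator (TF, kinase or phosphatase)
#' from the modulation of its regulon targets in a molecular signature.
#' Signature statistics are rank-transformed to symmetric normal-quantile
#' scores q; the normalized enrichment score of a regulator with targets i is
#' NES = sum(w_i * m_i * q_i) / sqrt(sum(w_i^2)), with mode m in [-1, 1] and
#' weight w in (0, 1]. A two-sided p-value is taken from the standard normal.
#'
#' @param signature tibble with columns `id` (analyte: gene, or gene_residue
#'   for phosphosites) and `statistic`; ids must be unique and finite
#' @param regulons tibble with columns `regulator`, `target`, `mode`, `weight`
#' @param min_targets regulons with fewer targets present in the signature
#'   are skipped (count reported)
#' @return tibble with `regulator`, `nes`, `p_value`, `n_targets`
#' @export
footprint_enrichment <- function(signature, regulons, min_targets = 5) {
  signature <- as_tibble(signature)
  regulons <- as_tibble(regulons)
  require_columns(signature, c("id", "statistic"), "signature")
  require_columns(regulons, c("regulator", "target", "mode"), "regulons")
  if (anyDuplicated(signature$id)) abort("signature analyte ids must be unique")
  if (any(!is.finite(signature$statistic))) abort("signature statistics must be finite")
  if (!"weight" %in% names(regulons)) regulons$weight <- 1
  q <- setNames(signature_quantiles(signature$statistic), signature$id)
  reg <- regulons[regulons$target %in% signature$id, , drop = FALSE]
  counts <- table(reg$regulator)
  skipped <- sum(counts < min_targets)
  if (skipped > 0) {
    inform(sprintf("footprint_enrichment: skipped %d regulon(s) with fewer than %d targets in the signature",
                   skipped, min_targets))
  }
  keep <- names(counts)[counts >= min_targets]
  reg <- reg[reg$regulator %in% keep, , drop = FALSE]
  out <- reg |>
    group_by(.data$regulator) |>
    summarise(
      nes = sum(.data$weight * .data$mode * q[.data$target]) /
        sqrt(sum(.data$weight^2)),
      n_targets = n(),
      .groups = "drop"
    )
  out$p_value <- 2 * pnorm(-abs(out$nes))
  out[, c("regulator", "nes", "p_value", "n_targets")]
}

#' Weight enrichment scores by target over-representation
#'
#' For each regulator, an over-representation p-value is computed from the
#' hypergeometric distribution: with N analytes in the signature, K of them
#' significant, n regulon targets present and k of those significant,
#' p = P[X >= k]. The weighted activity score is NES * (1 - p), so regulators
#' whose targets are enriched in significantly modulated analytes keep most
#' of their enrichment score.
#'
#' @param enrichment_table output of [footprint_enrichment()]
#' @param signature tibble with columns `id`, `statistic`, `significant`
#' @param regulons tibble with columns `regulator`, `target`
#' @return the enrichment table with `p_hyper` and `weighted_score` columns;
#'   regulators with no targets in the signature are dropped
#' @export
hypergeometric_weighting <- function(enrichment_table, signature, regulons) {
  signature <- as_tibble(signature)
  require_columns(signature, c("id", "significant"), "signature")
  regulons <- as_tibble(regulons)
  N <- nrow(signature)
  K <- sum(signature$significant)
  sig_ids <- signature$id[signature$significant]
  reg <- regulons[regulons$target %in% signature$id, , drop = FALSE]
  stats <- reg |>
    group_by(.data$regulator) |>
    summarise(n = n(), k = sum(.data$target %in% sig_ids), .groups = "drop")
  out <- inner_join(enrichment_table, stats, by = "regulator")
  out <- out[out$n > 0, , drop = FALSE]
  out$p_hyper <- phyper(out$k - 1, K, N - K, out$n, lower.tail = FALSE)
  degenerate <- out$p_hyper >= 1 - 1e-12 & out$k == out$n
  if (any(degenerate)) {
    inform(sprintf("hypergeometric_weighting: %d saturated regulon(s) weighted to zero",
                   sum(degenerate)))
  }
  out$weighted_score <- out$nes * (1 - out$p_hyper)
  out$n <- out$k <- NULL
  out
}

#' Rescue regulators with significant proteomic modulation
#'
#' Builds the footprint activity table, keeping regulators significant by
#' enrichment and additionally rescuing regulators that are non-significant
#' by enrichment but significantly modulated in proteomics: those enter with
#' activity = sign of the proteomics fold-change and method
#' "proteomics_rescue". When both calls are significant but discordant in
#' sign, the enrichment call wins and a discordance flag is set.
#'
#' @param enrichment_table output of [footprint_enrichment()] or
#'   [hypergeometric_weighting()]
#' @param proteomics_table tibble with `gene_name`, `difference`, `significant`
#' @param sig_threshold enrichment records with p_value below this are
#'   significant
#' @return activity tibble with `gene_name`, `final_score`, `activity`,
#'   `p_value`, `method`, `discordant_proteomics`
#' @export
proteomics_correction <- function(enrichment_table, proteomics_table = NULL,
                                  sig_threshold = 0.05) {
  et <- as_tibble(enrichment_table)
  score_col <- if ("weighted_score" %in% names(et)) "weighted_score" else "nes"
  et$final_score <- et[[score_col]]
  et$sig <- et$p_value < sig_threshold
  kept <- et[et$sig, , drop = FALSE]
  out <- tibble(
    gene_name = kept$regulator,
    final_score = kept$final_score,
    activity = sign_int(kept$final_score),
    p_value = kept$p_value,
    method = "footprint",
    discordant_proteomics = FALSE
  )
  if (!is.null(proteomics_table)) {
    prot <- as_tibble(proteomics_table)
    require_columns(prot, c("gene_name", "difference", "significant"), "proteomics table")
    prot_sig <- prot[prot$significant %in% TRUE, , drop = FALSE]
    rescue <- et[!et$sig & et$regulator %in% prot_sig$gene_name, , drop = FALSE]
    if (nrow(rescue) > 0) {
      resc <- inner_join(rescue, prot_sig, by = c(regulator = "gene_name"))
      out <- bind_rows(out, tibble(
        gene_name = resc$regulator,
        final_score = resc$difference,
        activity = sign_int(resc$difference),
        p_value = resc$p_value,
        method = "proteomics_rescue",
        discordant_proteomics = FALSE
      ))
    }
    conc <- inner_join(out[out$method == "footprint", c("gene_name", "activity")],
                       prot_sig, by = "gene_name")
    disc <- conc$gene_name[sign_int(conc$difference) != conc$activity &
                             sign_int(conc$difference) != 0L]
    out$discordant_proteomics[out$gene_name %in% disc] <- TRUE
  }
  out
}

#' PhosphoScore: protein activity from regulatory phosphosites
#'
#' Scores each protein as the mean over its significant regulatory
#' phosphosites of (site statistic x regulatory sign). Sites annotated as
#' regulating only protein abundance are excluded when `activity_only` is
#' TRUE. Proteins with no eligible site are absent from the output.
#'
#' @param phospho_table tibble with `gene_name`, `residue`, `difference`,
#'   `significant`
#' @param regulatory_site_db tibble with `gene_name`, `residue`, `sign`
#'   (+1 activating / -1 inhibiting) and `role` in
#'   {"activity", "abundance", "both"}
#' @param activity_only exclude abundance-only sites
#' @param significant_only use only significant sites (default); set FALSE to
#'   use all quantified sites
#' @return activity tibble with `gene_name`, `final_score`, `activity`,
#'   `n_sites`, `method`
#' @export
phospho_score <- function(phospho_table, regulatory_site_db,
                          activity_only = TRUE, significant_only = TRUE) {
  phospho_table <- as_tibble(phospho_table)
  regulatory_site_db <- as_tibble(regulatory_site_db)
  require_columns(phospho_table, c("gene_name", "residue", "difference"), "phospho table")
  require_columns(regulatory_site_db, c("gene_name", "residue", "sign"),
                  "regulatory-site table")
  if (!"role" %in% names(regulatory_site_db)) regulatory_site_db$role <- "activity"
  db <- regulatory_site_db
  if (activity_only) db <- db[db$role != "abundance", , drop = FALSE]
  rows <- inner_join(phospho_table, db, by = c("gene_name", "residue"))
  if (significant_only) {
    require_columns(phospho_table, "significant", "phospho table")
    rows <- rows[rows$significant %in% TRUE, , drop = FALSE]
  }
  out <- rows |>
    group_by(.data$gene_name) |>
    summarise(final_score = mean(.data$difference * .data$sign),
              n_sites = n(), .groups = "drop")
  out <- out[out$final_score != 0, , drop = FALSE]
  out$activity <- sign_int(out$final_score)
  out$method <- "phosphoscore"
  out[, c("gene_name", "final_score", "activity", "n_sites", "method")]
}

#' Combine footprint and PhosphoScore activities
#'
#' Union of the footprint-based and PhosphoScore activity tables. When a
#' protein appears in both, the footprint record is kept and agreement with
#' PhosphoScore is recorded in `phospho_concordant`. Every record is
#' annotated with its molecular function (TF, KIN, PP, OTHER); proteins
#' absent from the annotation are labeled OTHER (count reported).
#'
#' @param footprint_tables a footprint activity tibble or list of them (e.g.
#'   one per molecular function)
#' @param phosphoscore_table output of [phospho_score()] (or NULL)
#' @param mol_function_annotation tibble with `gene_name`, `mol_function`
#' @return combined activity tibble with `gene_name`, `mf`, `final_score`,
#'   `activity`, `p_value`, `method`, flags
#' @export
combine_activities <- function(footprint_tables, phosphoscore_table = NULL,
                               mol_function_annotation = NULL) {
  if (is.data.frame(footprint_tables)) footprint_tables <- list(footprint_tables)
  fp <- bind_rows(footprint_tables)
  if (nrow(fp) > 0 && anyDuplicated(fp$gene_name)) {
    fp <- fp |> group_by(.data$gene_name) |> dplyr::slice(1) |> ungroup()
  }
  fp$phospho_concordant <- NA
  if (!is.null(phosphoscore_table) && nrow(phosphoscore_table) > 0) {
    ps <- as_tibble(phosphoscore_table)
    both <- intersect(fp$gene_name, ps$gene_name)
    if (length(both)) {
      ps_act <- setNames(ps$activity, ps$gene_name)
      idx <- fp$gene_name %in% both
      fp$phospho_concordant[idx] <- fp$activity[idx] == ps_act[fp$gene_name[idx]]
    }
    only <- ps[!ps$gene_name %in% fp$gene_name, , drop = FALSE]
    if (nrow(only)) {
      only$p_value <- NA_real_
      only$phospho_concordant <- NA
      fp <- bind_rows(fp, only[, intersect(names(only),
        c("gene_name", "final_score", "activity", "p_value", "method",
          "n_sites", "phospho_concordant"))])
    }
  }
  fp$mf <- "OTHER"
  if (!is.null(mol_function_annotation)) {
    ann <- as_tibble(mol_function_annotation)
    require_columns(ann, c("gene_name", "mol_function"), "annotation table")
    mf <- setNames(ann$mol_function, ann$gene_name)
    hit <- fp$gene_name %in% names(mf)
    fp$mf[hit] <- unname(mf[fp$gene_name[hit]])
    if (any(!hit)) {
      inform(sprintf("combine_activities: %d protein(s) missing from annotation labeled OTHER",
                     sum(!hit)))
    }
  }
  front <- c("gene_name", "mf", "final_score", "activity", "p_value", "method")
  for (col in front) {
    if (!col %in% names(fp)) {
      fp[[col]] <- if (col %in% c("final_score", "p_value")) numeric(nrow(fp)) * NA else
        rep(NA_character_, nrow(fp))
    }
  }
  fp[, c(front, setdiff(names(fp), front))]
}
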