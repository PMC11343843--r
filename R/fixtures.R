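#' Generate a toy signed prior-knowledge network
#'
#' Builds a connected, signed, directed toy PKN with stratified node roles
#' and a layered backbone (perturbed source nodes feeding kinases and
#' phosphatases, which feed other signaling proteins, which feed
#' transcription factors), plus random extra edges up to the requested
#' density. A configurable fraction of edges carries a phosphorylation
#' mechanism with a synthetic residue token.
#'
#' Role counts follow the rounding rule: TF, KIN and PP counts are
#' `round(fraction * n)` in that order and OTHER receives the remainder.
#'
#' @param n_nodes number of nodes (>= 4); the first `n_sources` nodes are
#'   source-like perturbed candidates (role OTHER)
#' @param edge_density target edge density in (0, 1) relative to the
#'   complete digraph without self-loops
#' @param role_fractions named fractions for TF, KIN, PP (OTHER is the
#'   remainder)
#' @param phospho_fraction fraction of edges carrying a phosphorylation
#'   mechanism and residue
#' @param n_sources number of source-like nodes
#' @param positive_fraction fraction of activating (+1) edges
#' @param seed RNG seed; the graph is a pure function of (parameters, seed)
#' @return a [pkn] object; source candidates are named "G1", "G2", ...
#' @export
make_toy_pkn <- function(n_nodes = 30, edge_density = 0.08,
                         role_fractions = c(TF = 0.25, KIN = 0.3, PP = 0.05),
                         phospho_fraction = 0.5, n_sources = 1,
                         positive_fraction = 0.6, seed = 1) {
  if (n_nodes < 4) abort("make_toy_pkn: n_nodes must be >= 4")
  if (edge_density <= 0 || edge_density >= 1 + 1e-9) abort("make_toy_pkn: density must lie in (0, 1]")
  m_target <- round(edge_density * n_nodes * (n_nodes - 1))
  if (m_target < 1) abort("make_toy_pkn: parameters yield fewer than one edge")
  with_seed(seed, {
    genes <- paste0("G", seq_len(n_nodes))
    n_tf <- round(role_fractions[["TF"]] * n_nodes)
    n_kin <- round(role_fractions[["KIN"]] * n_nodes)
    n_pp <- round(role_fractions[["PP"]] * n_nodes)
    n_oth <- n_nodes - n_tf - n_kin - n_pp
    if (n_oth < n_sources) abort("make_toy_pkn: not enough OTHER nodes for the sources")
    roles <- c(rep("OTHER", n_sources),
               sample(c(rep("TF", n_tf), rep("KIN", n_kin), rep("PP", n_pp),
                        rep("OTHER", n_oth - n_sources))))
    names(roles) <- genes
    sources <- genes[seq_len(n_sources)]
    kin <- genes[roles %in% c("KIN", "PP")]
    oth <- setdiff(genes[roles == "OTHER"], sources)
    tf <- genes[roles == "TF"]

    # layered backbone guaranteeing reachability source -> KIN -> OTHER -> TF
    backbone <- list()
    link_layer <- function(upstream, downstream) {
      if (!length(upstream) || !length(downstream)) return(NULL)
      tibble(source = sample(upstream, length(downstream), replace = TRUE),
             target = downstream)
    }
    backbone[[1]] <- link_layer(sources, kin)
    backbone[[2]] <- link_layer(if (length(kin)) kin else sources, oth)
    backbone[[3]] <- link_layer(if (length(oth)) oth else kin, tf)
    pairs <- distinct(bind_rows(backbone))
    pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]

    all_pairs <- expand.grid(source = genes, target = genes,
                             stringsAsFactors = FALSE)
    all_pairs <- all_pairs[all_pairs$source != all_pairs$target, ]
    key <- paste(all_pairs$source, all_pairs$target)
    free <- all_pairs[!key %in% paste(pairs$source, pairs$target), ]
    n_extra <- max(0, m_target - nrow(pairs))
    if (n_extra > 0 && nrow(free) > 0) {
      pairs <- bind_rows(pairs, free[sample(nrow(free), min(n_extra, nrow(free))), ])
    }
    m <- nrow(pairs)
    mech <- sample(c("phosphorylation", "binding"), m, replace = TRUE,
                   prob = c(phospho_fraction, 1 - phospho_fraction))
    # transcriptional (indirect) edges: regulation of a TF target by a TF
    mech[pairs$source %in% tf & mech != "phosphorylation"] <- "transcriptional"
    residue <- ifelse(mech == "phosphorylation",
                      paste0(sample(c("S", "T", "Y"), m, replace = TRUE,
                                    prob = c(0.6, 0.3, 0.1)),
                             sample(10:999, m, replace = TRUE)),
                      NA_character_)
    edges <- tibble(
      source = pairs$source, target = pairs$target,
      sign = sample(c(1L, -1L), m, replace = TRUE,
                    prob = c(positive_fraction, 1 - positive_fraction)),
      direct = mech != "transcriptional",
      mechanism = mech,
      residue = residue,
      source_db = "toy"
    )
    nodes <- tibble(gene = genes, mol_function = unname(roles),
                    entity_type = "protein")
    pkn(edges, nodes)
  })
}

#' Derive toy regulons from a PKN
#'
#' Builds regulons from the PKN edges: TF regulons target their downstream
#' genes (transcript analytes, mode = edge sign, weight 1); kinase and
#' phosphatase regulons target phosphosite analytes (gene_residue keys of
#' their phosphorylation edges). Regulons are optionally padded with
#' synthetic off-network targets (analytes that are measured but not part
#' of the network) up to `min_targets`, and an `atlas_fraction` of entries
#' receives atlas-style percentile-derived weights in [0.5, 0.9].
#'
#' @param pkn a [pkn] object with TF/KIN/PP node roles
#' @param min_targets pad every regulon to at least this many targets
#' @param atlas_fraction fraction of kinase-regulon entries given
#'   atlas-style weights
#' @param seed RNG seed
#' @return tibble with `regulator`, `target`, `mode`, `weight`, `mf`
#' @export
make_regulons <- function(pkn, min_targets = 0, atlas_fraction = 0, seed = 1) {
  stopifnot(inherits(pkn, "pkn"))
  mf <- setNames(pkn$nodes$mol_function, pkn$nodes$gene)
  with_seed(seed, {
    e <- pkn$edges
    tf_rows <- e[mf[e$source] %in% "TF", , drop = FALSE]
    tf_reg <- tibble(regulator = tf_rows$source, target = tf_rows$target,
                     mode = as.numeric(tf_rows$sign), weight = 1,
                     mf = "TF")
    kin_rows <- e[mf[e$source] %in% c("KIN", "PP") &
                    e$mechanism %in% "phosphorylation" & !is.na(e$residue), , drop = FALSE]
    kin_reg <- tibble(regulator = kin_rows$source,
                      target = site_key(kin_rows$target, kin_rows$residue),
                      mode = as.numeric(kin_rows$sign), weight = 1,
                      mf = unname(mf[kin_rows$source]))
    reg <- bind_rows(tf_reg, kin_reg)
    reg <- reg[!duplicated(reg[, c("regulator", "target")]), , drop = FALSE]
    if (min_targets > 0 && nrow(reg) > 0) {
      pads <- list()
      for (r in unique(reg$regulator)) {
        n_have <- sum(reg$regulator == r)
        n_need <- min_targets - n_have
        if (n_need > 0) {
          this_mf <- reg$mf[reg$regulator == r][1]
          tgt <- if (this_mf == "TF") {
            paste0("TGT", r, "_", seq_len(n_need))
          } else {
            site_key(paste0("SUB", r, "_", seq_len(n_need)),
                     paste0("S", sample(100:999, n_need, replace = TRUE)))
          }
          pads[[r]] <- tibble(regulator = r, target = tgt,
                              mode = sample(c(1, -1), n_need, replace = TRUE,
                                            prob = c(0.7, 0.3)),
                              weight = 1, mf = this_mf)
        }
      }
      reg <- bind_rows(reg, bind_rows(pads))
    }
    if (atlas_fraction > 0 && nrow(reg) > 0) {
      ii <- which(reg$mf %in% c("KIN", "PP"))
      pick <- ii[runif(length(ii)) < atlas_fraction]
      reg$weight[pick] <- atlas_weight(runif(length(pick), 88, 100), 88)
    }
    reg
  })
}

#' Plant ground-truth regulator activities
#'
#' @param regulators character vector (or a regulon tibble, whose unique
#'   regulators are used)
#' @param seed RNG seed
#' @return named integer vector of planted activities in \{-1, +1\}
#' @export
make_planted_truth <- function(regulators, seed = 1) {
  if (is.data.frame(regulators)) regulators <- unique(regulators$regulator)
  with_seed(seed, setNames(sample(c(1L, -1L), length(regulators), replace = TRUE),
                           regulators))
}

#' Simulate omics contrasts from regulons and a planted truth
#'
#' Every regulon target receives statistic = mode x activity + N(0, sigma);
#' targets of regulators absent from the truth receive pure noise. The
#' significance flag is |statistic| > 1.96 * sigma, mirroring the pipeline's
#' z-threshold convention. Phosphosite analytes (gene_residue keys) are
#' split back into `gene_name` + `residue` columns. When a regulatory-site
#' table is given, one phospho row per regulatory site is added with
#' statistic = site sign x protein activity + noise, so that PhosphoScore
#' can recover the planted protein activities. A proteomics table covering
#' the planted proteins (attenuated signal) is also produced.
#'
#' @param regulons tibble from [make_regulons()]
#' @param truth named activity vector from [make_planted_truth()]
#' @param regulatory_sites optional tibble with `gene_name`, `residue`,
#'   `sign`, `role`
#' @param sigma Gaussian noise standard deviation (>= 0)
#' @param proteomics_attenuation multiplier on the planted activity for the
#'   proteomics signal
#' @param seed RNG seed
#' @return list with `transcriptomics`, `phosphoproteomics`, `proteomics`
#'   tibbles sharing the analyte-statistic schema
#' @export
simulate_omics <- function(regulons, truth, regulatory_sites = NULL,
                           sigma = 0.5, proteomics_attenuation = 0.5, seed = 1) {
  if (sigma < 0) abort("simulate_omics: sigma must be >= 0")
  regulons <- as_tibble(regulons)
  if (any(!truth %in% c(-1L, 1L))) abort("planted activities must be -1 or +1")
  with_seed(seed, {
    act <- ifelse(regulons$regulator %in% names(truth),
                  truth[regulons$regulator], 0)
    stat <- regulons$mode * act + rnorm(nrow(regulons), 0, sigma)
    sig_cut <- 1.96 * sigma
    is_site <- grepl("_[STY]\\d+$", regulons$target)
    tx <- tibble(gene_name = regulons$target[!is_site],
                 difference = stat[!is_site],
                 significant = abs(stat[!is_site]) > sig_cut)
    tx <- tx[!duplicated(tx$gene_name), , drop = FALSE]
    ph_sites <- split_site_key(regulons$target[is_site])
    ph <- tibble(gene_name = ph_sites$gene_name, residue = ph_sites$residue,
                 difference = stat[is_site],
                 significant = abs(stat[is_site]) > sig_cut)
    if (!is.null(regulatory_sites)) {
      rs <- as_tibble(regulatory_sites)
      act_rs <- ifelse(rs$gene_name %in% names(truth), truth[rs$gene_name], 0)
      stat_rs <- rs$sign * act_rs + rnorm(nrow(rs), 0, sigma)
      ph <- bind_rows(ph, tibble(gene_name = rs$gene_name, residue = rs$residue,
                                 difference = stat_rs,
                                 significant = abs(stat_rs) > sig_cut))
    }
    ph <- ph[!duplicated(ph[, c("gene_name", "residue")]), , drop = FALSE]
    prot_genes <- unique(c(names(truth), regulons$regulator))
    prot_stat <- ifelse(prot_genes %in% names(truth),
                        proteomics_attenuation * truth[prot_genes], 0) +
      rnorm(length(prot_genes), 0, sigma * proteomics_attenuation)
    prot <- tibble(gene_name = prot_genes, difference = prot_stat,
                   significant = abs(prot_stat) > 1.96 * sigma * proteomics_attenuation)
    list(transcriptomics = tx, phosphoproteomics = ph, proteomics = prot)
  })
}

#' Build a gold standard from a planted truth
#'
#' Expected activities equal the planted activities; a seeded subset of
#' `round(drop_fraction * n)` entities is flagged not-inferable and is then
#' excluded from quality metrics.
#'
#' @param truth named activity vector
#' @param drop_fraction fraction of entities flagged not-inferable, in [0, 1)
#' @param seed RNG seed
#' @return tibble with `id`, `expected`, `inferable`
#' @export
make_gold_standard <- function(truth, drop_fraction = 0, seed = 1) {
  if (drop_fraction < 0 || drop_fraction >= 1) {
    abort("make_gold_standard: drop_fraction must lie in [0, 1)")
  }
  n_drop <- round(drop_fraction * length(truth))
  with_seed(seed, {
    dropped <- if (n_drop > 0) sample(names(truth), n_drop) else character()
    tibble(id = names(truth), expected = as.integer(truth),
           inferable = !names(truth) %in% dropped)
  })
}

#' Synthetic regulatory phosphosites for a set of proteins
#'
#' @param genes proteins to annotate
#' @param sites_per_gene regulatory sites per protein
#' @param activating_fraction fraction of sites with activating (+1) sign
#' @param seed RNG seed
#' @return tibble with `gene_name`, `residue`, `sign`, `role`
#' @export
make_regulatory_sites <- function(genes, sites_per_gene = 2,
                                  activating_fraction = 0.7, seed = 1) {
  with_seed(seed, {
    n <- length(genes) * sites_per_gene
    tibble(
      gene_name = rep(genes, each = sites_per_gene),
      residue = paste0(sample(c("S", "T", "Y"), n, replace = TRUE, prob = c(.6, .3, .1)),
                       sample(1000:1999, n)),
      sign = sample(c(1L, -1L), n, replace = TRUE,
                    prob = c(activating_fraction, 1 - activating_fraction)),
      role = sample(c("activity", "both", "abundance"), n, replace = TRUE,
                    prob = c(0.6, 0.25, 0.15))
    )
  })
}

#' Synthetic protein-to-phenotype edges
#'
#' @param pkn a [pkn] object; TFs and OTHER proteins are linked to phenotypes
#' @param n_phenotypes number of phenotype labels (up to the built-in list)
#' @param edges_per_phenotype regulators per phenotype
#' @param seed RNG seed
#' @return tibble with `protein`, `phenotype`, `sign`
#' @export
make_phenotype_edges <- function(pkn, n_phenotypes = 10, edges_per_phenotype = 3,
                                 seed = 1) {
  stopifnot(inherits(pkn, "pkn"))
  labels <- c("Proliferation", "Apoptosis", "Autophagy", "Cell cycle progression",
              "Cell death", "Protein synthesis", "Glycolysis", "Adipogenesis",
              "Fatty acid biosynthesis", "Glycogen biosynthesis")
  labels <- labels[seq_len(min(n_phenotypes, length(labels)))]
  pool <- pkn$nodes$gene[pkn$nodes$mol_function %in% c("TF", "OTHER", "KIN")]
  with_seed(seed, {
    bind_rows(lapply(labels, function(ph) {
      prot <- sample(pool, min(edges_per_phenotype, length(pool)))
      tibble(protein = prot, phenotype = ph,
             sign = sample(c(1L, -1L), length(prot), replace = TRUE))
    }))
  })
}

#' Generate a complete coherent fixture bundle
#'
#' Produces every input the pipeline needs, with a planted ground truth that
#' is sign-coherent with the PKN: activities are propagated from the source
#' node(s) along the network (state of a node = parent state x edge sign on
#' its discovery path), so that an optimal sign-coherent model exists and
#' quality metrics against the gold standard are meaningful.
#'
#' @param n_nodes,edge_density,phospho_fraction,seed passed to [make_toy_pkn()]
#' @param min_targets regulon padding floor (see [make_regulons()])
#' @param sigma omics noise level
#' @param drop_fraction not-inferable fraction of the gold standard
#' @return list with `pkn`, `sources`, `truth`, `regulons`,
#'   `regulatory_sites`, `omics` (list of three tables), `phenotype_edges`,
#'   `gold`, `annotation`
#' @export
make_fixture_bundle <- function(n_nodes = 40, edge_density = 0.06,
                                phospho_fraction = 0.6, min_targets = 6,
                                sigma = 0.5, drop_fraction = 0.1, seed = 1) {
  pkn <- make_toy_pkn(n_nodes = n_nodes, edge_density = edge_density,
                      phospho_fraction = phospho_fraction, seed = seed)
  sources <- setNames(1L, pkn$nodes$gene[1])
  # coherent planted truth: propagate the perturbation through the network
  states <- setNames(rep(0L, nrow(pkn$nodes)), pkn$nodes$gene)
  states[names(sources)] <- sources
  frontier <- names(sources)
  edges <- pkn$edges
  while (length(frontier)) {
    nxt <- character()
    for (u in frontier) {
      out <- edges[edges$source == u, , drop = FALSE]
      for (i in seq_len(nrow(out))) {
        v <- out$target[i]
        if (states[v] == 0L) {
          states[v] <- states[u] * out$sign[i]
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  mf <- setNames(pkn$nodes$mol_function, pkn$nodes$gene)
  truth_genes <- names(states)[states != 0L & names(states) != names(sources)[1]]
  truth <- states[truth_genes]
  regulons <- make_regulons(pkn, min_targets = min_targets, seed = seed + 1)
  reg_sites <- make_regulatory_sites(
    intersect(truth_genes, pkn$nodes$gene[mf %in% c("OTHER", "KIN", "PP", "TF")]),
    seed = seed + 2
  )
  # regulatory sites must agree with the edge residues so that model edges
  # can be validated by the phospho table
  edge_sites <- pkn$edges[pkn$edges$mechanism %in% "phosphorylation" &
                            !is.na(pkn$edges$residue), , drop = FALSE]
  reg_sites <- bind_rows(
    reg_sites,
    tibble(gene_name = edge_sites$target, residue = edge_sites$residue,
           sign = 1L, role = "activity")
  )
  reg_sites <- reg_sites[!duplicated(reg_sites[, c("gene_name", "residue")]), , drop = FALSE]
  omics <- simulate_omics(regulons, truth, regulatory_sites = reg_sites,
                          sigma = sigma, seed = seed + 3)
  phenotype_edges <- make_phenotype_edges(pkn, seed = seed + 4)
  gold <- make_gold_standard(truth, drop_fraction = drop_fraction, seed = seed + 5)
  annotation <- tibble(gene_name = pkn$nodes$gene,
                       mol_function = pkn$nodes$mol_function)
  list(pkn = pkn, sources = sources, truth = truth, regulons = regulons,
       regulatory_sites = reg_sites, omics = omics,
       phenotype_edges = phenotype_edges, gold = gold, annotation = annotation)
}
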