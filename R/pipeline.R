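#' Default pipeline configuration
#'
#' Returns the full parameter set of the three-step pipeline with its tuned
#' defaults: hypergeometric weighting on, proteomics correction on, phospho
#' normalization on, activity-only regulatory sites, atlas integration on,
#' direct-only filtering off, PKN preprocessing on, three-layered naive
#' network with connect-all, vanilla three-shot optimization, proximity
#' preprocessing on with path length 4 and the mean null statistic, cascade
#' removal on, unweighted regulator contributions, optimizer states used.
#'
#' @param ... overrides as name = value pairs
#' @return a named list of class `pipeline_config`
#' @export
default_config <- function(...) {
  cfg <- list(
    # Step 1
    hypergeometric = TRUE,
    proteomics_correction = TRUE,
    normalize_phospho = TRUE,
    activity_only_sites = TRUE,
    min_targets = 5,
    sig_threshold = 0.05,
    z_threshold = 1.96,
    # Step 2
    include_atlas = TRUE,
    direct_only = FALSE,
    preprocess_pkn = TRUE,
    layout = "three",
    max_len = 4,
    connect_all = TRUE,
    flavor = "vanilla",
    shots = 3,
    beta = 0.2,
    # Step 3
    proxpath_preprocess = TRUE,
    phenotype_max_len = 4,
    proxpath_stat = "mean",
    remove_cascades = TRUE,
    weight_by_paths = FALSE,
    use_optimizer_states = TRUE,
    n_random = 100,
    # global
    seed = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    abort(sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")))
  }
  structure(modifyList(cfg, overrides), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; values omitted from the file keep their
#' defaults. The configuration round-trips losslessly through
#' [write_config()].
#'
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}

#' Write a pipeline configuration to YAML
#' @param config a `pipeline_config`
#' @param path output file
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full three-step pipeline
#'
#' Executes protein-activity inference (Step 1), naive-network construction
#' and sign-coherent optimization (Step 2) and phenotype attachment (Step 3)
#' on an input bundle, honoring which omics layers are present: with
#' transcriptomics only, only TF activities are inferred; phosphoproteomics
#' drives kinase/phosphatase footprints and PhosphoScore. Outputs are
#' returned and, when `output_dir` is given, written to disk (activity
#' table, model SIF/TSV/GraphML, phenotype table, metrics, run log).
#'
#' @param config a `pipeline_config` from [default_config()]
#' @param inputs list with `pkn`, `sources` (named sign vector), `regulons`,
#'   and optionally `regulatory_sites`, `omics` (list with any of
#'   `transcriptomics`, `phosphoproteomics`, `proteomics`),
#'   `phenotype_edges`, `annotation`, `gold`
#' @param output_dir optional output directory
#' @return list with `activities`, `naive`, `model`, `paths`,
#'   `phenotype_activities`, `metrics`, `config`
#' @export
run_pipeline <- function(config = default_config(), inputs, output_dir = NULL) {
  if (!inherits(config, "pipeline_config")) abort("config must come from default_config()/read_config()")
  if (is.null(inputs$pkn) || !inherits(inputs$pkn, "pkn")) {
    abort("run_pipeline: a PKN is mandatory (inputs$pkn)")
  }
  if (is.null(inputs$regulons)) abort("run_pipeline: regulons are mandatory (inputs$regulons)")
  if (is.null(inputs$sources) || !length(inputs$sources)) {
    abort("run_pipeline: at least one perturbed source node is mandatory (inputs$sources)")
  }
  omics <- inputs$omics %||% list()
  if (all(vapply(omics, is.null, TRUE))) abort("run_pipeline: at least one omics layer is required")
  set.seed(config$seed)
  log <- list(seed = config$seed, config = unclass(config))

  tx <- omics$transcriptomics
  ph <- omics$phosphoproteomics
  prot <- omics$proteomics

  # ---- Step 1: protein activities -------------------------------------
  if (!is.null(ph) && config$normalize_phospho && !is.null(prot)) {
    ph <- normalize_phospho(ph, prot, z_threshold = config$z_threshold)
  }
  regulons <- as_tibble(inputs$regulons)
  mf_of <- if ("mf" %in% names(regulons)) setNames(regulons$mf, regulons$regulator) else NULL
  footprints <- list()
  run_footprint <- function(signature, regs) {
    if (is.null(signature) || nrow(regs) == 0) return(NULL)
    et <- footprint_enrichment(signature, regs, min_targets = config$min_targets)
    if (config$hypergeometric && "significant" %in% names(signature)) {
      et <- hypergeometric_weighting(et, signature, regs)
    }
    proteomics_correction(et, if (config$proteomics_correction) prot else NULL,
                          sig_threshold = config$sig_threshold)
  }
  if (!is.null(tx)) {
    tf_regs <- if (!is.null(mf_of)) {
      regulons[mf_of[regulons$regulator] %in% "TF", , drop = FALSE]
    } else regulons
    sig <- tibble(id = tx$gene_name, statistic = tx$difference,
                  significant = tx$significant %||% FALSE)
    footprints$tf <- run_footprint(sig, tf_regs)
  }
  if (!is.null(ph)) {
    kin_regs <- if (!is.null(mf_of)) {
      regulons[mf_of[regulons$regulator] %in% c("KIN", "PP"), , drop = FALSE]
    } else regulons
    sig <- tibble(id = site_key(ph$gene_name, ph$residue),
                  statistic = ph$difference,
                  significant = ph$significant %||% FALSE)
    sig <- sig[!duplicated(sig$id), , drop = FALSE]
    footprints$kin <- run_footprint(sig, kin_regs)
  }
  ps <- NULL
  if (!is.null(ph) && !is.null(inputs$regulatory_sites)) {
    ps <- phospho_score(ph, inputs$regulatory_sites,
                        activity_only = config$activity_only_sites)
  }
  activities <- combine_activities(footprints[!vapply(footprints, is.null, TRUE)],
                                   ps, inputs$annotation)
  if (nrow(activities) == 0) abort("run_pipeline: no protein activity could be inferred")

  # ---- Step 2: network construction and optimization -------------------
  pkn <- inputs$pkn
  if (!config$include_atlas || config$direct_only) {
    pkn <- assemble_pkn(pkn$edges, direct_only = config$direct_only,
                        include_atlas = config$include_atlas, nodes = pkn$nodes)
  }
  if (config$preprocess_pkn) {
    quantified <- unique(c(
      if (!is.null(tx)) tx$gene_name, if (!is.null(ph)) ph$gene_name,
      if (!is.null(prot)) prot$gene_name,
      names(inputs$sources), activities$gene_name
    ))
    pkn <- preprocess_pkn(pkn, quantified)
  }
  naive <- build_naive_network(pkn, inputs$sources, activities,
                               layout = config$layout, max_len = config$max_len,
                               connect_all = config$connect_all)
  model <- run_multishot(naive, shots = config$shots, flavor = config$flavor,
                         beta = config$beta)
  if (!is.null(ph)) model <- validate_edges_with_phospho(model, ph)

  # ---- Step 3: phenotype inference -------------------------------------
  paths <- NULL
  pheno_act <- NULL
  if (!is.null(inputs$phenotype_edges) && nrow(model$nodes) > 0) {
    quantified <- unique(c(activities$gene_name, names(inputs$sources),
                           if (!is.null(prot)) prot$gene_name))
    paths <- proxpath_proximity(
      pkn, proteins = model$nodes$gene, phenotype_edges = inputs$phenotype_edges,
      max_len = config$phenotype_max_len, stat = config$proxpath_stat,
      preprocess = config$proxpath_preprocess, quantified_analytes = quantified,
      n_random = config$n_random, seed = config$seed
    )
    pheno_act <- phenotype_activity(
      model, paths, activities = activities,
      remove_cascades = config$remove_cascades,
      weight_by_paths = config$weight_by_paths,
      use_optimizer_states = config$use_optimizer_states
    )
    model <- attach_phenotypes(model, pheno_act, paths)
  }

  metrics <- NULL
  if (!is.null(inputs$gold)) {
    preds <- tibble(id = activities$gene_name, activity = activities$activity)
    metrics <- prf_rmse(preds, inputs$gold)
  }

  result <- list(activities = activities, naive = naive, model = model,
                 paths = paths, phenotype_activities = pheno_act,
                 metrics = metrics, config = config)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(activities, file.path(output_dir, "activities.tsv"), progress = FALSE)
    write_model(model, output_dir)
    if (!is.null(pheno_act) && nrow(pheno_act)) {
      readr::write_tsv(pheno_act[, c("phenotype", "activity", "n_regulators")],
                       file.path(output_dir, "phenotypes.tsv"), progress = FALSE)
    }
    if (!is.null(metrics)) {
      readr::write_tsv(as_tibble(metrics[c("precision", "recall", "rmse",
                                           "tp", "fp", "fn", "tn")]),
                       file.path(output_dir, "metrics.tsv"), progress = FALSE)
    }
    log$n_activities <- nrow(activities)
    log$model_nodes <- nrow(model$nodes)
    log$model_edges <- nrow(model$edges)
    yaml::write_yaml(log, file.path(output_dir, "run_log.yaml"))
  }
  result
}
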