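#' Precision, recall and RMSE against a gold standard
#'
#' An inferred entity matching the expected sign is a true positive,
#' diverging a false positive. False negatives are inferable gold entities
#' not inferred. True negatives follow the literal definition "entities with
#' opposite activity than expected and not inferred": they can only be
#' counted when a `candidates` table of entities scored during inference but
#' excluded from the final output is supplied; otherwise TN = 0. TN feeds no
#' downstream formula. RMSE is the root mean squared difference between
#' predicted signs (scores clipped to -1/+1) and expected signs over the
#' inferred-and-gold intersection. Not-inferable gold entities are excluded
#' from every count.
#'
#' @param predictions tibble with `id` and signed `activity` (or a score
#'   whose sign is used)
#' @param gold tibble with `id`, `expected` (-1/+1) and optional logical
#'   `inferable` (default TRUE)
#' @param candidates optional tibble with `id`, `activity` of entities
#'   scored but not included in the final predictions
#' @return list of class `metric_bundle` with precision, recall, rmse, tp,
#'   fp, fn, tn, n_inferred
#' @export
prf_rmse <- function(predictions, gold, candidates = NULL) {
  predictions <- as_tibble(predictions)
  gold <- as_tibble(gold)
  require_columns(predictions, c("id", "activity"), "predictions")
  require_columns(gold, c("id", "expected"), "gold standard")
  if (!"inferable" %in% names(gold)) gold$inferable <- TRUE
  gold <- gold[gold$inferable %in% TRUE, , drop = FALSE]
  pred_sign <- setNames(sign_int(predictions$activity), predictions$id)
  inter <- gold[gold$id %in% names(pred_sign), , drop = FALSE]
  tp <- sum(pred_sign[inter$id] == inter$expected)
  fp <- sum(pred_sign[inter$id] != inter$expected)
  fn <- sum(!gold$id %in% names(pred_sign))
  tn <- 0L
  if (!is.null(candidates)) {
    cand <- as_tibble(candidates)
    cand <- cand[!cand$id %in% predictions$id, , drop = FALSE]
    cg <- inner_join(cand, gold, by = "id")
    tn <- sum(sign_int(cg$activity) == -cg$expected)
  }
  rmse <- if (nrow(inter) == 0) NA_real_ else
    sqrt(mean((pred_sign[inter$id] - inter$expected)^2))
  structure(list(
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    rmse = rmse,
    tp = tp, fp = fp, fn = fn, tn = tn,
    n_inferred = nrow(inter)
  ), class = "metric_bundle")
}

#' @export
print.metric_bundle <- function(x, ...) {
  cat(sprintf("<metric_bundle> precision %.3f, recall %.3f, RMSE %s (TP %d, FP %d, FN %d, TN %d)\n",
              x$precision, x$recall,
              if (is.na(x$rmse)) "NA" else sprintf("%.3f", x$rmse),
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Topological metrics of a signaling model
#'
#' Node/edge/component counts, global clustering coefficient on the
#' undirected projection, diameter of the largest component, and the fit of
#' the degree distribution to a power law measured as the Kolmogorov-Smirnov
#' distance of a maximum-likelihood discrete power-law fit.
#'
#' @param model a `signaling_model` or igraph
#' @return list with n_nodes, n_edges, n_components, clustering_coefficient,
#'   diameter, power_law_fit
#' @export
topology_metrics <- function(model) {
  g <- if (inherits(model, "signaling_model")) model_graph(model) else model
  if (igraph::vcount(g) == 0) abort("topology_metrics: empty graph")
  und <- igraph::as_undirected(g, mode = "collapse")
  comps <- igraph::components(und)
  cc <- igraph::transitivity(und, type = "global")
  if (is.na(cc)) cc <- 0
  big <- igraph::induced_subgraph(und, which(comps$membership == which.max(comps$csize)))
  diam <- if (igraph::vcount(big) <= 1) 0 else igraph::diameter(big, unconnected = FALSE)
  degs <- igraph::degree(und)
  plf <- if (length(unique(degs[degs > 0])) < 2) 0 else {
    fit <- suppressWarnings(igraph::fit_power_law(degs[degs > 0], implementation = "plfit"))
    fit$KS.stat
  }
  list(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    n_components = comps$no,
    clustering_coefficient = cc,
    diameter = diam,
    power_law_fit = plf
  )
}

check_components <- function(bundle, needed, where) {
  missing <- needed[!vapply(needed, function(k)
    !is.null(bundle[[k]]) && !is.na(bundle[[k]]), TRUE)]
  if (length(missing)) {
    abort(sprintf("%s: missing component(s): %s", where,
                  paste(missing, collapse = ", ")))
  }
}

#' Combined quality score for network construction
#'
#' (precision*0.5 + recall*0.5 + SignRatio*0.5 + ClusteringCoefficient*0.5)
#'   - (NormTime*0.2 + PowerLawFit)
#'
#' SignRatio is the fraction of model edges validated by significant
#' phosphorylation events; NormTime is the computation time normalized by
#' its maximum across compared runs.
#'
#' @param bundle named list with `precision`, `recall`, `sign_ratio`,
#'   `clustering_coefficient`, `norm_time`, `power_law_fit`
#' @return the combined score (numeric scalar)
#' @export
combined_score_step2 <- function(bundle) {
  check_components(bundle, c("precision", "recall", "sign_ratio",
                             "clustering_coefficient", "norm_time",
                             "power_law_fit"), "combined_score_step2")
  (bundle$precision * 0.5 + bundle$recall * 0.5 + bundle$sign_ratio * 0.5 +
      bundle$clustering_coefficient * 0.5) -
    (bundle$norm_time * 0.2 + bundle$power_law_fit)
}

#' Combined quality score for phenotype inference
#'
#' (precision + recall) - (normRMSE + normTime*0.5), where normRMSE and
#' normTime are each value divided by its maximum across compared runs.
#'
#' @param bundle named list with `precision`, `recall`, `norm_rmse`,
#'   `norm_time`
#' @return the combined score (numeric scalar)
#' @export
combined_score_step3 <- function(bundle) {
  check_components(bundle, c("precision", "recall", "norm_rmse", "norm_time"),
                   "combined_score_step3")
  (bundle$precision + bundle$recall) -
    (bundle$norm_rmse + bundle$norm_time * 0.5)
}

#' Degree-preserving rewiring of a signed network
#'
#' Generates randomized versions of the PKN by double-edge swaps applied
#' independently within the positive-edge set and within the negative-edge
#' set, so that every node's signed in- and out-degree is exactly preserved.
#' Swapping continues until at least `fraction` of each sign class's edges
#' differ from the original wiring (or a swap-attempt budget is exhausted on
#' very constrained graphs).
#'
#' @param pkn a [pkn] object with at least two same-sign edges
#' @param fraction fraction of edges required to move (in (0, 1])
#' @param n_reps number of randomized networks
#' @param seed RNG seed
#' @return list of [pkn] objects
#' @export
rewire_network <- function(pkn, fraction = 1.0, n_reps = 1, seed = 1) {
  stopifnot(inherits(pkn, "pkn"))
  if (fraction <= 0 || fraction > 1) abort("fraction must lie in (0, 1]")
  counts <- table(pkn$edges$sign)
  if (all(counts < 2)) abort("rewire_network: graph too small to swap (need >= 2 same-sign edges)")
  with_seed(seed, {
    lapply(seq_len(n_reps), function(rep) {
      edges <- pkn$edges
      for (s in c(1L, -1L)) {
        ii <- which(edges$sign == s)
        if (length(ii) < 2) next
        sub <- edges[ii, , drop = FALSE]
        orig_keys <- paste(sub$source, sub$target)
        all_keys <- function(e) paste(e$source, e$target)
        target_moved <- ceiling(fraction * nrow(sub))
        max_attempts <- 200L * nrow(sub)
        attempts <- 0L
        while (sum(!all_keys(sub) %in% orig_keys) < target_moved &&
               attempts < max_attempts) {
          attempts <- attempts + 1L
          pick <- sample(nrow(sub), 2)
          a <- sub[pick[1], ]; b <- sub[pick[2], ]
          new1 <- c(a$source, b$target); new2 <- c(b$source, a$target)
          if (new1[1] == new1[2] || new2[1] == new2[2]) next
          existing <- paste(edges$source, edges$target)
          existing[ii][pick] <- ""
          if (paste(new1, collapse = " ") %in% existing ||
              paste(new2, collapse = " ") %in% existing) next
          sub$target[pick[1]] <- new1[2]
          sub$target[pick[2]] <- new2[2]
          edges$target[ii] <- sub$target
        }
        edges[ii, ] <- sub
      }
      structure(list(edges = edges, nodes = pkn$nodes), class = "pkn")
    })
  })
}

#' Shuffle analyte statistics in an omics table
#'
#' For a seeded random subset of `round(fraction * nrow)` rows, the
#' statistic values are permuted among those rows; the remaining rows are
#' untouched. Used to probe the degradation of inference quality under
#' increasing input noise.
#'
#' @param table omics tibble with a `difference` column (or `statistic`)
#' @param fraction fraction of rows to shuffle
#' @param n_reps number of shuffled tables
#' @param seed RNG seed
#' @return list of shuffled tables
#' @export
shuffle_analytes <- function(table, fraction = 1.0, n_reps = 100, seed = 1) {
  table <- as_tibble(table)
  col <- if ("difference" %in% names(table)) "difference" else "statistic"
  require_columns(table, col, "omics table")
  if (nrow(table) == 0) abort("shuffle_analytes: empty table")
  n_pick <- round(fraction * nrow(table))
  with_seed(seed, {
    lapply(seq_len(n_reps), function(rep) {
      out <- table
      rows <- sample(nrow(out), n_pick)
      out[[col]][rows] <- out[[col]][rows][sample(n_pick)]
      out
    })
  })
}
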