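layer_of <- function(genes, sources, activities) {
  mf <- setNames(activities$mf, activities$gene_name)
  m <- unname(mf[genes])
  out <- rep("other", length(genes))
  out[m %in% c("KIN", "PP")] <- "kinase_phosphatase"
  out[m %in% "TF"] <- "TF"
  out[genes %in% sources] <- "source"
  setNames(out, genes)
}

#' Build a layered naive network from a PKN
#'
#' Extracts from the PKN the subgraph spanned by all shortest paths (of
#' length at most `max_len` per layer boundary) that bridge consecutive
#' node layers: perturbed source nodes to kinases/phosphatases (layer 1),
#' kinases/phosphatases to other signaling proteins (layer 2), and the
#' latter to transcription factors (layer 3). The `one` layout connects the
#' sources directly to all inferred proteins; `two` merges layers 2 and 3.
#' With `connect_all`, every PKN edge whose endpoints both already appear in
#' the network is added, capturing interactions among proteins discovered on
#' distinct shortest paths.
#'
#' @param pkn a [pkn] object
#' @param sources named integer vector of perturbed nodes with signs
#'   (-1/+1)
#' @param activities activity tibble from [combine_activities()] (columns
#'   `gene_name`, `mf`, `final_score`, `activity`)
#' @param layout "one", "two" or "three" layered
#' @param max_len maximum shortest-path length per layer boundary (scalar or
#'   one value per boundary)
#' @param connect_all add PKN edges among already-included nodes
#' @return a `naive_network` object (igraph + edge table with the boundary
#'   index that introduced each edge + per-node layer assignment)
#' @export
build_naive_network <- function(pkn, sources, activities,
                                layout = c("three", "two", "one"),
                                max_len = 4, connect_all = TRUE) {
  stopifnot(inherits(pkn, "pkn"))
  layout <- match.arg(layout)
  g <- pkn_graph(pkn)
  vnames <- igraph::V(g)$name

  missing_src <- setdiff(names(sources), vnames)
  if (length(missing_src)) {
    inform(sprintf("build_naive_network: %d source(s) absent from the PKN skipped: %s",
                   length(missing_src), paste(missing_src, collapse = ", ")))
  }
  sources <- sources[names(sources) %in% vnames]
  if (!length(sources)) abort("no perturbed source node is present in the PKN")
  act <- activities[activities$gene_name %in% vnames, , drop = FALSE]
  n_missing <- nrow(activities) - nrow(act)
  if (n_missing > 0) {
    inform(sprintf("build_naive_network: %d inferred protein(s) absent from the PKN skipped", n_missing))
  }

  kin <- act$gene_name[act$mf %in% c("KIN", "PP")]
  oth <- act$gene_name[act$mf == "OTHER"]
  tf <- act$gene_name[act$mf == "TF"]
  boundaries <- switch(layout,
    one = list(list(from = names(sources), to = act$gene_name)),
    two = list(list(from = names(sources), to = kin),
               list(from = kin, to = c(oth, tf))),
    three = list(list(from = names(sources), to = kin),
                 list(from = kin, to = oth),
                 list(from = oth, to = tf))
  )
  max_len <- rep_len(max_len, length(boundaries))

  # unique (source, target) pairs for path search; parallel signed edges are
  # re-attached afterwards
  pair_graph <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  edge_rows <- list()
  present <- names(sources)
  for (b in seq_along(boundaries)) {
    from <- intersect(unique(boundaries[[b]]$from), igraph::V(pair_graph)$name)
    to <- setdiff(intersect(unique(boundaries[[b]]$to), igraph::V(pair_graph)$name), from)
    if (!length(from) || !length(to)) {
      warn(sprintf("build_naive_network: boundary %d has an empty node set; skipped", b))
      next
    }
    for (f in from) {
      paths <- suppressWarnings(
        igraph::all_shortest_paths(pair_graph, from = f, to = to, mode = "out")$res
      )
      for (p in paths) {
        nm <- igraph::as_ids(p)
        len <- length(nm) - 1L
        if (len >= 1 && len <= max_len[b]) {
          edge_rows[[length(edge_rows) + 1L]] <-
            tibble(source = nm[-length(nm)], target = nm[-1], boundary = b)
        }
      }
    }
    present <- unique(c(present, unlist(lapply(edge_rows, function(x) c(x$source, x$target)))))
  }
  pairs <- if (length(edge_rows)) distinct(bind_rows(edge_rows)) else
    tibble(source = character(), target = character(), boundary = integer())
  pairs <- pairs |> group_by(.data$source, .data$target) |>
    summarise(boundary = min(.data$boundary), .groups = "drop")

  if (nrow(pairs) == 0) {
    warn("build_naive_network: no admissible path between any layer pair; the naive network is empty")
  }

  node_set <- unique(c(names(sources), pairs$source, pairs$target))
  if (connect_all && nrow(pairs) > 0) {
    extra <- pkn$edges[pkn$edges$source %in% node_set &
                         pkn$edges$target %in% node_set &
                         pkn$edges$source != pkn$edges$target, c("source", "target")]
    extra <- distinct(extra)
    extra <- anti_join(extra, pairs, by = c("source", "target"))
    if (nrow(extra)) {
      bnd <- setNames(rep(NA_integer_, length(node_set)), node_set)
      for (b in rev(seq_along(boundaries))) {
        bnd[unique(c(pairs$source[pairs$boundary == b], pairs$target[pairs$boundary == b]))] <- b
      }
      bnd[names(sources)] <- 1L
      extra$boundary <- pmax(bnd[extra$source], bnd[extra$target], na.rm = TRUE)
      pairs <- bind_rows(pairs, extra)
    }
  }

  edges <- inner_join(pkn$edges, pairs, by = c("source", "target"))
  layers <- layer_of(node_set, names(sources), act)
  structure(list(
    edges = edges,
    nodes = node_set,
    layers = layers,
    sources = sources,
    activities = act,
    layout = layout,
    max_len = max_len,
    n_boundaries = length(boundaries)
  ), class = "naive_network")
}

#' @export
print.naive_network <- function(x, ...) {
  cat(sprintf("<naive_network> layout %s: %d nodes, %d edges, %d boundaries\n",
              x$layout, length(x$nodes), nrow(x$edges), x$n_boundaries))
  invisible(x)
}

measured_weights <- function(activities) {
  activities <- activities[sign_int(activities$activity) != 0L, , drop = FALSE]
  if (nrow(activities) == 0) return(tibble(gene = character(), sign = integer(), weight = double()))
  w <- abs(activities$final_score)
  mx <- max(w)
  if (!is.finite(mx) || mx == 0) w[] <- 1 else w <- w / mx
  tibble(gene = activities$gene_name, sign = as.integer(activities$activity), weight = w)
}

new_signaling_model <- function(states, edges, naive, objective, flavor, shots = 1L) {
  keep <- names(states)[states != 0L]
  edges <- as_tibble(edges)
  if (nrow(edges) > 0) {
    meta <- naive$edges[, c("source", "target", "sign", "direct", "mechanism",
                            "residue", "source_db")]
    meta <- meta[!duplicated(meta[, c("source", "target", "sign")]), , drop = FALSE]
    edges <- left_join(edges, meta, by = c("source", "target", "sign"))
  }
  nodes <- tibble(
    gene = keep,
    state = as.integer(states[keep]),
    layer = unname(naive$layers[keep] %||% rep(NA_character_, length(keep)))
  )
  structure(list(
    nodes = nodes,
    edges = edges,
    states = states,
    objective = objective,
    flavor = flavor,
    shots = shots,
    sign_ratio = NA_real_
  ), class = "signaling_model")
}

#' @export
print.signaling_model <- function(x, ...) {
  cat(sprintf("<signaling_model> %s, %d shot(s): %d nodes (%d+/%d-), %d edges; objective %.4g\n",
              x$flavor, x$shots, nrow(x$nodes), sum(x$nodes$state > 0),
              sum(x$nodes$state < 0), nrow(x$edges), x$objective))
  if (!is.na(x$sign_ratio)) cat(sprintf("  SignRatio: %.3f\n", x$sign_ratio))
  invisible(x)
}

#' Convert a signaling model to an igraph object
#' @param model a `signaling_model`
#' @return directed igraph with node attribute `state` and edge attributes
#' @export
model_graph <- function(model) {
  stopifnot(inherits(model, "signaling_model"))
  nodes <- model$nodes
  if ("phenotype" %in% names(nodes)) nodes$phenotype[is.na(nodes$phenotype)] <- FALSE
  igraph::graph_from_data_frame(as.data.frame(model$edges), directed = TRUE,
                                vertices = as.data.frame(nodes))
}

#' Optimize a naive network into a sign-coherent model
#'
#' Runs the exact sign-coherent optimization over the naive network. The
#' `vanilla` flavor uses the perturbed nodes as fixed-sign sources; the
#' `inverse` flavor attaches an artificial perturbation node to a candidate
#' receptor set with free-sign edges and leaves its sign unconstrained.
#'
#' @param naive a `naive_network`
#' @param flavor "vanilla" or "inverse"
#' @param beta edge-inclusion penalty
#' @param receptors candidate receptor genes for the inverse flavor
#'   (defaults to the perturbed nodes)
#' @param activities measured activities (defaults to those stored in the
#'   naive network); weights are |score| normalized to [0, 1]
#' @return a `signaling_model`
#' @export
ilp_optimize <- function(naive, flavor = c("vanilla", "inverse"), beta = 0.2,
                         receptors = NULL, activities = NULL) {
  stopifnot(inherits(naive, "naive_network"))
  flavor <- match.arg(flavor)
  activities <- activities %||% naive$activities
  edges <- distinct(naive$edges[, c("source", "target", "sign")])
  measured <- measured_weights(activities)
  measured <- measured[measured$gene %in% c(naive$nodes, names(naive$sources)), , drop = FALSE]
  if (flavor == "vanilla") {
    if (!length(naive$sources)) abort("vanilla optimization requires at least one fixed-sign source")
    sol <- solve_sign_coherent(edges, naive$sources, measured, beta = beta)
    return(new_signaling_model(sol$states, sol$edges, naive, sol$objective, flavor))
  }
  receptors <- receptors %||% names(naive$sources)
  receptors <- intersect(receptors, naive$nodes)
  if (!length(receptors)) abort("inverse optimization requires a candidate receptor set present in the network")
  pert <- ".perturbation"
  aug <- bind_rows(edges,
                   tibble(source = pert, target = receptors, sign = 1L),
                   tibble(source = pert, target = receptors, sign = -1L))
  sols <- lapply(c(1L, -1L), function(s) {
    solve_sign_coherent(aug, setNames(s, pert), measured, beta = beta)
  })
  best <- sols[[which.min(vapply(sols, `[[`, 0, "objective"))]]
  naive_aug <- naive
  naive_aug$edges <- bind_rows(
    naive$edges,
    tibble(source = pert, target = receptors, sign = 1L, direct = TRUE,
           mechanism = "perturbation", residue = NA_character_,
           source_db = "artificial"),
    tibble(source = pert, target = receptors, sign = -1L, direct = TRUE,
           mechanism = "perturbation", residue = NA_character_,
           source_db = "artificial")
  )
  naive_aug$layers <- c(naive$layers, setNames("source", pert))
  new_signaling_model(best$states, best$edges, naive_aug, best$objective, flavor)
}

#' Multi-shot optimization over network layers
#'
#' With `shots = 1` a single optimization covers the whole naive network.
#' With 2 or 3 shots the layer boundaries are split into consecutive groups
#' and solved sequentially: each shot is seeded with the previous shot's
#' solved nonzero node states as fixed-sign sources, and the per-shot
#' solutions are merged into one model. On merge conflicts the more upstream
#' shot wins (count reported).
#'
#' @param naive a `naive_network` with layer boundaries
#' @param shots number of sequential optimizations (1, 2 or 3; capped at the
#'   number of boundaries)
#' @param flavor passed to [ilp_optimize()] for the first shot
#' @param beta edge-inclusion penalty
#' @param receptors inverse-flavor receptor candidates (first shot only)
#' @return a `signaling_model` combining all shots
#' @export
run_multishot <- function(naive, shots = 3, flavor = c("vanilla", "inverse"),
                          beta = 0.2, receptors = NULL) {
  stopifnot(inherits(naive, "naive_network"))
  flavor <- match.arg(flavor)
  shots <- as.integer(shots)
  stopifnot(shots %in% 1:3)
  if (shots > naive$n_boundaries) {
    warn(sprintf("run_multishot: %d shot(s) requested but only %d boundary(ies); capping",
                 shots, naive$n_boundaries))
    shots <- naive$n_boundaries
  }
  if (shots == 1L) {
    mod <- ilp_optimize(naive, flavor = flavor, beta = beta, receptors = receptors)
    mod$shots <- 1L
    return(mod)
  }
  groups <- vector("list", shots)
  for (k in seq_len(shots)) {
    groups[[k]] <- if (k < shots) k else k:naive$n_boundaries
  }
  all_states <- naive$sources
  sel_edges <- list()
  objective <- 0
  act <- naive$activities
  for (k in seq_along(groups)) {
    sub_edges <- naive$edges[naive$edges$boundary %in% groups[[k]], , drop = FALSE]
    sub_nodes <- unique(c(sub_edges$source, sub_edges$target))
    if (k == 1L) {
      src <- naive$sources
    } else {
      # seed with every state solved so far (original sources included)
      solved <- all_states[all_states != 0L]
      src <- solved[names(solved) %in% sub_nodes]
    }
    sub_meas <- measured_weights(act[act$gene_name %in% setdiff(sub_nodes, names(src)), , drop = FALSE])
    if (nrow(sub_meas) == 0) {
      warn(sprintf("run_multishot: shot %d has no measured nodes; skipped", k))
      next
    }
    if (!length(src)) {
      warn(sprintf("run_multishot: shot %d has no seeded sources; skipped", k))
      next
    }
    sub <- distinct(sub_edges[, c("source", "target", "sign")])
    sol <- if (k == 1L && flavor == "inverse") {
      sub_naive <- naive
      sub_naive$edges <- sub_edges
      sub_naive$nodes <- sub_nodes
      sub_naive$activities <- act[act$gene_name %in% sub_nodes, , drop = FALSE]
      m <- ilp_optimize(sub_naive, flavor = "inverse", beta = beta, receptors = receptors)
      list(states = m$states, edges = m$edges[, c("source", "target", "sign")],
           objective = m$objective)
    } else {
      solve_sign_coherent(sub, src, sub_meas, beta = beta)
    }
    objective <- objective + sol$objective
    new_states <- sol$states[sol$states != 0L]
    conflicts <- intersect(names(new_states), names(all_states)[all_states != 0L])
    conflicts <- conflicts[new_states[conflicts] != all_states[conflicts]]
    if (length(conflicts)) {
      inform(sprintf("run_multishot: %d state conflict(s) at shot %d resolved in favor of the upstream shot",
                     length(conflicts), k))
      new_states <- new_states[!names(new_states) %in% conflicts]
    }
    keep_new <- setdiff(names(new_states), names(all_states))
    all_states <- c(all_states, new_states[keep_new])
    sel <- as_tibble(sol$edges)
    sel <- sel[!(sel$target %in% conflicts), , drop = FALSE]
    sel_edges[[k]] <- sel
  }
  edges <- if (length(sel_edges)) distinct(bind_rows(sel_edges)) else
    tibble(source = character(), target = character(), sign = integer())
  # merged states must stay coherent and supported: drop incoherent edges,
  # then zero out any nonzero non-source node left without a supporting
  # incoming edge, iterating to a fixed point
  all_nodes <- unique(c(naive$nodes, names(all_states), edges$source, edges$target))
  st <- setNames(rep(0L, length(all_nodes)), all_nodes)
  st[names(all_states)] <- as.integer(all_states)
  src_names <- names(naive$sources)
  if (flavor == "inverse") src_names <- c(src_names, ".perturbation")
  repeat {
    if (nrow(edges)) {
      ok <- st[edges$source] != 0L & st[edges$target] == edges$sign * st[edges$source]
      edges <- edges[ok, , drop = FALSE]
    }
    supported <- unique(edges$target)
    bad <- names(st)[st != 0L & !names(st) %in% src_names & !names(st) %in% supported]
    if (!length(bad)) break
    st[bad] <- 0L
  }
  new_signaling_model(st, edges, naive, objective, flavor, shots = shots)
}

#' Flag model edges validated by phosphoproteomics
#'
#' A phosphorylation edge is flagged `quantified` when its (target gene,
#' residue) phosphosite appears in the phospho table, and `validated` when
#' that site is significant. The model is annotated with the SignRatio: the
#' fraction of model edges validated by significant phosphorylation events.
#'
#' @param model a `signaling_model`
#' @param phospho_table tibble with `gene_name`, `residue`, `significant`
#' @return the model with per-edge flags and `sign_ratio` filled in
#' @export
validate_edges_with_phospho <- function(model, phospho_table) {
  stopifnot(inherits(model, "signaling_model"))
  phospho_table <- as_tibble(phospho_table)
  require_columns(phospho_table, c("gene_name", "residue", "significant"), "phospho table")
  edges <- model$edges
  if (nrow(edges) == 0) {
    model$sign_ratio <- NA_real_
    return(model)
  }
  is_ptm <- !is.na(edges$mechanism) & edges$mechanism == "phosphorylation" &
    !is.na(edges$residue)
  key <- paste(edges$target, edges$residue, sep = "_")
  pkey <- paste(phospho_table$gene_name, phospho_table$residue, sep = "_")
  sig_key <- pkey[phospho_table$significant %in% TRUE]
  edges$quantified <- is_ptm & key %in% pkey
  edges$validated <- is_ptm & key %in% sig_key
  model$edges <- edges
  model$sign_ratio <- sum(edges$validated) / nrow(edges)
  model
}
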