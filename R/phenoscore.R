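# Signed-path machinery: a graph with signed edges is "doubled" into parity
# layers so that a breadth-first distance in the doubled graph equals the
# shortest path with a given aggregate sign in the original graph.
doubled_graph <- function(edges) {
  up <- paste0(edges$source, "|+")
  un <- paste0(edges$source, "|-")
  s <- ifelse(edges$sign > 0, "+", "-")
  flip <- ifelse(edges$sign > 0, "-", "+")
  d <- tibble(
    from = c(up, un),
    to = c(paste0(edges$target, "|", s), paste0(edges$target, "|", flip))
  )
  igraph::graph_from_data_frame(as.data.frame(d), directed = TRUE)
}

parity_vertex <- function(g, gene, parity) {
  nm <- paste0(gene, "|", parity)
  ifelse(nm %in% igraph::V(g)$name, nm, NA_character_)
}

# number of walks of length <= max_len and aggregate sign `cls` between two
# nodes, by dynamic programming on the doubled adjacency matrix
signed_walk_count <- function(edges, from, to, cls, max_len) {
  nodes_p <- unique(c(paste0(edges$source, "|+"), paste0(edges$source, "|-"),
                      paste0(edges$target, "|+"), paste0(edges$target, "|-")))
  n <- length(nodes_p)
  ix <- setNames(seq_len(n), nodes_p)
  A <- matrix(0, n, n)
  s <- ifelse(edges$sign > 0, "+", "-")
  flip <- ifelse(edges$sign > 0, "-", "+")
  A[cbind(ix[paste0(edges$source, "|+")], ix[paste0(edges$target, "|", s)])] <- 1
  A[cbind(ix[paste0(edges$source, "|-")], ix[paste0(edges$target, "|", flip)])] <- 1
  start <- ix[paste0(from, "|+")]
  end <- ix[paste0(to, "|", if (cls > 0) "+" else "-")]
  if (is.na(start) || is.na(end)) return(0)
  v <- numeric(n); v[start] <- 1
  total <- 0
  for (l in seq_len(max_len)) {
    v <- as.numeric(v %*% A)
    total <- total + v[end]
  }
  total
}

#' Functional proximity of proteins to phenotypes
#'
#' For each (protein, phenotype, sign class) the observed score is the
#' shortest-path length among paths whose aggregate edge-sign product equals
#' the class, restricted to length <= `max_len`. Each observation is
#' compared to a null distribution of path lengths from `n_random`
#' degree-matched random source nodes (sampled without replacement from the
#' protein nodes closest in total degree; paths longer than `max_len` or
#' absent are censored at `max_len + 1`). The z-score is
#' (observed - stat(null)) / sd(null) and a pair is significant when
#' z <= -1.96, i.e. the protein is closer to the phenotype than random
#' proteins of similar connectivity.
#'
#' @param pkn a [pkn] object
#' @param proteins character vector of query proteins (model nodes)
#' @param phenotype_edges tibble with `protein`, `phenotype`, `sign` linking
#'   proteins to phenotype nodes
#' @param max_len maximum admissible path length
#' @param stat null-summary statistic, "mean" or "median"
#' @param preprocess discard paths traversing proteins absent from
#'   `quantified_analytes` (query proteins and phenotypes are exempt)
#' @param quantified_analytes gene symbols quantified in the experiment
#' @param n_random null-distribution size R
#' @param z_cutoff significance cutoff (z <= cutoff)
#' @param seed seed for the null sampling
#' @return tibble of phenotype paths: `regulator`, `phenotype`, `path_sign`,
#'   `length`, `z`, `significant`, `n_paths`
#' @export
proxpath_proximity <- function(pkn, proteins, phenotype_edges, max_len = 4,
                               stat = c("mean", "median"), preprocess = FALSE,
                               quantified_analytes = NULL, n_random = 100,
                               z_cutoff = -1.96, seed = 1) {
  stopifnot(inherits(pkn, "pkn"))
  stat <- match.arg(stat)
  stat_fun <- if (stat == "mean") mean else stats::median
  phenotype_edges <- as_tibble(phenotype_edges)
  require_columns(phenotype_edges, c("protein", "phenotype", "sign"), "phenotype-edge table")
  phenotypes <- unique(phenotype_edges$phenotype)
  edges <- bind_rows(
    pkn$edges[, c("source", "target", "sign")],
    tibble(source = phenotype_edges$protein, target = phenotype_edges$phenotype,
           sign = as.integer(phenotype_edges$sign))
  )
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  if (preprocess) {
    if (is.null(quantified_analytes)) {
      abort("preprocess = TRUE requires quantified_analytes")
    }
    exempt <- unique(c(proteins, phenotypes,
                       pkn$nodes$gene[pkn$nodes$entity_type != "protein"]))
    drop_nodes <- setdiff(unique(c(edges$source, edges$target)),
                          c(quantified_analytes, exempt))
    edges <- edges[!(edges$source %in% drop_nodes) &
                     !(edges$target %in% drop_nodes), , drop = FALSE]
  }
  gd <- doubled_graph(edges)
  all_nodes <- unique(c(edges$source, edges$target))
  protein_nodes <- setdiff(all_nodes, phenotypes)
  deg <- table(c(edges$source, edges$target))
  degree_of <- function(g) {
    d <- as.numeric(deg[g])
    ifelse(is.na(d), 0, d)
  }

  signed_dist <- function(from, phenotype) {
    v0 <- parity_vertex(gd, from, "+")
    if (is.na(v0)) return(c(`1` = Inf, `-1` = Inf))
    to_pos <- parity_vertex(gd, phenotype, "+")
    to_neg <- parity_vertex(gd, phenotype, "-")
    targets <- c(to_pos, to_neg)
    ok <- !is.na(targets)
    out <- c(`1` = Inf, `-1` = Inf)
    if (any(ok)) {
      dmat <- igraph::distances(gd, v = v0, to = targets[ok], mode = "out")
      out[c("1", "-1")[ok]] <- as.numeric(dmat)
    }
    out
  }

  rows <- list()
  for (p in intersect(proteins, all_nodes)) {
    d0 <- abs(degree_of(p) - vapply(protein_nodes, degree_of, 0))
    names(d0) <- protein_nodes
    pool_all <- protein_nodes[order(d0, protein_nodes)]
    if (length(pool_all) > n_random) {
      cut_val <- sort(d0)[n_random]
      pool <- protein_nodes[d0 <= cut_val]
    } else {
      pool <- pool_all
    }
    null_src <- if (length(pool) <= n_random) pool else {
      with_seed(seed, sample(pool, n_random))
    }
    for (ph in phenotypes) {
      obs <- signed_dist(p, ph)
      null_mat <- vapply(null_src, signed_dist, c(`1` = 0, `-1` = 0), phenotype = ph)
      null_mat[!is.finite(null_mat) | null_mat > max_len] <- max_len + 1
      for (cls in c(1L, -1L)) {
        o <- obs[[as.character(cls)]]
        if (!is.finite(o) || o > max_len) next
        null_lens <- null_mat[as.character(cls), ]
        mu <- stat_fun(null_lens)
        s <- sd(null_lens)
        z <- if (is.na(s) || s == 0) {
          if (o == mu) 0 else sign(o - mu) * Inf
        } else (o - mu) / s
        rows[[length(rows) + 1L]] <- tibble(
          regulator = p, phenotype = ph, path_sign = cls,
          length = as.integer(o), z = z, significant = z <= z_cutoff,
          n_paths = signed_walk_count(edges, p, ph, cls, max_len)
        )
      }
    }
  }
  if (!length(rows)) {
    return(tibble(regulator = character(), phenotype = character(),
                  path_sign = integer(), length = integer(), z = double(),
                  significant = logical(), n_paths = double()))
  }
  bind_rows(rows)
}

dominant_paths <- function(paths) {
  paths[paths$significant, , drop = FALSE] |>
    group_by(.data$regulator, .data$phenotype) |>
    arrange(.data$z, dplyr::desc(.data$path_sign), .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
}

#' Phenotype activity from upstream regulators (PhenoScore)
#'
#' Aggregates the signed activities of a phenotype's upstream regulators in
#' the model into one phenotype activity:
#' activity = sum_i w_i * path_sign_i * activity_i / sum_i w_i,
#' where the sum runs over eligible regulators (model proteins with a
#' significant proximity path to the phenotype), path_sign is the dominant
#' path sign of the regulator-phenotype pair, and w_i is the number of
#' significant paths when `weight_by_paths` is TRUE, 1 otherwise.
#'
#' @param model a `signaling_model`
#' @param paths output of [proxpath_proximity()]
#' @param activities Step-1 activity table; required when
#'   `use_optimizer_states` is FALSE so that only experimentally inferred
#'   proteins contribute, with their inferred activities
#' @param remove_cascades drop regulators reachable in the model from
#'   another eligible regulator of the same phenotype, keeping only
#'   independent regulators
#' @param weight_by_paths weight each regulator by its number of significant
#'   paths to the phenotype
#' @param use_optimizer_states use all nonzero model node states (TRUE) or
#'   only Step-1 inferred proteins (FALSE)
#' @return tibble with `phenotype`, `activity` (in [-1, 1] for signed
#'   regulator activities), `n_regulators` and a `regulators` list-column
#'   breakdown; phenotypes with no eligible regulator are omitted
#' @export
phenotype_activity <- function(model, paths, activities = NULL,
                               remove_cascades = TRUE, weight_by_paths = FALSE,
                               use_optimizer_states = TRUE) {
  stopifnot(inherits(model, "signaling_model"))
  dom <- dominant_paths(paths)
  states <- setNames(model$nodes$state, model$nodes$gene)
  dom <- dom[dom$regulator %in% names(states), , drop = FALSE]
  if (!use_optimizer_states) {
    if (is.null(activities)) {
      abort("use_optimizer_states = FALSE requires the Step-1 activity table")
    }
    act <- setNames(as.numeric(activities$activity), activities$gene_name)
    dom <- dom[dom$regulator %in% names(act), , drop = FALSE]
    dom$reg_activity <- unname(act[dom$regulator])
  } else {
    dom$reg_activity <- unname(as.numeric(states[dom$regulator]))
  }
  if (nrow(dom) == 0) {
    return(tibble(phenotype = character(), activity = double(),
                  n_regulators = integer(), regulators = list()))
  }
  if (remove_cascades && nrow(model$edges) > 0) {
    mg <- igraph::graph_from_data_frame(
      as.data.frame(model$edges[, c("source", "target")]), directed = TRUE)
    reach <- igraph::distances(mg, mode = "out")
    keep <- rep(TRUE, nrow(dom))
    for (ph in unique(dom$phenotype)) {
      ii <- which(dom$phenotype == ph)
      regs <- dom$regulator[ii]
      for (j in seq_along(ii)) {
        r <- regs[j]
        others <- intersect(setdiff(regs, r), rownames(reach))
        if (r %in% colnames(reach) && length(others) &&
            any(is.finite(reach[others, r]) & reach[others, r] > 0)) {
          keep[ii[j]] <- FALSE
        }
      }
    }
    dom <- dom[keep, , drop = FALSE]
  }
  dom$w <- if (weight_by_paths) pmax(dom$n_paths, 1) else 1
  parts <- split(dom, dom$phenotype)
  bind_rows(lapply(names(parts), function(ph) {
    d <- parts[[ph]]
    tibble(
      phenotype = ph,
      activity = sum(d$w * d$path_sign * d$reg_activity) / sum(d$w),
      n_regulators = nrow(d),
      regulators = list(tibble(regulator = d$regulator, path_sign = d$path_sign,
                               reg_activity = d$reg_activity, weight = d$w))
    )
  }))
}

#' Attach phenotype nodes to a signaling model
#'
#' Appends one node per inferred phenotype, carrying its activity, and one
#' signed edge per eligible regulator using the regulator's dominant path
#' sign. Phenotypes omitted upstream (no eligible regulators) leave the
#' model unchanged.
#'
#' @param model a `signaling_model`
#' @param phenotype_activities output of [phenotype_activity()]
#' @param paths output of [proxpath_proximity()] (unused beyond provenance;
#'   the regulator breakdown in `phenotype_activities` drives the edges)
#' @return the model with phenotype nodes and edges appended and a
#'   `phenotypes` element holding the activity table
#' @export
attach_phenotypes <- function(model, phenotype_activities, paths = NULL) {
  stopifnot(inherits(model, "signaling_model"))
  pa <- phenotype_activities
  if (is.null(pa) || nrow(pa) == 0) return(model)
  nodes <- model$nodes
  if (!"phenotype" %in% names(nodes)) nodes$phenotype <- FALSE
  if (!"activity" %in% names(nodes)) nodes$activity <- as.numeric(nodes$state)
  new_nodes <- tibble(
    gene = pa$phenotype,
    state = sign_int(pa$activity),
    layer = "phenotype",
    phenotype = TRUE,
    activity = pa$activity
  )
  edge_rows <- lapply(seq_len(nrow(pa)), function(i) {
    br <- pa$regulators[[i]]
    tibble(source = br$regulator, target = pa$phenotype[i],
           sign = as.integer(br$path_sign), direct = FALSE,
           mechanism = "phenotype_regulation", residue = NA_character_,
           source_db = "proximity")
  })
  new_edges <- bind_rows(edge_rows)
  model$nodes <- bind_rows(nodes, new_nodes)
  model$edges <- bind_rows(model$edges, new_edges)
  model$phenotypes <- pa
  model
}
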