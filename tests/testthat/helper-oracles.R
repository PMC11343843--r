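# Independent oracles used to cross-check the package's implementations.
# These deliberately re-derive each quantity from first principles (exhaustive
# enumeration, closed forms) and share no code with the package internals.

# Brute-force optimum of the sign-coherent subnetwork program: enumerate all
# node-state assignments and all subsets of sign-eligible edges, checking the
# support and acyclicity constraints explicitly.
brute_force_sign_coherent <- function(edges, source_states, measured, beta) {
  nodes <- unique(c(edges$source, edges$target, names(source_states), measured$gene))
  n <- length(nodes)
  free <- setdiff(nodes, names(source_states))
  mw <- setNames(rep(0, n), nodes)
  ms <- setNames(rep(0L, n), nodes)
  if (nrow(measured)) {
    mw[measured$gene] <- measured$weight
    ms[measured$gene] <- measured$sign
  }
  grid <- expand.grid(rep(list(c(-1L, 0L, 1L)), length(free)))
  best <- Inf
  for (gi in seq_len(max(nrow(grid), 1))) {
    st <- setNames(rep(0L, n), nodes)
    st[names(source_states)] <- source_states
    if (length(free)) st[free] <- unlist(grid[gi, ])
    mismatch <- sum(mw * abs(ms - st))
    # edges that could legally be selected under this assignment
    elig <- which(st[edges$source] != 0L &
                    st[edges$target] == edges$sign * st[edges$source])
    need <- names(st)[st != 0L & !nodes %in% names(source_states)]
    feasible_cost <- Inf
    k <- length(elig)
    for (mask in 0:(2^k - 1)) {
      sel <- elig[bitwAnd(mask, bitwShiftL(1, seq_len(k) - 1)) > 0]
      if (!all(need %in% edges$target[sel])) next
      if (length(sel) > 1) {
        g <- igraph::graph_from_data_frame(
          data.frame(from = edges$source[sel], to = edges$target[sel]))
        if (!igraph::is_dag(g)) next
      }
      cost <- mismatch + beta * length(sel)
      if (cost < feasible_cost) feasible_cost <- cost
    }
    if (feasible_cost < best) best <- feasible_cost
  }
  best
}

# random small optimization instance (<= 6 nodes, <= 8 edges)
random_ilp_instance <- function(seed) {
  set.seed(seed)
  n <- sample(4:6, 1)
  nodes <- paste0("N", seq_len(n))
  m <- sample(5:8, 1)
  pairs <- expand.grid(source = nodes, target = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pairs <- pairs[sample(nrow(pairs), min(m, nrow(pairs))), ]
  edges <- tibble::tibble(source = pairs$source, target = pairs$target,
                          sign = sample(c(-1L, 1L), nrow(pairs), replace = TRUE))
  src <- nodes[1]
  meas_nodes <- sample(setdiff(nodes, src), sample(2:3, 1))
  list(
    edges = edges,
    source_states = stats::setNames(sample(c(-1L, 1L), 1), src),
    measured = tibble::tibble(gene = meas_nodes,
                              sign = sample(c(-1L, 1L), length(meas_nodes), replace = TRUE),
                              weight = round(stats::runif(length(meas_nodes), 0.2, 1), 2)),
    beta = round(stats::runif(1, 0, 0.4), 2)
  )
}

# exact hypergeometric upper-tail P[X >= k] by combinatorial summation
hyper_tail_oracle <- function(N, K, n, k) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# independent evaluation of the footprint enrichment statistic
nes_oracle <- function(signature, regulon) {
  n <- nrow(signature)
  r <- rank(signature$statistic, ties.method = "average")
  q <- stats::qnorm(r / (n + 1))
  names(q) <- signature$id
  idx <- match(regulon$target, signature$id)
  keep <- !is.na(idx)
  w <- regulon$weight[keep]
  m <- regulon$mode[keep]
  sum(w * m * q[idx[keep]]) / sqrt(sum(w^2))
}

# shortest signed walk length between two nodes by adjacency-matrix powers
signed_walk_oracle <- function(edges, from, to, cls, max_len) {
  nodes <- unique(c(edges$source, edges$target))
  n <- length(nodes)
  Ap <- matrix(0, n, n, dimnames = list(nodes, nodes))
  An <- Ap
  for (i in seq_len(nrow(edges))) {
    if (edges$sign[i] > 0) Ap[edges$source[i], edges$target[i]] <- 1
    else An[edges$source[i], edges$target[i]] <- 1
  }
  # state: (positive-parity reach, negative-parity reach)
  vp <- setNames(numeric(n), nodes); vp[from] <- 1
  vn <- setNames(numeric(n), nodes)
  for (l in seq_len(max_len)) {
    vp2 <- as.numeric(vp %*% Ap + vn %*% An)
    vn2 <- as.numeric(vp %*% An + vn %*% Ap)
    names(vp2) <- names(vn2) <- nodes
    vp <- vp2; vn <- vn2
    hit <- if (cls > 0) vp[to] else vn[to]
    if (!is.na(hit) && hit > 0) return(l)
  }
  Inf
}

`%||%` <- function(a, b) if (is.null(a)) b else a
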