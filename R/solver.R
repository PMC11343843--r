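#' Exact sign-coherent subnetwork optimization
#'
#' Finds a global optimum of the CARNIVAL-style integer program: assign every
#' node a state in \{-1, 0, +1\} and select a set of edges minimizing
#'
#'   sum over measured nodes of w_m * |measured_m - state_m|
#'     + beta * (number of selected edges)
#'
#' subject to: an edge may be selected only if its source state is nonzero;
#' every selected edge (u -> v, s) is coherent, i.e. state_v = s * state_u;
#' every nonzero non-source node has at least one selected incoming edge;
#' and the selected edge set is acyclic.
#'
#' The search exploits the structure of the program: for any feasible state
#' assignment, every nonzero node must be reachable from a fixed-sign source
#' through coherent edges among nonzero nodes ("grounded"), and the minimal
#' supporting edge set is then a breadth-first parent forest with exactly one
#' incoming edge per nonzero non-source node. The optimizer therefore
#' branches over grounded state assignments with admissible cost bounds,
#' which yields the exact optimum of the integer program.
#'
#' @param edges tibble/data.frame with columns `source`, `target`, `sign`
#'   (in \{-1, +1\}); parallel edges of opposite sign are allowed
#' @param source_states named integer vector of fixed source signs (-1/+1)
#' @param measured tibble with columns `gene`, `sign` (-1/+1) and optional
#'   `weight` (> 0, defaults to 1). A node that is both a source and
#'   measured keeps its fixed source sign; its mismatch still counts.
#' @param beta edge-inclusion penalty (>= 0)
#' @return list with `states` (named integer vector over all nodes),
#'   `edges` (selected-edge tibble), `objective`, `mismatch_cost`, `n_edges`
#' @export
solve_sign_coherent <- function(edges, source_states, measured = NULL, beta = 0.2) {
  if (beta < 0) abort("beta must be >= 0")
  edges <- as_tibble(edges)
  require_columns(edges, c("source", "target", "sign"), "edge table")
  edges <- distinct(edges[, c("source", "target", "sign")])
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  if (is.null(measured)) measured <- tibble(gene = character(), sign = integer())
  measured <- as_tibble(measured)
  if (!"weight" %in% names(measured)) measured$weight <- 1
  if (any(!measured$sign %in% c(-1, 1))) abort("measured signs must be -1 or +1")
  if (length(source_states) == 0) abort("at least one fixed-sign source is required")
  if (any(!source_states %in% c(-1, 1))) abort("source states must be -1 or +1")

  nodes <- unique(c(edges$source, edges$target, names(source_states), measured$gene))
  n <- length(nodes)
  idx <- setNames(seq_len(n), nodes)
  src <- rep(0L, n); src[idx[names(source_states)]] <- as.integer(source_states)
  is_src <- src != 0L
  mw <- rep(0, n); ms <- rep(0L, n)
  if (nrow(measured)) {
    mi <- idx[measured$gene]
    mw[mi] <- measured$weight
    ms[mi] <- as.integer(measured$sign)
  }
  e_from <- idx[edges$source]; e_to <- idx[edges$target]; e_sgn <- as.integer(edges$sign)
  out_edges <- split(seq_along(e_from), factor(e_from, levels = seq_len(n)))

  # achievable signed states by BFS from the sources over signed edges
  ach <- matrix(FALSE, n, 2)  # columns: state -1, state +1
  colix <- function(s) (s + 3L) %/% 2L  # -1 -> 1, +1 -> 2
  queue <- list()
  for (i in which(is_src)) {
    ach[i, colix(src[i])] <- TRUE
    queue[[length(queue) + 1L]] <- c(i, src[i])
  }
  while (length(queue)) {
    it <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
    u <- it[1]; su <- it[2]
    for (e in out_edges[[u]]) {
      v <- e_to[e]; sv <- e_sgn[e] * su
      if (!ach[v, colix(sv)]) {
        ach[v, colix(sv)] <- TRUE
        queue[[length(queue) + 1L]] <- c(v, sv)
      }
    }
  }

  # nodes that cannot help explain any measured node are fixed at 0
  rev_adj <- split(e_from, factor(e_to, levels = seq_len(n)))
  useful <- rep(FALSE, n)
  stack <- which(mw > 0)
  useful[stack] <- TRUE
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    for (u in rev_adj[[v]]) if (!useful[u]) { useful[u] <- TRUE; stack <- c(stack, u) }
  }

  free <- which(!is_src & (ach[, 1] | ach[, 2]) & useful)
  # order free nodes by distance from the sources (stabilizes pruning)
  dist <- rep(Inf, n); dist[is_src] <- 0
  frontier <- which(is_src)
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(unlist(lapply(frontier, function(u) e_to[out_edges[[u]]])))
    nxt <- nxt[is.finite(nxt) & dist[nxt] > d]
    dist[nxt] <- d
    frontier <- nxt
  }
  free <- free[order(dist[free], free)]

  # fixed costs: sources and unassignable nodes have determined states
  state0 <- rep(0L, n); state0[is_src] <- src[is_src]
  fixed_cost <- sum(mw * abs(ms - state0) * (is_src | !(seq_len(n) %in% free)))

  # per-node candidate states and admissible lower bounds
  cand <- lapply(free, function(v) {
    s_opts <- c(0L, c(-1L, 1L)[ach[v, ]])
    cost <- mw[v] * abs(ms[v] - s_opts) + beta * (s_opts != 0L)
    s_opts[order(cost)]
  })
  lb <- vapply(seq_along(free), function(j) {
    v <- free[j]
    min(mw[v] * abs(ms[v] - cand[[j]]) + beta * (cand[[j]] != 0L))
  }, 0)
  lb_suffix <- rev(cumsum(rev(c(lb, 0))))

  env <- new.env(parent = emptyenv())
  env$best <- Inf; env$best_states <- state0
  state <- state0

  grounded_check <- function(state) {
    # BFS from nonzero sources through coherent edges among nonzero nodes
    seen <- rep(FALSE, n)
    q <- which(is_src & state != 0L)
    seen[q] <- TRUE
    parent <- rep(NA_integer_, n)
    while (length(q)) {
      u <- q[[1]]; q <- q[-1]
      for (e in out_edges[[u]]) {
        v <- e_to[e]
        if (!seen[v] && state[v] != 0L && state[v] == e_sgn[e] * state[u]) {
          seen[v] <- TRUE
          parent[v] <- e
          q <- c(q, v)
        }
      }
    }
    if (all(seen[state != 0L & !is_src])) parent else NULL
  }

  nfree <- length(free)
  recurse <- function(j, cost) {
    if (cost + lb_suffix[j] >= env$best) return(invisible())
    if (j > nfree) {
      parent <- grounded_check(state)
      if (!is.null(parent) && cost < env$best) {
        env$best <- cost
        env$best_states <- state
        env$best_parent <- parent
      }
      return(invisible())
    }
    v <- free[j]
    for (s in cand[[j]]) {
      step <- mw[v] * abs(ms[v] - s) + beta * (s != 0L)
      if (cost + step + lb_suffix[j + 1L] < env$best) {
        state[v] <<- s
        recurse(j + 1L, cost + step)
        state[v] <<- 0L
      }
    }
    invisible()
  }
  recurse(1L, fixed_cost)

  states <- setNames(as.integer(env$best_states), nodes)
  parent <- env$best_parent %||% rep(NA_integer_, n)
  sel <- parent[!is.na(parent)]
  sel_edges <- tibble(
    source = nodes[e_from[sel]],
    target = nodes[e_to[sel]],
    sign = e_sgn[sel]
  )
  n_edges <- nrow(sel_edges)
  list(
    states = states,
    edges = sel_edges,
    objective = env$best,
    mismatch_cost = env$best - beta * n_edges,
    n_edges = n_edges
  )
}
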