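pheno_pkn <- function() {
  edges <- tibble::tibble(
    source = c("A", "B", "C", "U", "A"),
    target = c("B", "C", "D", "D", "U"),
    sign = c(1L, -1L, 1L, 1L, 1L),
    direct = TRUE, mechanism = "binding", residue = NA_character_,
    source_db = "toy"
  )
  nodes <- tibble::tibble(gene = c("A", "B", "C", "D", "U"),
                          mol_function = "OTHER", entity_type = "protein")
  pkn(edges, nodes)
}

test_that("direct phenotype edges yield length-1 signed paths", {
  p <- pheno_pkn()
  pe <- tibble::tibble(protein = "D", phenotype = "Growth", sign = 1L)
  paths <- proxpath_proximity(p, proteins = "D", phenotype_edges = pe,
                              max_len = 4, n_random = 3, seed = 1)
  d <- paths[paths$regulator == "D", ]
  expect_equal(d$length, 1L)
  expect_equal(d$path_sign, 1L)
})

test_that("path signs multiply along the path and preprocessing drops undetected intermediates", {
  p <- pheno_pkn()
  pe <- tibble::tibble(protein = "D", phenotype = "Growth", sign = 1L)
  # A -> B -> C -> D -> Growth has sign 1*-1*1*1 = -1 at length 4
  paths <- proxpath_proximity(p, proteins = "A", phenotype_edges = pe,
                              max_len = 4, n_random = 3, seed = 1)
  a <- paths[paths$regulator == "A", ]
  expect_true(nrow(a) >= 1)
  neg <- a[a$path_sign == -1L, ]
  expect_equal(neg$length, 4L)
  # the shorter positive route A -> U -> D -> Growth runs through U
  pos <- a[a$path_sign == 1L, ]
  expect_equal(pos$length, 3L)
  # dropping U as undetected removes the positive route
  pre <- proxpath_proximity(p, proteins = "A", phenotype_edges = pe,
                            max_len = 4, preprocess = TRUE,
                            quantified_analytes = c("A", "B", "C", "D"),
                            n_random = 3, seed = 1)
  a_pre <- pre[pre$regulator == "A", ]
  expect_false(any(a_pre$path_sign == 1L))
  expect_true(any(a_pre$path_sign == -1L))
})

test_that("observed path lengths match an independent signed-walk oracle", {
  p <- pheno_pkn()
  pe <- tibble::tibble(protein = c("D", "B"), phenotype = "Growth",
                       sign = c(1L, -1L))
  all_edges <- dplyr::bind_rows(
    p$edges[, c("source", "target", "sign")],
    tibble::tibble(source = pe$protein, target = pe$phenotype, sign = pe$sign)
  )
  paths <- proxpath_proximity(p, proteins = c("A", "B", "C"),
                              phenotype_edges = pe, max_len = 4,
                              n_random = 3, seed = 1)
  for (i in seq_len(nrow(paths))) {
    expect_equal(
      paths$length[i],
      signed_walk_oracle(all_edges, paths$regulator[i], paths$phenotype[i],
                         paths$path_sign[i], 4),
      info = sprintf("%s -> %s (%d)", paths$regulator[i], paths$phenotype[i],
                     paths$path_sign[i])
    )
  }
})

test_that("the sampled null equals the exhaustive null when R covers all candidates", {
  set.seed(5)
  # 12-node random graph plus one phenotype
  edges <- tibble::tibble(
    source = sample(paste0("N", 1:12), 24, replace = TRUE),
    target = sample(paste0("N", 1:12), 24, replace = TRUE),
    sign = sample(c(1L, -1L), 24, replace = TRUE)
  )
  edges <- edges[edges$source != edges$target, ]
  edges <- edges[!duplicated(edges[, c("source", "target")]), ]
  nodes <- tibble::tibble(gene = paste0("N", 1:12), mol_function = "OTHER",
                          entity_type = "protein")
  p <- pkn(edges, nodes)
  pe <- tibble::tibble(protein = c("N3", "N7"), phenotype = "Growth", sign = 1L)
  exhaustive <- proxpath_proximity(p, proteins = "N1", phenotype_edges = pe,
                                   max_len = 4, n_random = 1000, seed = 1)
  sampled <- proxpath_proximity(p, proteins = "N1", phenotype_edges = pe,
                                max_len = 4, n_random = 999, seed = 99)
  # with R >= the candidate pool both calls enumerate the same null
  expect_equal(exhaustive$z, sampled$z, tolerance = 1e-12)
  # oracle: null over all candidate sources, censored at max_len + 1
  all_edges <- dplyr::bind_rows(p$edges[, c("source", "target", "sign")],
                                tibble::tibble(source = pe$protein,
                                               target = pe$phenotype,
                                               sign = pe$sign))
  cands <- setdiff(unique(c(edges$source, edges$target)), "Growth")
  for (i in seq_len(nrow(exhaustive))) {
    lens <- vapply(cands, function(s) {
      l <- signed_walk_oracle(all_edges, s, "Growth", exhaustive$path_sign[i], 4)
      if (is.finite(l)) l else 5
    }, 0)
    z_oracle <- (exhaustive$length[i] - mean(lens)) / sd(lens)
    expect_equal(exhaustive$z[i], z_oracle, tolerance = 1e-12)
  }
})

toy_model <- function(states, edges = NULL) {
  nodes <- tibble::tibble(gene = names(states), state = as.integer(states),
                          layer = "other")
  if (is.null(edges)) {
    edges <- tibble::tibble(source = character(), target = character(),
                            sign = integer())
  }
  structure(list(nodes = nodes, edges = edges,
                 states = setNames(as.integer(states), names(states)),
                 objective = 0, flavor = "vanilla", shots = 1L,
                 sign_ratio = NA_real_), class = "signaling_model")
}

toy_paths <- function(df) {
  col <- function(nm, default) if (nm %in% names(df)) df[[nm]] else default
  tibble::tibble(regulator = df$regulator, phenotype = col("phenotype", "P"),
                 path_sign = df$path_sign, length = 1L,
                 z = col("z", -3), significant = TRUE,
                 n_paths = col("n_paths", 1))
}

test_that("phenotype activity is the signed (weighted) mean of regulator activities", {
  m <- toy_model(c(R1 = 1L, R2 = 1L))
  # two activators, both active: unanimous +1
  pa <- phenotype_activity(m, toy_paths(tibble::tibble(
    regulator = c("R1", "R2"), path_sign = c(1L, 1L))), remove_cascades = FALSE)
  expect_equal(pa$activity, 1)
  # one activator and one inhibitor, both active: cancellation to 0
  pa0 <- phenotype_activity(m, toy_paths(tibble::tibble(
    regulator = c("R1", "R2"), path_sign = c(1L, -1L))), remove_cascades = FALSE)
  expect_equal(pa0$activity, 0)
  # weighted 3:1 activator vs inhibitor: (3 - 1) / 4 = +0.5
  paw <- phenotype_activity(m, toy_paths(tibble::tibble(
    regulator = c("R1", "R2"), path_sign = c(1L, -1L), n_paths = c(3, 1))),
    remove_cascades = FALSE, weight_by_paths = TRUE)
  expect_equal(paw$activity, 0.5)
  expect_equal(paw$n_regulators, 2L)
})

test_that("flipping every regulator state flips every phenotype activity exactly", {
  set.seed(8)
  states <- setNames(sample(c(1L, -1L), 6, replace = TRUE), paste0("R", 1:6))
  paths <- toy_paths(tibble::tibble(
    regulator = paste0("R", 1:6),
    path_sign = sample(c(1L, -1L), 6, replace = TRUE),
    n_paths = sample(1:4, 6, replace = TRUE)))
  for (w in c(FALSE, TRUE)) {
    a <- phenotype_activity(toy_model(states), paths, remove_cascades = FALSE,
                            weight_by_paths = w)
    b <- phenotype_activity(toy_model(-states), paths, remove_cascades = FALSE,
                            weight_by_paths = w)
    expect_equal(b$activity, -a$activity, tolerance = 1e-15)
    expect_true(all(abs(a$activity) <= 1))
  }
})

test_that("cascade removal keeps only independent regulators and never adds any", {
  edges <- tibble::tibble(source = "R1", target = "R2", sign = 1L)
  m <- toy_model(c(R1 = 1L, R2 = 1L), edges)
  paths <- toy_paths(tibble::tibble(regulator = c("R1", "R2"),
                                    path_sign = c(1L, 1L)))
  with_casc <- phenotype_activity(m, paths, remove_cascades = FALSE)
  no_casc <- phenotype_activity(m, paths, remove_cascades = TRUE)
  expect_equal(with_casc$n_regulators, 2L)
  expect_equal(no_casc$n_regulators, 1L)  # R2 is downstream of R1: dropped
  expect_equal(no_casc$regulators[[1]]$regulator, "R1")
  # with no model edges cascade removal is a no-op
  m_empty <- toy_model(c(R1 = 1L, R2 = 1L))
  same <- phenotype_activity(m_empty, paths, remove_cascades = TRUE)
  expect_equal(same$n_regulators, 2L)
})

test_that("step-1-only mode restricts regulators to inferred proteins", {
  m <- toy_model(c(R1 = 1L, R2 = -1L))
  paths <- toy_paths(tibble::tibble(regulator = c("R1", "R2"),
                                    path_sign = c(1L, 1L)))
  act <- tibble::tibble(gene_name = "R1", activity = 1L)
  pa <- phenotype_activity(m, paths, activities = act, remove_cascades = FALSE,
                           use_optimizer_states = FALSE)
  expect_equal(pa$n_regulators, 1L)
  expect_equal(pa$activity, 1)
  expect_error(phenotype_activity(m, paths, use_optimizer_states = FALSE),
               "activity table")
})

test_that("attaching phenotypes appends one node and one edge per regulator", {
  m <- toy_model(c(R1 = 1L, R2 = 1L),
                 tibble::tibble(source = "R1", target = "X", sign = 1L))
  paths <- toy_paths(tibble::tibble(regulator = c("R1", "R2"),
                                    path_sign = c(1L, -1L)))
  pa <- phenotype_activity(m, paths, remove_cascades = FALSE)
  n_nodes <- nrow(m$nodes); n_edges <- nrow(m$edges)
  out <- attach_phenotypes(m, pa, paths)
  expect_equal(nrow(out$nodes), n_nodes + 1)
  expect_equal(nrow(out$edges), n_edges + 2)
  ph_edges <- out$edges[out$edges$target == "P", ]
  expect_setequal(ph_edges$source, c("R1", "R2"))
  expect_equal(sort(ph_edges$sign), c(-1L, 1L))
  # empty phenotype table leaves the model unchanged
  unchanged <- attach_phenotypes(m, pa[0, ], paths)
  expect_equal(nrow(unchanged$nodes), n_nodes)
})
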