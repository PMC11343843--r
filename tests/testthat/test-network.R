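chain_pkn <- function(extra = NULL) {
  edges <- tibble::tibble(
    source = c("S", "K", "O"),
    target = c("K", "O", "T"),
    sign = 1L, direct = TRUE,
    mechanism = c("phosphorylation", "phosphorylation", "binding"),
    residue = c("S100", "S200", NA), source_db = "toy"
  )
  if (!is.null(extra)) edges <- dplyr::bind_rows(edges, extra)
  nodes <- tibble::tibble(gene = c("S", "K", "O", "T"),
                          mol_function = c("OTHER", "KIN", "OTHER", "TF"),
                          entity_type = "protein")
  extra_genes <- setdiff(unique(c(edges$source, edges$target)), nodes$gene)
  if (length(extra_genes)) {
    nodes <- dplyr::bind_rows(nodes, tibble::tibble(
      gene = extra_genes, mol_function = "OTHER", entity_type = "protein"))
  }
  pkn(edges, nodes)
}

chain_activities <- function(scores = c(K = 1, O = 1, T = 1)) {
  tibble::tibble(
    gene_name = names(scores),
    mf = c(K = "KIN", O = "OTHER", T = "TF")[names(scores)],
    final_score = unname(scores),
    activity = as.integer(sign(scores)),
    p_value = 0.01, method = "footprint"
  )
}

test_that("layer boundaries respect the maximum shortest-path length", {
  p <- chain_pkn()
  act <- chain_activities()
  # direct edge source -> kinase admitted at max_len 1
  n1 <- build_naive_network(p, c(S = 1L), act, layout = "three", max_len = 1,
                            connect_all = FALSE)
  expect_true(all(c("S", "K", "O", "T") %in% n1$nodes))
  expect_equal(nrow(n1$edges), 3)
  # a 2-hop pair is excluded at max_len 1 but included at max_len 2
  p2 <- chain_pkn(tibble::tibble(source = "S", target = "M", sign = 1L,
                                 direct = TRUE, mechanism = "binding",
                                 residue = NA, source_db = "toy")) # S->M only
  p2b <- pkn(dplyr::bind_rows(p2$edges,
                              tibble::tibble(source = "M", target = "K2", sign = 1L,
                                             direct = TRUE, mechanism = "binding",
                                             residue = NA, source_db = "toy")),
             dplyr::bind_rows(p2$nodes,
                              tibble::tibble(gene = "K2", mol_function = "KIN",
                                             entity_type = "protein")))
  act2 <- dplyr::bind_rows(chain_activities(),
                           tibble::tibble(gene_name = "K2", mf = "KIN",
                                          final_score = 1, activity = 1L,
                                          p_value = 0.01, method = "footprint"))
  short <- build_naive_network(p2b, c(S = 1L), act2, layout = "three",
                               max_len = c(1, 1, 1), connect_all = FALSE)
  expect_false("K2" %in% c(short$edges$source, short$edges$target))
  long <- build_naive_network(p2b, c(S = 1L), act2, layout = "three",
                              max_len = c(2, 1, 1), connect_all = FALSE)
  expect_true("K2" %in% long$edges$target)
})

test_that("connect_all adds PKN edges among nodes found on distinct paths", {
  # two parallel branches S->K1 and S->K2 plus a cross edge K1->K2 in the PKN
  edges <- tibble::tibble(
    source = c("S", "S", "K1"),
    target = c("K1", "K2", "K2"),
    sign = 1L, direct = TRUE, mechanism = "phosphorylation",
    residue = paste0("S", 1:3), source_db = "toy"
  )
  nodes <- tibble::tibble(gene = c("S", "K1", "K2"),
                          mol_function = c("OTHER", "KIN", "KIN"),
                          entity_type = "protein")
  p <- pkn(edges, nodes)
  act <- tibble::tibble(gene_name = c("K1", "K2"), mf = "KIN",
                        final_score = 1, activity = 1L, p_value = 0.01,
                        method = "footprint")
  no_extra <- build_naive_network(p, c(S = 1L), act, layout = "one",
                                  max_len = 1, connect_all = FALSE)
  with_extra <- build_naive_network(p, c(S = 1L), act, layout = "one",
                                    max_len = 1, connect_all = TRUE)
  expect_equal(nrow(with_extra$edges), nrow(no_extra$edges) + 1)
  expect_true(any(with_extra$edges$source == "K1" & with_extra$edges$target == "K2"))
})

test_that("single-shot optimization reduces to the plain optimizer", {
  p <- chain_pkn()
  act <- chain_activities()
  naive <- build_naive_network(p, c(S = 1L), act, layout = "three", max_len = 1)
  one <- run_multishot(naive, shots = 1)
  direct <- ilp_optimize(naive)
  expect_equal(sort(one$nodes$gene), sort(direct$nodes$gene))
  expect_equal(one$objective, direct$objective)
  # the chain is fully coherent: all four nodes recovered
  expect_setequal(one$nodes$gene, c("S", "K", "O", "T"))
})

test_that("three-shot optimization can retain nodes the single shot prunes", {
  # K has a weak activity score; O contradicts the only coherent path.
  # In one shot the solver prefers dropping K (mismatch 0.1 < beta 0.3);
  # per-shot weight renormalization makes K worth keeping in shot 1.
  p <- chain_pkn()
  act <- chain_activities(c(K = 0.1, O = -1, T = 1))
  naive <- build_naive_network(p, c(S = 1L), act, layout = "three", max_len = 1)
  one <- run_multishot(naive, shots = 1, beta = 0.3)
  suppressWarnings(three <- run_multishot(naive, shots = 3, beta = 0.3))
  expect_equal(nrow(one$nodes), 1)   # only the source survives
  expect_gte(nrow(three$nodes), nrow(one$nodes))
  expect_setequal(three$nodes$gene, c("S", "K"))
  # merged multishot states still satisfy coherence and support
  st <- three$states
  if (nrow(three$edges)) {
    expect_equal(unname(st[three$edges$target]),
                 unname(three$edges$sign * st[three$edges$source]))
  }
})

test_that("disjoint shot solutions merge without conflicts", {
  p <- chain_pkn()
  act <- chain_activities()
  naive <- build_naive_network(p, c(S = 1L), act, layout = "three", max_len = 1)
  expect_no_message(three <- run_multishot(naive, shots = 3), message = "conflict")
  expect_setequal(three$nodes$gene, c("S", "K", "O", "T"))
  expect_equal(unname(three$states[c("S", "K", "O", "T")]), rep(1L, 4))
})

test_that("inverse optimization finds a perturbation sign explaining the data", {
  p <- chain_pkn()
  # all measurements negative: the artificial perturbation should go negative
  act <- chain_activities(c(K = -1, O = -1, T = -1))
  naive <- build_naive_network(p, c(S = 1L), act, layout = "three", max_len = 1)
  inv <- ilp_optimize(naive, flavor = "inverse", beta = 0.1, receptors = "S")
  # the free-sign perturbation edges let the model explain all-negative data
  expect_equal(unname(inv$states[c("K", "O", "T")]), rep(-1L, 3))
  expect_true(abs(inv$states[".perturbation"]) == 1L)
  expect_equal(inv$objective - 0.1 * nrow(inv$edges), 0, tolerance = 1e-12)
})

test_that("phospho validation flags edges and computes the SignRatio", {
  edges <- tibble::tibble(
    source = paste0("U", 1:10), target = paste0("V", 1:10), sign = 1L,
    direct = TRUE,
    mechanism = c(rep("phosphorylation", 6), rep("binding", 4)),
    residue = c(paste0("S", 1:6), rep(NA, 4)), source_db = "toy"
  )
  naive <- structure(list(edges = edges, layers = NULL), class = "naive_network")
  states <- setNames(rep(1L, 20), c(paste0("U", 1:10), paste0("V", 1:10)))
  model <- signalflow:::new_signaling_model(states, edges[, c("source", "target", "sign")],
                                            naive, 0, "vanilla")
  # 3 matching sites of which 2 significant over 10 edges: SignRatio 0.2
  ph <- tibble::tibble(gene_name = c("V1", "V2", "V3"),
                       residue = c("S1", "S2", "S3"),
                       difference = 1,
                       significant = c(TRUE, TRUE, FALSE))
  out <- validate_edges_with_phospho(model, ph)
  expect_equal(sum(out$edges$quantified), 3)
  expect_equal(sum(out$edges$validated), 2)
  expect_equal(out$sign_ratio, 0.2)
  # non-PTM edges are never flagged
  expect_false(any(out$edges$quantified[out$edges$mechanism == "binding"]))
})

test_that("model exports round-trip through GraphML", {
  p <- chain_pkn()
  act <- chain_activities()
  naive <- build_naive_network(p, c(S = 1L), act, layout = "three", max_len = 1)
  model <- ilp_optimize(naive)
  dir <- withr::local_tempdir()
  write_model(model, dir)
  g <- igraph::read_graph(file.path(dir, "model.graphml"), format = "graphml")
  expect_equal(sort(igraph::V(g)$name), sort(model$nodes$gene))
  states <- setNames(igraph::V(g)$state, igraph::V(g)$name)
  expect_equal(states[model$nodes$gene], setNames(model$nodes$state, model$nodes$gene))
  sif <- readLines(file.path(dir, "model.sif"))
  expect_length(sif, nrow(model$edges))
})
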