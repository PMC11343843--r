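test_that("phospho normalization subtracts the parent protein and z-scores the result", {
  # corrected fold-changes land on [1, -1, 2, 0, 3]
  phospho <- tibble::tibble(
    gene_name = c("A", "B", "C", "D", "E"),
    residue = paste0("S", 1:5),
    difference = c(3, 0, 2.5, 1, 3)
  )
  prot <- tibble::tibble(gene_name = c("A", "B", "C", "D"),
                         difference = c(2, 1, 0.5, 1))
  out <- normalize_phospho(phospho, prot)
  corrected <- c(1, -1, 2, 0, 3)
  expect_equal(out$difference, corrected, tolerance = 1e-15)
  z_expected <- (corrected - mean(corrected)) / sd(corrected)
  expect_equal(out$z, z_expected, tolerance = 1e-12)
  expect_equal(out$z[1], 0)
  expect_false(any(out$significant))  # max |z| is ~1.26 < 1.96
  expect_false(out$parent_quantified[5])  # E has no quantified parent
})

test_that("phospho normalization significance is strictly greater than the threshold", {
  phospho <- tibble::tibble(gene_name = c("A", "B", "C"), residue = "S1",
                            difference = c(-1, 0, 1))
  prot <- tibble::tibble(gene_name = "Z", difference = 0)
  out <- normalize_phospho(phospho, prot, z_threshold = 1)
  expect_equal(abs(out$z), c(1, 0, 1))
  expect_false(any(out$significant))  # |z| == threshold exactly: not significant
  out2 <- normalize_phospho(phospho, prot, z_threshold = 1 - 1e-9)
  expect_equal(sum(out2$significant), 2)
  # equal modulation in phospho and proteomics cancels out
  ph <- tibble::tibble(gene_name = c("A", "B"), residue = "S1", difference = c(2, 1))
  pr <- tibble::tibble(gene_name = c("A", "B"), difference = c(2, 0))
  expect_equal(normalize_phospho(ph, pr)$difference[1], 0)
  # degenerate zero-variance corrected distribution errors with guidance
  same <- tibble::tibble(gene_name = c("A", "B"), residue = "S1", difference = c(1, 1))
  expect_error(normalize_phospho(same, tibble::tibble(gene_name = "Z", difference = 0)),
               "zero\\s+variance")
})

make_signature <- function(n = 10, seed = 1) {
  set.seed(seed)
  tibble::tibble(id = paste0("T", seq_len(n)), statistic = rnorm(n),
                 significant = FALSE)
}

test_that("footprint enrichment follows mode, is antisymmetric and matches the oracle", {
  sig <- make_signature(10)
  top <- sig$id[which.max(sig$statistic)]
  reg_up <- tibble::tibble(regulator = "R", target = top, mode = 1, weight = 1)
  up <- footprint_enrichment(sig, reg_up, min_targets = 1)
  expect_gt(up$nes, 0)
  reg_dn <- reg_up; reg_dn$mode <- -1
  dn <- footprint_enrichment(sig, reg_dn, min_targets = 1)
  expect_equal(dn$nes, -up$nes, tolerance = 1e-15)

  reg3 <- tibble::tibble(regulator = "R3", target = c("T1", "T4", "T7"),
                         mode = c(1, -1, 1), weight = c(1, 0.6, 0.8))
  got <- footprint_enrichment(sig, reg3, min_targets = 3)
  expect_equal(got$nes, nes_oracle(sig, reg3), tolerance = 1e-12)

  # below min_targets the regulon is skipped with a log message
  expect_message(
    none <- footprint_enrichment(sig, reg3, min_targets = 4),
    "skipped"
  )
  expect_equal(nrow(none), 0)
})

test_that("negating every signature statistic negates every enrichment score exactly", {
  set.seed(11)
  sig <- make_signature(40, seed = 11)
  regs <- tibble::tibble(
    regulator = rep(paste0("R", 1:6), each = 5),
    target = sample(sig$id, 30, replace = TRUE),
    mode = sample(c(1, -1), 30, replace = TRUE),
    weight = runif(30, 0.5, 1)
  )
  regs <- regs[!duplicated(regs[, c("regulator", "target")]), ]
  a <- footprint_enrichment(sig, regs, min_targets = 2)
  sig_neg <- sig; sig_neg$statistic <- -sig_neg$statistic
  b <- footprint_enrichment(sig_neg, regs, min_targets = 2)
  expect_equal(b$nes, -a$nes, tolerance = 1e-12)
})

test_that("hypergeometric weighting matches the exact combinatorial sum", {
  sig <- tibble::tibble(id = paste0("T", 1:10), statistic = 1:10 / 10,
                        significant = c(rep(TRUE, 4), rep(FALSE, 6)))
  reg <- tibble::tibble(regulator = "R", target = c("T1", "T2", "T3"),
                        mode = 1, weight = 1)
  et <- footprint_enrichment(sig, reg, min_targets = 1)
  out <- hypergeometric_weighting(et, sig, reg)
  # N=10, K=4, n=3, k=3: p = C(4,3)C(6,0)/C(10,3) = 1/30
  expect_equal(out$p_hyper, 1 / 30, tolerance = 1e-12)
  expect_equal(out$weighted_score, et$nes * (1 - 1 / 30), tolerance = 1e-12)
  # no significant analytes anywhere: p = 1, weighted score 0
  sig0 <- sig; sig0$significant <- FALSE
  out0 <- hypergeometric_weighting(et, sig0, reg)
  expect_equal(out0$p_hyper, 1)
  expect_equal(out0$weighted_score, 0)
  # saturated table: every analyte significant, p = 1 by construction
  sig1 <- sig; sig1$significant <- TRUE
  expect_message(out1 <- hypergeometric_weighting(et, sig1, reg), "saturated")
  expect_equal(out1$weighted_score, 0)
})

test_that("proteomics correction rescues and flags discordance", {
  et <- tibble::tibble(regulator = c("A", "B", "C"),
                       nes = c(3, 0.5, -2.5),
                       p_value = c(0.001, 0.4, 0.01),
                       n_targets = 5)
  prot <- tibble::tibble(gene_name = c("B", "C"),
                         difference = c(1.3, 1.1),
                         significant = c(TRUE, TRUE))
  out <- proteomics_correction(et, prot)
  # B: non-significant enrichment but significant proteomics: rescued as +1
  b <- out[out$gene_name == "B", ]
  expect_equal(b$method, "proteomics_rescue")
  expect_equal(b$activity, 1L)
  # C: significant in both with discordant signs: enrichment wins, flagged
  c_ <- out[out$gene_name == "C", ]
  expect_equal(c_$method, "footprint")
  expect_equal(c_$activity, -1L)
  expect_true(c_$discordant_proteomics)
  # A: significant enrichment, no proteomics record: unchanged
  a <- out[out$gene_name == "A", ]
  expect_equal(a$activity, 1L)
  expect_false(a$discordant_proteomics)
  # without proteomics only enrichment-significant records remain
  out2 <- proteomics_correction(et, NULL)
  expect_setequal(out2$gene_name, c("A", "C"))
})

test_that("PhosphoScore averages signed site statistics over significant sites", {
  db <- tibble::tibble(
    gene_name = c("P1", "P2", "P2", "P3"),
    residue = c("S10", "S20", "T30", "S40"),
    sign = c(1L, 1L, -1L, 1L),
    role = c("activity", "activity", "both", "abundance")
  )
  ph <- tibble::tibble(
    gene_name = c("P1", "P2", "P2", "P3"),
    residue = c("S10", "S20", "T30", "S40"),
    difference = c(2, 2, 1, 1.5),
    significant = TRUE
  )
  out <- phospho_score(ph, db, activity_only = TRUE)
  expect_equal(out$final_score[out$gene_name == "P1"], 2)       # single activating site
  expect_equal(out$activity[out$gene_name == "P1"], 1L)
  expect_equal(out$final_score[out$gene_name == "P2"], 0.5)     # (2*1 + 1*(-1)) / 2
  expect_equal(out$activity[out$gene_name == "P2"], 1L)
  expect_false("P3" %in% out$gene_name)                          # abundance-only excluded
  with_ab <- phospho_score(ph, db, activity_only = FALSE)
  expect_true("P3" %in% with_ab$gene_name)
  # non-significant sites are ignored by default
  ph2 <- ph; ph2$significant <- c(FALSE, TRUE, TRUE, TRUE)
  out2 <- phospho_score(ph2, db)
  expect_false("P1" %in% out2$gene_name)
})

test_that("combining activities unions methods and annotates molecular function", {
  fp <- tibble::tibble(gene_name = c("A", "B"), final_score = c(2, -1),
                       activity = c(1L, -1L), p_value = c(0.01, 0.02),
                       method = "footprint", discordant_proteomics = FALSE)
  ps <- tibble::tibble(gene_name = c("B", "C"), final_score = c(-0.5, 1),
                       activity = c(-1L, 1L), n_sites = 1L, method = "phosphoscore")
  ann <- tibble::tibble(gene_name = c("A", "B"), mol_function = c("TF", "KIN"))
  expect_message(out <- combine_activities(fp, ps, ann), "missing from annotation")
  expect_equal(nrow(out), 3)  # |footprint| + |phosphoscore-only|
  expect_equal(out$method[out$gene_name == "C"], "phosphoscore")
  expect_equal(out$method[out$gene_name == "B"], "footprint")
  expect_true(out$phospho_concordant[out$gene_name == "B"])
  expect_equal(out$mf[out$gene_name == "A"], "TF")
  expect_equal(out$mf[out$gene_name == "C"], "OTHER")
})
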