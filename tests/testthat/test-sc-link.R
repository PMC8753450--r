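test_that("bulk clones link to cells by CDR3 with coverage flags", {
  trb <- c(rep("AAACCCGGGTTT", 7), rep("CCCAAAGGGTTT", 3), synthetic_cdr3(5))
  sc <- make_sc(n_cells = 15, trb = trb, fill = 5L)
  keys <- clone_key(c("AAACCCGGGTTT", "CCCAAAGGGTTT", "TTTTTTAAAAAA"),
                    "TRBV5-1", "TRBJ2-1")
  link <- link_bulk_clones(sc, keys, min_cells = 5L)
  expect_equal(link$n_cells, c(7L, 3L, 0L))
  expect_equal(link$under_covered, c(FALSE, TRUE, TRUE))
  expect_equal(sort(link$barcodes[[1]]), sprintf("bc%04d", 1:7))
  expect_length(link$barcodes[[3]], 0L)           # absent clone: empty, no error
})

test_that("linkage falls back to (CDR3aa, V gene) when nucleotide calls are absent", {
  sc <- make_sc(n_cells = 6, fill = 5L)
  sc$cells$trb_cdr3_aa <- c(rep("CASSLAPGF", 4), "CASSLAPGF", "CASSOTHER")
  sc$cells$trb_v_gene <- c(rep("TRBV5-1*01", 4), "TRBV9", "TRBV5-1")
  bulk <- repertoire(data.frame(
    cdr3_nt = "AAACCCGGGTTT", cdr3_aa = "CASSLAPGF", v_call = "TRBV5-1*01",
    j_call = "TRBJ2-1", templates = 12L, productive = TRUE))
  key <- bulk$clones$key
  expect_message(link <- link_bulk_clones(sc, key, bulk = bulk), "CDR3aa")
  expect_equal(link$n_cells, 4L)   # V-gene mismatch and other CDR3 excluded
  expect_error(suppressMessages(link_bulk_clones(sc, key)),
               class = "clonodyn_config_error")
})

test_that("top-abundant comparator respects rank, ties, lineage and exclusions", {
  # 12 bulk clones with descending counts; a tie at the k-th rank
  counts <- c(120L, 110L, 100L, 90L, 80L, 70L, 60L, 50L, 40L, 30L, 30L, 20L)
  bulk <- make_rep(counts)
  ord <- order(-bulk$clones$templates, bulk$clones$cdr3_nt)
  # cells: 6 per clone, all gated CD8_EM
  cl <- bulk$clones
  trb <- rep(cl$cdr3_nt, each = 6L)
  sc <- make_sc(n_cells = length(trb), trb = trb, fill = 5L)
  sc$cells$subset <- "CD8_EM"

  comp <- top_abundant_comparator(sc, bulk, k = 10, lineage = "CD8")
  expect_length(comp$keys, 10L)
  expect_equal(comp$keys, cl$key[ord][1:10])
  # the tie at 30 resolves to the lexicographically smaller CDR3
  tied <- cl[cl$templates == 30L, ]
  kept <- intersect(comp$keys, tied$key)
  expect_equal(kept, tied$key[order(tied$cdr3_nt)[1]])

  # excluding a top clone pulls in the next rank
  comp2 <- top_abundant_comparator(sc, bulk, k = 10, lineage = "CD8",
                                   exclude_keys = cl$key[ord][1])
  expect_false(cl$key[ord][1] %in% comp2$keys)
  expect_true(all(cl$key[ord][2:11] %in% comp2$keys))

  # majority-CD4 cells are ineligible for a CD8 comparator
  sc$cells$subset <- "CD4_EM"
  expect_warning(comp3 <- top_abundant_comparator(sc, bulk, k = 10,
                                                  lineage = "CD8"),
                 "eligible")
  expect_length(comp3$keys, 0L)
})

test_that("differential signatures recover shifted genes and control the null", {
  set.seed(71)
  n_genes <- 400; n_per <- 120
  lambda <- rlnorm(n_genes, 0, 1)
  shifted <- sample(n_genes, 20)
  bc <- sprintf("bc%04d", seq_len(2 * n_per))
  lam <- matrix(lambda, n_genes, 2 * n_per)
  lam[shifted, seq_len(n_per)] <- lam[shifted, seq_len(n_per)] * 4
  genes <- Matrix::Matrix(matrix(rpois(length(lam), lam), n_genes,
                                 dimnames = list(sprintf("g%03d", 1:n_genes), bc)),
                          sparse = TRUE)
  sc <- make_sc(n_cells = 2 * n_per, genes = genes, fill = 5L)
  de <- differential_signature(sc, bc[seq_len(n_per)], bc[n_per + seq_len(n_per)],
                               features = "genes")
  hits <- de$feature[de$tier == "**" & de$log_fc > 0]
  expect_gte(sum(sprintf("g%03d", shifted) %in% hits), 18L)

  # tiers are a deterministic function of the Bonferroni-adjusted p
  expect_true(all((de$tier == "**") == (de$adj_p < 0.01)))
  expect_true(all((de$tier == "*") == (de$adj_p >= 0.01 & de$adj_p < 0.05)))
  expect_true(all(de$adj_p >= de$p_value - 1e-15))

  # two iid samples from one population: nothing should clear "**"
  lam0 <- matrix(lambda, n_genes, 2 * n_per)
  genes0 <- Matrix::Matrix(matrix(rpois(length(lam0), lam0), n_genes,
                                  dimnames = list(rownames(genes), bc)),
                           sparse = TRUE)
  sc0 <- make_sc(n_cells = 2 * n_per, genes = genes0, fill = 5L)
  de0 <- differential_signature(sc0, bc[seq_len(n_per)],
                                bc[n_per + seq_len(n_per)], features = "genes")
  expect_lte(sum(de0$tier == "**"), 1L)

  expect_error(differential_signature(sc, bc[1:3], bc[4:20]),
               class = "clonodyn_size_error")
  expect_error(differential_signature(sc, bc[1:10], bc[5:20]), "disjoint")
})

test_that("rank-sum p-values agree with wilcox.test per feature", {
  set.seed(5)
  sc <- make_sc(n_cells = 60, fill = 5L)
  # put structured counts in the ADT panel and test the protein modality
  sc$adt[, "PD-1"] <- c(rpois(30, 40), rpois(30, 8))
  sc$adt[, "TIM-3"] <- rpois(60, 15)
  bc <- sc$cells$barcode
  de <- differential_signature(sc, bc[1:30], bc[31:60], features = "proteins")
  clr <- t(apply(log1p(sc$adt), 1, function(r) r - mean(r)))
  for (m in c("PD-1", "TIM-3", "CD27")) {
    ref <- wilcox.test(clr[1:30, m], clr[31:60, m], exact = FALSE,
                       correct = TRUE)$p.value
    expect_equal(de$p_value[de$feature == m], ref, tolerance = 1e-9)
  }
  # Bonferroni multiplier is the full panel size
  expect_equal(de$adj_p, pmin(1, de$p_value * ncol(sc$adt)))
})

test_that("module scores are centered, order-invariant, and discriminative", {
  bulk <- make_rep(c(300L, 200L, 100L, 50L))
  act_key <- bulk$clones$key[1]
  sim <- simulate_single_cell(n_cells = 2000, bulk = bulk, n_genes = 600,
                              module_genes = sprintf("gene%04d", 1:20),
                              activated_clone_keys = act_key,
                              module_fold = 4, trb_recovery = 1, seed = 31)
  sc <- sim$cells

  # centering contract: when module genes genuinely match their control
  # genes' expression (homogeneous world), scores average ~0. (In a
  # heavy-tailed expression world a fixed module keeps a small quantization
  # offset from its expression bins — a known property of bin-matched
  # background subtraction, noted in the vignette.)
  set.seed(91)
  n_h <- 300; bc_h <- sprintf("bc%04d", 1:2000)
  hom <- Matrix::Matrix(matrix(rpois(n_h * 2000, 2), n_h,
                               dimnames = list(sprintf("h%03d", 1:n_h), bc_h)),
                        sparse = TRUE)
  sc_h <- make_sc(n_cells = 2000, genes = hom, fill = 5L)
  s0 <- module_score(sc_h, sprintf("h%03d", 101:120), seed = 9)
  expect_lt(abs(mean(s0)), 0.02)

  # activated cells separate from the rest: AUROC of the score >= 0.95
  s1 <- module_score(sc, sprintf("gene%04d", 1:20), seed = 9)
  act <- sim$truth$activated
  r <- rank(s1)
  n1 <- sum(act); n0 <- sum(!act)
  auroc <- (sum(r[act]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  expect_gte(auroc, 0.95)

  # invariant to cell and gene ordering
  set.seed(77)
  perm <- sample(ncol(sc$genes))
  sc_perm <- sc
  sc_perm$genes <- sc$genes[sample(nrow(sc$genes)), perm]
  sc_perm$adt <- sc$adt[perm, ]
  sc_perm$cells <- sc$cells[perm, ]
  s2 <- module_score(sc_perm, sprintf("gene%04d", 1:20), seed = 9)
  expect_equal(s2[names(s1)], s1, tolerance = 1e-12)

  expect_warning(module_score(sc, c("gene0001", "NOT_A_GENE"), seed = 1),
                 "absent")
  expect_error(suppressWarnings(module_score(sc, "NOT_A_GENE", seed = 1)),
               class = "clonodyn_config_error")
})

test_that("clone phenotype composition measures stability as TV distance", {
  mk <- function(subsets, trb) {
    sc <- make_sc(n_cells = length(subsets), trb = trb, fill = 5L)
    sc$cells$subset <- subsets
    sc
  }
  nt <- "AAACCCGGGTTT"
  key <- clone_key(nt, "TRBV5-1", "TRBJ2-1")
  stable <- list(Day0 = mk(rep("CD8_EM", 10), rep(nt, 10)),
                 EOC2 = mk(rep("CD8_EM", 8), rep(nt, 8)))
  res <- clone_phenotype_composition(stable, key)
  expect_equal(res$stability$stability, 0)
  expect_true(res$stability$evaluable)

  flipped <- list(Day0 = mk(rep("CD8_EM", 10), rep(nt, 10)),
                  EOC2 = mk(rep("CD8_TE", 10), rep(nt, 10)))
  res2 <- clone_phenotype_composition(flipped, key)
  expect_equal(res2$stability$stability, 1)

  sparse <- list(Day0 = mk(rep("CD8_EM", 10), rep(nt, 10)),
                 EOC2 = mk(rep("CD8_EM", 3), rep(nt, 3)))
  res3 <- clone_phenotype_composition(sparse, key)
  expect_false(res3$stability$evaluable)
  expect_true(is.na(res3$stability$stability))
})

test_that("multinomially resampled stable clones rarely look unstable", {
  # 30 cells/timepoint drawn from a fixed composition: TV from baseline stays
  # below 0.2 for >= 95% of clones (multinomial sampling oracle)
  # stable clones are phenotypically coherent: one dominant subset
  set.seed(23)
  probs <- c(CD8_EM = 0.85, CD8_TE = 0.10, CD8_CM = 0.05)
  stab <- replicate(100, {
    draw <- function() rep(names(probs), rmultinom(1, 30, probs))
    nt <- "AAACCCGGGTTT"
    s1 <- draw(); s2 <- draw()
    sc1 <- make_sc(n_cells = 30, trb = rep(nt, 30), fill = 5L)
    sc1$cells$subset <- s1
    sc2 <- make_sc(n_cells = 30, trb = rep(nt, 30), fill = 5L)
    sc2$cells$subset <- s2
    key <- clone_key(nt, "TRBV5-1", "TRBJ2-1")
    clone_phenotype_composition(list(Day0 = sc1, EOC2 = sc2), key)$stability$stability
  })
  expect_gte(mean(stab < 0.2), 0.95)
})
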