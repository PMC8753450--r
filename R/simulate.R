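# Ground-truth generators: longitudinal bulk repertoires with controlled
# overdispersion and spiked expansions, and matched single-cell tables with
# subset-structured ADT counts and gene-module activation.
#
# Defaults echo the survey-depth world of the source data: 5,000 clones with
# power-law clone sizes (tail exponent alpha = 2), 2e4 templates per sample
# (the trial sampled 13,634-31,247 T cells per timepoint), and modest
# between-sample overdispersion phi = 1e-4 (~3x binomial count variance at
# this depth).

random_cdr3 <- function(n, min_codons = 12L, max_codons = 16L) {
  vapply(seq_len(n), function(i) {
    len <- 3L * sample(min_codons:max_codons, 1L)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

translate_dna <- function(nt) {
  codons <- substring(nt, seq(1, nchar(nt) - 2, 3), seq(3, nchar(nt), 3))
  code <- Biostrings_free_translate(codons)
  paste(code, collapse = "")
}

# minimal standard-code translation (avoids a Biostrings dependency for
# synthetic sequences only)
Biostrings_free_translate <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  tab <- setNames(aa, codons)
  function(cod) unname(tab[cod])
})

draw_base_frequencies <- function(n_clones, law, alpha, lnorm_meanlog, lnorm_sdlog) {
  w <- switch(law,
    powerlaw = runif(n_clones)^(-1 / (alpha - 1)),   # Pareto tail P(w>x) ~ x^-(alpha-1)
    lognormal = rlnorm(n_clones, lnorm_meanlog, lnorm_sdlog),
    stop_clonodyn("unknown clone frequency law '%s'", law,
                  class = "clonodyn_config_error"))
  w / sum(w)
}

#' Simulate a longitudinal bulk repertoire series with known truth
#'
#' Base clone frequencies are drawn once per subject from a power-law
#' (clone-size tail exponent `alpha`) or lognormal law. Per sample, each
#' clone's frequency is perturbed by a Beta draw with mean equal to its base
#' frequency and dispersion `phi`, the vector renormalized, and template
#' counts drawn multinomially at depth `n_templates` — giving (approximately)
#' beta-binomial count marginals at dispersion `phi` while keeping each
#' sample compositionally valid. Spikes multiply their target clone's
#' frequency by `fold` at the listed timepoint(s) before renormalization;
#' spikes are transient (a clone returns to baseline at timepoints where it
#' is not listed). Novel spikes (`clone = NA`) enter as brand-new clones,
#' absent at every other timepoint, at frequency `fold * novel_ref_frequency`.
#'
#' @param n_clones number of background clones, default 5000.
#' @param law `"powerlaw"` (default) or `"lognormal"`.
#' @param alpha power-law clone-size tail exponent, default 2.
#' @param lnorm_meanlog,lnorm_sdlog lognormal parameters (law = "lognormal").
#' @param n_templates template depth per sample, default 2e4.
#' @param phi between-sample beta-binomial overdispersion in `[0, 1)`,
#'   default 1e-4.
#' @param timepoints ordered timepoint labels to generate, baseline first.
#' @param spikes data.frame with columns `clone` (base-clone index, or `NA`
#'   for a novel clone), `fold` (> 0), `timepoint`; NULL for none.
#' @param novel_ref_frequency reference frequency a fold-1 novel spike would
#'   enter at, default 1e-4 (one template in 1e4 — near the detection floor).
#' @param subject_id,compartment sample metadata.
#' @param seed RNG seed; the generator is a pure function of (config, seed).
#' @return list with `repertoires` (named list of [repertoire()] by
#'   timepoint) and `truth`: spiked keys with folds/timepoints and baseline
#'   frequencies, per-sample realized (pre-sampling) frequencies, `phi`,
#'   `seed`.
#' @export
simulate_repertoire_series <- function(n_clones = 5000L, law = "powerlaw",
                                       alpha = 2, lnorm_meanlog = -9,
                                       lnorm_sdlog = 1.5,
                                       n_templates = 2e4, phi = 1e-4,
                                       timepoints = c("Day0", "EOC2", "EOC4"),
                                       spikes = NULL,
                                       novel_ref_frequency = 1e-4,
                                       subject_id = "SYN1", compartment = "PB",
                                       seed = 1L) {
  assert_that(phi >= 0 && phi < 1, "phi must be in [0, 1)")
  if (!is.null(spikes)) {
    stopifnot(all(c("clone", "fold", "timepoint") %in% names(spikes)))
    bad <- spikes$clone[!is.na(spikes$clone) &
                          (spikes$clone < 1 | spikes$clone > n_clones)]
    assert_that(length(bad) == 0L, "spike on nonexistent clone index %s",
                paste(bad, collapse = ", "), class = "clonodyn_config_error")
    assert_that(all(spikes$timepoint %in% timepoints),
                "spike timepoint outside generated timepoints",
                class = "clonodyn_config_error")
    assert_that(all(spikes$fold > 0), "spike folds must be positive",
                class = "clonodyn_config_error")
  }
  with_seed(seed, {
    base <- draw_base_frequencies(n_clones, law, alpha, lnorm_meanlog, lnorm_sdlog)
    novel_idx <- which(is.na(spikes$clone))
    n_novel <- length(novel_idx)
    n_all <- n_clones + n_novel
    cdr3 <- random_cdr3(n_all)
    v <- sprintf("TRBV%02d-1", sample(2:30, n_all, replace = TRUE))
    j <- sprintf("TRBJ%d-%d", sample(1:2, n_all, replace = TRUE),
                 sample(1:6, n_all, replace = TRUE))
    keys <- clone_key(cdr3, v, j)
    aa <- vapply(cdr3, translate_dna, character(1))
    base_all <- c(base, rep(0, n_novel))
    spike_row_clone <- spikes$clone
    if (n_novel) spike_row_clone[novel_idx] <- n_clones + seq_len(n_novel)

    realized <- list(); reps <- list()
    for (tp in timepoints) {
      f <- base_all
      if (!is.null(spikes)) {
        at_tp <- which(spikes$timepoint == tp)
        for (r in at_tp) {
          i <- spike_row_clone[r]
          f[i] <- if (base_all[i] > 0) f[i] * spikes$fold[r]
                  else spikes$fold[r] * novel_ref_frequency
        }
      }
      f <- f / sum(f)
      if (phi > 0) {
        nz <- f > 0
        a <- f[nz] * (1 - phi) / phi
        b <- (1 - f[nz]) * (1 - phi) / phi
        f[nz] <- rbeta(sum(nz), a, b)
        f <- f / sum(f)
      }
      counts <- as.integer(rmultinom(1L, size = n_templates, prob = f))
      realized[[tp]] <- f
      obs <- counts > 0L
      reps[[tp]] <- repertoire(
        data.frame(cdr3_nt = cdr3[obs], cdr3_aa = aa[obs], v_call = v[obs],
                   j_call = j[obs], templates = counts[obs],
                   productive = TRUE, stringsAsFactors = FALSE),
        subject_id = subject_id, timepoint = tp, compartment = compartment)
    }
    truth_spikes <- if (is.null(spikes)) {
      data.frame(key = character(0), clone = integer(0), fold = numeric(0),
                 timepoint = character(0), baseline_frequency = numeric(0))
    } else {
      data.frame(key = keys[spike_row_clone], clone = spike_row_clone,
                 fold = spikes$fold, timepoint = spikes$timepoint,
                 baseline_frequency = base_all[spike_row_clone],
                 stringsAsFactors = FALSE)
    }
    list(repertoires = reps,
         truth = list(spikes = truth_spikes, keys = keys,
                      base_frequencies = base_all,
                      realized_frequencies = realized,
                      phi = phi, seed = seed))
  })
}

# Which of the 13 panel markers a subset's cells carry. CD45RO mirrors
# CD45RA- memory; activation/exhaustion markers are negative by default and
# elevated only in designated activated clones.
subset_marker_profile <- function(subset) {
  m <- setNames(rep(FALSE, length(REQUIRED_MARKERS)), REQUIRED_MARKERS)
  m["CD3"] <- TRUE
  lineage <- sub("_.*$", "", subset)
  state <- sub("^[^_]*_", "", subset)
  if (subset == "Treg") {
    m[c("CD4", "CD25", "CCR7", "CD45RO")] <- TRUE
  } else {
    m[lineage] <- TRUE
    m["CD127"] <- TRUE
    if (state %in% c("naive", "CM")) m["CCR7"] <- TRUE
    if (state %in% c("naive", "TE")) m["CD45RA"] <- TRUE else m["CD45RO"] <- TRUE
  }
  m
}

#' Simulate a CITE-seq style single-cell T-cell table with known truth
#'
#' Cells are assigned subsets by the given proportions; ADT counts are
#' negative-binomial around subset-specific positive/negative marker means
#' (default 16-fold separation); TRB clonotypes are drawn from the coupled
#' bulk repertoire's productive frequencies; gene counts are Poisson around
#' lognormal gene-level means, with the module genes' means multiplied by
#' `module_fold` in cells of designated activated clones.
#'
#' @param n_cells number of cells, default 2000.
#' @param bulk a [repertoire()] the clonotype draws are coupled to.
#' @param subset_proportions named numeric vector over subset labels,
#'   summing to 1 (tolerance 1e-9).
#' @param adt_mean_neg,adt_mean_pos negative/positive marker NB means,
#'   defaults 20 and 320 (16-fold).
#' @param adt_size NB size (inverse dispersion), default 10.
#' @param n_genes genes in the expression matrix, default 1000.
#' @param module_genes character vector of gene names (subset of
#'   `gene1..geneN`) elevated in activated clones; default first 20.
#' @param activated_clone_keys bulk clone keys whose cells are "activated".
#' @param module_fold mean fold elevation of module genes, default 4.
#' @param trb_recovery fraction of cells with a recovered TRB, default 0.9.
#' @param subject_id,timepoint sample metadata.
#' @param seed RNG seed.
#' @return list with `cells` (an [sc_table()]) and `truth` (per-cell subset
#'   labels, clone keys, activation flags, and the config).
#' @export
simulate_single_cell <- function(n_cells = 2000L, bulk,
                                 subset_proportions = c(
                                   CD4_naive = 0.15, CD4_CM = 0.15,
                                   CD4_EM = 0.15, Treg = 0.05,
                                   CD8_naive = 0.10, CD8_CM = 0.10,
                                   CD8_EM = 0.20, CD8_TE = 0.10),
                                 adt_mean_neg = 20, adt_mean_pos = 320,
                                 adt_size = 10, n_genes = 1000L,
                                 module_genes = NULL,
                                 activated_clone_keys = character(0),
                                 module_fold = 4, trb_recovery = 0.9,
                                 subject_id = "SYN1", timepoint = "Day0",
                                 seed = 1L) {
  stopifnot(inherits(bulk, "repertoire"))
  assert_that(abs(sum(subset_proportions) - 1) < 1e-9,
              "subset proportions must sum to 1",
              class = "clonodyn_config_error")
  gene_names <- sprintf("gene%04d", seq_len(n_genes))
  if (is.null(module_genes)) module_genes <- gene_names[1:20]
  assert_that(all(module_genes %in% gene_names),
              "module_genes outside the generated gene list",
              class = "clonodyn_config_error")
  cl <- bulk$clones[bulk$clones$productive, , drop = FALSE]
  pfreq <- cl$templates / sum(cl$templates)
  with_seed(seed, {
    subs <- sample(names(subset_proportions), n_cells, replace = TRUE,
                   prob = subset_proportions)
    barcodes <- sprintf("cell%05d-1", seq_len(n_cells))
    # ADT: NB around the subset's positive/negative means
    profiles <- vapply(names(subset_proportions), subset_marker_profile,
                       logical(length(REQUIRED_MARKERS)))
    mu <- t(ifelse(profiles[, subs, drop = FALSE], adt_mean_pos, adt_mean_neg))
    adt <- matrix(rnbinom(length(mu), size = adt_size, mu = as.numeric(mu)),
                  nrow = n_cells,
                  dimnames = list(barcodes, REQUIRED_MARKERS))
    # clonotypes coupled to bulk frequencies
    clone_i <- sample.int(nrow(cl), n_cells, replace = TRUE, prob = pfreq)
    has_trb <- runif(n_cells) < trb_recovery
    trb_nt <- ifelse(has_trb, cl$cdr3_nt[clone_i], NA_character_)
    trb_aa <- ifelse(has_trb, cl$cdr3_aa[clone_i], NA_character_)
    trb_v <- ifelse(has_trb, cl$v_call[clone_i], NA_character_)
    activated <- has_trb & cl$key[clone_i] %in% activated_clone_keys
    # genes: Poisson around lognormal gene means, module elevated when activated
    lambda <- rlnorm(n_genes, meanlog = 0, sdlog = 1)
    lam_mat <- matrix(lambda, nrow = n_genes, ncol = n_cells)
    mi <- match(module_genes, gene_names)
    lam_mat[mi, activated] <- lam_mat[mi, activated] * module_fold
    counts <- matrix(rpois(length(lam_mat), as.numeric(lam_mat)),
                     nrow = n_genes,
                     dimnames = list(gene_names, barcodes))
    genes <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
    cells <- sc_table(
      data.frame(barcode = barcodes, trb_cdr3_nt = trb_nt,
                 trb_cdr3_aa = trb_aa, trb_v_gene = trb_v,
                 tra_cdr3_aa = NA_character_, stringsAsFactors = FALSE),
      adt, genes, subject_id = subject_id, timepoint = timepoint)
    list(cells = cells,
         truth = list(subset = setNames(subs, barcodes),
                      clone_key = setNames(cl$key[clone_i], barcodes),
                      has_trb = setNames(has_trb, barcodes),
                      activated = setNames(activated, barcodes),
                      module_genes = module_genes, module_fold = module_fold,
                      seed = seed))
  })
}
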