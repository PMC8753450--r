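# Bulk-to-single-cell clonotype linkage, supervised differential signatures
# for clones of interest, and per-cell gene-module scores.

key_parts <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(cdr3_nt = vapply(parts, `[`, character(1), 1L),
             v_call = vapply(parts, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Link bulk-identified clones to single cells
#'
#' Matches each bulk clone key to the cells harboring the same TCRβ CDR3.
#' Primary match is on the CDR3β nucleotide sequence; when the single-cell
#' VDJ calls carry no nucleotide CDR3, matching falls back to (CDR3β amino
#' acid, V gene) with a message noting the downgrade. Clones linked to fewer
#' than `min_cells` cells are flagged under-covered and are excluded from
#' differential signatures by default (clone-level statements need >= 5
#' cells with the CDR3).
#'
#' @param cells an [sc_table()].
#' @param bulk_keys character vector of clone keys ([clone_key()] format).
#' @param min_cells coverage threshold, default 5.
#' @param bulk optional bulk [repertoire()]; required for the amino-acid
#'   fallback (the key alone carries no CDR3 amino-acid sequence).
#' @return data.frame of class `clone_link`: `key`, `n_cells`,
#'   `under_covered`, and a list-column `barcodes`.
#' @export
link_bulk_clones <- function(cells, bulk_keys, min_cells = 5L, bulk = NULL) {
  stopifnot(inherits(cells, "sc_table"))
  meta <- cells$cells
  parts <- key_parts(bulk_keys)
  have_nt <- any(!is.na(meta$trb_cdr3_nt) & nzchar(meta$trb_cdr3_nt))
  if (have_nt) {
    hits <- lapply(parts$cdr3_nt, function(nt)
      meta$barcode[!is.na(meta$trb_cdr3_nt) & meta$trb_cdr3_nt == nt])
  } else {
    message("no nucleotide CDR3 in single-cell VDJ; matching on (CDR3aa, V gene)")
    assert_that(!is.null(bulk) && inherits(bulk, "repertoire"),
                "amino-acid fallback needs the bulk repertoire (bulk =)",
                class = "clonodyn_config_error")
    aa <- bulk$clones$cdr3_aa[match(bulk_keys, bulk$clones$key)]
    strip <- function(g) sub("\\*.*$", "", g)
    hits <- lapply(seq_len(nrow(parts)), function(i) {
      if (is.na(aa[i]) || !nzchar(aa[i])) return(character(0))
      aa_ok <- !is.na(meta$trb_cdr3_aa) & meta$trb_cdr3_aa == aa[i]
      v_ok <- if (is.null(meta$trb_v_gene)) TRUE else
        !is.na(meta$trb_v_gene) & strip(meta$trb_v_gene) == parts$v_call[i]
      meta$barcode[aa_ok & v_ok]
    })
  }
  n <- vapply(hits, length, integer(1))
  out <- data.frame(key = bulk_keys, n_cells = n,
                    under_covered = n < min_cells, stringsAsFactors = FALSE)
  out$barcodes <- hits
  class(out) <- c("clone_link", "data.frame")
  out
}

#' Top-k abundant bulk clones as a comparator cell set
#'
#' Picks the `k` most abundant bulk clones (by templates; ties broken by
#' lexicographically smaller CDR3) whose linked cells are majority of the
#' requested lineage, excluding any clone in the clones-of-interest set —
#' the "ten most abundant CD8+ clones" comparator of the supervised
#' signature analyses.
#'
#' @param cells a gated [sc_table()].
#' @param bulk_rep the matching bulk [repertoire()].
#' @param k number of comparator clones, default 10.
#' @param lineage `"CD8"` or `"CD4"`.
#' @param exclude_keys clone keys excluded (clones of interest).
#' @param min_cells linkage coverage threshold, default 5.
#' @return list with `keys` (selected comparator clones) and `barcodes`
#'   (their pooled cells); warns when fewer than `k` clones are eligible.
#' @export
top_abundant_comparator <- function(cells, bulk_rep, k = 10L,
                                    lineage = c("CD8", "CD4"),
                                    exclude_keys = character(0),
                                    min_cells = 5L) {
  lineage <- match.arg(lineage)
  stopifnot(inherits(cells, "sc_table"), inherits(bulk_rep, "repertoire"))
  cl <- bulk_rep$clones[bulk_rep$clones$productive, , drop = FALSE]
  cl <- cl[order(-cl$templates, cl$cdr3_nt), , drop = FALSE]
  cl <- cl[!(cl$key %in% exclude_keys), , drop = FALSE]
  link <- link_bulk_clones(cells, cl$key, min_cells = min_cells)
  lab <- cells$cells$subset
  majority_lineage <- vapply(link$barcodes, function(bc) {
    if (!length(bc)) return(FALSE)
    sub <- lab[match(bc, cells$cells$barcode)]
    mean(startsWith(sub, lineage), na.rm = TRUE) > 0.5
  }, logical(1))
  eligible <- which(!link$under_covered & majority_lineage)
  if (length(eligible) < k) {
    warning(sprintf("only %d eligible comparator clones (requested %d)",
                    length(eligible), k))
  }
  sel <- head(eligible, k)
  list(keys = link$key[sel],
       barcodes = unique(unlist(link$barcodes[sel])))
}

# Vectorized two-sided Mann-Whitney/Wilcoxon rank-sum test per matrix row
# (features x cells), normal approximation with tie correction and
# continuity correction — the convention of single-cell DE toolchains.
rank_sum_rows <- function(mat, in_a) {
  n1 <- sum(in_a); n2 <- sum(!in_a); n <- n1 + n2
  stats_p <- t(apply(mat, 1L, function(v) {
    r <- rank(v)
    U <- sum(r[in_a]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) return(c(U, 1))
    z <- (abs(U - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
    c(U, min(1, 2 * stats::pnorm(z, lower.tail = FALSE)))
  }))
  list(U = stats_p[, 1L], p = stats_p[, 2L])
}

#' Supervised differential signature between two cell groups
#'
#' Per-feature two-sided Wilcoxon rank-sum tests between clones-of-interest
#' cells and comparator cells, Bonferroni-corrected with the total number of
#' features in the modality (all genes, or all panel proteins). Genes are
#' log-normalized (counts per 10,000, log1p); ADT counts use a centered
#' log-ratio per cell. Features are ordered by adjusted p then |logFC|, and
#' tiered: `"**"` adjusted p < 0.01, `"*"` adjusted p in [0.01, 0.05), `"."`
#' otherwise.
#'
#' @param cells an [sc_table()].
#' @param barcodes_a,barcodes_b cell barcodes of the two groups (must be
#'   disjoint, each of size >= `min_cells`).
#' @param features `"genes"` or `"proteins"`.
#' @param min_cells group size floor, default 5.
#' @return data.frame of class `de_result`: `feature`, `mean_a`, `mean_b`,
#'   `log_fc`, `statistic`, `p_value`, `adj_p`, `tier`.
#' @export
differential_signature <- function(cells, barcodes_a, barcodes_b,
                                   features = c("genes", "proteins"),
                                   min_cells = 5L) {
  features <- match.arg(features)
  stopifnot(inherits(cells, "sc_table"))
  assert_that(length(intersect(barcodes_a, barcodes_b)) == 0L,
              "cell groups must be disjoint")
  assert_that(length(barcodes_a) >= min_cells && length(barcodes_b) >= min_cells,
              "both groups need at least %d cells", min_cells,
              class = "clonodyn_size_error")
  if (features == "genes") {
    norm <- normalize_gex(cells$genes)
    mat <- as.matrix(norm[, c(barcodes_a, barcodes_b), drop = FALSE])
  } else {
    clr <- normalize_adt_clr(cells$adt)
    mat <- t(clr[c(barcodes_a, barcodes_b), , drop = FALSE])
  }
  in_a <- c(rep(TRUE, length(barcodes_a)), rep(FALSE, length(barcodes_b)))
  rs <- rank_sum_rows(mat, in_a)
  mean_a <- rowMeans(mat[, in_a, drop = FALSE])
  mean_b <- rowMeans(mat[, !in_a, drop = FALSE])
  adj <- pmin(1, rs$p * nrow(mat))   # Bonferroni over all features in modality
  out <- data.frame(feature = rownames(mat), mean_a = mean_a, mean_b = mean_b,
                    log_fc = mean_a - mean_b, statistic = rs$U,
                    p_value = rs$p, adj_p = adj,
                    tier = ifelse(adj < 0.01, "**", ifelse(adj < 0.05, "*", ".")),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$adj_p, -abs(out$log_fc)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Per-clone mean-expression matrix for heatmap export
#'
#' Mean normalized expression of the given features over the cells of each
#' clone — the values the signature heatmaps display.
#'
#' @param cells an [sc_table()].
#' @param link a [link_bulk_clones()] result.
#' @param feature_names features (genes or markers) to include.
#' @param features `"genes"` or `"proteins"`.
#' @return matrix, features x clones.
#' @export
clone_mean_matrix <- function(cells, link, feature_names,
                              features = c("genes", "proteins")) {
  features <- match.arg(features)
  if (features == "genes") {
    norm <- normalize_gex(cells$genes)
    get <- function(bc) rowMeans(as.matrix(norm[feature_names, bc, drop = FALSE]))
  } else {
    clr <- t(normalize_adt_clr(cells$adt))
    get <- function(bc) rowMeans(clr[feature_names, bc, drop = FALSE])
  }
  out <- vapply(link$barcodes, function(bc) {
    if (!length(bc)) rep(NA_real_, length(feature_names)) else get(bc)
  }, numeric(length(feature_names)))
  out <- matrix(out, nrow = length(feature_names),
                dimnames = list(feature_names, link$key))
  out
}

#' Per-cell gene-module score
#'
#' For each cell: mean log-normalized expression of the module genes minus
#' the mean of a background control set — genes binned by their
#' dataset-average expression into `n_bins` bins, with `n_ctrl` controls
#' sampled (seeded) per module gene from the matching bin. A cell whose
#' module genes behave like the background scores ~0.
#'
#' @param cells an [sc_table()].
#' @param gene_set character vector of gene names; genes absent from the
#'   matrix are dropped with a warning.
#' @param n_bins expression bins, default 25.
#' @param n_ctrl control genes per module gene, default 100.
#' @param seed RNG seed for control sampling.
#' @return Named numeric vector of per-cell scores (names = barcodes).
#' @export
module_score <- function(cells, gene_set, n_bins = 25L, n_ctrl = 100L,
                         seed = 1L) {
  stopifnot(inherits(cells, "sc_table"))
  present <- intersect(gene_set, rownames(cells$genes))
  if (length(present) < length(gene_set)) {
    warning(sprintf("%d module gene(s) absent from the matrix, dropped",
                    length(gene_set) - length(present)))
  }
  assert_that(length(present) > 0L, "no module genes present in the matrix",
              class = "clonodyn_config_error")
  norm <- normalize_gex(cells$genes)
  avg <- Matrix::rowMeans(norm)
  bins <- cut(rank(avg, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  names(bins) <- rownames(norm)
  ctrl <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      pool <- names(bins)[bins == bins[g]]
      pool <- setdiff(pool, g)
      if (!length(pool)) return(character(0))
      sample(pool, min(n_ctrl, length(pool)), replace = FALSE)
    }))
  })
  ctrl <- unique(ctrl)
  mod_mean <- Matrix::colMeans(norm[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(norm[ctrl, , drop = FALSE])
  setNames(as.numeric(mod_mean - ctrl_mean), colnames(norm))
}

#' Per-clone subset composition and phenotype stability
#'
#' For each clone with enough cells at every compared timepoint, the
#' composition vector over gated subsets per timepoint, and a stability
#' metric: the maximum over timepoints of the total-variation distance from
#' the baseline composition (0 = identical phenotype distribution at all
#' timepoints, 1 = completely disjoint).
#'
#' @param samples named list of gated [sc_table()]s keyed by timepoint
#'   (first element = baseline).
#' @param clone_keys bulk clone keys to evaluate.
#' @param min_cells per-timepoint coverage floor, default 5.
#' @return list with `composition` (long data.frame key/timepoint/subset/
#'   fraction/n_cells) and `stability` (key, stability, evaluable).
#' @export
clone_phenotype_composition <- function(samples, clone_keys, min_cells = 5L) {
  stopifnot(length(samples) >= 2L, !is.null(names(samples)))
  subsets <- sort(unique(unlist(lapply(samples, function(s) s$cells$subset))))
  comp_one <- function(s, key) {
    link <- link_bulk_clones(s, key, min_cells = min_cells)
    bc <- link$barcodes[[1L]]
    lab <- s$cells$subset[match(bc, s$cells$barcode)]
    tab <- table(factor(lab, levels = subsets))
    list(n = length(bc),
         frac = if (length(bc)) as.numeric(tab) / length(bc) else rep(NA_real_, length(subsets)))
  }
  comp_rows <- list(); stab_rows <- list()
  for (key in clone_keys) {
    per_tp <- lapply(samples, comp_one, key = key)
    ns <- vapply(per_tp, `[[`, numeric(1), "n")
    evaluable <- all(ns >= min_cells)
    for (tp in names(samples)) {
      comp_rows[[length(comp_rows) + 1L]] <-
        data.frame(key = key, timepoint = tp, subset = subsets,
                   fraction = per_tp[[tp]]$frac, n_cells = per_tp[[tp]]$n,
                   stringsAsFactors = FALSE)
    }
    stab <- if (evaluable) {
      base <- per_tp[[1L]]$frac
      max(vapply(per_tp[-1L], function(z) sum(abs(z$frac - base)) / 2, numeric(1)))
    } else NA_real_
    stab_rows[[length(stab_rows) + 1L]] <-
      data.frame(key = key, stability = stab, evaluable = evaluable,
                 stringsAsFactors = FALSE)
  }
  list(composition = do.call(rbind, comp_rows),
       stability = do.call(rbind, stab_rows))
}
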