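# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk except files the tests themselves write.

# deterministic unique CDR3 nucleotide strings: index -> base-4 word
synthetic_cdr3 <- function(n, len = 12L) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n) - 1L, function(i) {
    digits <- integer(len)
    for (j in seq_len(len)) {
      digits[j] <- i %% 4L
      i <- i %/% 4L
    }
    paste(bases[digits + 1L], collapse = "")
  }, character(1))
}

# small repertoire from a count vector
make_rep <- function(counts, productive = rep(TRUE, length(counts)),
                     subject_id = "S1", timepoint = "Day0",
                     compartment = "PB", cdr3 = NULL) {
  n <- length(counts)
  cdr3 <- cdr3 %||% synthetic_cdr3(n)
  repertoire(data.frame(
    cdr3_nt = cdr3,
    cdr3_aa = vapply(seq_len(n), function(i) paste0("CASS", i, "F"), character(1)),
    v_call = sprintf("TRBV%02d-1", (seq_len(n) %% 20) + 2L),
    j_call = sprintf("TRBJ%d-%d", (seq_len(n) %% 2) + 1L, (seq_len(n) %% 6) + 1L),
    templates = counts, productive = productive, stringsAsFactors = FALSE),
    subject_id = subject_id, timepoint = timepoint, compartment = compartment)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built sc_table with controllable ADT counts per cell.
# adt_rows: matrix/data.frame with one named column per marker; other markers
# filled with `fill`.
make_sc <- function(adt_rows = NULL, n_cells = nrow(adt_rows), trb = NULL,
                    genes = NULL, fill = 0L) {
  markers <- c("CD3", "CD4", "CD8", "CCR7", "CD45RA", "CD45RO", "CD127",
               "CD25", "PD-1", "TIM-3", "CD27", "HLA-DR", "4-1BB")
  bc <- sprintf("bc%04d", seq_len(n_cells))
  adt <- matrix(fill, n_cells, length(markers),
                dimnames = list(bc, markers))
  if (!is.null(adt_rows)) {
    for (m in colnames(adt_rows)) adt[, m] <- adt_rows[, m]
  }
  if (is.null(genes)) {
    genes <- Matrix::Matrix(0L, nrow = 3, ncol = n_cells, sparse = TRUE,
                            dimnames = list(c("geneA", "geneB", "geneC"), bc))
  }
  cells <- data.frame(barcode = bc,
                      trb_cdr3_nt = trb %||% rep(NA_character_, n_cells),
                      trb_cdr3_aa = NA_character_, tra_cdr3_aa = NA_character_,
                      stringsAsFactors = FALSE)
  sc_table(cells, adt, genes)
}

# O(m^2) brute force of the BH step-up definition:
# q_i = min over sorted positions j with p_(j) >= p_i of m * p_(j) / j
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  vapply(p, function(pi) {
    cand <- which(ps >= pi - 1e-300)
    min(1, min(m * ps[cand] / cand))
  }, numeric(1))
}

# independent two-sided Fisher p by sorting hypergeometric masses
fisher_two_sided_oracle <- function(x1, N1, x2, N2) {
  s <- x1 + x2
  k <- max(0L, s - N2):min(s, N1)
  dh <- dhyper(k, N1, N2, s)
  ord <- order(dh)
  cum <- cumsum(dh[ord])
  pos <- which(k[ord] == x1)
  thr <- dh[k == x1] * (1 + 1e-12)
  last <- max(which(dh[ord] <= thr))
  min(1, cum[last])
}
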