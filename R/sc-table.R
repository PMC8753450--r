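# Single-cell container: per-cell clonotype calls, ADT (antibody-derived tag)
# counts over a marker panel, and a sparse gene-expression matrix.

REQUIRED_MARKERS <- c("CD3", "CD4", "CD8", "CCR7", "CD45RA", "CD45RO",
                      "CD127", "CD25", "PD-1", "TIM-3", "CD27", "HLA-DR",
                      "4-1BB")

#' Construct a single-cell T-cell table
#'
#' The substrate for gating, bulk-clone linkage, differential signatures and
#' module scoring: one row per cell with its paired TRA/TRB CDR3 calls, an
#' ADT count matrix over a named marker panel, and a sparse gene count
#' matrix.
#'
#' @param cells data.frame with columns `barcode`, `trb_cdr3_nt`,
#'   `trb_cdr3_aa`, `tra_cdr3_aa` (chain columns may be `NA` for cells
#'   without a recovered chain). A `subset` column is added (NA until gated).
#' @param adt integer matrix, cells x markers, rownames = barcodes, colnames
#'   = marker names (must include the core panel: CD3, CD4, CD8, CCR7,
#'   CD45RA, CD45RO, CD127, CD25, PD-1, TIM-3, CD27, HLA-DR, 4-1BB).
#' @param genes sparse non-negative integer Matrix, genes x cells, dimnames
#'   set (gene names, barcodes).
#' @param subject_id,timepoint sample metadata.
#' @return Object of class `sc_table`.
#' @export
sc_table <- function(cells, adt, genes, subject_id = "subject",
                     timepoint = "Day0") {
  cells <- as.data.frame(cells)
  assert_that(!anyDuplicated(cells$barcode), "duplicate cell barcodes")
  for (col in c("trb_cdr3_nt", "trb_cdr3_aa", "tra_cdr3_aa")) {
    if (is.null(cells[[col]])) cells[[col]] <- NA_character_
  }
  if (is.null(cells$subset)) cells$subset <- NA_character_
  adt <- as.matrix(adt)
  missing_m <- setdiff(REQUIRED_MARKERS, colnames(adt))
  assert_that(length(missing_m) == 0L, "ADT panel missing marker(s): %s",
              paste(missing_m, collapse = ", "),
              class = "clonodyn_config_error")
  assert_that(identical(rownames(adt), cells$barcode),
              "ADT rows must align with cell barcodes")
  genes <- methods::as(genes, "CsparseMatrix")
  assert_that(identical(colnames(genes), cells$barcode),
              "gene matrix columns must align with cell barcodes")
  structure(list(cells = cells, adt = adt, genes = genes,
                 subject_id = subject_id, timepoint = timepoint),
            class = "sc_table")
}

#' @export
print.sc_table <- function(x, ...) {
  n_trb <- sum(!is.na(x$cells$trb_cdr3_nt) & nzchar(x$cells$trb_cdr3_nt))
  cat(sprintf("<sc_table> %s / %s: %d cells (%d with TRB), %d markers, %d genes\n",
              x$subject_id, x$timepoint, nrow(x$cells), n_trb,
              ncol(x$adt), nrow(x$genes)))
  invisible(x)
}

#' Read a single-cell sample from standard 10x-style files
#'
#' Assembles an [sc_table()] from a Matrix-Market gene matrix with
#' features/barcodes TSVs, an ADT count TSV (barcode column + one column per
#' marker), and a filtered-contig CSV for VDJ (columns `barcode`, `chain`,
#' `cdr3`, `cdr3_nt`, `v_gene`, `j_gene`, `productive`). Only productive TRB
#' and TRA contigs are used; when a cell has several productive contigs of a
#' chain the first is kept.
#'
#' @param mtx,features,barcodes paths for the sparse gene counts (genes x
#'   cells), gene names (first column), and cell barcodes (first column).
#' @param adt path to the ADT TSV.
#' @param vdj path to the contig CSV.
#' @param subject_id,timepoint sample metadata.
#' @return An [sc_table()].
#' @export
read_sc_sample <- function(mtx, features, barcodes, adt, vdj,
                           subject_id = "subject", timepoint = "Day0") {
  for (p in c(mtx, features, barcodes, adt, vdj)) {
    assert_that(file.exists(p), "file not found: %s", p, class = "clonodyn_io_error")
  }
  gm <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  feat <- read.delim(features, header = FALSE, stringsAsFactors = FALSE)[[1]]
  bc <- read.delim(barcodes, header = FALSE, stringsAsFactors = FALSE)[[1]]
  dimnames(gm) <- list(feat, bc)
  adt_df <- read.delim(adt, check.names = FALSE, stringsAsFactors = FALSE)
  adt_m <- as.matrix(adt_df[, setdiff(names(adt_df), "barcode"), drop = FALSE])
  rownames(adt_m) <- adt_df$barcode
  adt_m <- adt_m[match(bc, rownames(adt_m)), , drop = FALSE]
  rownames(adt_m) <- bc

  contigs <- utils::read.csv(vdj, stringsAsFactors = FALSE)
  contigs <- contigs[contigs$productive %in% c("True", "TRUE", TRUE, "true"), ]
  pick <- function(chain, col) {
    sub <- contigs[contigs$chain == chain, ]
    sub <- sub[!duplicated(sub$barcode), ]
    sub[[col]][match(bc, sub$barcode)]
  }
  cells <- data.frame(barcode = bc,
                      trb_cdr3_nt = toupper(pick("TRB", "cdr3_nt")),
                      trb_cdr3_aa = pick("TRB", "cdr3"),
                      trb_v_gene = pick("TRB", "v_gene"),
                      tra_cdr3_aa = pick("TRA", "cdr3"),
                      stringsAsFactors = FALSE)
  sc_table(cells, adt_m, gm, subject_id = subject_id, timepoint = timepoint)
}

#' Write the tabular parts of an sc_table to a directory
#'
#' Emits `cells.tsv` (barcodes, chains, subset labels), `adt.tsv`, the gene
#' matrix as `genes.mtx` + `features.tsv` + `barcodes.tsv`, and a 10x-style
#' `contigs.csv` so the directory reads back through [read_sc_sample()].
#'
#' @param x an [sc_table()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sc_sample <- function(x, dir) {
  stopifnot(inherits(x, "sc_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(x$cells, file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  adt_df <- data.frame(barcode = rownames(x$adt), x$adt, check.names = FALSE)
  write.table(adt_df, file.path(dir, "adt.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  Matrix::writeMM(x$genes, file.path(dir, "genes.mtx"))
  writeLines(rownames(x$genes), file.path(dir, "features.tsv"))
  writeLines(colnames(x$genes), file.path(dir, "barcodes.tsv"))
  has_trb <- !is.na(x$cells$trb_cdr3_nt) & nzchar(x$cells$trb_cdr3_nt)
  has_tra <- !is.na(x$cells$tra_cdr3_aa) & nzchar(x$cells$tra_cdr3_aa)
  v_gene <- x$cells$trb_v_gene %||% rep(NA_character_, nrow(x$cells))
  contig_block <- function(keep, chain, cdr3, cdr3_nt, v) {
    n <- sum(keep)
    data.frame(barcode = x$cells$barcode[keep], chain = rep(chain, n),
               cdr3 = cdr3[keep], cdr3_nt = cdr3_nt[keep],
               v_gene = v[keep], j_gene = rep(NA_character_, n),
               productive = rep("True", n), stringsAsFactors = FALSE)
  }
  na_col <- rep(NA_character_, nrow(x$cells))
  contigs <- rbind(
    contig_block(has_trb, "TRB", x$cells$trb_cdr3_aa, x$cells$trb_cdr3_nt,
                 v_gene),
    contig_block(has_tra, "TRA", x$cells$tra_cdr3_aa, na_col, na_col))
  utils::write.csv(contigs, file.path(dir, "contigs.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

# log-normalized gene expression: counts per 10,000 per cell, then log1p.
normalize_gex <- function(genes) {
  cs <- Matrix::colSums(genes)
  cs[cs == 0] <- 1
  m <- genes %*% Matrix::Diagonal(x = 1e4 / cs)
  dimnames(m) <- dimnames(genes)
  m@x <- log1p(m@x)
  m
}

# centered log-ratio ADT transform per cell across the panel.
normalize_adt_clr <- function(adt) {
  lg <- log1p(adt)
  sweep(lg, 1L, rowMeans(lg), "-")
}
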