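#' Repertoire richness, Shannon entropy and normalized clonality
#'
#' Clonality is the immunosequencing-industry normalization of Shannon
#' entropy: with clone proportions `p_i = c_i / sum(c)`, entropy
#' `H = -sum(p_i * log(p_i))` (natural log), richness `R` the number of
#' distinct clones, and `clonality = 1 - H / log(R)`. Clonality is 0 for a
#' maximally diverse sample and 1 for a monoclonal one; a monoclonal sample
#' (`R = 1`) is defined as clonality 1.
#'
#' @param counts vector of positive integer clone counts (templates for bulk,
#'   cells for single-cell). Zeros are dropped.
#' @return A one-row data.frame of class `diversity_result` with columns
#'   `richness`, `entropy_nats`, `clonality`, `n_templates`.
#' @examples
#' clonality(c(8, 1, 1))  # clonality ~ 0.418
#' @export
clonality <- function(counts) {
  counts <- counts[!is.na(counts) & counts > 0]
  assert_that(length(counts) > 0, "clonality undefined for empty/all-zero counts",
              class = "clonodyn_undefined_error")
  p <- counts / sum(counts)
  H <- -sum(p * log(p))
  R <- length(counts)
  cl <- if (R >= 2L) 1 - H / log(R) else 1
  structure(data.frame(richness = R, entropy_nats = H,
                       clonality = min(max(cl, 0), 1),
                       n_templates = sum(counts)),
            class = c("diversity_result", "data.frame"))
}

#' Clonality of a bulk repertoire (productive clones only)
#'
#' @param rep a [repertoire()].
#' @return A `diversity_result` row, as [clonality()].
#' @export
repertoire_clonality <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  clonality(rep$clones$templates[rep$clones$productive])
}

#' Per-subset single-cell clonality
#'
#' Counts cells per clonotype within each gated subset and applies
#' [clonality()]. One cell counts once (cell counts, not UMI counts), matching
#' the one-template-one-cell interpretation of bulk counts. Cells without a
#' recovered TRB chain are excluded; subsets with fewer than `min_cells`
#' TRB-bearing cells are reported as `NA` with a reason.
#'
#' @param cells a gated [sc_table()] (see [gate_subsets()]).
#' @param subsets subset labels to evaluate; default all labels present.
#' @param min_cells minimum TRB-bearing cells per subset (default 20).
#' @return data.frame with one row per subset: `subset`, `n_cells`,
#'   `richness`, `entropy_nats`, `clonality`, `reason`.
#' @export
subset_clonality <- function(cells, subsets = NULL, min_cells = 20L) {
  stopifnot(inherits(cells, "sc_table"))
  meta <- cells$cells
  assert_that(!all(is.na(meta$subset)), "cells are not gated; run gate_subsets()",
              class = "clonodyn_config_error")
  has_trb <- !is.na(meta$trb_cdr3_nt) & nzchar(meta$trb_cdr3_nt)
  if (is.null(subsets)) {
    subsets <- sort(unique(meta$subset[!is.na(meta$subset) & meta$subset != "unassigned"]))
  }
  out <- lapply(subsets, function(s) {
    keep <- has_trb & !is.na(meta$subset) & meta$subset == s
    n <- sum(keep)
    if (n < min_cells) {
      return(data.frame(subset = s, n_cells = n, richness = NA_integer_,
                        entropy_nats = NA_real_, clonality = NA_real_,
                        reason = if (n == 0L) "no TRB-bearing cells" else
                          sprintf("fewer than %d cells", min_cells)))
    }
    d <- clonality(as.integer(table(meta$trb_cdr3_nt[keep])))
    data.frame(subset = s, n_cells = n, richness = d$richness,
               entropy_nats = d$entropy_nats, clonality = d$clonality,
               reason = "")
  })
  do.call(rbind, out)
}

#' Whole-sample single-cell clonality
#'
#' Clonality over cells-per-clonotype counts of all TRB-bearing cells,
#' comparable with the bulk value from [repertoire_clonality()].
#'
#' @param cells an [sc_table()].
#' @return A `diversity_result` row.
#' @export
sc_clonality <- function(cells) {
  stopifnot(inherits(cells, "sc_table"))
  trb <- cells$cells$trb_cdr3_nt
  trb <- trb[!is.na(trb) & nzchar(trb)]
  assert_that(length(trb) > 0, "no TRB-bearing cells",
              class = "clonodyn_undefined_error")
  clonality(as.integer(table(trb)))
}
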