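# ADT-based T-cell subset gating, analogous to flow cytometry on raw marker
# counts: per-marker cutoffs on log1p counts, then boolean gate rules.

GATING_MARKERS <- c("CD3", "CD4", "CD8", "CCR7", "CD45RA", "CD127", "CD25")

#' Build a gating scheme from per-marker cutoffs
#'
#' Cutoffs act on `log1p(count)`; a cell is positive for a marker when its
#' transformed count is strictly above the cutoff.
#'
#' @param cutoffs named numeric vector of positive cutoffs; must cover CD3,
#'   CD4, CD8, CCR7, CD45RA, CD127, CD25.
#' @return Object of class `gating_scheme`.
#' @export
gating_scheme <- function(cutoffs) {
  missing_m <- setdiff(GATING_MARKERS, names(cutoffs))
  assert_that(length(missing_m) == 0L, "gating scheme missing marker(s): %s",
              paste(missing_m, collapse = ", "),
              class = "clonodyn_config_error")
  assert_that(all(cutoffs > 0), "cutoffs must be positive")
  structure(list(cutoffs = cutoffs), class = "gating_scheme")
}

#' @export
print.gating_scheme <- function(x, ...) {
  cat("<gating_scheme> log1p-count cutoffs:\n")
  print(round(x$cutoffs, 3))
  invisible(x)
}

#' Derive per-marker cutoffs automatically
#'
#' For each gating marker, separates positive from negative cells by Otsu's
#' two-component threshold on the `log1p` counts. A marker whose two Otsu
#' classes are separated by less than `min_separation` (log scale; default
#' `log(4)`, a 4-fold count difference) is effectively unimodal — e.g. CD3 on
#' a FACS-enriched T-cell product, where every cell is positive — and gets
#' the panel-pooled cutoff instead: Otsu on the pooled `log1p` counts of all
#' gating markers, which is reliably bimodal because every cell carries both
#' positive and negative markers. With several samples (e.g. one per
#' timepoint of a subject), the consensus cutoff is the median of the
#' per-sample cutoffs — mirroring consensus gates built by comparing median
#' cutoffs across timepoints within a sample.
#'
#' @param samples an [sc_table()] or list of them.
#' @param min_separation minimum between-class mean difference (log1p scale)
#'   for a marker-specific cutoff, default `log(4)`.
#' @return A [gating_scheme()].
#' @export
auto_gating_scheme <- function(samples, min_separation = log(4)) {
  if (inherits(samples, "sc_table")) samples <- list(samples)
  per_sample <- vapply(samples, function(s) {
    lg <- log1p(s$adt[, GATING_MARKERS, drop = FALSE])
    pooled <- otsu_threshold(as.numeric(lg))
    vapply(GATING_MARKERS, function(m) {
      cut <- otsu_threshold(lg[, m])
      above <- lg[, m] > cut
      if (!any(above) || all(above) ||
          mean(lg[above, m]) - mean(lg[!above, m]) < min_separation) pooled
      else cut
    }, numeric(1))
  }, numeric(length(GATING_MARKERS)))
  per_sample <- matrix(per_sample, nrow = length(GATING_MARKERS),
                       dimnames = list(GATING_MARKERS, NULL))
  gating_scheme(apply(per_sample, 1L, median))
}

#' Gate cells into T-cell subsets
#'
#' Thresholded positive/negative calls feed the standard rules: among CD3+
#' cells, CD4+ and CD8+ are mutually exclusive (both or neither positive →
#' `"unassigned"`); within each lineage, CCR7/CD45RA define naive
#' (CCR7+CD45RA+), central memory CM (CCR7+CD45RA−), effector memory EM
#' (CCR7−CD45RA−) and terminal effector TE (CCR7−CD45RA+, i.e. EM
#' re-expressing CD45RA); CD4+ cells that are CD127-low and CD25-high are
#' regulatory T cells (`"Treg"`), overriding the CD4 memory label. CD3−
#' cells are `"unassigned"`.
#'
#' @param cells an [sc_table()].
#' @param scheme a [gating_scheme()], or `"auto"` to derive one from this
#'   sample via [auto_gating_scheme()].
#' @return The [sc_table()] with its `subset` column filled with labels like
#'   `"CD8_EM"`, `"CD4_naive"`, `"Treg"`, `"unassigned"`.
#' @export
gate_subsets <- function(cells, scheme = "auto") {
  stopifnot(inherits(cells, "sc_table"))
  if (identical(scheme, "auto")) scheme <- auto_gating_scheme(cells)
  stopifnot(inherits(scheme, "gating_scheme"))
  lg <- log1p(cells$adt[, GATING_MARKERS, drop = FALSE])
  pos <- sweep(lg, 2L, scheme$cutoffs[GATING_MARKERS], ">")

  lab <- rep("unassigned", nrow(pos))
  cd3 <- pos[, "CD3"]
  lineage <- ifelse(pos[, "CD4"] & !pos[, "CD8"], "CD4",
                    ifelse(pos[, "CD8"] & !pos[, "CD4"], "CD8", NA))
  mem <- ifelse(pos[, "CCR7"] & pos[, "CD45RA"], "naive",
                ifelse(pos[, "CCR7"] & !pos[, "CD45RA"], "CM",
                       ifelse(!pos[, "CCR7"] & !pos[, "CD45RA"], "EM", "TE")))
  ok <- cd3 & !is.na(lineage)
  lab[ok] <- paste(lineage[ok], mem[ok], sep = "_")
  treg <- cd3 & !is.na(lineage) & lineage == "CD4" & !pos[, "CD127"] & pos[, "CD25"]
  lab[treg] <- "Treg"
  cells$cells$subset <- lab
  cells
}

#' Subset frequencies and percent change between timepoints
#'
#' Fractions of assigned CD3+ cells per subset (unassigned cells are excluded
#' from the denominator, which is documented in the output), and, when a
#' baseline table is supplied, the percent change
#' `100 * (f_t - f_0) / f_0` per subset.
#'
#' @param cells a gated [sc_table()].
#' @param baseline optional gated [sc_table()] at baseline for percent
#'   change.
#' @return data.frame with `subset`, `n_cells`, `fraction` (of assigned
#'   CD3+), and when `baseline` is given `fraction_baseline` and
#'   `percent_change` (`NA` where the baseline fraction is 0).
#' @export
subset_frequencies <- function(cells, baseline = NULL) {
  stopifnot(inherits(cells, "sc_table"))
  frac <- function(x) {
    lab <- x$cells$subset
    assert_that(!all(is.na(lab)), "cells are not gated; run gate_subsets()",
                class = "clonodyn_config_error")
    lab <- lab[!is.na(lab) & lab != "unassigned"]
    tab <- table(lab)
    data.frame(subset = names(tab), n_cells = as.integer(tab),
               fraction = as.numeric(tab) / sum(tab), stringsAsFactors = FALSE)
  }
  out <- frac(cells)
  attr(out, "denominator") <- "assigned CD3+ cells (unassigned excluded)"
  if (!is.null(baseline)) {
    f0 <- frac(baseline)
    out$fraction_baseline <- f0$fraction[match(out$subset, f0$subset)]
    out$fraction_baseline[is.na(out$fraction_baseline)] <- 0
    out$percent_change <- ifelse(out$fraction_baseline > 0,
                                 100 * (out$fraction - out$fraction_baseline) /
                                   out$fraction_baseline, NA_real_)
  }
  out
}
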