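#' Pairwise differential clonotype abundance between two repertoires
#'
#' Tests every clone observed in either repertoire (with at least `min_total`
#' templates across the pair) for a change in productive frequency, using the
#' conditional exact test with beta-binomial component marginals
#' ([clone_test()]), then applies Benjamini-Hochberg correction across all
#' tested clones of the comparison. A clone is classified `expanded` if
#' `q < fdr_threshold` and its follow-up frequency exceeds baseline,
#' `contracted` for the reverse, else `unchanged`. Expanded clones whose
#' baseline productive frequency is strictly below `novel_baseline_max`
#' (including clones absent at baseline) are additionally flagged `novel` —
#' the expansions from undetectable or near-undetectable (< 0.1%) baseline
#' that the irAE analysis keys on.
#'
#' Statistics use productive clones and productive template totals only.
#' `log2_fold` substitutes the pseudo-frequency `1/(2N)` for zero counts; it
#' is descriptive and never enters classification.
#'
#' @param rep1 baseline [repertoire()].
#' @param rep2 follow-up [repertoire()].
#' @param null a [betabin_null()] or bare numeric `phi` (default 0: pure
#'   Fisher exact).
#' @param fdr_threshold BH q cutoff, default 0.01.
#' @param novel_baseline_max novel-expansion baseline frequency bound,
#'   default 0.001 (strict `<`; a clone at exactly 0.1% is not novel).
#' @param min_total minimum `x1 + x2` for a clone to enter the test family,
#'   default 2 (present/absent singletons carry no testable signal and
#'   inflate the BH denominator).
#' @return Object of class `diff_abundance`: `records` (one row per tested
#'   clone: counts, frequencies, `log2_fold`, `p_value`, `q_value`, `class`,
#'   `novel`), `n_expanded`, `n_contracted`, comparison metadata, and the
#'   null used.
#' @export
differential_abundance <- function(rep1, rep2, null = 0, fdr_threshold = 0.01,
                                   novel_baseline_max = 0.001, min_total = 2L) {
  stopifnot(inherits(rep1, "repertoire"), inherits(rep2, "repertoire"))
  if (!identical(rep1$subject_id, rep2$subject_id) ||
      !identical(rep1$compartment, rep2$compartment)) {
    warning("comparing repertoires from different subjects or compartments")
  }
  phi <- null_phi(null)
  c1 <- rep1$clones[rep1$clones$productive, , drop = FALSE]
  c2 <- rep2$clones[rep2$clones$productive, , drop = FALSE]
  N1 <- rep1$total_productive_templates
  N2 <- rep2$total_productive_templates
  keys <- sort(union(c1$key, c2$key))
  meta <- list(subject = rep1$subject_id, compartment = rep1$compartment,
               timepoint1 = rep1$timepoint, timepoint2 = rep2$timepoint)
  if (length(keys) == 0L) {
    warning("no productive clones in either repertoire")
    rec <- data.frame(key = character(0), x1 = integer(0), x2 = integer(0),
                      N1 = integer(0), N2 = integer(0), f1 = numeric(0),
                      f2 = numeric(0), log2_fold = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      class = character(0), novel = logical(0))
    return(structure(c(list(records = rec, n_expanded = 0L, n_contracted = 0L,
                            null = betabin_null(phi), fdr_threshold = fdr_threshold,
                            novel_baseline_max = novel_baseline_max), meta),
                     class = "diff_abundance"))
  }
  x1 <- c1$templates[match(keys, c1$key)]; x1[is.na(x1)] <- 0L
  x2 <- c2$templates[match(keys, c2$key)]; x2[is.na(x2)] <- 0L
  tested <- (x1 + x2) >= min_total
  keys <- keys[tested]; x1 <- x1[tested]; x2 <- x2[tested]

  f1 <- x1 / N1
  f2 <- x2 / N2
  pf1 <- ifelse(x1 == 0L, 1 / (2 * N1), f1)
  pf2 <- ifelse(x2 == 0L, 1 / (2 * N2), f2)
  log2_fold <- log2(pf2 / pf1)

  p <- clone_test_batch(x1, x2, N1, N2, phi)
  q <- benjamini_hochberg(p)
  class_ <- rep("unchanged", length(keys))
  class_[q < fdr_threshold & f2 > f1] <- "expanded"
  class_[q < fdr_threshold & f2 < f1] <- "contracted"
  novel <- class_ == "expanded" & f1 < novel_baseline_max

  rec <- data.frame(key = keys, x1 = x1, x2 = x2, N1 = N1, N2 = N2,
                    f1 = f1, f2 = f2, log2_fold = log2_fold,
                    p_value = p, q_value = q, class = class_, novel = novel,
                    stringsAsFactors = FALSE)
  rec <- rec[order(rec$q_value, rec$p_value, rec$key), , drop = FALSE]
  rownames(rec) <- NULL
  structure(c(list(records = rec,
                   n_expanded = sum(class_ == "expanded"),
                   n_contracted = sum(class_ == "contracted"),
                   null = if (inherits(null, "betabin_null")) null else betabin_null(phi),
                   fdr_threshold = fdr_threshold,
                   novel_baseline_max = novel_baseline_max), meta),
            class = "diff_abundance")
}

#' @export
print.diff_abundance <- function(x, ...) {
  cat(sprintf("<diff_abundance> %s %s: %s -> %s\n", x$subject, x$compartment,
              x$timepoint1, x$timepoint2))
  cat(sprintf("  %d clones tested (phi = %.3g), q < %g: %d expanded (%d novel), %d contracted\n",
              nrow(x$records), x$null$phi, x$fdr_threshold, x$n_expanded,
              sum(x$records$novel), x$n_contracted))
  invisible(x)
}

#' @export
summary.diff_abundance <- function(object, n = 10L, ...) {
  print(object)
  sig <- object$records[object$records$class != "unchanged", , drop = FALSE]
  if (nrow(sig)) {
    cat("Top differentially abundant clones:\n")
    print(head(sig[, c("key", "x1", "x2", "f1", "f2", "log2_fold", "q_value",
                       "class", "novel")], n))
  }
  invisible(object)
}
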