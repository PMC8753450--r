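# The subsampling experiment: clonotype overlap between two equal-sized
# subsamples of one single-cell sample, and the audit of clones that look
# "emergent" in single-cell data alone.

#' Clonotype overlap between equal-sized subsamples
#'
#' For each subsample size `s`, repeatedly draws two independent subsamples
#' of `s` TRB-bearing cells without replacement (the two draws model two
#' hypothetical experiments on the same specimen and may share cells) and
#' measures the overlap of their clonotype sets. Overlap rises with `s`:
#' small single-cell experiments mostly miss each other's clones, which is
#' why clone discovery from shallow single-cell sampling alone is biased.
#'
#' Default overlap is the Jaccard index
#' `|A ∩ B| / |A ∪ B|` (symmetric, bounded); `method = "containment"` gives
#' the fraction of A's clonotypes found in B instead — the denominator the
#' source analyses leave ambiguous, so both are exposed.
#'
#' @param cells an [sc_table()].
#' @param sizes increasing subsample sizes; max must not exceed the number
#'   of TRB-bearing cells.
#' @param n_reps subsample pairs per size, default 200.
#' @param seed RNG seed.
#' @param method `"jaccard"` (default) or `"containment"`.
#' @return data.frame of class `overlap_curve`: `size`, `mean_overlap`,
#'   `sd_overlap`, `n_reps`; seed and method kept as attributes.
#' @export
overlap_curve <- function(cells, sizes, n_reps = 200L, seed = 1L,
                          method = c("jaccard", "containment")) {
  method <- match.arg(method)
  stopifnot(inherits(cells, "sc_table"))
  trb <- cells$cells$trb_cdr3_nt
  trb <- trb[!is.na(trb) & nzchar(trb)]
  assert_that(max(sizes) <= length(trb),
              "max subsample size %d exceeds the %d TRB-bearing cells",
              max(sizes), length(trb), class = "clonodyn_domain_error")
  res <- with_seed(seed, {
    lapply(sort(sizes), function(s) {
      ov <- vapply(seq_len(n_reps), function(r) {
        a <- unique(sample(trb, s))
        b <- unique(sample(trb, s))
        if (method == "jaccard") {
          length(intersect(a, b)) / length(union(a, b))
        } else {
          length(intersect(a, b)) / length(a)
        }
      }, numeric(1))
      data.frame(size = s, mean_overlap = mean(ov), sd_overlap = sd(ov),
                 n_reps = n_reps)
    })
  })
  out <- do.call(rbind, res)
  attr(out, "seed") <- seed
  attr(out, "method") <- method
  class(out) <- c("overlap_curve", "data.frame")
  out
}

#' Audit apparently emergent single-cell clones against bulk truth
#'
#' Candidates are clonotypes with at least one cell at timepoint `t` and no
#' cells at any earlier single-cell timepoint — what a single-cell-only
#' analysis would call "emerging". Each candidate is checked against bulk:
#' it is `corroborated` only if the bulk test flags it significantly
#' expanded at `t` AND its bulk baseline productive frequency is below the
#' novelty threshold; otherwise it is `false_emergent` (it was already
#' detectable at baseline, or its expansion is not statistically supported).
#'
#' @param sc_series named list of [sc_table()]s keyed by timepoint, in
#'   series order.
#' @param t the timepoint at which emergence is claimed (must not be the
#'   first element).
#' @param bulk_diff [differential_abundance()] result, baseline vs `t`.
#' @param bulk_baseline baseline bulk [repertoire()].
#' @param novel_baseline_max novelty threshold on bulk baseline frequency,
#'   default 0.001.
#' @return data.frame of class `emergence_audit`: per candidate
#'   `trb_cdr3_nt`, `n_cells_at_t`, `bulk_baseline_frequency`,
#'   `bulk_significant`, `verdict`; the `false_emergent_fraction` is an
#'   attribute.
#' @export
audit_emergent_clones <- function(sc_series, t, bulk_diff, bulk_baseline,
                                  novel_baseline_max = 0.001) {
  stopifnot(is.list(sc_series), !is.null(names(sc_series)),
            inherits(bulk_diff, "diff_abundance"),
            inherits(bulk_baseline, "repertoire"))
  it <- match(t, names(sc_series))
  assert_that(!is.na(it) && it > 1L,
              "timepoint '%s' must follow at least one earlier single-cell timepoint", t,
              class = "clonodyn_config_error")
  get_trb <- function(s) {
    v <- s$cells$trb_cdr3_nt
    v[!is.na(v) & nzchar(v)]
  }
  at_t <- get_trb(sc_series[[it]])
  earlier <- unique(unlist(lapply(sc_series[seq_len(it - 1L)], get_trb)))
  cand <- sort(setdiff(unique(at_t), earlier))

  # bulk records are keyed by (cdr3_nt | V | J); match on the CDR3nt part
  rec_nt <- key_parts(bulk_diff$records$key)$cdr3_nt
  base_nt <- key_parts(bulk_baseline$clones$key)$cdr3_nt
  base_freq <- vapply(cand, function(nt) {
    i <- which(base_nt == nt & bulk_baseline$clones$productive)
    if (!length(i)) 0 else
      sum(bulk_baseline$clones$templates[i]) / bulk_baseline$total_productive_templates
  }, numeric(1))
  bulk_sig <- vapply(cand, function(nt) {
    i <- which(rec_nt == nt)
    length(i) > 0L && any(bulk_diff$records$class[i] == "expanded")
  }, logical(1))
  verdict <- ifelse(bulk_sig & base_freq < novel_baseline_max,
                    "corroborated", "false_emergent")
  out <- data.frame(trb_cdr3_nt = cand,
                    n_cells_at_t = as.integer(table(at_t)[cand]),
                    bulk_baseline_frequency = base_freq,
                    bulk_significant = bulk_sig,
                    verdict = verdict,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "false_emergent_fraction") <-
    if (nrow(out)) mean(out$verdict == "false_emergent") else NA_real_
  class(out) <- c("emergence_audit", "data.frame")
  out
}
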