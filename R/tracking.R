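# Clone trajectories across timepoints/compartments, temporal association of
# expansions with clinical events (irAEs), and blood/marrow concordance.

order_timepoints <- function(tp, timepoint_order) {
  unknown <- setdiff(tp, timepoint_order)
  assert_that(length(unknown) == 0L,
              "unknown timepoint(s): %s (allowed: %s)",
              paste(unknown, collapse = ", "),
              paste(timepoint_order, collapse = ", "),
              class = "clonodyn_config_error")
  timepoint_order[timepoint_order %in% tp]
}

#' Assemble per-clone trajectories across a repertoire series
#'
#' Collects, for every clone that is a novel expansion (significant with
#' baseline productive frequency < 0.1%) in any supplied comparison, its
#' productive frequency at every available (timepoint, compartment) sample
#' (zero where absent), the per-comparison class, and the earliest timepoint
#' at which it is significant. A `temporary` flag marks clones whose class
#' returns to unchanged/contracted at the timepoint after they first expand —
#' the transient expansions seen around irAE onset.
#'
#' @param repertoires list of [repertoire()] for one subject (all timepoints
#'   and compartments, baseline included).
#' @param diff_results list of [differential_abundance()] results for the
#'   same subject, each baseline-vs-timepoint.
#' @param timepoint_order ordered timepoint labels.
#' @return Object of class `clone_trajectories`: `frequencies` (long
#'   data.frame key/timepoint/compartment/frequency), `classes` (long
#'   key/timepoint/compartment/class/novel), and `clones` (key,
#'   first_significant_timepoint, temporary).
#' @export
build_trajectories <- function(repertoires, diff_results,
                               timepoint_order = default_timepoint_order()) {
  stopifnot(length(repertoires) >= 1L, length(diff_results) >= 1L)
  subj <- unique(vapply(repertoires, `[[`, character(1), "subject_id"))
  assert_that(length(subj) == 1L, "repertoires span multiple subjects",
              class = "clonodyn_config_error")
  tps <- vapply(repertoires, `[[`, character(1), "timepoint")
  baseline <- timepoint_order[1L]
  assert_that(baseline %in% tps, "baseline timepoint '%s' missing from series",
              baseline, class = "clonodyn_config_error")
  tp_order <- order_timepoints(unique(tps), timepoint_order)

  # clones of interest: novel-expanded in any comparison
  keys <- sort(unique(unlist(lapply(diff_results, function(d)
    d$records$key[d$records$novel]))))
  if (length(keys) == 0L) {
    warning("no novel expansions in any comparison")
  }

  freq <- do.call(rbind, lapply(repertoires, function(r) {
    data.frame(key = keys,
               timepoint = rep(r$timepoint, length(keys)),
               compartment = rep(r$compartment, length(keys)),
               frequency = if (length(keys)) unname(productive_frequency(r, keys)) else numeric(0),
               stringsAsFactors = FALSE)
  }))

  classes <- do.call(rbind, lapply(diff_results, function(d) {
    i <- match(keys, d$records$key)
    data.frame(key = keys,
               timepoint = rep(d$timepoint2, length(keys)),
               compartment = rep(d$compartment, length(keys)),
               class = ifelse(is.na(i), "unchanged", d$records$class[i]),
               novel = ifelse(is.na(i), FALSE, d$records$novel[i]),
               stringsAsFactors = FALSE)
  }))

  first_sig <- vapply(keys, function(k) {
    sig_tp <- classes$timepoint[classes$key == k & classes$class != "unchanged"]
    if (!length(sig_tp)) return(NA_character_)
    order_timepoints(unique(sig_tp), timepoint_order)[1L]
  }, character(1))

  temporary <- vapply(seq_along(keys), function(i) {
    if (is.na(first_sig[i])) return(FALSE)
    later <- tp_order[match(first_sig[i], tp_order) + 1L]
    if (is.na(later)) return(FALSE)
    cls <- classes$class[classes$key == keys[i] & classes$timepoint == later]
    length(cls) > 0L && all(cls != "expanded")
  }, logical(1))

  clones_df <- data.frame(key = keys,
                          first_significant_timepoint = unname(first_sig),
                          temporary = temporary, stringsAsFactors = FALSE)
  rownames(clones_df) <- NULL
  structure(list(subject = subj,
                 frequencies = freq, classes = classes,
                 clones = clones_df,
                 timepoint_order = tp_order),
            class = "clone_trajectories")
}

#' @export
print.clone_trajectories <- function(x, ...) {
  cat(sprintf("<clone_trajectories> %s: %d clone(s) across %s\n", x$subject,
              nrow(x$clones), paste(x$timepoint_order, collapse = " < ")))
  invisible(x)
}

#' Partition significant clones around a clinical event
#'
#' Splits the trajectory clones by `first_significant_timepoint` into those
#' first significant at the event timepoint, strictly before it, and strictly
#' after — the temporal-association summary used to relate novel clonal
#' expansions to irAE onset.
#'
#' @param trajectories a [build_trajectories()] result.
#' @param event_timepoint timepoint label of the clinical event.
#' @param event_label free-text event description (e.g. "hypothyroidism").
#' @param timepoint_order ordered timepoint labels.
#' @return Object of class `event_association` with the three key sets,
#'   `n_preceding`, and the event metadata.
#' @export
event_association <- function(trajectories, event_timepoint, event_label = "",
                              timepoint_order = default_timepoint_order()) {
  stopifnot(inherits(trajectories, "clone_trajectories"))
  assert_that(event_timepoint %in% timepoint_order,
              "unknown event timepoint '%s'", event_timepoint,
              class = "clonodyn_config_error")
  cl <- trajectories$clones[!is.na(trajectories$clones$first_significant_timepoint), ]
  pos <- match(cl$first_significant_timepoint, timepoint_order)
  ev <- match(event_timepoint, timepoint_order)
  novel_at_event <- trajectories$classes
  at_event_keys <- cl$key[pos == ev]
  structure(list(event_label = event_label, event_timepoint = event_timepoint,
                 clones_expanded_at_event = at_event_keys,
                 clones_preceding = cl$key[pos < ev],
                 clones_following = cl$key[pos > ev],
                 n_preceding = sum(pos < ev)),
            class = "event_association")
}

#' @export
print.event_association <- function(x, ...) {
  cat(sprintf("<event_association> %s at %s: %d at event, %d preceding, %d following\n",
              if (nzchar(x$event_label)) x$event_label else "event",
              x$event_timepoint, length(x$clones_expanded_at_event),
              x$n_preceding, length(x$clones_following)))
  invisible(x)
}

#' Blood/marrow concordance of expansion magnitudes
#'
#' For clones significant at timepoint `t` in either compartment, pairs the
#' log2 fold changes observed in bone marrow and peripheral blood and
#' summarizes their agreement with a Spearman rank correlation plus a
#' two-sided permutation p-value (label shuffling, seeded). Spearman is used
#' because fold changes are heavy-tailed.
#'
#' @param diff_bm,diff_pb [differential_abundance()] results for the same
#'   subject and timepoint pair in BM and PB.
#' @param n_perm permutations for the p-value (default 10000).
#' @param seed RNG seed for the permutations.
#' @return list with `pairs` (key, log2_fold_bm, log2_fold_pb), `rho`,
#'   `p_value`, `n`; or reason string when fewer than 3 paired clones exist.
#' @export
compartment_concordance <- function(diff_bm, diff_pb, n_perm = 10000L, seed = 1L) {
  stopifnot(inherits(diff_bm, "diff_abundance"), inherits(diff_pb, "diff_abundance"))
  sig_keys <- union(diff_bm$records$key[diff_bm$records$class != "unchanged"],
                    diff_pb$records$key[diff_pb$records$class != "unchanged"])
  i_bm <- match(sig_keys, diff_bm$records$key)
  i_pb <- match(sig_keys, diff_pb$records$key)
  keep <- !is.na(i_bm) & !is.na(i_pb)
  pairs <- data.frame(key = sig_keys[keep],
                      log2_fold_bm = diff_bm$records$log2_fold[i_bm[keep]],
                      log2_fold_pb = diff_pb$records$log2_fold[i_pb[keep]],
                      stringsAsFactors = FALSE)
  if (nrow(pairs) < 3L) {
    return(structure(list(pairs = pairs, rho = NA_real_, p_value = NA_real_,
                          n = nrow(pairs),
                          reason = "fewer than 3 clones paired across compartments"),
                     class = "compartment_concordance"))
  }
  rho <- cor(pairs$log2_fold_bm, pairs$log2_fold_pb, method = "spearman")
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    cor(pairs$log2_fold_bm, sample(pairs$log2_fold_pb), method = "spearman"),
    numeric(1)))
  p <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
  structure(list(pairs = pairs, rho = rho, p_value = p, n = nrow(pairs),
                 reason = ""),
            class = "compartment_concordance")
}

#' @export
print.compartment_concordance <- function(x, ...) {
  if (nzchar(x$reason %||% "")) {
    cat(sprintf("<compartment_concordance> undefined: %s\n", x$reason))
  } else {
    cat(sprintf("<compartment_concordance> rho = %.3f (n = %d, permutation p = %.4g)\n",
                x$rho, x$n, x$p_value))
  }
  invisible(x)
}
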