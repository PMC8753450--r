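#' Construct a bulk TCRβ repertoire
#'
#' A repertoire is one bulk TCRβ sequencing sample: a table of rearrangements
#' (clones) with template counts, plus the subject / timepoint / compartment
#' metadata axes along which the longitudinal analysis runs. Template counts
#' are the number of input DNA molecules attributed to a rearrangement and are
#' the count datum of every downstream test.
#'
#' Rows with identical clone keys (see [clone_key()]) are aggregated by
#' summing templates; zero-template rows are dropped.
#'
#' @param clones data.frame with columns `cdr3_nt`, `cdr3_aa`, `v_call`,
#'   `j_call`, `templates`, `productive`.
#' @param subject_id,timepoint,compartment sample metadata. `compartment` is
#'   one of `"BM"` (bone marrow), `"PB"` (peripheral blood), `"sortedCD8"`.
#' @return An object of class `repertoire`: the clone table (with a `key`
#'   column) plus `total_templates` and `total_productive_templates`.
#' @examples
#' rep <- repertoire(data.frame(
#'   cdr3_nt = c("TGTGCCAGC", "TGTGCCTGG"), cdr3_aa = c("CAS", "CAW"),
#'   v_call = c("TRBV5-1*01", "TRBV7-2"), j_call = c("TRBJ2-1", "TRBJ1-1"),
#'   templates = c(8L, 2L), productive = c(TRUE, TRUE)))
#' rep$total_templates
#' @export
repertoire <- function(clones, subject_id = "subject", timepoint = "Day0",
                       compartment = c("PB", "BM", "sortedCD8")) {
  compartment <- match.arg(compartment)
  req <- c("cdr3_nt", "cdr3_aa", "v_call", "j_call", "templates", "productive")
  missing_cols <- setdiff(req, names(clones))
  assert_that(length(missing_cols) == 0L,
              "clone table missing column(s): %s", paste(missing_cols, collapse = ", "),
              class = "clonodyn_format_error")
  clones <- as.data.frame(clones)[, req]
  clones$templates <- as.integer(clones$templates)
  clones$productive <- as.logical(clones$productive)
  assert_that(all(clones$templates >= 0L), "negative template count")
  assert_that(all(grepl("^[ACGTN]*$", toupper(clones$cdr3_nt))),
              "cdr3_nt contains characters outside ACGTN")
  clones$cdr3_nt <- toupper(clones$cdr3_nt)
  clones <- clones[clones$templates > 0L, , drop = FALSE]
  clones$key <- clone_key(clones$cdr3_nt, clones$v_call, clones$j_call)
  if (anyDuplicated(clones$key)) {
    agg <- tapply(clones$templates, clones$key, sum)
    first <- clones[!duplicated(clones$key), , drop = FALSE]
    first$templates <- as.integer(agg[first$key])
    clones <- first
  }
  clones <- clones[order(clones$key), , drop = FALSE]
  rownames(clones) <- NULL
  structure(list(
    subject_id = subject_id,
    timepoint = timepoint,
    compartment = compartment,
    clones = clones,
    total_templates = sum(clones$templates),
    total_productive_templates = sum(clones$templates[clones$productive])
  ), class = "repertoire")
}

#' Derive a cross-sample clone key
#'
#' Bulk-vs-bulk comparisons identify a clone by its CDR3 nucleotide sequence
#' plus gene-level V and J calls; allele suffixes (`*01`) are stripped because
#' allele calls are unstable across samples while template counts are
#' rearrangement-level.
#'
#' @param cdr3_nt,v_call,j_call character vectors (recycled together).
#' @return Character vector of deterministic keys.
#' @export
clone_key <- function(cdr3_nt, v_call, j_call) {
  strip <- function(g) sub("\\*.*$", "", g)
  paste(toupper(cdr3_nt), strip(v_call), strip(j_call), sep = "|")
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("<repertoire> %s / %s / %s: %d clones, %d templates (%d productive)\n",
              x$subject_id, x$timepoint, x$compartment, nrow(x$clones),
              x$total_templates, x$total_productive_templates))
  invisible(x)
}

#' Productive frequency of clones in a repertoire
#'
#' The clone's template share among productive (in-frame, stop-codon-free)
#' rearrangements — the frequency scale on which novel expansions are defined
#' (a "novel" expansion starts below 0.1% productive frequency at baseline).
#' Absent keys have frequency 0; unproductive clones have frequency 0 and do
#' not contribute to the denominator.
#'
#' @param rep a [repertoire()].
#' @param keys character vector of clone keys; default all keys in `rep`.
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
productive_frequency <- function(rep, keys = NULL) {
  stopifnot(inherits(rep, "repertoire"))
  assert_that(rep$total_productive_templates > 0L,
              "repertoire has zero productive templates: frequency undefined",
              class = "clonodyn_undefined_error")
  cl <- rep$clones
  if (is.null(keys)) keys <- cl$key
  idx <- match(keys, cl$key)
  f <- ifelse(is.na(idx) | !cl$productive[pmax(idx, 1L)], 0,
              cl$templates[pmax(idx, 1L)] / rep$total_productive_templates)
  f[is.na(idx)] <- 0
  setNames(as.numeric(f), keys)
}
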