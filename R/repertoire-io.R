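# Readers/writers for the tabular formats bulk repertoires live in.
# AIRR Rearrangement TSV is read AND written; the ImmunoSEQ export dialect is
# read-only, through the versioned column map shipped in
# inst/extdata/immunoseq_column_map.tsv.

AIRR_COLUMNS <- c("junction", "junction_aa", "v_call", "j_call",
                  "duplicate_count", "productive")

immunoseq_column_map <- function() {
  path <- system.file("extdata", "immunoseq_column_map.tsv", package = "clonodyn")
  if (!nzchar(path)) {
    path <- file.path("inst", "extdata", "immunoseq_column_map.tsv")
  }
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a bulk repertoire from a rearrangement TSV
#'
#' Supports the AIRR Rearrangement TSV (columns `junction`, `junction_aa`,
#' `v_call`, `j_call`, `duplicate_count`, `productive`) and the ImmunoSEQ
#' export dialect (columns mapped via the versioned table shipped with the
#' package, e.g. `nucleotide` → `junction`, `aminoAcid` → `junction_aa`,
#' `sequenceStatus` → `productive` where `"In"` means productive). Rows with
#' zero templates are dropped and duplicate clone keys aggregated by summing
#' templates.
#'
#' @param path TSV file path.
#' @param dialect `"airr"` or `"immunoseq"`.
#' @param subject_id,timepoint,compartment sample metadata attached to the
#'   returned repertoire.
#' @return A [repertoire()].
#' @export
read_repertoire <- function(path, dialect = c("airr", "immunoseq"),
                            subject_id = "subject", timepoint = "Day0",
                            compartment = "PB") {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), "file not found: %s", path,
              class = "clonodyn_io_error")
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (dialect == "immunoseq") {
    map <- immunoseq_column_map()
    present <- map[map$immunoseq %in% names(df), , drop = FALSE]
    # keep the first mapped source per AIRR target (count column aliases)
    present <- present[!duplicated(present$airr), , drop = FALSE]
    extra <- setdiff(names(df), map$immunoseq)
    if (length(extra)) {
      message("ignoring unmapped ImmunoSEQ column(s): ",
              paste(extra, collapse = ", "))
    }
    df <- df[, present$immunoseq, drop = FALSE]
    names(df) <- present$airr
    if ("productive" %in% names(df)) {
      df$productive <- df$productive %in% c("In", "TRUE", "T", "true")
    }
  }
  missing_cols <- setdiff(AIRR_COLUMNS, names(df))
  assert_that(length(missing_cols) == 0L,
              "missing mandatory column(s): %s", paste(missing_cols, collapse = ", "),
              class = "clonodyn_format_error")
  counts <- suppressWarnings(as.integer(df$duplicate_count))
  bad <- which(is.na(counts) | as.numeric(df$duplicate_count) != counts)
  assert_that(length(bad) == 0L,
              "non-integer template count at data row %s",
              paste(head(bad, 3L), collapse = ", "),
              class = "clonodyn_parse_error")
  if (dialect == "airr" && is.character(df$productive)) {
    df$productive <- toupper(df$productive) %in% c("T", "TRUE")
  }
  repertoire(data.frame(cdr3_nt = df$junction, cdr3_aa = df$junction_aa,
                        v_call = df$v_call, j_call = df$j_call,
                        templates = counts, productive = df$productive,
                        stringsAsFactors = FALSE),
             subject_id = subject_id, timepoint = timepoint,
             compartment = compartment)
}

#' Write a repertoire as an AIRR Rearrangement TSV
#'
#' Round-trip guarantee: `read_repertoire(write_repertoire(rep))` reproduces
#' `rep` clone-by-clone (keys, counts, productive flags).
#'
#' @param rep a [repertoire()].
#' @param path output TSV path.
#' @param dialect only `"airr"` is writable.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(rep, path, dialect = "airr") {
  stopifnot(inherits(rep, "repertoire"))
  assert_that(identical(dialect, "airr"), "only the AIRR dialect is writable",
              class = "clonodyn_io_error")
  cl <- rep$clones
  out <- data.frame(junction = cl$cdr3_nt, junction_aa = cl$cdr3_aa,
                    v_call = cl$v_call, j_call = cl$j_call,
                    duplicate_count = cl$templates,
                    productive = ifelse(cl$productive, "T", "F"),
                    stringsAsFactors = FALSE)
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  assert_that(ok, "cannot write to %s", path, class = "clonodyn_io_error")
  invisible(path)
}
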