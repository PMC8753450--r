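# Orchestration: manifest validation and the end-to-end run on synthetic or
# user data. All stage outputs are plain TSV; a run log records package
# version, seeds and every parameter so no output number is untraceable.

#' Validate a sample manifest
#'
#' A manifest lists the files of a longitudinal experiment, one row per
#' sample: columns `subject`, `timepoint`, `compartment`, `path`,
#' `datatype`. Rows must be unique on (subject, timepoint, compartment,
#' datatype), timepoints must be known labels, and every path must exist.
#' Rows are returned ordered by the configured timepoint order.
#'
#' @param path manifest TSV path.
#' @param timepoint_order ordered timepoint labels.
#' @param check_paths verify listed files exist (default TRUE).
#' @return The validated manifest data.frame.
#' @export
validate_manifest <- function(path, timepoint_order = default_timepoint_order(),
                              check_paths = TRUE) {
  assert_that(file.exists(path), "manifest not found: %s", path,
              class = "clonodyn_io_error")
  m <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("subject", "timepoint", "compartment", "path", "datatype")
  missing_cols <- setdiff(req, names(m))
  assert_that(length(missing_cols) == 0L, "manifest missing column(s): %s",
              paste(missing_cols, collapse = ", "),
              class = "clonodyn_format_error")
  keyv <- do.call(paste, c(m[c("subject", "timepoint", "compartment", "datatype")],
                           sep = "/"))
  dup <- which(duplicated(keyv))
  assert_that(length(dup) == 0L, "duplicate manifest row %s (%s)",
              paste(dup, collapse = ", "),
              paste(keyv[dup], collapse = "; "),
              class = "clonodyn_validation_error")
  unknown <- setdiff(m$timepoint, timepoint_order)
  assert_that(length(unknown) == 0L,
              "unknown timepoint label(s): %s (allowed: %s)",
              paste(unknown, collapse = ", "),
              paste(timepoint_order, collapse = ", "),
              class = "clonodyn_validation_error")
  if (check_paths) {
    gone <- m$path[!file.exists(m$path)]
    assert_that(length(gone) == 0L, "manifest path(s) not found: %s",
                paste(gone, collapse = ", "), class = "clonodyn_io_error")
  }
  m[order(match(m$timepoint, timepoint_order), m$compartment, m$datatype), ,
    drop = FALSE]
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' End-to-end synthetic run of the whole pipeline
#'
#' Simulates a longitudinal bulk repertoire series with spiked expansions and
#' a matched single-cell series, then chains every stage: differential
#' abundance per timepoint against baseline, clone trajectories and event
#' association, ADT gating, bulk-to-single-cell linkage, differential
#' signatures, subset clonality, the subsample overlap curve and the
#' emergent-clone audit. All artifacts are written as TSV under `out_dir`,
#' plus `run_log.txt` with versions, seeds and parameters. Given the same
#' `config` (including seeds) the statistical outputs are byte-identical
#' across runs.
#'
#' @param config named list overriding defaults; honored keys: `seed`,
#'   `n_clones`, `n_templates`, `phi`, `timepoints`, `n_spikes`,
#'   `spike_fold`, `fdr_threshold`, `novel_baseline_max`, `n_cells`,
#'   `overlap_sizes`, `overlap_reps`. May also be a path to a JSON file with
#'   those keys.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with the in-memory stage results (`series`,
#'   `diffs`, `trajectories`, `sc`, `gated`, `overlap`, `audit`).
#' @export
run_all <- function(config = list(), out_dir = tempfile("clonodyn_run_")) {
  if (is.character(config) && length(config) == 1L) {
    assert_that(file.exists(config), "config file not found: %s", config,
                class = "clonodyn_io_error")
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- list(seed = 1L, n_clones = 2000L, n_templates = 2e4, phi = 1e-4,
              timepoints = c("Day0", "EOC2", "EOC4"), n_spikes = 5L,
              spike_fold = 20, fdr_threshold = 0.01,
              novel_baseline_max = 0.001, n_cells = 1500L,
              overlap_sizes = c(100L, 200L, 400L), overlap_reps = 50L)
  cfg[names(config)] <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # stage 1: simulate bulk series with novel spikes at the middle timepoint
  event_tp <- cfg$timepoints[2L]
  spikes <- data.frame(clone = rep(NA_integer_, cfg$n_spikes),
                       fold = cfg$spike_fold, timepoint = event_tp)
  sim <- simulate_repertoire_series(
    n_clones = cfg$n_clones, n_templates = cfg$n_templates, phi = cfg$phi,
    timepoints = cfg$timepoints, spikes = spikes, seed = cfg$seed)
  for (tp in names(sim$repertoires)) {
    write_repertoire(sim$repertoires[[tp]],
                     file.path(out_dir, sprintf("repertoire_%s.tsv", tp)))
  }
  write_tsv(sim$truth$spikes, file.path(out_dir, "truth_spikes.tsv"))

  # stage 2: differential abundance vs baseline
  base_tp <- cfg$timepoints[1L]
  diffs <- lapply(cfg$timepoints[-1L], function(tp) {
    differential_abundance(sim$repertoires[[base_tp]], sim$repertoires[[tp]],
                           null = cfg$phi, fdr_threshold = cfg$fdr_threshold,
                           novel_baseline_max = cfg$novel_baseline_max)
  })
  names(diffs) <- cfg$timepoints[-1L]
  for (tp in names(diffs)) {
    write_tsv(diffs[[tp]]$records, file.path(out_dir, sprintf("diffabund_%s.tsv", tp)))
  }

  # stage 3: trajectories + event association at the spike timepoint
  traj <- build_trajectories(sim$repertoires, diffs,
                             timepoint_order = cfg$timepoints)
  write_tsv(traj$frequencies, file.path(out_dir, "trajectories.tsv"))
  write_tsv(traj$clones, file.path(out_dir, "trajectory_clones.tsv"))
  assoc <- event_association(traj, event_tp, "synthetic event",
                             timepoint_order = cfg$timepoints)

  # stage 4: single-cell layer at the event timepoint, activated = spiked
  sc <- lapply(cfg$timepoints, function(tp) {
    simulate_single_cell(n_cells = cfg$n_cells, bulk = sim$repertoires[[tp]],
                         activated_clone_keys = sim$truth$spikes$key,
                         subject_id = "SYN1", timepoint = tp,
                         seed = cfg$seed + match(tp, cfg$timepoints))
  })
  names(sc) <- cfg$timepoints
  scheme <- auto_gating_scheme(lapply(sc, `[[`, "cells"))
  gated <- lapply(sc, function(s) gate_subsets(s$cells, scheme))
  write_tsv(subset_frequencies(gated[[event_tp]], baseline = gated[[base_tp]]),
            file.path(out_dir, "subset_frequencies.tsv"))
  write_tsv(subset_clonality(gated[[event_tp]]),
            file.path(out_dir, "subset_clonality.tsv"))

  link <- link_bulk_clones(gated[[event_tp]], sim$truth$spikes$key)
  covered <- link$key[!link$under_covered]
  de <- NULL
  if (length(covered)) {
    comp <- top_abundant_comparator(gated[[event_tp]],
                                    sim$repertoires[[event_tp]],
                                    lineage = "CD8", exclude_keys = covered)
    coi_cells <- unique(unlist(link$barcodes[!link$under_covered]))
    comp_cells <- setdiff(comp$barcodes, coi_cells)
    if (length(coi_cells) >= 5L && length(comp_cells) >= 5L) {
      de <- differential_signature(gated[[event_tp]], coi_cells, comp_cells,
                                   features = "genes")
      write_tsv(de, file.path(out_dir, "de_genes.tsv"))
      heat <- clone_mean_matrix(gated[[event_tp]], link[!link$under_covered, ],
                                head(de$feature, 20L))
      write_tsv(data.frame(feature = rownames(heat), heat, check.names = FALSE),
                file.path(out_dir, "heatmap_gene_means.tsv"))
    }
  }

  # stage 5: overlap curve + emergence audit at the event timepoint
  ov <- overlap_curve(gated[[event_tp]], sizes = cfg$overlap_sizes,
                      n_reps = cfg$overlap_reps, seed = cfg$seed)
  write_tsv(as.data.frame(ov), file.path(out_dir, "overlap_curve.tsv"))
  audit <- audit_emergent_clones(gated, event_tp, diffs[[event_tp]],
                                 sim$repertoires[[base_tp]],
                                 novel_baseline_max = cfg$novel_baseline_max)
  write_tsv(as.data.frame(audit), file.path(out_dir, "emergence_audit.tsv"))

  log_lines <- c(
    sprintf("clonodyn %s", as.character(packageVersion("clonodyn"))),
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "parameters:",
    vapply(names(cfg), function(k)
      sprintf("  %s = %s", k, paste(cfg[[k]], collapse = ",")), character(1)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(config = cfg, series = sim, diffs = diffs,
                 trajectories = traj, association = assoc, sc = sc,
                 gated = gated, de = de, overlap = ov, audit = audit,
                 out_dir = out_dir))
}
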