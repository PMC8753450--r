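# A small hand-built longitudinal world: 8 background clones, one clone that
# expands from undetectable only at EOC4, plus one that expands at EOC2.
build_world <- function() {
  bg <- c(6000L, 2500L, 800L, 300L, 200L, 100L, 60L, 40L)
  day0 <- make_rep(bg, timepoint = "Day0")
  eoc2_counts <- c(bg - c(40L, 10L, 0L, 0L, 0L, 0L, 0L, 0L), 50L)   # clone 9 up
  eoc2 <- make_rep(eoc2_counts, timepoint = "EOC2")
  eoc4_counts <- c(bg - c(60L, 20L, 0L, 0L, 0L, 0L, 0L, 0L), 0L, 70L) # 9 gone, 10 up
  eoc4 <- make_rep(eoc4_counts, timepoint = "EOC4")
  reps <- list(Day0 = day0, EOC2 = eoc2, EOC4 = eoc4)
  diffs <- list(differential_abundance(day0, eoc2, null = 0),
                differential_abundance(day0, eoc4, null = 0))
  list(reps = reps, diffs = diffs,
       key9 = setdiff(eoc2$clones$key, day0$clones$key),
       key10 = setdiff(eoc4$clones$key, eoc2$clones$key))
}

test_that("trajectories select novel expansions and date their onset", {
  w <- build_world()
  traj <- build_trajectories(w$reps, w$diffs)
  expect_setequal(traj$clones$key, c(w$key9, w$key10))
  expect_equal(traj$clones$first_significant_timepoint[traj$clones$key == w$key9],
               "EOC2")
  expect_equal(traj$clones$first_significant_timepoint[traj$clones$key == w$key10],
               "EOC4")
  # never-significant background clones are excluded by construction
  expect_false(any(w$reps$Day0$clones$key %in% traj$clones$key))

  # trajectory frequencies equal productive_frequency recomputed from source
  for (tp in names(w$reps)) {
    got <- traj$frequencies[traj$frequencies$timepoint == tp, ]
    expect_equal(got$frequency,
                 unname(productive_frequency(w$reps[[tp]], got$key)))
  }

  # clone 9 contracts after its expansion: flagged temporary
  expect_true(traj$clones$temporary[traj$clones$key == w$key9])

  expect_error(build_trajectories(w$reps[c("EOC2", "EOC4")], w$diffs),
               class = "clonodyn_config_error")
})

test_that("event association partitions clones by onset timepoint", {
  w <- build_world()
  traj <- build_trajectories(w$reps, w$diffs)

  ev4 <- event_association(traj, "EOC4", "hypothyroidism")
  expect_setequal(ev4$clones_expanded_at_event, w$key10)
  expect_equal(ev4$n_preceding, 1L)              # clone 9 expanded at EOC2
  expect_setequal(ev4$clones_preceding, w$key9)

  ev2 <- event_association(traj, "EOC2", "early event")
  expect_equal(ev2$n_preceding, 0L)
  expect_setequal(ev2$clones_following, w$key10)

  # partition is exhaustive and disjoint over significant clones
  all_keys <- c(ev4$clones_expanded_at_event, ev4$clones_preceding,
                ev4$clones_following)
  expect_setequal(all_keys, traj$clones$key)
  expect_equal(anyDuplicated(all_keys), 0L)

  expect_error(event_association(traj, "EOC99"),
               class = "clonodyn_config_error")
})

test_that("spiked synthetic trajectories show rise and decay", {
  dry <- simulate_repertoire_series(n_clones = 1000L, phi = 0,
                                    timepoints = c("Day0", "EOC2", "EOC4"),
                                    seed = 88)
  spikes <- data.frame(clone = NA_integer_, fold = 60, timepoint = "EOC2")
  sim <- simulate_repertoire_series(n_clones = 1000L, phi = 0,
                                    timepoints = c("Day0", "EOC2", "EOC4"),
                                    spikes = spikes, seed = 88)
  diffs <- lapply(c("EOC2", "EOC4"), function(tp)
    differential_abundance(sim$repertoires$Day0, sim$repertoires[[tp]], null = 0))
  traj <- build_trajectories(sim$repertoires, diffs)
  key <- sim$truth$spikes$key
  expect_true(key %in% traj$clones$key)
  f <- traj$frequencies[traj$frequencies$key == key, ]
  f <- setNames(f$frequency, f$timepoint)
  expect_equal(unname(f["Day0"]), 0)                  # novel: absent at baseline
  expect_gt(f["EOC2"], 0.002)                         # ~ 60 * 1e-4 spike
  expect_lt(f["EOC4"], f["EOC2"] / 5)                 # transient, decays
})

test_that("compartment concordance recovers perfect and inverted agreement", {
  base_pb <- make_rep(c(4000L, 2000L, 800L, 400L, 100L), compartment = "PB")
  # same five clones, both compartments expand clones 3-5 identically
  up <- c(0L, 0L, 400L, 300L, 200L)
  foll_pb <- make_rep(c(4000L, 2000L, 800L, 400L, 100L) + up,
                      timepoint = "EOC2", compartment = "PB")
  base_bm <- make_rep(c(4000L, 2000L, 800L, 400L, 100L), compartment = "BM")
  foll_bm <- make_rep(c(4000L, 2000L, 800L, 400L, 100L) + up,
                      timepoint = "EOC2", compartment = "BM")
  d_pb <- differential_abundance(base_pb, foll_pb, null = 0)
  d_bm <- differential_abundance(base_bm, foll_bm, null = 0)
  cc <- compartment_concordance(d_bm, d_pb, n_perm = 500, seed = 3)
  expect_gte(cc$n, 3)
  expect_equal(cc$rho, 1)
  expect_lt(cc$p_value, 0.05)

  # anti-ordered folds: construct the records directly
  fake <- function(folds) {
    structure(list(records = data.frame(
      key = paste0("K", seq_along(folds)), class = "expanded",
      log2_fold = folds, stringsAsFactors = FALSE)), class = "diff_abundance")
  }
  cc2 <- compartment_concordance(fake(1:5), fake(5:1), n_perm = 500, seed = 3)
  expect_equal(cc2$rho, -1)

  # fewer than three paired clones is undefined with a reason
  d_small <- differential_abundance(base_pb, base_pb, null = 0)
  cc3 <- compartment_concordance(d_small, d_small, n_perm = 100, seed = 1)
  expect_true(is.na(cc3$rho))
  expect_match(cc3$reason, "fewer than 3")
})

test_that("permutation p-values are uniform under a shuffled null", {
  # shuffle one compartment's folds so no real association exists
  set.seed(19)
  ps <- replicate(100, {
    x <- rnorm(15); y <- sample(rnorm(15))
    pairs <- data.frame(key = as.character(1:15), log2_fold_bm = x,
                        log2_fold_pb = y)
    rho <- cor(x, y, method = "spearman")
    perm <- vapply(1:400, function(i)
      cor(x, sample(y), method = "spearman"), numeric(1))
    (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / 401
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
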