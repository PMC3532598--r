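# Synthetic data generator: event structure, atlas geometry, signal
# planting, noise model, determinism.

test_that("event tables have the stated session and trial structure", {
  ev <- generate_events(n_sessions = 4, trials_per_session = 30, seed = 1)
  expect_equal(nrow(ev), 120)
  expect_equal(as.vector(table(ev$session)), rep(30, 4))
  # threat balanced within each session
  expect_true(all(table(ev$session, ev$threat) == 15))
  # anticipation durations within [4, 8]; stimulation follows anticipation
  expect_true(all(ev$anticipation_duration >= 4 & ev$anticipation_duration <= 8))
  expect_equal(ev$stimulation_onset,
               ev$anticipation_onset + ev$anticipation_duration)
  # time-ordered and non-overlapping within each session
  for (s in 1:4) {
    e <- ev[ev$session == s, ]
    expect_true(all(diff(e$anticipation_onset) > 0))
    expect_true(all(e$anticipation_onset[-1] >
                      (e$stimulation_onset + e$stimulation_duration)[-nrow(e)]))
  }
  expect_true(all(attr(ev, "session_duration") >=
                    tapply(ev$stimulation_onset + ev$stimulation_duration,
                           ev$session, max)))
})

test_that("degenerate label balance and invalid session counts behave", {
  ev <- generate_events(2, 2, label_balance = 1, seed = 1)
  expect_true(all(ev$label == "pain"))
  ev0 <- generate_events(2, 2, label_balance = 0, seed = 1)
  expect_true(all(ev0$label == "no_pain"))
  expect_error(generate_events(1, 10), "2 sessions")
})

test_that("event generation is deterministic given the seed", {
  a <- generate_events(3, 12, seed = 77)
  b <- generate_events(3, 12, seed = 77)
  expect_identical(a, b)
  c <- generate_events(3, 12, seed = 78)
  expect_false(identical(a, c))
})

test_that("atlas regions are disjoint, nonempty and correctly named", {
  atlas <- generate_atlas(c(24, 24, 24), 26, 2, seed = 1)
  expect_length(atlas$region_names, 28)
  expect_equal(atlas$control_regions, c("HG.L", "HG.R"))
  counts <- table(atlas$labels[atlas$labels > 0])
  expect_length(counts, 28)
  expect_true(all(counts == 27))   # 3^3 blocks
  # disjointness: total labeled voxels equals the sum of per-region counts
  expect_equal(sum(atlas$labels > 0), sum(counts))
  # each name resolves to its own voxel set
  all_idx <- region_voxels(atlas, NULL)
  per <- unlist(lapply(atlas$region_names, function(r) region_voxels(atlas, r)))
  expect_setequal(all_idx, per)
  expect_equal(length(per), length(unique(per)))
})

test_that("single-region atlases and impossible packings are handled", {
  a1 <- generate_atlas(c(6, 6, 6), n_regions = 1, n_control = 0)
  expect_length(a1$region_names, 1)
  expect_gte(sum(a1$labels > 0), 1)
  expect_error(generate_atlas(c(6, 6, 6), 26, 2), "cannot pack")
})

test_that("signal specs reject control regions and invalid noise", {
  atlas <- generate_atlas(c(10, 10, 8), 4, 1)
  expect_error(signal_spec(atlas, regions = "CTRL1", effect_size_mean = 1),
               "control")
  expect_error(signal_spec(atlas, noise_sd = 0), "noise_sd")
  spec <- signal_spec(atlas, c("R01", "R03"), effect_size_mean = 2)
  expect_equal(sum(spec$informative_voxel_mask), 2 * 27)
  expect_true(all(atlas$labels[spec$informative_voxel_mask] %in% c(1, 3)))
})

test_that("subject simulation is bitwise reproducible and honours the null", {
  atlas <- generate_atlas(c(8, 8, 4), 2, 1)
  ev <- generate_events(2, 4, seed = 5)
  null_spec <- signal_spec(atlas, effect_size_mean = 0, effect_size_sd = 0)
  s1 <- simulate_subject(ev, atlas, null_spec, seed = 9)
  s2 <- simulate_subject(ev, atlas, null_spec, seed = 9)
  expect_identical(s1$volumes, s2$volumes)
  expect_identical(s1$truth$effect_size, 0)
  s3 <- simulate_subject(ev, atlas, null_spec, seed = 10)
  expect_false(identical(s1$volumes, s3$volumes))
  # fixed effect size without between-subject spread
  spec <- signal_spec(atlas, "R01", effect_size_mean = 2, effect_size_sd = 0)
  s4 <- simulate_subject(ev, atlas, spec, seed = 9)
  expect_equal(s4$truth$effect_size, 2)
})

test_that("AR(1) and drift parameters are recoverable from noise-only runs", {
  atlas <- generate_atlas(c(8, 8, 4), 2, 1)
  ev <- generate_events(2, 4, seed = 5)
  spec <- signal_spec(atlas, effect_size_mean = 0, noise_sd = 1,
                      ar1_rho = 0.3, drift_amplitude = 0, base_amplitude = 0)
  rhos <- vapply(1:10, function(i) {
    s <- simulate_subject(ev, atlas, spec, seed = 200 + i)
    y <- t(matrix(s$volumes, prod(dim(s$volumes)[1:3]), dim(s$volumes)[4]))
    sess <- rep(seq_along(s$session_n_volumes), s$session_n_volumes)
    ar1_fit_whiten(scale(y, scale = FALSE), sessions = sess)$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 0.3), 0.05)
})

test_that("groups share the atlas and reproduce from the master seed", {
  atlas <- generate_atlas(c(8, 8, 4), 2, 1)
  spec <- signal_spec(atlas, "R01", effect_size_mean = 1, effect_size_sd = 0)
  g1 <- generate_group(2, atlas, spec, n_sessions = 2,
                       trials_per_session = 4, seed = 31)
  g2 <- generate_group(2, atlas, spec, n_sessions = 2,
                       trials_per_session = 4, seed = 31)
  expect_identical(g1$subjects[[1]]$volumes, g2$subjects[[1]]$volumes)
  expect_identical(g1$subjects[[2]]$volumes, g2$subjects[[2]]$volumes)
  expect_identical(g1$subjects[[1]]$atlas, g1$subjects[[2]]$atlas)
  # zero between-subject spread: identical effect sizes
  effs <- vapply(g1$subjects, function(s) s$truth$effect_size, numeric(1))
  expect_equal(effs[1], effs[2])
  expect_error(generate_group(1, atlas, spec), "2 subjects")
})
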