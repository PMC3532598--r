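# Fixtures are generated in code. Toy beta series skip the simulator and GLM
# so classifier-level tests stay fast; simulated fixtures exercise the whole
# chain and are shared across test files via a memoizing cache.

# beta series built directly: V voxels, `informative` columns carry a mean
# difference of `effect` between pain and no-pain trials (both phases)
toy_beta <- function(n_sessions = 2, trials_per_session = 8, V = 12,
                     effect = 0, informative = seq_len(min(4, V)),
                     seed = 1, atlas = NULL, balanced = TRUE) {
  set.seed(seed)
  n <- n_sessions * trials_per_session
  label <- if (balanced)
    as.vector(vapply(seq_len(n_sessions), function(s)
      sample(rep_len(c("pain", "no_pain"), trials_per_session)),
      character(trials_per_session)))
  else sample(c("pain", "no_pain"), n, replace = TRUE)
  meta <- data.frame(
    session = rep(seq_len(n_sessions), each = trials_per_session),
    trial = rep(seq_len(trials_per_session), n_sessions),
    label = label,
    threat = as.vector(vapply(seq_len(n_sessions), function(s)
      sample(rep_len(c("high", "low"), trials_per_session)),
      character(trials_per_session))),
    stringsAsFactors = FALSE)
  mk <- function() {
    x <- matrix(rnorm(n * V), n, V)
    x[, informative] <- x[, informative] +
      effect * ifelse(meta$label == "pain", 0.5, -0.5)
    x
  }
  beta_series(mk(), mk(), meta, subject_id = "toy", atlas = atlas)
}

toy_group <- function(n_subjects = 4, ...) {
  lapply(seq_len(n_subjects), function(i) toy_beta(seed = 100 + i, ...))
}

# one simulated planted-signal group, built once per test run
.fixture_cache <- new.env(parent = emptyenv())

sim_group_fixture <- function() {
  if (is.null(.fixture_cache$group)) {
    cfg <- study_config(n_subjects = 4, n_sessions = 2,
                        trials_per_session = 10, grid_shape = c(10, 10, 8),
                        n_regions = 4, n_control = 1,
                        informative_regions = c("R01", "R02"),
                        effect_size_mean = 40, effect_size_sd = 5,
                        seed = 2024)
    .fixture_cache$group <- simulate_group_betas(cfg)
  }
  .fixture_cache$group
}
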