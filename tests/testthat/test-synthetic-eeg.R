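test_that("zero-spread trajectories are constant at the center frequency", {
  arch <- pattern_archetype("1", df_center = 10, df_spread = 0,
                            band_mixture = c(alpha = 1))
  traj <- generate_df_trajectory(arch, 90, seed = 3)
  expect_equal(traj, rep(10, 90))
})

test_that("an alpha trajectory spanning 8-9.5 Hz stays on the grid inside alpha", {
  arch <- pattern_archetype("1plus", df_center = 8.75, df_spread = 0.75,
                            band_mixture = c(alpha = 1))
  for (seed in 1:5) {
    traj <- generate_df_trajectory(arch, 90, seed = seed)
    expect_equal(min(traj), 8.0)
    expect_equal(max(traj), 9.5)
    expect_true(all(traj >= 8 & traj <= 12))
    expect_true(all(traj * 2 == round(traj * 2)))  # 0.5 Hz grid
  }
})

test_that("band occupancy matches the mixture to within one epoch", {
  arch <- pattern_archetype("2", df_center = 7.5, df_spread = 1.5,
                            band_mixture = c(alpha = 0.45, prealpha = 0.55))
  for (seed in 1:10) {
    traj <- generate_df_trajectory(arch, 90, seed = seed)
    n_alpha <- sum(band_of(traj) == "alpha")
    expect_true(n_alpha >= 40 && n_alpha <= 41)
  }
})

test_that("band occupancy converges to the mixture for long trajectories", {
  for (lab in c("2", "4", "5")) {
    arch <- default_archetypes(lab)
    traj <- generate_df_trajectory(arch, 900, seed = 11)
    occ <- table(factor(band_of(traj), names(arch$band_mixture))) / 900
    expect_true(all(abs(occ - arch$band_mixture) < 0.03),
                label = paste("occupancy, pattern", lab))
  }
})

test_that("trajectories and recordings are deterministic given the seed", {
  arch <- default_archetypes("2")
  expect_identical(generate_df_trajectory(arch, 90, seed = 5),
                   generate_df_trajectory(arch, 90, seed = 5))
  expect_false(identical(generate_df_trajectory(arch, 90, seed = 5),
                         generate_df_trajectory(arch, 90, seed = 6)))
  r1 <- quick_recording("3", seed = 9, duration = 10)
  r2 <- quick_recording("3", seed = 9, duration = 10)
  expect_identical(r1$samples, r2$samples)
})

test_that("invalid archetype configurations are rejected", {
  expect_error(pattern_archetype("7", 10, 0, c(alpha = 1)),
               class = "qeegcsa_config_error")
  expect_error(pattern_archetype("1", 10, 0, c(alpha = 0.5, delta = 0.4)),
               class = "qeegcsa_config_error")  # mixture does not sum to 1
  expect_error(pattern_archetype("1", 3, 0, c(alpha = 1)),
               class = "qeegcsa_config_error")  # center outside top band
  expect_error(default_archetypes("6"), class = "qeegcsa_config_error")
})

test_that("the pattern-5 trajectory never has more than 2 consecutive fast epochs", {
  arch <- default_archetypes("5")
  for (seed in 1:20) {
    traj <- generate_df_trajectory(arch, 90, seed = seed)
    fast <- traj >= 5.5
    r <- rle(fast)
    expect_lte(max(c(0, r$lengths[r$values])), 2)
  }
})

test_that("a pure synthesized tone puts its spectral maximum at the requested DF", {
  arch <- pattern_archetype("1", 10, 0, c(alpha = 1),
                            secondary_power_fraction = 0, noise_level = 0)
  x <- synthesize_epoch(10, arch, n_samples = 2048, fs = 1024, seed = 1)
  sp <- epoch_spectrum(x, 1024)
  expect_equal(dominant_frequency(sp), 10.0)
})

test_that("the pipeline DF estimate recovers the synthesized epoch DF at defaults", {
  arch <- default_archetypes("3")
  x <- synthesize_epoch(6.5, arch, n_samples = 2048, fs = 1024, seed = 2)
  expect_equal(dominant_frequency(epoch_spectrum(x, 1024)), 6.5)
  # a slow pattern-5 epoch lands in the delta-theta range
  arch5 <- default_archetypes("5")
  x5 <- synthesize_epoch(3.0, arch5, n_samples = 2048, fs = 1024, seed = 2)
  expect_true(band_of(dominant_frequency(epoch_spectrum(x5, 1024)))
              %in% c("delta", "theta"))
})

test_that("synthesize_epoch rejects frequencies at or above Nyquist", {
  arch <- default_archetypes("1")
  expect_error(synthesize_epoch(512, arch, 2048, 1024, 1),
               class = "qeegcsa_config_error")
})

test_that("a full-rate 19-channel pattern-1 recording classifies as pattern 1", {
  rec <- synthesize_recording(default_archetypes("1"),
                              channels = montage_10_20(),
                              duration = 240, fs = 1024, seed = 4)
  expect_equal(rec$fs, 1024)
  expect_equal(nrow(rec$samples), 19)
  res <- run_pipeline(list(subj = rec), pipeline_config())
  expect_equal(as.character(res$pattern), "1")
  expect_false(res$abnormal)
})

test_that("pattern-3 recordings have a slow stable dominant frequency", {
  rec <- quick_recording("3", seed = 6)
  d <- analyze_recording(rec, quick_config())$descriptors
  expect_lte(d$df_max, 7.9)
  expect_lt(d$dfv, 1.0)
})

test_that("posterior channels share the generating DF trajectory", {
  rec <- quick_recording("2", seed = 8)
  traj <- attr(rec, "df_trajectory")
  res <- analyze_recording(rec, quick_config())
  expect_equal(res$descriptors$df_per_epoch[[1]], traj[1:90])
})

test_that("degenerate recording lengths are handled", {
  rec <- quick_recording("1", duration = 2)
  eps <- epoch_signal(rec)
  expect_equal(dim(eps$epochs)[3], 1)
  expect_error(select_epochs(eps, 90), class = "qeegcsa_insufficient_data")
  expect_error(synthesize_recording(default_archetypes("1"), channels = character(0)),
               class = "qeegcsa_config_error")
})

test_that("generate_cohort reproduces the requested archetype counts exactly", {
  co <- generate_cohort(mci_cohort_spec(), seed = 2)
  expect_equal(nrow(co), 42)
  expect_false(anyDuplicated(co$subject_id) > 0)
  counts <- dplyr::count(co, group, pattern, .drop = TRUE)
  get <- function(g, p) {
    r <- counts$n[counts$group == g & counts$pattern == p]
    if (length(r) == 0) 0L else r
  }
  expect_equal(get("MCI-DLB", "1plus"), 9L)
  expect_equal(get("MCI-DLB", "2"), 10L)
  expect_equal(get("MCI-DLB", "3"), 1L)
  expect_equal(get("MCI-AD", "1"), 13L)
  expect_equal(get("MCI-AD", "2"), 1L)
  expect_equal(get("MCI-NC", "1"), 5L)
  expect_equal(get("MCI-NC", "1plus"), 2L)
  expect_equal(get("MCI-NC", "2"), 1L)
  # clinical-feature flags per group
  flags <- table(co$group[co$dlb_feature])
  expect_equal(as.integer(flags[c("MCI-DLB", "MCI-NC", "MCI-AD")]),
               c(15L, 2L, 2L))
})

test_that("a one-subject cohort spec yields a one-row table", {
  spec <- cohort_spec(tibble::tibble(group = "MCI-AD", pattern = "1", n = 1))
  co <- generate_cohort(spec, seed = 1)
  expect_equal(nrow(co), 1)
  expect_equal(as.character(co$pattern), "1")
})
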