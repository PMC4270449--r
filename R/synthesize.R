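#' Generate a per-epoch dominant-frequency trajectory
#'
#' Draws one dominant frequency (DF) per 2-s epoch on the 0.5 Hz grid. Band
#' occupancy follows the archetype's `band_mixture` with largest-remainder
#' quantization (empirical counts within one epoch of `mixture * n_epochs`);
#' within a band, values are uniform over the grid points inside the
#' archetype's DF window. Epochs are exchangeable (no serial structure) except
#' when the archetype caps runs of fast (pre-alpha/alpha) epochs, in which
#' case fast epochs are placed into inter-slow slots holding at most
#' `fast_run_cap` each.
#'
#' @param archetype A [pattern_archetype()].
#' @param n_epochs Number of epochs, `>= 2`.
#' @param seed Integer seed; the trajectory is a deterministic function of
#'   `(archetype, n_epochs, seed)`.
#' @return Numeric vector of `n_epochs` dominant frequencies (Hz).
#' @examples
#' generate_df_trajectory(default_archetypes("1plus"), 90, seed = 1)
#' @export
generate_df_trajectory <- function(archetype, n_epochs, seed) {
  stopifnot(inherits(archetype, "pattern_archetype"))
  if (n_epochs < 2) abort("n_epochs must be >= 2", class = "qeegcsa_config_error")
  withr::with_seed(as.integer(seed), {
    mix <- archetype$band_mixture
    counts <- largest_remainder(mix, n_epochs)
    bands_seq <- allocate_bands(counts, archetype$fast_run_cap)
    vals <- vapply(bands_seq, function(b) {
      s <- trajectory_support(archetype, b)
      if (length(s) == 1) s else sample(s, 1)
    }, numeric(1), USE.NAMES = FALSE)
    unname(vals)
  })
}

# Integer allocation of n items to categories proportional to weights,
# exact to within one item per category (largest remainder / Hamilton).
largest_remainder <- function(weights, n) {
  target <- weights / sum(weights) * n
  base <- floor(target)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(target - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

# Random band order; when cap is finite, fast bands (prealpha/alpha) are
# distributed into the slots between slow epochs, at most `cap` per slot, so
# no run of fast epochs exceeds `cap`.
allocate_bands <- function(counts, cap = Inf) {
  fast <- c("prealpha", "alpha")
  seq_all <- rep(names(counts), counts)
  if (!is.finite(cap)) {
    return(sample(seq_all))
  }
  slow <- sample(rep(names(counts)[!names(counts) %in% fast],
                     counts[!names(counts) %in% fast]))
  fast_seq <- sample(rep(names(counts)[names(counts) %in% fast],
                         counts[names(counts) %in% fast]))
  n_slots <- length(slow) + 1
  if (length(fast_seq) > cap * n_slots) {
    abort("fast_run_cap infeasible for this band mixture", class = "qeegcsa_config_error")
  }
  slots <- sort(sample(rep(seq_len(n_slots), cap), length(fast_seq)))
  out <- character(0)
  for (s in seq_len(n_slots)) {
    out <- c(out, fast_seq[slots == s])
    if (s <= length(slow)) out <- c(out, slow[s])
  }
  out
}

#' Synthesize one 2-s EEG epoch
#'
#' Builds a sample vector as a dominant sinusoid at `df`, optional secondary
#' sinusoids in the archetype's other occupied bands (total power
#' `secondary_power_fraction` times the dominant power), and a 1/f background
#' with seeded Gaussian phases scaled to `noise_level` microvolt RMS,
#' band-limited to 0.5--70 Hz.
#'
#' @param df Dominant frequency (Hz), `0 < df < fs/2`.
#' @param archetype A [pattern_archetype()] supplying amplitudes and mixture.
#' @param n_samples Number of samples.
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed.
#' @return Numeric vector of `n_samples` values (microvolt).
#' @export
synthesize_epoch <- function(df, archetype, n_samples, fs, seed) {
  if (df <= 0 || df >= fs / 2) {
    abort(paste0("df (", df, " Hz) must lie in (0, fs/2)"),
          class = "qeegcsa_config_error")
  }
  withr::with_seed(as.integer(seed), {
    phases <- runif(1 + 4, 0, 2 * pi)
    drop(epoch_bank(df, archetype, n_samples, fs,
                    phase = phases[1], gain = 1))
  })
}

# Vectorized epoch synthesis: one column per epoch. `df` is a vector of
# per-epoch dominant frequencies. Returns n_samples x n_epochs matrix.
# Relies on the caller for seeding.
epoch_bank <- function(df, archetype, n_samples, fs, phase = NULL, gain = 1) {
  n_e <- length(df)
  t <- seq(0, by = 1 / fs, length.out = n_samples)
  if (is.null(phase)) phase <- runif(n_e, 0, 2 * pi)
  A <- archetype$amplitude * gain
  sig <- A * sin(outer(t, 2 * pi * df) +
                   matrix(phase, n_samples, n_e, byrow = TRUE))
  # secondary components at fixed representative grid frequencies of the
  # other occupied bands
  spf <- archetype$secondary_power_fraction
  if (spf > 0) {
    reps <- c(delta = 2.5, theta = 4.5, prealpha = 6.5, alpha = 9.5)
    occupied <- names(archetype$band_mixture)[archetype$band_mixture > 0]
    df_band <- band_of(df)
    for (e in seq_len(n_e)) {
      other <- setdiff(occupied, df_band[e])
      if (length(other) == 0) next
      As <- A * sqrt(spf / length(other))
      for (b in other) {
        sig[, e] <- sig[, e] + As * sin(2 * pi * reps[[b]] * t + runif(1, 0, 2 * pi))
      }
    }
  }
  if (archetype$noise_level > 0) {
    sig <- sig + pink_noise(n_samples, n_e, fs, archetype$noise_level)
  }
  sig
}

# 1/f-power background noise, band-limited to 0.5-70 Hz, scaled to the
# requested RMS. Returns n x m matrix (m independent columns).
pink_noise <- function(n, m, fs, rms) {
  freqs <- seq_len(floor(n / 2)) * fs / n
  w <- ifelse(freqs >= 0.5 & freqs <= 70, 1 / sqrt(freqs), 0)
  spec <- matrix(complex(real = rnorm(length(freqs) * m),
                         imaginary = rnorm(length(freqs) * m)),
                 length(freqs), m) * w
  full <- matrix(0 + 0i, n, m)
  full[2:(length(freqs) + 1), ] <- spec
  idx <- n - seq_len(length(freqs) - if (n %% 2 == 0) 1 else 0) + 1
  full[idx, ] <- Conj(spec[seq_along(idx), ])
  x <- Re(mvfft(full, inverse = TRUE)) / n
  cur <- sqrt(colMeans(x^2))
  cur[cur == 0] <- 1
  sweep(x, 2, rms / cur, "*")
}

#' Synthesize a multichannel EEG recording
#'
#' Posterior channels (Pz, P3, P4, O1, O2) share one DF trajectory, with
#' independent per-channel phases, small gain jitter and independent
#' background noise; all other channels carry attenuated versions of the same
#' rhythm. Epochs are synthesized on the same 2-s boundaries that
#' [epoch_signal()] later uses.
#'
#' @param archetype A [pattern_archetype()].
#' @param channels Character vector of channel labels (default: 19-channel
#'   10-20 montage).
#' @param duration Recording length in seconds, `>= 2`.
#' @param fs Sampling rate (Hz), default 1024.
#' @param seed Integer seed.
#' @param n_artifacts Number of epochs to contaminate with a 500 microvolt
#'   rectangular transient (default 0); contaminated epoch indices are stored
#'   in the `artifact_epochs` attribute.
#' @return An `eeg_recording`: list with `samples` (channels x time matrix,
#'   microvolt), `fs`, `channel_labels`, `duration`, plus attributes
#'   `df_trajectory` (the generating truth) and `archetype_label`.
#' @export
synthesize_recording <- function(archetype,
                                 channels = montage_10_20(),
                                 duration = 240,
                                 fs = 1024,
                                 seed = 1,
                                 n_artifacts = 0) {
  stopifnot(inherits(archetype, "pattern_archetype"))
  if (length(channels) == 0) abort("channel list is empty", class = "qeegcsa_config_error")
  if (anyDuplicated(channels)) abort("channel labels must be unique", class = "qeegcsa_config_error")
  if (duration < 2) abort("duration must be >= 2 s", class = "qeegcsa_config_error")
  epoch_len <- 2
  n_epochs <- max(2L, as.integer(ceiling(duration / epoch_len)))
  traj <- generate_df_trajectory(archetype, n_epochs, seed)
  n_per <- round(epoch_len * fs)
  n_total <- round(duration * fs)
  samples <- withr::with_seed(as.integer(seed) + 1L, {
    m <- matrix(0, length(channels), n_total)
    for (ci in seq_along(channels)) {
      post <- channels[ci] %in% posterior_region()
      gain <- (if (post) 1 else 0.4) * exp(rnorm(1, 0, 0.05))
      bank <- epoch_bank(traj, archetype, n_per, fs, phase = NULL, gain = gain)
      m[ci, ] <- c(bank)[seq_len(n_total)]
    }
    if (n_artifacts > 0) {
      art <- sort(sample(seq_len(n_epochs), n_artifacts))
      for (e in art) {
        i0 <- (e - 1) * n_per + 1
        i1 <- min(i0 + round(0.2 * fs) - 1, n_total)
        if (i0 <= n_total) m[, i0:i1] <- m[, i0:i1] + 500
      }
      attr(m, "artifact_epochs") <- art
    }
    m
  })
  art <- attr(samples, "artifact_epochs")
  attr(samples, "artifact_epochs") <- NULL
  structure(
    list(samples = samples, fs = fs, channel_labels = channels,
         duration = duration),
    df_trajectory = traj,
    archetype_label = archetype$label,
    artifact_epochs = art,
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording>", length(x$channel_labels), "channels,",
      x$duration, "s at", x$fs, "Hz\n")
  lab <- attr(x, "archetype_label")
  if (!is.null(lab)) cat("  synthetic, pattern", lab, "archetype\n")
  invisible(x)
}

#' Specify a synthetic cohort
#'
#' @param groups Tibble/data frame with columns `group`, `pattern`, `n`:
#'   number of subjects of each observed outcome group carrying each CSA
#'   pattern archetype.
#' @param flags Optional tibble with columns `group`, `n_flagged`: number of
#'   subjects per group presenting a core or suggestive DLB clinical feature
#'   at admission.
#' @return A `cohort_spec` object.
#' @seealso [mci_cohort_spec()] for the built-in 42-subject MCI cohort.
#' @export
cohort_spec <- function(groups, flags = NULL) {
  groups <- as_tibble(groups)
  stopifnot(all(c("group", "pattern", "n") %in% names(groups)))
  if (any(groups$n <= 0)) abort("counts must be > 0", class = "qeegcsa_config_error")
  if (!all(as.character(groups$pattern) %in% PATTERN_LEVELS)) {
    abort("unknown pattern label in cohort spec", class = "qeegcsa_config_error")
  }
  structure(list(groups = groups, flags = flags), class = "cohort_spec")
}

#' The 42-subject MCI cohort specification
#'
#' Onset CSA-pattern composition of the three MCI outcome groups: MCI-DLB
#' (n = 20): 9 pattern 1plus, 10 pattern 2, 1 pattern 3; MCI-AD (n = 14):
#' 13 pattern 1, 1 pattern 2; MCI-NC (n = 8): 5 pattern 1, 2 pattern 1plus,
#' 1 pattern 2. Clinical DLB-feature flags: 15 / 2 / 2 subjects in
#' MCI-DLB / MCI-NC / MCI-AD.
#'
#' @return A [cohort_spec()].
#' @export
mci_cohort_spec <- function() {
  cohort_spec(
    groups = tibble(
      group = c("MCI-DLB", "MCI-DLB", "MCI-DLB",
                "MCI-AD", "MCI-AD",
                "MCI-NC", "MCI-NC", "MCI-NC"),
      pattern = c("1plus", "2", "3", "1", "2", "1", "1plus", "2"),
      n = c(9, 10, 1, 13, 1, 5, 2, 1)
    ),
    flags = tibble(
      group = c("MCI-DLB", "MCI-NC", "MCI-AD"),
      n_flagged = c(15, 2, 2)
    )
  )
}

#' Generate a cohort truth table
#'
#' Expands a [cohort_spec()] into one row per subject with the assigned
#' pattern archetype, its nominal DF/DFV, the observed outcome group, and the
#' clinical DLB-feature flag. Archetype counts per group match the spec
#' exactly; flag-positive subjects are assigned to the later-listed (more
#' affected) patterns within each group first.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (used only for subject-order shuffling within
#'   groups; counts are deterministic).
#' @param archetypes Named list of archetypes, by pattern label.
#' @return A tibble with columns `subject_id`, `group`, `pattern`,
#'   `df_nominal`, `dfv_nominal`, `dlb_feature`.
#' @examples
#' generate_cohort(mci_cohort_spec(), seed = 1)
#' @export
generate_cohort <- function(spec, seed = 1, archetypes = default_archetypes()) {
  stopifnot(inherits(spec, "cohort_spec"))
  rows <- spec$groups
  tab <- tibble(
    group = rep(rows$group, rows$n),
    pattern = rep(as.character(rows$pattern), rows$n)
  )
  nominal <- purrr::map(PATTERN_LEVELS, function(p) {
    if (p %in% names(archetypes)) archetype_nominal(archetypes[[p]]) else
      tibble(df_nominal = NA_real_, dfv_nominal = NA_real_)
  })
  names(nominal) <- PATTERN_LEVELS
  tab <- dplyr::bind_cols(tab, purrr::list_rbind(nominal[tab$pattern]))
  tab$dlb_feature <- FALSE
  if (!is.null(spec$flags)) {
    for (i in seq_len(nrow(spec$flags))) {
      g <- spec$flags$group[i]
      k <- spec$flags$n_flagged[i]
      idx <- rev(which(tab$group == g))[seq_len(min(k, sum(tab$group == g)))]
      tab$dlb_feature[idx] <- TRUE
    }
  }
  tab <- withr::with_seed(as.integer(seed), tab[sample(nrow(tab)), ])
  tab$subject_id <- sprintf("S%03d", seq_len(nrow(tab)))
  tab$pattern <- factor(tab$pattern, levels = PATTERN_LEVELS)
  dplyr::select(tab, "subject_id", "group", "pattern",
                "df_nominal", "dfv_nominal", "dlb_feature")
}
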