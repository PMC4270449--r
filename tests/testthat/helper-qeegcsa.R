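# Shared fixtures: compact synthetic recordings (posterior montage, 256 Hz,
# 180 s -> exactly 90 analysis epochs) keep the suite fast; frequency content
# below 70 Hz is identical to the full-rate default.

quick_config <- function(fs = 256, ...) pipeline_config(fs = fs, ...)

quick_recording <- function(label, seed = 1, duration = 180, fs = 256,
                            channels = posterior_region(), ...) {
  synthesize_recording(default_archetypes(label), channels = channels,
                       duration = duration, fs = fs, seed = seed, ...)
}

# Wrap a bare channels x samples matrix as a recording.
make_recording <- function(samples, fs, labels = paste0("ch", seq_len(nrow(samples)))) {
  structure(
    list(samples = samples, fs = fs, channel_labels = labels,
         duration = ncol(samples) / fs),
    class = "eeg_recording"
  )
}

# Hand-built CSA matrix from an epochs x bins power matrix on the 0.5 Hz grid.
make_csa <- function(power, freqs = seq(0.5, 70, by = 0.5), label = "test") {
  qeegcsa:::new_csa(power, freqs, label)
}

# A full descriptor row with overridable fields, for classifier tests.
make_desc <- function(...) {
  d <- tibble::tibble(
    df_mean = 9.5, df_mps = 9.5, df_min = 9.5, df_max = 9.5,
    dfv = 0, dfv_alpha = 0,
    fp_delta = 0, fp_theta = 0, fp_prealpha = 0, fp_alpha = 100,
    bi_delta = 0, bi_theta = 0, bi_prealpha = 0, bi_alpha = 100,
    freq_ratio = 10, max_fast_run = 90L, n_epochs = 90L
  )
  over <- list(...)
  for (nm in names(over)) d[[nm]] <- over[[nm]]
  d
}
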