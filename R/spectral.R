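#' Cut a recording into consecutive 2-s epochs
#'
#' @param recording An `eeg_recording`.
#' @param epoch_length Epoch length in seconds (default 2).
#' @return An `epoch_set`: list with `epochs` (channels x samples x epochs
#'   array), `artifact_flags` (logical per epoch, all `FALSE`), `fs`,
#'   `channel_labels`. Non-overlapping consecutive epochs; a trailing partial
#'   segment is discarded.
#' @export
epoch_signal <- function(recording, epoch_length = 2) {
  stopifnot(inherits(recording, "eeg_recording"))
  n_per <- round(epoch_length * recording$fs)
  n_total <- ncol(recording$samples)
  n_epochs <- n_total %/% n_per
  if (n_epochs < 1) {
    abort(paste0("recording duration (", n_total / recording$fs,
                 " s) is shorter than one epoch (", epoch_length, " s)"),
          class = "qeegcsa_input_error")
  }
  n_ch <- nrow(recording$samples)
  arr <- array(recording$samples[, seq_len(n_epochs * n_per)],
               dim = c(n_ch, n_per, n_epochs))
  structure(
    list(epochs = arr,
         artifact_flags = rep(FALSE, n_epochs),
         fs = recording$fs,
         channel_labels = recording$channel_labels),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set>", dim(x$epochs)[3], "epochs x", dim(x$epochs)[1],
      "channels,", dim(x$epochs)[2] / x$fs, "s each;",
      sum(x$artifact_flags), "flagged\n")
  invisible(x)
}

#' Flag artifact-contaminated epochs
#'
#' An epoch is flagged when its peak absolute amplitude on any channel
#' exceeds `amplitude_limit`. Flag-only: no epochs are deleted.
#'
#' @param epochs An `epoch_set`.
#' @param amplitude_limit Peak amplitude limit in microvolt, `> 0`
#'   (default 100).
#' @return The `epoch_set` with updated `artifact_flags`.
#' @export
reject_artifacts <- function(epochs, amplitude_limit = 100) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (amplitude_limit <= 0) {
    abort("amplitude_limit must be > 0", class = "qeegcsa_config_error")
  }
  peak <- apply(abs(epochs$epochs), 3, max)
  epochs$artifact_flags <- epochs$artifact_flags | (peak > amplitude_limit)
  epochs
}

#' Select the analysis epochs
#'
#' Returns the first `n` artifact-free epochs in temporal order (90 epochs
#' are analyzed per subject by default).
#'
#' @param epochs An `epoch_set`.
#' @param n Number of clean epochs to keep (default 90).
#' @return An `epoch_set` of exactly `n` unflagged epochs.
#' @export
select_epochs <- function(epochs, n = 90) {
  stopifnot(inherits(epochs, "epoch_set"))
  clean <- which(!epochs$artifact_flags)
  if (length(clean) < n) {
    abort(
      paste0("insufficient clean data: ", length(clean),
             " artifact-free epochs available, ", n, " required"),
      class = "qeegcsa_insufficient_data",
      available = length(clean)
    )
  }
  keep <- clean[seq_len(n)]
  epochs$epochs <- epochs$epochs[, , keep, drop = FALSE]
  epochs$artifact_flags <- epochs$artifact_flags[keep]
  epochs
}

#' Power spectrum of a single epoch
#'
#' Hann-windowed periodogram with power correction, so that the summed bin
#' powers equal the epoch's mean square amplitude (Parseval, within window
#' effects). Output is restricted to the 0.5--70 Hz analysis range; bin
#' spacing is `1 / epoch_length` (0.5 Hz for the standard 2-s epoch).
#'
#' @param x Numeric sample vector of one epoch (microvolt).
#' @param fs Sampling rate (Hz).
#' @return Named numeric vector of bin powers (microvolt^2); names are bin
#'   center frequencies in Hz.
#' @export
epoch_spectrum <- function(x, fs) {
  m <- epoch_spectra(matrix(x, ncol = 1), fs)
  stats::setNames(m[1, ], colnames(m))
}

# Batched periodogram: columns of `x` are epochs; returns epochs x bins
# matrix with frequency column names.
epoch_spectra <- function(x, fs) {
  n <- nrow(x)
  if (n < 2) abort("epoch too short", class = "qeegcsa_input_error")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)  # periodic Hann
  X <- mvfft(x * w)
  k <- seq_len(floor(n / 2))
  freqs <- k * fs / n
  scale <- 2 / (n * sum(w^2))
  p <- t(Mod(X[k + 1, , drop = FALSE])^2 * scale)
  if (n %% 2 == 0) p[, length(k)] <- p[, length(k)] / 2  # Nyquist not doubled
  keep <- freqs >= 0.5 & freqs <= 70
  p <- p[, keep, drop = FALSE]
  colnames(p) <- format(freqs[keep], trim = TRUE)
  attr(p, "freqs") <- freqs[keep]
  p
}

#' Build a compressed spectral array
#'
#' Computes per-epoch power spectra for the selected epochs of each channel,
#' checking the 0.5 Hz frequency-resolution contract.
#'
#' @param epochs An `epoch_set` (typically after [select_epochs()]).
#' @param channel Single channel label, or `NULL` to return a per-channel
#'   list.
#' @return A `csa_matrix` (epochs x frequency-bins power matrix, microvolt^2,
#'   with attributes `freqs` and `channel`), or a named list of them.
#' @export
build_csa <- function(epochs, channel = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_e <- dim(epochs$epochs)[3]
  if (n_e < 1) abort("no epochs", class = "qeegcsa_input_error")
  one <- function(ci) {
    x <- matrix(epochs$epochs[ci, , ], ncol = n_e)
    p <- epoch_spectra(x, epochs$fs)
    new_csa(p, attr(p, "freqs"), epochs$channel_labels[ci])
  }
  if (!is.null(channel)) {
    ci <- match(channel, epochs$channel_labels)
    if (is.na(ci)) {
      abort(paste0("channel '", channel, "' not present"),
            class = "qeegcsa_input_error")
    }
    return(one(ci))
  }
  out <- lapply(seq_along(epochs$channel_labels), one)
  names(out) <- epochs$channel_labels
  out
}

new_csa <- function(power, freqs, label) {
  stopifnot(all(power >= -1e-12))
  structure(unclass(power), freqs = freqs, channel = label,
            class = c("csa_matrix", "matrix"))
}

#' @export
print.csa_matrix <- function(x, ...) {
  cat("<csa_matrix>", attr(x, "channel"), ":", nrow(x), "epochs x",
      ncol(x), "bins (", min(attr(x, "freqs")), "-", max(attr(x, "freqs")),
      "Hz, step", diff(attr(x, "freqs"))[1], "Hz )\n")
  invisible(x)
}

#' @method as_tibble csa_matrix
#' @export
as_tibble.csa_matrix <- function(x, ...) {
  tibble(
    epoch = rep(seq_len(nrow(x)), times = ncol(x)),
    freq = rep(attr(x, "freqs"), each = nrow(x)),
    power = c(unclass(x))
  )
}

#' Average CSA matrices over a scalp region
#'
#' Per-epoch, per-bin arithmetic mean of the member channels' power (the
#' posterior region Pz, P3, P4, O1, O2 drives classification).
#'
#' @param spectra Named list of `csa_matrix` objects, by channel.
#' @param region Character vector of channel labels (default posterior).
#' @return A single `csa_matrix` labelled with the region.
#' @export
region_average <- function(spectra, region = posterior_region()) {
  missing <- setdiff(region, names(spectra))
  if (length(missing) > 0) {
    abort(paste0("region channel(s) missing from spectra: ",
                 paste(missing, collapse = ", ")),
          class = "qeegcsa_input_error")
  }
  acc <- Reduce(`+`, lapply(spectra[region], unclass)) / length(region)
  new_csa(acc, attr(spectra[[region[1]]], "freqs"),
          paste(region, collapse = "+"))
}

#' Mean power spectrum and relative band powers
#'
#' The mean power spectrum (mPS) is the per-bin mean over epochs. Relative
#' band powers are each band's share (percent) of the summed mPS over the
#' four bands, and are additionally reported log10-transformed.
#'
#' @param csa A `csa_matrix`.
#' @param bands Band scheme.
#' @return A `csa_mps`: list with `power` (named per-bin means), `freqs`,
#'   `band_power` (microvolt^2 per band), `relative` (percent, sums to 100),
#'   `log_relative`.
#' @export
mean_power_spectrum <- function(csa, bands = band_scheme()) {
  stopifnot(inherits(csa, "csa_matrix"))
  if (nrow(csa) < 1) abort("empty CSA", class = "qeegcsa_input_error")
  freqs <- attr(csa, "freqs")
  mps <- colMeans(unclass(csa))
  bf <- band_of(freqs, bands)
  band_power <- vapply(bands$band, function(b) sum(mps[!is.na(bf) & bf == b]),
                       numeric(1))
  total <- sum(band_power)
  relative <- if (total > 0) 100 * band_power / total else band_power * NA
  structure(
    list(power = mps, freqs = freqs, band_power = band_power,
         relative = relative, log_relative = log10(relative)),
    class = "csa_mps"
  )
}

#' @export
print.csa_mps <- function(x, ...) {
  cat("<csa_mps> relative band power (%):\n")
  print(round(x$relative, 2))
  invisible(x)
}
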