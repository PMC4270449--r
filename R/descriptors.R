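#' Dominant frequency of a spectrum
#'
#' The bin-center frequency at which spectral power is maximal within the
#' search band (1--12 Hz by default, the range the pattern rules read). Ties
#' are broken toward the lowest frequency.
#'
#' @param spectrum Named numeric vector of bin powers, or a `csa_matrix` row.
#' @param freqs Bin center frequencies; taken from names if missing.
#' @param search_band Length-2 numeric, inclusive search range in Hz.
#' @return Dominant frequency in Hz.
#' @export
dominant_frequency <- function(spectrum, freqs = NULL, search_band = c(1, 12)) {
  if (is.null(freqs)) freqs <- as.numeric(names(spectrum))
  keep <- freqs >= search_band[1] & freqs <= search_band[2]
  if (!any(keep)) abort("empty spectrum over search band", class = "qeegcsa_input_error")
  p <- spectrum[keep]
  f <- freqs[keep]
  if (all(p <= 0)) {
    abort("all-zero spectrum over search band: dominant frequency undefined",
          class = "qeegcsa_undefined_df")
  }
  f[which.max(p)]  # which.max returns the first (lowest-frequency) maximum
}

# Per-epoch DFs of a CSA matrix.
csa_dominant_frequencies <- function(csa, search_band = c(1, 12)) {
  freqs <- attr(csa, "freqs")
  keep <- freqs >= search_band[1] & freqs <= search_band[2]
  sub <- unclass(csa)[, keep, drop = FALSE]
  if (any(rowSums(sub > 0) == 0)) {
    abort("epoch with all-zero spectrum over search band",
          class = "qeegcsa_undefined_df")
  }
  freqs[keep][max.col(sub, ties.method = "first")]
}

#' Dominant-frequency variability
#'
#' Dispersion of the per-epoch dominant frequencies. The default estimator is
#' the range width (max minus min), the reading under which a DF trajectory
#' varying between 8 and 9.5 Hz has a variability of 1.5 Hz; standard
#' deviation and mean absolute successive difference are selectable
#' alternatives (never mixed within a run).
#'
#' @param df_per_epoch Numeric vector of per-epoch DFs, length `>= 2`.
#' @param estimator One of `"range_width"`, `"sd"`, `"successive_mean"`.
#' @return DFV in Hz.
#' @examples
#' df_variability(c(8, 8.5, 9, 9.5))                       # 1.5
#' df_variability(c(8, 8.5, 9, 9.5), "successive_mean")    # 0.5
#' @export
df_variability <- function(df_per_epoch,
                           estimator = c("range_width", "sd", "successive_mean")) {
  estimator <- match.arg(estimator)
  if (length(df_per_epoch) < 2) {
    abort("at least 2 epochs required for DFV", class = "qeegcsa_input_error")
  }
  switch(estimator,
    range_width = max(df_per_epoch) - min(df_per_epoch),
    sd = stats::sd(df_per_epoch),
    successive_mean = mean(abs(diff(df_per_epoch)))
  )
}

#' Frequency prevalence
#'
#' Percentage of epochs whose dominant frequency falls in each band.
#'
#' @param df_per_epoch Numeric vector of per-epoch DFs.
#' @param bands Band scheme.
#' @return Named numeric vector of percentages (one per band); sums to 100
#'   when every DF lies in \[1, 12\] Hz.
#' @export
frequency_prevalence <- function(df_per_epoch, bands = band_scheme()) {
  if (length(df_per_epoch) < 1) abort("no epochs", class = "qeegcsa_input_error")
  b <- band_of(df_per_epoch, bands)
  vapply(bands$band, function(bb) 100 * sum(!is.na(b) & b == bb) / length(b),
         numeric(1))
}

#' Band inscription
#'
#' Percentage of epochs containing, within each band, at least one strict
#' local spectral maximum whose power exceeds that epoch's noise reference.
#' The noise reference is the epoch's mean power over the 1--12 Hz analysis
#' band — the simplest reproducible surrogate for the mean amplitude of
#' random (noise) peaks.
#'
#' @param csa A `csa_matrix`.
#' @param bands Band scheme.
#' @return Named numeric vector of per-band percentages (each in
#'   \[0, 100\]; no sum constraint).
#' @export
band_inscription <- function(csa, bands = band_scheme()) {
  stopifnot(inherits(csa, "csa_matrix"))
  freqs <- attr(csa, "freqs")
  keep <- freqs >= 1 & freqs <= 12
  p <- unclass(csa)[, keep, drop = FALSE]
  f <- freqs[keep]
  n_e <- nrow(p)
  nb <- ncol(p)
  # strict local maxima on the grid (edges count against one neighbour)
  left <- cbind(-Inf, p[, -nb, drop = FALSE])
  right <- cbind(p[, -1, drop = FALSE], -Inf)
  is_peak <- p > left & p > right
  ref <- rowMeans(p)
  supra <- is_peak & (p > ref)
  bf <- band_of(f, bands)
  vapply(bands$band, function(bb) {
    cols <- which(!is.na(bf) & bf == bb)
    100 * sum(rowSums(supra[, cols, drop = FALSE]) > 0) / n_e
  }, numeric(1))
}

#' Frequency ratio
#'
#' Power of the dominant fast band (alpha when FP-alpha >= FP-pre-alpha,
#' otherwise pre-alpha) divided by the summed power of all slower bands, from
#' the mean power spectrum. With equal band powers the alpha-led ratio is
#' 1/3 (alpha versus delta + theta + pre-alpha).
#'
#' @param mps A `csa_mps` from [mean_power_spectrum()].
#' @param fp Named frequency-prevalence vector (decides the fast band).
#' @return Ratio (unitless); 0 when the fast band carries no power.
#' @export
frequency_ratio <- function(mps, fp) {
  stopifnot(inherits(mps, "csa_mps"))
  bp <- mps$band_power
  fast <- if (fp[["alpha"]] >= fp[["prealpha"]]) "alpha" else "prealpha"
  slower <- if (fast == "alpha") c("delta", "theta", "prealpha") else c("delta", "theta")
  denom <- sum(bp[slower])
  if (denom <= 0) abort("zero power in slower bands: frequency ratio undefined",
                        class = "qeegcsa_input_error")
  unname(bp[fast] / denom)
}

# Longest run of consecutive epochs whose DF is pre-alpha or alpha (>= 5.5
# Hz); the pattern-5 rule reads this.
max_fast_run <- function(df_per_epoch) {
  fast <- df_per_epoch >= 5.5
  if (!any(fast)) return(0L)
  r <- rle(fast)
  max(r$lengths[r$values])
}

#' Compute the six CSA descriptors
#'
#' Summarizes a (region-averaged) CSA matrix into the descriptor set the
#' pattern classifier reads: dominant frequency (mean of epoch DFs and DF of
#' the mPS), DF range, DF variability (all epochs, and over alpha-dominant
#' epochs only), frequency prevalence, band inscription, and the frequency
#' ratio.
#'
#' @param csa A `csa_matrix` of the selected analysis epochs.
#' @param bands Band scheme.
#' @param dfv_estimator DFV estimator, see [df_variability()].
#' @return A one-row tibble (class `csa_descriptors`) with columns `df_mean`,
#'   `df_mps`, `df_min`, `df_max`, `dfv`, `dfv_alpha` (`NA` when no epoch is
#'   alpha-dominant), `fp_delta`, `fp_theta`, `fp_prealpha`, `fp_alpha`,
#'   `bi_delta`, `bi_theta`, `bi_prealpha`, `bi_alpha`, `freq_ratio`,
#'   `max_fast_run`, `n_epochs`, and a `df_per_epoch` list column.
#' @export
csa_describe <- function(csa, bands = band_scheme(),
                         dfv_estimator = c("range_width", "sd", "successive_mean")) {
  dfv_estimator <- match.arg(dfv_estimator)
  dfs <- csa_dominant_frequencies(csa)
  mps <- mean_power_spectrum(csa, bands)
  fp <- frequency_prevalence(dfs, bands)
  bi <- band_inscription(csa, bands)
  alpha_dfs <- dfs[band_of(dfs, bands) %in% "alpha"]
  dfv_alpha <- if (length(alpha_dfs) >= 2) {
    df_variability(alpha_dfs, dfv_estimator)
  } else if (length(alpha_dfs) == 1) 0 else NA_real_
  out <- tibble(
    df_mean = mean(dfs),
    df_mps = dominant_frequency(mps$power, mps$freqs),
    df_min = min(dfs),
    df_max = max(dfs),
    dfv = df_variability(dfs, dfv_estimator),
    dfv_alpha = dfv_alpha,
    fp_delta = fp[["delta"]], fp_theta = fp[["theta"]],
    fp_prealpha = fp[["prealpha"]], fp_alpha = fp[["alpha"]],
    bi_delta = bi[["delta"]], bi_theta = bi[["theta"]],
    bi_prealpha = bi[["prealpha"]], bi_alpha = bi[["alpha"]],
    freq_ratio = frequency_ratio_or_zero(mps, fp),
    max_fast_run = max_fast_run(dfs),
    n_epochs = length(dfs),
    df_per_epoch = list(dfs)
  )
  class(out) <- c("csa_descriptors", class(out))
  out
}

# As frequency_ratio() but total in degenerate spectra: a zero-power fast
# band yields 0, a zero-power slow denominator yields Inf (classification
# does not read the ratio, so describe() stays total).
frequency_ratio_or_zero <- function(mps, fp) {
  bp <- mps$band_power
  fast <- if (fp[["alpha"]] >= fp[["prealpha"]]) "alpha" else "prealpha"
  if (bp[[fast]] <= 0) return(0)
  slower <- if (fast == "alpha") c("delta", "theta", "prealpha") else c("delta", "theta")
  if (sum(bp[slower]) <= 0) return(Inf)
  frequency_ratio(mps, fp)
}
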