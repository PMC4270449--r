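PATTERN_LEVELS <- c("1", "1plus", "2", "3", "4", "5")

#' Construct a CSA pattern archetype
#'
#' An archetype parameterizes the synthetic-EEG generator for one of the six
#' CSA patterns: where the per-epoch dominant frequency (DF) lives
#' (`df_center`, `df_spread`), how epochs distribute over the four frequency
#' bands (`band_mixture`), how much power secondary (non-dominant) spectral
#' components carry, and the RMS level of the 1/f background.
#'
#' @param label Pattern label, one of `"1"`, `"1plus"`, `"2"`, `"3"`, `"4"`,
#'   `"5"`.
#' @param df_center Center of the DF trajectory (Hz). Must lie inside the band
#'   with the highest mixture probability.
#' @param df_spread Half-width of the DF window (Hz), `>= 0`. Per-epoch DFs are
#'   drawn uniformly from the 0.5 Hz grid points inside
#'   `[df_center - df_spread, df_center + df_spread]` intersected with the
#'   epoch's band.
#' @param band_mixture Named numeric vector of per-band probabilities
#'   (`delta`, `theta`, `prealpha`, `alpha`) that an epoch's DF falls in that
#'   band; must sum to 1.
#' @param secondary_power_fraction Power of non-dominant band components as a
#'   fraction of the dominant component's power, in `[0, 1)`.
#' @param noise_level RMS amplitude of the 1/f background (microvolt).
#' @param amplitude Peak amplitude of the dominant sinusoid (microvolt).
#' @param fast_run_cap Maximum allowed number of consecutive epochs with a
#'   pre-alpha or alpha DF (`Inf` = unconstrained). The pattern-5 archetype
#'   uses 2, realizing "no alpha/pre-alpha dominant activity in more than 2
#'   subsequent epochs".
#' @return An object of class `pattern_archetype`.
#' @seealso [default_archetypes()] for the six built-in archetypes.
#' @export
pattern_archetype <- function(label,
                              df_center,
                              df_spread,
                              band_mixture,
                              secondary_power_fraction = 0,
                              noise_level = 5,
                              amplitude = 30,
                              fast_run_cap = Inf) {
  label <- as.character(label)
  if (!label %in% PATTERN_LEVELS) {
    abort(paste0(
      "Invalid pattern label '", label, "'; must be one of ",
      paste(PATTERN_LEVELS, collapse = ", ")
    ), class = "qeegcsa_config_error")
  }
  bands <- band_scheme()
  mix <- rep(0, nrow(bands))
  names(mix) <- bands$band
  if (is.null(names(band_mixture)) || !all(names(band_mixture) %in% bands$band)) {
    abort("band_mixture must be named with band names (delta, theta, prealpha, alpha)",
          class = "qeegcsa_config_error")
  }
  mix[names(band_mixture)] <- band_mixture
  if (abs(sum(mix) - 1) > 1e-8) {
    abort("band_mixture entries must sum to 1", class = "qeegcsa_config_error")
  }
  if (df_spread < 0) abort("df_spread must be >= 0", class = "qeegcsa_config_error")
  top_band <- names(mix)[which.max(mix)]
  if (!identical(band_of(df_center), top_band)) {
    abort(paste0(
      "df_center (", df_center, " Hz) must lie inside the band with highest ",
      "mixture probability (", top_band, ")"
    ), class = "qeegcsa_config_error")
  }
  if (secondary_power_fraction < 0 || secondary_power_fraction >= 1) {
    abort("secondary_power_fraction must be in [0, 1)", class = "qeegcsa_config_error")
  }
  structure(
    list(
      label = label,
      df_center = df_center,
      df_spread = df_spread,
      band_mixture = mix,
      secondary_power_fraction = secondary_power_fraction,
      noise_level = noise_level,
      amplitude = amplitude,
      fast_run_cap = fast_run_cap
    ),
    class = "pattern_archetype"
  )
}

#' @export
print.pattern_archetype <- function(x, ...) {
  cat("<pattern_archetype> pattern", x$label, "\n")
  cat("  DF center", x$df_center, "Hz, spread", x$df_spread, "Hz\n")
  mix <- x$band_mixture[x$band_mixture > 0]
  cat("  band mixture:", paste(names(mix), sprintf("%.2f", mix), collapse = ", "), "\n")
  cat("  secondary power fraction", x$secondary_power_fraction,
      "| noise", x$noise_level, "uV RMS | amplitude", x$amplitude, "uV\n")
  invisible(x)
}

#' Built-in archetypes for the six CSA patterns
#'
#' Default generator settings for each pattern, chosen so that recordings
#' synthesized from an archetype satisfy the corresponding classification
#' rule:
#'
#' * `1` stable alpha: constant DF at 9.5 Hz.
#' * `1plus` unstable alpha: DF uniform over 8.5--10.5 Hz (range-width DFV
#'   2.0 Hz), all epochs alpha-dominant.
#' * `2` unstable alpha with pre-alpha: 45% alpha / 55% pre-alpha epochs,
#'   DF over 6--9 Hz.
#' * `3` stable pre-alpha: constant DF at 6.5 Hz.
#' * `4` unstable pre-alpha with theta/delta: 50% pre-alpha, 30% theta,
#'   20% delta.
#' * `5` unstable low frequency: mostly delta/theta with occasional pre-alpha
#'   epochs never exceeding 2 in a row.
#'
#' @param label Optional single pattern label; if given, that archetype alone
#'   is returned.
#' @return A named list of `pattern_archetype` objects (or a single one).
#' @examples
#' default_archetypes("3")
#' @export
default_archetypes <- function(label = NULL) {
  arch <- list(
    "1" = pattern_archetype("1", 9.5, 0.25, c(alpha = 1)),
    "1plus" = pattern_archetype("1plus", 9.5, 1, c(alpha = 1)),
    "2" = pattern_archetype("2", 7.5, 1.5, c(alpha = 0.45, prealpha = 0.55),
                            secondary_power_fraction = 0.2),
    "3" = pattern_archetype("3", 6.5, 0.25, c(prealpha = 1)),
    "4" = pattern_archetype("4", 6, 4.5,
                            c(prealpha = 0.5, theta = 0.3, delta = 0.2),
                            secondary_power_fraction = 0.2),
    "5" = pattern_archetype("5", 2.5, 5,
                            c(delta = 0.55, theta = 0.35, prealpha = 0.1),
                            secondary_power_fraction = 0.1,
                            fast_run_cap = 2)
  )
  if (is.null(label)) return(arch)
  label <- as.character(label)
  if (!label %in% names(arch)) {
    abort(paste0("Unknown archetype label '", label, "'"),
          class = "qeegcsa_config_error")
  }
  arch[[label]]
}

#' Nominal descriptor values implied by an archetype
#'
#' The expected dominant frequency and the range-width DF variability of the
#' archetype's trajectory distribution, used to populate cohort truth tables
#' without synthesizing signals.
#'
#' @param archetype A `pattern_archetype`.
#' @return A one-row tibble with `df_nominal` and `dfv_nominal` (Hz).
#' @export
archetype_nominal <- function(archetype) {
  stopifnot(inherits(archetype, "pattern_archetype"))
  mix <- archetype$band_mixture
  vals <- lapply(names(mix)[mix > 0], function(b) trajectory_support(archetype, b))
  means <- vapply(vals, mean, numeric(1))
  lo <- min(vapply(vals, min, numeric(1)))
  hi <- max(vapply(vals, max, numeric(1)))
  tibble(
    df_nominal = sum(mix[mix > 0] * means),
    dfv_nominal = hi - lo
  )
}

# Grid values an epoch in `band` can take under `archetype`: band grid
# intersected with the DF window, falling back to the full band grid when the
# window misses the band entirely.
trajectory_support <- function(archetype, band) {
  g <- band_grid(band)
  win <- g[g >= archetype$df_center - archetype$df_spread &
           g <= archetype$df_center + archetype$df_spread]
  if (length(win) == 0) g else win
}
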