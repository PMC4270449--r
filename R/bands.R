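#' Frequency-band scheme for CSA analysis
#'
#' The four-band partition of the 1--12 Hz analysis range used throughout the
#' pipeline: delta \[1, 4), theta \[4, 5.5), pre-alpha (fast theta) \[5.5, 8)
#' and alpha \[8, 12\]. Bands are half-open at the top except alpha, so that on
#' the 0.5 Hz frequency grid 7.5 Hz and below is pre-alpha or slower while
#' 8.0 Hz is alpha (a dominant frequency \eqn{\le} 7.9 Hz marks pre-alpha).
#'
#' @return A tibble with columns `band` (delta, theta, prealpha, alpha),
#'   `lower` and `upper` (Hz).
#' @examples
#' band_scheme()
#' @export
band_scheme <- function() {
  tibble(
    band  = c("delta", "theta", "prealpha", "alpha"),
    lower = c(1, 4, 5.5, 8),
    upper = c(4, 5.5, 8, 12)
  )
}

#' Assign frequencies to bands
#'
#' @param freq Numeric vector of frequencies (Hz).
#' @param bands Band scheme, as returned by [band_scheme()].
#' @return Character vector of band names; `NA` outside \[1, 12\] Hz.
#' @examples
#' band_of(c(2, 4, 5.5, 7.9, 8, 12, 13))
#' @export
band_of <- function(freq, bands = band_scheme()) {
  out <- rep(NA_character_, length(freq))
  for (i in seq_len(nrow(bands))) {
    hit <- freq >= bands$lower[i] & freq < bands$upper[i]
    out[!is.na(hit) & hit] <- bands$band[i]
  }
  # alpha is closed at the top
  top <- max(bands$upper)
  out[!is.na(freq) & freq == top] <- bands$band[nrow(bands)]
  out
}

#' Grid frequencies belonging to one band
#'
#' @param band Band name.
#' @param bands Band scheme.
#' @param step Grid spacing in Hz.
#' @return Numeric vector of 0.5 Hz grid frequencies inside the band.
#' @keywords internal
band_grid <- function(band, bands = band_scheme(), step = 0.5) {
  lo <- min(bands$lower)
  hi <- max(bands$upper)
  grid <- seq(lo, hi, by = step)
  grid[band_of(grid, bands) == band]
}

# Posterior derivations of the 10-20 montage driving classification.
POSTERIOR_CHANNELS <- c("Pz", "P3", "P4", "O1", "O2")

# Full 19-channel 10-20 montage.
MONTAGE_10_20 <- c(
  "Fp1", "Fp2", "Fz", "F3", "F4", "F7", "F8",
  "Cz", "C3", "C4", "Pz", "P3", "P4",
  "T3", "T4", "T5", "T6", "O1", "O2"
)

#' Standard 10-20 montage and posterior region
#'
#' @return Character vector of channel labels.
#' @export
montage_10_20 <- function() MONTAGE_10_20

#' @rdname montage_10_20
#' @export
posterior_region <- function() POSTERIOR_CHANNELS
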