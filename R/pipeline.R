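#' Pipeline configuration
#'
#' Collects the analysis parameters; the defaults are the standard
#' acquisition/analysis settings (2-s epochs, 90 analyzed epochs, 1024 Hz,
#' posterior region, range-width DFV, 100 microvolt artifact limit).
#'
#' @param epoch_length Epoch length in seconds.
#' @param n_epochs Number of artifact-free epochs analyzed per subject.
#' @param fs Expected sampling rate in Hz (informative; the recording's own
#'   rate is used).
#' @param bands Band scheme tibble.
#' @param region Channel labels averaged before descriptor computation.
#' @param dfv_estimator DFV estimator, see [df_variability()].
#' @param amplitude_limit Artifact peak-amplitude limit (microvolt).
#' @param seed Integer seed recorded in the run manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(epoch_length = 2,
                            n_epochs = 90,
                            fs = 1024,
                            bands = band_scheme(),
                            region = posterior_region(),
                            dfv_estimator = "range_width",
                            amplitude_limit = 100,
                            seed = NULL) {
  if (epoch_length <= 0 || n_epochs < 2 || amplitude_limit <= 0) {
    abort("invalid pipeline configuration", class = "qeegcsa_config_error")
  }
  dfv_estimator <- match.arg(dfv_estimator,
                             c("range_width", "sd", "successive_mean"))
  structure(
    list(epoch_length = epoch_length, n_epochs = n_epochs, fs = fs,
         bands = bands, region = region, dfv_estimator = dfv_estimator,
         amplitude_limit = amplitude_limit, seed = seed),
    class = "pipeline_config"
  )
}

#' Analyze one recording into a region CSA and its descriptors
#'
#' Epochs the recording, flags artifacts, selects the first `n_epochs` clean
#' epochs, computes per-channel spectra, averages the configured region, and
#' derives the CSA descriptors.
#'
#' @param recording An `eeg_recording` (or a file path readable by
#'   [read_recording()]).
#' @param config A [pipeline_config()].
#' @return A list with `csa` (region `csa_matrix`), `mps`, and `descriptors`
#'   (one-row tibble).
#' @export
analyze_recording <- function(recording, config = pipeline_config()) {
  if (is.character(recording)) recording <- read_recording(recording)
  missing <- setdiff(config$region, recording$channel_labels)
  if (length(missing) > 0) {
    abort(paste0("recording lacks region channel(s): ",
                 paste(missing, collapse = ", ")),
          class = "qeegcsa_input_error")
  }
  eps <- epoch_signal(recording, config$epoch_length)
  eps <- reject_artifacts(eps, config$amplitude_limit)
  eps <- select_epochs(eps, config$n_epochs)
  # spectra only needed for the region channels
  keep <- match(config$region, eps$channel_labels)
  eps_region <- eps
  eps_region$epochs <- eps$epochs[keep, , , drop = FALSE]
  eps_region$channel_labels <- eps$channel_labels[keep]
  spectra <- build_csa(eps_region)
  csa <- region_average(spectra, config$region)
  desc <- csa_describe(csa, config$bands, config$dfv_estimator)
  list(csa = csa,
       mps = mean_power_spectrum(csa, config$bands),
       descriptors = desc)
}

#' Run the full per-subject pipeline
#'
#' For each input recording: epoch, reject artifacts, select the analysis
#' epochs, compute spectra, average the posterior region, build the CSA,
#' derive descriptors, classify the pattern, flag abnormality, and predict
#' the dementia outcome. Per-subject failures are logged as warnings and the
#' subject is skipped.
#'
#' @param recordings Named list of `eeg_recording` objects and/or file paths;
#'   names become subject ids.
#' @param config A [pipeline_config()].
#' @return A tibble, one row per successfully analyzed subject, with the
#'   descriptor columns plus `pattern`, `rule_id`, `fallback`, `abnormal`,
#'   `predicted_group`. The effective configuration and failures are attached
#'   as the `manifest` attribute.
#' @export
run_pipeline <- function(recordings, config = pipeline_config()) {
  if (length(recordings) == 0) {
    abort("empty input set", class = "qeegcsa_input_error")
  }
  ids <- names(recordings) %||% paste0("S", seq_along(recordings))
  ids[ids == ""] <- paste0("S", which(ids == ""))
  failures <- character(0)
  rows <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    res <- tryCatch({
      out <- analyze_recording(recordings[[i]], config)
      d <- out$descriptors
      d$subject_id <- ids[i]
      d$region <- paste(config$region, collapse = "+")
      d
    }, error = function(e) {
      warn(paste0("subject '", ids[i], "' failed: ", conditionMessage(e)))
      NULL
    })
    if (is.null(res)) failures <- c(failures, ids[i]) else rows[[i]] <- res
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    abort("all subjects failed", class = "qeegcsa_input_error")
  }
  out <- classify_pattern(dplyr::bind_rows(rows))
  out$abnormal <- is_abnormal(out)
  out$predicted_group <- predict_outcome(out$pattern)
  out <- dplyr::relocate(out, "subject_id", "region", "pattern", "abnormal",
                         "predicted_group", "rule_id", "fallback")
  attr(out, "manifest") <- list(
    config = unclass(config)[setdiff(names(config), "bands")],
    bands = as.data.frame(config$bands),
    n_input = length(recordings),
    failed = failures,
    package_version = as.character(utils::packageVersion("qeegcsa"))
  )
  out
}
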