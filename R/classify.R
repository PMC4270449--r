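#' Classify CSA descriptors into the six EEG patterns
#'
#' Applies the rule-based pattern definitions, in order of decreasing
#' specificity, to each row of a descriptor table:
#'
#' 1. **Pattern 1** (stable alpha): mean DF >= 8 Hz, FP-alpha >= 60%,
#'    DFV of alpha-dominant epochs < 0.6 Hz, DFV of all epochs < 1.6 Hz,
#'    BI of each slow band (pre-alpha, theta, delta) < 30%.
#' 2. **Pattern 3** (stable pre-alpha): no alpha-dominant epoch,
#'    FP-pre-alpha >= 70%, DF range inside 5.6--7.9 Hz, DFV < 1.0 Hz.
#' 3. **Pattern 1plus** (unstable alpha): every epoch alpha-dominant
#'    (FP-alpha = 100%) with DFV >= 1.5 Hz.
#' 4. **Pattern 2** (unstable alpha with pre-alpha/theta): alpha dominant in
#'    some but fewer than 50% of epochs, DFV > 2 Hz, FP-pre-alpha > 40%.
#' 5. **Pattern 5** (unstable low frequency): no alpha-dominant epoch, no
#'    more than 2 consecutive pre-alpha/alpha-dominant epochs, DFV > 4 Hz.
#' 6. **Pattern 4** (unstable pre-alpha with theta/delta): no alpha-dominant
#'    epoch, pre-alpha dominant in some but fewer than 70% of epochs,
#'    theta/delta dominant in >= 40%, DFV > 2 Hz.
#'
#' Pattern 5 is tested before pattern 4 because its run-length clause is the
#' more specific of the two and every low-frequency recording with occasional
#' pre-alpha epochs also satisfies the pattern-4 thresholds. Descriptor sets
#' that fire no rule receive a label from a monotone fallback interpolation
#' of the printed thresholds (tagged `fallback = TRUE`): alpha-dominant
#' recordings go to 1/1plus (FP-alpha >= 60%, split at DFV 1.5 Hz) or 2
#' (0 < FP-alpha < 60%); alpha-absent recordings go to 3 (FP-pre-alpha >=
#' 70%), 5 (fast runs <= 2 or DFV > 4 Hz), else 4. The function is total:
#' every descriptor set receives exactly one label.
#'
#' @param desc A `csa_descriptors` tibble (one or more rows) with at least
#'   `df_mean`, `dfv`, `dfv_alpha`, `fp_*`, `bi_*`, `max_fast_run`.
#' @param trace If `TRUE`, attach a `rule_trace` list column recording every
#'   rule evaluated, in order, and whether it fired.
#' @return The input tibble with added columns `pattern` (factor with levels
#'   1, 1plus, 2, 3, 4, 5), `rule_id`, `fallback`.
#' @export
classify_pattern <- function(desc, trace = FALSE) {
  desc <- as_tibble(desc)
  need <- c("df_mean", "dfv", "dfv_alpha", "fp_delta", "fp_theta",
            "fp_prealpha", "fp_alpha", "bi_delta", "bi_theta", "bi_prealpha",
            "max_fast_run")
  missing <- setdiff(need, names(desc))
  if (length(missing) > 0) {
    abort(paste0("descriptor column(s) missing: ", paste(missing, collapse = ", ")),
          class = "qeegcsa_input_error")
  }
  rules <- rule_table()
  fired <- matrix(FALSE, nrow(desc), nrow(rules))
  for (i in seq_len(nrow(rules))) {
    f <- rules$test[[i]](desc)
    fired[, i] <- !is.na(f) & f
  }
  first <- apply(fired, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  out <- desc
  out$pattern <- factor(rules$label[first], levels = PATTERN_LEVELS)
  out$rule_id <- rules$id[first]
  out$fallback <- rules$fallback[first]
  if (anyNA(first)) {
    # unreachable by construction (the fallback chain is exhaustive), kept as
    # a guard for malformed descriptor values
    bad <- which(is.na(first))
    out$pattern[bad] <- factor("4", levels = PATTERN_LEVELS)
    out$rule_id[bad] <- "FB_DEFAULT"
    out$fallback[bad] <- TRUE
  }
  if (trace) {
    out$rule_trace <- lapply(seq_len(nrow(desc)), function(r) {
      upto <- if (is.na(first[r])) nrow(rules) else first[r]
      tibble(rule = rules$id[seq_len(upto)],
             fired = fired[r, seq_len(upto)])
    })
  }
  out
}

# Ordered rule set: verbatim pattern definitions first (decreasing
# specificity), then the exhaustive fallback chain.
rule_table <- function() {
  tibble(
    id = c("P1", "P3", "P1PLUS", "P2", "P5", "P4",
           "FB_ALPHA_STABLE", "FB_ALPHA_UNSTABLE", "FB_ALPHA_MIXED",
           "FB_PREALPHA_STABLE", "FB_LOW_FREQ", "FB_SLOW_MIXED"),
    label = c("1", "3", "1plus", "2", "5", "4",
              "1", "1plus", "2", "3", "5", "4"),
    fallback = rep(c(FALSE, TRUE), c(6, 6)),
    test = list(
      function(d) d$df_mean >= 8 & d$fp_alpha >= 60 &
        !is.na(d$dfv_alpha) & d$dfv_alpha < 0.6 & d$dfv < 1.6 &
        d$bi_prealpha < 30 & d$bi_theta < 30 & d$bi_delta < 30,
      function(d) d$fp_alpha == 0 & d$fp_prealpha >= 70 &
        d$df_min >= 5.6 & d$df_max <= 7.9 & d$dfv < 1.0,
      function(d) d$fp_alpha == 100 & d$dfv >= 1.5,
      function(d) d$fp_alpha > 0 & d$fp_alpha < 50 & d$dfv > 2 &
        d$fp_prealpha > 40,
      function(d) d$fp_alpha == 0 & d$max_fast_run <= 2 & d$dfv > 4,
      function(d) d$fp_alpha == 0 & d$fp_prealpha > 0 & d$fp_prealpha < 70 &
        (d$fp_theta + d$fp_delta) >= 40 & d$dfv > 2,
      function(d) d$fp_alpha >= 60 & d$dfv < 1.5,
      function(d) d$fp_alpha >= 60 & d$dfv >= 1.5,
      function(d) d$fp_alpha > 0,
      function(d) d$fp_prealpha >= 70,
      function(d) d$max_fast_run <= 2 | d$dfv > 4,
      function(d) rep(TRUE, nrow(d))
    )
  )
}

#' Abnormal-EEG flag
#'
#' An EEG is abnormal when its CSA pattern differs from 1 and either the mean
#' epoch dominant frequency is below 8.0 Hz or the DF variability exceeds
#' 1.5 Hz. Pattern-1 recordings are never abnormal.
#'
#' @param desc Descriptor tibble with `df_mean` and `dfv`.
#' @param pattern Pattern labels (vector, recycled); defaults to
#'   `desc$pattern` if present.
#' @return Logical vector.
#' @export
is_abnormal <- function(desc, pattern = NULL) {
  pattern <- pattern %||% desc$pattern
  if (is.null(pattern)) {
    abort("pattern labels required (classify first)", class = "qeegcsa_input_error")
  }
  as.character(pattern) != "1" & (desc$df_mean < 8.0 | desc$dfv > 1.5)
}

#' Predict dementia outcome from the CSA pattern
#'
#' Pattern 1 at the MCI stage predicts conversion to Alzheimer's disease;
#' any other pattern (1plus, 2, 3, 4, 5) predicts conversion to dementia
#' with Lewy bodies. Non-conversion is never predicted.
#'
#' @param pattern Vector of pattern labels.
#' @return Character vector, `"AD-like"` or `"DLB-like"`.
#' @export
predict_outcome <- function(pattern) {
  p <- as.character(pattern)
  bad <- !p %in% PATTERN_LEVELS
  if (any(bad)) {
    abort(paste0("unknown pattern label(s): ", paste(unique(p[bad]), collapse = ", ")),
          class = "qeegcsa_input_error")
  }
  ifelse(p == "1", "AD-like", "DLB-like")
}
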