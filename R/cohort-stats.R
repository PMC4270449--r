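#' Confusion summary of observed versus predicted groups
#'
#' Cross-tabulates observed against predicted class labels and reports
#' per-class and overall correct-classification percentages (diagonal over
#' row sum, and summed diagonal over total).
#'
#' @param observed,predicted Equal-length label vectors.
#' @param classes Class order for rows and columns; every label must appear
#'   in it.
#' @return A `csa_confusion`: list with `matrix` (observed x predicted
#'   counts), `per_class_correct` (%), `overall_correct` (%). Percentages are
#'   unrounded; [tidy()] / [glance()] report them rounded to one decimal in
#'   the style of a predictive-value table.
#' @export
confusion <- function(observed, predicted,
                      classes = c("MCI-DLB", "MCI-NC", "MCI-AD")) {
  observed <- as.character(observed)
  predicted <- as.character(predicted)
  if (length(observed) != length(predicted)) {
    abort("observed and predicted must have equal length", class = "qeegcsa_input_error")
  }
  stray <- setdiff(unique(c(observed, predicted)), classes)
  if (length(stray) > 0) {
    abort(paste0("label(s) outside class order: ", paste(stray, collapse = ", ")),
          class = "qeegcsa_input_error")
  }
  m <- table(factor(observed, classes), factor(predicted, classes))
  m <- matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m))
  rs <- rowSums(m)
  per_class <- ifelse(rs > 0, 100 * diag(m) / rs, NA_real_)
  structure(
    list(matrix = m,
         per_class_correct = per_class,
         overall_correct = 100 * sum(diag(m)) / sum(m)),
    class = "csa_confusion"
  )
}

#' @export
print.csa_confusion <- function(x, ...) {
  cat("<csa_confusion>\n")
  m <- cbind(x$matrix, `correct %` = round(x$per_class_correct, 1))
  print(m)
  cat("overall correct:", round(x$overall_correct, 1), "%\n")
  invisible(x)
}

#' @method tidy csa_confusion
#' @export
tidy.csa_confusion <- function(x, ...) {
  m <- x$matrix
  out <- as_tibble(as.data.frame.table(m, responseName = "n"))
  names(out) <- c("observed", "predicted", "n")
  out$observed <- as.character(out$observed)
  out$predicted <- as.character(out$predicted)
  correct <- tibble(observed = rownames(m),
                    correct_pct = round(x$per_class_correct, 1))
  dplyr::left_join(out, correct, by = "observed")
}

#' @method glance csa_confusion
#' @export
glance.csa_confusion <- function(x, ...) {
  tibble(n = sum(x$matrix),
         overall_correct = round(x$overall_correct, 1))
}

#' EEG-pattern outcome predictor over a cohort
#'
#' Maps each subject's onset CSA pattern through [predict_outcome()]:
#' AD-like becomes `MCI-AD`, DLB-like becomes `MCI-DLB`. `MCI-NC` is never
#' predicted.
#'
#' @param cohort Cohort tibble with a `pattern` column.
#' @return Character vector of predicted groups.
#' @export
eeg_predictor <- function(cohort) {
  if (!"pattern" %in% names(cohort) || anyNA(cohort$pattern)) {
    abort("cohort must carry an onset pattern for every subject",
          class = "qeegcsa_input_error")
  }
  ifelse(predict_outcome(cohort$pattern) == "AD-like", "MCI-AD", "MCI-DLB")
}

#' Clinical-feature outcome predictor over a cohort
#'
#' Subjects presenting a core or suggestive DLB clinical feature at
#' admission are predicted `MCI-DLB`, all others `MCI-AD`.
#'
#' @param cohort Cohort tibble with a logical `dlb_feature` column.
#' @return Character vector of predicted groups.
#' @export
clinical_predictor <- function(cohort) {
  if (!"dlb_feature" %in% names(cohort) || anyNA(cohort$dlb_feature)) {
    abort("cohort must carry the DLB clinical-feature flag for every subject",
          class = "qeegcsa_input_error")
  }
  ifelse(cohort$dlb_feature, "MCI-DLB", "MCI-AD")
}

#' Conversion rate of abnormal-EEG subjects
#'
#' Among subjects whose EEG is abnormal (pattern different from 1 with
#' either DF < 8.0 Hz or DFV > 1.5 Hz), the fraction observed to convert to
#' DLB.
#'
#' @param cohort Cohort tibble with columns `group`, `pattern`, and DF/DFV
#'   columns (`df_mean`/`dfv`, or nominal `df_nominal`/`dfv_nominal` from
#'   [generate_cohort()]).
#' @return The fraction (0--1); errors when no subject has an abnormal EEG.
#' @export
abnormal_eeg_conversion_rate <- function(cohort) {
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(cohort)) return(cohort[[nm]])
    NULL
  }
  df <- pick("df_mean", "df_nominal")
  dfv <- pick("dfv", "dfv_nominal")
  if (is.null(df) || is.null(dfv)) {
    abort("cohort must carry DF and DFV columns", class = "qeegcsa_input_error")
  }
  abn <- is_abnormal(tibble(df_mean = df, dfv = dfv), cohort$pattern)
  if (!any(abn)) {
    abort("no abnormal-EEG subjects: conversion rate undefined",
          class = "qeegcsa_undefined_rate")
  }
  sum(abn & cohort$group == "MCI-DLB") / sum(abn)
}

#' Group comparison statistics
#'
#' One-way ANOVA with Bonferroni-adjusted pairwise comparisons, checked with
#' the Kruskal-Wallis statistic — the supporting statistics for comparing a
#' descriptor (e.g. DFV) across outcome groups.
#'
#' @param data Data frame.
#' @param value,group Column names (strings) of the response and grouping
#'   variable.
#' @return A one-row tibble with `f_statistic`, `anova_p`, `kruskal_statistic`,
#'   `kruskal_p`, and a `pairwise` list column of Bonferroni-adjusted
#'   pairwise p-values.
#' @export
compare_groups <- function(data, value, group) {
  g <- factor(data[[group]])
  v <- data[[value]]
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    abort("need >= 2 groups with >= 2 observations each",
          class = "qeegcsa_input_error")
  }
  a <- summary(aov(v ~ g))[[1]]
  kw <- kruskal.test(v, g)
  pw <- pairwise.t.test(v, g, p.adjust.method = "bonferroni")
  tibble(
    f_statistic = a$`F value`[1],
    anova_p = a$`Pr(>F)`[1],
    kruskal_statistic = unname(kw$statistic),
    kruskal_p = kw$p.value,
    pairwise = list(pw$p.value)
  )
}

#' Spearman rank correlation
#'
#' @param x,y Paired numeric vectors.
#' @return A one-row tibble with `rho` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Fisher exact test for a 2x2 table
#'
#' @param tab 2x2 contingency matrix.
#' @return A one-row tibble with `odds_ratio` and `p_value`.
#' @export
fisher_2x2 <- function(tab) {
  ft <- fisher.test(tab)
  tibble(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}
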