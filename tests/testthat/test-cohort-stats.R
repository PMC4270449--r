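test_that("confusion counts are exact and percentages follow the definitions", {
  obs <- c("MCI-DLB", "MCI-DLB", "MCI-AD", "MCI-NC")
  cm <- confusion(obs, obs)
  expect_equal(unname(cm$per_class_correct[c("MCI-DLB", "MCI-AD")]), c(100, 100))
  expect_equal(cm$overall_correct, 100)
  expect_error(confusion(obs, c(obs[-1], "other")), class = "qeegcsa_input_error")
  expect_error(confusion(obs, obs[-1]), class = "qeegcsa_input_error")
})

test_that("random label sets match a brute-force recount oracle", {
  classes <- c("MCI-DLB", "MCI-NC", "MCI-AD")
  withr::with_seed(42, {
    obs <- sample(classes, 1000, replace = TRUE)
    pred <- sample(classes, 1000, replace = TRUE)
  })
  cm <- confusion(obs, pred, classes)
  for (a in classes) for (b in classes) {
    expect_equal(cm$matrix[a, b], sum(obs == a & pred == b))
  }
  expect_equal(cm$overall_correct, 100 * sum(obs == pred) / 1000)
  # permutation stability
  perm <- withr::with_seed(1, sample(1000))
  cm2 <- confusion(obs[perm], pred[perm], classes)
  expect_equal(cm2$matrix, cm$matrix)
})

test_that("the EEG-pattern predictor reproduces the onset-cohort predictive values", {
  co <- generate_cohort(mci_cohort_spec(), seed = 3)
  pred <- eeg_predictor(co)
  expect_false(any(pred == "MCI-NC"))
  cm <- confusion(co$group, pred)
  expect_equal(unname(cm$matrix["MCI-NC", ]), c(3L, 0L, 5L))
  expect_equal(round(cm$per_class_correct[["MCI-DLB"]], 1), 100.0)
  expect_equal(round(cm$per_class_correct[["MCI-AD"]], 1), 92.9)
  # the overall rate implied by the rows (the printed table's own overall row
  # is inconsistent with its counts and is not reproduced)
  expect_equal(round(cm$overall_correct, 1), 78.6)
  # all-pattern-1 cohort -> everyone predicted MCI-AD
  co1 <- generate_cohort(cohort_spec(tibble::tibble(
    group = "MCI-AD", pattern = "1", n = 5)), seed = 1)
  expect_equal(unique(eeg_predictor(co1)), "MCI-AD")
})

test_that("the clinical-feature predictor reproduces the flag-based table", {
  co <- generate_cohort(mci_cohort_spec(), seed = 4)
  cm <- confusion(co$group, clinical_predictor(co))
  expect_equal(round(cm$per_class_correct[["MCI-DLB"]], 1), 75.0)
  expect_equal(round(cm$per_class_correct[["MCI-AD"]], 1), 85.7)
  expect_equal(round(cm$overall_correct, 1), 64.3)
  # no subject flagged -> all predicted MCI-AD
  co$dlb_feature <- FALSE
  expect_equal(unique(clinical_predictor(co)), "MCI-AD")
})

test_that("the abnormal-EEG conversion rate counts pattern/DF/DFV jointly", {
  co <- generate_cohort(mci_cohort_spec(), seed = 5)
  expect_equal(abnormal_eeg_conversion_rate(co), 20 / 24)
  # recount oracle on a large random cohort
  withr::with_seed(9, {
    big <- tibble::tibble(
      group = sample(c("MCI-DLB", "MCI-NC", "MCI-AD"), 1000, replace = TRUE),
      pattern = sample(c("1", "1plus", "2", "3", "4", "5"), 1000, replace = TRUE),
      df_mean = runif(1000, 3, 11),
      dfv = runif(1000, 0, 5)
    )
  })
  abn <- big$pattern != "1" & (big$df_mean < 8 | big$dfv > 1.5)
  expect_equal(abnormal_eeg_conversion_rate(big),
               sum(abn & big$group == "MCI-DLB") / sum(abn))
  # all-normal cohort errors
  allnorm <- tibble::tibble(group = "MCI-AD", pattern = "1",
                            df_mean = 9.5, dfv = 0.1)
  expect_error(abnormal_eeg_conversion_rate(allnorm),
               class = "qeegcsa_undefined_rate")
})

test_that("an independent table has zero inertia and centered coordinates", {
  tab <- outer(c(10, 20), c(6, 4)) / 10  # rank-1: rows proportional to margins
  ca <- correspondence_analysis(tab)
  expect_lt(ca$total_inertia, 1e-20)
  expect_true(all(abs(ca$row_coords) < 1e-9))
  expect_true(all(abs(ca$col_coords) < 1e-9))
})

test_that("CA places pattern 1 near MCI-AD and pattern 2 near MCI-DLB", {
  tab <- matrix(c(0, 13, 5, 19, 1, 3, 1, 0, 0), 3, byrow = TRUE,
                dimnames = list(c("P1", "P2", "P3"),
                                c("MCI-DLB", "MCI-AD", "MCI-NC")))
  ca <- correspondence_analysis(tab)
  d <- function(r, c) sqrt(sum((ca$row_coords[r, ] - ca$col_coords[c, ])^2))
  expect_equal(which.min(vapply(colnames(tab), function(c) d("P1", c), 1)),
               c("MCI-AD" = 2L))
  expect_equal(which.min(vapply(colnames(tab), function(c) d("P2", c), 1)),
               c("MCI-DLB" = 1L))
})

test_that("CA coordinates agree with an independent reference up to sign", {
  withr::with_seed(12, tab <- matrix(rpois(12, 20), 4, 3))
  ca <- correspondence_analysis(tab)
  ref <- MASS::corresp(tab, nf = 2)
  for (k in 1:2) {
    ref_row <- ref$rscore[, k] * ref$cor[k]
    err <- min(max(abs(ca$row_coords[, k] - ref_row)),
               max(abs(ca$row_coords[, k] + ref_row)))
    expect_lt(err, 1e-8)
    ref_col <- ref$cscore[, k] * ref$cor[k]
    err_c <- min(max(abs(ca$col_coords[, k] - ref_col)),
                 max(abs(ca$col_coords[, k] + ref_col)))
    expect_lt(err_c, 1e-8)
  }
})

test_that("total inertia equals the chi-square statistic over the grand total", {
  withr::with_seed(30, {
    for (i in 1:5) {
      tab <- matrix(rpois(12, 15) + 1, 4, 3)
      ca <- correspondence_analysis(tab)
      chi <- suppressWarnings(chisq.test(tab)$statistic)
      expect_equal(ca$total_inertia, unname(chi) / sum(tab), tolerance = 1e-10)
    }
  })
})

test_that("zero-margin rows are dropped with a warning", {
  tab <- rbind(c(5, 3), c(0, 0), c(2, 8))
  expect_warning(ca <- correspondence_analysis(tab), "zero-margin")
  expect_equal(nrow(ca$row_coords), 2)
})

test_that("group comparisons and correlations match their reference behaviour", {
  d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 4),
                      v = rep(c(1, 2, 3, 4), 3))
  gc <- compare_groups(d, "v", "g")
  expect_equal(gc$f_statistic, 0)
  expect_true(all(gc$pairwise[[1]] == 1, na.rm = TRUE))
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1.0)
  expect_error(compare_groups(tibble::tibble(g = "a", v = 1), "v", "g"),
               class = "qeegcsa_input_error")
  ft <- fisher_2x2(matrix(c(10, 2, 3, 12), 2))
  expect_lt(ft$p_value, 0.05)
})

test_that("tidiers return the documented shapes", {
  co <- generate_cohort(mci_cohort_spec(), seed = 6)
  cm <- confusion(co$group, eeg_predictor(co))
  td <- tidy(cm)
  expect_equal(nrow(td), 9)
  expect_equal(sum(td$n), 42)
  expect_equal(glance(cm)$overall_correct, 78.6)
  ca <- correspondence_analysis(matrix(c(5, 1, 2, 8, 1, 4), 2))
  expect_true(all(c("level", "dim1", "side") %in% names(tidy(ca))))
  expect_s3_class(glance(ca), "tbl_df")
})
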