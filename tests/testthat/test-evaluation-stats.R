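test_that("evaluate_fields counts matches, precision and recall correctly", {
  truth <- lapply(1:4, function(i) {
    make_record(report_id = paste0("R", i), psa = 5, t = "pT2c")
  })
  # 3 exact matches, 1 prediction missing where truth is present
  pred <- truth
  pred[[4]] <- make_record(report_id = "R4", psa = nm(), t = "pT2c")
  ev <- evaluate_fields(pred, truth)
  row <- ev[ev$parameter == "PSA", ]
  expect_equal(row$accuracy, 0.75)
  expect_equal(row$precision, 1.0)
  expect_equal(row$recall, 0.75)
  expect_equal(round_half_up(row$f1), 0.857)

  # identical predictions: everything 1.0
  ev2 <- evaluate_fields(truth, truth)
  expect_true(all(ev2$accuracy == 1))
  expect_true(all(ev2$f1[!is.na(ev2$precision)] == 1))

  # both-missing counts for accuracy but not precision/recall denominators
  n_stage_row <- ev[ev$parameter == "N-Stage", ]
  expect_equal(n_stage_row$accuracy, 1)     # both missing on all 4
  expect_true(is.na(n_stage_row$precision))

  # micro row pools all 16 x n pairs
  micro <- ev[ev$parameter == "Overall (micro)", ]
  expect_equal(micro$accuracy, sum(ev$correct[ev$parameter !=
                                                "Overall (micro)"]) /
                 (16 * 4))
  expect_error(evaluate_fields(pred[1:3], truth), "same report_id")
})

test_that("x_code predictions score as values, not as missing", {
  truth <- list(make_record(report_id = "R1",
                            m = missing_value("x_code", "pMx")))
  pred_nm <- list(make_record(report_id = "R1", m = nm()))
  ev <- evaluate_fields(pred_nm, truth)
  row <- ev[ev$parameter == "M-Stage", ]
  expect_equal(row$accuracy, 0)  # "not mentioned" != recorded "pMx"
  expect_equal(row$recall, 0)    # truth value present, not recovered
  pred_x <- list(make_record(report_id = "R1",
                             m = missing_value("x_code", "Mx")))
  ev2 <- evaluate_fields(pred_x, truth)
  expect_equal(ev2[ev2$parameter == "M-Stage", "accuracy"], 1)
})

test_that("micro accuracy from pooled correct counts is exact", {
  bench <- load_benchmark("extraction_benchmark_internal")
  per_param <- bench[bench$parameter != "Overall (micro)", ]
  n_docs <- benchmark_n_docs("extraction_benchmark_internal")
  micro <- sum(per_param$correct) / (length(PARAMETER_NAMES) * n_docs)
  expect_equal(sum(per_param$correct), 2334)
  expect_equal(round_half_up(micro), 0.973)
})

test_that("evaluate_staging collapses Unknown and computes macro rows", {
  truth <- c(rep("IIB", 35), rep("IIIB", 3),
             "Unknown (Missing N-Stage)", "Unknown (Missing PSA)")
  pred <- c(rep("IIB", 33), "IIIB", "Unknown (Missing M-Stage)",
            rep("IIIB", 3), "Unknown (Missing Grade Group)", "IIB")
  tab <- evaluate_staging(pred, truth)
  iib <- tab[tab$class == "IIB", ]
  expect_equal(iib$tp, 33)
  expect_equal(iib$fp, 1)
  expect_equal(iib$fn, 2)
  expect_equal(round_half_up(iib$precision), 0.971)
  expect_equal(round_half_up(iib$recall), 0.943)
  expect_equal(round_half_up(iib$f1), 0.957)
  unk <- tab[tab$class == "Unknown", ]
  expect_equal(unk$tp, 1)
  # classes ordered by stage order, Unknown last, macro terminal
  expect_equal(tab$class, c("IIB", "IIIB", "Unknown", "Overall (macro)"))
  macro <- tab[tab$class == "Overall (macro)", ]
  expect_equal(macro$f1,
               mean(tab$f1[tab$class != "Overall (macro)"]))

  # perfect predictions
  perfect <- evaluate_staging(truth, truth)
  expect_true(all(perfect$f1 == 1))
})

test_that("per-class metrics from printed counts reproduce benchmark cells", {
  for (name in c("staging_benchmark_internal",
                 "staging_benchmark_external")) {
    bench <- load_benchmark(name)
    per_class <- bench[bench$class != "Overall (macro)", ]
    computed <- staging_metrics_from_counts(per_class$tp, per_class$fp,
                                            per_class$fn,
                                            class = per_class$class)
    for (col in c("precision", "recall", "f1")) {
      expect_equal(round_half_up(computed[[col]]), bench[[col]],
                   tolerance = 1e-9,
                   label = sprintf("%s %s", name, col))
    }
  }
})

test_that("F1 of a degenerate class is 0 by convention", {
  tab <- staging_metrics_from_counts(tp = c(0, 5), fp = c(0, 0),
                                     fn = c(3, 0))
  expect_equal(tab$f1[1], 0)
  expect_true(is.na(tab$precision[1]))
  expect_equal(tab$recall[1], 0)
})

test_that("wilson_ci reproduces printed intervals and its invariants", {
  ci <- wilson_ci(35, 122)
  expect_equal(round(100 * ci$lower, 1), 21.4)
  expect_equal(round(100 * ci$upper, 1), 37.3)
  ci <- wilson_ci(9, 72)
  expect_equal(round(100 * ci$lower, 1), 6.7)
  expect_equal(round(100 * ci$upper, 1), 22.1)
  # boundary: zero successes
  ci <- wilson_ci(0, 50)
  expect_equal(ci$lower, 0)
  expect_gt(ci$upper, 0)
  # interval contains the point estimate; width shrinks with n
  set.seed(2)
  for (i in 1:25) {
    n <- sample(10:500, 1)
    x <- sample(0:n, 1)
    ci <- wilson_ci(x, n)
    expect_lte(ci$lower, x / n + 1e-12)
    expect_gte(ci$upper, x / n - 1e-12)
    ci4 <- wilson_ci(4 * x, 4 * n)  # same p-hat, larger n
    expect_lt(ci4$upper - ci4$lower, ci$upper - ci$lower + 1e-12)
  }
  expect_error(wilson_ci(5, 0))
  expect_error(wilson_ci(6, 5))
})

test_that("fisher_exact matches enumeration and the stats oracle", {
  res <- fisher_exact(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
  expect_equal(res$p_value, 2 / 252)
  expect_match(res$method, "2x2")
  res <- fisher_exact(matrix(c(2, 3, 3, 2), 2, byrow = TRUE))
  expect_equal(res$p_value, 1)
  # identical rows are always p = 1
  expect_equal(fisher_exact(matrix(c(7, 3, 7, 3), 2,
                                   byrow = TRUE))$p_value, 1)
  # independent oracle: stats::fisher.test over random small tables
  set.seed(11)
  for (i in 1:40) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9,
                 label = paste(tab, collapse = ","))
  }
  # r x 2 exact path
  rx2 <- matrix(c(10, 2, 3, 9, 5, 5), ncol = 2, byrow = TRUE)
  res <- fisher_exact(rx2)
  expect_equal(res$p_value, stats::fisher.test(rx2)$p.value,
               tolerance = 1e-9)
  expect_error(fisher_exact(matrix(c(0, 0, 1, 2), 2)), "empty margin")
})

test_that("chi_squared computes the Pearson statistic without correction", {
  res <- chi_squared(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  res <- chi_squared(matrix(c(20, 10, 10, 20), 2))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-9)
  expect_equal(res$df, 1)
  # direction agrees with Fisher on a strongly associated table
  strong <- matrix(c(20, 2, 3, 19), 2)
  expect_lt(chi_squared(strong)$p_value, 0.001)
  expect_lt(fisher_exact(strong)$p_value, 0.001)
  expect_error(chi_squared(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "empty margin")
})

test_that("round_half_up rounds halves away from zero", {
  expect_equal(round_half_up(0.9725), 0.973)
  expect_equal(round_half_up(0.9375), 0.938)
  expect_equal(round_half_up(0.8445), 0.845)
  expect_equal(round_half_up(-0.0005), -0.001)
})
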