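test_that("the same seed reproduces the corpus exactly", {
  cfg <- generator_config(n_patients = 25, seed = 99, noise_rate = 0.2)
  c1 <- sample_corpus(cfg)
  c2 <- sample_corpus(cfg)
  expect_identical(c1, c2)
  c3 <- sample_corpus(generator_config(n_patients = 25, seed = 100))
  expect_false(identical(c1$reports, c3$reports))
})

test_that("coherent-mode corpora validate cleanly and stage definitively", {
  corpus <- sample_corpus(generator_config(n_patients = 1000, seed = 2024))
  v <- validate_corpus(corpus$records)
  expect_equal(nrow(v$errors), 0)

  # with no missing data every record stages to a definite group
  zero_missing <- stats::setNames(
    rep(0, length(default_missing_rates())),
    names(default_missing_rates()))
  cfg <- generator_config(n_patients = 300, seed = 5,
                          marginals = list(n = c(N0 = 112, N1 = 14) / 126,
                                           m = c(M0 = 1)),
                          missing_rates = zero_missing)
  corpus2 <- sample_corpus(cfg)
  labels <- vapply(corpus2$records,
                   function(r) stage_label(stage_record(r)), character(1))
  expect_false(any(startsWith(labels, "Unknown")))
  expect_equal(nrow(validate_corpus(corpus2$records)$errors), 0)
})

test_that("degenerate marginals stage every record to IIB", {
  cfg <- generator_config(
    n_patients = 40, seed = 3,
    marginals = list(t = c(T2c = 1), n = c(N0 = 1), m = c(M0 = 1),
                     gg = c(`2` = 1), psa = list(fixed = 6)),
    missing_rates = stats::setNames(rep(0, 10),
                                    names(default_missing_rates())))
  corpus <- sample_corpus(cfg)
  stages <- vapply(corpus$records,
                   function(r) stage_record(r)$stage, character(1))
  expect_equal(unique(stages), "IIB")
})

test_that("marginal fidelity: empirical frequencies within 3 SE at n = 10000", {
  cfg <- generator_config(n_patients = 10000, seed = 314)
  corpus <- sample_corpus(cfg)
  n <- length(corpus$records)
  check_margin <- function(observed_counts, probs, label) {
    for (cat in names(probs)) {
      p <- probs[[cat]]
      se <- sqrt(p * (1 - p) / n)
      obs <- (observed_counts[[cat]] %||% 0) / n
      expect_lt(abs(obs - p), 3 * se + 1e-9,
                label = sprintf("%s '%s' (obs %.4f vs %.4f)",
                                label, cat, obs, p))
    }
  }
  `%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
  mr <- default_missing_rates()
  mg <- default_marginals()
  t_obs <- table(vapply(corpus$records, function(r) {
    if (is_missing(r$t_stage)) "missing" else r$t_stage$code
  }, character(1)))
  # concrete T marginal is scaled by the non-missing rate
  check_margin(as.list(t_obs), as.list(mg$t * (1 - mr[["t"]])), "T")
  gg_obs <- table(vapply(corpus$records, function(r) {
    g <- r$gleason$reported_grade_group
    if (is_missing(g)) "missing" else as.character(g)
  }, character(1)))
  check_margin(as.list(gg_obs), as.list(mg$gg * (1 - mr[["gg"]])), "GG")
  n_obs <- table(vapply(corpus$records, function(r) {
    if (is_missing(r$n_stage, "x_code")) "Nx"
    else if (is_missing(r$n_stage)) "missing" else r$n_stage$code
  }, character(1)))
  check_margin(as.list(n_obs), as.list(mg$n * (1 - mr[["n"]])), "N")
  # PSA log-normal: median near the configured center
  psa <- vapply(corpus$records, function(r) {
    if (is_missing(r$psa_ng_ml)) NA_real_ else r$psa_ng_ml
  }, numeric(1))
  expect_lt(abs(stats::median(psa, na.rm = TRUE) - 8), 0.5)
})

test_that("rendered dialects carry their signature structures", {
  rec <- make_record(t = "pT3b", n = "pN1", m = nm(),
                     primary = 4, secondary = 5, pct_secondary = 35,
                     gg = 5, psa = 22.4, epe = "Present", svi = "Present",
                     pni = "Present", histology = "Acinar adenocarcinoma",
                     margins = "Involved", nodes_examined = 14,
                     nodes_mets = 2)
  syn <- render_report(rec, "synoptic")
  expect_match(syn, "Seminal vesicle invasion: present", fixed = TRUE)
  expect_match(syn, "Gleason score: 4 + 5 = 9 (65% pattern 4)",
               fixed = TRUE)
  tab <- render_report(rec, "tabulated")
  expect_match(tab, "GG5 | 9-10   | X", fixed = TRUE)
  expect_false(grepl("WHO Grade Group:", tab, fixed = TRUE))
  nar <- render_report(rec, "narrative")
  expect_match(nar, "The pathologic stage is pT3b pN1.", fixed = TRUE)
  expect_match(nar, "Preoperative serum PSA was 22.4 ng/mL", fixed = TRUE)
})

test_that("injection induces exactly the targeted code", {
  t3a <- make_record(t = "pT3a", epe = "Present", svi = "Absent",
                     n = "pN0", nodes_examined = 10, nodes_mets = 0,
                     primary = 3, secondary = 4, gg = 2)
  t3b <- make_record(t = "pT3b", epe = "Present", svi = "Present",
                     n = "pN1", nodes_examined = 10, nodes_mets = 2,
                     primary = 4, secondary = 5, gg = 5)
  get_codes <- function(rec) {
    vapply(validate_record(rec), `[[`, character(1), "code")
  }

  out <- inject_inconsistency(t3a, "T2_stage_with_EPE_should_be_T3a")
  expect_equal(get_codes(out), "T2_stage_with_EPE_should_be_T3a")
  expect_equal(attr(out, "injected_code"),
               "T2_stage_with_EPE_should_be_T3a")

  out <- inject_inconsistency(t3a, "SVI_present_should_be_T3b_or_higher")
  expect_equal(get_codes(out), "SVI_present_should_be_T3b_or_higher")

  out <- inject_inconsistency(t3a, "T3a_stage_but_no_EPE")
  expect_equal(get_codes(out), "T3a_stage_but_no_EPE")

  out <- inject_inconsistency(t3a, "N0_stage_but_positive_lymph_nodes")
  expect_equal(get_codes(out), "N0_stage_but_positive_lymph_nodes")

  out <- inject_inconsistency(t3b, "N1_stage_but_no_positive_lymph_nodes")
  expect_equal(get_codes(out), "N1_stage_but_no_positive_lymph_nodes")

  out <- inject_inconsistency(t3b, "T3b_stage_but_no_SVI")
  expect_equal(get_codes(out), "T3b_stage_but_no_SVI")

  out <- inject_inconsistency(t3a, "Gleason_7_inconsistent_with_GG3")
  expect_equal(get_codes(out), "Gleason_7_inconsistent_with_GG3")

  # impossible targets signal a typed condition
  t1 <- make_record(t = "T1c", epe = "Absent", svi = "Absent")
  expect_error(inject_inconsistency(t1, "T3a_stage_but_no_EPE"),
               class = "prostaging_injection_impossible")
  expect_error(inject_inconsistency(t1, "N1_stage_but_no_positive_lymph_nodes"),
               class = "prostaging_injection_impossible")
  expect_error(inject_inconsistency(t3a, "no_such_code"), "unknown")
})

test_that("corrupt_corpus at rate 0 is the identity", {
  corpus <- sample_corpus(generator_config(n_patients = 30, seed = 8))
  set.seed(1)
  out <- corrupt_corpus(corpus$records, "T3a_stage_but_no_EPE", 0)
  expect_identical(out$records, corpus$records)
  expect_false(any(out$injected))
})

test_that("most-recent-report merge prefers the newest, fills from older", {
  older <- make_record(report_id = "R1", t = "pT2c", psa = 5.1, gg = 2,
                       primary = 3, secondary = 4)
  newer <- make_record(report_id = "R2", t = "pT3a", epe = "Present")
  merged <- merge_patient_reports(list(older, newer))
  expect_equal(merged$report_id, "R2")
  expect_equal(merged$t_stage$code, "T3a")   # newest wins
  expect_equal(merged$psa_ng_ml, 5.1)        # filled from older
  expect_equal(merged$gleason$reported_grade_group, 2L)
  corpus <- sample_corpus(generator_config(n_patients = 10,
                                           reports_per_patient = 3,
                                           seed = 4))
  expect_length(corpus$records, 30)
  expect_length(corpus$merged, 10)
})
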