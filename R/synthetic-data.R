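# Seeded generator of coherent ground-truth records, free-text rendering in
# three report dialects, and targeted inconsistency injection.
#
# Coherence enforced by construction (stricter than real reports, which is
# what makes injected corruptions identifiable): EPE Present iff T >= T3a;
# SVI Present iff T3b/T4; positive nodes iff N1; reported Grade Group equals
# the pattern-derived group; secondary percentage complements the primary's.

#' Generator configuration
#'
#' Defaults emulate the marginal value distributions of a 152-case internal
#' radical-prostatectomy series: T-stage dominated by pT2c/pT3a/pT3b,
#' N-stage mostly pN0 with ~14% pNx, M-stage almost never recorded, Grade
#' Groups concentrated in GG2-GG3, and a right-skewed (log-normal) PSA with
#' median near 8 ng/mL.
#'
#' @param n_patients Number of patients.
#' @param reports_per_patient Reports per patient (>= 1). When > 1, the most
#'   recent report is the reference and earlier reports only fill fields it
#'   is missing (see [merge_patient_reports()]).
#' @param marginals Named list of categorical probability tables for `t`,
#'   `n`, `m`, `gg`, `pni`, `histology`, `margins`, plus `psa` (either
#'   `list(meanlog=, sdlog=)` or `list(fixed=)`) and `pct_primary` (vector
#'   of candidate primary-pattern percentages). Categorical tables must sum
#'   to 1; special categories `"Nx"`, `"Mx"` draw x_code missing values and
#'   `"missing"` draws a not-mentioned value.
#' @param missing_rates Named per-parameter probabilities of replacing a
#'   drawn value with "not mentioned" (names: `t`, `n`, `m`, `gg`, `epe`,
#'   `pni`, `psa`, `histology`, `margins`, `pct`).
#' @param dialect_mix Weights over `c("narrative", "synoptic", "tabulated")`.
#' @param noise_rate Probability, per rendered report, of degraded phrasing
#'   (implicit capsular-defect wording for EPE; Gleason percentage omitted).
#' @param tertiary_rate Probability of recording a tertiary pattern.
#' @param loose Relax the EPE/SVI coupling (realism studies): invasion
#'   indicators are then drawn independently of T.
#' @param seed Integer seed; fully determines the corpus.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 150,
                             reports_per_patient = 1,
                             marginals = default_marginals(),
                             missing_rates = default_missing_rates(),
                             dialect_mix = c(narrative = 1, synoptic = 1,
                                             tabulated = 1) / 3,
                             noise_rate = 0,
                             tertiary_rate = 0.08,
                             loose = FALSE,
                             seed = 1L) {
  defaults <- default_marginals()
  for (nm in names(defaults)) {
    if (is.null(marginals[[nm]])) marginals[[nm]] <- defaults[[nm]]
  }
  mr <- default_missing_rates()
  for (nm in names(missing_rates)) mr[[nm]] <- missing_rates[[nm]]
  for (nm in c("t", "n", "m", "gg", "pni", "histology", "margins")) {
    p <- marginals[[nm]]
    if (abs(sum(p) - 1) > 1e-8) {
      stop(sprintf("marginal '%s' must sum to 1", nm), call. = FALSE)
    }
  }
  stopifnot(n_patients >= 0, reports_per_patient >= 1,
            noise_rate >= 0, noise_rate <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 reports_per_patient = as.integer(reports_per_patient),
                 marginals = marginals, missing_rates = mr,
                 dialect_mix = dialect_mix / sum(dialect_mix),
                 noise_rate = noise_rate, tertiary_rate = tertiary_rate,
                 loose = isTRUE(loose), seed = as.integer(seed)),
            class = "generator_config")
}

#' Default categorical marginals of the generator
#'
#' @return Named list of probability tables (see [generator_config()]).
#' @export
default_marginals <- function() {
  list(
    t = c(T2a = 2, T2b = 3, T2c = 72, T3a = 47, T3b = 22, T4 = 0) / 146,
    n = c(N0 = 112, N1 = 14, Nx = 22) / 148,
    m = c(M0 = 3, missing = 149) / 152,
    gg = c(`1` = 2, `2` = 70, `3` = 48, `4` = 4, `5` = 20) / 144,
    pni = c(Present = 139, Absent = 12) / 151,
    histology = c(`Acinar adenocarcinoma` = 0.95,
                  `Ductal adenocarcinoma` = 0.05),
    margins = c(Negative = 0.8, Involved = 0.2),
    psa = list(meanlog = log(8), sdlog = 0.75),
    pct_primary = seq(55, 90, by = 5))
}

#' Default per-parameter missing ("not mentioned") rates
#'
#' @return Named numeric vector.
#' @export
default_missing_rates <- function() {
  c(t = 6 / 152, n = 4 / 152, m = 0, gg = 8 / 152, epe = 2 / 152,
    pni = 1 / 152, psa = 0, histology = 0.02, margins = 0.02, pct = 0.05)
}

draw_cat <- function(p) sample(names(p), 1L, prob = p)

patterns_for_gg <- function(gg) {
  switch(as.character(gg),
         "1" = c(3L, 3L),
         "2" = c(3L, 4L),
         "3" = c(4L, 3L),
         "4" = rbind(c(4L, 4L), c(3L, 5L), c(5L, 3L))[sample.int(3, 1L), ],
         "5" = rbind(c(4L, 5L), c(5L, 4L), c(5L, 5L))[sample.int(3, 1L), ])
}

#' Sample one coherent pathology record
#'
#' Uses the current RNG state; [sample_corpus()] seeds it from the config.
#'
#' @param config A [generator_config()].
#' @param patient_id,report_id Identifiers for the record.
#' @return A [pathology_record()] that passes [validate_record()] cleanly.
#' @export
sample_record <- function(config, patient_id = "P1", report_id = "R1") {
  mg <- config$marginals
  mr <- config$missing_rates
  miss <- function(rate) stats::runif(1) < rate
  nm <- function() missing_value("not_mentioned")

  t_code <- draw_cat(mg$t)
  gg <- as.integer(draw_cat(mg$gg))
  n_cat <- draw_cat(mg$n)

  # invasion indicators follow T unless the loose flag decouples them
  if (config$loose) {
    epe <- sample(c("Present", "Absent"), 1L)
    svi <- sample(c("Present", "Absent"), 1L, prob = c(0.2, 0.8))
  } else {
    epe <- if (t_code %in% T_GE_T3) "Present" else "Absent"
    svi <- if (t_code %in% c("T3b", "T4")) "Present" else "Absent"
  }

  pats <- patterns_for_gg(gg)
  pct_primary <- sample(mg$pct_primary, 1L)
  tertiary <- if (stats::runif(1) < config$tertiary_rate) {
    sample(setdiff(3:5, pats[2]), 1L)
  } else nm()

  if (n_cat == "Nx") {
    n_stage <- missing_value("x_code", "pNx")
    nodes_examined <- nm()
    nodes_mets <- nm()
  } else {
    n_stage <- tnm_code("p", "N", n_cat)
    nodes_examined <- sample(4:24, 1L)
    nodes_mets <- if (n_cat == "N1") sample(1:3, 1L) else 0L
  }

  m_cat <- draw_cat(mg$m)
  m_stage <- switch(m_cat,
                    missing = nm(),
                    Mx = missing_value("x_code", "pMx"),
                    M0 = tnm_code("c", "M", "M0"),
                    M1 = tnm_code("c", "M", "M1"))

  psa <- if (!is.null(mg$psa$fixed)) mg$psa$fixed else {
    max(0.1, round(stats::rlnorm(1, mg$psa$meanlog, mg$psa$sdlog), 1))
  }

  pathology_record(
    patient_id = patient_id, report_id = report_id,
    t_stage = if (miss(mr[["t"]])) nm() else tnm_code("p", "T", t_code),
    n_stage = if (miss(mr[["n"]])) nm() else n_stage,
    m_stage = if (miss(mr[["m"]])) nm() else m_stage,
    gleason = gleason_info(
      primary = pats[1], secondary = pats[2], tertiary = tertiary,
      pct_secondary = if (miss(mr[["pct"]])) nm()
                      else complement_secondary_percentage(pct_primary),
      reported_grade_group = if (miss(mr[["gg"]])) nm() else gg),
    psa_ng_ml = if (miss(mr[["psa"]])) nm() else psa,
    epe = if (miss(mr[["epe"]])) nm() else epe,
    svi = svi,
    perineural_invasion = if (miss(mr[["pni"]])) nm()
                          else draw_cat(mg$pni),
    histologic_subtype = if (miss(mr[["histology"]])) nm()
                         else draw_cat(mg$histology),
    resection_margins = if (miss(mr[["margins"]])) nm()
                        else draw_cat(mg$margins),
    nodes_examined = nodes_examined,
    nodes_with_metastasis = nodes_mets)
}

#' Sample a corpus of records with rendered report text
#'
#' Seeds the RNG from `config$seed` (restoring the caller's RNG state on
#' exit), draws `n_patients x reports_per_patient` records, and renders each
#' in a dialect drawn from `dialect_mix`.
#'
#' @param config A [generator_config()].
#' @return List with `records`, `reports` (list of `report_id`, `dialect`,
#'   `text`), `merged` (per-patient reference records after the
#'   most-recent-report merge; equal to `records` when
#'   `reports_per_patient = 1`), and `manifest` (config + seed).
#' @export
sample_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  records <- list()
  reports <- list()
  dialects <- names(config$dialect_mix)
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%04d", i)
    for (j in seq_len(config$reports_per_patient)) {
      rid <- sprintf("%s-R%d", pid, j)
      rec <- sample_record(config, patient_id = pid, report_id = rid)
      dialect <- sample(dialects, 1L, prob = config$dialect_mix)
      txt <- render_report(rec, dialect, noise_rate = config$noise_rate)
      records[[length(records) + 1L]] <- rec
      reports[[length(reports) + 1L]] <- list(report_id = rid,
                                              dialect = dialect, text = txt)
    }
  }
  merged <- if (config$reports_per_patient > 1) {
    pids <- vapply(records, `[[`, character(1), "patient_id")
    lapply(split(records, pids)[unique(pids)], merge_patient_reports)
  } else records
  list(records = records, reports = reports, merged = unname(merged),
       manifest = list(config = unclass(config), seed = config$seed))
}

#' Merge a patient's reports into one reference record
#'
#' The most recent report (last in list order) is the reference; earlier
#' reports fill only the fields it is missing (once a value is identified it
#' is adopted as final).
#'
#' @param records A patient's records, oldest first.
#' @return A single [pathology_record()] with the reference `report_id`.
#' @export
merge_patient_reports <- function(records) {
  stopifnot(length(records) >= 1)
  merged <- record_to_list(records[[length(records)]])
  for (older in rev(records)[-1]) {
    older_list <- record_to_list(older)
    for (p in PARAMETER_NAMES) {
      v <- merged[[p]]
      if (is.list(v) && !is.null(v$missing) && v$missing != "x_code") {
        merged[[p]] <- older_list[[p]]
      }
    }
  }
  record_from_list(merged)
}

# ---- report rendering --------------------------------------------------

gleason_sentence <- function(record, omit_pct = FALSE) {
  gl <- record$gleason
  if (is_missing(gl$primary) || is_missing(gl$secondary)) return(NULL)
  s <- sprintf("Gleason score %d + %d = %d", gl$primary, gl$secondary,
               gl$primary + gl$secondary)
  if (!omit_pct && !is_missing(gl$pct_secondary)) {
    s <- sprintf("%s (%d%% pattern %d)", s,
                 as.integer(round(100 - gl$pct_secondary)), gl$primary)
  }
  s
}

grade_grid <- function(gg) {
  rows <- c("Grade Group | Gleason score | Mark",
            vapply(1:5, function(g) {
              score <- c("<=6", "3+4=7", "4+3=7", "8", "9-10")[g]
              sprintf("GG%d | %-6s | %s", g, score,
                      if (g == gg) "X" else "")
            }, character(1)))
  paste(rows, collapse = "\n")
}

# implicit EPE wording the baseline extractor deliberately does not parse
IMPLICIT_EPE_TEXT <- paste("Frozen section shows a small capsular defect",
                           "with tumor infiltrates forming margins.")

render_synoptic <- function(record, omit_pct, implicit_epe, tabulated) {
  gl <- record$gleason
  line <- function(label, value) {
    if (is_missing(value, c("not_mentioned", "dash"))) return(NULL)
    v <- if (is_missing(value, "x_code")) value$literal
         else if (inherits(value, "tnm_code")) format(value)
         else as.character(value)
    sprintf("%s: %s", label, v)
  }
  gs <- gleason_sentence(record, omit_pct)
  lines <- c(
    "RADICAL PROSTATECTOMY SPECIMEN",
    line("Histologic type", record$histologic_subtype),
    if (!is.null(gs)) sub("^Gleason score ", "Gleason score: ", gs),
    line("Tertiary Gleason pattern", gl$tertiary),
    if (tabulated && !is_missing(gl$reported_grade_group)) {
      grade_grid(gl$reported_grade_group)
    } else {
      line("WHO Grade Group", gl$reported_grade_group)
    },
    line("T stage", record$t_stage),
    line("N stage", record$n_stage),
    line("M stage", record$m_stage),
    if (implicit_epe) IMPLICIT_EPE_TEXT
    else line("Extraprostatic extension", tolower_presence(record$epe)),
    line("Seminal vesicle invasion", tolower_presence(record$svi)),
    line("Perineural invasion", tolower_presence(record$perineural_invasion)),
    line("Resection margins", tolower_presence(record$resection_margins)),
    line("Lymph nodes examined", record$nodes_examined),
    line("Lymph nodes with metastasis", record$nodes_with_metastasis),
    if (!is_missing(record$psa_ng_ml)) {
      sprintf("PSA: %.1f ng/mL", record$psa_ng_ml)
    })
  paste(lines, collapse = "\n")
}

tolower_presence <- function(x) {
  if (is_missing(x)) x else tolower(as.character(x))
}

render_narrative <- function(record, omit_pct, implicit_epe) {
  gl <- record$gleason
  sentences <- c("Radical prostatectomy specimen.")
  if (!is_missing(record$histologic_subtype)) {
    sentences <- c(sentences,
                   sprintf("The tumor is a %s.",
                           tolower(record$histologic_subtype)))
  }
  gs <- gleason_sentence(record, omit_pct)
  if (!is.null(gs)) sentences <- c(sentences, paste0(gs, "."))
  if (!is_missing(gl$tertiary)) {
    sentences <- c(sentences,
                   sprintf("Tertiary Gleason pattern %d is noted.",
                           gl$tertiary))
  }
  if (!is_missing(gl$reported_grade_group)) {
    sentences <- c(sentences,
                   sprintf("WHO Grade Group %d.", gl$reported_grade_group))
  }
  tnm <- c(if (!is_missing(record$t_stage)) format(record$t_stage),
           if (!is_missing(record$n_stage, c("not_mentioned", "dash"))) {
             if (is_missing(record$n_stage)) record$n_stage$literal
             else format(record$n_stage)
           },
           if (!is_missing(record$m_stage, c("not_mentioned", "dash"))) {
             if (is_missing(record$m_stage)) record$m_stage$literal
             else format(record$m_stage)
           })
  if (length(tnm) > 0) {
    sentences <- c(sentences,
                   sprintf("The pathologic stage is %s.",
                           paste(tnm, collapse = " ")))
  }
  presence_sentence <- function(label, value) {
    if (is_missing(value)) return(NULL)
    sprintf("%s is %s.", label, tolower(value))
  }
  sentences <- c(
    sentences,
    if (implicit_epe) IMPLICIT_EPE_TEXT
    else presence_sentence("Extraprostatic extension", record$epe),
    presence_sentence("Seminal vesicle invasion", record$svi),
    presence_sentence("Perineural invasion", record$perineural_invasion))
  if (!is_missing(record$resection_margins)) {
    sentences <- c(sentences,
                   sprintf("Resection margins are %s.",
                           tolower(record$resection_margins)))
  }
  if (!is_missing(record$nodes_examined)) {
    n_ex <- record$nodes_examined
    mets <- record$nodes_with_metastasis
    s <- sprintf("%d lymph nodes were examined", n_ex)
    if (!is_missing(mets)) {
      s <- sprintf("%s and %d contained metastatic carcinoma", s, mets)
    }
    sentences <- c(sentences, paste0(s, "."))
  }
  if (!is_missing(record$psa_ng_ml)) {
    sentences <- c(sentences,
                   sprintf("Preoperative serum PSA was %.1f ng/mL.",
                           record$psa_ng_ml))
  }
  paste(sentences, collapse = " ")
}

#' Render a record as free report text
#'
#' Dialects: `"synoptic"` (key: value lines), `"narrative"` (prose),
#' `"tabulated"` (synoptic with the Grade Group as a grid whose correct row
#' is marked "X"). With probability `noise_rate` the rendering degrades:
#' EPE is phrased only implicitly as a capsular defect, and the Gleason
#' percentage is omitted — the failure modes a pattern extractor cannot
#' recover.
#'
#' @param record A [pathology_record()].
#' @param dialect One of `"narrative"`, `"synoptic"`, `"tabulated"`.
#' @param noise_rate Probability in `[0,1]` (consumes RNG draws when > 0).
#' @return Single character string of report text.
#' @export
render_report <- function(record,
                          dialect = c("synoptic", "narrative", "tabulated"),
                          noise_rate = 0) {
  dialect <- match.arg(dialect)
  noisy <- noise_rate > 0 && stats::runif(1) < noise_rate
  implicit_epe <- noisy && identical(record$epe, "Present")
  omit_pct <- noisy
  switch(dialect,
         synoptic = render_synoptic(record, omit_pct, implicit_epe, FALSE),
         tabulated = render_synoptic(record, omit_pct, implicit_epe, TRUE),
         narrative = render_narrative(record, omit_pct, implicit_epe))
}

# ---- targeted inconsistency injection ---------------------------------

injection_impossible <- function(code, reason) {
  structure(class = c("prostaging_injection_impossible", "error",
                      "condition"),
            list(message = sprintf("cannot inject '%s': %s", code, reason),
                 call = NULL))
}

set_record_field <- function(record, field, value) {
  lst <- record_to_list(record)
  lst[[field]] <- field_to_json_value(value)
  record_from_list(lst)
}

#' Minimally corrupt a record to trigger one consistency-error code
#'
#' Edits the smallest set of fields needed so that [validate_record()]
#' fires the target code. For the parameterized Gleason family pass the
#' rendered code, e.g. `"Gleason_7_inconsistent_with_GG3"`. When the target
#' cannot be induced on this record (e.g. `T3a_stage_but_no_EPE` on a T2
#' record whose SVI would co-fire) a condition of class
#' `prostaging_injection_impossible` is signalled so the caller can
#' resample.
#'
#' @param record A coherent [pathology_record()].
#' @param target_code A consistency-error code.
#' @return The corrupted record, with the injected code in
#'   `attr(, "injected_code")`.
#' @export
inject_inconsistency <- function(record, target_code) {
  tc <- t_code_of(record)
  nc <- n_code_of(record)
  out <- NULL
  if (target_code == "T2_stage_with_EPE_should_be_T3a") {
    if (identical(record$epe, "Present") && !identical(record$svi,
                                                       "Present")) {
      out <- set_record_field(record, "T-Stage", tnm_code("p", "T", "T2c"))
    } else if (!is.null(tc) && tc %in% T2_FAMILY) {
      out <- set_record_field(record, "EPE", "Present")
    } else {
      stop(injection_impossible(target_code,
                                "needs EPE present without SVI, or a T2"))
    }
  } else if (target_code == "SVI_present_should_be_T3b_or_higher") {
    if (!is.null(tc) && tc == "T3a") {
      out <- set_record_field(record, "SVI", "Present")
    } else {
      stop(injection_impossible(target_code, "needs a T3a record"))
    }
  } else if (target_code == "N0_stage_but_positive_lymph_nodes") {
    if (is.null(nc) || nc != "N0") {
      stop(injection_impossible(target_code, "needs an N0 record"))
    }
    rec <- record
    if (is_missing(rec$nodes_examined) || rec$nodes_examined < 2) {
      rec <- set_record_field(rec, "Number of Lymph Nodes examined", 12L)
    }
    out <- set_record_field(rec, "Lymph Nodes with Metastasis", 2L)
  } else if (target_code == "N1_stage_but_no_positive_lymph_nodes") {
    if (is.null(nc) || nc != "N1") {
      stop(injection_impossible(target_code, "needs an N1 record"))
    }
    out <- set_record_field(record, "Lymph Nodes with Metastasis", 0L)
  } else if (target_code == "T3b_stage_but_no_SVI") {
    if (is.null(tc) || tc != "T3b") {
      stop(injection_impossible(target_code, "needs a T3b record"))
    }
    out <- set_record_field(record, "SVI", "Absent")
  } else if (target_code == "T3a_stage_but_no_EPE") {
    if (is.null(tc) || tc != "T3a") {
      stop(injection_impossible(target_code, "needs a T3a record"))
    }
    out <- set_record_field(record, "EPE", "Absent")
  } else if (grepl("^Gleason_[0-9]+_inconsistent_with_GG[1-5]$",
                   target_code)) {
    m <- regmatches(target_code,
                    regexec("^Gleason_([0-9]+)_inconsistent_with_GG([1-5])$",
                            target_code))[[1]]
    s <- as.integer(m[2]); g <- as.integer(m[3])
    if (s < 6 || s > 10) {
      stop(injection_impossible(target_code, "Gleason sum must be 6-10"))
    }
    pairs <- expand.grid(p = 3:5, q = 3:5)
    pairs <- pairs[pairs$p + pairs$q == s, , drop = FALSE]
    pairs$gg <- mapply(grade_group_from_patterns, pairs$p, pairs$q)
    pairs <- pairs[pairs$gg != g, , drop = FALSE]
    if (nrow(pairs) == 0) {
      stop(injection_impossible(target_code,
                                "no pattern pair with that sum discords"))
    }
    rec <- set_record_field(record, "Primary Gleason Pattern", pairs$p[1])
    rec <- set_record_field(rec, "Secondary Gleason Pattern", pairs$q[1])
    out <- set_record_field(rec, "WHO Grade Group", g)
  } else {
    stop(sprintf("unknown error code '%s'", target_code), call. = FALSE)
  }
  attr(out, "injected_code") <- target_code
  out
}

#' Corrupt a corpus at a given rate
#'
#' Each record is corrupted toward `target_code` with probability `rate`;
#' records on which the target is impossible are left unchanged.
#'
#' @param records List of [pathology_record()]s.
#' @param target_code Consistency-error code.
#' @param rate Corruption probability in `[0,1]`.
#' @return List with `records` (corpus with corruptions applied) and
#'   `injected` (logical vector of which records were corrupted).
#' @export
corrupt_corpus <- function(records, target_code, rate) {
  stopifnot(rate >= 0, rate <= 1)
  injected <- logical(length(records))
  out <- records
  for (i in seq_along(records)) {
    if (stats::runif(1) >= rate) next
    corrupted <- tryCatch(inject_inconsistency(records[[i]], target_code),
                          prostaging_injection_impossible =
                            function(e) NULL)
    if (!is.null(corrupted)) {
      out[[i]] <- corrupted
      injected[i] <- TRUE
    }
  }
  list(records = out, injected = injected)
}
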