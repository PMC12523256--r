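# Consistency validation of staging and grading data.
#
# Five rule families, evaluated independently per record; rules whose
# fields are missing stay silent. Codes are descriptive strings; the
# Gleason rule's code is parameterized by the Gleason sum and the reported
# Grade Group ("Gleason_7_inconsistent_with_GG3").

#' Error codes emitted by the consistency validator
#'
#' The Gleason family is parameterized; `gleason_error_code()` renders it.
#'
#' @format Character vector of the five fixed codes.
#' @export
CONSISTENCY_CODES <- c(
  "T2_stage_with_EPE_should_be_T3a",
  "SVI_present_should_be_T3b_or_higher",
  "N0_stage_but_positive_lymph_nodes",
  "N1_stage_but_no_positive_lymph_nodes",
  "T3b_stage_but_no_SVI",
  "T3a_stage_but_no_EPE"
)

#' Render the Gleason-concordance error code
#'
#' @param gleason_sum Primary + secondary pattern sum.
#' @param reported_gg Reported WHO Grade Group.
#' @return e.g. `"Gleason_7_inconsistent_with_GG3"`.
#' @export
gleason_error_code <- function(gleason_sum, reported_gg) {
  sprintf("Gleason_%d_inconsistent_with_GG%d",
          as.integer(gleason_sum), as.integer(reported_gg))
}

consistency_error <- function(code, report_id, detail) {
  structure(list(code = code, report_id = report_id, detail = detail),
            class = "consistency_error")
}

t_code_of <- function(record) {
  if (is_missing(record$t_stage)) NULL else record$t_stage$code
}
n_code_of <- function(record) {
  if (is_missing(record$n_stage)) NULL else record$n_stage$code
}

#' Validate one record for staging/grade inconsistencies
#'
#' Rule families, in emission order:
#' 1. T2-family stage with EPE present (EPE defines pT3a).
#' 2. SVI present in a T2 or T3a stage (SVI defines pT3b).
#' 3. N0 with positive lymph nodes / N1 without positive nodes.
#' 4. Gleason sum discordant with the reported WHO Grade Group (fires only
#'    when primary, secondary and the reported group are all present;
#'    tertiary patterns are ignored).
#' 5. T3b without SVI / T3a without EPE.
#'
#' Missing fields silence the rules that need them; multiple errors may
#' coexist on one record. Pure: the record is never mutated.
#'
#' @param record A [pathology_record()].
#' @return List of `consistency_error`s (possibly empty), in rule order.
#' @export
#' @examples
#' r <- pathology_record("p1", "r1", t_stage = "pT2c", epe = "Present")
#' validate_record(r)[[1]]$code # "T2_stage_with_EPE_should_be_T3a"
validate_record <- function(record) {
  errors <- list()
  add <- function(code, detail) {
    errors[[length(errors) + 1L]] <<- consistency_error(code,
                                                        record$report_id,
                                                        detail)
  }
  tc <- t_code_of(record)
  nc <- n_code_of(record)
  epe <- record$epe
  svi <- record$svi
  mets <- record$nodes_with_metastasis

  # 1. T2 stages with EPE present
  if (!is.null(tc) && tc %in% T2_FAMILY && identical(epe, "Present")) {
    add("T2_stage_with_EPE_should_be_T3a",
        sprintf("T-stage %s recorded with EPE present; EPE defines pT3a", tc))
  }
  # 2. SVI present in T2 or T3a
  if (!is.null(tc) && tc %in% c(T2_FAMILY, "T3a") &&
      identical(svi, "Present")) {
    add("SVI_present_should_be_T3b_or_higher",
        sprintf("SVI present with T-stage %s; SVI defines pT3b", tc))
  }
  # 3. N-stage vs positive lymph-node count
  if (!is.null(nc) && !is_missing(mets)) {
    if (nc == "N0" && mets > 0) {
      add("N0_stage_but_positive_lymph_nodes",
          sprintf("N0 recorded but %d lymph node(s) with metastasis", mets))
    }
    if (nc == "N1" && mets == 0) {
      add("N1_stage_but_no_positive_lymph_nodes",
          "N1 recorded but zero lymph nodes with metastasis")
    }
  }
  # 4. Gleason sum vs reported Grade Group
  gl <- record$gleason
  if (!is_missing(gl$primary) && !is_missing(gl$secondary) &&
      !is_missing(gl$reported_grade_group)) {
    derived <- grade_group_from_patterns(gl$primary, gl$secondary)
    if (derived != gl$reported_grade_group) {
      add(gleason_error_code(gl$primary + gl$secondary,
                             gl$reported_grade_group),
          sprintf(
            "Gleason %d + %d = %d implies Grade Group %d, report states %d",
            gl$primary, gl$secondary, gl$primary + gl$secondary, derived,
            gl$reported_grade_group))
    }
  }
  # 5. T3b without SVI / T3a without EPE
  if (!is.null(tc) && tc == "T3b" && identical(svi, "Absent")) {
    add("T3b_stage_but_no_SVI",
        "T-stage T3b recorded but SVI absent; SVI defines pT3b")
  }
  if (!is.null(tc) && tc == "T3a" && identical(epe, "Absent")) {
    add("T3a_stage_but_no_EPE",
        "T-stage T3a recorded but EPE absent; EPE defines pT3a")
  }
  errors
}

#' Validate a corpus and summarize error frequencies
#'
#' @param records List of [pathology_record()]s.
#' @return List with `errors` (data frame `report_id`, `error_code`,
#'   `detail`), `summary` (data frame `error_code`, `n`, `percent` — percent
#'   over flagged *errors*, matching an "n (%)" error-frequency table), and
#'   counts `n_records`, `n_flagged_records`, `percent_flagged_records`
#'   (flagged cases over the corpus).
#' @export
validate_corpus <- function(records) {
  all_errors <- lapply(records, validate_record)
  flat <- do.call(rbind, c(list(
    data.frame(report_id = character(), error_code = character(),
               detail = character(), stringsAsFactors = FALSE)),
    lapply(all_errors, function(errs) {
      if (length(errs) == 0) return(NULL)
      data.frame(report_id = vapply(errs, `[[`, character(1), "report_id"),
                 error_code = vapply(errs, `[[`, character(1), "code"),
                 detail = vapply(errs, `[[`, character(1), "detail"),
                 stringsAsFactors = FALSE)
    })))
  n_records <- length(records)
  flagged <- unique(flat$report_id)
  if (nrow(flat) > 0) {
    tab <- table(flat$error_code)
    summary <- data.frame(error_code = names(tab),
                          n = as.integer(tab),
                          percent = 100 * as.integer(tab) / nrow(flat),
                          stringsAsFactors = FALSE)
    summary <- summary[order(-summary$n, summary$error_code), ]
    rownames(summary) <- NULL
  } else {
    summary <- data.frame(error_code = character(), n = integer(),
                          percent = numeric(), stringsAsFactors = FALSE)
  }
  list(errors = flat, summary = summary,
       n_records = n_records,
       n_flagged_records = length(flagged),
       percent_flagged_records =
         if (n_records > 0) 100 * length(flagged) / n_records else 0)
}

#' Export consistency errors as CSV sheets
#'
#' Writes `consistency_errors.csv` (report_id, error_code, detail) and
#' `error_summary.csv` (error_code, n, percent) into `dir`.
#'
#' @param validation Result of [validate_corpus()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_consistency_errors <- function(validation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "consistency_errors.csv")
  p2 <- file.path(dir, "error_summary.csv")
  utils::write.csv(validation$errors, p1, row.names = FALSE)
  utils::write.csv(validation$summary, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
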