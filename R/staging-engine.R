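# Prioritized rule-based AJCC 8th-edition prostate staging.
#
# Rules are tested in priority order; a rule fires only when every one of
# its conditions is definitely true. A condition on a missing field is
# undecidable: once any potentially-firing rule is blocked by missing data
# no later rule may fire (its priority is uncertain), and the result is
# Unknown listing the union of blocking fields in the fixed order
# T-Stage, N-Stage, M-Stage, Grade Group, PSA.

STAGE_ELEMENT_ORDER <- c(t = "T-Stage", n = "N-Stage", m = "M-Stage",
                         gg = "Grade Group", psa = "PSA")

STAGE_LEVELS <- c("I", "IIA", "IIB", "IIC", "IIIA", "IIIB", "IIIC",
                  "IVA", "IVB", "Unknown")

#' Staging-relevant projection of a record
#'
#' @param t,n,m T/N/M codes as bare code strings (e.g. `"T3a"`, `"N0"`),
#'   `tnm_code` objects, or `missing_value`s.
#' @param grade_group Grade Group 1-5 or missing.
#' @param psa PSA in ng/mL or missing.
#' @return An object of class `staging_input`.
#' @export
staging_input <- function(t = missing_value(), n = missing_value(),
                          m = missing_value(), grade_group = missing_value(),
                          psa = missing_value()) {
  code_of <- function(x, category) {
    if (is_missing(x)) return(x)
    if (inherits(x, "tnm_code")) return(x$code)
    parsed <- parse_tnm(x, category)
    if (is_missing(parsed)) parsed else parsed$code
  }
  if (!is_missing(grade_group)) {
    grade_group <- as.integer(grade_group)
    stopifnot(grade_group %in% 1:5)
  }
  if (!is_missing(psa)) {
    psa <- as.numeric(psa)
    stopifnot(!is.na(psa), psa >= 0)
  }
  structure(list(t = code_of(t, "T"), n = code_of(n, "N"),
                 m = code_of(m, "M"), gg = grade_group, psa = psa,
                 imputations = list()),
            class = "staging_input")
}

#' Impute M0 for missing M-stage
#'
#' Radical prostatectomy is performed for localized disease, so a missing
#' M-stage is imputed as M0 before rule evaluation. By default every missing
#' kind is imputed, including the recorded-but-uninformative `x_code` "pMx";
#' `pmx_policy = "block"` leaves x_code values missing so that they block
#' staging instead (either behaviour of the reference pipeline can be
#' reproduced).
#'
#' @param input A [staging_input()].
#' @param pmx_policy `"impute"` (default) or `"block"`.
#' @return The input with `m = "M0"` and an imputation note when imputed.
#' @export
impute_m <- function(input, pmx_policy = c("impute", "block")) {
  pmx_policy <- match.arg(pmx_policy)
  stopifnot(inherits(input, "staging_input"))
  if (is_missing(input$m)) {
    if (is_missing(input$m, "x_code") && pmx_policy == "block") return(input)
    input$imputations <- c(input$imputations,
                           list(list(field = "M-Stage", value = "M0")))
    input$m <- "M0"
  }
  input
}

# One staging rule: ordered conditions, each a function of the input
# returning TRUE, FALSE, or NA (undecidable), tagged with the element it
# reads. The IIA rule's PSA condition is "< 20" rather than the tabulated
# ">= 10, < 20": under the priority order Stage I has already captured
# T1-T2a with PSA < 10, so the relaxed bound closes the T2b/T2c, GG1,
# PSA < 10 gap exactly as AJCC 8e assigns it (IIA).
staging_rules <- function() {
  cond <- function(element, fn) list(element = element, fn = fn)
  tri <- function(x, pred) if (is_missing(x)) NA else pred(x)
  t_in <- function(set) function(i) tri(i$t, function(v) v %in% set)
  n_is <- function(code) function(i) tri(i$n, function(v) v == code)
  m_is <- function(code) function(i) tri(i$m, function(v) v == code)
  gg_in <- function(set) function(i) tri(i$gg, function(v) v %in% set)
  psa_lt <- function(x) function(i) tri(i$psa, function(v) v < x)
  psa_ge <- function(x) function(i) tri(i$psa, function(v) v >= x)
  list(
    list(id = 1L, stage = "IVB",
         conds = list(cond("m", m_is("M1")))),
    list(id = 2L, stage = "IVA",
         conds = list(cond("n", n_is("N1")), cond("m", m_is("M0")))),
    list(id = 3L, stage = "IIIC",
         conds = list(cond("gg", gg_in(5L)), cond("n", n_is("N0")),
                      cond("m", m_is("M0")))),
    list(id = 4L, stage = "IIIB",
         conds = list(cond("t", t_in(T_GE_T3)), cond("n", n_is("N0")),
                      cond("m", m_is("M0")), cond("gg", gg_in(1:4)))),
    list(id = 5L, stage = "IIIA",
         conds = list(cond("psa", psa_ge(20)), cond("t", t_in(T_LE_T2)),
                      cond("n", n_is("N0")), cond("m", m_is("M0")),
                      cond("gg", gg_in(1:4)))),
    list(id = 6L, stage = "I",
         conds = list(cond("t", t_in(T_LE_T2A)), cond("n", n_is("N0")),
                      cond("m", m_is("M0")), cond("gg", gg_in(1L)),
                      cond("psa", psa_lt(10)))),
    list(id = 7L, stage = "IIA",
         conds = list(cond("t", t_in(T_LE_T2)), cond("n", n_is("N0")),
                      cond("m", m_is("M0")), cond("gg", gg_in(1L)),
                      cond("psa", psa_lt(20)))),
    list(id = 8L, stage = "IIB",
         conds = list(cond("t", t_in(T_LE_T2)), cond("n", n_is("N0")),
                      cond("m", m_is("M0")), cond("gg", gg_in(2L)),
                      cond("psa", psa_lt(20)))),
    list(id = 9L, stage = "IIC",
         conds = list(cond("t", t_in(T_LE_T2)), cond("n", n_is("N0")),
                      cond("m", m_is("M0")), cond("gg", gg_in(3:4)),
                      cond("psa", psa_lt(20)))))
}

new_staging_result <- function(stage, missing_elements = character(),
                               fired_rule = NA_integer_,
                               imputations = list(),
                               report_id = NA_character_) {
  structure(list(stage = stage, missing_elements = missing_elements,
                 fired_rule = fired_rule, imputations = imputations,
                 report_id = report_id),
            class = "staging_result")
}

#' @export
format.staging_result <- function(x, ...) stage_label(x)

#' @export
print.staging_result <- function(x, ...) {
  cat(sprintf("<staging_result %s>", stage_label(x)))
  if (!is.na(x$fired_rule)) cat(sprintf(" rule %d", x$fired_rule))
  cat("\n")
  invisible(x)
}

#' Human-readable stage label
#'
#' Renders `"IIB"` or, for undecidable inputs,
#' `"Unknown (Missing N-Stage, Grade Group)"`.
#'
#' @param result A `staging_result`.
#' @return Character label.
#' @export
stage_label <- function(result) {
  if (result$stage != "Unknown") return(result$stage)
  sprintf("Unknown (Missing %s)",
          paste(result$missing_elements, collapse = ", "))
}

#' Collapse a stage label to its unified class
#'
#' All `"Unknown (Missing ...)"` labels collapse to `"Unknown"` for
#' classification scoring.
#'
#' @param label Character stage label(s).
#' @return Character vector of collapsed labels.
#' @export
collapse_unknown <- function(label) {
  ifelse(startsWith(label, "Unknown"), "Unknown", label)
}

#' Assign an AJCC 8th-edition prognostic stage group
#'
#' Applies the prioritized staging rules to an M-imputed input (see
#' [impute_m()]). Rule order: M1 -> IVB; N1 -> IVA; GG5 -> IIIC; T3/T4 ->
#' IIIB; PSA >= 20 -> IIIA; then I / IIA / IIB / IIC. PSA boundaries are
#' half-open: Stage I needs PSA < 10, IIA-eligibility PSA < 20 (>= 10 only
#' by priority over Stage I), IIIA PSA >= 20.
#'
#' @param input A [staging_input()], already M-imputed.
#' @return A `staging_result` (total: every input yields a stage or Unknown).
#' @export
#' @examples
#' assign_stage(impute_m(staging_input("T2c", "N1", "M0", 2, 6)))   # IVA
#' assign_stage(impute_m(staging_input("T3a", "N0", "M0", 5, 3)))   # IIIC
assign_stage <- function(input) {
  stopifnot(inherits(input, "staging_input"))
  blocked <- character()
  for (rule in staging_rules()) {
    vals <- vapply(rule$conds, function(cc) cc$fn(input), logical(1))
    if (any(vals %in% FALSE)) next
    if (all(vals %in% TRUE)) {
      if (length(blocked) == 0) {
        return(new_staging_result(rule$stage, fired_rule = rule$id,
                                  imputations = input$imputations))
      }
      # an earlier rule of higher priority is undecidable: cannot fire
      next
    }
    elems <- vapply(rule$conds, `[[`, character(1), "element")
    blocked <- union(blocked, STAGE_ELEMENT_ORDER[elems[is.na(vals)]])
  }
  if (length(blocked) == 0) {
    # unreachable for valid inputs: the rule set is total on complete inputs
    blocked <- unname(STAGE_ELEMENT_ORDER[vapply(
      c("t", "n", "m", "gg", "psa"),
      function(e) is_missing(input[[e]]), logical(1))])
  }
  ordered <- STAGE_ELEMENT_ORDER[STAGE_ELEMENT_ORDER %in% blocked]
  new_staging_result("Unknown", missing_elements = unname(ordered),
                     imputations = input$imputations)
}

#' Stage a pathology record
#'
#' Projects the record onto its staging elements (Grade Group taken from the
#' reported WHO Grade Group when present, else derived from the Gleason
#' patterns), imputes missing M-stage, and applies [assign_stage()].
#'
#' @param record A [pathology_record()].
#' @param pmx_policy Passed to [impute_m()].
#' @return A `staging_result` carrying the record's `report_id`.
#' @export
stage_record <- function(record, pmx_policy = c("impute", "block")) {
  pmx_policy <- match.arg(pmx_policy)
  input <- staging_input_from_record(record)
  result <- assign_stage(impute_m(input, pmx_policy))
  result$report_id <- record$report_id
  result
}

#' Staging input projected from a record
#'
#' @param record A [pathology_record()].
#' @return A [staging_input()] (not yet M-imputed).
#' @export
staging_input_from_record <- function(record) {
  gl <- record$gleason
  gg <- gl$reported_grade_group
  if (is_missing(gg) && !is_missing(gl$primary) && !is_missing(gl$secondary)) {
    gg <- grade_group_from_patterns(gl$primary, gl$secondary)
  }
  staging_input(t = record$t_stage, n = record$n_stage, m = record$m_stage,
                grade_group = gg, psa = record$psa_ng_ml)
}

#' Serialize staging results as JSON Lines
#'
#' One object per report: `report_id`, `stage` (the human-readable label,
#' Unknown rendered as `"Unknown (Missing X, Y)"`), `missing_elements`,
#' `fired_rule`, `imputations`.
#'
#' @param results List of `staging_result`s.
#' @param path Output path.
#' @export
write_staging_jsonl <- function(results, path) {
  lines <- vapply(results, function(r) {
    jsonlite::toJSON(list(
      report_id = r$report_id,
      stage = stage_label(r),
      missing_elements = r$missing_elements,
      fired_rule = if (is.na(r$fired_rule)) NULL else r$fired_rule,
      imputations = r$imputations), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
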