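# Domain types for structured radical-prostatectomy pathology data:
# TNM codes, missing-value semantics, Gleason/Grade-Group arithmetic.

#' Canonical parameter names of a structured prostatectomy report
#'
#' The 16 parameters extracted from a radical-prostatectomy pathology report,
#' spelled exactly as used in record JSON serialization and evaluation.
#'
#' @format Character vector of length 16.
#' @export
PARAMETER_NAMES <- c(
  "EPE",
  "Histologic Subtype",
  "Lymph Nodes with Metastasis",
  "M-Stage",
  "N-Stage",
  "Number of Lymph Nodes examined",
  "Percentage of Secondary Gleason Pattern",
  "Perineural Invasion",
  "Primary Gleason Pattern",
  "Resection Margins",
  "Secondary Gleason Pattern",
  "SVI",
  "PSA",
  "T-Stage",
  "Tertiary Gleason Pattern",
  "WHO Grade Group"
)

TNM_VOCAB <- list(
  T = c("T1", "T1a", "T1b", "T1c", "T2", "T2a", "T2b", "T2c",
        "T3", "T3a", "T3b", "T4"),
  N = c("N0", "N1", "Nx"),
  M = c("M0", "M1", "Mx")
)

# T-code groupings used by the staging rules ("T1-T2a", "T1-T2", "T3/T4").
T_LE_T2A <- c("T1", "T1a", "T1b", "T1c", "T2", "T2a")
T_LE_T2  <- c(T_LE_T2A, "T2b", "T2c")
T_GE_T3  <- c("T3", "T3a", "T3b", "T4")
T2_FAMILY <- c("T2", "T2a", "T2b", "T2c")

#' Missing-value marker
#'
#' A field of a pathology record is either a concrete value or exactly one
#' missing-value marker. Three kinds are distinguished: `not_mentioned` (the
#' report is silent), `dash` (an explicit "-" entry), and `x_code` (a
#' recorded but uninformative TNM code such as "pNx" or "pMx"). The `x_code`
#' kind keeps its literal token because downstream scoring treats "pNx" and
#' "not mentioned" as *different* values even though both block definitive
#' staging.
#'
#' @param kind One of `"not_mentioned"`, `"dash"`, `"x_code"`.
#' @param literal Raw token as it appeared (required for `x_code`).
#' @return An object of class `missing_value`.
#' @export
missing_value <- function(kind = c("not_mentioned", "dash", "x_code"),
                          literal = NULL) {
  kind <- match.arg(kind)
  if (kind == "x_code" && (is.null(literal) || !nzchar(literal))) {
    stop("an x_code missing value must carry its literal token", call. = FALSE)
  }
  structure(list(kind = kind, literal = literal %||% ""),
            class = "missing_value")
}

#' @export
format.missing_value <- function(x, ...) {
  switch(x$kind,
         not_mentioned = "Not mentioned",
         dash = "-",
         x_code = x$literal)
}

#' @export
print.missing_value <- function(x, ...) {
  cat("<missing:", x$kind, if (nzchar(x$literal)) x$literal, ">\n")
  invisible(x)
}

#' Test for a missing-value marker
#'
#' @param x Any object.
#' @param kinds Optional subset of kinds to test for.
#' @return `TRUE` if `x` is a `missing_value` (of one of `kinds`).
#' @export
is_missing <- function(x, kinds = NULL) {
  if (!inherits(x, "missing_value")) return(FALSE)
  is.null(kinds) || x$kind %in% kinds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' TNM code
#'
#' @param prefix `"p"`, `"c"`, or `""` (prefix is descriptive metadata only;
#'   staging ignores it).
#' @param category `"T"`, `"N"`, or `"M"`.
#' @param code A code from the category's vocabulary (e.g. `"T3a"`, `"N0"`).
#' @return An object of class `tnm_code`.
#' @export
tnm_code <- function(prefix, category, code) {
  stopifnot(category %in% c("T", "N", "M"))
  if (!prefix %in% c("p", "c", "")) {
    stop("TNM prefix must be 'p', 'c' or ''", call. = FALSE)
  }
  if (!code %in% TNM_VOCAB[[category]]) {
    stop(sprintf("'%s' is not a valid %s-category code", code, category),
         call. = FALSE)
  }
  structure(list(prefix = prefix, category = category, code = code),
            class = "tnm_code")
}

#' @export
format.tnm_code <- function(x, ...) paste0(x$prefix, x$code)

#' @export
print.tnm_code <- function(x, ...) {
  cat("<tnm:", format(x), ">\n")
  invisible(x)
}

#' Parse a TNM token
#'
#' Case-insensitive parsing of tokens such as `"pT3a"`, `"cM0"`, `"N1"`.
#' The optional p/c prefix is preserved. `"Nx"`/`"Mx"` (any prefix) are
#' recorded-but-uninformative and map to an `x_code` missing value that
#' retains the literal token; empty strings, `"-"` and `"not mentioned"` map
#' to the corresponding missing kinds. Any other non-empty token is an error.
#'
#' @param text Raw token.
#' @param category `"T"`, `"N"`, or `"M"`.
#' @return A `tnm_code` or a `missing_value`.
#' @export
#' @examples
#' parse_tnm("pT3a", "T")
#' parse_tnm("pNx", "N") # x_code missing value carrying "pNx"
parse_tnm <- function(text, category = c("T", "N", "M")) {
  category <- match.arg(category)
  if (inherits(text, "missing_value")) return(text)
  if (is.null(text) || length(text) == 0 || is.na(text)) {
    return(missing_value("not_mentioned"))
  }
  raw <- trimws(as.character(text))
  if (!nzchar(raw)) return(missing_value("not_mentioned"))
  if (raw == "-") return(missing_value("dash"))
  if (tolower(raw) %in% c("not mentioned", "not_mentioned", "null", "na",
                          "none", "unknown")) {
    return(missing_value("not_mentioned"))
  }
  m <- regmatches(raw, regexec("^([pc]?)([TNMtnm])([0-9][a-cA-C]?|[xX])$", raw,
                               ignore.case = TRUE))[[1]]
  if (length(m) == 0) {
    stop(sprintf("malformed %s-category TNM token: '%s'", category, raw),
         call. = FALSE)
  }
  prefix <- tolower(m[2])
  cat_letter <- toupper(m[3])
  suffix <- m[4]
  if (cat_letter != category) {
    stop(sprintf("token '%s' is %s-category, expected %s",
                 raw, cat_letter, category), call. = FALSE)
  }
  if (tolower(suffix) == "x") {
    if (category == "T") {
      stop(sprintf("malformed T-category TNM token: '%s'", raw), call. = FALSE)
    }
    return(missing_value("x_code", literal = paste0(prefix, category, "x")))
  }
  code <- paste0(category, substr(suffix, 1, 1),
                 tolower(substr(suffix, 2, 2)))
  if (!code %in% TNM_VOCAB[[category]]) {
    stop(sprintf("malformed %s-category TNM token: '%s'", category, raw),
         call. = FALSE)
  }
  tnm_code(prefix, category, code)
}

#' Gleason grading information
#'
#' @param primary,secondary,tertiary Gleason patterns in `{3,4,5}` or a
#'   `missing_value`. Patterns 1-2 are obsolete under ISUP 2014 and rejected.
#' @param pct_secondary Percentage of the secondary pattern in `[0,100]` or
#'   missing.
#' @param reported_grade_group WHO/ISUP Grade Group 1-5 as stated by the
#'   report, or missing. Concordance with the patterns is *not* enforced
#'   here; that is the consistency validator's job.
#' @return An object of class `gleason_info`.
#' @export
gleason_info <- function(primary = missing_value(),
                         secondary = missing_value(),
                         tertiary = missing_value(),
                         pct_secondary = missing_value(),
                         reported_grade_group = missing_value()) {
  chk_pattern <- function(x, what) {
    if (is_missing(x)) return(x)
    x <- as.integer(x)
    if (is.na(x) || !x %in% 3:5) {
      stop(sprintf("%s Gleason pattern must be 3, 4 or 5", what),
           call. = FALSE)
    }
    x
  }
  if (!is_missing(pct_secondary)) {
    pct_secondary <- as.numeric(pct_secondary)
    if (is.na(pct_secondary) || pct_secondary < 0 || pct_secondary > 100) {
      stop("pct_secondary must lie in [0, 100]", call. = FALSE)
    }
  }
  if (!is_missing(reported_grade_group)) {
    reported_grade_group <- as.integer(reported_grade_group)
    if (is.na(reported_grade_group) || !reported_grade_group %in% 1:5) {
      stop("reported Grade Group must be 1-5", call. = FALSE)
    }
  }
  structure(list(primary = chk_pattern(primary, "primary"),
                 secondary = chk_pattern(secondary, "secondary"),
                 tertiary = chk_pattern(tertiary, "tertiary"),
                 pct_secondary = pct_secondary,
                 reported_grade_group = reported_grade_group),
            class = "gleason_info")
}

#' ISUP 2014 Grade Group from Gleason patterns
#'
#' Maps primary + secondary Gleason patterns to the WHO/ISUP Grade Group:
#' sum <= 6 -> 1; 3+4 -> 2; 4+3 -> 3; sum 8 -> 4; sum 9-10 -> 5.
#'
#' @param primary,secondary Gleason patterns in `{3,4,5}`.
#' @return Integer Grade Group 1-5.
#' @export
#' @examples
#' grade_group_from_patterns(3, 4) # 2
#' grade_group_from_patterns(4, 3) # 3
grade_group_from_patterns <- function(primary, secondary) {
  primary <- as.integer(primary)
  secondary <- as.integer(secondary)
  if (anyNA(c(primary, secondary)) ||
      !primary %in% 3:5 || !secondary %in% 3:5) {
    stop("Gleason patterns must be in {3, 4, 5}", call. = FALSE)
  }
  s <- primary + secondary
  if (s <= 6) return(1L)
  if (s == 7L) return(if (primary == 3L) 2L else 3L)
  if (s == 8L) return(4L)
  5L
}

#' Complement of the primary Gleason-pattern percentage
#'
#' Reports often state only the primary pattern's proportion (e.g. "60%
#' pattern 4"); the secondary proportion is its complement.
#'
#' @param pct_primary Percentage in `[0, 100]`.
#' @return `100 - pct_primary`.
#' @export
complement_secondary_percentage <- function(pct_primary) {
  pct_primary <- as.numeric(pct_primary)
  if (is.na(pct_primary) || pct_primary < 0 || pct_primary > 100) {
    stop("percentage must lie in [0, 100]", call. = FALSE)
  }
  100 - pct_primary
}

#' Structured pathology record
#'
#' One radical-prostatectomy report's 16 structured parameters plus patient
#' and report identifiers. Every field is either a concrete value or a
#' [missing_value()].
#'
#' @param patient_id,report_id Identifiers (non-empty strings).
#' @param t_stage,n_stage,m_stage A `tnm_code`, a `missing_value`, or a raw
#'   token (parsed with [parse_tnm()]).
#' @param gleason A [gleason_info()].
#' @param psa_ng_ml Serum PSA in ng/mL (non-negative) or missing.
#' @param epe,svi,perineural_invasion `"Absent"`, `"Present"`, or missing.
#' @param histologic_subtype,resection_margins Free strings or missing.
#' @param nodes_examined,nodes_with_metastasis Non-negative counts or
#'   missing. `nodes_with_metastasis <= nodes_examined` is enforced when both
#'   are present unless `allow_incoherent_counts = TRUE` (real reports can
#'   violate it; the validator, not the constructor, flags incoherence).
#' @param allow_incoherent_counts Override for the node-count invariant.
#' @return An object of class `pathology_record`.
#' @export
pathology_record <- function(patient_id, report_id,
                             t_stage = missing_value(),
                             n_stage = missing_value(),
                             m_stage = missing_value(),
                             gleason = gleason_info(),
                             psa_ng_ml = missing_value(),
                             epe = missing_value(),
                             svi = missing_value(),
                             perineural_invasion = missing_value(),
                             histologic_subtype = missing_value(),
                             resection_margins = missing_value(),
                             nodes_examined = missing_value(),
                             nodes_with_metastasis = missing_value(),
                             allow_incoherent_counts = FALSE) {
  stopifnot(is.character(patient_id), nzchar(patient_id),
            is.character(report_id), nzchar(report_id),
            inherits(gleason, "gleason_info"))
  coerce_stage <- function(x, category) {
    if (inherits(x, c("tnm_code", "missing_value"))) x
    else parse_tnm(x, category)
  }
  t_stage <- coerce_stage(t_stage, "T")
  n_stage <- coerce_stage(n_stage, "N")
  m_stage <- coerce_stage(m_stage, "M")
  coerce_presence <- function(x, what) {
    if (is_missing(x)) return(x)
    x <- as.character(x)
    canon <- c(absent = "Absent", present = "Present")[tolower(x)]
    if (is.na(canon)) {
      stop(sprintf("%s must be 'Absent' or 'Present'", what), call. = FALSE)
    }
    unname(canon)
  }
  epe <- coerce_presence(epe, "EPE")
  svi <- coerce_presence(svi, "SVI")
  perineural_invasion <- coerce_presence(perineural_invasion,
                                         "perineural invasion")
  if (!is_missing(psa_ng_ml)) {
    psa_ng_ml <- as.numeric(psa_ng_ml)
    if (is.na(psa_ng_ml) || psa_ng_ml < 0) {
      stop("PSA must be a non-negative number of ng/mL", call. = FALSE)
    }
  }
  coerce_count <- function(x, what) {
    if (is_missing(x)) return(x)
    x <- as.integer(x)
    if (is.na(x) || x < 0) stop(sprintf("%s must be a non-negative integer",
                                        what), call. = FALSE)
    x
  }
  nodes_examined <- coerce_count(nodes_examined, "nodes_examined")
  nodes_with_metastasis <- coerce_count(nodes_with_metastasis,
                                        "nodes_with_metastasis")
  if (!is_missing(nodes_examined) && !is_missing(nodes_with_metastasis) &&
      nodes_with_metastasis > nodes_examined && !allow_incoherent_counts) {
    stop("nodes_with_metastasis exceeds nodes_examined ",
         "(set allow_incoherent_counts = TRUE to keep the raw values)",
         call. = FALSE)
  }
  structure(list(patient_id = patient_id, report_id = report_id,
                 t_stage = t_stage, n_stage = n_stage, m_stage = m_stage,
                 gleason = gleason, psa_ng_ml = psa_ng_ml,
                 epe = epe, svi = svi,
                 perineural_invasion = perineural_invasion,
                 histologic_subtype = if (is_missing(histologic_subtype))
                   histologic_subtype else as.character(histologic_subtype),
                 resection_margins = if (is_missing(resection_margins))
                   resection_margins else as.character(resection_margins),
                 nodes_examined = nodes_examined,
                 nodes_with_metastasis = nodes_with_metastasis),
            class = "pathology_record")
}

#' @export
print.pathology_record <- function(x, ...) {
  cat(sprintf("<pathology_record %s / %s>\n", x$patient_id, x$report_id))
  for (p in PARAMETER_NAMES) {
    v <- record_field(x, p)
    cat(sprintf("  %-40s %s\n", p,
                if (is_missing(v)) format(v) else format(v)))
  }
  invisible(x)
}

# Map a canonical parameter name to the record's value for it.
#' Read a record field by canonical parameter name
#'
#' @param record A [pathology_record()].
#' @param parameter One of [PARAMETER_NAMES].
#' @return Concrete value or `missing_value`.
#' @export
record_field <- function(record, parameter) {
  switch(parameter,
         "EPE" = record$epe,
         "Histologic Subtype" = record$histologic_subtype,
         "Lymph Nodes with Metastasis" = record$nodes_with_metastasis,
         "M-Stage" = record$m_stage,
         "N-Stage" = record$n_stage,
         "Number of Lymph Nodes examined" = record$nodes_examined,
         "Percentage of Secondary Gleason Pattern" =
           record$gleason$pct_secondary,
         "Perineural Invasion" = record$perineural_invasion,
         "Primary Gleason Pattern" = record$gleason$primary,
         "Resection Margins" = record$resection_margins,
         "Secondary Gleason Pattern" = record$gleason$secondary,
         "SVI" = record$svi,
         "PSA" = record$psa_ng_ml,
         "T-Stage" = record$t_stage,
         "Tertiary Gleason Pattern" = record$gleason$tertiary,
         "WHO Grade Group" = record$gleason$reported_grade_group,
         stop(sprintf("unknown parameter '%s'", parameter), call. = FALSE))
}

# numeric parameters compared with absolute tolerance 0.01
NUMERIC_PARAMETERS <- c("PSA", "Percentage of Secondary Gleason Pattern",
                        "Lymph Nodes with Metastasis",
                        "Number of Lymph Nodes examined",
                        "Primary Gleason Pattern",
                        "Secondary Gleason Pattern",
                        "Tertiary Gleason Pattern", "WHO Grade Group")
TNM_PARAMETERS <- c("T-Stage" = "T", "N-Stage" = "N", "M-Stage" = "M")

#' Normalize a field value for equality scoring
#'
#' Case-folds strings, strips p/c TNM prefixes, collapses every missing kind
#' EXCEPT `x_code` to a single absent token (an `x_code` such as "pNx" keeps
#' its prefix-stripped literal: it is a recorded value and scores as one).
#' Numeric parameters are kept numeric and compared with absolute tolerance
#' 0.01 by [values_match()].
#'
#' @param field Canonical parameter name.
#' @param value Concrete value or `missing_value`.
#' @return Canonical token (string or numeric).
#' @export
normalize_for_match <- function(field, value) {
  if (is_missing(value, c("not_mentioned", "dash"))) return("__absent__")
  if (is_missing(value, "x_code")) {
    return(sub("^[pc]", "", tolower(value$literal)))
  }
  if (inherits(value, "tnm_code")) return(tolower(value$code))
  if (field %in% names(TNM_PARAMETERS) && is.character(value)) {
    parsed <- tryCatch(parse_tnm(value, TNM_PARAMETERS[[field]]),
                       error = function(e) NULL)
    if (!is.null(parsed)) return(normalize_for_match(field, parsed))
  }
  if (field %in% NUMERIC_PARAMETERS) {
    num <- suppressWarnings(as.numeric(value))
    if (!is.na(num)) return(num)
  }
  tolower(trimws(as.character(value)))
}

#' Equality of two field values under scoring normalization
#'
#' @param field Canonical parameter name.
#' @param a,b Values (concrete or `missing_value`).
#' @return `TRUE`/`FALSE`.
#' @export
values_match <- function(field, a, b) {
  na <- normalize_for_match(field, a)
  nb <- normalize_for_match(field, b)
  if (is.numeric(na) && is.numeric(nb)) return(abs(na - nb) <= 0.01)
  if (is.numeric(na) != is.numeric(nb)) return(FALSE)
  identical(na, nb)
}
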