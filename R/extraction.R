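# Report-to-record extraction: the extractor interface contract, a
# deterministic offline baseline (regex over the renderer's dialects), and
# tolerant parsing of LLM-style JSON output ({value, evidence, confidence}
# per parameter).

#' Construct an extraction result
#'
#' @param report_id Report identifier.
#' @param fields Named list over [PARAMETER_NAMES]; each element a list
#'   `value` (string/number or `missing_value`), `evidence` (verbatim
#'   substring of the source text, or `""`), `confidence` (in `[0,1]`).
#'   Omitted parameters become missing fields.
#' @return An object of class `extraction_result`.
#' @export
extraction_result <- function(report_id, fields = list()) {
  out <- stats::setNames(vector("list", length(PARAMETER_NAMES)),
                         PARAMETER_NAMES)
  for (p in PARAMETER_NAMES) {
    f <- fields[[p]]
    if (is.null(f)) {
      out[[p]] <- list(value = missing_value("not_mentioned"),
                       evidence = "", confidence = 0)
    } else {
      conf <- as.numeric(f$confidence %||% 0)
      stopifnot(conf >= 0, conf <= 1)
      out[[p]] <- list(value = f$value %||% missing_value("not_mentioned"),
                       evidence = as.character(f$evidence %||% ""),
                       confidence = conf)
    }
  }
  structure(list(report_id = report_id, fields = out),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat(sprintf("<extraction_result %s>\n", x$report_id))
  for (p in PARAMETER_NAMES) {
    f <- x$fields[[p]]
    v <- if (is_missing(f$value)) format(f$value) else as.character(f$value)
    cat(sprintf("  %-40s %-14s conf %.2f\n", p, v, f$confidence))
  }
  invisible(x)
}

extraction_failure <- function(report_id, reason) {
  structure(list(report_id = report_id, reason = reason),
            class = "extraction_failure")
}

#' Test for an extraction failure signal
#'
#' @param x Any object.
#' @return `TRUE` for the structured failure returned by
#'   [parse_extraction_json()] on malformed input.
#' @export
is_extraction_failure <- function(x) inherits(x, "extraction_failure")

#' Parse LLM-style extraction JSON
#'
#' Tolerant parsing of model output in the `{parameter: {value, evidence,
#' confidence}}` schema: markdown code fences and commentary around the
#' outermost `{...}` are stripped, unknown keys are ignored, missing keys
#' become missing fields. Malformed JSON yields a structured failure signal
#' (not an error) so callers can exclude the report from downstream
#' processing.
#'
#' @param text Raw model output.
#' @param report_id Identifier attached to the result or failure.
#' @return An [extraction_result()] or an `extraction_failure`.
#' @export
parse_extraction_json <- function(text, report_id = NA_character_) {
  if (is.null(text) || length(text) != 1 || is.na(text)) {
    return(extraction_failure(report_id, "no text"))
  }
  stripped <- gsub("```[a-zA-Z]*", "", text)
  first <- regexpr("{", stripped, fixed = TRUE)
  last <- max(gregexpr("}", stripped, fixed = TRUE)[[1]])
  if (first < 0 || last < 0 || last < first) {
    return(extraction_failure(report_id, "no JSON object found"))
  }
  payload <- substr(stripped, first, last)
  parsed <- tryCatch(jsonlite::fromJSON(payload, simplifyVector = FALSE),
                     error = function(e) e)
  if (inherits(parsed, "error")) {
    return(extraction_failure(report_id,
                              paste("malformed JSON:",
                                    conditionMessage(parsed))))
  }
  fields <- list()
  for (p in intersect(names(parsed), PARAMETER_NAMES)) {
    entry <- parsed[[p]]
    if (!is.list(entry)) entry <- list(value = entry)
    value <- entry$value
    if (is.null(value) ||
        (is.character(value) &&
         tolower(value) %in% c("not mentioned", "null", ""))) {
      value <- missing_value("not_mentioned")
    }
    conf <- suppressWarnings(as.numeric(entry$confidence %||% 0))
    fields[[p]] <- list(value = value,
                        evidence = entry$evidence %||% "",
                        confidence = min(1, max(0, conf, na.rm = TRUE)))
  }
  extraction_result(report_id, fields)
}

# regex helper: first match with capture groups; NULL when no match
rx <- function(text, pattern, ignore_case = TRUE) {
  m <- regexec(pattern, text, ignore.case = ignore_case, perl = TRUE)
  r <- regmatches(text, m)[[1]]
  if (length(r) == 0) NULL else r
}

#' Deterministic baseline extractor
#'
#' Pattern-based extraction of all 16 parameters from the report dialects
#' the synthetic renderer emits (synoptic key:value lines, narrative prose,
#' tabulated Grade-Group grid with an "X" mark). The Percentage of Secondary
#' Gleason Pattern is computed as the complement when the text states only
#' the primary pattern's share ("(60% pattern 4)" with primary 4 gives 40).
#' Evidence is the matched span; confidence is 1.0 for pattern hits and 0.0
#' for misses. Pure and total: unmatched parameters become missing fields,
#' never errors.
#'
#' @param text Report text.
#' @param report_id Identifier attached to the result.
#' @return An [extraction_result()].
#' @export
baseline_extract <- function(text, report_id = NA_character_) {
  fields <- list()
  hit <- function(parameter, value, evidence) {
    fields[[parameter]] <<- list(value = value, evidence = evidence,
                                 confidence = 1)
  }

  m <- rx(text, "\\b([pc]?T[1-4][abc]?)\\b", ignore_case = FALSE)
  if (!is.null(m)) hit("T-Stage", m[2], m[1])
  m <- rx(text, "\\b([pc]?N[01x])\\b", ignore_case = FALSE)
  if (!is.null(m)) hit("N-Stage", m[2], m[1])
  m <- rx(text, "\\b([pc]?M[01x])\\b", ignore_case = FALSE)
  if (!is.null(m)) hit("M-Stage", m[2], m[1])

  m <- rx(text, "PSA:?\\s*(?:was\\s*)?([0-9]+(?:\\.[0-9]+)?)\\s*ng/mL")
  if (!is.null(m)) hit("PSA", as.numeric(m[2]), m[1])

  m <- rx(text,
          paste0("Gleason score:?\\s*([3-5])\\s*\\+\\s*([3-5])\\s*=\\s*",
                 "[0-9]+[ab]?"))
  if (!is.null(m)) {
    hit("Primary Gleason Pattern", as.integer(m[2]), m[1])
    hit("Secondary Gleason Pattern", as.integer(m[3]), m[1])
    pct <- rx(text, "\\(([0-9]+(?:\\.[0-9]+)?)%\\s*pattern\\s*([3-5])\\)")
    if (!is.null(pct)) {
      share <- as.numeric(pct[2])
      which_pattern <- as.integer(pct[3])
      value <- if (which_pattern == as.integer(m[2])) {
        complement_secondary_percentage(share)  # primary's share stated
      } else {
        share
      }
      hit("Percentage of Secondary Gleason Pattern", value, pct[1])
    }
  }

  m <- rx(text, "Tertiary Gleason pattern:?\\s*([3-5])")
  if (!is.null(m)) hit("Tertiary Gleason Pattern", as.integer(m[2]), m[1])

  m <- rx(text, "WHO Grade Group:?\\s*([1-5])")
  if (is.null(m)) {
    m <- rx(text, "GG([1-5])\\s*\\|[^|\\n]*\\|\\s*X[ \\t]*(?:\\n|$)")
  }
  if (!is.null(m)) hit("WHO Grade Group", as.integer(m[2]), m[1])

  m <- rx(text, "((?:acinar|ductal) adenocarcinoma)")
  if (!is.null(m)) hit("Histologic Subtype", m[2], m[1])

  presence <- function(parameter, pattern) {
    m <- rx(text, paste0(pattern, "(?::| is)?\\s*(present|absent)"))
    if (!is.null(m)) {
      hit(parameter, paste0(toupper(substr(m[2], 1, 1)),
                            substring(m[2], 2)), m[1])
    }
  }
  presence("EPE", "Extraprostatic extension")
  presence("SVI", "Seminal vesicle invasion")
  presence("Perineural Invasion", "Perineural invasion")

  m <- rx(text, "Resection margins(?::| are)?\\s*([A-Za-z]+)")
  if (!is.null(m)) hit("Resection Margins", m[2], m[1])

  m <- rx(text, "Lymph nodes examined:\\s*([0-9]+)")
  if (is.null(m)) m <- rx(text, "([0-9]+) lymph nodes were examined")
  if (!is.null(m)) {
    hit("Number of Lymph Nodes examined", as.integer(m[2]), m[1])
  }
  m <- rx(text, "Lymph nodes with metastasis:\\s*([0-9]+)")
  if (is.null(m)) m <- rx(text, "([0-9]+) contained metastatic")
  if (!is.null(m)) hit("Lymph Nodes with Metastasis", as.integer(m[2]), m[1])

  extraction_result(report_id, fields)
}

#' Convert an extraction result to a typed pathology record
#'
#' Values are parsed with the record model's parsers: TNM tokens via
#' [parse_tnm()] (so `"pNx"` becomes an x_code missing value preserving its
#' literal), `"not mentioned"`/empty become not-mentioned missing values,
#' numerics are coerced locale-independently. Type-invalid values (e.g. a
#' non-numeric PSA) are dropped to missing and collected in
#' `attr(, "field_errors")` rather than raising.
#'
#' @param extraction An [extraction_result()].
#' @param patient_id Patient id for the record (defaults to the report id).
#' @return A [pathology_record()].
#' @export
to_record <- function(extraction, patient_id = NULL) {
  stopifnot(inherits(extraction, "extraction_result"))
  rid <- if (is.na(extraction$report_id)) "unknown" else extraction$report_id
  lst <- list(patient_id = patient_id %||% rid, report_id = rid)
  errors <- list()
  for (p in PARAMETER_NAMES) {
    value <- extraction$fields[[p]]$value
    if (is_missing(value)) {
      lst[[p]] <- field_to_json_value(value)
      next
    }
    coerced <- tryCatch({
      if (p %in% names(TNM_PARAMETERS)) {
        field_to_json_value(parse_tnm(value, TNM_PARAMETERS[[p]]))
      } else if (p %in% NUMERIC_PARAMETERS) {
        num <- suppressWarnings(as.numeric(value))
        if (is.na(num)) stop(sprintf("'%s' is not numeric", value))
        num
      } else {
        as.character(value)
      }
    }, error = function(e) e)
    if (inherits(coerced, "error")) {
      errors[[p]] <- conditionMessage(coerced)
      lst[[p]] <- field_to_json_value(missing_value("not_mentioned"))
    } else {
      lst[[p]] <- coerced
    }
  }
  record <- tryCatch(record_from_list(lst), error = function(e) e)
  if (inherits(record, "error")) {
    errors[["record"]] <- conditionMessage(record)
    lst[["Lymph Nodes with Metastasis"]] <-
      field_to_json_value(missing_value("not_mentioned"))
    record <- record_from_list(lst)
  }
  attr(record, "field_errors") <- errors
  record
}

#' Serialize extraction results as JSON Lines
#'
#' One object per report in the `{value, evidence, confidence}` schema.
#'
#' @param results List of [extraction_result()]s.
#' @param path Output path.
#' @export
write_extractions_jsonl <- function(results, path) {
  lines <- vapply(results, function(r) {
    obj <- list(report_id = r$report_id)
    for (p in PARAMETER_NAMES) {
      f <- r$fields[[p]]
      obj[[p]] <- list(
        value = if (is_missing(f$value)) "not mentioned" else f$value,
        evidence = f$evidence, confidence = f$confidence)
    }
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
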