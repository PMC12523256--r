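# JSON / JSONL serialization of pathology records.
# One JSON object per report: "patient_id", "report_id", and the 16
# canonical parameter keys. Missing values are encoded as
# {"missing": "<kind>", "literal": "<raw token>"}.

field_to_json_value <- function(value) {
  if (is_missing(value)) {
    return(list(missing = value$kind, literal = value$literal))
  }
  if (inherits(value, "tnm_code")) return(format(value))
  value
}

json_value_to_field <- function(x, field) {
  if (is.null(x)) return(missing_value("not_mentioned"))
  if (is.list(x) && !is.null(x$missing)) {
    return(missing_value(x$missing, literal = x$literal %||% NULL))
  }
  if (field %in% names(TNM_PARAMETERS)) {
    return(parse_tnm(x, TNM_PARAMETERS[[field]]))
  }
  x
}

#' Convert a pathology record to a plain list for JSON serialization
#'
#' @param record A [pathology_record()].
#' @return Named list with `patient_id`, `report_id` and the 16 parameters.
#' @export
record_to_list <- function(record) {
  out <- list(patient_id = record$patient_id, report_id = record$report_id)
  for (p in PARAMETER_NAMES) {
    out[[p]] <- field_to_json_value(record_field(record, p))
  }
  out
}

#' Rebuild a pathology record from its serialized list form
#'
#' @param x Named list as produced by [record_to_list()] (or parsed JSON).
#' @return A [pathology_record()].
#' @export
record_from_list <- function(x) {
  fv <- function(p) json_value_to_field(x[[p]], p)
  pathology_record(
    patient_id = as.character(x$patient_id),
    report_id = as.character(x$report_id),
    t_stage = fv("T-Stage"),
    n_stage = fv("N-Stage"),
    m_stage = fv("M-Stage"),
    gleason = gleason_info(
      primary = fv("Primary Gleason Pattern"),
      secondary = fv("Secondary Gleason Pattern"),
      tertiary = fv("Tertiary Gleason Pattern"),
      pct_secondary = fv("Percentage of Secondary Gleason Pattern"),
      reported_grade_group = fv("WHO Grade Group")),
    psa_ng_ml = fv("PSA"),
    epe = fv("EPE"),
    svi = fv("SVI"),
    perineural_invasion = fv("Perineural Invasion"),
    histologic_subtype = fv("Histologic Subtype"),
    resection_margins = fv("Resection Margins"),
    nodes_examined = fv("Number of Lymph Nodes examined"),
    nodes_with_metastasis = fv("Lymph Nodes with Metastasis"),
    allow_incoherent_counts = TRUE)
}

#' Write records as JSON Lines
#'
#' @param records List of [pathology_record()]s.
#' @param path Output file path.
#' @export
write_records_jsonl <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(record_to_list(r), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read records from JSON Lines
#'
#' @param path Input file path.
#' @return List of [pathology_record()]s.
#' @export
read_records_jsonl <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("record corpus not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    record_from_list(jsonlite::fromJSON(l, simplifyVector = FALSE))
  })
}
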