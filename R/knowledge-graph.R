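# In-memory property graph of pathology data, replacing a graph-database
# runtime. Six node labels (Patient, Pathology_Report, TNM_Stage, Grade,
# PSA_Value, AJCC_Stage); nodes are unique per (label, key); exports are
# deterministically ordered for diff-friendliness.

GRAPH_NODE_LABELS <- c("Patient", "Pathology_Report", "TNM_Stage", "Grade",
                       "PSA_Value", "AJCC_Stage")
GRAPH_EDGE_TYPES <- c("HAS_REPORT", "HAS_T_STAGE", "HAS_N_STAGE",
                      "HAS_M_STAGE", "HAS_GRADE", "HAS_PSA", "CLASSIFIED_AS")

empty_property_graph <- function() {
  structure(list(nodes = list(), edges = list()), class = "property_graph")
}

node_id <- function(label, key) paste(label, key, sep = "\x1f")

graph_add_node <- function(graph, label, key, properties = list()) {
  stopifnot(label %in% GRAPH_NODE_LABELS)
  id <- node_id(label, key)
  if (is.null(graph$nodes[[id]])) {
    graph$nodes[[id]] <- list(label = label, key = as.character(key),
                              properties = properties)
  }
  graph
}

graph_add_edge <- function(graph, type, source_label, source_key,
                           target_label, target_key) {
  stopifnot(type %in% GRAPH_EDGE_TYPES)
  graph$edges[[length(graph$edges) + 1L]] <-
    list(type = type,
         source_label = source_label, source_key = as.character(source_key),
         target_label = target_label, target_key = as.character(target_key))
  graph
}

#' @export
print.property_graph <- function(x, ...) {
  cat(sprintf("<property_graph: %d nodes, %d edges>\n",
              length(x$nodes), length(x$edges)))
  invisible(x)
}

psa_node_key <- function(psa) sprintf("%.2f", round(psa, 2))

record_report_properties <- function(record) {
  props <- list()
  put <- function(name, value) {
    if (!is_missing(value)) props[[name]] <<- value
  }
  put("histologic_subtype", record$histologic_subtype)
  put("resection_margins", record$resection_margins)
  put("nodes_examined", record$nodes_examined)
  put("nodes_with_metastasis", record$nodes_with_metastasis)
  put("primary_gleason_pattern", record$gleason$primary)
  put("secondary_gleason_pattern", record$gleason$secondary)
  put("tertiary_gleason_pattern", record$gleason$tertiary)
  put("pct_secondary_gleason_pattern", record$gleason$pct_secondary)
  put("epe", record$epe)
  put("svi", record$svi)
  put("perineural_invasion", record$perineural_invasion)
  props
}

#' Build the property graph from records and staging results
#'
#' One `Patient` node per distinct patient, one `Pathology_Report` node per
#' record (carrying the non-staging fields as properties), and shared
#' `TNM_Stage` (keyed by code + category), `Grade`, `PSA_Value` (value
#' rounded to 2 decimals) and `AJCC_Stage` nodes deduplicated by key.
#' Missing fields produce no edge. The `HAS_GRADE` target is the effective
#' Grade Group used for staging (reported, else pattern-derived).
#'
#' @param records List of [pathology_record()]s (distinct `report_id`s).
#' @param stagings List of `staging_result`s, or `NULL` to compute them with
#'   [stage_record()].
#' @param pmx_policy Passed to [stage_record()] when stagings are computed.
#' @return A `property_graph`.
#' @export
build_graph <- function(records, stagings = NULL,
                        pmx_policy = c("impute", "block")) {
  pmx_policy <- match.arg(pmx_policy)
  ids <- vapply(records, `[[`, character(1), "report_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate report_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(stagings)) {
    stagings <- lapply(records, stage_record, pmx_policy = pmx_policy)
  }
  staging_by_id <- stats::setNames(stagings,
                                   vapply(stagings, `[[`, character(1),
                                          "report_id"))
  g <- empty_property_graph()
  for (record in records) {
    rid <- record$report_id
    g <- graph_add_node(g, "Patient", record$patient_id,
                        list(patient_id = record$patient_id))
    g <- graph_add_node(g, "Pathology_Report", rid,
                        record_report_properties(record))
    g <- graph_add_edge(g, "HAS_REPORT", "Patient", record$patient_id,
                        "Pathology_Report", rid)
    for (cat in c(T = "T", N = "N", M = "M")) {
      stage_field <- switch(cat, T = record$t_stage, N = record$n_stage,
                            M = record$m_stage)
      if (is_missing(stage_field)) next
      key <- paste(stage_field$code, cat, sep = "|")
      g <- graph_add_node(g, "TNM_Stage", key,
                          list(code = stage_field$code, type = cat))
      g <- graph_add_edge(g, paste0("HAS_", cat, "_STAGE"),
                          "Pathology_Report", rid, "TNM_Stage", key)
    }
    input <- staging_input_from_record(record)
    if (!is_missing(input$gg)) {
      g <- graph_add_node(g, "Grade", input$gg,
                          list(grade_group = input$gg))
      g <- graph_add_edge(g, "HAS_GRADE", "Pathology_Report", rid,
                          "Grade", input$gg)
    }
    if (!is_missing(record$psa_ng_ml)) {
      key <- psa_node_key(record$psa_ng_ml)
      g <- graph_add_node(g, "PSA_Value", key,
                          list(value = as.numeric(key)))
      g <- graph_add_edge(g, "HAS_PSA", "Pathology_Report", rid,
                          "PSA_Value", key)
    }
    staging <- staging_by_id[[rid]]
    if (!is.null(staging)) {
      label <- stage_label(staging)
      g <- graph_add_node(g, "AJCC_Stage", label, list(stage = label))
      g <- graph_add_edge(g, "CLASSIFIED_AS", "Pathology_Report", rid,
                          "AJCC_Stage", label)
    }
  }
  g
}

report_neighbors <- function(graph, report_id) {
  Filter(function(e) e$source_label == "Pathology_Report" &&
           e$source_key == report_id, graph$edges)
}

#' Re-derive a report's AJCC stage from the graph
#'
#' Reads the report's `HAS_T/N/M_STAGE`, `HAS_GRADE` and `HAS_PSA`
#' neighbors, reconstructs a [staging_input()] (absent edges become missing
#' fields), and applies [impute_m()] + [assign_stage()]. Under the default
#' `pmx_policy = "impute"` the returned label equals the `CLASSIFIED_AS`
#' target stored at build time.
#'
#' @param graph A `property_graph`.
#' @param report_id Report identifier; unknown ids are an error.
#' @param pmx_policy Passed to [impute_m()].
#' @return Character stage label.
#' @export
stage_from_graph <- function(graph, report_id,
                             pmx_policy = c("impute", "block")) {
  pmx_policy <- match.arg(pmx_policy)
  if (is.null(graph$nodes[[node_id("Pathology_Report", report_id)]])) {
    stop(sprintf("unknown report_id: '%s'", report_id), call. = FALSE)
  }
  edges <- report_neighbors(graph, report_id)
  pick <- function(type) Filter(function(e) e$type == type, edges)
  tnm_of <- function(type) {
    es <- pick(type)
    if (length(es) == 0) return(missing_value("not_mentioned"))
    strsplit(es[[1]]$target_key, "|", fixed = TRUE)[[1]][1]
  }
  gg_edges <- pick("HAS_GRADE")
  psa_edges <- pick("HAS_PSA")
  input <- staging_input(
    t = tnm_of("HAS_T_STAGE"), n = tnm_of("HAS_N_STAGE"),
    m = tnm_of("HAS_M_STAGE"),
    grade_group = if (length(gg_edges)) as.integer(gg_edges[[1]]$target_key)
                  else missing_value("not_mentioned"),
    psa = if (length(psa_edges)) as.numeric(psa_edges[[1]]$target_key)
          else missing_value("not_mentioned"))
  stage_label(assign_stage(impute_m(input, pmx_policy)))
}

sorted_nodes <- function(graph) {
  if (length(graph$nodes) == 0) return(list())
  ord <- order(vapply(graph$nodes, `[[`, character(1), "label"),
               vapply(graph$nodes, `[[`, character(1), "key"),
               method = "radix")
  unname(graph$nodes[ord])
}

sorted_edges <- function(graph) {
  if (length(graph$edges) == 0) return(list())
  keyfun <- function(f) vapply(graph$edges, `[[`, character(1), f)
  ord <- order(keyfun("type"), keyfun("source_label"), keyfun("source_key"),
               keyfun("target_label"), keyfun("target_key"),
               method = "radix")
  unname(graph$edges[ord])
}

cypher_props <- function(properties) {
  if (length(properties) == 0) return("")
  parts <- vapply(names(properties), function(nm) {
    v <- properties[[nm]]
    val <- if (is.numeric(v)) {
      format(v, scientific = FALSE, trim = TRUE)
    } else {
      sprintf("'%s'", gsub("'", "\\\\'", as.character(v)))
    }
    sprintf("%s: %s", nm, val)
  }, character(1))
  paste0(", ", paste(parts, collapse = ", "))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Export the property graph
#'
#' @param graph A `property_graph`.
#' @param format `"json"` (nodes + edges arrays), `"cypher"` (a script of
#'   MERGE statements, nodes then relationships), or `"graphml"`.
#' @param path Optional file to write (UTF-8).
#' @return The export as a single character string (invisibly when `path`
#'   is given).
#' @export
export_graph <- function(graph, format = c("json", "cypher", "graphml"),
                         path = NULL) {
  format <- match.arg(format)
  nodes <- sorted_nodes(graph)
  edges <- sorted_edges(graph)
  out <- switch(format,
    json = as.character(jsonlite::toJSON(
      list(nodes = lapply(nodes, function(n)
             list(label = n$label, key = n$key, properties = n$properties)),
           edges = lapply(edges, function(e)
             list(type = e$type, source_label = e$source_label,
                  source_key = e$source_key, target_label = e$target_label,
                  target_key = e$target_key))),
      auto_unbox = TRUE, digits = NA, pretty = FALSE)),
    cypher = {
      stmts <- c(
        vapply(nodes, function(n) {
          sprintf("MERGE (:%s {_key: '%s'%s});", n$label,
                  gsub("'", "\\\\'", n$key), cypher_props(n$properties))
        }, character(1)),
        vapply(edges, function(e) {
          sprintf(paste0("MATCH (a:%s {_key: '%s'}), (b:%s {_key: '%s'}) ",
                         "MERGE (a)-[:%s]->(b);"),
                  e$source_label, gsub("'", "\\\\'", e$source_key),
                  e$target_label, gsub("'", "\\\\'", e$target_key), e$type)
        }, character(1)))
      paste0(paste(stmts, collapse = "\n"),
             if (length(stmts)) "\n" else "")
    },
    graphml = {
      prop_keys <- sort(unique(unlist(lapply(nodes, function(n)
        names(n$properties)))))
      header <- c(
        '<?xml version="1.0" encoding="UTF-8"?>',
        '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
        '  <key id="label" for="node" attr.name="label" attr.type="string"/>',
        '  <key id="type" for="edge" attr.name="type" attr.type="string"/>',
        vapply(prop_keys, function(k) sprintf(
          '  <key id="p_%s" for="node" attr.name="%s" attr.type="string"/>',
          k, k), character(1)),
        '  <graph id="G" edgedefault="directed">')
      node_xml <- unlist(lapply(nodes, function(n) {
        c(sprintf('    <node id="%s">',
                  xml_escape(paste(n$label, n$key, sep = "::"))),
          sprintf('      <data key="label">%s</data>', xml_escape(n$label)),
          vapply(names(n$properties), function(k) sprintf(
            '      <data key="p_%s">%s</data>', k,
            xml_escape(as.character(n$properties[[k]]))), character(1)),
          '    </node>')
      }))
      edge_xml <- unlist(lapply(edges, function(e) {
        c(sprintf('    <edge source="%s" target="%s">',
                  xml_escape(paste(e$source_label, e$source_key, sep = "::")),
                  xml_escape(paste(e$target_label, e$target_key,
                                   sep = "::"))),
          sprintf('      <data key="type">%s</data>', e$type),
          '    </edge>')
      }))
      paste(c(header, node_xml, edge_xml, "  </graph>", "</graphml>", ""),
            collapse = "\n")
    })
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(out), con)
    return(invisible(out))
  }
  out
}

#' Parse a JSON graph dump back into a property graph
#'
#' Inverse of `export_graph(graph, "json")`; export -> parse -> export is
#' byte-identical.
#'
#' @param text JSON string (or path to a file when `is_path = TRUE`).
#' @param is_path Treat `text` as a file path.
#' @return A `property_graph`.
#' @export
parse_graph_json <- function(text, is_path = FALSE) {
  if (is_path) text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  parsed <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  g <- empty_property_graph()
  for (n in parsed$nodes) {
    g <- graph_add_node(g, n$label, n$key, n$properties %||% list())
  }
  for (e in parsed$edges) {
    g <- graph_add_edge(g, e$type, e$source_label, e$source_key,
                        e$target_label, e$target_key)
  }
  g
}

#' Node and edge counts of a property graph
#'
#' @param graph A `property_graph`.
#' @return Named list `n_nodes`, `n_edges`, `nodes_by_label`,
#'   `edges_by_type`.
#' @export
graph_counts <- function(graph) {
  labels <- vapply(graph$nodes, `[[`, character(1), "label")
  types <- vapply(graph$edges, `[[`, character(1), "type")
  list(n_nodes = length(graph$nodes), n_edges = length(graph$edges),
       nodes_by_label = table(factor(labels, levels = GRAPH_NODE_LABELS)),
       edges_by_type = table(factor(types, levels = GRAPH_EDGE_TYPES)))
}
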