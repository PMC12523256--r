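# Bundled reference benchmark tables (printed values from published
# extraction/staging evaluations) used as inputs by the arithmetic
# reproduction checks.

#' Load a bundled benchmark table
#'
#' @param name One of `"extraction_benchmark_internal"` (n = 150 documents),
#'   `"extraction_benchmark_external"` (n = 88),
#'   `"staging_benchmark_internal"`, `"staging_benchmark_external"`,
#'   `"stage_distribution"`.
#' @return Data frame.
#' @export
load_benchmark <- function(name = c("extraction_benchmark_internal",
                                    "extraction_benchmark_external",
                                    "staging_benchmark_internal",
                                    "staging_benchmark_external",
                                    "stage_distribution")) {
  name <- match.arg(name)
  path <- system.file("extdata", "benchmarks", paste0(name, ".tsv"),
                      package = "prostaging", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Document counts of the bundled extraction benchmarks
#'
#' @param name Benchmark name as in [load_benchmark()].
#' @return Number of documents the benchmark's counts are taken over.
#' @export
benchmark_n_docs <- function(name) {
  switch(name,
         extraction_benchmark_internal = 150L,
         extraction_benchmark_external = 88L,
         stop("no document count for ", name, call. = FALSE))
}
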