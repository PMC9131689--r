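# End-to-end wiring: configuration validation, the parse -> cascade ->
# classify -> aggregate -> write sequence, staged atomic output and the
# FilterTrace sidecar.

#' Build and validate a pipeline configuration
#'
#' @param input Path to the registry export.
#' @param format `"xml"` or `"flat"`.
#' @param vocabulary Path to the NDD vocabulary YAML.
#' @param lexicon_dir Directory of intervention-class lexicons.
#' @param annotation_table Path to the agent annotation CSV.
#' @param window Length-2 update-window dates.
#' @param fuzzy_threshold Optional override of the vocabulary's edit-distance
#'   threshold.
#' @param exclude_enrollment_ids Ids treated as extremes by the enrollment
#'   mean.
#' @param recency_cutoff Date for the recency fraction.
#' @param out_dir Output directory for the report bundle.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input, format = c("flat", "xml"),
                            vocabulary = tb_resource("ndd_vocabulary.yaml"),
                            lexicon_dir = tb_resource("lexicons"),
                            annotation_table = tb_resource("agent_annotations.csv"),
                            window = default_update_window(),
                            fuzzy_threshold = NULL,
                            exclude_enrollment_ids = character(),
                            recency_cutoff = as.Date("2016-06-06"),
                            out_dir) {
  format <- match.arg(format)
  for (path in c(input, vocabulary, annotation_table)) {
    if (!file.exists(path)) {
      abort(sprintf("no such file: %s", path), class = "trialbasket_config_error")
    }
  }
  if (!dir.exists(lexicon_dir)) {
    abort(sprintf("no such lexicon directory: %s", lexicon_dir),
          class = "trialbasket_config_error")
  }
  window <- as.Date(window)
  if (length(window) != 2 || any(is.na(window)) || window[1] > window[2]) {
    abort("window must be two dates with start <= end",
          class = "trialbasket_config_error")
  }
  structure(list(input = input, format = format, vocabulary = vocabulary,
                 lexicon_dir = lexicon_dir,
                 annotation_table = annotation_table, window = window,
                 fuzzy_threshold = fuzzy_threshold,
                 exclude_enrollment_ids = exclude_enrollment_ids,
                 recency_cutoff = as.Date(recency_cutoff),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the whole pipeline
#'
#' Executes parse -> filter cascade -> agent classification -> aggregation ->
#' table writing. Output is staged in a temporary sibling directory and moved
#' into place only after every table is written, so a failed run leaves no
#' partial outputs; identical inputs produce byte-identical output
#' directories.
#'
#' @param config A `pipeline_config`.
#' @param quiet Suppress the FilterTrace log lines on stderr.
#' @return The `summary_bundle`, invisibly, with the output directory in
#'   attribute `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dataset <- switch(config$format,
                    xml = parse_registry_xml(config$input),
                    flat = parse_flat_table(config$input))
  vocab <- load_vocabulary(config$vocabulary)
  if (!is.null(config$fuzzy_threshold)) {
    vocab$fuzzy_threshold <- as.integer(config$fuzzy_threshold)
  }
  lexicons <- load_lexicons(config$lexicon_dir)
  annotations <- load_agent_annotations(config$annotation_table)
  cascade <- run_filter_cascade(dataset, vocab, lexicons, annotations,
                                window = config$window)
  if (!quiet) {
    msg <- paste(sprintf("%s=%d", names(cascade$trace),
                         unlist(cascade$trace)), collapse = " ")
    message("filter cascade: ", msg)
  }
  bundle <- build_summary_bundle(
    cascade, annotations,
    exclude_enrollment_ids = config$exclude_enrollment_ids,
    recency_cutoff = config$recency_cutoff)

  staging <- paste0(config$out_dir, ".staging")
  if (dir.exists(staging)) unlink(staging, recursive = TRUE)
  write_tables(bundle, staging)
  if (dir.exists(config$out_dir)) unlink(config$out_dir, recursive = TRUE)
  ok <- file.rename(staging, config$out_dir)
  if (!ok) {
    # cross-device fallback: copy then remove
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    file.copy(list.files(staging, full.names = TRUE), config$out_dir)
    unlink(staging, recursive = TRUE)
  }
  attr(bundle, "out_dir") <- config$out_dir
  invisible(bundle)
}
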