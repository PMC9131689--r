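# Trial-record data model and registry I/O (XML study records and flat
# one-row-per-trial tables).

FLAT_COLUMNS <- c(
  "nct_id", "title", "conditions", "eligibility_text", "intervention_names",
  "intervention_types", "phase_labels", "status", "study_type",
  "last_update_date", "start_date", "projected_end_date", "actual_end_date",
  "enrollment", "n_arms", "biomarker_described", "sponsor_class",
  "age_min", "age_max"
)

# Intra-cell separator for multi-valued flat-table cells. "|" because commas
# occur inside condition names and treatment-goal text.
CELL_SEP <- "|"

#' Construct a single trial record
#'
#' Builds a one-row tibble in the registry-record layout used throughout the
#' package. Multi-valued fields (`conditions`, `phase_labels`) are character
#' vectors; `interventions` is a data frame with columns `name` and
#' `declared_type` (the registry's free-text intervention type, `NA` when the
#' registry did not declare one).
#'
#' @param nct_id Registry identifier, `"NCT"` followed by 8 digits.
#' @param title Free-text study title.
#' @param conditions Character vector of free-text condition names.
#' @param eligibility_text Free text, optionally containing
#'   "Inclusion Criteria" / "Exclusion Criteria" blocks.
#' @param interventions Data frame with columns `name`, `declared_type`.
#' @param phase_labels Subset of `phase 1`..`phase 4`, `not applicable`.
#' @param status Registry status (see [registry_statuses()][ndd_labels]).
#' @param study_type `"interventional"`, `"observational"` or `"other"`.
#' @param last_update_date,start_date,projected_end_date,actual_end_date
#'   `Date` or `NA`.
#' @param enrollment,n_arms Non-negative integer or `NA`.
#' @param biomarker_described Logical.
#' @param sponsor_class One of `biopharma`, `nih_academic`, `public_private`,
#'   `other`.
#' @param age_min,age_max Optional age range in years.
#' @return A one-row tibble.
#' @export
trial_record <- function(nct_id, title = NA_character_,
                         conditions = character(),
                         eligibility_text = NA_character_,
                         interventions = NULL,
                         phase_labels = character(),
                         status = "unknown",
                         study_type = "interventional",
                         last_update_date = as.Date(NA),
                         start_date = as.Date(NA),
                         projected_end_date = as.Date(NA),
                         actual_end_date = as.Date(NA),
                         enrollment = NA_integer_,
                         n_arms = NA_integer_,
                         biomarker_described = FALSE,
                         sponsor_class = "other",
                         age_min = NA_real_, age_max = NA_real_) {
  if (is.null(interventions)) {
    interventions <- tibble(name = character(), declared_type = character())
  }
  interventions <- as_tibble(interventions)
  tibble(
    nct_id = nct_id, title = title,
    conditions = list(unname(as.character(conditions))),
    eligibility_text = eligibility_text,
    interventions = list(interventions),
    phase_labels = list(unname(as.character(phase_labels))),
    status = status, study_type = study_type,
    last_update_date = as.Date(last_update_date),
    start_date = as.Date(start_date),
    projected_end_date = as.Date(projected_end_date),
    actual_end_date = as.Date(actual_end_date),
    enrollment = as.integer(enrollment), n_arms = as.integer(n_arms),
    biomarker_described = isTRUE(biomarker_described),
    sponsor_class = sponsor_class,
    age_min = as.numeric(age_min), age_max = as.numeric(age_max)
  )
}

#' Assemble and validate a registry dataset
#'
#' @param records Tibble of trial records ([trial_record()] rows bound
#'   together), possibly zero rows.
#' @param provenance List tagging the source (`path`, `encoding`).
#' @return A `registry_dataset` object.
#' @export
registry_dataset <- function(records = NULL,
                             provenance = list(path = NA_character_,
                                               encoding = "memory")) {
  if (is.null(records) || nrow(records) == 0) {
    records <- trial_record("NCT00000000")[0, ]
  }
  validate_records(records)
  structure(list(records = as_tibble(records), provenance = provenance),
            class = "registry_dataset")
}

validate_records <- function(records) {
  ids <- records$nct_id
  bad <- ids[!is_valid_nct(ids)]
  if (length(bad) > 0) {
    abort(sprintf("invalid NCT identifier(s): %s",
                  paste(utils::head(bad, 5), collapse = ", ")),
          class = "trialbasket_validation_error")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate NCT identifier(s): %s",
                  paste(dup, collapse = ", ")),
          class = "trialbasket_validation_error")
  }
  for (i in seq_len(nrow(records))) {
    ph <- records$phase_labels[[i]]
    if (anyDuplicated(ph)) {
      abort(sprintf("%s: duplicated phase labels", ids[i]),
            class = "trialbasket_validation_error")
    }
    enr <- records$enrollment[i]
    if (!is.na(enr) && enr < 0) {
      abort(sprintf("%s: negative enrollment", ids[i]),
            class = "trialbasket_validation_error")
    }
    iv <- records$interventions[[i]]
    if (nrow(iv) > 0 && any(!nzchar(trimws(iv$name)))) {
      abort(sprintf("%s: empty intervention name", ids[i]),
            class = "trialbasket_validation_error")
    }
    if (!records$sponsor_class[i] %in% sponsor_classes()) {
      abort(sprintf("%s: unknown sponsor class '%s'", ids[i],
                    records$sponsor_class[i]),
            class = "trialbasket_validation_error")
    }
  }
  invisible(records)
}

#' @export
print.registry_dataset <- function(x, ...) {
  cat(sprintf("<registry_dataset> %d records (source: %s, %s)\n",
              nrow(x$records),
              x$provenance$path %||% "<memory>", x$provenance$encoding))
  invisible(x)
}

# --- XML ingestion -----------------------------------------------------------

#' Parse a clinicaltrials.gov-style XML study-record file
#'
#' Reads a file containing one or more `<clinical_study>` elements (either as
#' root or under a container element) and extracts the captured-field subset
#' of the public study-record schema; all other elements are ignored by
#' design, which makes the reader tolerant of schema versions.
#'
#' @param path Path to an XML file.
#' @return A `registry_dataset`.
#' @export
parse_registry_xml <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "trialbasket_io_error")
  }
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(sprintf("malformed XML in %s: %s", path, conditionMessage(e)),
          class = "trialbasket_parse_error")
  })
  studies <- if (xml2::xml_name(doc) == "clinical_study") {
    list(doc)
  } else {
    as.list(xml2::xml_find_all(doc, ".//clinical_study"))
  }
  rows <- lapply(studies, parse_study_element)
  records <- if (length(rows) == 0) NULL else bind_rows(rows)
  registry_dataset(records, provenance = list(path = path, encoding = "xml"))
}

xml_text1 <- function(node, xpath) {
  n <- xml2::xml_find_first(node, xpath)
  if (inherits(n, "xml_missing")) NA_character_ else trimws(xml2::xml_text(n))
}

parse_study_element <- function(study) {
  nct <- xml_text1(study, ".//id_info/nct_id")
  if (is.na(nct)) nct <- xml_text1(study, ".//nct_id")
  if (is.na(nct)) {
    abort("study element without an NCT identifier",
          class = "trialbasket_validation_error")
  }
  iv_nodes <- xml2::xml_find_all(study, "./intervention")
  interventions <- tibble(
    name = vapply(iv_nodes, function(n) xml_text1(n, "./intervention_name"),
                  character(1)),
    declared_type = vapply(iv_nodes,
                           function(n) {
                             t <- xml_text1(n, "./intervention_type")
                             if (is.na(t)) NA_character_ else tolower(t)
                           }, character(1))
  )
  completion <- xml2::xml_find_first(study, "./completion_date")
  proj_end <- actual_end <- NA_character_
  if (!inherits(completion, "xml_missing")) {
    type <- xml2::xml_attr(completion, "type")
    val <- trimws(xml2::xml_text(completion))
    if (identical(type, "Actual")) actual_end <- val else proj_end <- val
  }
  update <- xml_text1(study, "./last_update_posted")
  if (is.na(update)) update <- xml_text1(study, "./last_update_submitted")
  trial_record(
    nct_id = nct,
    title = xml_text1(study, "./brief_title"),
    conditions = trimws(xml2::xml_text(xml2::xml_find_all(study, "./condition"))),
    eligibility_text = xml_text1(study, "./eligibility/criteria/textblock"),
    interventions = interventions,
    phase_labels = parse_phase_string(xml_text1(study, "./phase")),
    status = normalize_status(xml_text1(study, "./overall_status")),
    study_type = normalize_study_type(xml_text1(study, "./study_type")),
    last_update_date = parse_registry_date(update, "last_update_posted"),
    start_date = parse_registry_date(xml_text1(study, "./start_date"), "start_date"),
    projected_end_date = parse_registry_date(proj_end, "completion_date"),
    actual_end_date = parse_registry_date(actual_end, "completion_date"),
    enrollment = parse_count(xml_text1(study, "./enrollment")),
    n_arms = parse_count(xml_text1(study, "./number_of_arms")),
    biomarker_described = !is.na(xml_text1(study, "./biospec_descr/textblock")),
    sponsor_class = normalize_sponsor(
      xml_text1(study, "./sponsors/lead_sponsor/agency_class")),
    age_min = parse_age(xml_text1(study, "./eligibility/minimum_age")),
    age_max = parse_age(xml_text1(study, "./eligibility/maximum_age"))
  )
}

parse_phase_string <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  parts <- trimws(strsplit(x, "/")[[1]])
  out <- vapply(parts, function(p) {
    p <- tolower(p)
    if (p %in% c("n/a", "na", "not applicable")) return("not applicable")
    p <- gsub("phase\\s*", "phase ", p)
    if (p %in% phase_vocabulary()) p else NA_character_
  }, character(1), USE.NAMES = FALSE)
  unique(out[!is.na(out)])
}

normalize_status <- function(x) {
  if (is.na(x)) return("unknown")
  s <- normalize_text(x)
  if (s == "unknown status") s <- "unknown"
  if (!s %in% registry_statuses()) {
    warn(sprintf("unrecognized registry status '%s'; recorded as 'unknown'", x))
    s <- "unknown"
  }
  s
}

normalize_study_type <- function(x) {
  if (is.na(x)) return("other")
  s <- normalize_text(x)
  if (startsWith(s, "interventional")) return("interventional")
  if (startsWith(s, "observational")) return("observational")
  "other"
}

normalize_sponsor <- function(x) {
  if (is.na(x)) return("other")
  s <- normalize_text(x)
  if (s %in% sponsor_classes()) return(s)
  switch(s,
         "industry" = "biopharma",
         "nih" = "nih_academic",
         "nih academic" = "nih_academic",
         "public private" = "public_private",
         "other")
}

parse_count <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NA_integer_)
  n <- suppressWarnings(as.integer(x))
  if (is.na(n) || n < 0) {
    abort(sprintf("invalid count '%s'", x), class = "trialbasket_parse_error")
  }
  n
}

parse_age <- function(x) {
  if (is.na(x) || toupper(x) == "N/A") return(NA_real_)
  m <- regmatches(x, regexec("^([0-9]+)\\s*(Year|Month|Week|Day)s?", x,
                             ignore.case = TRUE))[[1]]
  if (length(m) == 0) return(NA_real_)
  val <- as.numeric(m[2])
  switch(tolower(m[3]), year = val, month = val / 12,
         week = val / 52.18, day = val / 365.25)
}

# --- Flat-table I/O ----------------------------------------------------------

#' Read a flat one-row-per-trial registry table
#'
#' The table is a UTF-8 CSV with a header row; multi-valued cells use `"|"`
#' as the intra-cell separator (commas occur inside condition names).
#' `intervention_names` and `intervention_types` are parallel `"|"`-joined
#' lists.
#'
#' @param path Path to the CSV file.
#' @return A `registry_dataset`.
#' @export
parse_flat_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "trialbasket_io_error")
  }
  df <- utils::read.csv(path, colClasses = "character", comment.char = "#",
                        check.names = FALSE, na.strings = NULL)
  if (!"nct_id" %in% names(df)) {
    abort("flat table is missing the nct_id column",
          class = "trialbasket_schema_error")
  }
  missing_cols <- setdiff(FLAT_COLUMNS, names(df))
  for (col in missing_cols) df[[col]] <- rep("", nrow(df))
  blank <- which(!nzchar(trimws(df$nct_id)))
  if (length(blank) > 0) {
    abort(sprintf("blank nct_id at data row(s): %s",
                  paste(blank, collapse = ", ")),
          class = "trialbasket_schema_error")
  }
  rows <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    nm <- split_cell(r$intervention_names)
    ty <- split_cell(r$intervention_types, keep_empty = TRUE)
    if (length(ty) < length(nm)) ty <- c(ty, rep(NA_character_, length(nm) - length(ty)))
    trial_record(
      nct_id = r$nct_id,
      title = blank_na(r$title),
      conditions = split_cell(r$conditions),
      eligibility_text = blank_na(r$eligibility_text),
      interventions = tibble(name = nm, declared_type = ty[seq_along(nm)]),
      phase_labels = split_cell(r$phase_labels),
      status = normalize_status(blank_na(r$status)),
      study_type = normalize_study_type(blank_na(r$study_type)),
      last_update_date = parse_registry_date(blank_na(r$last_update_date)),
      start_date = parse_registry_date(blank_na(r$start_date)),
      projected_end_date = parse_registry_date(blank_na(r$projected_end_date)),
      actual_end_date = parse_registry_date(blank_na(r$actual_end_date)),
      enrollment = blank_int(r$enrollment),
      n_arms = blank_int(r$n_arms),
      biomarker_described = identical(r$biomarker_described, "true"),
      sponsor_class = normalize_sponsor(blank_na(r$sponsor_class)),
      age_min = blank_num(r$age_min),
      age_max = blank_num(r$age_max)
    )
  })
  records <- if (length(rows) == 0) NULL else bind_rows(rows)
  registry_dataset(records, provenance = list(path = path, encoding = "flat"))
}

split_cell <- function(x, keep_empty = FALSE) {
  if (is.na(x) || !nzchar(x)) return(character())
  parts <- trimws(strsplit(x, CELL_SEP, fixed = TRUE)[[1]])
  if (keep_empty) ifelse(nzchar(parts), parts, NA_character_)
  else parts[nzchar(parts)]
}

blank_na <- function(x) if (is.na(x) || !nzchar(x)) NA_character_ else x
blank_int <- function(x) if (is.na(x) || !nzchar(x)) NA_integer_ else as.integer(x)
blank_num <- function(x) if (is.na(x) || !nzchar(x)) NA_real_ else as.numeric(x)

#' Write a registry dataset as a flat table
#'
#' Deterministic: fixed column order, rows sorted by `nct_id`, so writing the
#' same dataset twice yields byte-identical files. Re-parsable by
#' [parse_flat_table()].
#'
#' @param dataset A `registry_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flat_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "registry_dataset"))
  rec <- dataset$records
  rec <- rec[order(rec$nct_id), ]
  fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))
  fmt_na <- function(x) ifelse(is.na(x), "", as.character(x))
  out <- tibble(
    nct_id = rec$nct_id,
    title = fmt_na(rec$title),
    conditions = vapply(rec$conditions, paste, character(1), collapse = CELL_SEP),
    eligibility_text = fmt_na(rec$eligibility_text),
    intervention_names = vapply(rec$interventions, function(iv)
      paste(iv$name, collapse = CELL_SEP), character(1)),
    intervention_types = vapply(rec$interventions, function(iv)
      paste(ifelse(is.na(iv$declared_type), "", iv$declared_type),
            collapse = CELL_SEP), character(1)),
    phase_labels = vapply(rec$phase_labels, paste, character(1), collapse = CELL_SEP),
    status = rec$status,
    study_type = rec$study_type,
    last_update_date = fmt_date(rec$last_update_date),
    start_date = fmt_date(rec$start_date),
    projected_end_date = fmt_date(rec$projected_end_date),
    actual_end_date = fmt_date(rec$actual_end_date),
    enrollment = fmt_na(rec$enrollment),
    n_arms = fmt_na(rec$n_arms),
    biomarker_described = ifelse(rec$biomarker_described, "true", "false"),
    sponsor_class = rec$sponsor_class,
    age_min = fmt_na(rec$age_min),
    age_max = fmt_na(rec$age_max)
  )
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(paste0("# registry flat table; intra-cell separator: ", CELL_SEP),
             con)
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}
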