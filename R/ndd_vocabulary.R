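# Disease-name normalization: free-text condition names and eligibility
# criteria are mapped to the 10 canonical NDD reporting labels, tolerating
# spelling variants, misspellings and alternate names. Stage variants
# (PDD -> PD, LBD -> DLB, FTD -> FTLD) fold into their reporting label at the
# vocabulary level, so stage-only disease combinations can never look like a
# multi-disorder basket downstream.

#' Load an NDD vocabulary resource
#'
#' The resource is a YAML file mapping each canonical reporting label to a
#' list of variant strings (full names, abbreviations, alternate names and
#' folded stage variants). Variants are normalized (case, punctuation) at
#' load; a variant assigned to two different labels is a load-time error,
#' never silently resolved.
#'
#' @param path Path to the YAML resource. Defaults to the packaged
#'   vocabulary.
#' @return An `ndd_vocabulary` object with the normalized variant lookup and
#'   the fuzzy-match threshold.
#' @export
load_vocabulary <- function(path = tb_resource("ndd_vocabulary.yaml")) {
  raw <- yaml::read_yaml(path)
  labels <- raw$labels
  if (is.null(labels)) {
    abort("vocabulary file has no 'labels' section",
          class = "trialbasket_resource_error")
  }
  unknown <- setdiff(names(labels), ndd_labels())
  if (length(unknown) > 0) {
    abort(sprintf("vocabulary defines non-canonical label(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "trialbasket_resource_error")
  }
  missing <- setdiff(ndd_labels(), names(labels))
  if (length(missing) > 0) {
    abort(sprintf("vocabulary missing label(s): %s",
                  paste(missing, collapse = ", ")),
          class = "trialbasket_resource_error")
  }
  lookup <- tibble(
    label = rep(names(labels), lengths(labels)),
    raw_variant = unlist(labels, use.names = FALSE)
  ) |>
    mutate(variant = normalize_text(.data$raw_variant)) |>
    filter(nzchar(.data$variant)) |>
    distinct(.data$label, .data$variant, .keep_all = TRUE)
  collisions <- lookup |>
    count(.data$variant) |>
    filter(.data$n > 1)
  if (nrow(collisions) > 0) {
    abort(sprintf("variant(s) assigned to more than one label: %s",
                  paste(collisions$variant, collapse = "; ")),
          class = "trialbasket_resource_error")
  }
  empty <- setdiff(ndd_labels(), unique(lookup$label))
  if (length(empty) > 0) {
    abort(sprintf("label(s) with no variants: %s",
                  paste(empty, collapse = ", ")),
          class = "trialbasket_resource_error")
  }
  structure(
    list(
      lookup = lookup,
      fuzzy_threshold = as.integer(raw$fuzzy_threshold %||% 1L),
      max_variant_tokens = max(lengths(strsplit(lookup$variant, " ")))
    ),
    class = "ndd_vocabulary"
  )
}

#' @export
print.ndd_vocabulary <- function(x, ...) {
  cat(sprintf("<ndd_vocabulary> %d labels, %d variants, fuzzy threshold %d\n",
              length(unique(x$lookup$label)), nrow(x$lookup),
              x$fuzzy_threshold))
  invisible(x)
}

# Minimum string length for approximate matching. Short strings are
# abbreviations (AD, PD, ALS, ...) where a single edit would cross diseases,
# so they match only exactly, as standalone tokens.
FUZZY_MIN_NCHAR <- 8L

match_normalized <- function(norm, vocab) {
  lookup <- vocab$lookup
  hit <- lookup$label[lookup$variant == norm]
  if (length(hit) > 0) return(hit)
  if (nchar(norm) >= FUZZY_MIN_NCHAR && vocab$fuzzy_threshold > 0) {
    long <- lookup[nchar(lookup$variant) >= FUZZY_MIN_NCHAR, ]
    cand <- long[abs(nchar(long$variant) - nchar(norm)) <= vocab$fuzzy_threshold, ]
    if (nrow(cand) > 0) {
      d <- utils::adist(norm, cand$variant)[1, ]
      return(unique(cand$label[d <= vocab$fuzzy_threshold]))
    }
  }
  character()
}

#' Normalize one condition name to canonical NDD labels
#'
#' Exact variant match (case and punctuation insensitive) first; failing
#' that, approximate match within the vocabulary's edit-distance threshold,
#' applied only to strings of at least 8 characters. The bare word
#' "dementia" carries no disease qualifier and returns the empty set.
#'
#' @param text A condition name (any string).
#' @param vocab An `ndd_vocabulary`.
#' @return Character vector of canonical labels (sorted, usually length 0
#'   or 1).
#' @export
normalize_condition_text <- function(text, vocab) {
  if (is.null(text) || is.na(text)) return(character())
  sort(unique(match_normalized(normalize_text(text), vocab)))
}

#' Scan eligibility criteria for NDD mentions
#'
#' Only the inclusion portion is scanned: everything before an "Exclusion
#' Criteria" heading, when one is present, so diseases mentioned only as
#' exclusions never count. Matching slides a token n-gram window (up to the
#' longest variant length) over the normalized text and applies the same
#' exact-then-fuzzy rule as [normalize_condition_text()].
#'
#' @param text An eligibility-criteria block (any string).
#' @param vocab An `ndd_vocabulary`.
#' @return Sorted character vector of canonical labels found.
#' @export
scan_eligibility_text <- function(text, vocab) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(character())
  incl <- inclusion_block(text)
  tokens <- strsplit(normalize_text(incl), " ", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) return(character())
  found <- character()
  max_n <- min(vocab$max_variant_tokens, length(tokens))
  for (n in seq_len(max_n)) {
    if (length(tokens) < n) break
    starts <- seq_len(length(tokens) - n + 1)
    grams <- vapply(starts, function(s)
      paste(tokens[s:(s + n - 1)], collapse = " "), character(1))
    for (g in unique(grams)) {
      found <- c(found, match_normalized(g, vocab))
    }
  }
  sort(unique(found))
}

inclusion_block <- function(text) {
  # split on the first "Exclusion Criteria" heading, tolerant of case and
  # punctuation around it
  m <- regexpr("exclusion\\s+criteria", text, ignore.case = TRUE)
  if (m[1] > 0) substr(text, 1, m[1] - 1) else text
}

#' Canonical NDD set for a whole trial record
#'
#' Union of [normalize_condition_text()] over the record's condition list and
#' [scan_eligibility_text()] over its eligibility text. Stage folding has
#' already happened at the vocabulary level, so a record whose conditions are
#' all stages of one disease yields a singleton set.
#'
#' @param record A one-row trial record (see [trial_record()]).
#' @param vocab An `ndd_vocabulary`.
#' @return Sorted character vector of canonical labels.
#' @export
trial_ndd_set <- function(record, vocab) {
  from_conditions <- unlist(lapply(record$conditions[[1]],
                                   normalize_condition_text, vocab = vocab))
  from_elig <- scan_eligibility_text(record$eligibility_text[[1]], vocab)
  sort(unique(c(from_conditions, from_elig)))
}
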