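# Lexicon-based intervention classification and agent annotation. The
# classifier is rule-based by design: curated plain-text phrase lists, one
# file per intervention class, give exact reproducibility; no statistical
# model is fitted.

# Multi-match resolution order. Removal classes must win over the permissive
# drug default, so class priority is primary; within a class the longest
# matching phrase is reported.
CLASS_PRIORITY <- c("placebo", "device", "stem_cell", "biomarker",
                    "behavioral", "supplement", "other", "drug")

#' Load the intervention-class lexicons
#'
#' Reads one plain-text file per intervention class from a directory
#' (`<class>.txt`, one phrase per line, `#` comments). Phrases are normalized
#' at load; the same phrase appearing in two class files is a validation
#' error naming both classes.
#'
#' @param dir Directory of lexicon files. Defaults to the packaged lexicons.
#' @return A `lexicon_set` object.
#' @export
load_lexicons <- function(dir = tb_resource("lexicons")) {
  if (!dir.exists(dir)) {
    abort(sprintf("no such lexicon directory: %s", dir),
          class = "trialbasket_resource_error")
  }
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (length(files) == 0) {
    abort(sprintf("no lexicon files (*.txt) in %s", dir),
          class = "trialbasket_resource_error")
  }
  classes <- sub("\\.txt$", "", basename(files))
  bad <- setdiff(classes, intervention_classes())
  if (length(bad) > 0) {
    abort(sprintf("lexicon file(s) for unknown class(es): %s",
                  paste(bad, collapse = ", ")),
          class = "trialbasket_resource_error")
  }
  entries <- purrr::map2_dfr(files, classes, function(f, cl) {
    lines <- readLines(f, encoding = "UTF-8", warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    tibble(class = cl, phrase = normalize_text(lines))
  }) |>
    distinct(.data$class, .data$phrase)
  dup <- entries |>
    count(.data$phrase) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    where <- entries |>
      filter(.data$phrase %in% dup$phrase) |>
      summarise(classes = paste(sort(.data$class), collapse = " + "),
                .by = "phrase")
    abort(paste0("phrase(s) present in more than one lexicon: ",
                 paste(sprintf("'%s' (%s)", where$phrase, where$classes),
                       collapse = "; ")),
          class = "trialbasket_resource_error")
  }
  if (!"placebo" %in% entries$class) {
    abort("placebo lexicon is empty or missing",
          class = "trialbasket_resource_error")
  }
  structure(list(entries = entries, priority = CLASS_PRIORITY),
            class = "lexicon_set")
}

#' @export
print.lexicon_set <- function(x, ...) {
  cat(sprintf("<lexicon_set> %d phrases across %d classes\n",
              nrow(x$entries), length(unique(x$entries$class))))
  invisible(x)
}

# does `phrase` occur in `name` as a whole-token subsequence?
phrase_in_name <- function(phrase, name_norm) {
  grepl(paste0("(^| )", phrase, "( |$)"), name_norm, fixed = FALSE)
}

#' Classify an intervention name
#'
#' The normalized name is matched against each class's phrase list (phrases
#' match as whole-token subsequences). When phrases from several classes
#' match, class priority resolves the tie (placebo > device > stem_cell >
#' biomarker > behavioral > supplement > other > drug). Names matching no
#' lexicon default to `drug` when the registry declared the intervention a
#' drug, else `other`.
#'
#' @param name Intervention name (non-empty string).
#' @param lexicons A `lexicon_set` from [load_lexicons()].
#' @param declared_type The registry's free-text intervention type, or `NA`.
#' @return One of the intervention-class labels.
#' @export
classify_intervention <- function(name, lexicons, declared_type = NA_character_) {
  stopifnot(is.character(name), length(name) == 1, nzchar(trimws(name)))
  norm <- normalize_text(name)
  entries <- lexicons$entries
  hits <- entries[vapply(entries$phrase, phrase_in_name, logical(1),
                         name_norm = norm), ]
  if (nrow(hits) > 0) {
    for (cl in lexicons$priority) {
      if (cl %in% hits$class) return(cl)
    }
  }
  dt <- if (is.na(declared_type)) "" else normalize_text(declared_type)
  if (dt == "drug") "drug" else "other"
}

# --- Agent annotation table --------------------------------------------------

#' Load the curated agent annotation table
#'
#' CSV with columns `canonical_name`, `synonyms` (`"|"`-joined), `moa_class`
#' (`symptomatic` or `dmt`), `cadro` (one of [cadro_categories()]), `goal`.
#' The packaged default transcribes the curated multi-NDD agent set. A
#' synonym mapping to two canonical names, a non-binary MOA value, or an
#' off-vocabulary CADRO category are load-time errors.
#'
#' @param path Path to the CSV. Defaults to the packaged table.
#' @return An `agent_annotations` object.
#' @export
load_agent_annotations <- function(path = tb_resource("agent_annotations.csv")) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = NULL)
  needed <- c("canonical_name", "synonyms", "moa_class", "cadro", "goal")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(sprintf("annotation table missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "trialbasket_resource_error")
  }
  bad_moa <- df$canonical_name[!df$moa_class %in% c("symptomatic", "dmt")]
  if (length(bad_moa) > 0) {
    abort(sprintf("agent(s) without a single dominant MOA class: %s",
                  paste(bad_moa, collapse = ", ")),
          class = "trialbasket_resource_error")
  }
  # a blank CADRO cell is tolerated for symptomatic agents (defaulted to
  # neurotransmitter receptors at assignment time)
  bad_cadro <- df$canonical_name[!df$cadro %in% cadro_categories() &
                                   !(df$cadro == "" &
                                       df$moa_class == "symptomatic")]
  if (length(bad_cadro) > 0) {
    abort(sprintf("agent(s) with off-vocabulary CADRO category: %s",
                  paste(bad_cadro, collapse = ", ")),
          class = "trialbasket_resource_error")
  }
  syn <- purrr::map2_dfr(df$canonical_name, df$synonyms, function(canon, s) {
    alts <- split_cell(s)
    tibble(alias = normalize_text(c(canon, alts)), canonical = canon)
  }) |> distinct(.data$alias, .data$canonical)
  clash <- syn |> count(.data$alias) |> filter(.data$n > 1)
  if (nrow(clash) > 0) {
    abort(sprintf("synonym(s) mapping to more than one canonical agent: %s",
                  paste(clash$alias, collapse = ", ")),
          class = "trialbasket_resource_error")
  }
  structure(list(table = as_tibble(df), synonym_lookup = syn),
            class = "agent_annotations")
}

#' @export
print.agent_annotations <- function(x, ...) {
  cat(sprintf("<agent_annotations> %d agents (%d symptomatic, %d dmt)\n",
              nrow(x$table), sum(x$table$moa_class == "symptomatic"),
              sum(x$table$moa_class == "dmt")))
  invisible(x)
}

#' Canonicalize a drug agent name
#'
#' Synonym-table lookup after normalization; unknown drugs return their
#' normalized name unchanged, which makes the operation idempotent.
#'
#' @param name Drug intervention name.
#' @param annotations An `agent_annotations` object.
#' @return Canonical agent name string.
#' @export
canonicalize_agent <- function(name, annotations) {
  norm <- normalize_text(name)
  hit <- annotations$synonym_lookup$canonical[
    annotations$synonym_lookup$alias == norm]
  if (length(hit) == 1) hit else norm
}

#' Look up an agent's dominant mechanism-of-action class
#'
#' @param agent Canonical agent name.
#' @param annotations An `agent_annotations` object.
#' @return `"symptomatic"`, `"dmt"`, or `NA_character_` when the agent has no
#'   annotation; unannotated agents are surfaced downstream as unclassified,
#'   never silently defaulted.
#' @export
classify_moa <- function(agent, annotations) {
  row <- annotations$table[annotations$table$canonical_name == agent, ]
  if (nrow(row) == 0) NA_character_ else row$moa_class[[1]]
}

#' Look up an agent's CADRO therapeutic-target category
#'
#' Symptomatic agents without an explicit annotation default to
#' `neurotransmitter receptors` (symptomatic treatment in this domain acts on
#' transmitter or transmitter-receptor function).
#'
#' @param agent Canonical agent name.
#' @param annotations An `agent_annotations` object.
#' @return A CADRO category string, or `NA_character_` for unannotated
#'   agents.
#' @export
assign_cadro <- function(agent, annotations) {
  row <- annotations$table[annotations$table$canonical_name == agent, ]
  if (nrow(row) == 0) return(NA_character_)
  cad <- row$cadro[[1]]
  if (!nzchar(cad) && row$moa_class[[1]] == "symptomatic") {
    return("neurotransmitter receptors")
  }
  cad
}
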