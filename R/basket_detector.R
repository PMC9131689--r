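# The filter cascade: update window -> interventional studies -> canonical
# NDD set -> multi-NDD basket rule -> drug-intervention classification.
# The counting unit for basket entries is the trial-agent pair: one trial
# testing several distinct drugs contributes one entry per drug.

#' Default registry update window
#'
#' The analysis window for posted registry updates:
#' 2010-01-01 through 2021-06-06, both ends inclusive.
#' @return A length-2 `Date` vector `c(start, end)`.
#' @export
default_update_window <- function() {
  as.Date(c("2010-01-01", "2021-06-06"))
}

#' Restrict a dataset to an update window
#'
#' Keeps records whose `last_update_date` lies in `[start, end]` inclusive.
#' Records with an absent update date cannot be placed in the window and are
#' dropped (their count is reported via the `n_missing_date` attribute and
#' surfaced in the cascade's FilterTrace).
#'
#' @param dataset A `registry_dataset`.
#' @param start,end Window bounds (`Date` or ISO strings), `start <= end`.
#' @return A filtered `registry_dataset` with attribute `n_missing_date`.
#' @export
apply_update_window <- function(dataset, start, end) {
  stopifnot(inherits(dataset, "registry_dataset"))
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end)) {
    abort("window bounds must be valid dates", class = "trialbasket_argument_error")
  }
  if (start > end) {
    abort("window start is after window end", class = "trialbasket_argument_error")
  }
  rec <- dataset$records
  missing <- is.na(rec$last_update_date)
  keep <- !missing & rec$last_update_date >= start & rec$last_update_date <= end
  out <- registry_dataset(rec[keep, ], provenance = dataset$provenance)
  attr(out, "n_missing_date") <- sum(missing)
  out
}

#' Is a record an eligible study for basket detection?
#'
#' True iff the study is interventional. Every status in the registry status
#' vocabulary is accepted, and a missing phase label does not exclude a
#' record (registry entries commonly omit the phase).
#'
#' @param record A one-row trial record.
#' @return Logical scalar.
#' @export
is_eligible_study <- function(record) {
  identical(record$study_type[[1]], "interventional")
}

#' Detect basket entries in one trial record
#'
#' Computes the record's canonical NDD set; a set of fewer than two distinct
#' disorders yields nothing (stage-variant-only combinations such as AD+MCI
#' or PD+PDD never reach size two because stage folding precedes counting).
#' Otherwise one basket entry is emitted per distinct canonical agent whose
#' intervention classifies as a non-placebo drug.
#'
#' @param record A one-row trial record that already passed
#'   [is_eligible_study()] and the update window.
#' @param vocab An `ndd_vocabulary`.
#' @param lexicons A `lexicon_set`.
#' @param annotations An `agent_annotations` object.
#' @return Tibble of basket entries (possibly zero rows) with columns
#'   `nct_id`, `agent`, `ndd_set` (list), `moa_class`, `cadro`,
#'   `phase_labels` (list), `sponsor_class`, `enrollment`, `duration_weeks`,
#'   `last_update_date`, `start_date`.
#' @export
detect_baskets <- function(record, vocab, lexicons, annotations) {
  empty <- tibble(
    nct_id = character(), agent = character(), ndd_set = list(),
    moa_class = character(), cadro = character(), phase_labels = list(),
    sponsor_class = character(), enrollment = integer(),
    duration_weeks = numeric(), last_update_date = as.Date(character()),
    start_date = as.Date(character())
  )
  ndds <- trial_ndd_set(record, vocab)
  if (length(ndds) < 2) return(empty)
  iv <- record$interventions[[1]]
  if (nrow(iv) == 0) return(empty)
  classes <- vapply(seq_len(nrow(iv)), function(i)
    classify_intervention(iv$name[i], lexicons, iv$declared_type[i]),
    character(1))
  drugs <- iv$name[classes == "drug"]
  if (length(drugs) == 0) return(empty)
  agents <- sort(unique(vapply(drugs, canonicalize_agent, character(1),
                               annotations = annotations)))
  end_date <- record$actual_end_date[[1]]
  if (is.na(end_date)) end_date <- record$projected_end_date[[1]]
  dur <- if (is.na(end_date) || is.na(record$start_date[[1]])) NA_real_
         else as.numeric(end_date - record$start_date[[1]]) / 7
  bind_rows(lapply(agents, function(a) {
    tibble(
      nct_id = record$nct_id[[1]],
      agent = a,
      ndd_set = list(ndds),
      moa_class = classify_moa(a, annotations),
      cadro = assign_cadro(a, annotations),
      phase_labels = record$phase_labels,
      sponsor_class = record$sponsor_class[[1]],
      enrollment = record$enrollment[[1]],
      duration_weeks = dur,
      last_update_date = record$last_update_date[[1]],
      start_date = record$start_date[[1]]
    )
  }))
}

#' Run the full filter cascade over a registry dataset
#'
#' Applies, in order: update window, interventional-study eligibility,
#' canonical NDD set computation, the multi-NDD basket rule, and drug
#' classification. Returns the basket entries sorted by (agent, nct_id) for
#' reproducible tables, together with a FilterTrace of per-stage record
#' counts.
#'
#' @param dataset A `registry_dataset`.
#' @param vocab An `ndd_vocabulary`.
#' @param lexicons A `lexicon_set`.
#' @param annotations An `agent_annotations` object.
#' @param window Length-2 date vector, default [default_update_window()].
#' @return List with elements `baskets` (tibble of trial-agent entries) and
#'   `trace` (named list of stage counts; the final stage counts trial-agent
#'   pairs and may exceed the prior stage because one trial can contribute
#'   several agents).
#' @export
run_filter_cascade <- function(dataset, vocab, lexicons, annotations,
                               window = default_update_window()) {
  stopifnot(inherits(dataset, "registry_dataset"))
  in_window <- apply_update_window(dataset, window[1], window[2])
  rec <- in_window$records
  eligible_idx <- which(vapply(seq_len(nrow(rec)), function(i)
    is_eligible_study(rec[i, ]), logical(1)))
  eligible <- rec[eligible_idx, ]

  ndd_sets <- lapply(seq_len(nrow(eligible)), function(i)
    trial_ndd_set(eligible[i, ], vocab))
  n_ndd1 <- sum(lengths(ndd_sets) >= 1)
  multi_idx <- which(lengths(ndd_sets) >= 2)

  basket_rows <- lapply(multi_idx, function(i)
    detect_baskets(eligible[i, ], vocab, lexicons, annotations))
  baskets <- bind_rows(basket_rows)
  if (nrow(baskets) == 0) {
    baskets <- detect_baskets(trial_record("NCT00000000"), vocab,
                              lexicons, annotations)
  }
  baskets <- baskets[order(baskets$agent, baskets$nct_id), ]
  trace <- list(
    n_total = nrow(dataset$records),
    n_missing_update_date = attr(in_window, "n_missing_date"),
    n_in_window = nrow(rec),
    n_interventional = nrow(eligible),
    n_ndd_ge1 = n_ndd1,
    n_ndd_ge2 = length(multi_idx),
    n_with_drug = length(unique(baskets$nct_id)),
    n_basket_entries = nrow(baskets)
  )
  list(baskets = as_tibble(baskets), trace = trace)
}
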