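# Landscape summaries over basket entries: per-agent tables, per-NDD agent
# counts, pairwise disease co-occurrence, phase and sponsor distributions,
# trimmed means and recency.

#' Summarize basket entries per agent
#'
#' One row per canonical agent within each MOA class: the number of basket
#' entries (trial-agent pairs), the union of the agent's per-trial NDD sets,
#' and the agent's annotation fields. Rows are sorted by MOA class then
#' agent name.
#'
#' @param baskets Tibble of basket entries from [run_filter_cascade()].
#' @param annotations Optional `agent_annotations` used to attach treatment
#'   goals.
#' @return Tibble with columns `agent`, `moa_class`, `n_trials`, `ndd_union`
#'   (list), `cadro`, `goal`.
#' @export
summarize_agents <- function(baskets, annotations = NULL) {
  empty <- tibble(agent = character(), moa_class = character(),
                  n_trials = integer(), ndd_union = list(),
                  cadro = character(), goal = character())
  if (nrow(baskets) == 0) return(empty)
  out <- baskets |>
    summarise(
      n_trials = dplyr::n(),
      ndd_union = list(sort(unique(unlist(.data$ndd_set)))),
      cadro = .data$cadro[[1]],
      .by = c("agent", "moa_class")
    ) |>
    arrange(.data$moa_class, .data$agent)
  out$goal <- NA_character_
  if (!is.null(annotations)) {
    idx <- match(out$agent, annotations$table$canonical_name)
    out$goal <- ifelse(is.na(idx), NA_character_,
                       annotations$table$goal[idx])
  }
  out[, c("agent", "moa_class", "n_trials", "ndd_union", "cadro", "goal")]
}

#' Count distinct agents targeting each NDD
#'
#' For a given MOA class, the number of distinct agents whose NDD union
#' contains each reporting label.
#'
#' @param summaries Output of [summarize_agents()].
#' @param moa_class `"symptomatic"`, `"dmt"`, or `NULL` for all agents.
#' @return Tibble with columns `ndd`, `n_agents`, one row per reporting
#'   label (zeros included), sorted by descending count then label.
#' @export
count_agents_per_ndd <- function(summaries, moa_class = NULL) {
  if (!is.null(moa_class)) {
    summaries <- summaries[summaries$moa_class %in% moa_class, ]
  }
  counts <- vapply(ndd_labels(), function(lbl)
    sum(vapply(summaries$ndd_union, function(u) lbl %in% u, logical(1))),
    integer(1))
  tibble(ndd = ndd_labels(), n_agents = unname(counts)) |>
    arrange(desc(.data$n_agents), .data$ndd)
}

#' Count basket entries per unordered NDD pair
#'
#' The number of basket entries whose NDD set contains both labels, for
#' every unordered pair of reporting labels; an entry with k disorders
#' contributes to choose(k, 2) pairs. Storage is symmetric (`a` < `b`
#' lexicographically).
#'
#' @param baskets Tibble of basket entries.
#' @return Tibble with columns `ndd_a`, `ndd_b`, `n_entries`, all 45 pairs,
#'   sorted by descending count then labels.
#' @export
count_pairwise_ndd <- function(baskets) {
  labs <- sort(ndd_labels())
  pairs <- utils::combn(labs, 2)
  n <- vapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    sum(vapply(baskets$ndd_set, function(s) a %in% s && b %in% s, logical(1)))
  }, integer(1))
  tibble(ndd_a = pairs[1, ], ndd_b = pairs[2, ], n_entries = n) |>
    arrange(desc(.data$n_entries), .data$ndd_a, .data$ndd_b)
}

#' Phase distribution
#'
#' When `unit = "agents"`, an agent with basket entries in several phases is
#' counted once per phase, so counts may sum to more than the number of
#' agents; entries with no phase label fall in an `unassigned` bucket. When
#' `unit = "trial entries"`, each basket entry contributes once per phase
#' label it carries.
#'
#' @param baskets Tibble of basket entries.
#' @param unit `"agents"` or `"trial entries"`.
#' @param moa_class Optional MOA-class filter.
#' @return Tibble with columns `phase`, `n`, with the counting unit recorded
#'   in attribute `unit`.
#' @export
distribution_by_phase <- function(baskets, unit = c("agents", "trial entries"),
                                  moa_class = NULL) {
  unit <- match.arg(unit)
  if (!is.null(moa_class)) baskets <- baskets[baskets$moa_class %in% moa_class, ]
  buckets <- c(phase_vocabulary(), "unassigned")
  bucketize <- function(ph) if (length(ph) == 0) "unassigned" else ph
  if (nrow(baskets) == 0) {
    out <- tibble(phase = buckets, n = 0L)
    attr(out, "unit") <- unit
    return(out)
  }
  if (unit == "agents") {
    pairs <- unique(bind_rows(lapply(seq_len(nrow(baskets)), function(i)
      tibble(agent = baskets$agent[i],
             phase = bucketize(baskets$phase_labels[[i]])))))
    tab <- table(factor(pairs$phase, levels = buckets))
  } else {
    phases <- unlist(lapply(baskets$phase_labels, bucketize))
    tab <- table(factor(phases, levels = buckets))
  }
  out <- tibble(phase = buckets, n = as.integer(tab[buckets]))
  attr(out, "unit") <- unit
  out
}

#' Sponsor-class distribution over basket entries
#'
#' Trial-entry counts per sponsor class; counts sum to the number of
#' entries.
#'
#' @param baskets Tibble of basket entries.
#' @param moa_class Optional MOA-class filter.
#' @return Tibble with columns `sponsor_class`, `n`.
#' @export
distribution_by_sponsor <- function(baskets, moa_class = NULL) {
  if (!is.null(moa_class)) baskets <- baskets[baskets$moa_class %in% moa_class, ]
  tab <- table(factor(baskets$sponsor_class, levels = sponsor_classes()))
  out <- tibble(sponsor_class = sponsor_classes(),
                n = as.integer(tab[sponsor_classes()]))
  attr(out, "unit") <- "trial entries"
  out
}

#' Mean after excluding extremes
#'
#' The exclusion policy is either an explicit list of ids to drop (the
#' auditable route: the excluded trials are named) or a percentile band
#' `[p_lo, p_hi]` retaining the sorted values with positions in that band.
#' `NA` values are dropped before anything else and are not counted as
#' exclusions.
#'
#' @param values Data frame with columns `id` and `value`.
#' @param exclude_ids Character vector of ids to exclude (may be empty).
#' @param percentile_band Optional numeric `c(p_lo, p_hi)` in `[0, 1]`; when
#'   given, `exclude_ids` must be empty.
#' @return List with `mean`, `n_retained`, `excluded_ids`.
#' @export
robust_mean <- function(values, exclude_ids = character(),
                        percentile_band = NULL) {
  stopifnot(all(c("id", "value") %in% names(values)))
  values <- values[!is.na(values$value), ]
  if (nrow(values) == 0) {
    abort("no non-missing values", class = "trialbasket_argument_error")
  }
  if (!is.null(percentile_band)) {
    if (length(exclude_ids) > 0) {
      abort("give either exclude_ids or percentile_band, not both",
            class = "trialbasket_argument_error")
    }
    p_lo <- percentile_band[1]; p_hi <- percentile_band[2]
    stopifnot(p_lo >= 0, p_hi <= 1, p_lo <= p_hi)
    ord <- order(values$value, values$id)
    n <- nrow(values)
    lo <- floor(n * p_lo) + 1
    hi <- ceiling(n * p_hi)
    keep_idx <- ord[seq(lo, hi)]
    excluded <- values$id[setdiff(seq_len(n), keep_idx)]
    retained <- values$value[keep_idx]
  } else {
    drop <- values$id %in% exclude_ids
    excluded <- values$id[drop]
    retained <- values$value[!drop]
  }
  if (length(retained) == 0) {
    abort("exclusion policy removed every value",
          class = "trialbasket_argument_error")
  }
  list(mean = mean(retained), n_retained = length(retained),
       excluded_ids = sort(excluded))
}

#' Fraction of basket entries at or after a cutoff date
#'
#' Uses the entry's start date when present, else its last update date;
#' entries with neither are excluded from the denominator and counted in
#' `n_undated`.
#'
#' @param baskets Tibble of basket entries.
#' @param cutoff A `Date` (or ISO string).
#' @return List with `fraction`, `numerator`, `denominator`, `n_undated`.
#' @export
recency_fraction <- function(baskets, cutoff) {
  cutoff <- as.Date(cutoff)
  dates <- baskets$start_date
  dates[is.na(dates)] <- baskets$last_update_date[is.na(dates)]
  dated <- !is.na(dates)
  num <- sum(dates[dated] >= cutoff)
  den <- sum(dated)
  list(fraction = if (den == 0) NA_real_ else num / den,
       numerator = num, denominator = den, n_undated = sum(!dated))
}

# --- Bundle + output ---------------------------------------------------------

#' Assemble the full summary bundle
#'
#' Computes every landscape table from a cascade result: per-agent summaries
#' split by MOA class, per-NDD distinct-agent counts, pairwise NDD
#' co-occurrence, phase distributions (agent unit), sponsor distributions
#' (trial-entry unit), enrollment robust mean, recency, and the list of
#' entries whose agent had no MOA annotation (unclassified — never silently
#' defaulted).
#'
#' @param cascade Result of [run_filter_cascade()].
#' @param annotations An `agent_annotations` object.
#' @param exclude_enrollment_ids Ids treated as extremes for the enrollment
#'   mean.
#' @param recency_cutoff Date for [recency_fraction()].
#' @return A `summary_bundle` list.
#' @export
build_summary_bundle <- function(cascade, annotations,
                                 exclude_enrollment_ids = character(),
                                 recency_cutoff = as.Date("2016-06-06")) {
  baskets <- cascade$baskets
  summaries <- summarize_agents(baskets, annotations)
  unclassified <- baskets[is.na(baskets$moa_class), ]
  classified <- baskets[!is.na(baskets$moa_class), ]
  enrollment <- tibble(id = paste(baskets$nct_id, baskets$agent, sep = ":"),
                       value = as.numeric(baskets$enrollment))
  enroll_stat <- if (any(!is.na(enrollment$value))) {
    robust_mean(enrollment, exclude_ids = exclude_enrollment_ids)
  } else NULL
  structure(list(
    baskets = baskets,
    trace = cascade$trace,
    agent_summaries = summaries,
    unclassified_entries = unclassified,
    ndd_agent_counts = list(
      symptomatic = count_agents_per_ndd(summaries, "symptomatic"),
      dmt = count_agents_per_ndd(summaries, "dmt")
    ),
    pair_counts = count_pairwise_ndd(baskets),
    phase_distribution = list(
      symptomatic = distribution_by_phase(classified, "agents", "symptomatic"),
      dmt = distribution_by_phase(classified, "agents", "dmt")
    ),
    sponsor_distribution = list(
      symptomatic = distribution_by_sponsor(classified, "symptomatic"),
      dmt = distribution_by_sponsor(classified, "dmt")
    ),
    enrollment_mean = enroll_stat,
    recency = recency_fraction(baskets, recency_cutoff)
  ), class = "summary_bundle")
}

fmt_ndd_union <- function(u) vapply(u, paste, character(1), collapse = CELL_SEP)

write_csv_det <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the summary bundle as report tables
#'
#' Writes deterministic CSV tables (agent summaries per MOA class, per-NDD
#' agent counts, pairwise counts, phase and sponsor distributions, robust
#' statistics), a plain-text report, a JSON FilterTrace sidecar and a data
#' dictionary into `out_dir`. Byte-identical across repeated runs on
#' identical input.
#'
#' @param bundle A `summary_bundle`.
#' @param out_dir Output directory (created if absent).
#' @return Character vector of file paths written, invisibly.
#' @export
write_tables <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "summary_bundle"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) {
    abort(sprintf("cannot create output directory %s", out_dir),
          class = "trialbasket_io_error")
  }
  paths <- character()
  p <- function(name) {
    paths <<- c(paths, file.path(out_dir, name))
    file.path(out_dir, name)
  }

  sm <- bundle$agent_summaries
  for (cls in c("symptomatic", "dmt")) {
    df <- sm[!is.na(sm$moa_class) & sm$moa_class == cls, ]
    write_csv_det(
      tibble(agent = df$agent, n_trials = df$n_trials,
             ndds = fmt_ndd_union(df$ndd_union),
             cadro = df$cadro, goal = ifelse(is.na(df$goal), "", df$goal)),
      p(sprintf("agents_%s.csv", cls)))
  }
  bask <- bundle$baskets
  write_csv_det(
    tibble(nct_id = bask$nct_id, agent = bask$agent,
           ndd_set = fmt_ndd_union(bask$ndd_set),
           moa_class = ifelse(is.na(bask$moa_class), "unclassified",
                              bask$moa_class),
           sponsor_class = bask$sponsor_class,
           phase_labels = fmt_ndd_union(bask$phase_labels),
           enrollment = ifelse(is.na(bask$enrollment), "",
                               as.character(bask$enrollment))),
    p("basket_entries.csv"))
  write_csv_det(bundle$ndd_agent_counts$symptomatic,
                p("ndd_agent_counts_symptomatic.csv"))
  write_csv_det(bundle$ndd_agent_counts$dmt, p("ndd_agent_counts_dmt.csv"))
  write_csv_det(bundle$pair_counts, p("ndd_pair_counts.csv"))
  write_csv_det(bind_rows(
    mutate(bundle$phase_distribution$symptomatic, moa_class = "symptomatic"),
    mutate(bundle$phase_distribution$dmt, moa_class = "dmt")),
    p("phase_distribution.csv"))
  write_csv_det(bind_rows(
    mutate(bundle$sponsor_distribution$symptomatic, moa_class = "symptomatic"),
    mutate(bundle$sponsor_distribution$dmt, moa_class = "dmt")),
    p("sponsor_distribution.csv"))
  if (!is.null(bundle$enrollment_mean)) {
    em <- bundle$enrollment_mean
    write_csv_det(tibble(statistic = "enrollment_mean", mean = em$mean,
                         n_retained = em$n_retained,
                         excluded_ids = paste(em$excluded_ids,
                                              collapse = CELL_SEP)),
                  p("robust_stats.csv"))
  }
  jsonlite::write_json(bundle$trace, p("filter_trace.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  n_sym <- sum(bask$moa_class == "symptomatic", na.rm = TRUE)
  n_dmt <- sum(bask$moa_class == "dmt", na.rm = TRUE)
  report <- c(
    "Basket-trial landscape report",
    "=============================",
    "",
    sprintf("Basket entries (trial-agent pairs): %d", nrow(bask)),
    sprintf("Distinct agents: %d", length(unique(bask$agent))),
    sprintf("Symptomatic entries: %d (%d agents)", n_sym,
            length(unique(bask$agent[!is.na(bask$moa_class) &
                                       bask$moa_class == "symptomatic"]))),
    sprintf("Disease-modifying entries: %d (%d agents)", n_dmt,
            length(unique(bask$agent[!is.na(bask$moa_class) &
                                       bask$moa_class == "dmt"]))),
    sprintf("Unclassified entries (no MOA annotation): %d",
            nrow(bundle$unclassified_entries)),
    "",
    "Filter cascade:",
    sprintf("  %-24s %d", paste0(names(bundle$trace), ":"),
            unlist(bundle$trace)),
    ""
  )
  writeLines(report, p("report.txt"))
  writeLines(data_dictionary_text(), p("data_dictionary.txt"))
  invisible(paths)
}

data_dictionary_text <- function() {
  c("Data dictionary for report tables",
    "",
    "agents_<moa>.csv: one row per agent of the MOA class.",
    "  agent       canonical agent name",
    "  n_trials    number of basket entries (trial-agent pairs)",
    "  ndds        '|'-joined union of canonical NDD labels across trials",
    "  cadro       CADRO therapeutic-target category",
    "  goal        curated treatment goal (free text)",
    "basket_entries.csv: one row per trial-agent pair surviving the cascade.",
    "ndd_agent_counts_<moa>.csv: distinct agents whose NDD union contains",
    "  each reporting label.",
    "ndd_pair_counts.csv: basket entries containing both labels of each",
    "  unordered NDD pair (symmetric storage, ndd_a < ndd_b).",
    "phase_distribution.csv: agent-phase pair counts per MOA class; an agent",
    "  in several phases counts once per phase; 'unassigned' = no label.",
    "sponsor_distribution.csv: trial-entry counts per sponsor class.",
    "robust_stats.csv: mean after the named exclusions, with n_retained and",
    "  the excluded ids for auditability.",
    "filter_trace.json: per-stage record counts of the filter cascade.")
}
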