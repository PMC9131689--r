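# Synthetic registries with planted ground truth, and expansion of the
# packaged per-agent fixture tables into per-trial records. All random
# number use in the package is confined to this file; every other module is
# deterministic.

# Free-text spellings used when realizing a canonical label as a condition
# string. The first entry is the reference spelling; the rest are common
# registry variants.
ndd_condition_names <- function() {
  list(
    AD   = c("Alzheimer Disease", "Alzheimer's Disease"),
    PD   = c("Parkinson Disease", "Parkinson's Disease"),
    DLB  = c("Dementia With Lewy Bodies", "Lewy Body Dementia"),
    FTLD = c("Frontotemporal Lobar Degeneration", "Frontotemporal Dementia"),
    PSP  = c("Progressive Supranuclear Palsy"),
    CBD  = c("Corticobasal Degeneration", "Corticobasal Syndrome"),
    CTE  = c("Chronic Traumatic Encephalopathy"),
    HD   = c("Huntington Disease", "Huntington's Disease"),
    ALS  = c("Amyotrophic Lateral Sclerosis"),
    MSA  = c("Multiple System Atrophy")
  )
}

NON_NDD_CONDITIONS <- c(
  "Type 2 Diabetes Mellitus", "Essential Hypertension",
  "Major Depressive Disorder", "Rheumatoid Arthritis", "Chronic Migraine",
  "Atrial Fibrillation", "Multiple Sclerosis", "Psoriasis",
  "Chronic Obstructive Pulmonary Disease", "Osteoarthritis"
)

DISTRACTOR_DRUGS <- c("Aspirin", "Lisinopril", "Atorvastatin", "Omeprazole",
                      "Sertraline", "Metoprolol", "Gabapentin")

NON_DRUG_INTERVENTIONS <- tibble::tribble(
  ~name, ~declared_type,
  "Deep Brain Stimulation", "device",
  "Transcranial Magnetic Stimulation", "device",
  "Cognitive Behavioral Therapy", "behavioral",
  "Aerobic Exercise Program", "behavioral",
  "Tau PET Imaging", "biomarker",
  "Autologous Stem Cell Transplantation", "genetic"
)

#' Configuration for the synthetic registry generator
#'
#' Counts define how many records of each disposition are planted; rates
#' define record-level noise features the pipeline must tolerate.
#'
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param n_basket Planted multi-NDD drug trials (the ground-truth baskets).
#' @param n_single_ndd Trials listing exactly one NDD.
#' @param n_non_ndd Trials with no NDD condition.
#' @param n_stage_only Trials whose conditions are stage variants of one
#'   disease only (AD+MCI, PD+PDD) — excluded by design.
#' @param n_non_drug Multi-NDD trials whose interventions are devices,
#'   behavioral programs or biomarkers only.
#' @param n_out_of_window Multi-NDD drug trials whose last update falls
#'   before the window, so only the date filter excludes them.
#' @param placebo_arm_rate Probability a trial carries an extra placebo
#'   intervention (declared as a drug, as registries commonly do).
#' @param misspelling_rate Probability a condition string is perturbed
#'   within edit distance 1 (via [inject_text_noise()]).
#' @param eligibility_only_rate Probability one NDD of a planted basket
#'   appears only in the inclusion-criteria text, not the condition list.
#' @param date_window Generation range for update dates.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_basket = 20L, n_single_ndd = 30L,
                             n_non_ndd = 40L, n_stage_only = 10L,
                             n_non_drug = 10L, n_out_of_window = 0L,
                             placebo_arm_rate = 0.3, misspelling_rate = 0,
                             eligibility_only_rate = 0.2,
                             date_window = default_update_window()) {
  cfg <- list(seed = as.integer(seed), n_basket = as.integer(n_basket),
              n_single_ndd = as.integer(n_single_ndd),
              n_non_ndd = as.integer(n_non_ndd),
              n_stage_only = as.integer(n_stage_only),
              n_non_drug = as.integer(n_non_drug),
              n_out_of_window = as.integer(n_out_of_window),
              placebo_arm_rate = placebo_arm_rate,
              misspelling_rate = misspelling_rate,
              eligibility_only_rate = eligibility_only_rate,
              date_window = as.Date(date_window))
  counts <- unlist(cfg[c("n_basket", "n_single_ndd", "n_non_ndd",
                         "n_stage_only", "n_non_drug", "n_out_of_window")])
  if (any(counts < 0)) {
    abort("counts must be non-negative", class = "trialbasket_argument_error")
  }
  rates <- unlist(cfg[c("placebo_arm_rate", "misspelling_rate",
                        "eligibility_only_rate")])
  if (any(rates < 0 | rates > 1)) {
    abort("rates must lie in [0, 1]", class = "trialbasket_argument_error")
  }
  structure(cfg, class = "synthetic_config")
}

rand_date <- function(n, from, to) {
  from + sample.int(as.integer(to - from) + 1L, n, replace = TRUE) - 1L
}

pick_condition_name <- function(label) {
  pool <- ndd_condition_names()[[label]]
  pool[[sample.int(length(pool), 1)]]
}

#' Generate a synthetic registry with known ground truth
#'
#' Planted baskets draw agents from the packaged annotation table and NDD
#' sets of size 2-5 from the canonical labels. Distractor records (single
#' NDD, no NDD, stage-variant-only, non-drug, out-of-window) are realized per
#' the configuration; every generated record gets exactly one disposition
#' with a reason code. Deterministic given `config$seed`.
#'
#' @param config A `synthetic_config`.
#' @param annotations An `agent_annotations` object supplying agent names.
#' @return List with `dataset` (a `registry_dataset`), `truth` (list with
#'   `planted` — tibble of nct_id, agent, ndd_set — and `dispositions` —
#'   tibble of nct_id, disposition).
#' @export
generate_registry <- function(config, annotations = load_agent_annotations()) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed)

  win <- config$date_window
  agents_pool <- annotations$table$canonical_name
  records <- list()
  planted <- list()
  dispositions <- list()
  next_id <- 0L
  new_nct <- function() {
    next_id <<- next_id + 1L
    sprintf("NCT%08d", 10000000L + next_id)
  }
  base_record <- function(nct, conditions, interventions, eligibility,
                          update_date) {
    upd <- update_date
    start <- upd - sample.int(720L, 1)
    trial_record(
      nct_id = nct, title = paste("Synthetic study", nct),
      conditions = conditions, eligibility_text = eligibility,
      interventions = interventions,
      phase_labels = sample(list(character(), "phase 1", "phase 2", "phase 3",
                                 "phase 4", "not applicable",
                                 c("phase 1", "phase 2")), 1)[[1]],
      status = sample(registry_statuses(), 1),
      study_type = "interventional",
      last_update_date = upd, start_date = start,
      projected_end_date = start + sample.int(1000L, 1),
      enrollment = stats::rpois(1, 120),
      n_arms = sample(1:4, 1),
      sponsor_class = sample(sponsor_classes(), 1)
    )
  }
  maybe_placebo <- function(iv) {
    if (stats::runif(1) < config$placebo_arm_rate) {
      iv <- bind_rows(iv, tibble(name = "Placebo", declared_type = "drug"))
    }
    iv
  }

  # planted baskets
  for (i in seq_len(config$n_basket)) {
    nct <- new_nct()
    k <- sample(2:5, 1)
    ndds <- sort(sample(ndd_labels(), k))
    agent <- sample(agents_pool, 1)
    cond_labels <- ndds
    elig <- "Inclusion Criteria: adults able to consent."
    if (length(ndds) >= 2 && stats::runif(1) < config$eligibility_only_rate) {
      hidden <- ndds[length(ndds)]
      cond_labels <- setdiff(ndds, hidden)
      elig <- paste0("Inclusion Criteria: diagnosis of ",
                     pick_condition_name(hidden),
                     ". Exclusion Criteria: pregnancy.")
    }
    conds <- vapply(cond_labels, pick_condition_name, character(1))
    iv <- maybe_placebo(tibble(name = agent, declared_type = "drug"))
    records[[nct]] <- base_record(nct, conds, iv, elig,
                                  rand_date(1, win[1], win[2]))
    planted[[nct]] <- tibble(nct_id = nct, agent = agent,
                             ndd_set = list(ndds))
    dispositions[[nct]] <- tibble(nct_id = nct, disposition = "basket")
  }
  # single-NDD distractors
  for (i in seq_len(config$n_single_ndd)) {
    nct <- new_nct()
    lbl <- sample(ndd_labels(), 1)
    iv <- maybe_placebo(tibble(name = sample(DISTRACTOR_DRUGS, 1),
                               declared_type = "drug"))
    records[[nct]] <- base_record(nct, pick_condition_name(lbl), iv,
                                  "Inclusion Criteria: adults.",
                                  rand_date(1, win[1], win[2]))
    dispositions[[nct]] <- tibble(nct_id = nct, disposition = "single_ndd")
  }
  # non-NDD distractors; half mention an NDD only in the exclusion block,
  # which must not count
  for (i in seq_len(config$n_non_ndd)) {
    nct <- new_nct()
    elig <- if (i %% 2 == 0) {
      paste0("Inclusion Criteria: adults. Exclusion Criteria: ",
             pick_condition_name(sample(ndd_labels(), 1)),
             " or other neurodegenerative disease.")
    } else "Inclusion Criteria: adults."
    iv <- maybe_placebo(tibble(name = sample(DISTRACTOR_DRUGS, 1),
                               declared_type = "drug"))
    records[[nct]] <- base_record(nct, sample(NON_NDD_CONDITIONS, 1), iv,
                                  elig, rand_date(1, win[1], win[2]))
    dispositions[[nct]] <- tibble(nct_id = nct, disposition = "non_ndd")
  }
  # stage-variant-only distractors (fold to a single label)
  for (i in seq_len(config$n_stage_only)) {
    nct <- new_nct()
    conds <- if (i %% 2 == 0) {
      c("Alzheimer Disease", "Mild Cognitive Impairment")
    } else {
      c("Parkinson Disease", "Parkinson Disease Dementia")
    }
    iv <- maybe_placebo(tibble(name = sample(agents_pool, 1),
                               declared_type = "drug"))
    records[[nct]] <- base_record(nct, conds, iv,
                                  "Inclusion Criteria: adults.",
                                  rand_date(1, win[1], win[2]))
    dispositions[[nct]] <- tibble(nct_id = nct, disposition = "stage_only")
  }
  # multi-NDD but no drug intervention
  for (i in seq_len(config$n_non_drug)) {
    nct <- new_nct()
    ndds <- sort(sample(ndd_labels(), 2))
    conds <- vapply(ndds, pick_condition_name, character(1))
    iv <- NON_DRUG_INTERVENTIONS[sample.int(nrow(NON_DRUG_INTERVENTIONS), 1), ]
    records[[nct]] <- base_record(nct, conds, iv,
                                  "Inclusion Criteria: adults.",
                                  rand_date(1, win[1], win[2]))
    dispositions[[nct]] <- tibble(nct_id = nct, disposition = "non_drug")
  }
  # in every respect a basket, but updated before the window
  for (i in seq_len(config$n_out_of_window)) {
    nct <- new_nct()
    ndds <- sort(sample(ndd_labels(), 2))
    conds <- vapply(ndds, pick_condition_name, character(1))
    iv <- tibble(name = sample(agents_pool, 1), declared_type = "drug")
    records[[nct]] <- base_record(nct, conds, iv,
                                  "Inclusion Criteria: adults.",
                                  win[1] - sample.int(1000L, 1))
    dispositions[[nct]] <- tibble(nct_id = nct, disposition = "out_of_window")
  }

  recs <- if (length(records) == 0) NULL else bind_rows(records)
  dataset <- registry_dataset(recs,
                              provenance = list(path = NA_character_,
                                                encoding = "synthetic"))
  truth <- list(
    planted = if (length(planted) == 0) {
      tibble(nct_id = character(), agent = character(), ndd_set = list())
    } else bind_rows(planted),
    dispositions = if (length(dispositions) == 0) {
      tibble(nct_id = character(), disposition = character())
    } else bind_rows(dispositions)
  )
  if (config$misspelling_rate > 0) {
    noised <- inject_text_noise(dataset, config$misspelling_rate,
                                seed = config$seed + 1L)
    dataset <- noised$dataset
    truth$perturbation_log <- noised$log
  }
  list(dataset = dataset, truth = truth)
}

#' Perturb condition strings within edit distance one
#'
#' Applies at most one random single-character insert, delete or substitute
#' per condition string, at the given rate, never touching strings shorter
#' than 8 characters. Deterministic given the seed; a log of every
#' perturbation is returned alongside the dataset.
#'
#' @param dataset A `registry_dataset`.
#' @param rate Per-condition perturbation probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return List with `dataset` and `log` (tibble of nct_id, original,
#'   perturbed).
#' @export
inject_text_noise <- function(dataset, rate, seed = 1L) {
  stopifnot(inherits(dataset, "registry_dataset"), rate >= 0, rate <= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  rec <- dataset$records
  log <- list()
  if (rate > 0) {
    for (i in seq_len(nrow(rec))) {
      conds <- rec$conditions[[i]]
      for (j in seq_along(conds)) {
        if (nchar(conds[j]) >= 8 && stats::runif(1) < rate) {
          perturbed <- random_edit(conds[j])
          log[[length(log) + 1]] <- tibble(nct_id = rec$nct_id[i],
                                           original = conds[j],
                                           perturbed = perturbed)
          conds[j] <- perturbed
        }
      }
      rec$conditions[[i]] <- conds
    }
  }
  list(
    dataset = registry_dataset(rec, provenance = dataset$provenance),
    log = if (length(log) == 0) {
      tibble(nct_id = character(), original = character(),
             perturbed = character())
    } else bind_rows(log)
  )
}

random_edit <- function(s) {
  op <- sample(c("insert", "delete", "substitute"), 1)
  n <- nchar(s)
  letters_pool <- letters
  if (op == "insert") {
    pos <- sample.int(n + 1, 1) - 1
    paste0(substr(s, 1, pos), sample(letters_pool, 1),
           substr(s, pos + 1, n))
  } else if (op == "delete") {
    pos <- sample.int(n, 1)
    paste0(substr(s, 1, pos - 1), substr(s, pos + 1, n))
  } else {
    pos <- sample.int(n, 1)
    cur <- substr(s, pos, pos)
    repl <- sample(setdiff(letters_pool, tolower(cur)), 1)
    paste0(substr(s, 1, pos - 1), repl, substr(s, pos + 1, n))
  }
}

# --- Fixture expansion -------------------------------------------------------

#' Load the packaged per-agent fixture tables
#'
#' Two CSVs transcribing the curated per-agent characteristics of multi-NDD
#' basket trials (one table per MOA class): agent, number of trials,
#' treatment goal, and the `"|"`-joined NDD list.
#'
#' @param table1 Path to the symptomatic-agent fixture.
#' @param table2 Path to the disease-modifying-agent fixture.
#' @return Tibble of fixture rows with a `moa_class` column.
#' @export
load_fixture_tables <- function(table1 = tb_resource("table1_fixture.csv"),
                                table2 = tb_resource("table2_fixture.csv")) {
  read_one <- function(path) {
    df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
    needed <- c("agent", "n_trials", "moa_class", "goal", "ndds")
    missing <- setdiff(needed, names(df))
    if (length(missing) > 0) {
      abort(sprintf("fixture %s missing column(s): %s", path,
                    paste(missing, collapse = ", ")),
            class = "trialbasket_resource_error")
    }
    as_tibble(df)
  }
  bind_rows(read_one(table1), read_one(table2))
}

#' Expand per-agent fixture rows into per-trial registry records
#'
#' Emits `n_trials` per-trial records per agent, each carrying the agent's
#' full NDD list as conditions (per-trial NDD subsets are not published, so
#' every trial of an agent gets the union), synthetic sequential NCT ids,
#' interventional study type and an in-window update date. Per-agent totals
#' are conserved exactly. Deterministic: no randomness.
#'
#' @param fixture Tibble from [load_fixture_tables()].
#' @return A `registry_dataset`.
#' @export
expand_fixture_tables <- function(fixture = load_fixture_tables()) {
  rows <- list()
  next_id <- 0L
  names_map <- ndd_condition_names()
  for (i in seq_len(nrow(fixture))) {
    r <- fixture[i, ]
    n <- suppressWarnings(as.integer(r$n_trials))
    labels <- split_cell(r$ndds)
    if (!nzchar(trimws(r$agent)) || is.na(n) || n < 1 ||
        length(labels) < 2 || !all(labels %in% ndd_labels())) {
      abort(sprintf("malformed fixture row %d (agent '%s')", i, r$agent),
            class = "trialbasket_validation_error")
    }
    conds <- vapply(labels, function(l) names_map[[l]][[1]], character(1))
    for (k in seq_len(n)) {
      next_id <- next_id + 1L
      rows[[next_id]] <- trial_record(
        nct_id = sprintf("NCT%08d", 90000000L + next_id),
        title = paste("Fixture trial of", r$agent),
        conditions = conds,
        eligibility_text = "Inclusion Criteria: adults with a qualifying diagnosis.",
        interventions = tibble(name = r$agent, declared_type = "drug"),
        phase_labels = character(),
        status = "completed",
        study_type = "interventional",
        last_update_date = as.Date("2016-01-01"),
        sponsor_class = "other"
      )
    }
  }
  registry_dataset(if (length(rows) == 0) NULL else bind_rows(rows),
                   provenance = list(path = NA_character_,
                                     encoding = "fixture"))
}
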