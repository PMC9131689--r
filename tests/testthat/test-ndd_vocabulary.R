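test_that("the packaged vocabulary is sane and folding works", {
  expect_setequal(unique(tb_vocab$lookup$label), ndd_labels())
  counts <- table(tb_vocab$lookup$label)
  expect_true(all(counts >= 2))
  # stage variants fold into their reporting label
  expect_equal(normalize_condition_text("Parkinson Disease Dementia", tb_vocab), "PD")
  expect_equal(normalize_condition_text("PDD", tb_vocab), "PD")
  expect_equal(normalize_condition_text("LBD", tb_vocab), "DLB")
  expect_equal(normalize_condition_text("Frontotemporal Dementia", tb_vocab), "FTLD")
})

test_that("a variant assigned to two labels is a load-time error", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("fuzzy_threshold: 1", "labels:",
               "  AD: [Alzheimer Disease, dementia]",
               "  PD: [Parkinson Disease]",
               "  DLB: [Lewy Body Dementia, dementia]",
               "  FTLD: [Frontotemporal Dementia]",
               "  PSP: [Progressive Supranuclear Palsy]",
               "  CBD: [Corticobasal Degeneration]",
               "  CTE: [Chronic Traumatic Encephalopathy]",
               "  HD: [Huntington Disease]",
               "  ALS: [Amyotrophic Lateral Sclerosis]",
               "  MSA: [Multiple System Atrophy]"), path)
  expect_error(load_vocabulary(path), "dementia",
               class = "trialbasket_resource_error")
})

test_that("condition normalization matches names, variants and misspellings", {
  expect_equal(normalize_condition_text("Dementia With Lewy Bodies", tb_vocab), "DLB")
  expect_equal(normalize_condition_text("Lewy Body Dementia", tb_vocab), "DLB")
  expect_equal(normalize_condition_text("Type 2 Diabetes", tb_vocab), character())
  # one deletion, caught by fuzzy matching at threshold 1
  expect_equal(normalize_condition_text("Alzeimer Disease", tb_vocab), "AD")
  # bare 'dementia' has no disease qualifier
  expect_equal(normalize_condition_text("Dementia", tb_vocab), character())
  # abbreviations only match as standalone tokens, never inside words
  expect_equal(normalize_condition_text("Advanced cancer", tb_vocab), character())
  expect_equal(normalize_condition_text("AD", tb_vocab), "AD")
})

test_that("fuzzy matching agrees with a DP edit-distance oracle", {
  probes <- c("Alzeimer Disease", "Parkinsons Disease", "Parkinson Diseas",
              "Multiple Systm Atrophy", "Huntington Chorea", "Hentington Disease",
              "Dementia with Lewy Body", "Progressive Supranuclear Plasy",
              "Amyotrophc Lateral Sclerosis", "Corticobasal Degenerations",
              "Chronic Traumatic Encephalopathy", "Frontotemporal Degenertion",
              "diabetes mellitus", "essential tremor", "parkinsonism")
  for (p in probes) {
    expect_equal(normalize_condition_text(p, tb_vocab), oracle_match(p, tb_vocab),
                 label = sprintf("probe '%s'", p))
  }
})

test_that("matched set is monotone in the fuzzy threshold", {
  probes <- c("Alzeimer Disease", "Parkinson Diseas", "Huntington Diseases",
              "Multiple Systems Atrophy", "Lewy Body Dementias")
  for (t in 0:2) {
    v_lo <- tb_vocab; v_lo$fuzzy_threshold <- t
    v_hi <- tb_vocab; v_hi$fuzzy_threshold <- t + 1L
    for (p in probes) {
      lo <- normalize_condition_text(p, v_lo)
      hi <- normalize_condition_text(p, v_hi)
      expect_true(all(lo %in% hi),
                  label = sprintf("threshold %d subset of %d for '%s'", t, t + 1, p))
    }
  }
})

test_that("normalization is idempotent on canonical variant names", {
  for (i in seq_len(nrow(tb_vocab$lookup))) {
    got <- normalize_condition_text(tb_vocab$lookup$raw_variant[i], tb_vocab)
    expect_equal(got, tb_vocab$lookup$label[i],
                 label = sprintf("variant '%s'", tb_vocab$lookup$raw_variant[i]))
  }
})

test_that("eligibility scanning reads only the inclusion block", {
  txt <- "Inclusion Criteria: probable Alzheimer's disease or dementia with Lewy bodies."
  expect_equal(scan_eligibility_text(txt, tb_vocab), c("AD", "DLB"))
  excl <- "Inclusion Criteria: adults. Exclusion Criteria: Parkinson's disease."
  expect_equal(scan_eligibility_text(excl, tb_vocab), character())
  only_excl <- "Exclusion Criteria: Parkinson's disease"
  expect_equal(scan_eligibility_text(only_excl, tb_vocab), character())
})

test_that("eligibility scanning agrees with the brute-force n-gram oracle", {
  texts <- c(
    "Inclusion Criteria: diagnosis of multiple system atrophy or idiopathic Parkinson's disease; age 40-80. Exclusion Criteria: dementia with Lewy bodies.",
    "Inclusion Criteria: - Probable PSP by NINDS criteria - Corticobasal syndrome permitted",
    "Patients with Huntington's disease or amyotrophic lateral sclerosis (ALS)",
    "Inclusion Criteria: mild cognitive impairment or dementia of unclear etiology",
    "Inclusion: frontotemporal dementia (behavioral variant); Exclusion Criteria: Alzheimer disease, chronic traumatic encephalopathy"
  )
  for (txt in texts) {
    expect_equal(scan_eligibility_text(txt, tb_vocab), oracle_scan(txt, tb_vocab),
                 label = sprintf("text '%s'", substr(txt, 1, 40)))
  }
})

test_that("a record's NDD set is the union of its per-field matches", {
  rec <- make_record(
    conditions = c("Parkinson Disease Dementia"),
    eligibility = "Inclusion Criteria: patients with multiple system atrophy."
  )
  expect_equal(trial_ndd_set(rec, tb_vocab), c("MSA", "PD"))

  dementia_only <- make_record(conditions = "Dementia")
  expect_equal(trial_ndd_set(dementia_only, tb_vocab), character())

  # compositional oracle on generated records
  g <- generate_registry(synthetic_config(seed = 3, n_basket = 10,
                                          n_single_ndd = 5, n_non_ndd = 5,
                                          n_stage_only = 2, n_non_drug = 2),
                         tb_annotations)
  rec <- g$dataset$records
  for (i in seq_len(nrow(rec))) {
    expected <- sort(unique(c(
      unlist(lapply(rec$conditions[[i]], oracle_match, vocab = tb_vocab)),
      oracle_scan(rec$eligibility_text[[i]], tb_vocab)
    )))
    expect_equal(trial_ndd_set(rec[i, ], tb_vocab), expected,
                 label = rec$nct_id[i])
  }
})
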