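# small hand-built basket tables for aggregation tests
mini_baskets <- function() {
  tibble::tibble(
    nct_id = sprintf("NCT%08d", 1:6),
    agent = c("a", "a", "b", "b", "c", "c"),
    ndd_set = list(c("MSA", "PD"), c("PD", "PSP"), c("AD", "DLB", "PD"),
                   c("AD", "DLB"), c("ALS", "HD"), c("ALS", "HD")),
    moa_class = c("symptomatic", "symptomatic", "symptomatic", "symptomatic",
                  "dmt", "dmt"),
    cadro = c(rep("neurotransmitter receptors", 4), rep("tau", 2)),
    phase_labels = list("phase 2", "phase 3", "phase 2", character(),
                        "phase 1", "phase 1"),
    sponsor_class = c("biopharma", "biopharma", "nih_academic", "biopharma",
                      "nih_academic", "other"),
    enrollment = c(10L, 20L, 30L, 40L, NA, 60L),
    duration_weeks = c(4, 8, 12, NA, 2, 2),
    last_update_date = as.Date("2018-01-01") + 0:5,
    start_date = as.Date(c("2014-01-01", "2017-01-01", "2018-01-01",
                           "2013-01-01", "2019-01-01", NA))
  )
}

test_that("per-agent summaries aggregate trial counts and NDD unions", {
  sm <- summarize_agents(mini_baskets())
  expect_equal(nrow(sm), 3)
  a <- sm[sm$agent == "a", ]
  expect_equal(a$n_trials, 2L)
  expect_equal(a$ndd_union[[1]], c("MSA", "PD", "PSP"))
  expect_equal(sm$agent[sm$moa_class == "dmt"], "c")
  expect_equal(nrow(summarize_agents(mini_baskets()[0, ])), 0)
})

test_that("per-NDD agent counts equal a brute-force membership count", {
  sm <- summarize_agents(mini_baskets())
  tab <- count_agents_per_ndd(sm, "symptomatic")
  expect_equal(tab$n_agents[tab$ndd == "PD"], 2L)
  expect_equal(tab$n_agents[tab$ndd == "AD"], 1L)
  expect_equal(tab$n_agents[tab$ndd == "HD"], 0L)

  # random summaries, double-loop oracle
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(3:10, 1)
    fake <- tibble::tibble(
      agent = paste0("agent", seq_len(n)),
      moa_class = sample(c("symptomatic", "dmt"), n, replace = TRUE),
      n_trials = sample(1:5, n, replace = TRUE),
      ndd_union = replicate(n, sort(sample(ndd_labels(),
                                           sample(2:5, 1))), simplify = FALSE),
      cadro = "tau", goal = NA_character_
    )
    for (cls in c("symptomatic", "dmt")) {
      got <- count_agents_per_ndd(fake, cls)
      for (lbl in ndd_labels()) {
        manual <- 0L
        for (i in seq_len(n)) {
          if (fake$moa_class[i] == cls && lbl %in% fake$ndd_union[[i]]) {
            manual <- manual + 1L
          }
        }
        expect_equal(got$n_agents[got$ndd == lbl], manual,
                     label = sprintf("rep %d class %s label %s", rep, cls, lbl))
      }
    }
  }
})

test_that("pairwise NDD counts expand combinatorially and match a brute oracle", {
  one <- mini_baskets()[1, ]
  tab <- count_pairwise_ndd(one)
  expect_equal(tab$n_entries[tab$ndd_a == "MSA" & tab$ndd_b == "PD"], 1L)
  expect_equal(sum(tab$n_entries), 1L)

  # an entry with 3 disorders contributes to choose(3,2) = 3 pairs
  three <- mini_baskets()[3, ]
  expect_equal(sum(count_pairwise_ndd(three)$n_entries), 3L)

  # oracle over the full mini table
  tab <- count_pairwise_ndd(mini_baskets())
  b <- mini_baskets()
  for (j in seq_len(nrow(tab))) {
    manual <- sum(vapply(b$ndd_set, function(s)
      tab$ndd_a[j] %in% s && tab$ndd_b[j] %in% s, logical(1)))
    expect_equal(tab$n_entries[j], manual)
  }
  # symmetric storage covers each unordered pair exactly once
  expect_equal(nrow(tab), choose(10, 2))
  expect_true(all(tab$ndd_a < tab$ndd_b))
})

test_that("phase distribution counts agent-phase pairs with an unassigned bucket", {
  tab <- distribution_by_phase(mini_baskets(), "agents", "symptomatic")
  # agent a spans phases 2 and 3: counted in both
  expect_equal(tab$n[tab$phase == "phase 2"], 2L)  # a and b
  expect_equal(tab$n[tab$phase == "phase 3"], 1L)  # a
  expect_equal(tab$n[tab$phase == "unassigned"], 1L)  # b's unlabeled trial
  expect_equal(sum(distribution_by_phase(mini_baskets()[0, ], "agents")$n), 0L)

  # tally oracle on synthetic output
  g <- generate_registry(synthetic_config(seed = 13), tb_annotations)
  cas <- run_filter_cascade(g$dataset, tb_vocab, tb_lexicons, tb_annotations)
  tab <- distribution_by_phase(cas$baskets, "agents")
  pairs <- unique(do.call(rbind, lapply(seq_len(nrow(cas$baskets)), function(i) {
    ph <- cas$baskets$phase_labels[[i]]
    if (length(ph) == 0) ph <- "unassigned"
    data.frame(agent = cas$baskets$agent[i], phase = ph)
  })))
  for (p in tab$phase) {
    expect_equal(tab$n[tab$phase == p], sum(pairs$phase == p), label = p)
  }
})

test_that("sponsor distribution counts trial entries and sums to the total", {
  tab <- distribution_by_sponsor(mini_baskets())
  expect_equal(tab$n[tab$sponsor_class == "biopharma"], 3L)
  expect_equal(tab$n[tab$sponsor_class == "nih_academic"], 2L)
  expect_equal(sum(tab$n), nrow(mini_baskets()))
  expect_equal(sum(distribution_by_sponsor(mini_baskets()[0, ])$n), 0L)
})

test_that("robust mean honors both exclusion policies and reports bookkeeping", {
  vals <- tibble::tibble(id = letters[1:4], value = rep(10, 4))
  st <- robust_mean(vals)
  expect_equal(st$mean, 10)
  expect_equal(st$n_retained, 4L)
  expect_equal(st$excluded_ids, character())

  # percentile band dropping min and max: sort-and-trim gives mean 10, n 3
  ext <- tibble::tibble(id = letters[1:5], value = c(1, 10, 10, 10, 1000))
  st <- robust_mean(ext, percentile_band = c(0.2, 0.8))
  expect_equal(st$mean, 10)
  expect_equal(st$n_retained, 3L)
  expect_setequal(st$excluded_ids, c("a", "e"))

  # explicit id exclusion
  st <- robust_mean(ext, exclude_ids = c("a", "e"))
  expect_equal(st$mean, 10)
  expect_equal(st$n_retained, 3L)

  # empty exclusion equals the arithmetic mean exactly
  set.seed(4)
  rnd <- tibble::tibble(id = as.character(1:20), value = rnorm(20))
  expect_equal(robust_mean(rnd)$mean, mean(rnd$value))

  expect_error(robust_mean(ext, exclude_ids = letters[1:5]),
               class = "trialbasket_argument_error")
})

test_that("recency fraction reports numerator and denominator", {
  b <- mini_baskets()
  r <- recency_fraction(b, "2016-06-06")
  # start dates: 2014, 2017, 2018, 2013, 2019, NA->update 2018-01-06
  expect_equal(r$numerator, 4L)
  expect_equal(r$denominator, 6L)
  expect_equal(r$fraction, 4 / 6)
  old <- recency_fraction(b, "2030-01-01")
  expect_equal(old$fraction, 0)

  # comparison oracle on synthetic dates
  g <- generate_registry(synthetic_config(seed = 19), tb_annotations)
  cas <- run_filter_cascade(g$dataset, tb_vocab, tb_lexicons, tb_annotations)
  cutoff <- as.Date("2016-06-06")
  r <- recency_fraction(cas$baskets, cutoff)
  dates <- cas$baskets$start_date
  dates[is.na(dates)] <- cas$baskets$last_update_date[is.na(dates)]
  expect_equal(r$numerator, sum(dates >= cutoff, na.rm = TRUE))
  expect_equal(r$denominator, sum(!is.na(dates)))
})

test_that("summary bundle conserves entry counts and write_tables is deterministic", {
  g <- generate_registry(synthetic_config(seed = 29), tb_annotations)
  cas <- run_filter_cascade(g$dataset, tb_vocab, tb_lexicons, tb_annotations)
  bundle <- build_summary_bundle(cas, tb_annotations)
  # sum over agents of n_trials equals the cascade's final entry count
  expect_equal(sum(bundle$agent_summaries$n_trials), cas$trace$n_basket_entries)
  # no third path: every entry is classified or listed as unclassified
  expect_equal(sum(!is.na(cas$baskets$moa_class)) +
                 nrow(bundle$unclassified_entries),
               nrow(cas$baskets))

  d1 <- file.path(withr::local_tempdir(), "out1")
  d2 <- file.path(withr::local_tempdir(), "out2")
  write_tables(bundle, d1)
  write_tables(bundle, d2)
  files <- list.files(d1)
  expect_true(all(c("agents_symptomatic.csv", "agents_dmt.csv",
                    "ndd_pair_counts.csv", "filter_trace.json",
                    "report.txt", "data_dictionary.txt") %in% files))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE), label = f)
  }
})

test_that("an empty bundle writes header-only tables", {
  cas <- run_filter_cascade(registry_dataset(), tb_vocab, tb_lexicons,
                            tb_annotations)
  bundle <- build_summary_bundle(cas, tb_annotations)
  d <- file.path(withr::local_tempdir(), "empty_out")
  write_tables(bundle, d)
  sym <- readLines(file.path(d, "agents_symptomatic.csv"))
  expect_length(sym, 1)
  expect_match(sym, "agent")
})
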