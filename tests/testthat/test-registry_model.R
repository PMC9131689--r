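test_that("XML study records parse into trial records with captured fields", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_study_xml(path, list(
    study_spec("NCT02897963", "Multiple System Atrophy",
               iv_names = "Midodrine")
  ))
  ds <- parse_registry_xml(path)
  expect_s3_class(ds, "registry_dataset")
  expect_equal(nrow(ds$records), 1)
  r <- ds$records
  expect_equal(r$nct_id, "NCT02897963")
  expect_equal(r$conditions[[1]], "Multiple System Atrophy")
  expect_equal(r$interventions[[1]]$name, "Midodrine")
  expect_equal(r$interventions[[1]]$declared_type, "drug")
  expect_equal(r$phase_labels[[1]], "phase 2")
  expect_equal(r$status, "completed")
  expect_equal(r$study_type, "interventional")
  expect_equal(r$last_update_date, as.Date("2015-06-01"))
  expect_equal(r$enrollment, 100L)
  expect_equal(r$sponsor_class, "biopharma")
})

test_that("XML parsing handles empty containers, malformed files and duplicates", {
  empty <- withr::local_tempfile(fileext = ".xml")
  writeLines("<clinical_studies></clinical_studies>", empty)
  expect_equal(nrow(parse_registry_xml(empty)$records), 0)

  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<clinical_studies><clinical_study>", bad)
  expect_error(parse_registry_xml(bad), class = "trialbasket_parse_error")

  dup <- withr::local_tempfile(fileext = ".xml")
  write_study_xml(dup, list(
    study_spec("NCT00000001", "Parkinson Disease"),
    study_spec("NCT00000001", "Alzheimer Disease")
  ))
  expect_error(parse_registry_xml(dup), "NCT00000001",
               class = "trialbasket_validation_error")
})

test_that("XML parsing never invents values for absent optional fields", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("<clinical_studies><clinical_study>",
               "<id_info><nct_id>NCT00000042</nct_id></id_info>",
               "</clinical_study></clinical_studies>"), path)
  r <- parse_registry_xml(path)$records
  expect_true(is.na(r$title))
  expect_equal(r$conditions[[1]], character())
  expect_true(is.na(r$last_update_date))
  expect_true(is.na(r$start_date))
  expect_true(is.na(r$enrollment))
  expect_true(is.na(r$n_arms))
  expect_true(is.na(r$age_min))
  expect_equal(r$phase_labels[[1]], character())
})

test_that("flat tables split multi-valued cells on the declared separator", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("nct_id,conditions,intervention_names,intervention_types",
               'NCT00000007,"Multiple System Atrophy|Parkinson Disease",Droxidopa,drug'),
             path)
  ds <- parse_flat_table(path)
  expect_equal(ds$records$conditions[[1]],
               c("Multiple System Atrophy", "Parkinson Disease"))

  header_only <- withr::local_tempfile(fileext = ".csv")
  writeLines("nct_id,conditions", header_only)
  expect_equal(nrow(parse_flat_table(header_only)$records), 0)
})

test_that("flat-table schema errors name the problem", {
  no_id <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("title,conditions", "x,y"), no_id)
  expect_error(parse_flat_table(no_id), "nct_id",
               class = "trialbasket_schema_error")

  blank <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("nct_id,title", "NCT00000001,a", ",b"), blank)
  expect_error(parse_flat_table(blank), "row",
               class = "trialbasket_schema_error")
})

test_that("write/parse round trip is the identity on a synthetic registry", {
  g <- generate_registry(synthetic_config(seed = 11, n_basket = 8,
                                          n_single_ndd = 5, n_non_ndd = 5,
                                          n_stage_only = 3, n_non_drug = 3),
                         tb_annotations)
  path <- withr::local_tempfile(fileext = ".csv")
  write_flat_table(g$dataset, path)
  back <- parse_flat_table(path)
  orig <- g$dataset$records[order(g$dataset$records$nct_id), ]
  for (col in names(orig)) {
    expect_equal(back$records[[col]], orig[[col]], ignore_attr = TRUE,
                 label = sprintf("column %s after round trip", col))
  }
  # second cycle is a byte-level fixed point
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_flat_table(back, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("writing the same dataset twice is byte-identical", {
  ds <- registry_dataset(dplyr::bind_rows(
    make_record("NCT00000003", "Parkinson Disease"),
    make_record("NCT00000001", "Huntington Disease"),
    make_record("NCT00000002", "Alzheimer Disease")
  ))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_flat_table(ds, p1)
  write_flat_table(ds, p2)
  expect_identical(readLines(p1), readLines(p2))
  # rows come back sorted by nct_id
  expect_equal(parse_flat_table(p1)$records$nct_id,
               sprintf("NCT%08d", 1:3))
})

test_that("record validation enforces identifier shape and field invariants", {
  expect_error(registry_dataset(make_record("NCT123")),
               class = "trialbasket_validation_error")
  expect_error(
    registry_dataset(dplyr::bind_rows(make_record("NCT00000001"),
                                      make_record("NCT00000001"))),
    "duplicate", class = "trialbasket_validation_error")
  expect_error(
    registry_dataset(make_record("NCT00000001",
                                 phase_labels = c("phase 2", "phase 2"))),
    "phase", class = "trialbasket_validation_error")
  expect_error(
    registry_dataset(make_record("NCT00000001", enrollment = -5L)),
    "enrollment", class = "trialbasket_validation_error")
  expect_error(
    registry_dataset(make_record("NCT00000001",
                                 interventions = tibble::tibble(
                                   name = "  ", declared_type = "drug"))),
    class = "trialbasket_validation_error")
})

test_that("ambiguous or garbled dates raise instead of guessing", {
  expect_error(parse_registry_date("13/40/2020"),
               class = "trialbasket_date_error")
  expect_error(parse_registry_date("2020-13-40"),
               class = "trialbasket_date_error")
  expect_equal(parse_registry_date("01/01/2010"), as.Date("2010-01-01"))
  expect_equal(parse_registry_date("June 6, 2021"), as.Date("2021-06-06"))
})
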