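# In-code builders for small registry fixtures.

make_record <- function(nct = "NCT00000001", conditions = character(),
                        eligibility = NA_character_,
                        interventions = NULL, ...) {
  args <- list(nct_id = nct, conditions = conditions,
               eligibility_text = eligibility,
               interventions = interventions,
               last_update_date = as.Date("2015-06-01"),
               status = "completed")
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(trial_record, args)
}

drug_iv <- function(...) {
  tibble::tibble(name = c(...), declared_type = "drug")
}

# a minimal clinicaltrials.gov-style XML document
write_study_xml <- function(path, studies) {
  body <- vapply(studies, function(s) {
    conds <- paste(sprintf("  <condition>%s</condition>", s$conditions),
                   collapse = "\n")
    ivs <- paste(vapply(seq_along(s$iv_names), function(i) {
      sprintf(paste0("  <intervention>\n    <intervention_type>%s",
                     "</intervention_type>\n    <intervention_name>%s",
                     "</intervention_name>\n  </intervention>"),
              s$iv_types[i], s$iv_names[i])
    }, character(1)), collapse = "\n")
    sprintf(paste0(
      "<clinical_study>\n",
      "  <id_info><nct_id>%s</nct_id></id_info>\n",
      "  <brief_title>%s</brief_title>\n%s\n%s\n",
      "  <phase>%s</phase>\n",
      "  <overall_status>%s</overall_status>\n",
      "  <study_type>Interventional</study_type>\n",
      "  <last_update_posted>%s</last_update_posted>\n",
      "  <enrollment>%d</enrollment>\n",
      "  <sponsors><lead_sponsor><agency_class>%s</agency_class>",
      "</lead_sponsor></sponsors>\n",
      "</clinical_study>"),
      s$nct, s$title, conds, ivs, s$phase, s$status, s$update, s$enrollment,
      s$agency)
  }, character(1))
  writeLines(c("<clinical_studies>", body, "</clinical_studies>"), path)
  path
}

study_spec <- function(nct, conditions, iv_names = "Droxidopa",
                       iv_types = rep("Drug", length(iv_names)),
                       title = "A study", phase = "Phase 2",
                       status = "Completed", update = "June 1, 2015",
                       enrollment = 100L, agency = "Industry") {
  list(nct = nct, conditions = conditions, iv_names = iv_names,
       iv_types = iv_types, title = title, phase = phase, status = status,
       update = update, enrollment = enrollment, agency = agency)
}
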