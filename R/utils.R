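#' @importFrom rlang %||% abort warn .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# Controlled vocabularies used across the pipeline ---------------------------

#' Canonical reporting labels for the prespecified neurodegenerative disorders
#' @return Character vector of the 10 reporting labels.
#' @export
ndd_labels <- function() {
  c("AD", "PD", "DLB", "FTLD", "PSP", "CBD", "CTE", "HD", "ALS", "MSA")
}

# Stage-variant folding: severity stages of a disease fold into its reporting
# label and never count toward basket multiplicity on their own.
stage_folding_map <- function() {
  c(PDD = "PD", LBD = "DLB", FTD = "FTLD")
}

registry_statuses <- function() {
  c("not yet recruiting", "recruiting", "enrolling by invitation",
    "active not recruiting", "terminated", "completed", "suspended",
    "withdrawn", "unknown")
}

sponsor_classes <- function() {
  c("biopharma", "nih_academic", "public_private", "other")
}

phase_vocabulary <- function() {
  c("phase 1", "phase 2", "phase 3", "phase 4", "not applicable")
}

intervention_classes <- function() {
  c("drug", "behavioral", "biomarker", "device", "stem_cell", "supplement",
    "placebo", "other")
}

#' CADRO therapeutic-target categories
#'
#' The closed vocabulary of Common Alzheimer's Disease Research Ontology
#' target categories used to annotate agents.
#' @return Character vector of 20 category labels.
#' @export
cadro_categories <- function() {
  c("amyloid beta", "tau", "ApoE/lipids", "neurotransmitter receptors",
    "neurogenesis", "inflammation", "oxidative stress", "cell death",
    "proteostasis/proteinopathies", "metabolism and bioenergetics",
    "vasculature", "growth factors and hormones",
    "synaptic plasticity/neuroprotection", "gut-brain axis",
    "circadian rhythm", "environmental factors", "epigenetic regulators",
    "multi-target", "unknown", "other")
}

# Text normalization ----------------------------------------------------------

# Lowercase, drop possessive apostrophes, map remaining punctuation to
# spaces, squeeze whitespace. The single normalization used by the vocabulary
# matcher, the lexicon classifier and the agent synonym table.
normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[’']", "", x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}

# Date parsing ----------------------------------------------------------------

# ISO-8601 first, then MM/DD/YYYY, then the registry XML's "Month D, YYYY".
# Anything else raises rather than guessing.
parse_registry_date <- function(x, field = "date") {
  out <- as.Date(rep(NA, length(x)))
  for (i in seq_along(x)) {
    s <- x[[i]]
    if (is.null(s) || is.na(s) || !nzchar(trimws(s))) next
    s <- trimws(s)
    d <- NA
    if (grepl("^\\d{4}-\\d{2}-\\d{2}$", s)) {
      d <- as.Date(s, format = "%Y-%m-%d")
    } else if (grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", s)) {
      d <- as.Date(s, format = "%m/%d/%Y")
    } else if (grepl("^[A-Za-z]+ \\d{1,2}, \\d{4}$", s)) {
      d <- c_locale_date(s, "%B %d, %Y")
    } else if (grepl("^[A-Za-z]+ \\d{4}$", s)) {
      # registry records often carry month-resolution dates
      d <- c_locale_date(paste0(sub(" ", " 1, ", s)), "%B %d, %Y")
    }
    if (is.na(d)) {
      abort(sprintf("unparseable %s: '%s'", field, x[[i]]),
            class = "trialbasket_date_error")
    }
    out[i] <- d
  }
  out
}

c_locale_date <- function(s, fmt) {
  old <- Sys.getlocale("LC_TIME")
  on.exit(try(Sys.setlocale("LC_TIME", old), silent = TRUE), add = TRUE)
  try(Sys.setlocale("LC_TIME", "C"), silent = TRUE)
  as.Date(s, format = fmt)
}

# Path to a packaged resource file
tb_resource <- function(...) {
  system.file("extdata", ..., package = "trialbasket", mustWork = TRUE)
}

is_valid_nct <- function(x) grepl("^NCT[0-9]{8}$", x)
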