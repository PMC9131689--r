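# Independent oracles: deliberately naive implementations used only to
# cross-check the package's code paths.

# Levenshtein distance via the textbook dynamic program (independent of
# utils::adist, which the package uses internally).
lev_dp <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  na <- length(a); nb <- length(b)
  d <- matrix(0L, na + 1, nb + 1)
  d[, 1] <- 0:na
  d[1, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      cost <- if (a[i] == b[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + cost)
    }
  }
  d[na + 1, nb + 1]
}

# same normalization contract as the package, recomputed naively
naive_normalize <- function(x) {
  x <- tolower(x)
  x <- gsub("[’']", "", x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}

# Brute-force vocabulary matcher: tests every variant by exact equality and,
# for strings of >= 8 characters, by DP edit distance against every variant
# of >= 8 characters.
oracle_match <- function(text, vocab) {
  norm <- naive_normalize(text)
  lk <- vocab$lookup
  exact <- lk$label[lk$variant == norm]
  if (length(exact) > 0) return(sort(unique(exact)))
  if (nchar(norm) < 8) return(character())
  hits <- character()
  for (i in seq_len(nrow(lk))) {
    v <- lk$variant[i]
    if (nchar(v) >= 8 && lev_dp(norm, v) <= vocab$fuzzy_threshold) {
      hits <- c(hits, lk$label[i])
    }
  }
  sort(unique(hits))
}

# Brute-force eligibility scan: every token n-gram of the inclusion block
# (n up to the longest variant length), each matched with oracle_match.
oracle_scan <- function(text, vocab) {
  m <- regexpr("exclusion\\s+criteria", text, ignore.case = TRUE)
  if (m[1] > 0) text <- substr(text, 1, m[1] - 1)
  tokens <- strsplit(naive_normalize(text), " ")[[1]]
  tokens <- tokens[nzchar(tokens)]
  found <- character()
  max_n <- max(lengths(strsplit(vocab$lookup$variant, " ")))
  for (n in seq_len(min(max_n, length(tokens)))) {
    for (s in seq_len(length(tokens) - n + 1)) {
      gram <- paste(tokens[s:(s + n - 1)], collapse = " ")
      found <- c(found, oracle_match(gram, vocab))
    }
  }
  sort(unique(found))
}

# shared loaded resources (packaged defaults) for the whole suite
tb_vocab <- load_vocabulary()
tb_lexicons <- load_lexicons()
tb_annotations <- load_agent_annotations()
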