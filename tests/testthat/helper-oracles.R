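# Independent oracles and shared fixtures for the test suite.

# Brute-force recursive edit distance under the three-operation model
# (replace / delete / add, unit costs). Exponential: only for tiny strings.
lev_oracle <- function(a, b) {
  if (nchar(a) == 0L) return(nchar(b))
  if (nchar(b) == 0L) return(nchar(a))
  ta <- substr(a, 2, nchar(a))
  tb <- substr(b, 2, nchar(b))
  cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
  min(lev_oracle(ta, tb) + cost,   # substitute (or match)
      lev_oracle(ta, b) + 1L,      # delete from a
      lev_oracle(a, tb) + 1L)      # insert into a
}

# All strings over `alphabet` of length 0..max_len.
enumerate_strings <- function(alphabet, max_len) {
  out <- ""
  cur <- ""
  for (l in seq_len(max_len)) {
    cur <- as.vector(outer(cur, alphabet, paste0))
    out <- c(out, cur)
  }
  out
}

# Small toy dictionary used across modules (built in code, not from disk,
# so tests control the vocabulary exactly).
toy_terms <- c(
  "asthma", "asthme", "asthme du nourrisson", "hepatite", "hepatite a",
  "cholesterol", "alzheimer", "acupuncture", "insomnia", "inosine",
  "circulation accident", "chute accidentelle", "glucosidases", "sida",
  "suette miliaire", "rickettsioses", "tumeurs du sein", "therapeutique",
  "euthanasia", "grippe", "vaccins", "cancer"
)

toy_index <- function(terms = toy_terms, stops = c("du", "de", "la", "the", "of")) {
  term_index(terms, stops = stops)
}

# Fixture dictionary shipped with the package.
pkg_index <- local({
  idx <- NULL
  function() {
    if (is.null(idx)) idx <<- load_dictionary()
    idx
  }
})

expect_sorted <- function(x) expect_identical(x, sort(x))
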