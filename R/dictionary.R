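# Term dictionary loading, normalization and tiered indexing.

#' Build a term index from a character vector of terms
#'
#' Every term is segmented, lowercased, deaccented and phonemised; duplicate
#' normalized terms are dropped. The index exposes four access paths:
#' `by_surface` (normalized word -> terms containing it), `by_phone`
#' (phonetic code -> single words sharing it), `by_bag` (sorted phonemised
#' content-word multiset -> terms) and `vocabulary` (all distinct single
#' words). Stop words are removed from multi-word terms for the bag index
#' but kept in the token sequence.
#'
#' @param terms character vector of raw terms.
#' @param source source tag(s): recycled along `terms` (e.g. `"mesh_term"`,
#'   `"mesh_synonym"`, `"custom"`).
#' @param stops stop-word vector; see [load_stopwords()].
#' @param rules phoneme rule set; see [load_phoneme_rules()].
#' @return an object of class `term_index`.
#' @export
term_index <- function(terms, source = "custom",
                       stops = default_stopwords(),
                       rules = default_phoneme_rules()) {
  terms <- as.character(terms)
  terms <- terms[!is.na(terms) & nzchar(trimws(terms))]
  if (length(terms) == 0L) stop("empty dictionary")
  source <- rep_len(as.character(source), length(terms))

  tokens <- lapply(terms, function(t) normalize_word(segment_query(t)))
  keep <- vapply(tokens, length, integer(1)) > 0L
  terms <- terms[keep]; source <- source[keep]; tokens <- tokens[keep]
  norm <- vapply(tokens, paste, character(1), collapse = " ")
  dup <- duplicated(norm)
  terms <- terms[!dup]; source <- source[!dup]
  tokens <- tokens[!dup]; norm <- norm[!dup]

  vocabulary <- sort(unique(unlist(tokens)))
  vocab_codes <- phonemise(vocabulary, rules)
  code_of <- stats::setNames(vocab_codes, vocabulary)

  codes <- lapply(tokens, function(tk) unname(code_of[tk]))
  content <- lapply(tokens, remove_stopwords, stops = stops)
  content_codes <- lapply(content, function(tk) {
    if (length(tk)) unname(code_of[tk]) else character(0)
  })

  by_surface <- new.env(parent = emptyenv())
  for (i in seq_along(tokens)) {
    for (w in unique(tokens[[i]])) {
      assign(w, c(get0(w, envir = by_surface, ifnotfound = integer(0)), i),
             envir = by_surface)
    }
  }
  by_phone <- split(vocabulary, vocab_codes)
  bag_key <- vapply(content_codes, function(cc) {
    if (length(cc)) paste(sort(cc), collapse = "|") else NA_character_
  }, character(1))
  by_bag <- split(which(!is.na(bag_key)), bag_key[!is.na(bag_key)])

  structure(
    list(terms = data.frame(raw = terms, norm = norm, source = source,
                            word_count = lengths(tokens),
                            stringsAsFactors = FALSE),
         tokens = tokens, codes = codes,
         content_tokens = content, content_codes = content_codes,
         vocabulary = vocabulary, vocab_codes = code_of,
         by_surface = by_surface, by_phone = by_phone, by_bag = by_bag,
         stops = stops, rules = rules),
    class = "term_index"
  )
}

#' Load a term dictionary file into an index
#'
#' Accepts UTF-8 text with one term per line, or a 2-column TSV
#' (`term TAB source`). Lines starting with `#` are skipped.
#'
#' @param path dictionary file; defaults to the packaged fixture dictionary
#'   (~220 French medical terms assembled around the documented examples).
#' @inheritParams term_index
#' @return a `term_index`.
#' @export
load_dictionary <- function(path = NULL, stops = default_stopwords(),
                            rules = default_phoneme_rules()) {
  path <- path %||% ms_extdata("dictionary_fr.tsv")
  if (!file.exists(path)) stop("dictionary file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("empty dictionary: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- vapply(parts, `[[`, character(1), 1L)
  source <- vapply(parts, function(p) if (length(p) > 1L) p[[2]] else "custom",
                   character(1))
  term_index(terms, source = source, stops = stops, rules = rules)
}

#' @export
print.term_index <- function(x, ...) {
  cat("term_index:", nrow(x$terms), "terms,",
      length(x$vocabulary), "distinct words\n")
  wc <- table(pmin(x$terms$word_count, 4L))
  labels <- c("1 word", "2 words", "3 words", "4+ words")
  for (k in seq_along(labels)) {
    n <- if (as.character(k) %in% names(wc)) wc[[as.character(k)]] else 0L
    cat(sprintf("  %-8s %d\n", labels[k], n))
  }
  invisible(x)
}

#' Vocabulary of a term index
#'
#' @param index a `term_index`.
#' @return sorted character vector of all distinct single words.
#' @export
vocabulary <- function(index) {
  stopifnot(inherits(index, "term_index"))
  index$vocabulary
}

#' Correction candidates for one query word
#'
#' Tiered lookup mirroring the correction pipeline: (1) exact -- the word is
#' itself in the vocabulary; (2) phonetic -- vocabulary words with the same
#' phonetic code; (3) approximate -- vocabulary words accepted by the
#' combined normalized-Levenshtein / Stoilos test (see [accepts()]). By
#' default each tier short-circuits the next; `tiers = "union"` pools all
#' three. Words shorter than `min_word_len` skip the approximate tier
#' (they pass through uncorrected).
#'
#' @param word a single normalized query word.
#' @param index a `term_index`.
#' @param theta_lev,theta_sto acceptance thresholds; see [accepts()].
#' @param params a [stoilos_params()] object.
#' @param min_word_len minimum word length for the approximate tier
#'   (default 3).
#' @param tiers `"short_circuit"` (default) or `"union"`.
#' @return alphabetically sorted character vector of vocabulary words
#'   (possibly empty); never ranked.
#' @examples
#' idx <- load_dictionary()
#' words_within("alzaymer", idx)   # phonetic tier -> "alzheimer"
#' @export
words_within <- function(word, index, theta_lev = 0.2, theta_sto = 0.7,
                         params = stoilos_params(), min_word_len = 3L,
                         tiers = c("short_circuit", "union")) {
  stopifnot_scalar_string(word, "word")
  stopifnot(inherits(index, "term_index"))
  tiers <- match.arg(tiers)
  out <- character(0)

  exact <- if (word %in% index$vocabulary) word else character(0)
  if (length(exact) && tiers == "short_circuit") return(exact)
  out <- c(out, exact)

  code <- phonemise(word, index$rules)
  phonetic <- setdiff(index$by_phone[[code]] %||% character(0), word)
  if (length(phonetic) && tiers == "short_circuit") return(sort(phonetic))
  out <- c(out, phonetic)

  if (nchar(word) >= min_word_len) {
    vocab <- index$vocabulary
    m <- pmax(nchar(word), nchar(vocab))
    ln <- lev_dist_vec_cpp(word, vocab) / m
    cand <- if (is.infinite(theta_lev)) vocab else vocab[ln < theta_lev]
    if (theta_sto > -1 && length(cand)) {
      sims <- vapply(cand, function(v) stoilos_sim(word, v, params)$sim,
                     numeric(1))
      cand <- cand[sims > theta_sto]
    }
    out <- c(out, cand)
  }
  sort(unique(out))
}
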