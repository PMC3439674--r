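# Synthetic misspelling generator: Damerau-type single-edit typos, phonetic
# distortions, and seeded gold sets so the whole pipeline is testable
# without real query logs.

.typo_ops <- c("insertion", "deletion", "substitution", "transposition",
               "phonetic_swap")

# Grapheme pairs pronounced alike in French; applied in either direction.
# A doubling of any letter is also sound-preserving (duplicate letters are
# collapsed by the phonetic encoder).
.homophone_swaps <- list(
  c("ph", "f"), c("c", "k"), c("qu", "k"), c("y", "i"), c("au", "o"),
  c("eau", "o"), c("ai", "ei"), c("oi", "oy")
)

# AZERTY keyboard rows for adjacent-key substitutions.
.azerty_rows <- c("azertyuiop", "qsdfghjklm", "wxcvbn")

.azerty_neighbours <- function(ch) {
  for (row in .azerty_rows) {
    pos <- regexpr(ch, row, fixed = TRUE)
    if (pos > 0) {
      n <- nchar(row)
      out <- character(0)
      if (pos > 1) out <- c(out, substr(row, pos - 1, pos - 1))
      if (pos < n) out <- c(out, substr(row, pos + 1, pos + 1))
      return(out)
    }
  }
  character(0)
}

.apply_swap <- function(word, from, to, occurrence) {
  starts <- gregexpr(from, word, fixed = TRUE)[[1]]
  if (starts[1] == -1L) return(NULL)
  s <- starts[occurrence]
  paste0(substr(word, 1, s - 1), to,
         substr(word, s + nchar(from), nchar(word)))
}

#' Generate one misspelling of a word
#'
#' Applies exactly one error operation. The four Damerau operations cover
#' the bulk of typographic errors: `insertion` of one letter, `deletion` of
#' one letter, `substitution` of one letter (optionally biased to
#' AZERTY-adjacent keys), and `transposition` of two adjacent letters (e.g.
#' `"asthma"` to `"ashtma"`). `phonetic_swap` emulates cognitive errors: a
#' grapheme is replaced by a homophone grapheme (`c` and `k`, `ph` and `f`,
#' `y` and `i`, `au` and `o`, ...) or a letter is doubled, and the result is
#' kept only if it still has the same phonetic code as the input.
#'
#' Uses the current RNG state unless `seed` is given; the same seed always
#' yields the same output.
#'
#' @param word a single normalized word of at least 2 characters.
#' @param op one of `"insertion"`, `"deletion"`, `"substitution"`,
#'   `"transposition"`, `"phonetic_swap"`.
#' @param pos optional fixed 1-based position (for the Damerau operations);
#'   sampled uniformly when NULL.
#' @param seed optional integer seed.
#' @param layout `"none"` (uniform substitution letters) or `"azerty"`
#'   (adjacent-key substitutions when possible).
#' @param rules phoneme rule set, used to validate `phonetic_swap`.
#' @return the misspelled word, always different from `word`;
#'   `NA_character_` if no sound-preserving swap exists (phonetic_swap
#'   only).
#' @examples
#' make_typo("asthma", "transposition", pos = 3)  # "ashtma"
#' make_typo("asthma", "deletion", pos = 4)       # "astma"
#' @export
make_typo <- function(word, op = .typo_ops, pos = NULL, seed = NULL,
                      layout = c("none", "azerty"),
                      rules = default_phoneme_rules()) {
  stopifnot_scalar_string(word, "word")
  if (nchar(word) < 2L) stop("word too short for a typo: ", word)
  op <- match.arg(op, .typo_ops)
  layout <- match.arg(layout)
  if (!is.null(seed)) set.seed(seed)
  n <- nchar(word)
  chars <- strsplit(word, "", fixed = TRUE)[[1]]

  if (op == "insertion") {
    p <- pos %||% sample.int(n + 1L, 1L)
    letter <- sample(letters, 1L)
    return(paste0(substr(word, 1, p - 1), letter, substr(word, p, n)))
  }
  if (op == "deletion") {
    p <- pos %||% sample.int(n, 1L)
    return(paste0(substr(word, 1, p - 1), substr(word, p + 1, n)))
  }
  if (op == "substitution") {
    p <- pos %||% sample.int(n, 1L)
    pool <- setdiff(letters, chars[p])
    if (layout == "azerty") {
      adj <- setdiff(.azerty_neighbours(chars[p]), chars[p])
      if (length(adj)) pool <- adj
    }
    letter <- if (length(pool) == 1L) pool else sample(pool, 1L)
    return(paste0(substr(word, 1, p - 1), letter, substr(word, p + 1, n)))
  }
  if (op == "transposition") {
    swappable <- which(chars[-n] != chars[-1])
    if (length(swappable) == 0L) stop("no transposable adjacent pair in: ", word)
    p <- pos %||% if (length(swappable) == 1L) swappable else sample(swappable, 1L)
    if (!(p %in% swappable)) stop("transposition at pos would be a no-op")
    chars[c(p, p + 1L)] <- chars[c(p + 1L, p)]
    return(paste(chars, collapse = ""))
  }
  # phonetic_swap: enumerate candidate rewrites, keep sound-preserving ones
  cands <- character(0)
  for (pair in .homophone_swaps) {
    for (dir in list(pair, rev(pair))) {
      starts <- gregexpr(dir[1], word, fixed = TRUE)[[1]]
      if (starts[1] == -1L) next
      for (k in seq_along(starts)) {
        cand <- .apply_swap(word, dir[1], dir[2], k)
        if (!is.null(cand) && cand != word) cands <- c(cands, cand)
      }
    }
  }
  for (p in seq_len(n)) {   # letter doubling
    if (chars[p] %in% letters) {
      cands <- c(cands, paste0(substr(word, 1, p), chars[p],
                               substr(word, p + 1, n)))
    }
  }
  cands <- unique(cands[cands != word])
  if (length(cands) == 0L) return(NA_character_)
  code <- phonemise(word, rules)
  ok <- cands[vapply(cands, function(x) phonemise(x, rules) == code,
                     logical(1))]
  if (length(ok) == 0L) return(NA_character_)
  if (length(ok) == 1L) ok else sample(ok, 1L)
}

#' Generate a synthetic query set with gold-standard corrections
#'
#' Emulates the structure of real no-answer health queries: terms are drawn
#' from the dictionary, concatenated (optionally with stop words interposed)
#' into queries of 1 to 4+ content words, and a fraction `error_rate` of the
#' queries receives exactly one typo in one eligible word. The intended
#' term(s) and the intended word are recorded as gold corrections. Typos
#' that collide with an existing vocabulary word are rejected and resampled:
#' a misspelling that lands on a real term would not be detectable as an
#' error (real no-answer queries are, by construction, absent from the
#' dictionary).
#'
#' The default word-count mix (17/26/23/34% for 1/2/3/4+ words) follows the
#' observed structure of no-answer query logs. The default minimum length of
#' a word receiving a typo is 6 characters so that any single edit keeps the
#' normalized edit distance strictly below the 0.2 operating threshold
#' (1/6 < 0.2, whereas a deletion on a 5-letter word gives exactly 0.2,
#' which a strict comparison rejects).
#'
#' @param index a `term_index`.
#' @param n_queries number of queries to generate.
#' @param words_per_query named numeric vector of sampling weights for 1, 2,
#'   3 and 4 content words.
#' @param error_rate fraction of queries receiving a typo.
#' @param ops typo operations to sample from (see [make_typo()]).
#' @param seed integer seed; the whole set is reproducible from it.
#' @param stopword_rate probability of interposing a stop word between
#'   terms in multi-word queries.
#' @param min_typo_word_len minimum length of a word eligible for a typo.
#' @param layout substitution layout, see [make_typo()].
#' @return list with `queries` (character), `gold` (a [gold_set()]) and
#'   `meta` (data.frame with the sampled term, word, operation and typo per
#'   query).
#' @export
make_gold_set <- function(index, n_queries = 100L,
                          words_per_query = c("1" = 0.17, "2" = 0.26,
                                              "3" = 0.23, "4" = 0.34),
                          error_rate = 0.5,
                          ops = c("insertion", "deletion", "substitution",
                                  "transposition"),
                          seed = 1L, stopword_rate = 0.25,
                          min_typo_word_len = 6L,
                          layout = c("none", "azerty")) {
  stopifnot(inherits(index, "term_index"))
  if (nrow(index$terms) == 0L) stop("empty index")
  layout <- match.arg(layout)
  set.seed(seed)
  wc_choices <- as.integer(names(words_per_query))

  content_counts <- lengths(index$content_tokens)
  eligible_terms <- which(content_counts >= 1L)
  stops_pool <- if (length(index$stops)) index$stops else character(0)

  queries <- character(0)
  gold_expected <- list()
  needs <- logical(0)
  meta <- list()

  attempts <- 0L
  while (length(queries) < n_queries && attempts < 50L * n_queries) {
    attempts <- attempts + 1L
    k <- if (length(wc_choices) == 1L) wc_choices else
      sample(wc_choices, 1L, prob = words_per_query)
    picked <- integer(0)
    words <- character(0)
    while (length(words) < k) {
      room <- k - length(words)
      fits <- eligible_terms[content_counts[eligible_terms] <= room]
      if (length(fits) == 0L) break
      t <- if (length(fits) == 1L) fits else sample(fits, 1L)
      picked <- c(picked, t)
      words <- c(words, index$content_tokens[[t]])
    }
    if (length(words) == 0L) next

    inject <- runif(1) < error_rate
    typo_word <- NA_character_; typo <- NA_character_; op <- NA_character_
    if (inject) {
      elig <- which(nchar(words) >= min_typo_word_len)
      if (length(elig) == 0L) next   # resample a query with a long-enough word
      wi <- if (length(elig) == 1L) elig else sample(elig, 1L)
      op <- if (length(ops) == 1L) ops else sample(ops, 1L)
      typo <- NA_character_
      src_code <- phonemise(words[wi], index$rules)
      vocab_code_set <- unique(unname(index$vocab_codes))
      for (try in 1:20) {
        cand <- tryCatch(make_typo(words[wi], op, layout = layout,
                                   rules = index$rules),
                         error = function(e) NA_character_)
        if (is.na(cand) || cand %in% index$vocabulary) next
        # reject accidental homophones of a *different* dictionary word:
        # such a string is another term, not a recoverable misspelling
        cand_code <- phonemise(cand, index$rules)
        if (cand_code != src_code && cand_code %in% vocab_code_set) next
        typo <- cand
        break
      }
      if (is.na(typo)) next
      typo_word <- words[wi]
      words_q <- words
      words_q[wi] <- typo
    } else {
      words_q <- words
    }

    # interpose stop words to emulate natural phrasing
    if (length(words_q) > 1L && length(stops_pool) &&
        runif(1) < stopword_rate) {
      j <- sample.int(length(words_q) - 1L, 1L)
      words_q <- append(words_q, sample(stops_pool, 1L), after = j)
    }
    qtext <- paste(words_q, collapse = " ")
    if (qtext %in% queries) next

    expected <- unique(c(
      if (inject) typo_word,
      index$terms$norm[picked]
    ))
    queries <- c(queries, qtext)
    gold_expected[[length(queries)]] <- if (inject) expected else character(0)
    needs <- c(needs, inject)
    meta[[length(queries)]] <- data.frame(
      query = qtext, n_terms = length(picked),
      typo_word = typo_word, typo = typo, op = op,
      stringsAsFactors = FALSE)
  }
  if (length(queries) < n_queries) {
    warning("generated only ", length(queries), " of ", n_queries, " queries")
  }
  list(queries = queries,
       gold = gold_set(queries, gold_expected, needs),
       meta = do.call(rbind, meta))
}

#' Write the generated fixture files
#'
#' Emits the same file formats the other modules consume: a queries file
#' (one per line) and a gold TSV (`query`, pipe-joined `expected`,
#' `needs_correction`).
#'
#' @param gold_run output of [make_gold_set()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_fixtures <- function(gold_run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  qpath <- file.path(dir, "queries.txt")
  gpath <- file.path(dir, "gold.tsv")
  writeLines(gold_run$queries, qpath, useBytes = TRUE)
  g <- gold_run$gold
  df <- data.frame(query = g$query,
                   expected = vapply(g$expected, paste, character(1),
                                     collapse = "|"),
                   needs_correction = as.integer(g$needs_correction),
                   stringsAsFactors = FALSE)
  utils::write.table(df, gpath, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(c(queries = qpath, gold = gpath))
}
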