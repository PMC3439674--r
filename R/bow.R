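# Bag-of-words multi-word matching and the query-correction orchestrator.

# Multiset containment: every element of `small` occurs in `big` at least as
# often.
.bag_subset <- function(small, big) {
  if (length(small) == 0L) return(FALSE)
  if (length(small) > length(big)) return(FALSE)
  ts <- table(small)
  tb <- table(big)
  all(names(ts) %in% names(tb)) && all(ts <= tb[names(ts)])
}

#' Bag-of-words decomposition of a query into dictionary terms
#'
#' Given the query's normalized, stop-word-filtered tokens, repeatedly picks
#' the dictionary term whose phonemised content-word bag is the largest
#' subset of the remaining query-word bag, consumes those words, and stops
#' when no term's bag fits. Ties are broken by the term with the most words,
#' then alphabetically on the normalized term. Words are matched as
#' multisets (duplicates respected) on their phonetic codes, so homophonic
#' misspellings still bag.
#'
#' @param tokens character vector of normalized content words (stop words
#'   already removed), or a single raw query string, which is normalized
#'   with the index's stop-word list first.
#' @param index a `term_index`.
#' @return an object of class `bag_match`: list with `matched_terms`
#'   (character, raw dictionary terms in match order), `matched_norm`,
#'   `matched_idx` (row indices into the index's term table), `consumed`
#'   and `leftover` (character vectors of query tokens; together they
#'   reconstruct the input bag).
#' @examples
#' idx <- load_dictionary()
#' bag_of_words("vaccins de la grippe", idx)
#' @export
bag_of_words <- function(tokens, index) {
  stopifnot(inherits(index, "term_index"))
  if (length(tokens) == 1L && grepl("[^\\p{L}\\p{N}]", tokens, perl = TRUE)) {
    tokens <- normalize_query(tokens, index$stops)
  } else {
    tokens <- as.character(tokens)
  }
  codes <- if (length(tokens)) phonemise(tokens, index$rules) else character(0)
  remaining <- rep(TRUE, length(tokens))
  matched <- integer(0)
  consumed_idx <- integer(0)

  bag_sizes <- lengths(index$content_codes)
  repeat {
    rem_codes <- codes[remaining]
    if (length(rem_codes) == 0L) break
    fits <- which(vapply(index$content_codes, .bag_subset, logical(1),
                         big = rem_codes))
    if (length(fits) == 0L) break
    # largest bag; ties -> most words in the raw term, then alphabetical
    ord <- order(-bag_sizes[fits], -index$terms$word_count[fits],
                 index$terms$norm[fits])
    pick <- fits[ord[1]]
    matched <- c(matched, pick)
    for (code in index$content_codes[[pick]]) {
      j <- which(remaining & codes == code)[1]
      remaining[j] <- FALSE
      consumed_idx <- c(consumed_idx, j)
    }
  }
  structure(
    list(matched_terms = index$terms$raw[matched],
         matched_norm = index$terms$norm[matched],
         matched_idx = matched,
         consumed = tokens[sort(consumed_idx)],
         leftover = tokens[remaining]),
    class = "bag_match"
  )
}

#' @export
print.bag_match <- function(x, ...) {
  cat("bag_match:",
      if (length(x$matched_terms)) paste(x$matched_terms, collapse = "; ")
      else "(no term matched)", "\n")
  if (length(x$leftover)) cat("  leftover:", paste(x$leftover, collapse = " "), "\n")
  invisible(x)
}

# Replace tokens that are not vocabulary words by their alphabetically first
# correction candidate, recording all candidates.
.correct_tokens <- function(tokens, index, theta_lev, theta_sto, params,
                            min_word_len) {
  suggestions <- stats::setNames(vector("list", length(tokens)), tokens)
  corrected <- tokens
  for (i in seq_along(tokens)) {
    w <- tokens[i]
    if (w %in% index$vocabulary) {
      suggestions[[i]] <- character(0)   # exact self-match: nothing to fix
      next
    }
    cand <- words_within(w, index, theta_lev, theta_sto, params, min_word_len)
    suggestions[[i]] <- setdiff(cand, w)
    if (length(suggestions[[i]])) corrected[i] <- suggestions[[i]][1]
  }
  list(corrected = corrected, suggestions = suggestions)
}

#' Correct a query under one of four pipeline modes
#'
#' Orchestrates word-level correction and bag-of-words term matching:
#' \describe{
#'   \item{`ls_only`}{each content word gets its [words_within()] correction
#'     candidates; no term bagging.}
#'   \item{`bow_only`}{bag-of-words matching on the phonemised tokens; no
#'     word correction.}
#'   \item{`ls_then_bow`}{words are corrected first (each non-vocabulary
#'     word replaced by its alphabetically first candidate), then bagged.}
#'   \item{`bow_then_ls`}{tokens are bagged first; leftover words are then
#'     corrected and the corrected leftovers re-bagged (correction can only
#'     enable additional bags).}
#' }
#' Suggestions are always returned alphabetically sorted, never ranked.
#'
#' @param text a single raw query string.
#' @param index a `term_index`.
#' @param mode one of `"bow_then_ls"`, `"ls_only"`, `"bow_only"`,
#'   `"ls_then_bow"`.
#' @param theta_lev,theta_sto acceptance thresholds (defaults 0.2 / 0.7, the
#'   retained combined operating point).
#' @param params a [stoilos_params()] object.
#' @param min_word_len minimum word length for the approximate tier.
#' @param suggestion_cap optional per-word cap on the number of returned
#'   suggestions (`Inf` = unlimited, the default).
#' @return an object of class `query_correction`: list with `query`, `mode`,
#'   `tokens`, `suggestions` (named list per token), `matched_terms`,
#'   `matched_norm`, `leftover` and `proposals` (normalized strings pooled
#'   from word suggestions and matched terms, used by the evaluation
#'   harness).
#' @export
correct_query <- function(text, index,
                          mode = c("bow_then_ls", "ls_only", "bow_only",
                                   "ls_then_bow"),
                          theta_lev = 0.2, theta_sto = 0.7,
                          params = stoilos_params(), min_word_len = 3L,
                          suggestion_cap = Inf) {
  stopifnot_scalar_string(text, "text")
  stopifnot(inherits(index, "term_index"))
  mode <- match.arg(mode)
  tokens <- normalize_query(text, index$stops)
  suggestions <- stats::setNames(vector("list", length(tokens)), tokens)
  for (i in seq_along(suggestions)) suggestions[[i]] <- character(0)
  matched_terms <- character(0)
  matched_norm <- character(0)
  matched_idx <- integer(0)
  leftover <- character(0)

  if (mode == "ls_only") {
    cs <- .correct_tokens(tokens, index, theta_lev, theta_sto, params,
                          min_word_len)
    suggestions <- cs$suggestions
    leftover <- tokens[vapply(seq_along(tokens), function(i) {
      !(tokens[i] %in% index$vocabulary) && length(cs$suggestions[[i]]) == 0L
    }, logical(1))]
  } else if (mode == "bow_only") {
    bm <- bag_of_words(tokens, index)
    matched_terms <- bm$matched_terms
    matched_norm <- bm$matched_norm
    matched_idx <- bm$matched_idx
    leftover <- bm$leftover
  } else if (mode == "ls_then_bow") {
    cs <- .correct_tokens(tokens, index, theta_lev, theta_sto, params,
                          min_word_len)
    suggestions <- cs$suggestions
    bm <- bag_of_words(cs$corrected, index)
    matched_terms <- bm$matched_terms
    matched_norm <- bm$matched_norm
    matched_idx <- bm$matched_idx
    leftover <- bm$leftover
  } else { # bow_then_ls
    bm <- bag_of_words(tokens, index)
    matched_terms <- bm$matched_terms
    matched_norm <- bm$matched_norm
    matched_idx <- bm$matched_idx
    leftover <- bm$leftover
    if (length(leftover)) {
      cs <- .correct_tokens(leftover, index, theta_lev, theta_sto, params,
                            min_word_len)
      for (w in names(cs$suggestions)) suggestions[[w]] <- cs$suggestions[[w]]
      bm2 <- bag_of_words(cs$corrected, index)
      matched_terms <- c(matched_terms, bm2$matched_terms)
      matched_norm <- c(matched_norm, bm2$matched_norm)
      matched_idx <- c(matched_idx, bm2$matched_idx)
      leftover <- bm2$leftover
    }
  }

  if (is.finite(suggestion_cap)) {
    suggestions <- lapply(suggestions, utils::head, n = suggestion_cap)
  }
  # A matched term is a correction proposal only if it was reached through
  # some form of correction, i.e. at least one of its content words is not
  # already a word of the query; recognizing a correctly spelled term is
  # not a correction.
  corrective <- vapply(matched_idx, function(ti) {
    !all(index$content_tokens[[ti]] %in% tokens)
  }, logical(1))
  proposals <- sort(unique(c(unlist(suggestions, use.names = FALSE),
                             matched_norm[corrective])))
  structure(
    list(query = text, mode = mode, tokens = tokens,
         suggestions = suggestions,
         matched_terms = matched_terms, matched_norm = matched_norm,
         leftover = leftover, proposals = proposals),
    class = "query_correction"
  )
}

#' @export
print.query_correction <- function(x, ...) {
  cat(sprintf("query: '%s' [%s]\n", x$query, x$mode))
  if (length(x$matched_terms)) {
    cat("  matched terms:", paste(x$matched_terms, collapse = "; "), "\n")
  }
  has_sugg <- vapply(x$suggestions, length, integer(1)) > 0
  for (w in names(x$suggestions)[has_sugg]) {
    cat(sprintf("  %s -> %s\n", w, paste(x$suggestions[[w]], collapse = " | ")))
  }
  if (length(x$leftover)) {
    cat("  uncorrected:", paste(x$leftover, collapse = " "), "\n")
  }
  invisible(x)
}
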