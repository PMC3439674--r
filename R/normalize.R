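#' Segment a query or term into words
#'
#' Splits on every non-alphanumeric character: the segmentation character set
#' is the complement of Unicode letters and digits, so apostrophes and hyphens
#' also split (e.g. `"Creutzfeldt-Jakob"` becomes two words). Maximal runs of
#' alphanumeric characters are returned in order; empty strings never appear.
#'
#' @param text character vector of raw queries or terms.
#' @return For a single input, a character vector of words; for longer input,
#'   a list of such vectors.
#' @examples
#' segment_query("therapy of the breast cancer")
#' segment_query("Creutzfeldt-Jakob")
#' @export
segment_query <- function(text) {
  if (length(text) == 0L) return(character(0))
  out <- lapply(as.character(text), function(x) {
    if (is.na(x) || !nzchar(x)) return(character(0))
    parts <- strsplit(x, "[^\\p{L}\\p{N}]+", perl = TRUE)[[1]]
    parts[nzchar(parts)]
  })
  if (length(out) == 1L) out[[1]] else out
}

# Accented -> unaccented fold (Latin-1 + the ligatures used in French).
.accent_from <- paste0(
  "àáâãäåçèéêë",
  "ìíîïñòóôõö",
  "ùúûüýÿ",
  "ÀÁÂÃÄÅÇÈÉÊË",
  "ÌÍÎÏÑÒÓÔÕÖ",
  "ÙÚÛÜÝ"
)
.accent_to <- paste0(
  "aaaaaaceeee", "iiiinooooo", "uuuuyy",
  "aaaaaaceeee", "iiiinooooo", "uuuuy"
)

#' Lowercase and deaccent a word
#'
#' Maps every uppercase letter to lowercase and every accented Latin character
#' to its unaccented base letter (e.g. `"éèêë"` to `"e"`,
#' `"ç"` to `"c"`); the ligatures oe/ae are expanded. All other
#' characters pass through unchanged. The function is idempotent, so
#' dictionary terms and queries can be normalized identically.
#'
#' @param word character vector.
#' @return character vector of the same length.
#' @examples
#' normalize_word("A")
#' normalize_word("hèpatite")
#' @export
normalize_word <- function(word) {
  w <- chartr(.accent_from, .accent_to, as.character(word))
  w <- gsub("œ", "oe", w, fixed = TRUE)
  w <- gsub("Œ", "oe", w, fixed = TRUE)
  w <- gsub("æ", "ae", w, fixed = TRUE)
  w <- gsub("Æ", "ae", w, fixed = TRUE)
  tolower(w)
}

#' Remove stop words from a token sequence
#'
#' Order-preserving filter; the result contains exactly the tokens not in the
#' stop-word set. Tokens are assumed already normalized.
#'
#' @param tokens character vector of normalized words.
#' @param stops character vector of normalized stop words (see
#'   [load_stopwords()]).
#' @return character vector.
#' @export
remove_stopwords <- function(tokens, stops) {
  if (length(tokens) == 0L) return(character(0))
  tokens[!(tokens %in% stops)]
}

#' Load a stop-word list
#'
#' Reads a UTF-8 file with one word per line (`#` comments allowed), and
#' normalizes every entry so that all members are normalization fixed points.
#'
#' @param path file path; defaults to the packaged French list (~120 common
#'   function words). The list is configuration, never logic: supply your own
#'   to reproduce a specific deployment.
#' @return sorted character vector of unique normalized stop words.
#' @export
load_stopwords <- function(path = NULL) {
  path <- path %||% ms_extdata("stopwords_fr.txt")
  sort(unique(normalize_word(read_word_list(path))))
}

#' @rdname load_stopwords
#' @export
default_stopwords <- function() load_stopwords()

#' Normalize and segment a query into content tokens
#'
#' Convenience pipeline: segment, lowercase/deaccent, then drop stop words.
#'
#' @param text a single query string.
#' @param stops stop-word vector; `character(0)` keeps everything.
#' @return character vector of normalized content words.
#' @export
normalize_query <- function(text, stops = default_stopwords()) {
  remove_stopwords(normalize_word(segment_query(text)), stops)
}

#' Whole-word match of a query word against a term
#'
#' `TRUE` iff `word` equals one complete token of the term's segmented,
#' normalized form -- never a substring of a token, so `"sida"` does not match
#' `"glucosidases"` while `"accident"` matches `"circulation accident"`.
#'
#' @param word a single normalized word.
#' @param term a term string (raw or normalized).
#' @return logical.
#' @examples
#' exact_expression_match("accident", "circulation accident")
#' exact_expression_match("sida", "glucosidases")
#' @export
exact_expression_match <- function(word, term) {
  stopifnot_scalar_string(word, "word")
  stopifnot_scalar_string(term, "term")
  word %in% normalize_word(segment_query(term))
}
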