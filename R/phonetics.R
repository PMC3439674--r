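# Phonetic encoders: classic Soundex and the French medical Phonemisation
# rule engine. Both map a word to a code such that words pronounced alike
# collide; codes are compared for equality only.

.soundex_digit <- c(
  b = "1", f = "1", p = "1", v = "1",
  c = "2", g = "2", j = "2", k = "2", q = "2", s = "2", x = "2", z = "2",
  d = "3", t = "3",
  l = "4",
  m = "5", n = "5",
  r = "6"
)

#' Soundex phonetic code
#'
#' The classic 1918 name-matching code: a four-character string of the form
#' letter-digit-digit-digit. The first letter of the word is kept
#' (uppercased); each subsequent consonant contributes a digit (b/f/p/v=1,
#' c/g/j/k/q/s/x/z=2, d/t=3, l=4, m/n=5, r=6); vowels, h, w, y and duplicate
#' adjacent letters are ignored; the code is zero-padded to length 4 and
#' truncated beyond it.
#'
#' @param word character vector; each element must begin with a letter.
#' @return character vector of 4-character codes.
#' @examples
#' soundex("Robert")  # R163
#' soundex("Robin")   # R150
#' soundex("Smith")   # S530
#' @export
soundex <- function(word) {
  vapply(as.character(word), function(w) {
    if (is.na(w) || !nzchar(w)) stop("soundex: empty input")
    wl <- tolower(normalize_word(w))
    chars <- strsplit(wl, "", fixed = TRUE)[[1]]
    chars <- chars[chars %in% letters]
    if (length(chars) == 0L || !grepl("^[a-z]", wl)) {
      stop("soundex: input must start with a letter: ", w)
    }
    # duplicate adjacent letters are ignored
    keep <- c(TRUE, chars[-1] != chars[-length(chars)])
    chars <- chars[keep]
    first <- toupper(chars[1])
    rest <- chars[-1]
    digits <- unname(.soundex_digit[rest])
    digits <- digits[!is.na(digits)]
    # collapse adjacent identical digits
    if (length(digits) > 1L) {
      digits <- digits[c(TRUE, digits[-1] != digits[-length(digits)])]
    }
    code <- paste0(first, paste(digits, collapse = ""))
    code <- paste0(code, strrep("0", max(0L, 4L - nchar(code))))
    substr(code, 1L, 4L)
  }, character(1), USE.NAMES = FALSE)
}

# --- Phonemisation engine ----------------------------------------------------

# Context test for the `context` tier: `set` is "" (unconstrained),
# "!xyz" (char must not be in the set; word boundary passes) or
# "xyz" (char must be in the set; word boundary fails).
.ctx_ok <- function(char, set) {
  if (!nzchar(set)) return(TRUE)
  negated <- startsWith(set, "!")
  members <- strsplit(sub("^!", "", set), "", fixed = TRUE)[[1]]
  if (is.na(char)) return(negated)   # word boundary
  if (negated) !(char %in% members) else (char %in% members)
}

# Single left-to-right scan applying context-sensitive rules. The preceding
# context is read from the output built so far (so a nasal code digit blocks
# a following nasal rule, as the rule tables require); the following context
# is read from the untransformed remainder.
.apply_context_tier <- function(word, rules) {
  if (nrow(rules) == 0L) return(word)
  ord <- order(-nchar(rules$pattern), seq_len(nrow(rules)))
  rules <- rules[ord, , drop = FALSE]
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    applied <- FALSE
    for (r in seq_len(nrow(rules))) {
      pat <- rules$pattern[r]
      plen <- nchar(pat)
      if (i + plen - 1L > n) next
      if (substr(word, i, i + plen - 1L) != pat) next
      prev <- if (length(out)) substr(out[length(out)],
                                      nchar(out[length(out)]),
                                      nchar(out[length(out)])) else NA_character_
      nxt <- if (i + plen <= n) chars[i + plen] else NA_character_
      if (.ctx_ok(prev, rules$before[r]) && .ctx_ok(nxt, rules$after[r])) {
        out <- c(out, rules$replacement[r])
        i <- i + plen
        applied <- TRUE
        break
      }
    }
    if (!applied) {
      out <- c(out, chars[i])
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

.apply_end_rule <- function(word, pattern, replacement, before, minlen) {
  if (!endsWith(word, pattern)) return(word)
  if (minlen > 0 && nchar(word) < minlen) return(word)
  stem <- substr(word, 1L, nchar(word) - nchar(pattern))
  prev <- if (nzchar(stem)) substr(stem, nchar(stem), nchar(stem)) else NA_character_
  if (!.ctx_ok(prev, before)) return(word)
  res <- paste0(stem, replacement)
  if (nchar(res) < 2L) word else res
}

.collapse_doubles <- function(word) gsub("([a-z])\\1+", "\\1", word, perl = TRUE)

.phonemise_one <- function(word, rules, include_low_confidence) {
  w <- word
  if (nchar(w) < 2L) return(w)
  pick <- function(df) {
    if (include_low_confidence) df else df[df$confidence != "low", , drop = FALSE]
  }
  # silent er/ed endings pronounced as a closed e (code 8)
  if (w %in% rules$silent_endings) {
    w <- sub("(er|ed)$", "8", w)
  }
  # pre tier: orthographic rewrites before duplicate collapsing
  pre <- pick(rules$pre)
  for (r in seq_len(nrow(pre))) {
    pat <- pre$pattern[r]
    if (pat == "ill" && any(startsWith(w, rules$ill_exceptions))) next
    if (pre$position[r] == "end") {
      w <- .apply_end_rule(w, pat, pre$replacement[r], pre$before[r],
                           pre$minlen[r])
    } else {
      w <- gsub(pat, pre$replacement[r], w, fixed = TRUE)
    }
  }
  w <- .collapse_doubles(w)
  w <- .apply_context_tier(w, pick(rules$context))
  sub_rules <- pick(rules$subst)
  for (r in seq_len(nrow(sub_rules))) {
    w <- gsub(sub_rules$pattern[r], sub_rules$replacement[r], w, fixed = TRUE)
  }
  fin <- pick(rules$final)
  for (r in seq_len(nrow(fin))) {
    w <- .apply_end_rule(w, fin$pattern[r], fin$replacement[r],
                         fin$before[r], fin$minlen[r])
  }
  w <- .collapse_doubles(w)
  w
}

#' French medical phonetic transcription
#'
#' Encodes a normalized word as a phonetic code so that a misspelled word
#' with the right sound collides with the intended term: nasal vowels map to
#' the digit codes 4/1/0 only when the following letter does not neutralize
#' them, consonant combinations are rewritten (`ch -> 5`, `gn -> 7`,
#' `qu/c -> k`, `tion -> sion`, ...), vowel digraphs take vowel-sound codes
#' (`oi -> 2`, `ou -> 3`, `ai -> 8`), silent letters (h, many word-final
#' letters) are removed, and duplicate letters are collapsed. The output
#' alphabet is lowercase a-z plus the digits 0-8; the function is
#' deterministic and idempotent in the sense that equal inputs always give
#' equal codes.
#'
#' Words shorter than 2 characters are returned unchanged. Inputs are
#' expected to be normalized (lowercase, deaccented); see [normalize_word()].
#'
#' @param word character vector of normalized words.
#' @param rules a `phoneme_rules` object; see [load_phoneme_rules()].
#' @param include_low_confidence apply also the rules flagged `low`
#'   (best-effort transcriptions of damaged source material). Default FALSE.
#' @return character vector of phonetic codes.
#' @examples
#' phonemise("insomnia")        # "1somnia"
#' phonemise("cholesterol")     # "kolesterol"
#' phonemise("kollesterraulle") # "kolesterol"
#' phonemise("acupuncture")     # "akup1ktur"
#' @export
phonemise <- function(word, rules = default_phoneme_rules(),
                      include_low_confidence = FALSE) {
  if (length(word) == 0L) return(character(0))
  word <- as.character(word)
  if (any(is.na(word) | !nzchar(word))) stop("phonemise: empty input")
  vapply(word, .phonemise_one, character(1),
         rules = rules, include_low_confidence = include_low_confidence,
         USE.NAMES = FALSE)
}

#' Compare the sound of two strings
#'
#' `TRUE` iff both words have the same phonetic code under [phonemise()].
#'
#' @param a,b normalized words (single strings).
#' @inheritParams phonemise
#' @return logical.
#' @examples
#' same_sound("kollesterraulle", "cholesterol")  # TRUE
#' same_sound("alzaymer", "alzheimer")           # TRUE
#' @export
same_sound <- function(a, b, rules = default_phoneme_rules()) {
  identical(phonemise(a, rules), phonemise(b, rules))
}
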