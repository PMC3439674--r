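# Loading and validation of the phoneme rule set.
#
# The rule engine is data-driven so it can be audited and replaced: every
# rewrite lives in a TSV file, with a confidence flag separating well-attested
# rules from best-effort transcriptions of damaged sources.

#' Load a phoneme rule set
#'
#' Reads a TSV rule file with columns `tier`, `pattern`, `before`, `after`,
#' `position`, `replacement`, `minlen`, `confidence` and returns a
#' `phoneme_rules` object consumed by [phonemise()].
#'
#' Tiers, applied in this order by the engine:
#' \describe{
#'   \item{`pre`}{orthographic pre-pass (e.g. `y -> i`, silent word endings
#'     such as `ac -> a`); applied before duplicate-letter collapsing.}
#'   \item{`context`}{context-sensitive combinations, chiefly the nasal
#'     vowels (`an`, `en`, `in`, `un`, `oin`, ... to codes 4/1/0) and the
#'     `ge`/`gu` softenings. `before`/`after` hold the context sets: a bare
#'     set (`"ao234"`) means the neighbouring character must be in the set, a
#'     `!`-prefixed set means it must NOT be; empty means unconstrained.
#'     Word boundaries satisfy `!`-sets and fail bare sets.}
#'   \item{`subst`}{ordered global substitutions (`ch -> 5`, `gn -> 7`,
#'     `qu/c/q -> k`, `tion -> sion`, `oi -> 2`, `ou -> 3`, silent `h`
#'     deletion, ...).}
#'   \item{`final`}{word-final silences (final `s`, `e`; final `g` after a
#'     nasal code digit).}
#' }
#'
#' Rules with `confidence = "low"` transcribe typographically damaged source
#' material; they are kept for audit but skipped unless
#' `include_low_confidence = TRUE` in [phonemise()].
#'
#' @param path rule TSV; defaults to the packaged rule set.
#' @param silent_endings path to the lexicon of words ending in "er"/"ed"
#'   pronounced as a closed "e"; one word per line.
#' @param ill_exceptions path to the list of word stems in which "ill" is
#'   pronounced as a plain l.
#' @return an object of class `phoneme_rules`.
#' @export
load_phoneme_rules <- function(path = NULL,
                               silent_endings = NULL,
                               ill_exceptions = NULL) {
  path <- path %||% ms_extdata("phoneme_rules.tsv")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                          fileEncoding = "UTF-8")
  needed <- c("tier", "pattern", "before", "after", "position",
              "replacement", "minlen", "confidence")
  if (!all(needed %in% names(df))) {
    stop("rule file must have columns: ", paste(needed, collapse = ", "))
  }
  for (col in c("pattern", "before", "after", "position", "replacement",
                "confidence")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "", as.character(df[[col]]))
  }
  if (any(!nzchar(df$pattern))) stop("rule patterns must be non-empty")
  if (!all(df$tier %in% c("pre", "context", "subst", "final"))) {
    stop("unknown rule tier")
  }
  endings <- normalize_word(read_word_list(
    silent_endings %||% ms_extdata("silent_er_ed.txt")))
  bad <- endings[!grepl("(er|ed)$", endings)]
  if (length(bad)) stop("silent-ending lexicon entries must end in er/ed: ",
                        paste(bad, collapse = ", "))
  structure(
    list(
      pre = df[df$tier == "pre", , drop = FALSE],
      context = df[df$tier == "context", , drop = FALSE],
      subst = df[df$tier == "subst", , drop = FALSE],
      final = df[df$tier == "final", , drop = FALSE],
      silent_endings = endings,
      ill_exceptions = normalize_word(read_word_list(
        ill_exceptions %||% ms_extdata("ill_exceptions.txt")))
    ),
    class = "phoneme_rules"
  )
}

.rules_cache <- new.env(parent = emptyenv())

#' @rdname load_phoneme_rules
#' @export
default_phoneme_rules <- function() {
  if (is.null(.rules_cache$default)) {
    .rules_cache$default <- load_phoneme_rules()
  }
  .rules_cache$default
}

#' @export
print.phoneme_rules <- function(x, ...) {
  cat("phoneme rule set:",
      nrow(x$pre), "pre,",
      nrow(x$context), "context,",
      nrow(x$subst), "substitution,",
      nrow(x$final), "final rules;",
      sum(c(x$pre$confidence, x$context$confidence, x$subst$confidence,
            x$final$confidence) == "low"), "low-confidence\n")
  cat("silent er/ed lexicon:", length(x$silent_endings), "words;",
      "ill exceptions:", length(x$ill_exceptions), "stems\n")
  invisible(x)
}
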