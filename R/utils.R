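# Internal helpers shared across modules.

# Round half away from zero, the convention used for reported scores
# (base round() is half-to-even).
round_half_up <- function(x, digits = 0) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Path to a packaged data file under inst/extdata.
ms_extdata <- function(file) {
  path <- system.file("extdata", file, package = "medspell")
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}

# Read a UTF-8 word list, one entry per line, '#' comments and blanks skipped.
read_word_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

stopifnot_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string")
  }
}
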