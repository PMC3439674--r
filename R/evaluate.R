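# Evaluation harness: precision / recall / F-measure with Wald confidence
# intervals, gold-standard scoring of a correction run, and threshold-sweep
# suggestion-count matrices.

.check_count <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != round(x)) {
    stop(what, " must be a single non-negative integer")
  }
}

#' Precision of a correction run
#'
#' Proportion of queries properly corrected among those corrected. When no
#' query was corrected the value is 1 by convention, with attribute
#' `degenerate = TRUE`.
#'
#' @param correctly_corrected,corrected counts, with
#'   `corrected >= correctly_corrected >= 0`.
#' @return fraction in `[0, 1]`.
#' @export
precision <- function(correctly_corrected, corrected) {
  .check_count(correctly_corrected, "correctly_corrected")
  .check_count(corrected, "corrected")
  if (correctly_corrected > corrected) {
    stop("correctly_corrected cannot exceed corrected")
  }
  if (corrected == 0) return(structure(1, degenerate = TRUE))
  correctly_corrected / corrected
}

#' Recall of a correction run
#'
#' Proportion of queries properly corrected among those requiring
#' correction.
#'
#' @param correctly_corrected,to_be_corrected counts.
#' @return fraction in `[0, 1]`.
#' @export
recall <- function(correctly_corrected, to_be_corrected) {
  .check_count(correctly_corrected, "correctly_corrected")
  .check_count(to_be_corrected, "to_be_corrected")
  if (to_be_corrected == 0) return(structure(1, degenerate = TRUE))
  correctly_corrected / to_be_corrected
}

#' F-measure (harmonic mean of precision and recall)
#'
#' @param p,r fractions in `[0, 1]`. Returns 0 when both are 0.
#' @return fraction in `[0, 1]`.
#' @export
f_measure <- function(p, r) {
  stopifnot(is.numeric(p), is.numeric(r), p >= 0, p <= 1, r >= 0, r <= 1)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Wald 95% confidence interval for a proportion
#'
#' `x +/- 1.96 * sqrt(x (1 - x) / n)`, clipped to `[0, 1]`.
#'
#' @param x observed proportion in `[0, 1]`.
#' @param n sample size, `>= 1`.
#' @return numeric vector `c(lo, hi)`.
#' @export
confidence_interval <- function(x, n) {
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x <= 1)
  .check_count(n, "n")
  if (n == 0) stop("n must be >= 1")
  half <- 1.96 * sqrt(x * (1 - x) / n)
  c(max(0, x - half), min(1, x + half))
}

#' Read a gold-standard correction file
#'
#' TSV with columns `query`, `expected` (pipe-separated normalized
#' corrections, may be empty when no correction is needed) and
#' `needs_correction` (0/1).
#'
#' @param path file path.
#' @return data.frame with `query` (character), `expected` (list column of
#'   character vectors) and `needs_correction` (logical).
#' @export
load_gold <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                          fileEncoding = "UTF-8")
  if (!all(c("query", "expected", "needs_correction") %in% names(df))) {
    stop("gold file needs columns query, expected, needs_correction")
  }
  gold_set(df$query,
           strsplit(as.character(df$expected), "|", fixed = TRUE),
           as.logical(as.integer(df$needs_correction)))
}

#' Construct a gold set
#'
#' @param query character vector of unique queries.
#' @param expected list of character vectors of acceptable normalized
#'   corrections; must be non-empty wherever `needs_correction` is TRUE.
#' @param needs_correction logical vector.
#' @return data.frame of class `gold_set`.
#' @export
gold_set <- function(query, expected, needs_correction) {
  query <- as.character(query)
  if (anyDuplicated(query)) stop("gold queries must be unique")
  expected <- lapply(expected, function(e) e[nzchar(e)])
  if (any(needs_correction & lengths(expected) == 0L)) {
    stop("expected corrections must be non-empty when needs_correction")
  }
  out <- data.frame(query = query, needs_correction = needs_correction,
                    stringsAsFactors = FALSE)
  out$expected <- expected
  class(out) <- c("gold_set", "data.frame")
  out
}

#' Score a correction run against a gold set
#'
#' A query counts as corrected when it received at least one proposal
#' different from the query itself, and as correctly corrected when any
#' proposal is among the gold expected corrections. Proposals and gold
#' entries are compared as normalized strings.
#'
#' @param results named list mapping each query to its character vector of
#'   proposals (e.g. the `proposals` field of [correct_query()] output), or
#'   a list of `query_correction` objects.
#' @param gold a [gold_set()].
#' @return an object of class `eval_metrics`: precision, recall, f_measure,
#'   95% CIs, and the underlying counts.
#' @export
evaluate_run <- function(results, gold) {
  stopifnot(inherits(gold, "gold_set"))
  if (length(results) && inherits(results[[1]], "query_correction")) {
    results <- stats::setNames(lapply(results, `[[`, "proposals"),
                               vapply(results, `[[`, character(1), "query"))
  }
  missing <- setdiff(gold$query, names(results))
  if (length(missing)) {
    stop("results missing for queries: ", paste(missing, collapse = ", "))
  }
  n <- nrow(gold)
  corrected <- logical(n)
  correct <- logical(n)
  for (i in seq_len(n)) {
    q <- gold$query[i]
    props <- unique(results[[q]])
    qnorm <- paste(normalize_word(segment_query(q)), collapse = " ")
    props <- props[props != q & props != qnorm]
    corrected[i] <- length(props) > 0L
    correct[i] <- corrected[i] && any(props %in% gold$expected[[i]])
  }
  n_corrected <- sum(corrected)
  n_correct <- sum(correct)
  n_to_be <- sum(gold$needs_correction)
  p <- precision(n_correct, n_corrected)
  r <- recall(n_correct, n_to_be)
  structure(
    list(precision = as.numeric(p), recall = as.numeric(r),
         f_measure = f_measure(as.numeric(p), as.numeric(r)),
         ci_precision = if (n_corrected > 0)
           confidence_interval(as.numeric(p), n_corrected) else c(NA_real_, NA_real_),
         ci_recall = if (n_to_be > 0)
           confidence_interval(as.numeric(r), n_to_be) else c(NA_real_, NA_real_),
         n_corrected = n_corrected,
         n_correctly_corrected = n_correct,
         n_to_be_corrected = n_to_be,
         n_queries = n,
         degenerate_precision = isTRUE(attr(p, "degenerate"))),
    class = "eval_metrics"
  )
}

#' @export
print.eval_metrics <- function(x, ...) {
  pct <- function(v) sprintf("%.2f", round_half_up(100 * v, 2))
  ci <- function(v) if (anyNA(v)) "[-]" else
    sprintf("[%s-%s]", pct(v[1]), pct(v[2]))
  cat(sprintf("precision %s%% %s  recall %s%% %s  F %s%%\n",
              pct(x$precision), ci(x$ci_precision),
              pct(x$recall), ci(x$ci_recall), pct(x$f_measure)))
  cat(sprintf("  corrected %d (correct %d) / to be corrected %d / queries %d\n",
              x$n_corrected, x$n_correctly_corrected, x$n_to_be_corrected,
              x$n_queries))
  invisible(x)
}

#' Threshold-sweep suggestion counts
#'
#' For every pair of thresholds, counts the correction suggestions the
#' combined comparator test would propose over a query set: each query word
#' that is not itself a vocabulary word (exact self-matches are excluded)
#' contributes every vocabulary word accepted at those thresholds. Totals
#' are non-decreasing in `theta_lev` and non-increasing in `theta_sto` by
#' set containment.
#'
#' @param queries character vector of raw queries.
#' @param index a `term_index`.
#' @param theta_lev_grid,theta_sto_grid numeric vectors of thresholds; a
#'   `theta_sto` of -1 disables the Stoilos test for that row.
#' @param params a [stoilos_params()] object.
#' @param min_word_len minimum word length for the comparator (shorter words
#'   are skipped).
#' @return data.frame with one row per threshold pair: `theta_lev`,
#'   `theta_sto`, `total_suggestions`, `suggestions_per_query`,
#'   `answered_queries`.
#' @export
threshold_sweep <- function(queries, index,
                            theta_lev_grid, theta_sto_grid,
                            params = stoilos_params(), min_word_len = 3L) {
  stopifnot(inherits(index, "term_index"))
  if (length(theta_lev_grid) == 0L || length(theta_sto_grid) == 0L) {
    stop("threshold grids must be non-empty")
  }
  vocab <- index$vocabulary
  # score every (non-vocabulary query word, vocabulary word) pair once
  word_scores <- list()
  query_words <- vector("list", length(queries))
  for (qi in seq_along(queries)) {
    toks <- normalize_query(queries[qi], index$stops)
    toks <- toks[nchar(toks) >= min_word_len & !(toks %in% vocab)]
    query_words[[qi]] <- toks
    for (w in unique(toks)) {
      if (!is.null(word_scores[[w]])) next
      ln <- lev_dist_vec_cpp(w, vocab) / pmax(nchar(w), nchar(vocab))
      sims <- vapply(vocab, function(v) stoilos_sim(w, v, params)$sim,
                     numeric(1), USE.NAMES = FALSE)
      word_scores[[w]] <- list(ln = ln, sim = sims)
    }
  }
  grid <- expand.grid(theta_lev = theta_lev_grid, theta_sto = theta_sto_grid,
                      KEEP.OUT.ATTRS = FALSE)
  nq <- max(1L, length(queries))
  res <- lapply(seq_len(nrow(grid)), function(g) {
    tl <- grid$theta_lev[g]; ts <- grid$theta_sto[g]
    per_query <- vapply(query_words, function(toks) {
      if (length(toks) == 0L) return(0L)
      sum(vapply(toks, function(w) {
        sc <- word_scores[[w]]
        ok <- sc$ln < tl
        if (ts > -1) ok <- ok & (sc$sim > ts)
        sum(ok)
      }, integer(1)))
    }, integer(1))
    data.frame(theta_lev = tl, theta_sto = ts,
               total_suggestions = sum(per_query),
               suggestions_per_query = sum(per_query) / nq,
               answered_queries = sum(per_query > 0L))
  })
  do.call(rbind, res)
}
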