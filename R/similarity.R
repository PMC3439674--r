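# The two approximate string comparators and their combination.
#
# All scorers are pure and case-sensitive: callers are expected to normalize
# (lowercase, deaccent) both strings first, which keeps the math independent
# of any locale handling.

#' Parameters of the Stoilos similarity
#'
#' @param p steepness of the difference function, dimensionless, in
#'   `[0, Inf)`; default 0.6, the value of the worked reference computation.
#' @param winkler_P common-prefix scaling constant; Winkler's standard value
#'   is 0.1 and values above 0.25 are rejected.
#' @param winkler_Lmax maximum common-prefix length counted; standard 4.
#' @return an object of class `stoilos_params`.
#' @export
stoilos_params <- function(p = 0.6, winkler_P = 0.1, winkler_Lmax = 4L) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0) {
    stop("p must be a single number >= 0")
  }
  if (!is.numeric(winkler_P) || winkler_P < 0 || winkler_P > 0.25) {
    stop("winkler_P must be in [0, 0.25]")
  }
  if (!is.numeric(winkler_Lmax) || winkler_Lmax < 0) {
    stop("winkler_Lmax must be >= 0")
  }
  structure(list(p = p, winkler_P = winkler_P,
                 winkler_Lmax = as.integer(winkler_Lmax)),
            class = "stoilos_params")
}

#' Levenshtein edit distance
#'
#' Minimum number of single-character replacements, deletions and additions
#' transforming one string into the other (unit costs, no transposition
#' operation, so swapping two adjacent letters costs 2).
#'
#' @param a,b single strings.
#' @return non-negative integer.
#' @examples
#' levenshtein("eutanasia", "euthanasia")  # 1
#' @export
levenshtein <- function(a, b) {
  stopifnot_scalar_string(a, "a")
  stopifnot_scalar_string(b, "b")
  lev_dist_cpp(a, b)
}

#' Normalized Levenshtein distance
#'
#' Edit distance divided by the length of the longer string; in `[0, 1]`,
#' and 0 iff the strings are equal.
#'
#' @param a,b single strings, not both empty.
#' @return numeric in `[0, 1]`.
#' @examples
#' lev_norm("eutanasia", "euthanasia")  # 0.1
#' @export
lev_norm <- function(a, b) {
  stopifnot_scalar_string(a, "a")
  stopifnot_scalar_string(b, "b")
  m <- max(nchar(a), nchar(b))
  if (m == 0L) stop("lev_norm undefined for two empty strings")
  lev_dist_cpp(a, b) / m
}

#' Commonality by iterative longest-common-substring removal
#'
#' Finds the longest common contiguous substring of the two strings, removes
#' it from both (concatenating the remainders), and repeats until no common
#' substring of at least `min_piece` characters remains. Ties are broken by
#' the leftmost occurrence in the lexicographically earlier string, which
#' makes the result symmetric in its arguments. Returns the commonality
#' `2 * sum(piece lengths) / (|a| + |b|)` together with the trace.
#'
#' `min_piece` defaults to 2: single shared characters do not count as
#' commonality (this is what the reference worked computation implies, e.g.
#' Comm(Trigonocepahlie, Trigonocephalie) = 0.866 with unmatched remainders
#' "ah"/"ha"). Identical strings have commonality 1 by definition.
#'
#' @param a,b single strings, not both empty.
#' @param min_piece minimum common-substring length counted (default 2).
#' @return list with elements `comm` (numeric), `pieces` (character vector of
#'   removed substrings, in removal order), `u1`, `u2` (unmatched lengths
#'   scaled by each string's own length), `rest1`, `rest2` (the unmatched
#'   remainders).
#' @examples
#' commonality("Trigonocepahlie", "Trigonocephalie")$comm  # 0.8667
#' @export
commonality <- function(a, b, min_piece = 2L) {
  stopifnot_scalar_string(a, "a")
  stopifnot_scalar_string(b, "b")
  la <- nchar(a); lb <- nchar(b)
  if (la + lb == 0L) stop("commonality undefined for two empty strings")
  if (identical(a, b)) {
    return(list(comm = 1, pieces = a, u1 = 0, u2 = 0, rest1 = "", rest2 = ""))
  }
  # The greedy removal's tie-break depends on argument order; computing on
  # the lexicographically ordered pair makes commonality symmetric.
  if (identical(sort(c(a, b), method = "radix")[1], b)) {
    tr <- commonality(b, a, min_piece = min_piece)
    return(list(comm = tr$comm, pieces = tr$pieces,
                u1 = tr$u2, u2 = tr$u1, rest1 = tr$rest2, rest2 = tr$rest1))
  }
  ra <- a; rb <- b
  pieces <- character(0)
  repeat {
    if (!nzchar(ra) || !nzchar(rb)) break
    m <- lcs_longest_cpp(ra, rb)
    if (m[3] < min_piece) break
    pieces <- c(pieces, substr(ra, m[1], m[1] + m[3] - 1L))
    ra <- paste0(substr(ra, 1L, m[1] - 1L), substr(ra, m[1] + m[3], nchar(ra)))
    rb <- paste0(substr(rb, 1L, m[2] - 1L), substr(rb, m[2] + m[3], nchar(rb)))
  }
  matched <- sum(nchar(pieces))
  list(comm = 2 * matched / (la + lb),
       pieces = pieces,
       u1 = nchar(ra) / la,
       u2 = nchar(rb) / lb,
       rest1 = ra, rest2 = rb)
}

#' Stoilos difference term
#'
#' Based on the lengths of the unmatched substrings left by the commonality
#' matching, each scaled by its own string's length:
#' `Diff = u1*u2 / (p + (1-p) * (u1 + u2 - u1*u2))`. Zero whenever either
#' string is fully matched; in `[0, 1]`.
#'
#' @param a,b single strings, or NULL when `comm_trace` is supplied.
#' @param params a [stoilos_params()] object.
#' @param comm_trace optional precomputed result of [commonality()].
#' @return numeric in `[0, 1]`.
#' @export
stoilos_difference <- function(a = NULL, b = NULL, params = stoilos_params(),
                               comm_trace = NULL) {
  if (is.null(comm_trace)) comm_trace <- commonality(a, b)
  u1 <- comm_trace$u1; u2 <- comm_trace$u2
  prod_u <- u1 * u2
  if (prod_u == 0) return(0)
  p <- params$p
  prod_u / (p + (1 - p) * (u1 + u2 - prod_u))
}

# Length of the common prefix of two strings.
common_prefix_length <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ca <- strsplit(substr(a, 1, n), "", fixed = TRUE)[[1]]
  cb <- strsplit(substr(b, 1, n), "", fixed = TRUE)[[1]]
  diff <- which(ca != cb)
  if (length(diff) == 0L) n else diff[1] - 1L
}

#' Winkler common-prefix term
#'
#' `L * P * (1 - Comm)` where `L` is the length of the common prefix capped
#' at `winkler_Lmax` (standard 4) and `P` the scaling constant (standard
#' 0.1).
#'
#' @param a,b single strings.
#' @param comm the commonality of the pair; computed if missing.
#' @param params a [stoilos_params()] object.
#' @return non-negative numeric.
#' @export
winkler_term <- function(a, b, comm = NULL, params = stoilos_params()) {
  if (is.null(comm)) comm <- commonality(a, b)$comm
  L <- min(common_prefix_length(a, b), params$winkler_Lmax)
  L * params$winkler_P * (1 - comm)
}

#' Stoilos (ISub) similarity with full breakdown
#'
#' `Sim = Comm - Diff + Winkler`: commonality from iterative
#' longest-common-substring removal, difference from the unmatched-length
#' fractions with steepness `p`, plus the Winkler common-prefix bonus.
#' Values lie in `[-1, 1]`; identical strings score 1.
#'
#' @param a,b single strings, not both empty.
#' @param params a [stoilos_params()] object.
#' @return an object of class `similarity_breakdown`: list with `sim`, `lev`,
#'   `lev_norm`, `comm`, `diff`, `winkler`, `u1`, `u2`, `common_substrings`.
#' @examples
#' stoilos_sim("hyperaldoterisme", "hyperaldosteronisme")$sim  # 0.9486
#' @export
stoilos_sim <- function(a, b, params = stoilos_params()) {
  tr <- commonality(a, b)
  d <- stoilos_difference(params = params, comm_trace = tr)
  w <- winkler_term(a, b, comm = tr$comm, params = params)
  structure(
    list(a = a, b = b,
         lev = lev_dist_cpp(a, b),
         lev_norm = lev_dist_cpp(a, b) / max(nchar(a), nchar(b)),
         comm = tr$comm, diff = d, winkler = w,
         sim = tr$comm - d + w,
         u1 = tr$u1, u2 = tr$u2,
         common_substrings = tr$pieces),
    class = "similarity_breakdown"
  )
}

#' @export
print.similarity_breakdown <- function(x, ...) {
  cat(sprintf("'%s' vs '%s'\n", x$a, x$b))
  cat(sprintf("  Lev = %d  LevNorm = %.3f\n", x$lev, x$lev_norm))
  cat(sprintf("  Comm = %.3f  {%s}\n", x$comm,
              paste(x$common_substrings, collapse = ", ")))
  cat(sprintf("  Diff = %.4f (u1 = %.3f, u2 = %.3f)  Winkler = %.3f\n",
              x$diff, x$u1, x$u2, x$winkler))
  cat(sprintf("  Sim = %.3f\n", x$sim))
  invisible(x)
}

#' Combined threshold acceptance
#'
#' A candidate is accepted iff `lev_norm(a, b) < theta_lev` AND
#' `stoilos_sim(a, b) > theta_sto` (strict comparisons). Either test can be
#' disabled: `theta_lev = Inf` disables the Levenshtein test,
#' `theta_sto = -1` (or lower) the Stoilos test. The retained operating
#' point for combined correction is `theta_lev = 0.2`, `theta_sto = 0.7`.
#'
#' @param a,b single strings.
#' @param theta_lev normalized-Levenshtein threshold (accept below).
#' @param theta_sto Stoilos threshold (accept above).
#' @param params a [stoilos_params()] object.
#' @return logical.
#' @export
accepts <- function(a, b, theta_lev = 0.2, theta_sto = 0.7,
                    params = stoilos_params()) {
  if (!is.infinite(theta_lev) && (theta_lev < 0 || theta_lev > 1)) {
    stop("theta_lev must be in [0, 1] or Inf")
  }
  if (theta_sto > 1) stop("theta_sto must be <= 1")
  if (!is.infinite(theta_lev)) {
    if (!(lev_norm(a, b) < theta_lev)) return(FALSE)
  }
  if (theta_sto > -1) {
    if (!(stoilos_sim(a, b, params)$sim > theta_sto)) return(FALSE)
  }
  TRUE
}
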