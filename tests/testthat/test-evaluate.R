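test_that("precision, recall and F-measure follow their definitions", {
  expect_equal(precision(9, 10), 0.9)
  p0 <- precision(0, 0)
  expect_equal(as.numeric(p0), 1)
  expect_true(isTRUE(attr(p0, "degenerate")))
  expect_error(precision(5, 4), "exceed")
  expect_equal(recall(134, 163), 134 / 163)
  expect_equal(recall(0, 5), 0)
  expect_equal(recall(5, 5), 1)
  expect_equal(round_half_up(100 * f_measure(0.9503, 0.8220), 2), 88.15)
  expect_equal(f_measure(0.37, 0.37), 0.37)
  expect_equal(round_half_up(f_measure(1, 0.5), 4), 0.6667)
  expect_equal(f_measure(0, 0), 0)
})

test_that("a printed precision/recall row is internally consistent", {
  # 141 answered queries at precision 95.03% implies 134 correct;
  # 134 correct of 163 to-be-corrected gives the printed recall 82.20%
  correct <- round(141 * 0.9503)
  expect_identical(correct, 134)
  # agreement at the printed 2-decimal precision (134/163 = 82.2086...%)
  expect_lt(abs(100 * recall(correct, 163) - 82.20), 0.011)
})

test_that("Wald confidence intervals are computed and clipped", {
  expect_equal(confidence_interval(0.5, 100), c(0.402, 0.598))
  expect_equal(confidence_interval(0, 50), c(0, 0))
  expect_equal(confidence_interval(1, 50), c(1, 1))
  expect_error(confidence_interval(0.5, 0), "n must")
  # width shrinks with n and peaks at x = 0.5
  w <- function(x, n) diff(confidence_interval(x, n))
  expect_lt(w(0.5, 400), w(0.5, 100))
  expect_lt(w(0.9, 100), w(0.5, 100))
})

test_that("evaluate_run scores runs against a gold set", {
  gold <- gold_set(paste0("q", 1:10),
                   replicate(10, "fix", simplify = FALSE),
                   rep(TRUE, 10))
  perfect <- stats::setNames(replicate(10, "fix", simplify = FALSE),
                             gold$query)
  m <- evaluate_run(perfect, gold)
  expect_equal(c(m$precision, m$recall, m$f_measure), c(1, 1, 1))

  silent <- stats::setNames(replicate(10, character(0), simplify = FALSE),
                            gold$query)
  m2 <- evaluate_run(silent, gold)
  expect_equal(m2$n_corrected, 0L)
  expect_equal(m2$recall, 0)

  expect_error(evaluate_run(perfect[1:3], gold), "missing")
})

test_that("evaluate_run reproduces a hand-computed mixed run", {
  # 10 queries to correct; 8 receive proposals, 7 of them correct
  gold <- gold_set(paste0("q", 1:10),
                   lapply(1:10, function(i) paste0("w", i)),
                   rep(TRUE, 10))
  res <- lapply(1:10, function(i) {
    if (i <= 7) paste0("w", i)            # correct proposal
    else if (i == 8) "wrong"              # corrected, wrongly
    else character(0)                     # no proposal
  })
  names(res) <- gold$query
  m <- evaluate_run(res, gold)
  expect_equal(m$precision, 7 / 8)
  expect_equal(m$recall, 0.7)
  expect_equal(round_half_up(m$f_measure, 4), 0.7778)
  expect_equal(m$ci_recall,
               c(0.7 - 1.96 * sqrt(0.21 / 10), 0.7 + 1.96 * sqrt(0.21 / 10)))
})

test_that("proposals equal to the query itself do not count as corrections", {
  gold <- gold_set("asthme", list(character(0)), FALSE)
  m <- evaluate_run(list(asthme = "asthme"), gold)
  expect_equal(m$n_corrected, 0L)
})

test_that("threshold sweep counts match brute-force pair enumeration", {
  idx <- toy_index()
  queries <- c("astma", "hepatitte", "colesterol", "asthme", "zz")
  lev_grid <- c(0.2, 0.35)
  sto_grid <- c(-1, 0.7)
  sw <- threshold_sweep(queries, idx, lev_grid, sto_grid)
  vocab <- vocabulary(idx)
  stops <- idx$stops
  for (r in seq_len(nrow(sw))) {
    total <- 0L
    answered <- 0L
    for (q in queries) {
      toks <- normalize_query(q, stops)
      toks <- toks[nchar(toks) >= 3 & !(toks %in% vocab)]
      nq <- 0L
      for (w in toks) {
        for (v in vocab) {
          if (accepts(w, v, sw$theta_lev[r], sw$theta_sto[r])) nq <- nq + 1L
        }
      }
      total <- total + nq
      if (nq > 0) answered <- answered + 1L
    }
    expect_identical(sw$total_suggestions[r], total)
    expect_identical(sw$answered_queries[r], answered)
    expect_equal(sw$suggestions_per_query[r], total / length(queries))
  }
})

test_that("sweep totals are monotone in both thresholds", {
  idx <- toy_index()
  queries <- c("astma", "hepatitte", "colesterol", "akupunktur")
  sw <- threshold_sweep(queries, idx, c(0.1, 0.2, 0.3, 0.5),
                        c(0.3, 0.5, 0.7, 0.9))
  for (ts in unique(sw$theta_sto)) {
    sub <- sw[sw$theta_sto == ts, ]
    sub <- sub[order(sub$theta_lev), ]
    expect_true(all(diff(sub$total_suggestions) >= 0))
  }
  for (tl in unique(sw$theta_lev)) {
    sub <- sw[sw$theta_lev == tl, ]
    sub <- sub[order(sub$theta_sto), ]
    expect_true(all(diff(sub$total_suggestions) <= 0))
  }
})

test_that("gold files round-trip through load_gold", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("query\texpected\tneeds_correction",
               "astma\tasthme|asthme du nourrisson\t1",
               "asthme\t\t0"), f)
  g <- load_gold(f)
  expect_identical(g$query, c("astma", "asthme"))
  expect_identical(g$expected[[1]], c("asthme", "asthme du nourrisson"))
  expect_identical(g$needs_correction, c(TRUE, FALSE))
  expect_error(gold_set(c("a", "a"), list("x", "y"), c(TRUE, TRUE)), "unique")
})
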