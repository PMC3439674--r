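test_that("bag-of-words consumes the largest matchable term bags", {
  idx <- toy_index(c("therapeutique", "tumeurs du sein"),
                   stops = c("du", "de", "la"))
  bm <- bag_of_words(c("therapeutique", "tumeurs", "sein"), idx)
  expect_setequal(bm$matched_terms, c("therapeutique", "tumeurs du sein"))
  expect_identical(bm$leftover, character(0))
})

test_that("a one-word dictionary query matches itself with empty leftover", {
  idx <- toy_index()
  bm <- bag_of_words("asthme", idx)
  expect_identical(bm$matched_terms, "asthme")
  expect_identical(bm$leftover, character(0))
})

test_that("queries with no vocabulary words leave everything unmatched", {
  idx <- toy_index()
  bm <- bag_of_words(c("zzz", "qqq"), idx)
  expect_identical(bm$matched_terms, character(0))
  expect_setequal(bm$leftover, c("zzz", "qqq"))
})

test_that("bag matching works on phonetic codes, so homophones still bag", {
  idx <- toy_index("cholesterol")
  bm <- bag_of_words("kollesterraulle", idx)
  expect_identical(bm$matched_terms, "cholesterol")
})

test_that("consumed and leftover always reconstruct the input bag", {
  idx <- pkg_index()
  queries <- list(
    c("grippe", "vaccins"),
    c("asthme", "zzz", "asthme"),
    c("tumeurs", "sein", "poumon"),
    character(0),
    c("hepatite", "b")
  )
  for (q in queries) {
    bm <- bag_of_words(q, idx)
    expect_identical(sort(c(bm$consumed, bm$leftover)), sort(q))
  }
})

test_that("bagging terminates within one iteration per token", {
  idx <- pkg_index()
  q <- rep(c("grippe", "asthme"), 5)
  bm <- bag_of_words(q, idx)
  expect_lte(length(bm$matched_terms), length(q))
  expect_identical(bm$leftover, character(0))
})

test_that("correct_query orchestrates the four modes", {
  idx <- pkg_index()
  # homophonic misspelling resolved through the phonetic tier, then bagged
  r <- correct_query("kollesterraulle", idx, mode = "bow_then_ls")
  expect_identical(r$matched_norm, "cholesterol")
  # a verbatim dictionary term needs no suggestions in any mode
  for (m in c("bow_then_ls", "ls_only", "bow_only", "ls_then_bow")) {
    r2 <- correct_query("acupuncture", idx, mode = m)
    expect_identical(unlist(r2$suggestions, use.names = FALSE) %||% character(0),
                     character(0))
    expect_identical(r2$leftover, character(0))
  }
  expect_error(correct_query("x", idx, mode = "nope"))
})

test_that("word correction before bagging enables multi-word term matches", {
  idx <- toy_index("asthme du nourrisson", stops = "du")
  r <- correct_query("astma du nourrisson", idx, mode = "bow_then_ls",
                     theta_lev = 0.35, theta_sto = -1)
  expect_identical(r$matched_norm, "asthme du nourrisson")
  expect_true("asthme" %in% r$suggestions[["astma"]])
  # derived check: single-word oracle distance below threshold
  expect_lt(lev_oracle("astma", "asthme") / 6, 0.35)
})

test_that("bow_then_ls never matches fewer terms than bow_only", {
  idx <- pkg_index()
  queries <- c("gripe du nourrisson", "vaccins de la gripe",
               "asthme", "tumeur du sein", "kancer du poumon",
               "hepatitte b", "zzz qqq")
  for (q in queries) {
    n_bow <- length(correct_query(q, idx, mode = "bow_only")$matched_terms)
    n_both <- length(correct_query(q, idx, mode = "bow_then_ls")$matched_terms)
    expect_gte(n_both, n_bow, label = q)
  }
})

test_that("ls_only and bow_then_ls differ on a multi-word misspelled query", {
  idx <- pkg_index()
  q <- "vaccins de la gripe"
  ls <- correct_query(q, idx, mode = "ls_only")
  bow <- correct_query(q, idx, mode = "bow_then_ls")
  expect_identical(ls$matched_terms, character(0))
  expect_true(length(bow$matched_terms) >= 1)
  expect_true("grippe" %in% unlist(ls$suggestions))
})

test_that("suggestions are alphabetically sorted and cappable", {
  idx <- pkg_index()
  r <- correct_query("diabte", idx, mode = "ls_only", theta_lev = 0.4,
                     theta_sto = -1)
  s <- r$suggestions[["diabte"]]
  expect_sorted(s)
  r2 <- correct_query("diabte", idx, mode = "ls_only", theta_lev = 0.4,
                      theta_sto = -1, suggestion_cap = 1)
  expect_lte(length(r2$suggestions[["diabte"]]), 1L)
})
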