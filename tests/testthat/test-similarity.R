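test_that("edit distance matches the documented single-insertion example", {
  expect_identical(levenshtein("eutanasia", "euthanasia"), 1L)
  expect_identical(levenshtein("abc", "abc"), 0L)
  # adjacent transposition costs 2 under the three-operation model
  expect_identical(levenshtein("ashtma", "asthma"), 2L)
  expect_identical(levenshtein("ashtma", "asthma"), lev_oracle("ashtma", "asthma"))
})

test_that("edit distance equals the brute-force recursive oracle exhaustively", {
  strs <- enumerate_strings(c("a", "b"), 3)
  for (a in strs) {
    for (b in strs) {
      expect_identical(levenshtein(a, b), lev_oracle(a, b),
                       info = paste0("'", a, "' vs '", b, "'"))
    }
  }
})

test_that("normalized edit distance divides by the longer string", {
  expect_equal(lev_norm("eutanasia", "euthanasia"), 0.1)
  expect_equal(lev_norm("x", "x"), 0)
  expect_equal(lev_norm("", "abcd"), 1)
  expect_error(lev_norm("", ""), "empty")
})

test_that("commonality reproduces the documented substring traces", {
  tr <- commonality("Trigonocepahlie", "Trigonocephalie")
  expect_identical(tr$pieces, c("Trigonocep", "lie"))
  expect_equal(tr$comm, 2 * 13 / 30)
  expect_equal(c(tr$u1, tr$u2), c(2 / 15, 2 / 15))

  tr2 <- commonality("hyperaldoterisme", "hyperaldosteronisme")
  expect_setequal(tr2$pieces, c("hyperaldo", "ter", "isme"))
  expect_equal(tr2$comm, 2 * 16 / 35)
  expect_equal(tr2$u1, 0)

  expect_equal(commonality("abc", "xyz")$comm, 0)
  expect_equal(commonality("x", "x")$comm, 1)
})

test_that("commonality bookkeeping is internally consistent", {
  pairs <- list(c("amidale", "amygdale"), c("grippe", "gripe"),
                c("hepatite", "hepatite a"), c("abcd", "cdab"),
                c("suette", "suette miliaire"))
  for (pr in pairs) {
    tr <- commonality(pr[1], pr[2])
    matched <- sum(nchar(tr$pieces))
    expect_equal(tr$comm, 2 * matched / (nchar(pr[1]) + nchar(pr[2])))
    expect_equal(tr$u1, nchar(tr$rest1) / nchar(pr[1]))
    expect_equal(tr$u2, nchar(tr$rest2) / nchar(pr[2]))
  }
})

test_that("difference term reproduces the documented values at p = 0.6", {
  tr <- commonality("Trigonocepahlie", "Trigonocephalie")
  expect_equal(round_half_up(stoilos_difference(comm_trace = tr), 4), 0.0254)
  expect_equal(stoilos_difference("hyperaldoterisme", "hyperaldosteronisme"), 0)
  expect_equal(stoilos_difference("abc", "abc"), 0)
  expect_error(stoilos_params(p = -1), "p must")
})

test_that("winkler term uses the 4-character prefix cap", {
  comm <- commonality("hyperaldoterisme", "hyperaldosteronisme")$comm
  expect_equal(round_half_up(
    winkler_term("hyperaldoterisme", "hyperaldosteronisme", comm), 3), 0.034)
  expect_equal(winkler_term("abc", "abc", comm = 1), 0)
  expect_equal(winkler_term("abc", "xbc", comm = 0.5), 0)  # no shared prefix
})

test_that("full similarity composes Comm - Diff + Winkler", {
  br <- stoilos_sim("hyperaldoterisme", "hyperaldosteronisme")
  expect_equal(round_half_up(br$sim, 2), 0.95)
  expect_equal(br$sim, br$comm - br$diff + br$winkler)
  expect_equal(stoilos_sim("abc", "abc")$sim, 1)
  # composed from the two documented components and the uncapped prefix
  br2 <- stoilos_sim("Trigonocepahlie", "Trigonocephalie")
  expect_equal(br2$sim, br2$comm - br2$diff + 4 * 0.1 * (1 - br2$comm))
})

test_that("comparator scores are symmetric and in range", {
  set.seed(42)
  alph <- letters[1:6]
  for (i in 1:40) {
    a <- paste(sample(alph, sample(2:9, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alph, sample(2:9, 1), replace = TRUE), collapse = "")
    expect_equal(lev_norm(a, b), lev_norm(b, a))
    expect_gte(lev_norm(a, b), 0); expect_lte(lev_norm(a, b), 1)
    ca <- commonality(a, b); cb <- commonality(b, a)
    expect_equal(ca$comm, cb$comm)
    expect_equal(stoilos_difference(comm_trace = ca),
                 stoilos_difference(comm_trace = cb))
    s <- stoilos_sim(a, b)$sim
    expect_equal(s, stoilos_sim(b, a)$sim)
    expect_gte(s, -1); expect_lte(s, 1)
    expect_gte(ca$comm, 0); expect_lte(ca$comm, 1)
  }
})

test_that("any single edit keeps normalized distance within 1/n", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(2:12, 1)
    w <- paste(sample(letters[1:8], n, replace = TRUE), collapse = "")
    op <- sample(c("insertion", "deletion", "substitution"), 1)
    w2 <- make_typo(w, op)
    expect_lte(lev_norm(w, w2), 1 / n, label = paste(w, "->", w2))
    expect_lt(stoilos_sim(w, w2)$sim, 1)
  }
})

test_that("combined acceptance applies strict thresholds and disabling", {
  expect_true(accepts("eutanasia", "euthanasia", theta_lev = 0.2,
                      theta_sto = -1))
  expect_true(accepts("abc", "abc", theta_lev = 0.2, theta_sto = 0.7))
  expect_false(accepts("abc", "xyz", theta_lev = 0.2, theta_sto = 0.7))
  # strictness: LevNorm exactly at the threshold is rejected
  expect_false(accepts("abcde", "abcdx", theta_lev = 0.2, theta_sto = -1))
  # disabling the Levenshtein test
  expect_true(accepts("suette", "suette miliaire", theta_lev = Inf,
                      theta_sto = 0.7))
})
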