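---
title: "Correcting misspelled health-search queries: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting misspelled health-search queries: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medspell)
```

## The problem

Health information seekers query medical search tools with vocabulary they
do not master: terms are misspelled, accents are wrong or missing, and
multi-word queries mix controlled-vocabulary terms with everyday phrasing.
A query that matches no dictionary term returns nothing. medspell implements
a correction pipeline for French medical queries that combines three
complementary mechanisms, each catching an error class the others miss:

1. **Normalization** — segmentation on every non-alphanumeric character,
   lowercasing, deaccenting, stop-word removal. Catches trivial variation
   (case, accents, punctuation).
2. **Phonetic transcription** — a French medical phonetic encoder
   ("phonemisation") under which homophonic misspellings collide with the
   intended term (`kollesterraulle` and `cholestérol` both encode to
   `kolesterol`). Catches *cognitive* errors, where the user knows the sound
   but not the spelling.
3. **Approximate string comparison** — the normalized Levenshtein distance
   combined with the Stoilos (ISub) label similarity under a pair of
   thresholds. Catches *typographic* errors (the four Damerau single-edit
   operations), which alter the sound.

Multi-word queries are additionally decomposed by a bag-of-words matcher
into word multisets corresponding to dictionary terms.

## The comparators

For strings $S_1, S_2$, the normalized Levenshtein distance is

$$\mathrm{LevNorm}(S_1,S_2) = \frac{\mathrm{Lev}(S_1,S_2)}{\max(|S_1|,|S_2|)} \in [0,1],$$

with $\mathrm{Lev}$ the unit-cost edit distance over replace/delete/add (no
transposition operation: swapping two adjacent letters costs 2).

The Stoilos similarity, developed for ontology concept labels, is

$$\mathrm{Sim}(S_1,S_2) = \mathrm{Comm}(S_1,S_2) - \mathrm{Diff}(S_1,S_2) + \mathrm{Winkler}(S_1,S_2) \in [-1, 1].$$

*Commonality* removes the longest common contiguous substring from both
strings, repeats until none of length $\ge 2$ remains, and sets
$\mathrm{Comm} = 2\sum_i |\mathrm{MaxComSubString}_i| / (|S_1|+|S_2|)$.
*Difference* uses the unmatched lengths scaled by each string's own length,
$u_1, u_2$:

$$\mathrm{Diff} = \frac{u_1 u_2}{p + (1-p)\,(u_1 + u_2 - u_1 u_2)},$$

with steepness $p \ge 0$ (default 0.6, the value of the reference worked
computation; the reference text's rendering of this denominator is
typographically ambiguous, and this reading is adopted because it reproduces
the printed value 0.0254 exactly). *Winkler* is the common-prefix bonus
$L \cdot P \cdot (1-\mathrm{Comm})$ with $L$ the shared prefix length capped
at 4 and $P = 0.1$.

```{r}
print(stoilos_sim("hyperaldoterisme", "hyperaldosteronisme"))
```

Two numerical choices deserve a note.

* **Minimum piece length 2.** Counting single shared characters as
  commonality would drive $\mathrm{Comm}$ of any two strings over a common
  alphabet toward 1 (and makes the reference value 0.866 for the
  Trigonocepahlie/Trigonocephalie pair unreachable — the leftover "ah"/"ha"
  would be fully consumed). Identical strings are special-cased to
  $\mathrm{Comm}=1$.
* **Symmetry.** The greedy removal needs a tie-break among equally long
  common substrings. "Leftmost in the first argument" makes the score depend
  on argument order on adversarial inputs, so the computation runs on the
  lexicographically ordered pair (tie-break: leftmost in the
  lexicographically earlier string); commonality is then symmetric by
  construction. Note that $\mathrm{Sim}=1$ does not strictly imply equality:
  block permutations such as `abcd`/`cdab` reach $\mathrm{Comm}=1$; this is
  inherent to the substring-removal design and harmless at correction
  thresholds.

A candidate correction is **accepted** when
$\mathrm{LevNorm} < \theta_{lev}$ *and* $\mathrm{Sim} > \theta_{sto}$, both
strict. The default operating point is $\theta_{lev} = 0.2$,
$\theta_{sto} = 0.7$, the retained combination for manageable suggestion
counts; either test can be disabled ($\theta_{lev}=\infty$,
$\theta_{sto}=-1$). Strictness matters at the boundary: a deletion on a
5-letter word gives exactly $1/5 = 0.2$ and is rejected at
$\theta_{lev}=0.2$.

## Phonetic transcription

Classic Soundex (letter + three digits, vowels/h/w/y and duplicates
ignored) is included as the reference encoder for name matching, but it is
too coarse for French medical vocabulary. The phonemisation engine instead
applies ordered rule tiers, each tier's rules stored in a versioned TSV
(`inst/extdata/phoneme_rules.tsv`) so the rule base is auditable and
replaceable without touching code:

1. **Pre-pass** — orthographic rewrites that must see the raw spelling:
   `y -> i`, `ill -> 6` (with a lexical exception list: *ville*, *mille*,
   ...), silent word endings (`-ac -> -a`, `-irop(s) -> -iro`,
   `-omac -> -oma`), and the lexicon of words whose final *-er*/*-ed* is
   pronounced as a closed *e* (code 8).
2. **Duplicate collapse** — doubled letters are pronounced once.
3. **Context tier** — nasal vowels (`an/en/am/em -> 4`, `in/im/ain/ein/un
   -> 1`, `oin -> 0`) fire only when the following letter does not
   neutralize the nasal (a following vowel, n or m keeps the plain vowel:
   *insomnia* encodes `1somnia` but *inosine* is unchanged), plus the
   `ge`/`gu` softenings, which conversely fire only before the letters that
   trigger them. The rule file encodes both polarities (`!`-prefixed =
   forbidden set, bare = required set).
4. **Substitution tier** — ordered global rewrites: `sch/ch/sh -> 5` then
   `5o/5l/5r/5t -> ko/kl/kr/kt` (so *cholesterol* ends up `kolesterol`),
   `ph -> f`, `qu/c/q -> k`, `gn -> 7`, `tion -> sion`, vowel digraphs
   `oi -> 2`, `ou -> 3`, `ai/ei -> 8`, `au/eau -> o`, silent `h` deletion.
5. **Final-silence tier** — final `s`, final `e`, final `g` after a nasal
   code digit (*sang* -> `s4`).

The engine's conformance is defined by a curated example table
(`inst/extdata/homophones.tsv`): pairs that must collide
(*alzaymer*/*alzheimer*, *kancer*/*cancer*, ...) and pairs that must not
(*androstènes*/*androstenols*, the confusion that motivated moving beyond
Phonex-style numeric codes). A handful of source rules whose published
transcription is typographically damaged ship with `confidence = low` and
are skipped by default; they are retained in the file for audit and can be
enabled with `include_low_confidence = TRUE`.

Rules not present in the published tables but required by the published
example transcriptions were added deliberately: `au/eau -> o` (needed for
*kollesterraulle*), `ph -> f` and `y -> i` (needed for
*alzaymer*/*amygdale* and standard French phonology).

## Dictionary lookup and bag-of-words matching

`term_index()` normalizes and phonemises every dictionary term once and
builds four maps: word -> terms, phonetic code -> words, sorted phonemised
content-word bag -> terms, and the vocabulary of distinct words.
`words_within()` then resolves a query word through three tiers — exact,
phonetic, approximate — short-circuiting by default (a word that *is* a
dictionary word needs no correction; a homophone of a dictionary word is
that word). `tiers = "union"` pools all three for analyses that need the
full candidate set. Words shorter than 3 characters skip the approximate
tier: at length 2 a single edit already means half the word, and French
medical acronyms at length 3 remain correctable.

The bag-of-words matcher works on phonemised codes (so homophonic
misspellings still bag), consumes terms greedily — largest content bag
first, ties to the term with more words, then alphabetical — and stops when
no term bag fits the remaining words. Greedy (not exact set cover) is
deliberate: it is deterministic, linear in the query length, and the
iterative formulation matches how the matching is meant to behave.

`correct_query()` composes the pieces in four modes: `ls_only`, `bow_only`,
`ls_then_bow`, and the default `bow_then_ls`, which bags first, corrects
only the leftover words, and **re-bags the corrected leftovers** — without
the re-bagging step, word correction could never enable additional term
matches and the mode ordering could not matter.

## Evaluation harness

Precision is the fraction of corrected queries corrected properly, recall
the fraction of queries *requiring* correction that were corrected
properly, F their harmonic mean, each with a Wald 95% interval
$x \pm 1.96\sqrt{x(1-x)/n}$ clipped to $[0,1]$. A query counts as corrected
when it received at least one proposal different from itself (exact
self-matches are not corrections), and as properly corrected when a
proposal is in the gold set. `threshold_sweep()` reproduces the
suggestion-count matrices used for threshold choice; totals are monotone —
non-decreasing in $\theta_{lev}$, non-increasing in $\theta_{sto}$ — by set
containment, which the tests verify against brute-force pair enumeration.

Reported percentages are rounded half away from zero to 2 decimals.
Degenerate cases are conventions, flagged in the return value: precision is
1 when nothing was corrected, F is 0 when both components are 0.

## Synthetic data: what it emulates, what it does not

Real no-answer query logs and the licensed French MeSH dictionary are not
redistributable, so the package ships a ~240-term fixture dictionary built
around the documented example terms, and `make_gold_set()` generates
misspelled queries with a controlled error structure:

* **Word-count mix** 17/26/23/34% for 1/2/3/4+ content words — the observed
  structure of no-answer health queries; stop words are interposed with
  probability 0.25 to emulate natural phrasing.
* **Error operations**: the four Damerau single edits (insertion, deletion,
  substitution — optionally AZERTY-adjacent, since French keyboards drive
  typographic errors — and transposition), plus `phonetic_swap`, which
  substitutes a homophone grapheme (validated against the encoder, with
  letter doubling always available) to emulate cognitive errors.
* **Recoverability contract**: a candidate typo is rejected and resampled
  if it collides with a vocabulary word (a real no-answer query is by
  definition not in the dictionary) or if its phonetic code equals a
  *different* word's code (an accidental homophone of another term is that
  term, not a misspelling of the source). One error per query, exactly.
* **Minimum typo-word length 6**: with strict thresholds, a single edit on
  a word of length $n$ gives $\mathrm{LevNorm} \le 1/n$ (insertions:
  $1/(n{+}1)$), and $1/6 < 0.2$ holds strictly while a deletion at $n = 5$
  gives exactly 0.2 and is rejected. Length 6 is the shortest length at
  which single-edit recovery at the default threshold is provable.

Under these conditions two recovery guarantees hold and are asserted as
tests: single insertion/deletion/substitution errors are always recovered
by the comparator tier at $\theta_{lev} = 0.2$, and phonetic swaps are
always recovered by the phonetic tier alone.

What the generator does **not** model: word frequencies (no Zipf fit),
multiple errors per word, errors in stop words, real spelling-error
distributions conditioned on character context. Passing the synthetic
recovery tests therefore demonstrates correctness of the machinery under
the stated error model, not field performance on real logs — the harness
reproduces the evaluation *protocol* (the four-mode comparison with
P/R/F and CIs), whose dataset-dependent values are out of scope.

## Problem sizes and determinism

All shipped analyses are desk-scale by design: the fixture dictionary has
~240 terms (~290 distinct words), synthetic gold sets of 100–200 queries,
exhaustive comparator cross-checks over all string pairs up to length 6 on
a 3-letter alphabet, and sweep grids of a dozen cells. Everything
stochastic flows from a single integer seed; identical invocations of any
command produce byte-identical outputs.

## Known limitations

* The phonemisation rule base is constrained only by the published tables
  and examples; the full original rule set is not public. Coverage of rare
  French graphemes (`eu`, `ien`, soft `c` before e/i) is intentionally
  conservative — both dictionary and query pass through the same encoder,
  so internal consistency, not phonological completeness, is what the
  matching needs.
* Suggestion lists are alphabetical, never ranked; frequency- or
  probability-based ranking is out of scope.
* `Sim = 1` does not imply string equality (block permutations).
* The evaluation replaces human judgment with a gold file: results are
  reproducible in protocol, not comparable number-for-number with
  manually judged runs.
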