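---
title: "Scoring letter-fluency strategies: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring letter-fluency strategies: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(letterfluency)
```

This vignette documents the scientific model behind the package, the
conventions and tunable parameters, what the synthetic-data generator does
and does not emulate, and the choices made where the design was genuinely
open. It states no empirical result that the test suite or the acceptance
script does not itself compute.

## 1. The task and the unit of analysis

A letter-fluency trial asks a participant to produce, within a fixed time
(default 60 s), as many words as possible beginning with a target letter
(default *f*). The unit of analysis is the **ordered** token sequence of
one participant (`fluency_session`). Order is the whole point: both
strategy indices are functions of adjacency.

Three per-token annotations are derived, not supplied:

* `norm` — Unicode lowercase, leading/trailing punctuation stripped,
  internal hyphens/apostrophes kept (so *fire-fly* stays one item).
* `is_repetition` — the normalised form already occurred anywhere earlier
  in the session (not only immediately before); this is the standard
  fluency-scoring convention, and adjacency-only repetition would be a
  strictly weaker rule.
* `is_error` — the normalised form does not begin with the target letter.
  Clinical protocols sometimes add proper-noun or morphological-variant
  rules, but those cannot be decided from a transcript alone and are not
  part of the scoring tradition this package implements; the grapheme test
  is the only objective rule available, and it is what we pin down.

Errors and repetitions stay in the sequence for cluster/switch scoring
(they reveal the retrieval process) but are excluded from the number of
correct words (NoCW).

## 2. Phonological strategy: clusters and switches

Two consecutive words are *phonologically related* when any of four rules
holds on their ARPABET pronunciations (stress digits ignored throughout —
the relations are segmental):

| rule | definition | example |
|---|---|---|
| `first_two_phonemes` | first two phones equal | find–fire |
| `rhyme` | identical phones from the last stressed vowel to the end | fry–fly |
| `vowel_swap` | same phone count, exactly one differing position, both phones there vowels | flip–flop |
| `homonym` | identical phone sequence, different spelling | fair–fare |

Decisions a reader should know about:

* **Chaining, not common-feature clustering.** A cluster is a maximal run
  in which every *adjacent* pair is related. The scoring tradition's
  prose ("successively generated words") admits both readings; chaining
  is the standard operationalisation, is order-local, and is exactly
  testable against a brute-force oracle (the suite checks 100% agreement
  on 1,000 random sequences). Clusters therefore partition the sequence;
  overlapping-cluster variants are deliberately out of scope.
* **Singletons are clusters.** Cluster size is words − 1 (singleton 0,
  pair 1); MCS divides total size by the number of clusters *including*
  singletons. Only with singleton denominators can cohort MCS values fall
  in the sub-1 range typical of letter-fluency cohorts.
* **NoS** = number of clusters − 1 (transitions), 0 for empty input.
* **Tag precedence** (homonym > first_two_phonemes > rhyme > vowel_swap)
  affects only the reported audit tag; membership uses any-rule truth, so
  precedence can never change MCS or NoS.
* **Rhyme anchor.** The rhyme tail starts at the last vowel carrying
  primary or secondary stress; when no stress is marked, the last vowel.
* **Repeated identical words** are related via `first_two_phonemes` (and
  are repetitions, not homonyms — homonymy requires distinct spellings).
* **Out-of-lexicon words** (neologisms, transcription fragments — which
  the scoring rule explicitly keeps in clusters) degrade to a grapheme
  comparison: the first two *letters* of both words stand in for the
  first two phonemes; rhyme/vowel-swap/homonymy are unavailable without
  phones. The fallback is on by default (`fallback = TRUE`) because real
  transcripts contain unlexicalised items; turn it off to reproduce a
  strictly phonemic protocol.

## 3. Semantic strategy: turning angles and persistence length

Each word maps to an embedding vector; for consecutive in-vocabulary
words the turning angle is `acos` of their cosine similarity (cosine
clipped to [−1, 1] first), in degrees in [0, 180]. Out-of-vocabulary
words are dropped and logged — a zero-vector substitute would make the
cosine undefined. Repetitions are kept: a repeated word contributes a 0°
angle, which is the correct semantics of "maximally related".

The ordered angles are read as the bending angles of a discrete chain of
unit segments. For such a chain the worm-like-chain law gives
`E[cos θ(s)] = exp(-s / Lp)` with lag `s` in segments and persistence
length `Lp`. Two estimators are provided:

* `adjacent_cosine` (default): `Lp = -1 / log(cbar)`, `cbar` the mean
  adjacent cosine. Degenerate cases are pinned: `cbar <= 0` gives
  `Lp = 0` (no directional persistence at all), `cbar = 1` is flagged
  infinite (a perfectly straight chain).
* `lag_decay_fit`: the lag-`s` correlation is estimated as the mean over
  windows of the *product* of the window's adjacent cosines — for
  independent symmetric bending this equals the signed-heading
  correlation in expectation while staying deterministic given the angle
  magnitudes — and `log C(s)` is regressed through the origin on
  `s = 1..min(5, n-1)`; non-positive `C(s)` lags are dropped.

**No factor-of-two correction.** For thermally fluctuating 2-D polymers
the convention is `exp(-s/(2 Lp))`; here the angles are *data*, not
equipartitioned fluctuations, so the law is applied directly. Users who
want the polymer convention can halve the reported `Lp`; SR is unaffected
because it is defined from the mean cosine.

**The SR index.** The field reports a bounded index rather than a raw
length, but no closed formula is fixed by tradition; this package defines
`SR = max(0, cbar)`, which equals `exp(-1 / Lp)` under the default
estimator. It is bounded in [0, 1], dimensionless, strictly increasing in
`Lp`, and exactly `cos(θ)` for constant-angle sequences — all properties
the test suite locks. The raw `Lp` is reported alongside so any other
normalisation can be substituted.

**Minimum length.** Sessions with fewer than four in-vocabulary words
return `insufficient_data`: one or two angles cannot support a curvature
estimate, and the cohort exclusion rule (below) removes such participants
before statistics.

**Sign rule.** Cosines determine only angle magnitudes. The 2-D chain
diagram (`build_chain`, `plot`) needs signs: all-positive by default,
with alternating or seeded-random options for wandering plots. SR and Lp
never depend on the sign rule — only plots do.

## 4. Cohort statistics

* **Exclusions** (`apply_exclusions`): first the word-count rule
  (< 4 total productions), then, on the retained set, the outlier screen:
  value > mean + 3 SD, one-sided above the mean, on MCS and SR by default
  (the measures the screen is traditionally applied to; configurable,
  with a `two_sided` switch). The order matters — outlier statistics are
  computed on the word-count-filtered set — and matches how such screens
  are reported. Records with a missing screened measure are excluded as
  `unusable_record`.
* **Descriptives**: mean, sample SD (n − 1), range per measure; a
  single-row cohort reports SD 0 rather than NA so downstream tables stay
  numeric.
* **Pearson matrix**: pairwise-complete r, two-sided p from the
  t-transform with n − 2 df, stars at .05/.01/.001, no multiple-testing
  correction (none is conventional for these tables). Zero-variance
  columns yield NA.
* **Stepwise regression** (`stepwise_regression`): forward selection with
  backward elimination on partial-F p-values, pinned to the conventional
  entry 0.05 / removal 0.10 defaults (both exposed). For single-term
  steps the partial F is the squared t, so t p-values are used. Perfectly
  collinear candidates are aliased by `lm` and treated as never eligible.
  Tolerance is `1 − R²` of a retained predictor on the other retained
  predictors; VIF is its exact reciprocal. An empty final model is a
  reported outcome (R² = 0), not an error; at least 10 complete rows are
  required.

## 5. The synthetic world

`simulate_cohort()` generates a cohort whose every estimand has recorded
truth. What it emulates, and how the defaults were fixed once:

* **Lexicon** (`make_synthetic_lexicon`): ≥ 20 target-letter words built
  from a small ARPABET inventory, with at least three planted pairs per
  relation, each verified with `pair_relation` before the lexicon is
  returned. Six intruder ("error") words use vowels outside the
  target-word inventory, so they can never rhyme, vowel-swap or share
  first phonemes with a target word — an injected error always breaks a
  cluster, by construction.
* **Embeddings**: unit vectors on a great circle of the unit sphere in
  `embedding_dim` dimensions (default 50, a typical small embedding
  size), at seeded evenly spaced circle positions. A circle makes every
  consecutive cosine controllable by one scalar (the angular step) at the
  cost of genuinely low-dimensional geometry — see the honesty note
  below.
* **Angles** (`simulate_wlc_angles`): wrapped-Gaussian heading increments
  with variance `2 / Lp`, giving `E[cos] = exp(-1/Lp)` *exactly* (the
  wrapped-normal characteristic function), folded to magnitudes.
* **Walks** (`simulate_participant`): with probability `cluster_prob` the
  next word is a planted phonological relative of the current word;
  otherwise a semantic step rotates the circle position by a
  wrapped-Gaussian increment and snaps to the nearest word that is *not*
  related to the current one. That exclusion makes the planted cluster
  spans unambiguous: the suite checks that `find_clusters` recovers them
  exactly, including under error/repetition injection (repetitions
  duplicate the previous token and extend its span; errors insert an
  intruder and split a span — the recorded truth tracks both).
* **Scales**: cohort size 47, sequence lengths 1 + Poisson (truncated at
  20) with rates placing most lengths in the 4–15 band, error and
  repetition rates 5% each, true `Lp` in [1, 4.5] — the range whose
  `exp(-1/Lp)` image is SR ≈ 0.37–0.80, matching the scale on which
  letter-fluency SR values are reported. Demographics are drawn at
  realistic Alzheimer's-cohort scales (age ≈ N(72, 8.6) clipped, education
  ≈ N(11.8, 2.7), MMSE centred near 19).
* **The `"phonological"` preset** couples everything through one latent
  ability `a ~ U(0,1)`: length rate `3 + 9a`, clustering probability
  `0.1 + 0.35a`, true `Lp` declining across `lp_range` in `a` (Gaussian
  noise, SD 0.3), MMSE rising weakly in `a`. The slope 0.35 keeps switch
  counts dominated by sequence length, so the preset yields the empirical
  sign pattern — productive participants switch more (r(NoCW, NoS) > 0)
  and are less semantically persistent (r(NoCW, SR) < 0) — as a
  consequence of the generative design, not of per-seed tuning; the
  acceptance suite checks the signs end-to-end through the pipeline at a
  fixed seed.

**What a green test does not establish.** The generator's embeddings are
a 2-D circle: real embedding spaces are high-dimensional, anisotropic and
frequency-biased, and real cosine distributions are not wrapped-Gaussian.
The synthetic lexicon has clean, planted phonology: real transcripts
contain morphological families, proper nouns and dialectal
pronunciations. Green recovery tests therefore validate the *estimators
and scorers against their stated models*, not the clinical
generalisability of any particular cohort value; cohort-level numbers
from the restricted clinical corpus are intentionally out of scope.

## 6. Numerical and degenerate-input conventions

* Cosines are clipped to [−1, 1] before `acos`; angles are validated into
  [0, 180].
* `mean_cluster_size` of an empty span list is NA (missing), not 0; empty
  sequences give empty span lists and NoS 0.
* `Lp`: `cbar <= 0` → 0; `cbar >= 1` → `Inf` flag; fewer than 3 angles →
  `insufficient_data`.
* Lexicon/embedding parsing: malformed lexicon lines warn and skip, an
  empty lexicon errors; inconsistent embedding dimensions error; zero
  vectors and duplicate words are skipped/deduplicated with warnings.
* The pipeline treats per-participant failures as logged events and
  continues; missing input files fail early by name; an empty retained
  cohort still writes every artifact with headers.
* Reproducibility: every stochastic entry point takes a seed; a pipeline
  configuration is serialised with a content hash into `manifest.json`
  so artifacts are traceable.

## 7. Known limitations

* The worked-example angles of the originating analysis are conditional
  on a pinned pretrained embedding model that cannot be shipped; the
  acceptance test for them runs only when `LF_PRETRAINED_VECTORS` points
  at a word2vec-text export of that model, and fails otherwise by design.
* The CHAT reader is a minimal dialect (participant tiers, terminators,
  `[x N]` marks); retracing/overlap codes are stripped, not interpreted.
* ARPABET only; cross-linguistic phonologies would need a different
  relation set.
* The stepwise procedure is the pinned classical one; it inherits the
  well-known instabilities of stepwise selection and is provided for
  comparability, not as the recommended modelling strategy.
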