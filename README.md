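# letterfluency

Strategy scoring for letter (phonemic) verbal-fluency transcripts.

In a letter fluency trial a participant has 60 seconds to produce as many
words as possible starting with a given letter (classically *f*). Beyond
the raw number of correct words (NoCW), clinical neuropsychology reads the
*order* of the productions as evidence of retrieval strategy. This package
computes, per participant and per cohort, the two families of strategy
indices used for people with Alzheimer's disease and related populations:

* **Phonological strategy** — Troyer-style clustering and switching.
  Consecutive words are *related* when any of four rules holds on their
  ARPABET pronunciations: shared first two phonemes (*find–fire*), rhyme
  (*fry–fly*), a single vowel substitution (*flip–flop*), or homonymy
  (*fair–fare*). A cluster is a maximal run of consecutive related words;
  its size is the word count minus one (a singleton scores 0, two words
  score 1). Reported indices: mean cluster size
  **MCS** = (total cluster size) / (number of clusters, singletons
  included) and number of switches **NoS** = (number of clusters) − 1.
  Errors and repetitions participate in clustering but not in NoCW.

* **Semantic strategy** — a semantic-relatedness index built on the
  worm-like-chain picture. Each word maps to an embedding vector; the
  turning angle between consecutive words is
  θᵢ = arccos(cos-similarity(vᵢ, vᵢ₊₁)) ∈ [0°, 180°]. Read as the bending
  angles of a discrete unit-segment chain, directional correlation decays
  as ⟨cos θ(s)⟩ = exp(−s/Lp) with persistence length Lp (in segments);
  longer Lp means the semantic direction persists. The bounded index is
  **SR** = max(0, mean cos θᵢ) = exp(−1/Lp) ∈ [0, 1]. Sessions with fewer
  than four in-vocabulary words are excluded (one or two angles cannot
  support a curvature estimate).

* **Cohort statistics** — exclusion rules (< 4 words; > 3 SD above the
  mean on MCS or SR), descriptive tables, Pearson correlation matrices
  with significance stars, and stepwise multiple regression
  (enter p < .05, remove p > .10) with tolerance/VIF collinearity
  diagnostics.

* **Synthetic cohorts** — a fully seeded generator
  (`simulate_cohort()`) with planted phonological relations, worm-like
  chain angle sequences with known Lp, and injected errors/repetitions,
  so every stage is testable with recorded ground truth and no
  access-controlled clinical corpus.

## Worked example

Inputs shipped with the package: a minimal CHAT transcript, a small
CMU-format pronunciation lexicon, and a **synthetic** 2-D demo embedding
table (unit vectors on a circle — not a real language model; use your own
word2vec/GloVe text file for real analyses).

```r
library(letterfluency)
lex <- load_pron_lexicon(system.file("extdata", "cmudict-subset.txt",
                                     package = "letterfluency"))
emb <- load_embeddings(system.file("extdata", "embeddings-demo-synthetic.txt",
                                   package = "letterfluency"))
s <- read_chat_session(system.file("extdata", "example.cha",
                                   package = "letterfluency"))
s
#> <fluency_session> example: 10 tokens (letter 'f', 60s)
#>   find fire fry fly food food fox dog fertile fen

ph <- score_phonological(s, lex)
cat(sprintf("NoCW = %d, MCS = %.2f, NoS = %d\n", ph$nocw, ph$mcs, ph$nos))
#> NoCW = 8, MCS = 0.43, NoS = 6

semantic_relatedness(s$tokens$norm, emb)
#> <semantic_index> SR = 0.284 (Lp = 0.794 segments, 9 angles, 0 OOV)
```

Reading the output: of the 10 productions, *dog* is an error (wrong
letter) and the second *food* a repetition, leaving NoCW = 8. The
sequence partitions into 7 clusters — *find–fire* (first two phonemes),
*fry–fly* (rhyme), *food–food* (repetition, still clustered) and four
singletons — so MCS = 3/7 ≈ 0.43 and NoS = 6. Under the demo embedding
the mean consecutive cosine is 0.284, i.e. a short persistence length
(≈ 0.8 segments): this participant switches semantic direction sharply —
a phonological rather than semantic search pattern.

Cohort level, end to end on synthetic data:

```r
cohort <- simulate_cohort(synth_config(n_participants = 47, seed = 1,
                                       preset = "phonological"))
dir <- tempfile(); write_synthetic_inputs(cohort, dir)
run_pipeline(pipeline_config(file.path(dir, "transcripts"),
                             file.path(dir, "lexicon.dict"),
                             file.path(dir, "embeddings.txt"),
                             out_dir = file.path(dir, "out"),
                             demographics = file.path(dir, "demographics.csv")))
```

writes `indices.csv`, `exclusions.csv`, `descriptives.csv`,
`correlations.csv` (+ p-values), `regression.json`/`.txt` and a
`manifest.json` carrying the configuration hash.

A command-line driver is installed as `exec/letterfluency` with
subcommands `score`, `cohort`, `simulate`, `plot`; see `?lf_cli`.

## Limitations

The CHAT dialect is deliberately minimal (participant tiers, terminators,
`[x N]` repetition marks); full CHAT retracing/overlap codes are out of
scope. Semantic clustering criteria for category fluency, embedding
training, and audio processing are non-goals. See the methods vignette
(`vignettes/letter-fluency-methods.Rmd`) for the model, parameter and
design-choice discussion.
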