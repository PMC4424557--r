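---
title: "Methods: graph-propagated bilingual term lexicons from comparable corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-propagated bilingual term lexicons from comparable corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilex)
```

## The problem and the model

Clinical corpora in two languages — e.g. English and Chinese discharge
summaries — are *comparable*: they discuss the same kinds of problems,
treatments and tests, but are not translations of each other, follow very
different stylistic conventions, and share almost no general vocabulary
with standard bilingual resources. `bilex` induces candidate term
translations from such a pair of corpora plus a small seed lexicon of
known single-word term pairs.

Everything rests on one representation: the **seed-pair indexed context
vector**. Dimension *i* of the shared space corresponds to seed *pair* i
(not to a seed word), so a vector computed in either language is
comparable with any vector from the other. A term occurrence's context is
deliberately narrow — the nearest seed occurrence strictly left and
strictly right of its span, inside the sentence — because the two
languages' sentence conventions differ so much that any fixed window or
whole-sentence context would have systematically different scope on each
side. Weights are raw frequencies; no tf-idf or likelihood weighting is
used, matching the practice this design follows.

Three methods consume the representation:

1. **Baseline**: rank target terms by cosine of context vectors.
2. **Label propagation (LP)**: build, per language, an undirected graph
   joining terms that co-occur within a sentence, edge weight = context
   cosine (a co-occurrence-frequency weight is available behind
   `edge_weight = "freq"` but cosine is the default, it performs better).
   Seed vertices are clamped one-hot on their own dimension; all other
   vertices start uniform, `u(z) = 1/n`, and ten synchronous cycles of
   weight-normalized neighbour averaging follow. Ranking uses cosine of
   converged labels.
3. **MWT alignment**: for a source multi-word term, run LP per component
   word (on a graph where components are separate vertices — see
   `explode_mwt()`), keep the top `K = 100` candidate terms per component
   and flatten them to words (a word's similarity is the best score of any
   containing term); intersect the components' word sets; enumerate all
   word subsets of size 1..m and keep those that occur verbatim as a
   target-corpus term (order-insensitive word-set match via
   `build_word_index()`); score each survivor by the mean of
   sim(component, word) over all pairs.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `iterations` | 10 | propagation cycles; at package scale this is already at the fixed point (verified against `fixed_point_oracle()`), so more cycles change nothing |
| `K` | 100 | per-component candidate cutoff in MWT Step 1 |
| `n_max` | m | largest candidate-combination size; translations longer than the source term are unreachable by design |
| `edge_weight` | `"cosine"` | graph edge weight; `"freq"` = co-occurrence counts |
| `score_mode` | `"pairs-mean"` | Step-4 plausibility; `"best-match"` averages each component's best word similarity instead |
| `window_policy()` | sentence-bounded, no distance cap | context window; `max_token_distance` caps the nearest-seed search |

Deterministic tie-breaks throughout: equal-score candidates order by
higher corpus frequency then lexicographically; MWT candidates by shorter
term first, then lexicographically. All-zero context vectors are retained
and cosine with them is defined as 0. A vertex with no neighbours (or
all-zero incident weight) keeps its previous label, so isolated vertices
stay uniform. Labels are checked to remain on the probability simplex to
1e-9; the harmonic oracle solves one sparse linear system per connected
seed-reachable component and reproduces the iteration to residual
below 1e-10.

Two readings of the written procedure were genuinely open and are fixed
here as configuration:

* *Word-set matching* in MWT Step 3 uses **sets**, not multisets: a
  combination matches a term whose de-duplicated word set equals it.
  Inflectional variants do not match; only exact case-folded forms do.
* *Step-4 averaging* defaults to the all-pairs mean over (component,
  candidate word), with absent pairs contributing 0; the best-match mean
  is selectable. Both readings of "average similarity between component
  words" are defensible; the all-pairs mean is harsher on combinations
  containing a word only one component supports.
* A seed term belonging to several seed pairs owns all those dimensions
  when windowed, and as a graph vertex is clamped to the uniform mixture
  of its own dimensions (a vertex needs exactly one label).
* **Candidate policy**: ranking for *evaluation* excludes the seed
  lexicon's own target terms — test terms are by construction not covered
  by the seed dictionary, so proposing a known translation is never
  correct. `rank_lp()` itself defaults to ranking all vertices
  (`include_seeds = TRUE`), as the module contract specifies.

## What the synthetic generator emulates

`generate_comparable_corpora()` is first-class, tested code — the
package's stand-in for corpora that cannot be distributed. Its stated
world:

* **Seed scarcity**: 50 seed pairs by default, orders of magnitude fewer
  than the term vocabulary of a real corpus but proportionally similar to
  the real setting's ~1,200 seeds against tens of thousands of terms.
* **Shared affinities**: every planted translation pair draws one sparse
  set of `affinity_sparsity = 3` preferred seed dimensions, *shared across
  languages* and unique across pairs — this is the recoverable signal.
  Draws within a set are uniform (the symmetric choice).
* **Topical organization** (`n_topics`, default one topic per ten seed
  pairs): seed dimensions and pairs are partitioned into topics and each
  sentence draws all its term slots from one topic. Clinical text is
  topically coherent; without this structure every seed becomes a generic
  connector, all context profiles collapse toward one another, and the
  co-occurrence graph degenerates into a hairball in which propagation
  mixes before it absorbs. Topics interleave over dimension order so that
  a partial reveal of the lexicon (the scarcity experiments) thins seeds
  uniformly across topics.
* **Style asymmetry**: the source side packs 6 annotated terms per
  sentence against the target's 3, and 10 vs. 20 sentences per document —
  long run-on source sentences are modelled *only* through sentence
  length and per-language noise; no morphology is attempted.
* **Context noise** `noise_rate`: each flanking seed is replaced by a
  uniformly random seed with probability ε per language (default 0.05).
* **Rare multi-word terms**: each m-to-n pair contributes its component
  words as frequent single-word source terms (sharing the pair's
  affinity) while the full m-word term and its n-word translation occur
  only `mwt_term_occurrences` times (default 3; the recovery tests use 1).
  Multi-word terms are rare even when their components are common, and
  that rarity is exactly why direct propagation fails on them while
  component-wise alignment does not. The default m-to-n mix (11 2-to-1,
  14 2-to-2, 2 3-to-2, 1 3-to-3, 7 1-to-2, 2 2-to-3) mirrors the observed
  distribution in the motivating data, including the ~24% of pairs whose
  translation is *longer* than the source and therefore unreachable — a
  documented limitation of the method, reproduced deliberately.

What the generator does **not** model: real vocabulary, abbreviations
(and their very different conventions in the two languages),
segmentation errors, category noise, document-level discourse structure,
and permissible near-translations. A green test on this world therefore
establishes that the pipeline recovers planted distributional signal
under noise and asymmetry — not that it reaches any particular accuracy
on real clinical text.

## Desk-scale findings the tests document

Two empirical results of the acceptance suite deserve explanation.

**Zero-noise recovery** (criterion 6): with ε = 0 the planted source and
target context vectors have identical support, and both the baseline and
LP reach Acc₁ = 100%. This needs ~60 occurrences per term at 50 seed
pairs; at ~30 occurrences LP's cross-language sampling noise (realized
seed-profile differences between the two independently generated
corpora) occasionally flips a top-1 decision even without noise.

**Seed scarcity** (criterion 7) is implemented exactly as specified —
40% of seeds revealed, ε = 0.15, ten fixed generator seeds — and is the
suite's one deliberately red test. The propagation method's advantage
does not materialize at this scale: with only 20 revealed label
dimensions, every converged label is compressed toward its topic's
shared absorption profile, so high-frequency hidden-seed vertices sit
within ~0.02 label-cosine of the true translation and crowd a few gold
hits per run out of the top 10, while the count-space baseline — whose
sparse vectors are never smoothed — keeps them. In the motivating
regime the label space has ~1,220 dimensions and ~31,000 candidates;
there the baseline starves (its vectors are mostly empty) and
propagation's widened context wins. We probed topic granularity,
affinity sparsity, corpus size, seed-flank scarcity, window caps and
sentence-density symmetry without finding a desk-scale world that
starves the baseline while leaving propagation's own channel intact, and
chose to keep the criterion honest rather than weaken it. The
within-budget test prints both means; the assertion fails by ~0.06.

**MWT ordering** (criterion 8): with full terms planted once each,
component-wise alignment recovers 100% of planted 2-to-1 and 2-to-2
pairs in the top 10 (the threshold is ≥ 70%), and treating the same
multi-word terms as single propagation vertices recovers strictly fewer —
the qualitative ordering the method exists to produce.

## Known limitations

* Translations longer than the source term cannot be found (`n_max = m`).
* Exact word-set matching means morphological variants in the target
  corpus are distinct terms; no lemmatization is attempted.
* The subset enumeration in Step 3 is exponential in the intersection
  size for large `n_max`; with the default `n_max = m ≤ 3` and top-100
  candidate lists it is cheap (the count is Σⱼ C(q, j), reported in the
  pipeline log).
* Tokenization, word segmentation, term recognition and abbreviation
  resolution are out of scope: the corpus format carries pre-annotated
  term spans.
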