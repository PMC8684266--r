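---
title: "Medical-context vector spaces: model, protocols and design choices"
author: "medcontext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Medical-context vector spaces: model, protocols and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medcontext)
```

## The model

Chart review — reading a patient's notes to answer a clinical question —
usually starts from a keyword, and the keyword alone misses most of the
relevant text. Query expansion needs terms that are similar *for this
task*, and textual co-occurrence embeddings cannot see the forces that
shape clinical word choice: who wrote the note, in which section, for a
patient of what age, around which coded events.

`medcontext` represents each clinical term $w$ by a **medical-context
vector** $u_w = \{u_{c_1}(w), \dots, u_{c_{10}}(w)\}$: for each of ten
non-textual contexts $c_k$, the normalized frequencies with which $w$ is
used across that context's dimensions. The ten contexts fall into four
groups:

| group | context | dimensions |
|---|---|---|
| organizational | author department | departments observed |
| organizational | author staff type | staff types observed |
| medical events | ICD events | ICD codes within the event window |
| medical events | CPT events | CPT codes within the event window |
| medical events | chief complaints | complaint strings within the window |
| demographics | patient age | ten-year bins |
| demographics | patient gender | male / female / unknown |
| note structure | note type | note types observed |
| note structure | note section | section names |
| note structure | top note section | the five key sections |

Accumulation is a single pass over the corpus. Text is tokenized
(case-folded, split on non-alphanumeric runs, stop words and
single-character tokens removed, numerals kept); each token occurrence
increments, for every note-level context, the dimension the note
activates; for event-level contexts, *every* code of that system whose
timestamp lies within the event window of the note's timestamp; and for
the section contexts, the section the occurrence sits in. Counts are then
normalized per term and context to proportions (L1): the proportions are
directly interpretable as usage-frequency distributions, which is what
the per-context comparisons below assume. A context vector with no
evidence stays all-zero.

Two terms are compared one context at a time by cosine similarity
$S_{c_k}(w_i, w_j)$ of their usage vectors; the ten values form the
**medical-context similarity vector** $S(w_i, w_j)$. For non-negative
usage vectors every entry lies in $[0, 1]$. A pair with no shared
evidence in a context scores 0 there, and the cosine of an all-zero
vector is defined as 0 — absent evidence is treated as no similarity.

## Learning a reviewer's semantic preference

Given a topic word $K$ and a candidate set, each candidate $w$ is
featurized as $S(w, K)$. The reviewer's highlights supply labels: with
$H(w \mid D)$ the total number of times $w$ was highlighted across the
task's documents and an importance cutoff $I$, a candidate is *important*
when $H > I$ (strictly). A classifier fitted on these ten features scores
unlabeled candidates with a preference probability; for logistic
regression,

$$\ln\frac{P(\text{preferred})}{P(\text{non-preferred})}
 = \beta_0 + \sum_{k=1}^{10} \beta_k\, S_{c_k}(w, K),$$

the fitted $\beta_k$ are the reviewer's context weights, reported by
`interpretModel()` with one-tailed Wald $p$-values in the direction of
each estimate's sign. Random forest (100 trees) and an RBF-kernel SVM
with probability calibration are provided as alternatives; they rank
comparably but are not interpretable, which is why logistic regression
is the default.

The logistic fit is plain maximum likelihood rather than a penalized
fit: the coefficient table's standard errors and $p$-values are the
point of the method, the features are bounded in $[0, 1]$, and in the
intended regime (hundreds to thousands of candidates against ten
features) regularization adds nothing but bias. Embedding feature spaces
(tens to hundreds of raw dimensions on arbitrary scales) are instead
standardized per feature before logistic or SVM fits; the flag is stored
in the model and re-applied at prediction time.

## Evaluation protocols

**Preference prediction.** Starting at $I = 1$, label sets are built for
increasing cutoffs while at least 10 candidates remain important; each
retained cutoff is evaluated by seeded, stratified ten-fold
cross-validation with AUROC on the held-out folds. The floor of 10
positives guarantees at least one positive per fold, which is what makes
fold AUROCs well defined; `crossValidate()` refuses smaller label sets.
Two feature spaces are compared by a one-sided Mann–Whitney U test on
their two sets of fold AUROCs (exact when tie-free at these sizes,
tie-corrected normal approximation otherwise — the standard
`wilcox.test` behavior).

**Learning curve.** For each training fraction $x$ from 1% to 90% in 1%
steps, 100 repetitions each draw a stratified training set of size
$\max(2, \mathrm{round}(x n))$ — at least one instance per class,
degenerate draws redrawn and counted — train, and measure AUROC on the
complement (so the test set is refreshed with every draw). Stratification
and the size floor are this package's choices for the degenerate cases a
fraction-based protocol leaves open.

AUROC itself is computed by the Mann–Whitney identity from midranks,
ties credited one half — identical to exhaustive positive–negative pair
enumeration, which the test suite verifies.

## Tunable parameters

* `event_window_hours` (default **48 h**): events further than this from
  the note timestamp are ignored. The boundary is inclusive.
* `key_sections` (default *assessment, findings, family medical history,
  medications, problem list*): the sections feeding the top-note-section
  context, the sections that carry most chart-review signal.
* `age_bin_edges` (default `seq(0, 90, 10)`): ten-year bins labeled
  `"0-9"` … `"80-89"`, with the last bin open-ended (`"90+"`). Ten bins
  keep the age context at its conventional dimensionality; the edges are
  configurable where a corpus warrants an extra bin at very high ages.
* importance cutoff `I` (default 1): strict threshold on highlight
  counts; the sweep explores the whole usable range automatically.
* The stop-word list is a bundled set of standard English function words,
  overridable per call; numerals are retained since dosages and code
  fragments are informative tokens.

## The synthetic study conditions

Protected clinical corpora cannot ship with a package, so `medcontext`
includes a generator whose output exercises every module under known
ground truth. `syntheticSpec()` fixes the reference conditions:

* **800 notes, 1200 terms.** The candidate pool matches the size of
  practical chart-review candidate sets (roughly 1000–2000 terms).
* **Latent usage profiles.** Every term gets, per context, a categorical
  distribution drawn from a symmetric Dirichlet (concentration 0.4 —
  spiky, specialized usage). 60 *related terms* copy the topic word's
  distribution exactly in the three related contexts (chief complaint,
  note type, note section), so genuinely task-similar terms exist.
* **Notes.** Attributes are sampled uniformly (8 departments, 6 staff
  types, 6 note types, 3 genders, ages 0–99); up to 3 events per system
  land uniformly within ±96 h so that a deliberate mix falls inside and
  outside the 48 h window; 3 of 8 sections (5 of them key sections) are
  filled with 40 tokens each. A token is drawn with probability
  proportional to the product of the term's profile mass on every active
  attribute of the note *and* of the section being written — including
  the in-window event codes. Weighting by the event and section profiles
  is essential: without it those contexts would carry no term-specific
  signal and their planted reviewer weights would be unrecoverable in
  principle.
* **The reviewer.** Highlighting follows the same linear-logit form the
  logistic model fits: $p(w) = \sigma(\beta_0^* + \sum_k \beta_k^*
  S_{c_k}(K, w))$, each occurrence highlighted independently with
  probability $p(w) \times 0.25$. The planted weights are distinct
  across all ten contexts (dominated by chief complaint 6.0, note type
  4.0, note section 3.0) so that rank recovery is a meaningful check;
  the intercept of −10 yields on the order of 300 ever-highlighted terms
  and ~180 important terms at $I = 1$ out of 1199 candidates —
  proportions in line with real chart-review tasks. Matching the fitted
  model's form is deliberate: it makes parameter recovery well posed,
  and misspecified reviewers can be simulated by passing a modified
  weight vector.

What the generator does *not* emulate: real clinical language (tokens
are vocabulary identifiers), reviewer disagreement, section-boundary
ambiguity, code hierarchies, and the long-tailed dimension cardinalities
of production EMR systems. Passing tests therefore demonstrate that the
machinery is correct and that the protocols behave as designed under a
known preference structure — not that any particular clinical corpus
will show the same effect sizes.

One statistical subtlety of the design: because token-acceptance weights
are renormalized within each note, an extremely spiky high-frequency
term partially saturates its compatible notes, flattening its empirical
usage distribution relative to its latent profile. At moderate
concentrations the effect is negligible and empirical usage converges to
the planted profile (the suite checks total-variation distance < 0.1 at
2000 notes, concentration 2); at the spiky default it can reach ~0.15
for the most extreme terms. This bias affects absolute profile recovery,
not the similarity ranking or the preference experiments, which operate
on the accumulated (observed) space itself.

## Numerical and protocol choices

* Zero-usage cosine ≡ 0; normalized similarity values are clamped to
  $[0, 1]$ against floating-point overshoot.
* All rankings (dimensions, similar terms, recommendations) break ties
  lexicographically for determinism; vocabularies and dimension catalogs
  are kept in lexicographic order, making the vector-space archive and
  every report byte-reproducible under a fixed seed.
* Candidates missing from a space or embedding get zero feature rows
  with a warning (configurable to a hard error) — a missing candidate
  is evidence of nothing, and silently dropping it would desynchronize
  feature and label sets.
* Each generation stage derives its own RNG stream from the master seed,
  so stages are individually reproducible as well as end-to-end.

## Problem sizes

The test suite and the acceptance script run the full pipeline at the
reference conditions above (800 notes × 1200 terms), the complete
1%–90% × 100-repetition learning-curve grid for the medical-context
features and the random-embedding baseline, and oracle comparisons on
hundreds of randomized small instances. The acceptance script evaluates
the learning curve at fractions {1, 5, 10, 25, 50}% — the region where
the curves separate — with 100 repetitions each.

## Limitations

* Sections are taken as given (or a single "body" section); no section
  tagger is bundled.
* Event codes are opaque labels: no ICD-9/10 mapping or hierarchy
  rollups.
* Multi-word phrases are decomposed into tokens; phrase-level similarity
  is out of scope.
* The unsupervised `topKSimilar()` aggregates contexts by an unweighted
  mean — a convenience view; the supervised preference model is the
  principled aggregation.
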