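---
title: "Extrapolating lexical norms from word associations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extrapolating lexical norms from word associations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knnorms)
```

## The problem

Lexical norms are per-word numeric ratings collected from human judges:
how pleasant a word's referent is (valence), how activating (arousal),
how much control it conveys (dominance), how concrete it is, and at what
age its meaning is typically acquired (AoA).  Collecting them is
expensive, so a long line of work predicts ("extrapolates") norms for
unrated words from the words' positions in a semantic space.  `knnorms`
implements the simplest and empirically strongest variant of that
programme: predict a word's norm as the mean norm of its $k$ most
similar rated words, with similarity computed from either continued
free-association data (each participant gives the first three associates
of a cue word) or word--context co-occurrence counts.

## The model

Both data sources arrive as a nonnegative count matrix $C$ with words on
the rows.  For association data this is the cue-by-response tally,
restricted to responses that also served as cues so that it is square;
for corpus data it is a word-by-context count table.  Counts are
re-weighted by positive pointwise mutual information,

$$\mathrm{PPMI}_{ij} = \max\!\left(0,\; \log\frac{p_{ij}}{p_{i\cdot}\,p_{\cdot j}}\right),
\qquad p_{ij} = c_{ij}/N,$$

which removes the dominance of high-frequency words, and similarity is
the cosine between PPMI-weighted rows:

$$s(w_i, w_j) = \frac{\mathbf{x}_i \cdot \mathbf{x}_j}
{\lVert\mathbf{x}_i\rVert\,\lVert\mathbf{x}_j\rVert} \in [0, 1].$$

The prediction for a target word $t$ given a training set $T$ of rated
words is the unweighted mean rating of its $k$ nearest training
neighbors,

$$\hat{y}_t = \frac{1}{k} \sum_{w \in \mathrm{NN}_k(t, T)} y_w,$$

evaluated either leave-one-out (every rated word predicted from all the
others) or train/test (a held-out set predicted from a disjoint training
set), with $k$ swept over $\{1,\dots,50, 60, 70, 80, 90, 100\}$ and
quality summarized as the Pearson correlation between predictions and
human means at each $k$.

Assumptions worth making explicit: the norm must vary smoothly over the
similarity space (nearby words have similar ratings), the unweighted
neighbor mean must be adequate (no distance kernel), and predictions are
necessarily convex combinations of training values, so they can never
extrapolate beyond the observed rating range.

## Parameters that matter

* **`k`** (neighbors, unitless).  The only tuning parameter of the
  predictor.  Small `k` is noisy, large `k` over-smooths toward the
  grand mean; the sweep makes the trade-off visible and `sweep_k()`
  reports the maximum, breaking ties toward the smaller (more
  parsimonious) `k`.
* **PMI base and smoothing.**  Natural log, no smoothing.  The base is
  provably irrelevant to the cosine (a change of base rescales all
  weights by one constant), so it is not configurable; a unit test pins
  the invariance.
* **Neighbor weighting.**  The default is the plain mean; a
  similarity-weighted mean is available behind `weighted = TRUE` but off
  by default, matching the method under study.
* **Confidence intervals.**  Fisher $z$ with half-width
  $1.96/\sqrt{n-3}$.  The conventional 1.96 (rather than
  `qnorm(0.975)`) is the default multiplier; the difference never
  reaches the second decimal.
* **Reliability.**  Split-half with 10,000 random rater splits by
  default, Spearman--Brown corrected, mean across splits.  Halves are
  simple random partitions (no stratification); odd rater counts split
  `floor(R/2)` against the rest.
* **Attenuation.**  `disattenuate()` divides by
  $\sqrt{\mathrm{rel}_a\,\mathrm{rel}_b}$ with the prediction
  reliability conventionally set to 1, clipping at $|r| = 1$ with a
  warning.

## Tie-breaking and degenerate inputs

Neighbor ties are broken by descending similarity and then lexicographic
token order, making every prediction deterministic.  Words whose PPMI
vector is all zero have no direction; they are flagged by
`cosine_similarity()` and excluded from neighborhoods, and a target with
fewer than `k` eligible neighbors raises an error instead of silently
shrinking `k`.  Constant prediction vectors make the correlation
undefined; the affected `k` is recorded as `NA` and logged rather than
dropped.  `restrict_to_square()` iterates to a fixed point, so a cue
whose only responses were themselves dropped is removed too and the
operation is idempotent.

The incremental-variance analysis regresses human ratings on one
source's predictions and the residuals on the other source's
predictions.  The reported increment is the second fit's explained sum
of squares as a share of the human ratings' *total* variance, so it adds
with the first-stage $R^2$ to at most 1 and matches the additivity
implied by the published residual analyses; the F test is that of the
residual regression.

For comparing the two channels' correlations -- which share the human
ratings and are computed on the same words -- three published tests for
dependent overlapping correlations are evaluated (Steiger's 1980
modified $z$ with pooled correlation, the Meng--Rosenthal--Rubin 1992
$z$, and the Hittner--May--Silver 2003 $z$ with back-transformed mean
Fisher $z$), and the largest $p$ is reported as the conservative
decision value.  Which methods a "most conservative across methods"
umbrella spans varies between reports; with three standard tests the
conservative maximum may differ slightly from any particular published
choice.  The correlation between the two prediction vectors, which the
tests require, is computed from the vectors themselves.

## What the synthetic generator emulates

`generate_lexicon()` draws `vocab_size` words as i.i.d. standard-normal
vectors in a `latent_dim`-dimensional semantic space.  Each property is
a noisy linear projection onto a property direction -- the weakest
generative assumption under which k-NN extrapolation ought to work, and
the latent-direction view under which norms have previously been fitted
to semantic spaces.  Directions are drawn orthonormal so distinct
properties are independent by construction.  Projection noise
(`prop_noise_sd = 0.25` in latent units, against unit-variance
projections) leaves about 94% of true-norm variance carried by the
space, in the region of the published split-half reliabilities of human
norms (.91--.99).  True values are affinely mapped onto the rating
scale: Likert 1--7 for the affective properties and concreteness, 2--16
years for AoA to mimic its deviating, wider scale.

The association channel gives every cue `participants = 100` simulated
participants, each producing three distinct responses drawn without
replacement with probability $\propto \exp(\beta \cos(\ell_c,
\ell_r))$, self excluded, with sharpness `beta = 6` -- the regime in
which the cue's semantic neighborhood dominates responding without
being deterministic, and 100 participants matches the data-collection
floor of the association projects this emulates (300 tokens per cue).
The co-occurrence channel spends the *same total token budget*
(`vocab_size * participants * 3`) on a multinomial over word pairs with
sharpness `beta_text = 3`: the same latent structure through a flatter,
noisier distribution, emulating the empirical finding that text
co-occurrence carries the weaker signal for these properties.  Raters
are true value plus Gaussian noise (`rater_sd = 0.5` rating units,
about what per-rater Likert noise must be for 15--64 raters to reach
the published reliabilities), clipped to the scale.

All randomness flows from one master seed through named substreams
(lexicon, associations, raters, co-occurrence), so any component can be
regenerated independently and bit-identically.

What the generator does *not* emulate: Zipfian word frequencies and
response marginals, phonological/clang associations, multi-word
responses, rater cohort effects, and any non-semantic determinant of
AoA.  Passing the recovery suites therefore shows that the pipeline's
machinery is correct and that the method recovers norms when its core
assumption (norms as directions in a similarity space) holds -- it does
not show how far real association data satisfy that assumption.

Two scale effects of the generator are worth knowing.  First, because
the latent space is smooth and isotropic, the optimal `k` tends to sit
high in the grid (often at its top) -- real norms, with their lumpier
similarity structure, published optima between 8 and 50.  Second, at
the full default budget both channels approach the ceiling set by
`prop_noise_sd`, compressing the association-over-text gap toward zero;
the ordering is a data-limited-regime phenomenon, which is why the
channel-ordering suite runs at a reduced scale (200 words, 50
participants per cue) where the budget, not the noise floor, binds.

## Problem sizes used by the test and analysis runs

The property suites run leave-one-out sweeps on 500-word lexicons with
10 latent dimensions: recovery across 10 seeds at 25/50/100
participants per cue, channel ordering across 20 seeds at 200 words and
50 participants, and reliability recovery on 500 words with 12 parallel
raters and 1,000 random splits.  The analysis drivers and the
acceptance script run the full default configuration (500 words, 100
participants, both channels, all five properties) with 2,000 reliability
randomizations.  These sizes keep a full run in minutes on one core
while leaving the Monte Carlo error well inside the asserted margins.

## Known limitations

* Dense similarity matrices: a 12k-word vocabulary (the scale of the
  real association projects) needs ~1.2 GB as a dense matrix, which one
  desktop can hold, but counts and PPMI stay sparse throughout and
  neighbor ranking is row-wise, so a lazily-row-computed variant is a
  contained change if memory becomes binding.
* The leave-one-out excludes only the target, not its associates; a
  response-level dependency between a cue and its norm raters is not
  modelled.
* Multi-word responses are kept as single tokens after trimming;
  no spelling correction or lemmatization of responses is attempted.
* `NA` ratings are allowed in rater matrices, but the count channels
  have no missingness model.
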