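---
title: "Decoding semantic vectors from brain activation patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding semantic vectors from brain activation patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semdec)
```

## The problem

Distributional semantic models assign each word a vector whose geometry
tracks meaning: words used in similar contexts get similar vectors, and the
vector of a sentence can be approximated by averaging the vectors of its
content words. If the brain encodes such a space, then the fMRI activation
pattern evoked by reading a word or sentence should be a (noisy, highly
redundant) linear image of its semantic vector — and a linear *decoder*
trained on known stimulus/pattern pairs should recover the semantic vector
of a stimulus it has never seen.

`semdec` implements that pipeline: sampling a semantic space for stimulus
design, training per-dimension ridge decoders, selecting the voxels worth
decoding from, and scoring decoded vectors against text-derived ones with
the evaluation statistics and null models that the design requires.

## The model

Let $X$ be the training example matrix ($n$ stimuli $\times$ $p$ voxels,
each row a deconvolved per-stimulus activation image restricted to a
gray-matter mask) and $Z$ the matrix of text-derived semantic vectors ($n
\times d$). For each semantic dimension $z$ (a column of $Z$) the decoder
solves

$$\min_{b,\,b_0}\ \|Xb + b_0 - z\|_2^2 + \lambda\,\|b\|_2^2,$$

an independent ridge regression per dimension. The penalty $\lambda$ is
chosen *separately for each dimension* by generalized cross-validation
(GCV) on the training set:

$$\mathrm{GCV}(\lambda) =
  \frac{\|(I - H_\lambda)\tilde z\|^2}{n\,(1 - \mathrm{tr}(H_\lambda)/n)^2},$$

where $H_\lambda$ is the ridge smoother matrix on mean-centered data. GCV
is a rotation-invariant approximation to leave-one-out cross-validation
that requires no refitting per left-out point. We compute it along the
whole penalty grid from a single SVD of the centered training matrix,
shared across all $d$ dimensions; this is algebraically identical to
evaluating per-dimension hat matrices (the test suite verifies the identity
against an explicit hat-matrix evaluation to $10^{-10}$) and reduces the
cost per dimension to $O(r)$ per grid point.

Every voxel is mean-normalized across training stimuli, as is every
semantic dimension; the stored training means are reused to normalize test
images, so nothing about a test stimulus ever enters the fit. At decode
time the dimension means are added back, putting decoded vectors on the
same scale as the text-derived ones. The evaluation metrics are
correlations, which are insensitive to this restoration per vector, but
fixing the convention keeps decoded output directly comparable and
serializable.

### Tunable parameters

* `lambda_grid` — 20 points log-spaced in $[10^{-3}, 10^6]$
  (dimensionless). The source method names GCV but no grid; this range
  spans effectively unpenalized through near-constant fits, and the
  selected penalties in simulation sit well inside the interior.
* `folds` (informativeness CV) — 10 contiguous blocks in stimulus order.
  The reference analysis says only that scoring happens "in
  cross-validation within the training set"; contiguous blocks are the
  deterministic choice, and a seeded shuffle is exposed for designs where
  acquisition order correlates with content.
* `ridge_lambda` (informativeness) — fixed at 1, the value the reference
  analysis states for the neighborhood models.
* `n` (voxels selected) — 5000 at production scale, roughly 10% of a
  cortical mask; simulations here use the same ~5–10% fractions of much
  smaller grids.

## Voxel selection

Informativeness of a voxel is scored from the voxel *and its 26 adjacent
neighbors in 3D* (fewer at grid or mask boundaries — no padding, which
would fabricate signal): a ridge model with penalty 1 predicts each
semantic dimension from the neighborhood columns inside k-fold CV, held-out
predictions are concatenated across folds, and the score is the maximum
over dimensions of the correlation between predictions and truth. The top-n
scorers feed the decoder; ties at the boundary break toward the lower mask
position so selection is deterministic. Selection can be restricted to an
arbitrary sub-mask (e.g., a functional network); when the restriction holds
fewer voxels than requested, all of them are used, with a warning.

Because the score is a property of a *neighborhood*, voxels immediately
adjacent to an informative cluster score almost as highly as its members.
In recovery simulations this shows up as exact-$n$ selection capturing
most, but not all, of a planted informative set, with every false positive
lying on a blob boundary; doubling the selection size recovers ≥ 80% of the
planted set. This is inherent to neighborhood scoring, not a defect: at
production scale the requested 5000 voxels are a deliberate over-selection
for the same reason.

## Building and sampling the semantic space

To design a stimulus set that covers the space, the vocabulary is clustered
by spectral clustering of the cosine-similarity graph:

1. cosine similarity matrix $C$ over all word pairs;
2. rescale by $(C+1)/2$ into $[0,1]$ and zero the diagonal;
3. row-normalize so each row sums to 1;
4. take the leading `n_eig` eigenvectors (by real part) of the resulting
   row-stochastic matrix;
5. k-means with squared Euclidean distance and k-means++ seeding (10
   restarts, best within-cluster sum of squares kept) on the embedding.

Reference scale is a ~30,000-word vocabulary with $k = 200$ clusters on a
100-dimensional embedding. Numerical choices the procedure leaves open, and
how we fixed them:

* the row-stochastic matrix is non-symmetric, so its eigenvectors come from
  a general (complex) eigendecomposition; we order by the real part of the
  eigenvalue, take real parts of the eigenvectors, and fix each
  eigenvector's sign so its largest-magnitude entry is positive, making the
  embedding reproducible across LAPACK builds;
* the leading eigenvector of a connected row-stochastic matrix is constant
  (eigenvalue 1) and carries no cluster information. We keep it: dropping
  it would silently change the embedding dimensionality, and a constant
  coordinate is harmless to k-means;
* no re-normalization of embedding rows before k-means;
* token matching is exact and case-sensitive throughout — callers lowercase
  upstream.

Coverage of the space by a candidate stimulus set is diagnosed with
`dimension_usage()`: a dimension counts as represented by a word when the
word's absolute value on it falls in the top 10% of magnitude across the
whole vocabulary. With the real 180-word reference stimulus set against the
full GloVe vocabulary this measure reports at least 5 words per dimension
(median 16); reproducing those numbers requires the production embeddings,
so the package documents rather than asserts them.

Cluster-level interpretability screening (the manual step of discarding
uninterpretable clusters) is intentionally out of scope; per-cluster size
diagnostics are reported instead.

## Evaluation statistics and their nulls

**Pairwise classification.** For a pair of stimuli, compute the four
correlations between the two decoded and the two text vectors; the pair is
correct when the highest is a matched one. We use the strict form (a tie
counts as incorrect), and pairs involving a constant vector are excluded
and tallied. Chance is 0.5. Because all pairs sharing a stimulus share a
decoded vector, significance uses an exact binomial upper tail at a
deliberately conservative trial count: the number of distinct words (word
designs), or for sentence designs the printed passage-pair rules
(`conservative_count()`), with the observed fraction rescaled by rounding
to that count.

**Rank accuracy.** The true candidate's rank among all candidates, by
correlation, mapped to $1 - (\mathrm{rank}-1)/(n-1)$; ties get average
ranks, so a tie spanning the true item scores at the tie's average
(conservative and deterministic). Under the null the mean of $T$ scores is
normal with mean $0.5$ and variance $(R+1)/(12(R-1)T)$ for $R$ candidates;
using the number of passages rather than sentences for $T$ keeps the test
conservative under within-passage correlation.

**Word spotting.** Rank the entire vocabulary against a decoded vector and
score a sentence by its best-ranked constituent word. The whole vocabulary
competes — synonyms and category names may outrank the actual word, and no
exclusions are applied. The null simulates, per sentence, as many uniform
ranks as the sentence has words and takes the max; the median of the max of
$k$ uniforms is $0.5^{1/k}$, which the simulated null reproduces within
0.01, and with realistic sentence word counts the null median lands near
0.86–0.88 — far above 0.5, which is why the null simulation (not the naive
chance level) is the right reference. Distributions are compared with a
two-sided Kolmogorov–Smirnov test; histograms use 20 equal bins on $[0,1]$.
The null's word count is the number of *in-vocabulary content words* (the
only words that can score).

**Similarity structure.** The correlation between the text/text and
decoded/text stimulus-similarity matrices, diagonal included (the diagonal
holds each decoded vector's correlation with its own text vector);
`include_diagonal = FALSE` gives the off-diagonal variant.

**Restriction comparisons.** Decoders restricted to different voxel
sub-masks are compared by a one-sided paired t-test over per-sentence mean
accuracies (degenerate zero-variance differences fall back to the exact
boundary values 0, 0.5, or 1) and by an exact sign test over per-subject
rank accuracies; p-values are Bonferroni-corrected by the number of tasks
× networks × experiments.

## The synthetic-data generator

Simulations instantiate the forward model the decoding premise assumes:
$X = Z A^\top + \varepsilon$ with a sparse encoding matrix $A$ whose
nonzero rows form spatially contiguous blobs on the voxel grid and
$\varepsilon$ i.i.d. Gaussian. Defaults define the reference recovery
conditions used throughout the tests: 120 words in 24 clusters on a
50-dimensional sphere (cluster centers separated by cosine ≤ 0.5, members
jittered with SD 0.05 and renormalized), a 20×10×10 grid (2000 voxels) with
50 informative voxels, and `noise_sd = 1`. Noise is specified relative to
the signal: $A$ is rescaled so informative voxels have unit signal SD, so
`noise_sd = 1` is per-voxel SNR ≈ 1, and `noise_sd = 0` a noiseless
encoding. The dimensionality is kept far below the production 300 so the
full pipeline — per-fold voxel selection inside leave-10-out
cross-validation — runs in about a minute.

What the generator does *not* emulate: hemodynamics and temporal
autocorrelation (inputs represent deconvolved per-stimulus estimates),
spatially correlated noise, and between-subject variability. Passing
recovery tests therefore demonstrate that the estimator is correct and
well-calibrated under its own assumptions — not that real fMRI satisfies
those assumptions. Conversely the generator does reproduce the features
the statistics are sensitive to: hierarchical topic/passage/sentence
designs (the reference shapes, 24×4×4 = 384 and 24×3 passages with mixed
3–4 sentences = 243, are both constructible), within-passage semantic
similarity exceeding cross-topic similarity, and cluster structure
recoverable by the spectral pipeline.

A worked recovery run:

```{r pipeline, eval = FALSE}
cfg <- synthetic_config(seed = 12)           # 2000 voxels, 50 dims, SNR 1
sim <- simulate_experiment(cfg, "words")     # 120 word stimuli
cv  <- crossval_decode(sim$examples, sim$Z, k = 10, n_select = 100)
pairs <- t(combn(120, 2))
pairwise_accuracy(cv$decoded, sim$Z, pairs)
#> Pairwise accuracy: 0.989 (7059/7140 pairs)
```

Each of the 12 folds selects voxels, normalizes, and tunes its penalties on
its own 110 training stimuli only; the decoded matrix covers every stimulus
exactly once.

## Degenerate inputs and numerical conventions

* Zero-norm embedding rows abort cosine similarity with the offending
  token named; sub-2-word spaces cannot be row-normalized.
* A constant semantic dimension is excluded from informativeness scoring;
  if every dimension is constant, scoring aborts. A voxel whose
  neighborhood yields no valid correlation at all scores −1 (ranked last).
* A constant dimension at training time decodes to its mean, with zero
  coefficients, and is logged.
* Zero-variance voxels are retained in the decoder (ridge shrinks them),
  and logged.
* Singular values below `max(d) * 1e-12` are truncated in the GCV SVD.
* Correlation-undefined pairs/vectors: excluded and tallied (pairwise),
  an error (rank accuracy and word spotting, where a constant decoded
  vector means the decoder failed upstream).
* Voxel order is R's column-major convention (first axis fastest), 1-based
  mask positions; the geometry is serialized with every model, so model
  files are portable.

## Problem sizes in the test suite

Unit tests run on grids of a few hundred voxels and 20–120 stimuli;
the full-pipeline recovery test uses the default 2000-voxel, 50-dimension,
120-word configuration (about a minute); the monotone-noise and
voxel-recall suites average 5 seeds each at the same scale. The
chance-calibration checks use 2000 random pairs and 1000 rank items, as
the statistics' own convergence dictates.

## Known limitations

* The decoder is linear and per-dimension; cross-dimension structure is
  ignored at fit time (the source work names per-dimension voxel sets as
  future work, and so does this package).
* Encoding-direction models (predicting voxels from vectors) are out of
  scope.
* The spectral pipeline materializes the full similarity matrix; at the
  production vocabulary (~30k words) that is ~7 GB of doubles and a dense
  eigendecomposition — the sampling stage is an offline, once-per-space
  computation, and this implementation is sized for that use, not for
  repeated interactive clustering at full scale.
* Pronoun dereferencing and content-word extraction are the stimulus-table
  author's responsibility; the package consumes the extracted tokens.
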