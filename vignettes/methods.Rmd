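---
title: "Latent-structure metrics for human figure drawings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-structure metrics for human figure drawings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models implemented in `sketchlatent`, their
assumptions, the tunable parameters and why their defaults are what they
are, what the synthetic-study generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The pipeline at a glance

A drawing study consists of bitmap drawings linked to participants, three
kinds of crowd judgments (triadic similarity, pairwise quality, two-rater
checklists), and per-participant outcomes. The pipeline derives four
per-drawing metrics — machine embedding coordinates, human embedding
coordinates, quality-rank score, checklist score — compares their
structure, and measures how much variance each explains in participant
characteristics through a stepwise nested-model harness.

## Image preparation

Drawings are binarized (pixel is ink iff luminance falls below a
threshold; Otsu's histogram threshold by default because source images
vary in contrast, with a fixed-threshold override), cropped to the ink
bounding box with a small margin, and centered unscaled on a uniform white
square (224 px by default, matching common extractor input sizes).
Content larger than the target square is shrunk preserving aspect ratio;
a resampled pixel counts as ink when its source block is at least 25%
ink, which keeps thin strokes visible under heavy downscaling. Blank
images are rejected with a distinct error rather than silently embedded,
because cosine similarity is undefined on all-zero feature vectors. The
binarize–crop–pad pipeline is idempotent, crop never creates ink, and
padding conserves the ink-pixel count exactly; all three properties are
tested.

## Machine-derived embedding

The default feature extractor is deterministic and self-contained:
ink-fraction grids at 4x4, 8x8 and 16x16 resolution concatenated with six
global statistics (ink fraction, bounding-box height/width fractions,
centroid row/column fractions, perimeter fraction), 342 features in all.
It is sensitive to exactly the kinds of properties that drive
convolutional-feature similarity on sketches at a coarse level — where
ink is, how much, how large and how dense the figure is — while being
reproducible offline. Any object with the same contract (declared input
side, declared output length, deterministic function) can replace it; a
random-projection extractor ships for contract tests, and an adapter
around a pretrained network's penultimate layer satisfies the same
contract if one is available.

Cosine similarities are converted to chord distances
`delta = sqrt(2 (1 - s))` before classical MDS. The conversion is a
declared choice: for unit-normalized vectors the chord distance is the
Euclidean distance, so the resulting matrix is Euclidean-embeddable and
classical MDS is exact when the feature geometry is planar. Classical MDS
itself is the textbook double-centering eigendecomposition:
`B = -1/2 J delta^2 J`, coordinates are the top-`d` eigenvectors scaled
by the square roots of their eigenvalues. Negative eigenvalues (possible
for non-Euclidean inputs) are truncated, with their relative mass kept as
a diagnostic. Since any MDS solution is defined only up to
rotation/reflection, each axis's sign is canonicalized (largest-magnitude
loading positive) so that downstream regression inputs and plots are
reproducible; all *configuration* comparisons in tests go through
Procrustes alignment or distances.

## Human-derived (crowd-kernel) embedding

Triadic judgments are modeled by the crowd-kernel ratio likelihood: for
anchor `a` and options `b`, `c`,

    P(b chosen) = (mu + |x_a - x_c|^2) / (2 mu + |x_a - x_b|^2 + |x_a - x_c|^2).

`mu > 0` (default 0.1) regularizes the ratio — as `mu` grows all choices
tend to a fair coin; as `mu` shrinks the model approaches the pure
distance-ratio rule. The default is the package's own choice, exposed in
the configuration and swept in tests rather than asserted as canonical.

Coordinates are estimated by full-batch gradient descent on the total
negative log likelihood with backtracking step-halving (a step is accepted
only if the loss does not increase, so the accepted-loss trace is
monotone by construction), the best of 3 random restarts by train loss.
With a few hundred items, full-batch descent is faster and exactly
reproducible, which stochastic optimizers are not. 10% of trials (default)
are held out before fitting; an embedding is scored by the fraction of
held-out triplets whose chosen option lies strictly nearer the anchor,
with exact distance ties scoring one half (unbiased under the null).
Dimension selection fits 1–5 dimensions on one shared split and keeps the
dimension with the best holdout accuracy, ties toward the smaller model.

Two statistical points discovered during development are worth recording.
First, the likelihood saturates in scale: even for noiseless judges the
ratio rule cannot assign probability one, so the maximum-likelihood
configuration slightly distorts distances to match choice *probabilities*
rather than orderings; holdout accuracy near 0.9, not 1.0, is the
expected ceiling at ~30 triplets per item. Second, a point configuration
along a circular arc of at most a semicircle is *ordinally
one-dimensional*: chord distance is monotone in arc separation, so a 1D
embedding can satisfy almost all triplet constraints. The generator's
developmental manifold (below) is exactly such an arc, which is why the
dimension-selection validation uses a full-rank planted plane, while
recovery validation uses the generator's manifold.

## Quality-rank and checklist scores

The quality-rank score is the raw win proportion — wins divided by
appearances over all pairwise "better drawing" trials including the
drawing. No strength model is fitted by default (the win proportion *is*
the metric); a Bradley–Terry estimator is included as a clearly labeled
diagnostic. Drawings never sampled into a pair get a missing score rather
than zero, because "never shown" and "always rejected" must not be
conflated. With balanced appearances the appearance-weighted mean score
is exactly one half (every trial produces one win and two appearances).

The checklist score is the count of detected items per rater (0–12, items
head through clothes), and the final score is the mean of the two raters.
Inter-rater reliability is the Pearson correlation between the raters'
per-drawing totals; an explicitly labeled per-item variant (mean of the
12 per-item correlations) is also provided since "by-item" is ambiguous
in common usage.

## Structure comparison

Embedding spaces are compared by (i) nearest-neighbor overlap: the
fraction of drawings whose single nearest neighbor in one space falls in
the other space's top-K (default 10) for the same referent, reported in
both directions, with null level `K/(k-1)` for independent spaces;
(ii) cross-space coordinate regressions, each axis of one 2D space
regressed on both axes of the other plus their interaction; (iii) a
checklist-prediction ladder over six models (quality only, each embedding
only, quality x human, quality x machine, and quality x human + quality x
machine with full interactions within each pairing — the five-way full
factorial was rejected as over-parameterized for cohorts of a few hundred
drawings, and the chosen form preserves the nesting of the comparison
chain); and (iv) Pearson correlations between the upper triangles of
inter-drawing distance matrices, where the checklist's distance is the
absolute score difference (a valid 1D metric). Distance pairs are not
independent, so a Mantel-style permutation p-value is available as a
labeled extra; the plain correlation is the primary output.

Only the distance-based statistics (neighbors, overlap, distance
correlations) are invariant to rigid transforms of the embeddings, and
the tests assert exactly that. Coordinate-wise regressions are
axis-dependent by construction — rotating a space redistributes variance
across its axes — which is why axis-sign canonicalization matters for
their reproducibility.

## Outcome-model harness

Drawings are the analysis unit; participants contributing several
drawings appear once per drawing (participant ids are carried so
cluster-aware variants can be built on top). The ladder per outcome:

1. **baseline** — outcome ~ checklist + covariates;
2. **quality** — outcome ~ quality + covariates, with the increment over
   the checklist tested by comparing a model containing both metrics and
   their interaction against the baseline (nested ANOVA); the better
   step-1 metric is retained for subsequent steps;
3. **human / machine** — retained metric * (both embedding coordinates) +
   covariates, each compared to the step-1 reference;
4. **both** — both embedding blocks, compared to the better single
   embedding. This step is guarded: it is fitted only when its parameter
   count stays below one tenth of the sample size, which reproduces the
   customary omission of the joint model for the smaller outcome subsets.

For continuous outcomes the fits are OLS, reporting multiple and adjusted
R² (`1 - (1 - R^2)(n - 1)/(n - p - 1)`) and nested F-tests verified in
tests against the textbook residual-sum form. Age is log-transformed in
the demographic analysis (errors on non-positive ages); the other
sociodemographic factor is the covariate. For the motor/ASQ analyses the
covariates are age, gender and their interaction, untransformed age. For
binary outcomes the fits are logistic, step significance is the
likelihood-ratio chi-square on full-data fits (the standard deviance
ANOVA for GLMs), and predictive performance is the mean AUC over 100
random 90/10 splits; AUC uses the rank (Mann–Whitney) formulation with
ties counted one half and is tested against exhaustive pair enumeration.
Folds are drawn once and shared across ladder steps; a fold is redrawn if
its training part lacks a class or its test part is single-class.
Significance stars use the conventional 0.05/0.01/0.001 thresholds, and
no multiple-testing correction is applied across outcomes by default.

One calibration subtlety: repeated-holdout fold AUCs are strongly
correlated because they resample one dataset, so the across-fold standard
error understates the variance of the mean AUC. Null calibration of the
AUC is therefore evaluated across independently shuffled datasets.

## The synthetic-study generator

The generator's defaults are the study conditions. A cohort of 154
participants (129 children aged 22–106 months, 25 young adults), 53%
female, each contributing 1–3 drawings (weights 57/15/57 for children,
emulating the observed multiplicity; 2 for adults), about 300 drawings in
all; defaults for the judgment simulators are 31,832 triplets and 10,107
pairs in the study-scale profile and 3,000/1,500 in the desk profile.

Latent drawing ability is `z(log age) + 0.3 (female - 1/2) + N(0, 0.4)`:
log-age because drawing skill grows fast early and saturates; a gender
effect because higher scores for girls are a robust finding in this
literature. Each drawing's stage (scribble, circle-face, tadpole,
differentiated) comes from thresholding ability plus per-drawing noise
(thresholds -1.0/-0.2/0.7, noise SD 0.3, chosen so a default cohort
populates all four stages with differentiated figures most common).
Checklist part indicators are Bernoulli with logistic probabilities
increasing in ability, item difficulties ordered from head (easiest) to
clothes (hardest), masked by stage gates: scribbles contain no parts,
circle-faces only facial features, tadpoles no trunk, differentiated
figures always have head, body, arms and legs. True quality in [0, 1] is
dominated by stage (steps of 0.25) and refined by the part count, so it
is strictly monotone in stage for fixed noise.

The true perceptual space is a half-circle arc of radius 1.5 traced by
quality — scribbles at one end curving around to differentiated figures —
with Gaussian scatter (SD 0.1) and a gender displacement of 0.15 on the
second coordinate. The displacement plants the empirically motivated
phenomenon that drawing conventions are gendered (hair, clothing) in ways
visible to similarity judges over and above quality; without it, an
embedding-beyond-quality gender effect would not exist in the synthetic
world and the harness's power could not be validated. Triplet judges use
the same crowd-kernel likelihood as the embedder with `mu =
decision_noise` (so parameter recovery is well-posed), with
`decision_noise = 0` special-cased to the deterministic closer-option
limit. Pairwise judges follow a Bradley–Terry-style logistic in true
quality with discrimination 10 by default (sharp but not deterministic).
Checklist raters independently miss present parts at 5% and hallucinate
absent ones at 2%, rates that give per-drawing inter-rater reliability in
the mid-0.9s, as trained raters achieve.

Outcomes are linear in ability plus Gaussian noise, clipped to legal
ranges: five ASQ-style subscales (intercepts 40–45, slopes 3–6, SDs 6,
near-ceiling like real screening instruments, each in [0, 60]), grip
(12 + 6 x ability, SD 3) and pinch (4 + 1.5 x ability, SD 1) in
kilograms-of-force scale. ASQ outcomes are available for a random 42% of
children and strength for 78%, emulating the partial coverage typical of
such cohorts; adults have neither.

What the generator does **not** emulate: real stroke kinematics or
pressure, media differences beyond a label, scanner artifacts, rater
drift or worker-quality variation, ceiling-induced skew beyond clipping,
and any dependence structure among a participant's drawings beyond the
shared ability. Passing tests therefore show that the estimators and the
harness recover planted structure under this model — not that any
particular real-world effect size will replicate.

`simulate_analysis_table()` generates the merged per-drawing analysis
table directly from the latent model (ground truth plus measurement
noise), bypassing rendering and embedding estimation. The power and
type-I calibrations of the harness use it: those properties concern the
regression machinery, and hundreds of full crowd-kernel refits would add
nothing but runtime.

## Problem sizes used in validation

The test suite validates: classical MDS on 50 random planar
configurations of 30 points (Procrustes RMS below 1e-6); crowd-kernel
recovery on 60 manifold drawings with 30 noiseless triplets each across 5
seeds (holdout accuracy and distance Spearman both at least 0.90);
dimension selection on a 50-point full-rank plane across 10 seeds (1D
never selected); null calibrations with 2,000 random-label triplets, 10
label shuffles of a 154-participant cohort, and 1,000 null regressions at
n = 150 (embedding-step rejection rate within [0.03, 0.07] at alpha =
0.05); AUC against enumeration on 200 random small datasets; quality-rank
conservation on 5 simulated judgment sets plus the deterministic-judge
ordering; harness power over 200 study-scale simulations (at least 0.8
for both planted effects); and a desk-scale end-to-end run executed twice
with byte-identical CSV outputs. These sizes are the package's validation
conditions and are stated here so they can be scaled up by anyone wanting
tighter bounds.

## Known limitations

The crowd-kernel likelihood saturates in scale (above), so embeddings
from near-deterministic judges are ordinally faithful but metrically
compressed at large distances. The renderer produces schematic figures —
sufficient for occupancy-style features, far from the variability of real
children's drawings, and any CNN-based extractor will see them as
out-of-distribution. Win proportions from sparse pair sampling are noisy
for rarely shown drawings; the appearance counts are reported so users
can filter. The harness treats drawings as independent units exactly as
the analysis it implements does; with several drawings per participant
the nominal p-values are anti-conservative under strong within-
participant correlation, which is why participant ids are retained
end-to-end.
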