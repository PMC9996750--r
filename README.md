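# sketchlatent

Latent-structure metrics for children's human figure drawings.

For over a century, human figure drawings have been scored with feature
checklists (Draw-A-Man, Draw-A-Child): a rater ticks off which of a fixed
set of parts — head, eyes, nose, mouth, ears, hair, body, arms, legs,
hands, feet, clothes — appears in the drawing. Checklists compress a
drawing to a single number and discard most of its structure. This package
implements, end to end, an analysis that asks how much more a drawing can
tell us about the child who made it, using three alternative metrics:

1. **Machine-derived latent feature vectors.** Each binarized drawing is
   passed through a feature extractor (a deterministic multi-resolution
   ink-occupancy extractor by default; any extractor satisfying the same
   contract, e.g. a CNN penultimate layer, can be plugged in). The k
   feature vectors give a k x k cosine-similarity matrix `S`, converted to
   chord distances `delta_ij = sqrt(2 (1 - s_ij))` and reduced by
   classical multidimensional scaling — eigendecomposition of the
   double-centered squared-dissimilarity matrix — to `d` coordinates per
   drawing.
2. **Human-derived latent feature vectors.** Crowd raters answer triadic
   judgments ("which of these two drawings is more similar to the third?").
   Coordinates `x_1..x_k` are estimated by maximizing the crowd-kernel
   likelihood, in which option *b* is chosen over *c* for anchor *a* with
   probability

   ```
   P(b) = (mu + |x_a - x_c|^2) / (2 mu + |x_a - x_b|^2 + |x_a - x_c|^2)
   ```

   with 10% of trials held out to score each embedding dimensionality
   (1-5) by prediction accuracy.
3. **Quality-rank score.** Crowd raters answer pairwise forced choices
   ("which is the better drawing of a person?"); each drawing's score is
   wins / appearances, in [0, 1].

These metrics are compared with each other and with the mean-of-two-raters
12-item checklist (nearest-neighbor overlap across spaces, cross-space
coordinate regressions, distance-matrix correlations), and fed into a
stepwise nested-model harness predicting participant characteristics:
baseline (checklist) → quality-rank → + human embedding → + machine
embedding → both embeddings, with nested F-tests (linear outcomes,
adjusted R²) or likelihood-ratio tests and repeated-holdout AUC (binary
outcomes, 100 x 90/10 splits, rank-formulation AUC).

Because real drawing studies of this kind are rarely shareable, the
package ships a full synthetic-study generator: participants with ages,
genders, and a latent drawing ability; drawings that progress from
scribbles through circle-faces and tadpole figures to differentiated
figures (procedurally rendered as black-on-white bitmaps); simulated
triplet/pairwise judges driven by a planted 2D perceptual space and a
planted quality; two noisy checklist raters; and outcome scores (ASQ-style
subscales, grip/pinch strength) linearly coupled to ability. Every stage
of the pipeline is testable offline against this ground truth.

## Worked example

```r
library(sketchlatent)

study <- simulate_study(study_config(n_participants = 30L, n_adults = 5L,
                                     media_weights = c(1, 1, 1)),
                        n_triplets = 3000, n_pairs = 1500, seed = 1)

fit <- crowd_kernel(study$triplets, dims = 2, seed = 1)
fit
#> Crowd-kernel ordinal embedding (61 items, 2 dims, mu = 0.1)
#>   train: 2700 triplets, final loss 1145.32 (max iters reached)
#>   holdout accuracy: 0.753 on 300 triplets (0 skipped)

qt  <- quality_rank(study$pairs, drawing_ids = study$drawings$drawing_id)
chk <- checklist_scores(study$raters)
ok  <- !is.na(qt$score)
cor(chk$final[match(qt$drawing_id[ok], chk$drawing_id)], qt$score[ok])
#> [1] 0.90

tab <- simulate_analysis_table(154, seed = 1)
fit_linear_ladder(tab, "log_age", covariates = "gender")
#> Stepwise linear model ladder for 'log_age' (n = 294 drawings)
#>   covariates of no interest: gender
#>   step-1 metric retained: checklist
#>      step   n n_params multiple_r2 adjusted_r2 reference p_value stars
#>  baseline 294        2       0.694       0.692      <NA>      NA
#>   quality 294        2       0.650       0.647  baseline   0.000   ***
#>     human 294        6       0.741       0.736  baseline   0.000   ***
#>   machine 294        6       0.742       0.736  baseline   0.000   ***
#>      both 294       10       0.745       0.735   machine   0.513
```

Reading the ladder: the checklist alone explains 69% of the variance in
log age; the quality-rank score carries significant information beyond it
(the `quality` row's p-value tests the increment of a checklist x quality
model over the baseline); either embedding adds significant variance over
the retained step-1 metric; adding the second embedding on top of the
first does not (p = 0.51) — both embeddings capture overlapping extra
structure, mirroring the qualitative pattern such analyses show on real
cohorts. The holdout accuracy of 0.753 reflects the simulated judges'
decision noise (`decision_noise = 0.1`); noiseless judges give ~0.94.

The whole pipeline — generation, rendering, image prep, both embeddings,
quality scores, structure comparison, outcome ladders — runs with one
call:

```r
res <- run_all(run_config("desk"), out_dir = "my_run")
res$tables3_4      # per-outcome ladder summaries
```

which writes `participants.csv`, `triplets.csv`, `embedding_human.csv`,
`quality.csv`, `table1_cross_space.csv`, `tables3_4.csv`,
`summary_report.json`, and friends into `my_run/`. Identical configs give
byte-identical CSVs. `ingest_real()` loads an externally collected study
(PNG manifest + judgment/covariate CSVs) into the same pipeline.

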