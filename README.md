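# fuccicycle

Continuous cell-cycle phase from paired FUCCI imaging and single-cell
RNA-seq.

## The problem

Single-cell RNA-seq studies usually handle the cell cycle by binning cells
into the discrete phases G1, S and G2/M, although progression through the
cycle is continuous and most cells in an asynchronous culture sit between
the textbook states. When FUCCI reporter fluorescence (EGFP–geminin, which
accumulates through S/G2/M, and mCherry–CDT1, which accumulates through
G1) is imaged on the *same* cells that are sequenced, every cell gets a
continuous phase label, and expression can be modeled — and later
predicted — as a function of that label.

`fuccicycle` implements the full workflow for labs with such paired data,
and for anyone who wants a trained predictor of continuous phase:

* **Imaging**: nucleus detection in DAPI images and background-corrected
  log-sum fluorescence scores per channel
  (`detect_nuclei()`, `score_channel()`, `score_cell()`, `score_wells()`).
* **Phase**: plate-effect correction of the scores
  (`score ~ plate + individual`, sum-to-zero, Type III F-tests), circular
  phase as the quadrant-aware inverse tangent of the centered
  (EGFP, mCherry) pair, and a PAM-based discrete G1/S/G2M labeling
  (`correct_batch()`, `infer_fucci_phase()`, `classify_pam()`).
* **Expression**: sample/gene QC filters on a metrics table, CPM with
  pre-filter library sizes, and per-gene quantile normalization to a
  standard normal (`apply_sample_filters()`, `apply_gene_filters()`,
  `compute_cpm()`, `quantile_normalize()`).
* **Cyclic trends**: for each gene a periodic mean curve
  f̂_g(θ) estimated by order-2 (quadratic) trend filtering,

      minimize  ½ Σᵢ (yᵢ − βᵢ)² + λ ‖D⁽³⁾β‖₁,

  on the phase-ordered series concatenated three times (the middle third
  is kept, enforcing continuity at 0/2π), with 5-fold ordered
  cross-validation and the one-SE rule for λ; fits are scored by PVE and
  tested by a permutation null built from a low-dropout template gene
  (`fit_cyclic_trend()`, `cv_select_lambda()`, `permutation_test()`,
  `enrichment_odds_ratio()`). The solver is the package's own
  ADMM with an exact total-variation proximal step (C++, `src/`).
* **Prediction**: a naive-Bayes predictor — per-gene Gaussian likelihoods
  N(f̂_g(θ), σ̂_g²) multiplied across genes and maximized over K = 100
  equally spaced candidate phases; evaluated by the circular error
  min(|Δ|, 2π − |Δ|)/2π (range 0–50% of the cycle, random guessing
  averages 25%) under leave-one-individual-out cross-validation
  (`train_predictor()`, `predict_phase()`, `circular_error()`,
  `cross_validate_by_individual()`).
* **Adapters** for comparing other tools' outputs: cyclic orderings to
  equidistant angles, 2- or 3-column phase scores to angles,
  per-class misclassification rates, and PVE of the FUCCI scores under a
  candidate phase (`ordering_to_angles()`, `scores_to_angles()`,
  `misclassification_rates()`, `pve_of_scores_given_phase()`).
* **Synthetic data**: a seeded generator of paired ground truth — phases,
  cyclic expression on normalized and count scales, FUCCI scores with
  plate/individual structure, channel images, and binomial thinning
  (`simulate_truth()`, `simulate_cyclic_expression()`,
  `simulate_fucci_scores()`, `simulate_channel_images()`,
  `thin_counts()`).

A thin command-line interface over these functions is installed at
`exec/fuccicycle` with subcommands `qc`, `score-images`, `fucci-phase`,
`cyclic-genes`, `train`, `predict`, `crossval`, `simulate` and
`benchmark-adapt`.

## Worked example

A complete synthetic experiment — simulate paired data, correct batch
effects, infer phase, find cyclic genes, train and cross-validate the
predictor:

```r
library(fuccicycle)

truth <- simulate_truth(n_cells = 300, n_genes = 50, n_cyclic = 10, seed = 1)
expr <- simulate_cyclic_expression(truth)
scores <- simulate_fucci_scores(truth$cells$theta_true,
                                truth$cells$plate_id,
                                truth$cells$individual_id,
                                plate_offsets = c(plate_01 = 0.3, plate_02 = -0.1,
                                                  plate_03 = 0.2, plate_04 = -0.4),
                                seed = 2)

corrected <- correct_batch(scores)
theta <- infer_fucci_phase(corrected)
mean(circular_error(theta, truth$cells$theta_true))
#> [1] 0.0149

attr(classify_pam(corrected), "counts")
#> labels
#>  G1   S G2M
#>  94 101 105

qn <- quantile_normalize(compute_cpm(expr$counts, colSums(expr$counts)),
                         seed = 1)
report <- permutation_test(qn, theta, B = 200, seed = 3,
                           detection_rates = rowMeans(expr$counts > 0))
head(report[order(report$rank), ], 5)
#>      gene_id   pve empirical_p rank
#> 10 gene_0010 0.802     0.00498    1
#> 5  gene_0005 0.779     0.00498    2
#> 9  gene_0009 0.776     0.00498    3
#> 7  gene_0007 0.759     0.00498    4
#> 1  gene_0001 0.753     0.00498    5

model <- train_predictor(qn, theta, cyclic_report = report, n_genes = 5)
cross_validate_by_individual(qn, theta, truth$cells$individual_id,
                             gene_ids = model$genes)
#>   individual n_genes n_cells mean_error      se
#> 1    NA18500       5      50     0.0299 0.00280
#> 2    NA18501       5      50     0.0250 0.00344
#> 3    NA18502       5      50     0.0313 0.00311
#> 4    NA18503       5      50     0.0321 0.00349
#> 5    NA18504       5      50     0.0293 0.00282
#> 6    NA18505       5      50     0.0296 0.00318
```

Reading the output: the inferred FUCCI phase lands within 1.5% of the
cycle of the generating phase; the ten planted cyclic genes top the
permutation ranking (the five shown all reach the minimum attainable
p-value 1/201 at B = 200, i.e. their PVE beat every permuted-null fit);
and a five-gene predictor trained on five synthetic individuals places
held-out cells from the sixth within ~3% of the cycle on average
(random guessing would give 25%).

Models serialize to versioned JSON and round-trip exactly:

```r
serialize_model(model, "model.json")
predict_phase(qn[, 1:3], deserialize_model("model.json"))
```

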