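# vfarch — archetypes of binocular visual field loss

`vfarch` is an R package for studying *patterns* of binocular visual-field
(BVF) loss in glaucoma and their relation to vision-related quality of
life (VR-QoL). It is written for researchers working with standard
automated perimetry (Humphrey 24-2) and patient-reported outcomes, and it
covers the full analysis chain:

1. **Binocular integration** — paired monocular 24-2 tests from one visit
   are combined pointwise by quadratic summation,
   `B = sqrt(R² + L²)`, over the 52 locations shared by the two eyes,
   giving the integrated visual field (IVF), its mean sensitivity and the
   binocular foveal sensitivity.
2. **Quality control** — reliability filtering (unreliable iff FP > 10%,
   or FN > 10% with fixation losses > 20%), selection of the most recent
   reliable visit (patients with fewer than two reliable visits are
   excluded), and a homonymous-defect screen that flags pairs with high
   vertical-midline asymmetry *and* high interocular correlation for
   human review.
3. **Archetypal analysis** — each IVF is represented as a convex mixture
   of K archetypes (Cutler–Breiman), themselves convex mixtures of
   observed fields: `X ≈ W Z`, `Z = C X`, with simplex-constrained rows
   solved by augmented non-negative least squares plus an exact
   equality-constrained refit (Rcpp/Armadillo core). K is selected by
   10-fold cross-validation with a BIC slope criterion. Every
   decomposition's weights sum to 100%.
4. **QoL association** — questionnaire items (43-item default map, scored
   0–100 NEI-VFQ-style, 37 modelled aspects) are regressed on the
   archetype weights (archetype 1, the normal reference, excluded) with
   age, gender and binocular foveal sensitivity as covariates, via
   proportional-odds ordinal regression; significance is
   Bonferroni-corrected at 0.05/43. Expected scores can be predicted per
   patient.
5. **Synthetic data** — a first-class generator produces monocular pairs
   whose binocular combination is a noisy convex mixture of known defect
   templates, homonymous pairs, reliability metadata, and questionnaire
   responses from a known proportional-odds model, with full ground truth.

## Worked example

```r
library(vfarch)

# a synthetic cohort with 3 true defect templates, plus questionnaires
sim <- simulate_cohort(200, k_true = 3, noise_sigma = 1, seed = 42,
                       out_dir = "demo")
qol <- simulate_qol(sim$truth, seed = 42)
write.csv(qol, "demo/qol.csv", row.names = FALSE)

cfg <- pipeline_config(vf_csv = "demo/vf.csv", meta_csv = "demo/meta.csv",
                       qol_csv = "demo/qol.csv", out_dir = "demo/out",
                       k_min = 2, k_max = 6, folds = 10, restarts = 10,
                       seed = 42)
res <- run_pipeline(cfg)

res$k
#> [1] 3
res$model
#> <archetype_model> K = 3 on 52 locations; training RSS 1.057e+04
#>   best of 10 restarts (restart 8, 13 iterations); seed 42
#>   mean training weights (%): 35.0 32.6 32.4
round(head(res$weights[, -1], 3), 2)
#>         AT1   AT2   AT3   rss
#> P0001  0.00 81.40 18.60 54.58
#> P0002  0.00  5.10 94.90 55.09
#> P0003 50.69  1.08 48.23 64.81
```

Cross-validation recovered the true number of archetypes (K = 3). The
weights table reads naturally: patient `P0001` is 81% archetype 2 and 19%
archetype 3 with no normal component; the residual `rss` is the squared
reconstruction error left after the convex fit (~52 here, i.e. the ~1 dB
per-location noise floor of the generator). The association stage then
relates weights to the simulated questionnaire:

```r
tab <- res$assoc$table
head(tab[which(tab$significant), c("aspect", "predictor", "estimate", "p")])
#>                aspect predictor estimate        p
#> 1     near_activities       AT2  -0.0512 5.78e-19
#> 2     near_activities       AT3  -0.0431 6.13e-15
#> 3     near_activities       age  -0.0598 6.45e-06
#> 6 distance_activities       AT2  -0.0439 3.72e-15
#> 7 distance_activities       AT3  -0.0503 4.77e-18
```

Coefficients are log-odds per percentage point of archetype weight (or per
year of age); negative means worse reported function. The generator's true
per-percent effect was −0.03 on each defect archetype with −0.02/year of
age, so the recovered signs and magnitudes are in range. `res$predicted`
holds per-patient expected scores on the 0–100 scale (e.g. 30.8 for
patient `P0001`'s near-activities aspect — a heavily affected field).

A command-line interface wraps the same stages
(`simulate`, `qc`, `integrate`, `fit`, `select-k`, `decompose`,
`associate`, `predict`, `run`); see
`system.file("cli", "vfarch.R", package = "vfarch")`.

## Package layout

- `R/grid.R`, `R/vf.R` — 24-2 grid model, monocular/pair/IVF types,
  quadratic summation.
- `R/qc.R` — reliability, visit selection, midline asymmetry, interocular
  correlation, homonymous screen.
- `R/archetypes.R`, `src/archetypes.cpp` — simplex projection,
  alternating fit, cross-validation, BIC selection.
- `R/qol.R` — item map, 0–100 scoring, subscales, proportional-odds
  association, prediction, correlation matrix.
- `R/synthetic.R` — generators with ground truth.
- `R/io.R`, `R/pipeline.R`, `R/cli.R` — CSV/JSON interchange, end-to-end
  pipeline with manifests, CLI.
- `vignettes/binocular-archetypes.Rmd` — the methods vignette (model,
  assumptions, numerical choices, limitations).
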