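---
title: "Methods: archetypes of binocular visual field loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: archetypes of binocular visual field loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Glaucomatous damage is usually measured one eye at a time with standard
automated perimetry on the 24-2 grid, but what a patient experiences — and
what patient-reported outcomes measure — is the *binocular* visual field.
`vfarch` implements a complete analysis chain for studying *patterns* of
binocular field loss and their association with vision-related quality of
life (VR-QoL): integration of monocular pairs into a binocular field,
cohort quality control, archetypal analysis with data-driven model-order
selection, and proportional-odds regression of questionnaire outcomes on
archetype weights. Because the clinical datasets this kind of analysis is
run on are not generally shareable, the package also ships a fully
specified synthetic-data generator, so that every stage is exercised
end-to-end against known ground truth.

# Binocular integration

Each eye's 24-2 test provides 54 located sensitivities in dB; the two
layouts share 52 locations (each eye adds one nasal point at
$x = \pm 27^\circ$ in the $y = \pm 3^\circ$ rows). The binocular
sensitivity at a shared location is the quadratic (Nelson-Quigg) summation

$$B = \sqrt{R^2 + L^2},$$

with $R, L \ge 0$ the raw monocular sensitivities. $B$ is commutative and
satisfies $\max(R,L) \le B \le \sqrt2\,\max(R,L)$. The integrated visual
field (IVF) is the 52-vector of $B$ values; its mean sensitivity (IVF MS)
is the arithmetic mean; the binocular foveal sensitivity applies the same
formula to the two foveal values. Negative imported sensitivities are
clamped to 0 at construction, since the summation has no meaningful
interpretation below the psychophysical floor. Blind-spot locations are
*retained* in the IVF: each is an ordinary point for the fellow eye, and
archetypes with blind-spot-region defects are only expressible if those
columns exist.

# Quality control

*Reliability.* A monocular test is unreliable iff FP $> 10\%$, or FN
$> 10\%$ together with fixation losses $> 20\%$ (strict inequalities; FN
and FL count only jointly because they are weaker reliability markers than
FP). A visit is usable only when both eyes pass. Patients with fewer than
two reliable visits are excluded (the perimetric learning effect makes a
sole first test untrustworthy); among reliable visits the most recent one
is analysed, with date ties broken by stable input order.

*Homonymous screen.* Post-chiasmatic (neurological) defects respect the
vertical midline in the same way in both eyes. Each pair is summarised by
(i) the vertical-midline asymmetry — the mean absolute sensitivity
difference over the 26 mirror pairs with $|x| \le 21$, averaged over the
two eyes — and (ii) the interocular Pearson correlation over the 52 shared
locations. Pairs with both statistics high cluster away from glaucomatous
pairs. The original procedure drew the cluster by expert review; this
package flags at configurable thresholds (defaults 5 dB and 0.6, chosen so
the synthetic homonymous generator is detected with sensitivity 1.0 while
bilateral glaucoma-like fields produce a false-flag rate $\le 5\%$). A
flag marks the pair for human review; it excludes only under an explicit
option. Blind-spot locations are *not* excluded from either statistic
(only the unpaired nasal points drop out, by construction); for real data
this adds a small baseline asymmetry from the physiologic blind spot.

# Archetypal analysis

Archetypal analysis (Cutler–Breiman) represents each field
$x_i \in \mathbb{R}^{52}$ as a convex combination of $K$ archetypes
$z_1,\dots,z_K$, themselves convex combinations of the observed fields:
$X \approx W Z$, $Z = C X$, with the rows of $W$ ($n \times K$) and $C$
($K \times n$) on the probability simplex. Unlike principal components,
archetypes are extreme but *realistic* fields — actual corners of the data
cloud — which is what makes the decomposition clinically readable, and the
weights of a decomposition always sum to 100%.

## The simplex projection

The workhorse is the simplex-constrained least-squares projection
$\min_w \lVert B^\top w - t\rVert^2$ s.t. $w \ge 0, \sum_k w_k = 1$. We
solve it with non-negative least squares on the system augmented by a
constant row of magnitude $M$ (default $M = 200$) — the classical device
that enforces the sum constraint approximately — and then refit the
weights on the discovered support *exactly* under the equality constraint
through the KKT system. The refit matters: the augmented solution alone
deviates from the true constrained optimum by $O(1/M^2)$, which on
dB-scale data is around $10^{-5}$ — larger than the $10^{-6}$ agreement
we require against an independent quadratic-programming oracle. With the
refit, returned weights sum to one to machine precision and match the
oracle to $\sim 10^{-9}$. All solvers operate on Gram matrices, so the
per-field cost is independent of the grid size; inside the alternating
fit, each projection is warm-started from the previous iteration's support
and accepted only if the full KKT conditions verify.

## The alternating fit

Per restart, the composition matrix is seeded from $K$ random data points
and the algorithm alternates: (i) project every field on the current
archetypes (W-step); (ii) solve the unconstrained least-squares problem
for ideal archetypes $\hat Z$; (iii) project each row of $\hat Z$ back on
the convex hull of the data (C-step), giving $Z = CX$; (iv) evaluate
$\mathrm{RSS} = \lVert X - WZ\rVert_F^2$. The classical C-step does not
by itself guarantee a monotone RSS, so an iteration that would increase
it is rolled back and the restart stops there — the reported RSS trace is
non-increasing by construction, which is also asserted in the tests. An
archetype that loses all weight is re-seeded on the worst-reconstructed
field. A restart stops when the relative RSS improvement falls below
`tol` (default $10^{-6}$) or after `max_iter` (default 100) iterations;
the best of `restarts` (default 100, matching the reference procedure;
tests use 10–20) wins on training RSS. Archetypes are reported in
descending order of mean training weight — archetype 1 is therefore the
dominant (in practice near-normal) pattern; any published numbering is
figure-specific and not recoverable, so no attempt is made to match one.

Analysis runs on raw binocular dB vectors, with no normative-deviation
transform: the integration formula and IVF MS are defined on raw dB, and
a "normal" archetype is then free to emerge as the reference corner.

## Choosing the number of archetypes

Patients are partitioned once into `folds` folds (default 10, seeded, the
assignment shared across all candidate $K$). For each $(K,\text{fold})$
the model is fitted on the training folds and scored on the held-out fold
by the mean per-field squared projection residual (per-field normalisation
makes scores comparable across unequal folds; the convention is recorded
in the result). Fold assignment and restart initialisation draw from
independent sub-streams of one top-level seed, so changing the restart
count never changes the folds.

The selection rule follows the BIC slope criterion: at candidate $K$,
regress the pooled fold scores on the archetype count and compare, via
$\mathrm{BIC} = n\ln(\mathrm{RSS}/n) + p\ln n$, against the
constant-only model; the smallest $K$ whose slope is *not* warranted
(positive BIC difference) is selected. One design question is *which*
counts enter each candidate's regression. Pooling **all** counts
$\ge K$ looks natural but is statistically inconsistent for this purpose:
every added archetype buys a small genuine validation improvement by
refining the hull (noise chasing), and the power of the slope test against
that small decline grows with the number of pooled counts — so the rule
over-selects, the more so the wider the scan. On the package's own
calibration cohort (500 patients, 4 true templates, 1 dB noise, counts
2–8) the all-tail window selected $K=5$–6 in 10/10 seeded replicates,
while the *local* window — the `span = 3` counts from $K$ up, asking
exactly the local question "is the score still declining from here?" —
selected the true $K=4$ in 10/10. The local window is therefore the
default; the all-tail variant remains available (`window = "tail"`), and
the window used is recorded alongside the per-candidate BIC differences.
When the score is still declining at the end of the scanned range the
largest count is returned with a warning; a degenerate all-equal table
returns the smallest with a warning.

# Quality-of-life modelling

Questionnaire items are ordinal. After direction alignment (level 1 best),
level $\ell$ of an $L$-level item scores $100(L-\ell)/(L-1)$ — the
standard 0–100 standardisation where higher is better. The shipped default
map has 43 items: 10 grouped into 4 subscales (near activities, distance
activities, driving, social functioning — a subscale scores the mean of
its answered items and replaces them as a modelled "aspect") and 33
standalone items, i.e. 37 aspects. Published instruments assign non-linear
values to some items; the map accepts per-item level counts and direction
so an official mapping can be dropped in, but the shipped default is the
linear ladder.

Each aspect is modelled by a cumulative-logit proportional-odds
regression: the ordered aspect score on the archetype weights in percent
(archetype 1 — the normal reference — excluded: the weights sum to 100%,
so a full set is collinear with the intercepts) plus age, gender (0/1)
and binocular foveal sensitivity. IVF MS is deliberately not a covariate
(strongly collinear with the weights); an option drops the foveal
covariate to reproduce the corresponding sensitivity analysis. The sign
convention makes a positive coefficient mean better scores. Maximum
likelihood and Wald inference are delegated to `MASS::polr` — the
contract is the likelihood, the sign convention and Wald tests, not a
bespoke optimiser. Aspects with fewer than 3 distinct observed scores
fall back to binary logistic regression with a notice; non-convergence is
recorded per aspect without aborting the batch. Significance uses the
Bonferroni threshold $\alpha/n$ with $\alpha = 0.05$ and $n = 43$ applied
to the whole ensemble of aspects, not per questionnaire. Predicted scores
are the probability-weighted means of the observed score categories, so
they always lie inside the observed range.

# The synthetic world

The generator states, with full ground truth, the world the analysis
assumes — it is a first-class, tested module, not a fixture.

* **Normal eye.** Hill of vision $34 - 0.3\sqrt{x^2+y^2}$ dB at age 45,
  declining 0.05 dB/year, test–retest noise $\sigma = 1.5$ dB, clamp
  $[0, 40]$; fovea $35 - 0.05(\text{age}-45)$; blind spot at 0;
  reliability rates $\mathrm{Beta}(2, 30)$ (mean ~6%, mostly reliable).
  These are round, conventional magnitudes for a normal perimetric hill
  and its variability; they are stated once and not tuned.
* **Templates.** Six binocular patterns built from the $\sqrt2$-scaled
  age-45 normal: normal; superior and inferior hemifield depressions
  (−20 dB); superior paracentral defect (−15 dB, $|x|\le 9$,
  $3 \le y \le 9$); general depression (−15 dB); right-blind-spot-region
  loss (−20 dB, $9 \le x \le 21$, $|y| \le 9$); clamped at 0.
* **Cohort.** True field $T = \sum_k w_k\,\text{template}_k$ with
  Dirichlet($\alpha = 1$) weights over the first `k_true` templates;
  every fifth patient forced near-pure (max weight $\ge 0.9$) because
  archetypes are only identifiable if the data visit the vertices.
  Monocular fields are $R = L = T/\sqrt2$ at *all* 52 shared locations,
  so quadratic summation reproduces $T$ exactly at zero noise — this
  identity is the tested contract, which is why the cohort's monocular
  records do not zero the blind spot (the physiologic zeros live in the
  normal-eye and homonymous generators, whose contracts need them).
  Independent $N(0, \sigma^2)$ noise per eye and location (default
  $\sigma = 1$ dB) is added *monocularly*, so the binocular noise is
  realistically sub-additive after summation. Two reliable visits a year
  apart exercise visit selection. Ages Uniform(50, 85), gender
  Bernoulli(0.5). True binocular foveal sensitivity adds a 2 dB
  between-patient spread: without it, templates that spare the fovea make
  foveal sensitivity an exact linear function of age and the regression
  covariates collinear by construction. Draws are streamed per patient,
  so enlarging the cohort preserves earlier patients.
* **Homonymous pairs.** Both eyes from the same normal-eye draw, all
  $x < 0$ locations reduced by `severity_db` (default 25), clamp 0. At
  $\sigma = 1.5$ the interocular correlation measures 0.87–0.92 — far
  above the 0.6 screen threshold.
* **Questionnaires.** Per aspect, latent $\eta = \beta^\top x$ over
  (weights 2..k in percent, age, gender, true foveal), categories sampled
  from $P(\text{cat} \le c) = \mathrm{logit}^{-1}(\theta_c - \eta)$ on
  the best-is-highest ordering, cutpoints at logistic quantiles centred
  on the cohort mean latent; items of a subscale share the latent but are
  sampled independently. Defaults: $-0.03$ per percent on each defect
  archetype, $-0.02$/year of age, 0 for gender, $+0.05$/dB of foveal
  sensitivity — effect sizes in the plausible range for PRO instruments,
  chosen once.

**What the generator does not emulate** — and hence what a green test does
not establish: eccentricity-dependent response variability and
frequency-of-seeing floors; learning and fatigue effects; asymmetric
disease between the eyes (an option can shift defect mass, but the default
is symmetric); richer defect geometry than six templates (arcuate and
nasal-step patterns are absent); non-linear published item values;
informative missingness in questionnaires. Passing the recovery tests
shows the *method* works in the stated world, not that twelve specific
clinical archetypes would be reproduced.

# Numerical choices

* Penalty $M = 200$ (classical magnitude), with exact KKT refit making
  results insensitive to it; tolerance $10^{-6}$ relative RSS;
  `max_iter` 100; restarts 100 by default.
* NNLS gradient tolerances are scaled by the magnitude of the
  normal-equation right-hand side; warm-started supports are accepted
  only when primal and dual feasibility verify at $10^{-8}$ relative.
* Restart ties on RSS break toward the earlier restart; archetype
  display order ties are resolved by `order`'s stable sort.
* Model JSON is written with 17 significant digits, so a round-trip
  reproduces decompositions bit-for-bit in practice (tested at
  $10^{-12}$).
* Degenerate inputs: zero-variance eyes make the interocular correlation
  undefined (`NA` with a warning, never silently flagged); an archetype
  with no weight is re-seeded; an empty NNLS support falls back to the
  single nearest basis row.
* Seeds: one top-level integer; folds, restarts and per-patient
  simulation streams are derived through a fixed 31-bit mixing function,
  so results are reproducible and order-insensitive.

# Known limitations

The package analyses raw-dB fields only (no total/pattern deviation, no
30-2/10-2 layouts, no vendor XML/DICOM ingestion). The homonymous screen
only *flags* — distinguishing chiasmatic from pre-chiasmatic defects is
out of scope. The BIC window choice, while empirically motivated here, is
a heuristic: on real cohorts the selected K should be read alongside the
full score-versus-K curve, which `crossvalidate_k` returns in full.
Prediction of individual VR-QoL scores from archetype weights is
association-grade, not a validated clinical predictor.
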