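---
title: "Methods: co-expression scoring, synergy analysis and growth modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression scoring, synergy analysis and growth modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcsynergy)
```

This vignette is the package's own account of the statistical machinery:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the design was
genuinely open.

## 1. The mIF quantification cascade

The atom is a segmented cell with an ordinal staining class per marker
(0 = negative, 1 = weak, 2 = moderate, 3 = strong) for B7-H3, PSMA and
STEAP1. Three conventions anchor everything downstream:

* **H-score.** `H = 1·pct_weak + 2·pct_moderate + 3·pct_strong`,
  percentages on the 0–100 scale, so `H ∈ [0, 300]` and
  `H ≥ 100·(positive fraction)`.
* **Positivity pools weak and stronger.** A cell is positive when it
  stains at least weakly; co-positivity requires joint positivity. Every
  co-positive fraction therefore obeys the Fréchet bounds
  `[max(0, p1+p2−1), min(p1, p2)]`, and triple positivity is bounded by
  every pairwise value — both are enforced as property tests.
* **The cascade averages upward.** Core metrics are unweighted means over
  cells; tumor metrics are unweighted means over the tumor's cores
  (triplicate cores averaged per site); a tumor is double-positive for a
  pair when its *averaged* co-positive fraction reaches τ.

τ defaults to 0.20 — the 20 %-of-cells co-staining rule — and the
comparison is inclusive (`≥ τ`), so a fraction of exactly 0.20 is
positive. Applying τ to the core-averaged fraction (rather than calling
cores individually) keeps tumor classification and intra-tumoral
heterogeneity (below) from double-using the same thresholding; per-core
fractions are retained for the heterogeneity analysis.

Cohort percentages are reported rounded to one decimal
(`pct1(num, den)`); internal computation keeps full precision.

Phenotype comparisons of tumor-averaged H-scores use two-sided
Wilcoxon–Mann–Whitney tests with Holm's step-down adjustment. The exact
null distribution is enumerated when the combined sample size is ≤ 10
and there are no ties; otherwise the midrank normal approximation with
tie-corrected variance is used. The switch point is a convention (the
reference analysis does not state one); completely tied groups carry no
rank information and are reported as p = 1.

## 2. Heterogeneity indices

Within a *unit* — a patient whose samples are its tumor-level co-positive
fractions, or a tumor whose samples are its core-level fractions — the
index is the fraction of unordered sample pairs with discordant
positivity (one sample < τ, the other ≥ τ). With `k` of `n` samples
positive this equals `k(n−k)/C(n,2)`, which the tests verify against
exhaustive pair enumeration. Units with fewer than two samples are
non-informative and excluded.

Design choices that were genuinely open:

* **Estimator.** The reference figure labels its summary a
  "hypergeometric mean", an estimator name with no accompanying formula.
  This package uses the arithmetic mean of per-unit indices — a
  documented decision, not an inference of the original intent. Units
  are equally weighted by default; weighting by a unit's number of pairs
  is available (`weighting = "pair"`).
* **Bootstrap.** Percentile CI from B = 2000 resamples drawn over whole
  units with replacement. Resampling units (not pairs) respects the
  clustering of samples within patients/tumors; whether the original
  analysis resampled pairs or units is unstated.
* The sampling units themselves (tumors within patient for
  intra-patient; cores within tumor for intra-tumoral) mirror
  "different metastatic sites in a given patient" and "within a
  metastatic site".

## 3. Screen normalization and Bliss nomination

Plate wells are normalized against their own controls:
`v = (RLU − μ_pos)/(μ_veh − μ_pos)`, clipped to [0, 1]; `e = 1 − v`.
Anchoring on both vehicle and positive-control (staurosporine-class
maximal kill) wells makes the scale affine-invariant — rescaling all
luminescence leaves effects unchanged — and is a decision: the exact
normalization behind the reference screen figure is not given.
Replicate wells are averaged after normalization; `μ_veh ≤ μ_pos` is a
degenerate-controls error.

Nomination operationalizes "toxicity greater than the amplification of
individual effects" as a **Bliss excess**: pair (A, B) in a line has
excess `e_AB − (e_A + e_B − e_A·e_B)`, and is nominated when its agents
belong to different pharmacological subgroups and the excess is ≥ δ in at
least `min_lines` lines (defaults δ = 0.10, `min_lines` = 2). δ is a
margin on the fraction-affected scale chosen to sit well above
plate-noise-induced excess (at the default 5 % CV and triplicate wells
the excess SD is ≲ 0.03 for mid-range effects) while remaining far below
deliberately implanted interactions (0.25 in the recovery experiments).
Candidates are ranked by total excess across lines.

## 4. Median-effect fitting and the combination index

The median-effect model `fa/(1−fa) = (D/Dm)^m` is linear on double-log
axes; the fit is ordinary least squares of `log10(fa/(1−fa))` on
`log10 D`, with `m` the slope, `Dm = 10^(−intercept/m)`, and `r` the
correlation of the linearized fit. Numerical choices:

* Points with `fa` outside `[ε, 1−ε]`, ε = 0.005, are **dropped** (not
  winsorized): a point clipped to the boundary would enter the
  regression with arbitrarily extreme leverage on the logit scale, while
  fully affected/unaffected wells genuinely carry no information about
  the slope.
* A non-positive fitted slope is flagged (`noncytotoxic`) with a
  warning rather than an error — screens legitimately contain inactive
  agents.
* Noise-free model-generated curves must be recovered to machine
  precision (the fit is an exact inverse of the generator); this is a
  frozen test.

For a constant-ratio combination the combination curve is fitted on
total dose; at each grid `fa`, the total dose is split by the (constant)
ratio into `(d1, d2)` and

`CI(fa) = d1/DxA(fa) + d2/DxB(fa)`, `Dx(fa) = Dm·(fa/(1−fa))^(1/m)`.

This is the mutually-exclusive (Loewe-form) index, the dominant modern
usage; the non-exclusive form adding `(d1·d2)/(DxA·DxB)` is available via
`form = "nonexclusive"`. The summary CI is reported at `fa = 0.5` (ED50)
with the grid mean alongside, because published single-number CI values
rarely state their `fa`; classification uses a ±0.05 additivity band
around 1 so that near-unity indices are not over-read. The strongest
end-to-end oracle in the test suite is the *sham combination*: a drug
combined with itself at split doses must give CI = 1 at every `fa` to
1e−9.

## 5. The growth model

`log V ~ group + day:group + (1 | animal)`, REML, is the random-intercept
exponential-growth model: one log-linear slope per treatment arm, shared
measurement-error variance, and per-animal intercepts absorbing both
enrollment-volume spread and any constant rescaling of volumes (the fit
is provably invariant to multiplying all volumes by a constant). The
parameterization with `day:group` and no `day` main effect is an exact
reparameterization of `day + group + day:group` that exposes per-group
slopes directly.

* Volumes are analyzed on the natural-log scale; the base is irrelevant
  after back-transform but is used consistently.
* A group slope `s` is reported as `100·(exp(s)−1)` % per day; its CI is
  the monotone transform of the slope CI.
* Contrasts are tested on the slope scale with Satterthwaite degrees of
  freedom (`lmerTest::contest1D`) and reported as differences of daily
  percentages `100·(exp(s1)−exp(s2))` with a delta-method CI — the scale
  on which treatment effects like "reduced the daily growth rate by 2–3
  points" are stated.
* `growth_report()` renders CI bounds rounded to whole percentage points
  ("9-10% per day"), labelling the range explicitly as a confidence
  interval — published range statements often do not say which they are.

Degenerate designs (no within-animal replication, a group with < 2
animals or < 2 timepoints, non-positive volumes, an animal in two
groups) are rejected with specific errors.

## 6. What the synthetic generator emulates — and what it does not

The generator exists so that every stage has a recovery test against
known truth; its defaults are the package's fixed study conditions.

**mIF cohort.** 58 patients, 2–4 tumors each (~3 on average, i.e.
~170–180 tumors), 3 cores per tumor, 200 cells per core. Marker classes
are drawn from per-phenotype multinomials through a latent Gaussian
copula: cell-level latent normals are equicorrelated with correlation
ρ (`copositivity_coupling`), shifted per tumor (`tumor_sd = 0.5`) and per
core (`core_sd = 0.2`) on the probit scale. Consequences:

* ρ = 0 gives independent markers (co-positivity = product of
  marginals); ρ = 1 is comonotone (co-positivity attains the upper
  Fréchet bound). With three markers the equicorrelation must exceed
  −1/2, so the admissible range is (−0.5, 1]; the lower Fréchet bound is
  approached but not attained jointly for all pairs.
* The tumor/core shifts make expression vary across metastatic sites
  and within them, which is what gives the heterogeneity indices
  non-degenerate targets (intra-patient ≈ 0.2–0.35, intra-tumoral
  ≈ 0.08–0.13 at the defaults, the observed order of magnitude in
  multi-site autopsy cohorts).
* Per-cell class frequencies within a phenotype are free parameters —
  no public per-cell table exists to calibrate them. The defaults were
  chosen once so that AR-active tumors have roughly one-third of cells
  double-positive for each pair and a clear majority of AR-active
  tumors above the 20 % threshold, with PSMA largely lost in the
  neuroendocrine phenotype.
* The truth table carries the *exact* generating fractions per tumor
  (orthant probabilities of the shifted copula, computed by quadrature),
  so recovery tests compare estimates to analytic truth, not to another
  simulation.

**Screen.** 23 agents in 13 pharmacological subgroups across three
payload classes; the 13 subgroup representatives form C(13,2) = 78
pairs. Singles at two doses and pairs at low dose in triplicate wells
plus 6 vehicle and 6 positive-control wells fill a 384-well plate
exactly (23·2·3 + 78·3 + 12 = 384). RLU is
`baseline·(1 − effect)·lognormal(CV)` with CV = 0.05 — the
positive-valued, roughly constant-CV error structure of ATP-based
viability assays. Single-agent low-dose effects default to U(0.30, 0.85)
per agent × line: screening concentrations are pre-selected to be
effective, so near-null effects are not part of the design. The positive
control is modeled at effect 0.999 rather than 1.0 so control wells keep
strictly positive luminescence; the resulting 0.1 % normalization bias
is negligible against assay noise. High-dose effects follow
`1 − (1−e_low)²` (two low doses' worth of independent kill). Combination
effects are Bliss plus any configured excess, clipped to [0, 1] —
implanted excesses should therefore be placed on mid-range singles in
recovery experiments (the 0.25-excess pair uses singles of 0.45), since
an excess pushing past complete kill is physically unobservable.

**Dose-response and growth.** Curves are generated by inverting the
median-effect model with lognormal viability noise. Growth studies use
a four-arm design (vehicle 9.5 %/day, Bcl-xL inhibitor 6.5 %, ADC 3.5 %,
combination 1.5 %), 7 animals per arm, measurements every other day for
four weeks from ~100 mm³ enrollment, intercept SD 0.25 and residual SD
0.10 on the log scale — magnitudes typical of subcutaneous CDX studies.

**Not emulated:** image formation, segmentation and unmixing (the
pipeline starts from classified cells); spatial structure within cores
(cells are exchangeable, so neighborhood heterogeneity is out of reach);
pharmacokinetics, drug-antibody-ratio chemistry, and any mechanism of
apoptosis; dropout or attrition in animal studies. Passing recovery
tests on this generator therefore demonstrates the *estimators* are
correct and calibrated under the stated noise models — not that real
staining, screening or caliper data obey those models.

## 7. Problem sizes used in the test suite

Tests run the full cohort at reduced cell counts where the assertion
does not need precision (e.g. 8–58 patients, 20–500 cells per core), 100
seeds for median-effect and nomination recovery, 500 replicates of a
two-arm, 6-animal growth design for CI-coverage calibration
(92–98 % acceptance window around the nominal 95 %), and B = 300–1000
bootstrap replicates where only CI behavior (not its third decimal) is
under test. These sizes are the package's chosen trade-off between the
sharpness of each statistical assertion and keeping the suite quick to
run during development.

## 8. Known limitations

* The heterogeneity point estimator is a documented stand-in for an
  undefined published summary ("hypergeometric mean"); absolute values
  may not be comparable to the original figure, though orderings across
  pairs and levels are.
* CI values are only as good as the three median-effect fits behind
  them; strongly non-sigmoidal curves (mixed cell populations, biphasic
  responses) violate the model for single agents and combinations alike.
* The Bliss-excess nomination margin δ and the CI additivity band are
  conventions; sensitivity of nominations to δ should be reported
  alongside any real-screen analysis.
* The growth model assumes log-linear growth over the observation
  window; regrowth after treatment cessation or early plateaus call for
  piecewise or nonlinear extensions that are out of scope here.
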