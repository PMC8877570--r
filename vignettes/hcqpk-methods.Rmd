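---
title: "Population pharmacokinetics of whole-blood hydroxychloroquine and its metabolites: models and methods"
author: "hcqpk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of whole-blood hydroxychloroquine and its metabolites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcqpk)
```

## The problem

Hydroxychloroquine (HCQ) given orally to hospitalized adults is cleared
partly unchanged and partly through CYP2D6 into three metabolites:
desethylchloroquine (DesCQ), desethylhydroxychloroquine (DesHCQ) and
didesethylchloroquine (DiDesCQ). Whole-blood concentrations of all four
compounds are measured sparsely — typically one to nine therapeutic-drug-
monitoring samples per patient taken near the every-second-day clock — and
the clinical question is whether early exposure (the pre-dose "trough"
concentration 48 h and 72 h after the first dose) predicts outcomes such as
the length of hospital stay.

`hcqpk` provides the full modelling chain for this setting: a structural
compartment model, a nonlinear mixed-effects population layer, approximate
maximum-marginal-likelihood estimation, dosing-regimen simulation,
simulation-based diagnostics (VPC, NPDE), a synthetic-cohort generator with
known ground truth, and the exposure–outcome analyses.

## Structural model

Five compartments: an oral depot and one disposition compartment per
compound. Absorption is first order (`ka`, fixed at 1.15 h⁻¹) after a lag
(`lag`, fixed at 0.389 h); both are literature-fixed constants because
trough-biased sampling carries almost no information about the absorption
phase. The parent compartment loses drug by a direct apparent clearance
CL/F (`cl_parent`) and three formation clearances into the metabolite
compartments; each metabolite is eliminated by its own clearance. All
compartments share the parent apparent volume VP/F (`v`); the metabolite
volume is not separately identifiable from metabolite concentration data
alone, so VM/F ≡ VP/F. No parent peripheral compartment and no saturable
(Michaelis–Menten) elimination are modelled. The system is linear and
lower-triangular, so the multi-dose solution is a superposition of
closed-form exponential cascades; when two rate constants nearly coincide
(relative gap < 1e-9) the closed form is singular and the solver switches
to a scaling-and-squaring matrix exponential.

Doses are labelled milligrams converted to micromoles with the free-base
molar mass of HCQ (computed from the molecular formula); any salt-to-base
factor is absorbed into the apparent (/F) parameters, which is why absolute
bioavailability cannot be inferred. Each formation path converts one mole
of parent into one mole of metabolite, which is the reason the model works
internally in µmol/L; µg/L appears only at the I/O surface, converted per
compound by molar mass.

A derived quantity of interest is the fraction of parent drug converted to
the metabolites,

FM = Σ CLform / (CL/F + Σ CLform),

which is 0.746 (75%) at the package's reference estimates.

## Population layer

Between-subject variability is log-normal ("exponential") on five
parameters: CL/F, VP/F and the three metabolite clearances. The reported
ω values are interpreted as standard deviations of the log-scale random
effects, the usual reporting convention; under this reading the median
(not the mean) of an individual parameter equals its typical value, which
the tests verify by Monte Carlo. No off-diagonal (correlated) random
effects are modelled. Residual error is combined proportional plus
additive per compound, `var = (prop·f)² + add²`, with the additive SDs
quoted in µg/L and converted to µmol/L before use. Simulated observations
are *not* truncated at zero where they feed estimation-type machinery
(VPC, NPDE) — truncation would distort the additive-normal assumption —
but are floored at zero wherever a physical concentration table is
produced (written datasets, trough summaries).

## Estimation

The objective is −2 times an approximate log marginal likelihood of the
FOCE-with-interaction family: for every subject the joint density of
observations and random effects is maximized over the 5-dimensional η
(the empirical Bayes mode), the observation variances are evaluated at the
*individual* predictions (interaction), and the Laplace log-determinant
correction uses a Gauss–Newton curvature `JᵀWJ + ½ DᵀVD + Ω⁻¹` where `J`
is the finite-difference sensitivity of the predictions to η and `D` the
induced variance sensitivity. This approximation is exact for models
linear in η with η-free variance, which the test suite exploits: the same
code path, given a linear prediction function, must reproduce the
closed-form Gaussian marginal to 1e-6. Exact NONMEM objective values are
not an equivalence target (different constants and linearizations);
correctness is assessed by parameter recovery on simulated cohorts.

Practical choices:

* All population parameters are positivity-constrained by log transforms;
  the outer optimizer is `nlminb` with finite-difference gradients.
  `ka` and `lag` are fixed by default.
* Inner η modes are warm-started from the previous outer iterate. This
  makes the objective path-dependent at roughly the 1e-7 level, so
  convergence is declared when restarting the optimizer from the candidate
  optimum moves the objective by less than 0.1 units (up to five such
  polish rounds) — an objective-stability criterion, not a loosened
  tolerance. A `restarts` control (jittered starts, best objective wins)
  guards against local minima; it defaults to 1 because, starting from the
  package's reference estimates, extra restarts tripled runtime in testing
  without changing any recovered estimate.
* Records flagged `MDV = 1` are excluded from the likelihood; no explicit
  below-limit-of-quantification likelihood is implemented (LLOQ only
  annotates VPC output).
* Standard errors (optional, `se = TRUE`) come from the inverse of the
  numerically estimated Hessian of the objective at the optimum; on the
  log scale the SE of a parameter is directly its relative standard error.
  A singular Hessian yields `NA` RSEs rather than an error.
* η shrinkage is `100·(1 − SD(EBE)/ω)` per random effect. On the sparse
  design (1–9 samples) the parent-clearance shrinkage is substantial
  (~30–40%) and the volume shrinkage small, as expected when troughs
  inform concentration scale more than elimination rate.

Covariate selection follows the standard stepwise likelihood-ratio scheme:
continuous covariates enter as power models `θ·(cov/median)^β`, categorical
ones as multiplicative factors; forward addition requires ΔOFV > 3.84
(χ², 1 df, p < 0.05) and backward deletion removes terms whose loss raises
the OFV by < 10.83 (p < 0.001). Candidate fits warm-start at the current
estimates so nested optima are compared consistently. One caveat
discovered while validating the machinery: an effect on the parent
non-metabolite clearance is practically undetectable under the study's own
design (ω_CL = 1.327 and sparse sampling leave ΔOFV < 2 even at the true
coefficient), so the selection power test in this package plants its
known effect on the well-identified volume parameter instead.

The bootstrap resamples *subjects* with replacement, refits each replicate
from the same initial values, and reports the 2.5th/97.5th order
statistics of each parameter over the converged replicates; more than 20%
non-convergence flags the intervals unreliable.

## Simulation machinery

* **Regimen troughs.** Five named scenarios (200 mg bid; 200 mg tid;
  400 mg bid on day 1 then 200 mg bid; 400 mg bid on day 1 then 200 mg
  tid; 400 mg bid) with the dosing clock bid = q12h, tid = q8h, first dose
  at t = 0 and day-1 loading doses at 0 and 12 h. A trough at 48 h or 72 h
  is the concentration at the left limit t⁻, excluding a dose scheduled at
  exactly that time; this convention is also used for the loading-dose
  scenarios at 72 h. Simulations draw individuals with between-subject
  variability but no residual error and summarize the percentage below a
  200 µg/L threshold.
* **VPC.** Replicate datasets are simulated on each subject's own design;
  per quantile-based time bin (deciles by default, bins with < 3
  observations merged leftward with a warning) the observed 5th/50th/95th
  percentiles are compared with the 90% interval of the same percentiles
  across replicates.
* **NPDE.** Each observation is ranked within its simulated counterparts
  using mid-ranks for ties, mapped through the inverse normal via
  `(r + 0.5)/(n_rep + 1)`; an observation below every counterpart maps to
  the most extreme negative value, and an observation whose counterparts
  are all identical is flagged undefined. Within-subject decorrelation is
  not applied: the rank-based construction is the variant whose
  calibration (approximate standard normality on self-simulated data) the
  tests can verify directly.

## The synthetic-cohort generator

The generator defines the study conditions; it is not a tuning dial. Its
defaults emulate a 100-patient hospitalized cohort: per-subject sampling
counts `1 + Binomial(8, 0.29125)` (range 1–9, expectation 3.33, i.e.
≈ 333 blood draws in total — `design_seed()` = 8 reproduces exactly 333,
with all four compounds assayed at every draw); sampling times just before
24-h/48-h clock multiples (each selected slot minus Uniform(0, 4) h),
mirroring every-two-days trough-biased monitoring; covariates from
truncated normals (age 60.7 ± 15.9 y in [20, 94]; weight 83.6 ± 20.1 kg in
[37.5, 190]; height 1.71 ± 0.094 m in [1.52, 1.93]) and Bernoulli margins
(66% male, 25% ICU, 78% azithromycin, 42% loading dose). The regimen mix
assigns bid vs tid 1:1 independently of the loading-dose flag, a
documented assumption — the joint distribution of regimens is not part of
the emulated margins. Observation draws below zero are floored at the
assay-like zero (~3% of parent records at the default sigmas) so written
datasets always satisfy the event-record invariants.

Pharmacodynamic outcomes: length of stay is log-normal,
`log(LOS) = log(11) + β·(trough₄₈ − 350)/1000 + N(0, 0.55²)` rounded to
whole days with a 2-day floor; β = −1.1 per 1000 µg/L. These two numbers
were calibrated once, by simulation on seed blocks independent of every
test seed, so that the linear regression of stay on trough at the
analyzable n = 65 lands in the 0.05–0.25 r² band in ~90% of seeds
(median 0.13), and then frozen. Death is Bernoulli(0.08) independent of
exposure; ICU-unit patients count as ICU transfers and medicine-ward
patients transfer with probability 0.10; the composite outcome is poor on
death, ICU transfer or a stay of 10 days or more. Exactly 35% of subjects
(a rounded count, 35 of 100) have stay, transfer and composite outcome
masked, with vital status retained.

What passing tests on these cohorts do **not** show about real data: the
generator has no model misspecification (the estimation model is the
generating model), no assay LLOQ censoring, no dropout linked to outcome,
no dose-history uncertainty, and independent random effects. Recovery and
calibration results are therefore statements about internal consistency
of the machinery, not about robustness to the ways real cohorts deviate
from the model.

## Numerical choices and problem sizes

Tolerances: the analytic solver is tested against adaptive ODE integration
at 1e-8 relative on 100 random parameter sets; superposition holds to
1e-10; the inner η optimizer runs at 1e-10 relative tolerance and the
outer at 1e-6 (1e-5 in the small test fits). The test suite uses cohorts
of 4–60 subjects for unit-level checks and three full 100-subject,
6–9-samples-per-subject cohorts for the recovery experiment; the
acceptance script uses 500 individuals per regimen scenario and the same
three-cohort recovery design. These sizes were chosen so the whole suite
exercises every stage at meaningful statistical resolution while a single
fit stays under a minute.

## Known limitations

* The Laplace/Gauss–Newton objective differs from NONMEM's FOCE-I by
  constants and linearization details; OFVs are comparable within a run,
  not across implementations.
* RSEs from the numerical Hessian are expensive for the full 21-parameter
  model and are off by default (`se = FALSE`).
* No inter-occasion variability, covariate-dependent residual error,
  BLQ likelihood, or time-to-event modelling of the length of stay.
* The exposure–outcome stage is deliberately univariate (regression,
  one-way ANOVA, banded eCDFs, Holm correction for the metabolite
  family); it performs no causal adjustment.
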