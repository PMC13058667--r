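---
title: "Estimating and adjudicating the latent structure of psychiatric comorbidity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and adjudicating the latent structure of psychiatric comorbidity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psychspectra)
```

## The model

`psychspectra` treats each lifetime diagnosis $y_j \in \{0,1\}$ as the
dichotomisation of a standard-normal latent liability: $y_j = 1$ iff
$y_j^* > \tau_j$, with $\tau_j = \Phi^{-1}(1 - \text{prevalence}_j)$. The
liabilities share variance through a small number of correlated dimensions:

$$y^* = \Lambda \eta + \varepsilon, \qquad \eta \sim N(0, \Phi), \qquad
\operatorname{diag}(\Lambda \Phi \Lambda' + \Theta) = 1,$$

where $\Lambda$ holds standardized loadings, $\Phi$ the factor
correlations (unit diagonal), and $\Theta$ uniquenesses on the diagonal
plus a sparse set of *correlated residuals* — pairs of diagnoses (MDD and
dysthymia, schizophrenia and schizoaffective disorder, OCD and OCPD, the
ADHD subtypes) that covary beyond what their dimensions explain. A
*bifactor* variant adds a general liability factor on which every diagnosis
loads, all factors mutually orthogonal (the standard convention; it is a
configuration flag, not a structural assumption we defend).

Estimation is two-stage. Stage one estimates every pairwise tetrachoric
correlation by two-step maximum likelihood: thresholds are fixed at the
univariate probit estimates of the margins, and $\rho$ maximises the
bivariate-normal likelihood of the 2×2 counts. Stage two fits the factor
model to the assembled correlation matrix by least squares,

$$F(\theta) = \sum_{i<j} w_{ij}\,\big(r_{ij} - \sigma_{ij}(\theta)\big)^2,$$

with $w \equiv 1$ (ULS, default) or $w_{ij} = 1/\widehat{\operatorname{Var}}(r_{ij})$
(DWLS; pair variances from a delete-one-group jackknife over person
batches). The paper-style pseudo-chi-square $T = (n-1)\hat F$ feeds
CFI, TLI, and RMSEA against the zero-correlation null; it is *comparative,
not calibrated* — we never interpret $T$ against a chi-square reference,
only to rank models, which is also how the fit indices are used.

### Why two-stage least squares

Full-information ML on 39 binary variables is computationally out of scope
and the substantive contract here is correlation-structure fitting. ULS on
tetrachorics is a defensible, fully testable estimator: it returns the
generating parameters exactly (to 1e-6) whenever the input equals the
model-implied matrix, which gives every downstream layer a sharp oracle.
Because two-stage estimation invalidates naive ML standard errors, SEs come
from a person-level nonparametric bootstrap (default B = 100) re-running the
entire pipeline — tetrachorics, smoothing, fit — per resample, with factor
signs aligned to the point estimate.

## Numerical choices

* **Bivariate normal CDF**: Drezner–Wesolowsky/Genz adaptive Gauss–Legendre
  quadrature (6/12/20 nodes by $|\rho|$, tail-stabilised branch beyond
  0.925), absolute error below 1e-10; cross-checked in the tests against an
  independent quadrature implementation. The grid-search likelihood oracle
  used in tests shares this CDF, so any disagreement isolates the optimizer.
* **Zero cells**: 0.5 added to every cell of a table containing a zero
  (margins recomputed), keeping estimates bounded; disable with
  `zero_cell_add = 0`. Estimates are clipped to [−0.999, 0.999].
* **Canonicalisation**: each 2×2 table is reduced to a canonical orientation
  (non-negative association, fixed transpose orientation) before the 1-D
  search, so recoding a variable flips the estimate's sign *bit-exactly*
  and swapping the variables leaves it unchanged; tables with exactly zero
  sample association return $\rho = 0$ exactly.
* **Smoothing**: pairwise matrices can be indefinite; alternating
  projections onto the PSD cone and the unit-diagonal set (stop at max
  change < 1e-8 or 200 sweeps) restore a usable correlation matrix, with
  min eigenvalues before/after reported.
* **Optimisation**: analytic-gradient `nlminb` from five deterministic
  starts (loadings on a 0.3–0.7 grid, factor correlations at 0.3, residuals
  at 0); best discrepancy wins, ties to the first start. Convergence is
  declared at `nlminb` success or a scaled gradient norm below 1e-5.
  Admissibility is kept by a smooth quadratic penalty on communalities
  above 1 and |factor correlations| above 0.999 (a soft bound); solutions
  at the bound are flagged as Heywood cases rather than hidden.
* **Sign indeterminacy**: every factor's loading sum is made non-negative
  after optimisation; bootstrap replicates are additionally aligned to the
  point estimate.
* **Degenerate margins**: diagnoses with prevalence 0 or 1 have no defined
  tetrachoric correlation and are excluded with a report before estimation.

## Adjudication beyond fit indices

Conventional indices often barely move when diagnoses are shuffled across
dimensions, so the package computes *alternative indices* per factor:
**magnitude** (median absolute loading), **consistency** (SD of loadings),
and **precision** (mean bootstrap SE), pooled versions included — both the
per-factor and the pooled-over-all-loadings variants are emitted because
either pooling convention is defensible. Three sampling-based layers probe
the structure itself:

* `random_assignment_null()` refits K variants with diagnoses randomly
  reassigned to factors. The factor-size multiset is preserved by default
  (the most conservative null that keeps model complexity fixed);
  unconstrained assignment sits behind a flag. Null fits that hit Heywood
  bounds are *retained* and flagged — excluding them would bias the null
  toward better-behaved models.
* `split_half()` partitions persons into two disjoint halves, re-runs the
  full pipeline per half, and reports per-index |differences| plus the
  ICC of the loading vectors. The ICC variant is two-way, absolute
  agreement, single measure — ICC(A,1) — because both halves estimate the
  same quantity on the same scale, so level disagreement must count.
* `loo_scan()` refits with each diagnosis removed in turn. Since the
  tetrachoric matrix is estimated pairwise, removal only subsets it; no
  correlation re-estimation is needed. Deltas are *signed* (summaries
  report signed mean/median/SD/min/max); removals that would leave a factor
  with fewer than two indicators are skipped and flagged.

Data-driven refinement uses `candidate_scan()`: one-parameter refits
(warm-started at the base solution, so $\Delta F \ge 0$ by construction)
ranked by discrepancy drop. This replaces analytic modification indices —
the refit gives the same ranking signal without estimator-specific
derivative algebra — and deliberately accepts nothing automatically: the
scan is a shortlist for substantive scrutiny, not a stepwise search.

## External correlates

Persons are scored on the fitted dimensions by maximum a posteriori
estimation under the probit measurement model (damped Newton per distinct
response pattern; the probit log-likelihood is concave, so the optimum is
unique). Each external correlate is then regressed on each standardized
dimension score, one at a time — linear for continuous/ordinal (ordinal
treated as numeric), probit for binary — with bootstrap SEs, and a
Wald-type chi-square tests whether the coefficient profile differs across
dimensions (successive-difference contrasts with the bootstrap covariance;
invariant to factor ordering; generalized inverse with reduced df if the
covariance is singular).

Factor-score regression is an honest simplification of joint
SEM-with-covariates: scores are shrunken, so coefficients are attenuated by
roughly the score–factor correlation, and one-at-a-time regressions
estimate *marginal* associations ($\beta' \Phi e_f$ on the liability
scale), which blend direct effects across correlated dimensions. The tests
therefore judge recovery against the oracle regression on the *true*
generator factor scores, attenuation-corrected. A joint-estimation mode is
a documented extension point, not implemented.

## What the generator emulates — and what it does not

`six_factor_preset()` encodes the study conditions: 39 diagnoses on six
correlated dimensions (6–7 each, all sizes within 5–8), standardized
loadings in [0.4, 0.8] with Fear/Distress running lower (0.42–0.58) than
the other dimensions (0.56–0.80), a high Fear–Distress correlation (0.90),
moderate correlations elsewhere (0.35–0.50), lifetime prevalences from 0.05
(psychotic and neurodevelopmental conditions) to 0.35 (common mood
diagnoses), and uniqueness-level correlated residuals of 0.10–0.15 for the
classic pairs. Uniquenesses are solved from $\Lambda$ and $\Phi$ rather
than user-set, keeping loadings standardized; residual correlations are
injected by a shared standard-normal component scaled so the implied
correlation increment equals the target exactly, which also guarantees the
implied matrix is a true correlation matrix. Each positive diagnosis emits
1–4 raw code variants with uniform dates (carried but unused: lifetime
indicators are date-agnostic), and one global seed drives counter-based
sub-streams so each component regenerates independently.

External correlates mirror a demographic/clinical mix: a probit-linked
binary sex analog (male excess on Substance Use and Externalizing, female
excess on Fear and Distress), a continuous sleep-disturbance score
(strongest positive marginal on Distress, positive on Externalizing,
negative on Substance Use — the direct Substance Use weight is set to −0.9
precisely so the *marginal* association stays clearly negative despite
positive leakage through correlated dimensions), and ordinal income and
education analogs (negative, strongest for Substance Use). The
Externalizing–Substance Use correlation is set at 0.45; with a
substantially higher value, opposite-signed marginal sleep associations on
the two dimensions are arithmetically impossible at plausible effect sizes.

The generator does **not** simulate care-seeking, coding drift, diagnostic
misclassification, or any longitudinal dynamics. Passing recovery tests on
these data shows the estimator chain is correct and well-calibrated under
the liability-threshold model; it does not show that real EHR diagnoses
satisfy that model, that observed prevalences are unbiased, or that real
loadings are as homogeneous as the preset's.

## Problem sizes and tolerances used in the checks

Recovery and replication checks run at n = 20,000 persons (50,000 for
tetrachoric-matrix convergence, 10,000 for the 20-replicate model
discrimination and the K = 100 permutation null); the leave-one-out scan
uses an 18-diagnosis, three-dimension subset, which exercises every code
path at a fraction of the refit cost. At these sizes: loadings are
recovered within ±0.10 (RMSE < 0.05), factor correlations within ±0.10,
split-half loading ICC exceeds 0.9 with fit-index differences below 0.01,
and leave-one-out loading changes stay below 0.05. Exact-recovery checks
(model-implied input) are at 1e-6 or tighter. The tetrachoric calibration
check (200 replicates, true ρ = 0.5, n = 10,000) requires the mean estimate
within ±0.02; the likelihood-grid oracle agreement is 1e-3 on a fixed bank
of 25 tables.

## Known limitations

* No full-information estimation; the pseudo-chi-square is comparative
  only, and absolute fit cutoffs should not be applied to it.
* No polychoric (>2 category) support and no missing-data machinery — the
  binary-matrix design has no missingness.
* No ESEM or rotation-based exploration; cross-loadings enter only through
  explicit model text or the candidate scan.
* No measurement-invariance testing across demographic groups.
* Ordinal correlates are treated as numeric; a proportional-odds option is
  out of scope.
* Bootstrap SEs at small B are themselves noisy; B = 100 is a floor for
  reporting, not a recommendation for publication-grade intervals.
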