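---
title: "Functional-mapping multi-locus LASSO GWAS for ring-resolved tracheid traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional-mapping multi-locus LASSO GWAS for ring-resolved tracheid traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracheidGWAS)
```

## The problem

Wood tracheid traits — radial and tangential cell widths, wall thickness,
coarseness (mass per length) and microfibril angle (MFA) — are measured
ring by ring from pith to bark, so every tree contributes a *trajectory*
indexed by cambial age rather than a single phenotype. In a half-sib
progeny trial replicated on two sites, the trait signal of interest (the
family genetic effect) is entangled with site, block and site-by-family
effects, and the trajectories themselves are high-dimensional. The package
implements a functional-mapping association pipeline that (i) refines the
per-ring data with a mixed model, (ii) compresses each refined trajectory
into a handful of *latent traits*, and (iii) scans those latent traits with
a multi-locus penalised regression whose significance rule controls the
expected number of false selections.

## Stage 1 — per-ring mixed-model refinement

At each cambial age the observations follow the joint-site model

$$Y_{ijkl} = u + S_i + B_{j(i)} + F_k + SF_{ik} + e_{ijkl},$$

with fixed site ($S_i$) and block-within-site ($B_{j(i)}$) effects and
independent random family ($F_k \sim N(0,\sigma^2_F)$), site-by-family
($SF_{ik} \sim N(0,\sigma^2_{SF})$) and residual
($e \sim N(0,\sigma^2_e)$) terms. `fit_ring_mixed_model()` estimates the
three variances by EM-REML — chosen because it is monotone in the REML
likelihood and unconditionally keeps variances non-negative for this
two-component model at desk scale — with convergence declared when the
relative change in the REML log-likelihood falls below `1e-6` (at most 500
iterations; non-convergence is flagged, never silently accepted). Family
EBVs (BLUPs) come from the mixed-model equations at the converged
variances. With a single site the $SF$ term is aliased with $F$ and is
dropped, which is also what makes the balanced one-way closed form
$\mathrm{BLUP}_k = \sigma^2_F/(\sigma^2_F + \sigma^2_e/n_k)\,(\bar y_k -
\hat u)$ testable.

`refine_trajectories()` rebuilds, per family and age, `EBV + adjusted
mean(age)`. The adjusted mean is the fixed-effect prediction at the
*baseline* (first) site and block levels. Among the candidate "averages at
each age" (raw mean, level-weighted adjusted mean, baseline prediction)
only the baseline prediction is exactly invariant when one site's
observations are shifted by a constant, which is the property the
refinement exists to provide. The common level offset this introduces is
harmless: the association stage centres its responses, and a constant
shifts every family's spline intercept equally.

A property worth knowing: because the BLUP shrinkage factor varies with
age (family variance grows with age whenever slope heredity is present,
while the error variance does not), per-age shrinkage slightly distorts
the *shape* of refined trajectories, attenuating the spline intercept more
than a uniform shrinkage would. This is inherent to per-age refinement —
also in the original design of the analysis — and is why the pipeline-level
recovery tests assert ranking preservation rather than near-unit
correlation.

## Stage 2 — latent traits

For dimension and coarseness traits each refined trajectory is reduced by
ordinary least squares on the truncated-linear basis

$$y(t) = \beta_0 + \beta_1 t + \beta_2 (t - K_1)_+ + \beta_3 (t - K_2)_+ +
\varepsilon(t),$$

a continuous piecewise-linear curve with slope changes at the two knots.
Two knots are used throughout; `select_knots()` picks one shared integer
pair per trait by minimising the total SSE over all trajectories (ties go
to the smaller $K_1$, then $K_2$), and the per-curve coefficients
$\beta_0..\beta_3$ are the latent traits. On noise-free spline data the
coefficients are recovered to machine precision; with the documented
trajectory noise (`noise_sd = 0.05` trait units per ring) the correlation
between true and fitted $\beta_0$ and $\beta_1$ exceeds 0.9 at the default
between-family spreads. Rank-deficient cases (no rings beyond $K_2$) are
fitted with the identifiable subset and flagged.

MFA follows a different reduction because its trajectory is a monotone
decay from ~30° at the pith to a 10–12° plateau: `mfa_latents()` fits
`plateau + (start − plateau)·exp(−rate·(age − 1))` by Levenberg–Marquardt
(grid-profiled linear fallback), takes the age where the *fitted* curve
first reaches 20° as the transition age `MFA_TA` (solved on the fitted
curve, hence interpolated between rings), and averages the observed MFA at
ages at/below vs above it (`MFA_CORE`, `MFA_OUTER`). The exponential-decay
family is this package's own surrogate for the "central peak" regression
family used in earlier work on these data, whose parametric form is not
public; it is deliberately a swappable component. Curves whose fit never
reaches 20° within the observed ages are flagged `crossed = FALSE` and
excluded from association mapping rather than extrapolated. An optional
outlier screen drops rings whose residual from a preliminary fit exceeds 4
MADs — residuals, not raw values, so the legitimately high pith rings
survive.

## Stage 3 — stability-selection LASSO

Each latent trait is scanned with the multi-locus LASSO

$$\min_{\alpha_0, \alpha} \frac{1}{2n}\sum_i \Big(y_i - \alpha_0 -
c_i^\top\gamma - \sum_j x_{ij}\alpha_j\Big)^2 +
\lambda \sum_j |\alpha_j|,$$

with genotype codes 0/1/2, the first five genotype principal components as
*unpenalised* covariates, and a cyclic coordinate-descent solver
(soft-thresholding; convergence at maximum coefficient change `1e-7`;
covariates handled by Frisch–Waugh residualisation, which gives identical
penalised coefficients and is faster). The solver is validated against the
KKT conditions and an independent implementation in the test suite.

Significance is by stability selection: 100 half-samples (size
$\lfloor n/2\rfloor$, without replacement), each solved at a penalty
calibrated so that about $q$ markers are active. The calibration descends
a warm-started geometric path from that half-sample's $\lambda_{\max}$ and
stops when the active set reaches $q$ — the classic first-$q$-to-enter
rule, equivalent in effect to a binary search for the matching penalty but
cheaper. A marker's stability selection probability (SSP) is the fraction
of half-samples in which it is active. The threshold comes from the
false-selection bound $E[V] \le q^2 / ((2\pi - 1)p)$: the default $q$ is
the largest value keeping $E[V] \le 1$ at $\pi = 0.52$, and conversely
`buhlmann_threshold(178101, 84)` returns $\pi \approx 0.5198$ — the 0.52
operating threshold and a selection size of ~84 markers are mutually
consistent at the study's marker count. The subsample count (100) and
half-sample size are standard stability-selection practice; the original
analysis does not state its subsampling details, so these are package
defaults, not reconstructions.

## Stage 4 — effect characterisation

For the selected markers, effects are re-estimated jointly by an adaptive
LASSO: initial OLS (or ridge when the selected set is large) estimates give
weights $w_j = 1/|\hat\beta_j|^\gamma$ (default $\gamma = 1$, weights
capped at $10^6$), and the weighted fit's penalty is chosen by 5-fold
cross-validation. The data-adaptive weights shrink strong effects less
than the plain LASSO, countering its known tendency to under-estimate the
variance a QTL explains. Each marker's contribution is reported as
$\mathrm{PVE}_j = \mathrm{Var}(x_j\hat\alpha_j)/\mathrm{Var}(y)\times 100$
— the standard adaptive-LASSO variance decomposition, adopted here as a
package decision since no canonical formula is mandated by the analysis it
follows.

Gene action per marker uses the genotype-class means: $2a = |G_{BB} -
G_{AA}|$, $d = G_{AB} - (G_{BB} + G_{AA})/2$, and the ratio $d/a$. Modes:
$|d/a| \le 0.5$ additive, $0.5 < |d/a| < 1.25$ partial-to-full dominant,
$\ge 1.25$ over-dominant. The published bands are open intervals, so
boundary values are assigned to the lower-named class — a documented
convention, exercised at exactly 0.50 and 1.25 in the tests. The sign of
$d/a$ follows the VCF ref/alt orientation; only its magnitude is
orientation-free. `kw_genotype_test()` (a thin wrapper over
`stats::kruskal.test`) supplies the rank-based genotype-class test used to
annotate class-mean comparisons.

## The synthetic-data generator

`sim_config()` fixes the emulated study conditions; `simulate_study()`
produces a design table, half-sib genotypes, a spline-trait ring series
and an MFA ring series under one seed (byte-identical on repetition).
Defaults, and why:

* **Scale** — 200 families × 6 trees per site × 2 sites, 2,000 markers, 10
  QTLs: a desk-scale rendition of a two-trial progeny test that keeps the
  full structure (both random terms identifiable, realistic family
  replication) while the test suite runs in minutes.
* **Genotypes** — per marker an alternate-allele frequency uniform on
  `maf_range = (0.1, 0.5)`; mother genotypes Hardy–Weinberg within family;
  offspring get one maternal allele and one pollen allele drawn from the
  population frequency (open pollination, the half-sib assumption).
  Missingness is completely at random (`missing_rate = 0.02`), the
  simplest model consistent with a missingness filter. An optional
  two-subpopulation frequency shift (`subpop_delta`) exists solely to
  exercise the principal-component correction.
* **Variance components** — family 0.02, site-by-family 0.01, residual
  0.17 (trait units²): ring-level narrow-sense heritability
  $4\sigma^2_F/\sigma^2_P \approx 0.4$, mid-range for tracheid dimension
  traits, with G×E half the family variance.
* **Latent spread** — intercept variance equals the family variance;
  slope SDs (0.05, 0.04, 0.03) give between-family slope CVs near 30%,
  i.e. visible but not dominant trajectory-shape heredity.
* **QTL architecture** — additive QTLs on $\beta_0$ with $a = 0.03$, each
  explaining on the order of 2% of latent variance: sparse, small-effect,
  matching the regime the method targets.
* **MFA** — start 30° (SD 2°), plateau 11° (SD 1°), decay rate 0.19/ring
  (lognormal CV 0.15), ring noise 1°: crosses 20° near age 5 and settles
  at 10–12° by age ~10.

What the generator does *not* emulate: linkage disequilibrium between
markers, pedigree beyond half-sib, provenance structure beyond the
optional two-group shift, spatial field trends, and non-Gaussian
measurement error. Passing tests therefore demonstrate the statistical
machinery under the design's own assumptions, not robustness to violations
of them.

## Numerical choices and edge cases

* Marker filter: retain MAF ≥ 0.05 **and** missingness ≤ 0.20; equality is
  retained on both sides because the removal rule is strict ("< 0.05",
  "> 20%"). The filter is idempotent and reports per-marker decisions.
* Missing genotypes are mean-imputed after filtering; the LASSO
  standardises columns, so the imputation constant is immaterial there.
  The original missing mask is kept, and genotype-class means use only
  genuinely called genotypes.
* Principal components use a deterministic sign convention (largest
  loading positive).
* EM-REML floors variance iterates at `1e-8 · var(y)` to keep the
  mixed-model equations well-posed when a component collapses; a
  confounded fixed design is an error naming the aliased columns.
* Knot-grid ties resolve to the smaller $K_1$, then smaller $K_2$.
* `q_target` is floored from the bound inversion, keeping the implied
  $E[V]$ at or below the tolerance rather than rounding it above.
* Heterozygote-free markers report `d` (and the ratio, and the mode) as
  missing; `a = 0` leaves the ratio undefined rather than infinite.

## Problem sizes in the tests and the acceptance script

The stochastic validations run at: 50 pure-noise replicates of
`p = 2000, n = 200` with 100 half-samples each (false-selection control);
20 replicates of the full two-site design (EM-REML recovery, mean
estimates within 15%); 200 trajectories at the documented noise (spline
recovery, $r > 0.9$); and three `n = 500, p = 2000` scans with ten planted
QTLs each of standardised effect 0.3 (power ≥ 70% at SSP ≥ 0.52). These
sizes were chosen as the smallest at which the Monte-Carlo error is
clearly inside the asserted margins. Standardised effects are coefficients
on z-scored markers in response-SD units, so ten QTLs at 0.3 define a
high-heritability smoke scenario. Note a structural property of the
calibrated rule here: with $q = 8$ selections per half-sample (the largest
size keeping $E[V] \le 1$ at $\pi = 0.52$ for $p = 2000$) and ten true
QTLs competing for those slots, per-QTL inclusion frequencies plateau near
0.8 even for arbitrarily strong effects — power against the 0.52 threshold
is capped by slot competition, not by signal strength.

## Known limitations

* Only the univariate joint-site mixed model is implemented — the model
  the upstream analysis itself settled on — not bivariate/multivariate
  alternatives or AIC model competition.
* Family EBVs are the genetic unit (the model has no within-family tree
  term), so association responses are family-level by construction.
* The per-age-refinement shape distortion discussed under Stage 1.
* The adaptive-LASSO PVE is a variance decomposition of a penalised fit;
  with correlated selected markers the per-marker attribution is
  order-dependent in principle, though the joint fit mitigates this.
* The MFA decay family is a surrogate; trees whose true curve is
  non-monotone (e.g. compression-wood artefacts) are flagged and excluded
  rather than modelled.
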