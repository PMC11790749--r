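---
title: "Bifactor twin models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bifactor twin models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biftwin)
```

# The problem

Twin designs decompose the variance of a phenotype into additive genetic
(A), shared environmental (C) and non-shared environmental (E) components by
contrasting monozygotic (MZ) pairs, who share all segregating genes, with
dizygotic (DZ) pairs, who share half on average. For a multi-item symptom
scale with a known subscale structure — here a 20-item adult
attention/hyperactivity self-report scale with an 11-item inattention and a
9-item hyperactivity subscale — the interesting question is not just *how
heritable* the total score is, but at what level of generality genetic and
environmental influences act: on a general factor shared by all items, on
subscale (group) factors, or uniquely on single items.

`biftwin` implements the two bifactor twin models that answer this:

* **Bifactor common pathway (CP) model.** Items load on one general and two
  group phenotypic latent factors (mutually orthogonal, unit variance); each
  latent factor's variance is decomposed into A/C/E paths under the
  constraint $a_F^2 + c_F^2 + e_F^2 = 1$; item residuals get their own A/C/E
  paths.
* **Bifactor independent pathway (IP) model.** No phenotypic factor
  mediates: A, C and E each have their *own* bifactor loading structure
  (general + group columns) on the items, plus item-unique paths.

The model-implied covariance of the $2n$-vector of a pair
(`[twin1 items | twin2 items]`) is, with $r = 1$ (MZ) or $0.5$ (DZ):

* CP: within block $\Lambda\Lambda' + \mathrm{diag}(a_u^2+c_u^2+e_u^2)$,
  cross block $\Lambda\,\mathrm{diag}(r a_F^2 + c_F^2)\,\Lambda' +
  \mathrm{diag}(r a_u^2 + c_u^2)$.
* IP: within block $\Lambda_A\Lambda_A' + \Lambda_C\Lambda_C' +
  \Lambda_E\Lambda_E' + \mathrm{diag}(u^2)$, cross block
  $r\,\Lambda_A\Lambda_A' + \Lambda_C\Lambda_C' +
  \mathrm{diag}(r a_u^2 + c_u^2)$.

Both builders are verified in the test suite against a brute-force
structural oracle that assembles the full latent linear system and computes
$B\,\mathrm{Cov}(\eta)\,B'$.

# Estimation

Scores are treated as continuous multivariate normal despite their 0–3
ordinality, matching common practice for this scale and the treatment under
which the reference results were produced. Age, sex and cohort are
residualized out of the item scores by pooled OLS before fitting, and means
are then fixed at 0 (free means are supported through the `means` argument).

The objective is the full-information maximum likelihood (FIML) −2
log-likelihood: pairs are grouped by missingness pattern, and each group
contributes the multivariate-normal deviance of its observed subvector.
With complete data this reduces automatically to the sufficient-statistic
form (one Cholesky per zygosity per evaluation), which is what makes the
simulation studies in the tests affordable.

Optimization uses L-BFGS-B with *analytic gradients*: writing
$G = n(\Sigma^{-1} - \Sigma^{-1} S \Sigma^{-1})$ per missingness pattern
(scattered into the full matrix), the chain rule to loadings and paths needs
only a handful of small matrix products. Gradients are verified against
central finite differences in the tests. Design choices:

* The CP unit-variance constraint is enforced by deriving
  $e_F = \sqrt{1 - a_F^2 - c_F^2}$ ($e_F$ never enters the expected
  covariance because the factor variance is identically 1) plus a smooth
  quartic penalty on $a_F^2 + c_F^2 > 1$; outside that disc $\Sigma_{MZ}$
  is genuinely indefinite, so the objective also soft-fails (huge value)
  to make the line search back off.
* Paths are parameterized in path space with box bounds $[-3, 3]$; unique
  E paths are bounded below at $10^{-4}$ to avoid zero residual variance.
* Multi-start (default 5; first start from a Direct Schmid-Leiman-based
  heuristic, the rest jittered); the best −2LL is kept. Convergence uses
  `factr = 100` (≈ $10^{-8}$ relative) and `pgtol = 1e-6`.
* Loading columns are sign-identified by flipping each column to a
  nonnegative sum. The likelihood is sign-invariant (tested).
* Submodels (AE/CE/E) zero the dropped component at both the factor/source
  and item-unique level; a CP variant with E-only residuals is available
  via `unique_components = "E"`.

An identification caveat discovered during development and worth knowing:
a two-group bifactor loading structure with *column-constant* loadings is
empirically unidentified (all within-group covariances become equal, so
general and group loadings trade off along a likelihood ridge). The
simulator's default IP parameter set therefore uses the heterogeneous
published loading shape; this is essential, not cosmetic.

# Phenotypic bifactor workflow

`fit_dsl_bifactor()` implements Direct Schmid-Leiman estimation: (i)
principal-axis extraction of $m$ factors and oblique quartimin rotation
(oblimin with $\gamma = 0$, by Jennrich's gradient-projection algorithm with
multiple starts — `stats::varimax`/`promax` stall on a saddle for exactly
the strong-general-factor structures this package targets); (ii) a
one-factor solution on the factor correlations giving second-order loadings
$\gamma_k$; (iii) the classic Schmid-Leiman target (general $= P\gamma$,
groups $= P\,\mathrm{diag}\sqrt{1-\gamma^2}$); (iv) extraction of $m+1$
factors and orthogonal Procrustes rotation onto the target, then column
matching, sign convention, and structural zeroing (the cross-loading
solution is kept in the `"raw"` attribute).

Two accuracy notes, both tested rather than assumed. With two group factors
the factor correlation identifies only the product $\gamma_1\gamma_2$; the
equal-split convention $\gamma_k = \sqrt{\phi_{12}}$ is used, so noiseless
recovery is exact for structures with a shared $\gamma$ (and for the
published-loading regime the recovered general factor correlates > 0.95
with the reference column in simulation). Non-proportional loadings carry
the method's documented target bias (a few hundredths); we do not claim
byte-agreement with any particular implementation, only the recovery
properties.

Reliability indices follow the standard formulas on the loading matrix *as
given* (cross-loadings retained — the convention under which the published
values ω~h~ = 0.62, H = 0.88, ECV = 0.52 reproduce exactly):

* $\omega_h = (\sum\lambda_g)^2 / [(\sum\lambda_g)^2 +
  \sum_k(\sum_i\lambda_{ik})^2 + \sum_i u_i]$,
* $H = S/(1+S)$, $S = \sum \lambda^2/(1-\lambda^2)$,
* $\mathrm{ECV} = \sum\lambda_g^2 / \sum\lambda^2$,

with cutoffs ω~h~ > 0.5 and H > 0.7 attached to every report. For the
per-source indices of a fitted IP model, each source is treated as its own
bifactor solution: the ω~h~ denominator is that source's composite variance
(its column sums plus its own standardized unique variance). A
whole-composite denominator was considered and rejected: it forces the three
ω~h~ values to sum to at most 1, which is inconsistent with the published
per-source values (0.51 and 0.67 for A and E). The per-source convention
asks the scientifically intended question — *how coherent a general
dimension does this source carry?* — independently of the source's share of
total variance.

# The simulator: what it emulates, and what it does not

`simulate_twins()` is the generative mirror of the two models: factor/source
and item-unique A scores are drawn with cross-twin correlation 1 (MZ) or 0.5
(DZ), C scores are shared, E scores independent; items are the implied
linear combinations. Defaults state the published study's world: 1835 MZ and
3392 DZ pairs (35.1% / 64.9% of 5227 pairs), 17% of twins masked completely
at random (item-level MCAR per cell is available), age ~ N(22.85, 0.88²)
shared within pair, sex 0/1 with P(1) = 0.401 (shared for MZ), three birth
cohorts. Optional ordinalization cuts the unit-variance continuous scores at
(0.15, 0.90, 1.65), chosen once to give a right-skewed distribution whose
population mean total on 20 items is near the published 13.5/60; these
thresholds are a stated-world constant, not a tuning knob.

The packaged parameter sets `demo_cp_params()` (AE; factor heritabilities
0.40/0.42/0.33, published loading shape, unique variance split A:E = 2:46)
and `demo_ip_params()` (ACE; mean squared standardized effects exactly equal
to the published effect table) put the generator in the published regime.

What the simulator does *not* emulate: ordinal measurement in the fitted
model (items are analyzed as continuous, as in the reference analysis),
informative missingness, assortative mating, sex limitation,
gene–environment interplay, and rater effects. A green recovery test
therefore establishes correctness of the estimator under its own
assumptions, not robustness to their violation.

# Model comparison and uncertainty

`fit_statistics()` computes χ² against a saturated model (unstructured
symmetric covariance per zygosity, means 0; closed form when data are
complete, EM over missingness patterns otherwise) and CFI against an
independence baseline (diagonal covariance per zygosity, closed form even
under missingness): RMSEA $= \sqrt{\max(0, \chi^2 - df)/(df\,(N-1))}$, CFI
with the usual clipping, AIC $= -2LL + 2k$, BIC $= -2LL + k\ln N$. $N$ is
the number of twin pairs contributing data — the pair is the independent
sampling unit; the convention is explicit in the object and the identities
are asserted on every emitted statistic. Because the reference software's
raw-data RMSEA/CFI conventions are not printed anywhere we could verify,
formula-oracle equivalence (not byte equality with another package) is the
contract.

Likelihood-ratio tests between nested component sets are ordinary χ² tests,
deliberately without a boundary (50:50 mixture) correction, mirroring
standard practice in this literature. Since a dropped component enters the
likelihood only through squared paths, the information for $c$ at $c = 0$
vanishes and the test is conservative; the calibration test in the suite
accordingly checks that the empirical type-I rate does not *exceed* the
nominal level, and the p-value distribution under the null is super-uniform.

`bootstrap_ci()` resamples pairs with replacement within zygosity strata
(the pair is the exchangeable unit), refits from the point estimate, and
reports percentile intervals; replicates that fail to converge are dropped
and counted, with a flag above 5%. Fixed seed means bit-identical intervals.

# Runtime scaling of the simulation checks

The spec-level checks were scaled to keep the full suite within its runtime
budget on one CPU: LRT calibration runs 200 null replicates of a 6-item
two-group CP model at 250 MZ + 350 DZ pairs; bootstrap coverage runs 60
simulated datasets at B = 99 (instead of 100 × 199), which widens the
binomial acceptance band accordingly. The 6-item structure (3 items per
group) is the smallest that is comfortably identified; 2-item groups were
tried and are too weakly identified for stable small-sample fits. Parameter
recovery runs at the full 20-item, 2500 + 2500-pair scale.

# Known limitations

* Ordinal-threshold (liability) FIML is out of scope; treating 0–3 scores
  as continuous attenuates covariances somewhat and is inherited from the
  reference analysis.
* The saturated EM fit with heavy item-level missingness on 20 items is
  slow (per-pattern sweeps); twin-level missingness (3 patterns) is cheap.
* No dominance (ADE), sex-limitation or moderation models.
* CP/IP submodel LRTs at variance boundaries are conservative (see above).
* With two group factors, second-order loadings are identified only up to
  the product $\gamma_1\gamma_2$ in the DSL step; results for the general
  factor are unaffected, but group-column splits inherit the equal-split
  convention.
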