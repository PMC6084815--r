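---
title: "Models and methods behind twinmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind twinmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinmeth)
```

# The twin model

`twinmeth` decomposes the inter-individual variance of DNA methylation at a
CpG site (a beta value in [0, 1]) into additive genetic (A), shared
environment (C), and unique environment (E) proportions, using the contrast
between monozygotic (MZ) and dizygotic (DZ) same-sex twin pairs. The
assumptions are the classical ones: additive genetic factors correlate 1
within MZ pairs and 0.5 within DZ pairs; the shared environment correlates 1
within both; unique environment (which absorbs measurement error) is
independent between co-twins; and means and total variances are equal across
zygosity groups and across twin order. Under these assumptions a pair is
bivariate normal with

$$\Sigma_{MZ} = \begin{pmatrix} \sigma^2 & a^2+c^2 \\ a^2+c^2 & \sigma^2
\end{pmatrix},\qquad
\Sigma_{DZ} = \begin{pmatrix} \sigma^2 & a^2/2+c^2 \\ a^2/2+c^2 & \sigma^2
\end{pmatrix},\qquad \sigma^2 = a^2+c^2+e^2 .$$

Equal means/variances across groups is the default of the standard twin SEM
software this reproduces; freeing them is deliberately out of scope (the
published per-site estimates we cross-check against are mostly consistent
with the constrained model; where they are not — see the `fit_ace_summary`
discussion below — the difference is a fraction of a percentage point for
interior solutions).

## Full-information maximum likelihood (`fit_ace_fiml`)

The pair-level log-likelihood is maximized in **path coefficients**
$(\mu, a, c, e)$, so $a^2, c^2, e^2 \ge 0$ hold automatically and the
optimization is smooth and unconstrained. Numerical choices that matter:

* **Sufficient statistics.** With complete pairs and a common mean, the
  likelihood depends on the data only through per-group moments
  $(n, \sum y_1{+}y_2, \sum y_1^2{+}y_2^2, \sum y_1 y_2)$; each likelihood
  evaluation is O(1), which is what makes genome-wide fitting and the dense
  grid oracle cheap. Pairs with a missing member are dropped per site
  (complete-pairs analysis).
* **Internal standardization.** Beta-scale SDs are ~0.01–0.1, which makes a
  naive 4-parameter BFGS ill-conditioned (we observed premature stops with
  gradient norms ~1). Data are standardized internally to mean 0 / SD 1, fit,
  and mapped back (the log-likelihood Jacobian is added back), so all
  parameters are O(1).
* **Deterministic multi-start.** Two fixed starts — the Falconer solution
  (clamped to the interior) and an equal-thirds split — and the best
  optimum is kept; no random restarts, so refitting is exactly reproducible.
* **Boundary polish.** When the unconstrained solution has $a^2 < 0$ (i.e.
  $r_{DZ} > r_{MZ}/2$) the path-coefficient surface is flat in $a$ near 0 and
  BFGS stops at a small nonzero value. Any component ending below 1% of the
  variance triggers a refit with that path pinned at exactly zero; the pinned
  solution is kept unless it is worse by more than 1e-8. Boundary flags
  (`"A"`, `"C"`) record pinned components (magnitude threshold 1e-5 on the
  standardized scale).
* **Floors and tolerances.** $e$ is floored at 1e-6 of the total SD (the
  covariance matrix stays positive definite); the optimizer runs to a
  relative objective tolerance of 1e-14 and `converged` additionally
  requires a central-difference gradient norm below 1e-5·(1+|loglik|).
* **Scale.** Betas are modeled on their observed scale — no logit or other
  transform is applied by default, matching the variance components the
  estimates are compared against.

## Summary-statistic fit and Falconer estimates

`fit_ace_summary(r_MZ, r_DZ, n_MZ, n_DZ)` maximizes the two-group likelihood
of unit-variance correlation matrices. With two free correlations and two
observed ones the model is saturated, so the interior maximum is the Falconer
closed form exactly:

$$\hat A = 2(r_{MZ} - r_{DZ}),\qquad \hat C = 2 r_{DZ} - r_{MZ},\qquad
\hat E = 1 - r_{MZ}.$$

When a closed-form component is negative it is pinned at zero and the
remaining correlation parameter is re-estimated by a group-size-weighted 1-D
likelihood search: for $\hat A < 0$ both groups share $\rho = c^2$, for
$\hat C < 0$ the structure is $\rho_{MZ} = a^2$, $\rho_{DZ} = a^2/2$. For the
published low-heritability worked example ($r_{MZ} = 0.363$,
$r_{DZ} = 0.449$, 426/306 pairs) this yields $A = 0$ exactly and
$C = 39.9\%$; the original analysis printed $C = 40.2\%$, a discrepancy of
0.3 pp consistent with group-specific variances in the original software
defaults. `falconer_estimates` returns the raw closed form plus [0, 1]
truncation, for the places (DMP concordance-class panels) where the quick
estimator is the published method.

Equivalence of the three routes (FIML = summary fit = Falconer for interior
solutions, tolerance 1e-6) is enforced in the test suite on moment-matched
datasets — doubled, swap-symmetric data whitened so the ML moments equal the
target correlations exactly — and FIML optimality is checked against a dense
(A, C) simplex grid (step 0.002) with the mean and total variance profiled
out in closed form (GLS mean, then variance as the scaled quadratic form).

## Twin correlations and the sign test

Per-site MZ/DZ correlations are **double-entry** Pearson correlations: the
pair list is mirrored before correlating, making the statistic invariant to
the arbitrary ordering of twins in the manifest (the intraclass-correlation
analogue standard in twin work; a config switch gives the single-ordering
version). Correlations from fewer than 3 complete pairs, or constant values,
are reported missing.

The genome-wide "MZ more similar than DZ" test is an exact two-sided
binomial sign test, $p = \min(1, 2\min(P(X \le k), P(X \ge k)))$ under
$X \sim \mathrm{Bin}(m, 1/2)$, with tail sums accumulated in log space
(log-sum-exp over `lchoose`). For genome-scale $m$ the p-value underflows a
double — published values around $10^{-323}$ are underflow artifacts — so
`log10_p` is always reported and exact to ≥ 6 significant digits; the
printed form falls back to a mantissa/exponent string built from `log10_p`.

## Probe classification

A probe is *variable* when the range of its middle 80% of values
(q90 − q10) **strictly exceeds** 5%, and *intermediate* when its mean lies
in the **closed** interval [20%, 80%]; both thresholds are configurable. The
strict/closed reading follows the defining phrases ("greater than 5%",
"between 20% and 80%"); the quantile estimator is fixed to linear
interpolation of order statistics with quantile $p$ at rank $1 + (n-1)p$
(R's type 7) since no convention is stated in the source analyses —
published genome-wide probe counts are therefore not exactly reproducible
even in principle, and are not targeted. X-chromosome classification is
always computed per sex.

## Stratified comparisons, profiles, enrichment

* `compare_strata` contrasts A/C/E between probe sets by a two-sided
  Mann–Whitney U test: the exact permutation distribution is enumerated for
  combined n ≤ 16 (midranks, so ties are handled), the normal approximation
  with tie correction is used above. Means/SDs are reported in percent.
* Positional profiles slide a window (default 500 bp, step 100 bp, ≥ 50
  probes, all configurable — the source analyses do not state their
  parameters) over strand-aware TSS distances; under-filled windows are
  emitted missing, never zero.
* mQTL enrichment is a 2×2 Fisher exact test ((A > 0.8) × has-mQTL) with the
  p-value assembled in log space from `dhyper(log = TRUE)`; the odds ratio
  is the sample cross-product ratio, flagged when a margin is empty. mQTL
  flags are consumed as a per-probe table — mQTL discovery is out of scope.
* Cross-tissue covariation stratification reports median A above/below a
  covariation cutoff (default 0.5), the Mann–Whitney p, and the overall
  Pearson correlation between A and the score.

## Cluster-robust EWAS

Exposure association is site-wise OLS (`beta ~ exposure + adjustments`) over
all samples with complete data, singletons included. Family relatedness is
absorbed by a cluster-robust sandwich covariance clustered on family id:

$$\widehat V = \frac{G}{G-1}\,\frac{n-1}{n-k}\;
(X'X)^{-1}\Big(\sum_g X_g'\hat u_g \hat u_g' X_g\Big)(X'X)^{-1},$$

with Wald t statistics on $G - 1$ degrees of freedom. CR1 with $t(G-1)$ is
the conservative common default; the original analysis does not state its
correction, and its authors note their own DMP count is sensitive to that
choice — so the package logs the flavor and the tests assert calibration
(empirical type-I error at 5% within [4%, 6%] under a clustered null where
naive OLS exceeds 7%) rather than a specific probe list. The default smoking
contrast codes current smokers against former-plus-never, per the source
design. DMPs are sites with p below 1e-7.

`dmp_heritability_report` then (i) contrasts A/C/E at DMPs against
background, (ii) recomputes per-site MZ/DZ correlations restricted to pairs
concordant-unexposed and sign-tests the count of sites with
$r_{MZ} > r_{DZ}$ — heritability detected in never-exposed pairs cannot be
induced by the exposure, which is the design's key confound-control idea —
and (iii) tabulates Falconer estimates within each exposure-concordance
class.

# The synthetic cohort: what it emulates, and what a green test establishes

The generator draws, per site, latent pair values
$\mu + a(g_1, g_2) + c(s, s) + e(u_1, u_2)$ with standard-normal factors,
$\mathrm{corr}(g_1, g_2) = 1$ (MZ) or $0.5$ (DZ, via
$g_2 = 0.5 g_1 + \sqrt{0.75}\,g'$), and $a^2 = A\,\mathrm{total\_sd}^2$ etc.
Defaults mirror the emulated cohort design: **426 MZ / 306 DZ same-sex
pairs**, ~48.5%/49.2% female. Where the stated world gives no value, defaults
were chosen once: per-site truth defaults to the genome-wide average
decomposition (A = 15.9%, C = 16.7%, E = 67.4%), mean beta 0.5, total SD 0.05
(a typical "variable" site), mQTL MAF 0.25 with +0.05 beta per allele
(within the published per-allele effect range), exposure prevalence and
concordance chosen to resemble young-adult smoking clustered in families.

Two beta-scale mappings bracket the unknown noise model: **linear-clip**
(latent Gaussian clipped to [0, 1]; variance components are exact on the
observed scale when clipping is negligible, and > 1% clipping is warned
about and recorded) is the test workhorse; **logistic** applies deviations on
the logit scale and emulates realistic boundary-compressed distributions, but
distorts beta-scale components, so only the ordering property
($r_{MZ} > r_{DZ}$ when $A > 0$) is asserted there. mQTL genotypes are drawn
by explicit parental transmission (MZ co-twins share both transmitted
alleles; DZ transmissions are independent), giving Hardy–Weinberg margins and
sibling genotype correlation 0.5 — the SNP analogue of the 0.5 polygenic
correlation used for the latent terms. A single master seed feeds named
sub-streams (latent, genotype, exposure, sex), so changing the site count
does not perturb genotype draws.

What the green suite establishes: the estimators recover the generator's
truth at cohort scale (mean bias < 0.03 at 426/306 pairs over 500 sites), the
three fitting routes agree where theory says they must, the sign test and
Fisher test match enumeration, and the clustered EWAS is calibrated under
family-correlated nulls. What it does **not** establish: behavior under real
array artifacts (probe cross-hybridization, batch structure beyond a label,
cell-composition confounding with realistic correlation structure,
non-Gaussian site distributions beyond the logistic bracket), nor the
published genome-wide summary numbers, which depend on the undeposited
cohort.

# Degenerate inputs and tie-breaks

Zero total variance at a site is an error for a direct fit and a recorded
per-site failure (never fatal) in the genome-wide driver. Correlations of
±1 entering Fisher's z are clamped to ±(1 − 1e-12) with a logged count.
chrY probes are skipped with a count; chrX probes are fitted per sex only.
Welch's test on two identical constant groups returns p = 1. Under-filled
profile windows are missing, not zero. The multi-start optimizer breaks
exact ties by keeping the first-listed start.

# Known limitations

No standard errors or submodel selection (AE/CE/E) on the per-site
estimates — point estimates only, as in the published resource this
emulates. No dominance (ADE) models. The FIML implementation assumes
equal means/variances across zygosity and twin order (the config-free
choice); the summary fit inherits the same constraint. Genome-scale inputs
(450k probes) are supported by the O(1)-per-evaluation likelihood but the
driver is single-threaded; per-site independence makes chunked
parallelization trivial if ever needed, and serial/parallel results would be
identical by construction.
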