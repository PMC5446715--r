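---
title: "Reference-free cell-mixture adjustment in EWAS by iteratively reweighted SVA"
author: "iwsva maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free cell-mixture adjustment in EWAS by iteratively reweighted SVA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iwsva)
```

## The problem

Bulk DNA methylation measured in a heterogeneous tissue such as whole blood
is a convex mixture of cell-type-specific profiles. Writing the probes x
samples matrix as

$$Y_{p \times n} = A_{p \times q} B_{n \times q}^{T} + E_{p \times n},$$

with $A$ the mean methylation of $q$ purified cell types and $B$ the
unobserved per-sample cell proportions, any phenotype that shifts cell
composition (age, smoking, disease state) induces genome-wide spurious
associations in per-CpG tests: cell-mixture confounding. When reference
profiles for $A$ are unavailable, the composition signal has to be
recovered from $Y$ itself. Because composition varies a lot between
individuals, it dominates the methylation covariance and is recoverable by
matrix decomposition — but a plain SVD (PCA) of $Y$ also absorbs the
phenotype signal itself when many CpGs are truly associated, which
destroys power in dense-signal studies.

## The estimator

Surrogate variable analysis resolves this by weighting probes before the
decomposition. Each iteration assigns probe $j$ the weight

$$w_j = p_{\gamma,j}\,\bigl(1 - p_{b,j}^{\alpha}\bigr),$$

where $p_{\gamma,j}$ is the estimated probability that probe $j$ is driven
by unmodeled factors (association with the current surrogate variables
given the full design) and $p_{b,j}$ the probability that it is driven by
the primary variable conditional on those surrogate variables. The top $K$
right singular vectors of the reweighted, row-centered matrix
$\mathrm{diag}(w)\,Y$ become the next surrogate variables. Probes that
track hidden structure but not the phenotype dominate the decomposition,
so the surrogate variables converge to the unmodeled factors rather than
the signal.

`smartSVA()` adds three things to this classic scheme:

1. **An explicit convergence criterion.** Iteration stops when the
   Spearman correlation between consecutive weight vectors exceeds
   `corrThreshold` (default 0.999, deliberately stringent). A fixed
   iteration count — classic SVA stops after `B = 5` passes — leaves the
   weights far from their fixed point exactly in the heavily confounded
   settings where adjustment matters most; the resulting surrogate
   variables capture composition poorly and the tests stay inflated. Mode
   `"classic"` reproduces that behaviour for benchmarking.
2. **A power transform on $p_b$.** At initialization the surrogate
   variables come from the residuals of $Y$ on the full design, so under
   confounding the early $p_{b,j}$ estimates soak up composition effects
   and are badly miscalibrated. Softening them as $p_{b,j}^{\alpha}$ with
   $\alpha = 0.25$ (default) speeds convergence substantially; very small
   $\alpha$ degenerates toward PCA-like solutions and loses dense-signal
   power, so 0.25 is a balance, and $\alpha = 1$ recovers the classic
   weight exactly. Whether the transform should apply in every iteration
   or only the first is not decisive from the method's description; both
   are implemented (`soften = "always"`, the default, or `"first"`) and
   the two differ little once converged.
3. **QR-factored F statistics.** Both probability vectors require a
   nested-model F test per probe per iteration. Both tests share the big
   model $[X_{\mathrm{full}}, \mathrm{SV}]$; with orthonormal bases
   precomputed once per iteration, all residual sums of squares come from
   two matrix products, so the cost per iteration is $O(np)$ in the probe
   count rather than $O(n^2 p)$.

### The empirical-Bayes probability estimates

The method's description defers the estimation of $p_\gamma$ and $p_b$ to
the local-false-discovery-rate literature, so the concrete estimator here
is a package choice, made for testability rather than bit-compatibility
with any particular implementation: p-values are probit-transformed
($z = \Phi^{-1}(p)$), the marginal density $f(z)$ is estimated by Gaussian
kernel density estimation (bandwidth multiplier 1.5 — slight
oversmoothing stabilises the tails), the null proportion is
$\hat\pi_0 = \min(1, \Pr(p > 0.8)/0.2)$, and
$\mathrm{lfdr}(z) = \hat\pi_0\,\phi(z)/\hat f(z)$, clipped to $[0,1]$ and
made monotone nondecreasing in $p$ by a running maximum. Then
$p_\gamma = 1 - \mathrm{lfdr}(p^{(\gamma)})$ and
$p_b = 1 - \mathrm{lfdr}(p^{(b)})$. The calibration contract is checked by
simulation: uniform p-values give mean lfdr near 1, and a spiked mixture
gets low lfdr in its signal tail. Probes with zero residual variance are
excluded from the density estimate, given $p = 1$ and weight 0, and kept
in the output.

### Choosing K: random matrix theory

`estimateComponentsRMT()` counts the eigenvalues of the sample covariance
of the standardized data exceeding the Marchenko–Pastur upper edge
$\sigma^2 (1 + \sqrt{n/p})^2$ — the analytic maximum for a pure-noise
matrix of the same aspect ratio (no Tracy–Widom correction). Two
numerical choices matter:

- **Standardization is sample-wise** (each column to mean 0, variance 1
  across probes), with $\sigma^2$ the grand variance of the standardized
  entries. Probe-wise standardization would force every probe to equal
  variance and thereby erase the between-probe variance differences that
  carry the structure; on this package's own generator it detectably
  undercounts (it misses most composition dimensions), while the
  sample-wise variant recovers the full planted dimensionality.
- **Residualization reduces the dimension.** When a design with $k$
  columns is projected out, the data live in an $(n-k)$-dimensional
  sample subspace. The data are therefore rotated onto an orthonormal
  basis of the complement, and the edge uses the reduced aspect ratio
  $(n-k)/p$; without the rotation the re-standardization inflates all
  eigenvalues by roughly $n/(n-k)$ and produces spurious components.

In the full pipeline `K` is estimated on the residuals of the full model,
so the primary variable itself never counts as a component.

Numerical conventions elsewhere: probes are row-centered before every SVD
(surrogate variables must capture variance, not probe means); for
$p \gg n$ the top right singular vectors are computed from the $n \times n$
cross-product; the sign of each surrogate variable is fixed by forcing its
largest-magnitude entry positive; Spearman ties use average ranks, and two
weight vectors with zero rank variance count as converged only if equal.
Non-convergence at `maxIter` (default 100) is a warning, not an error,
because comparing against non-converged classic fits is part of the
intended use.

## What the simulator emulates

`simulateMethylation()` generates bulk methylation with known ground truth
along the pipeline: a stem-cell reference profile drawn from a
three-component normal mixture on the M-value scale (hypo-, hemi-,
hyper-methylated CpGs, giving the characteristic bimodal beta
distribution); two progenitors and eight leukocyte subtypes derived along
a two-lineage tree, each differentiation step perturbing a random probe
subset; per sample x subtype individual-specific differences; phenotype
effects at a designated DMP set (one shared M-scale effect per DMP by
default); Dirichlet cell proportions whose mean is tied to the phenotype
through per-subtype log2 fold changes $f_k \sim N(0, \sigma_F^2)$ — the
confounding dial; beta-scale mixing of the subtype profiles by the
proportions; then batch shifts (five balanced batches, assigned round-robin
after a random permutation, hence independent of phenotype) and
measurement error, both on the M-value scale. The beta and M views are
mutually consistent by the logit2 transform throughout.

### Default parameters

Defaults were fixed once, by calibrating the generator to the qualitative
regime the method addresses — an unadjusted analysis visibly inflated
under strong confounding, a "Perfect" adjustment (true proportions plus
batch indicators) well calibrated, and the true structure (7 composition
+ 4 batch dimensions at $q = 8$, 5 batches) detectable from the data —
while staying in the range of real blood methylation:

| parameter | default | meaning |
|---|---|---|
| `p`, `n` | 10,000, 100 (50/50 groups) | probes, samples |
| `mixture` | means (−4, 0, 4), sds 0.6, probs (0.45, 0.10, 0.45) | reference M-value mixture |
| `lineage` | `piC` 0.10, `sigmaC` 3.0 | fraction and sd of per-step cell-type differences |
| `individual` | `piI` 0.05, `sigmaI` 0.5 | individual-specific probes per sample x subtype |
| `signal` | `piG` 0.01, `sigmaG` 1.0, shared | DMP density and M-scale effect sd |
| `proportions` | blood-like `piP`, `phi` 20 | Dirichlet mean and concentration |
| `confounding` | `sigmaF` 0 | log2-fold-change sd linking phenotype to proportions |
| `batch` | 5 batches, `sigmaB` 0.3, all probes | batch shift sd |
| `noise` | `sigmaE` 0.3 | measurement error sd |

`sigmaC = 3` and `piC = 0.10` put cell-type-specific CpG contrasts at
$|\Delta\beta|$ up to ~0.5 with roughly 65% of probes differing somewhere
in the panel, and `phi = 20` gives proportion sds of ~0.04–0.10 —
both at the realistic end for purified leukocytes and healthy blood
donors. Weaker settings (e.g. `sigmaC` ~1, `phi` 50) leave the
composition eigenvalues below the detection edge: no reference-free
method can then recover the confounder, the unadjusted analysis is barely
inflated, and the benchmark becomes uninformative about the method.
Scenario studies vary `piG` over {0.001, 0.01, 0.1} and `sigmaF` over
{0, 0.3, 0.6} (no/moderate/strong confounding).

What the generator does **not** emulate: array probe-level artifacts
(type I/II probe chemistry, detection failures), genotype-driven
methylation, correlated CpG blocks (probes are conditionally independent
given the factors), non-Gaussian effect distributions, and missing
values. Passing tests therefore demonstrate correct behaviour under a
linear-mixture, factor-structured world with Gaussian perturbations — the
model class the estimator targets — not performance on any particular
array platform.

## Evaluation metrics

`fitEwas()` runs per-CpG OLS of M-values on
[intercept, adjustment, phenotype] with two-sided t-tests on the phenotype
coefficient, vectorized through one QR decomposition. `scoreRun()`
computes, against the simulation truth:

- **Genomic inflation on non-DMPs**: p-values are converted to 1-df
  chi-square quantiles and $\lambda = \mathrm{median}(\chi^2)/0.456$. The
  denominator is kept at the conventional printed value 0.456 rather than
  the exact null median 0.45494, so perfectly uniform p-values give
  $\lambda \approx 0.998$.
- **Observed FDR** after Benjamini–Hochberg at 5%:
  false discoveries / max(discoveries, 1).
- **FWER indicator** after Bonferroni at 5% (strict inequality
  $p < 0.05/m$); aggregated over replicates it estimates the family-wise
  error rate.
- **TPR** after each correction; reported as `NA` and excluded from
  aggregation when no DMPs were planted.
- **Cell-composition adjusted $R^2$**: canonical correlations $\rho_i$
  between the components and the proportions (last column dropped for the
  simplex redundancy), $R^2 = 1 - \prod_i (1 - \rho_i^2)$ with an
  Ezekiel-style correction $1-(1-R^2)(n-1)/(n-K-1)$. The exact
  multivariate statistic is not pinned down by convention; this form
  satisfies the endpoint contract (≈1 when the components span the
  proportions, ≈0 for independent noise, invariant under invertible
  linear transforms of either block) and that contract, not the formula,
  is what the tests assert.

`runBenchmark()` crosses signal density with confounding strength and
evaluates unadjusted, PCA (same K as the SVA fits, from RMT), classic SVA
(`B = 5`), the convergence-controlled fit, and the "Perfect" upper bound,
which adjusts for the true proportions (dropping the last column) and
batch indicators (dropping the first level) — the dropped columns are
fixed so designs are never singular.

## Problem sizes and what the checks cover

The study-scale checks in this package run the nine-scenario grid at
p = 10,000, n = 100 with 20 replicates per scenario, report means with
standard errors (sd/√reps), and assert: FDR and FWER within two
Monte-Carlo standard errors of the nominal 5%; unadjusted
$\lambda > 1.5$ under strong confounding while the adjusted
$\lambda$ stays in [0.85, 1.15]; dense-signal TPR at least that of PCA
and at least 0.7 of "Perfect"; composition $R^2 \ge 0.8$ and at least
classic SVA's under strong confounding; RMT planted-rank recovery over
100 seeds. Unit tests run the same operations at smaller sizes against
per-probe oracles. One caveat on the unadjusted comparator: even with no
confounding, omitted shared factors (batch, composition) combine with
their chance sample correlation to the phenotype to lift its $\lambda$
slightly above 1 (~1.2 at these sizes); that is a property of the design,
not an error in the tests.

## Known limitations

- The number of surrogate variables is exactly the RMT count; no
  uncertainty in $K$ is propagated. If the composition eigenvalues sit at
  the detection edge the adjustment degrades gracefully but the FDR
  guarantee weakens — this is intrinsic to reference-free adjustment, as
  the comparison with forced larger $K$ shows.
- Surrogate variables enter the association model as fixed covariates;
  their estimation uncertainty is ignored, as is standard.
- The lfdr estimator is a calibration-contract implementation; other
  choices (different bandwidths, spline-based $\pi_0$) shift probe
  weights slightly but not the fixed point.
- Mixing is linear on the beta scale while testing is on M-values; the
  induced nonlinearity means no linear adjustment — including the
  "Perfect" one — removes confounding exactly. The benchmark treats
  "Perfect" as the attainable bound for that reason.
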