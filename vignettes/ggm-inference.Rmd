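---
title: "Statistical inference for large-scale Gaussian graphical models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical inference for large-scale Gaussian graphical models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggminfer)
```

## The model and why point estimates are not enough

A gene co-expression network built from marginal correlations confounds
direct and indirect association: two genes can be strongly correlated only
because both respond to a third. The Gaussian graphical model (GGM) works
instead with the *precision matrix* $\Omega = \Sigma^{-1}$ of a
$p$-dimensional normal vector $X \sim N(0, \Sigma)$: genes $i$ and $j$ are
conditionally independent given all other genes if and only if
$\omega_{ij} = 0$, and the partial correlation is
$-\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}$. An edge in the network is a
non-zero $\omega_{ij}$.

In the high-dimensional regime ($p \gg n$) sparse point estimators such as
the graphical lasso recover a network but attach no uncertainty to any
edge. The methods in this package instead produce, for every pair, an
estimator that is *asymptotically normal* after a one-step bias
correction, with variance equal to the inverse Fisher information
$(\omega_{ii}\omega_{jj} + \omega_{ij}^2)/n$. That turns edge detection
into ordinary z-tests: confidence intervals and p-values per pair, and a
multiple-testing procedure with false-discovery-rate (FDR) control over
all $(p^2-p)/2$ pairs. The asymptotics hold under the usual sparsity
condition that the maximum node degree $s$ satisfies $s = o(n/\log p)$.

## The four estimators

All methods share a two-step structure. Step one is a lasso-type convex
program: either $p$ nodewise regressions of each gene on all others, or
one graphical lasso. Step two converts the fitted residual moments (or the
penalized precision estimate) into bias-corrected, asymptotically normal
quantities for every pair.

Write $\hat\beta_{\cdot,i}$ and $\hat\epsilon_i$ for the coefficients and
residuals of the regression of gene $i$ on the rest, and
$\hat r_{ij} = \hat\epsilon_i^\top \hat\epsilon_j / n$ for the residual
moments. The first-order bias correction is

$$\tilde r_{ij} = -\bigl(\hat r_{ij} + \hat r_{ii}\,\hat\beta_{i,j}
  + \hat r_{jj}\,\hat\beta_{j,i}\bigr), \qquad
  \check\omega_{ij} = \frac{\tilde r_{ij}}{\hat r_{ii}\hat r_{jj}},$$

which is an exact fixed point at the population values (a property the
test suite checks symbolically on a 3×3 precision matrix).

* **B_NW_SL** — nodewise *scaled* lasso (penalty and noise scale estimated
  jointly, so no tuning), followed by the correction above. The package
  realizes the pairwise estimator through $p$ regressions rather than
  $O(p^2)$ pairwise fits; both give the same first-order corrected
  estimates and the former is the only practical choice at large $p$.
* **D-S_NW_SL** — the de-sparsified relaxed inverse: with
  $\hat\Theta_{jj} = 1/\hat\sigma_j^2$,
  $\hat\Theta_{kj} = -\hat\beta_{k,j}/\hat\sigma_j^2$, the estimator is
  $\check\Omega = \hat\Theta + \hat\Theta^\top -
  \hat\Theta^\top \hat\Sigma \hat\Theta$. With no penalty and $n > p$ this
  is exactly the inverse sample covariance.
* **D-S_GL** — the de-sparsified graphical lasso
  $\check\Omega = 2\hat\Omega - \hat\Omega \hat\Sigma \hat\Omega$, with
  $\hat\Omega$ from the penalized log-determinant program at the
  tuning-free penalty $\sqrt{\log(p)/n}$.
* **GFC_SL / GFC_L** — the standardized statistics
  $\hat T_{ij} = \sqrt{n}\,\tilde r_{ij}/\sqrt{\hat r_{ii}\hat r_{jj}}$,
  built for simultaneous testing rather than interval estimation (no
  confidence intervals are defined for them). GFC_SL uses scaled-lasso
  regressions; GFC_L uses plain-lasso regressions with the penalty chosen
  by a null-calibration criterion (below).

## Global inference with FDR control

Each method yields asymptotically $N(0,1)$ statistics under the null, so a
single thresholding procedure serves all of them. For a level $\alpha$,
the threshold is

$$\hat t = \inf\Bigl\{\,0 \le t \le \sqrt{2\log p}:
  \frac{G(t)\,(p^2-p)/2}{\max(R(t),1)} \le \alpha\Bigr\},$$

with $G(t) = 2(1-\Phi(t))$ the two-sided null tail and $R(t)$ the number
of pairs with $|\hat T_{ij}| \ge t$. The numerator estimates the false
rejections under the null; the ratio estimates the FDR. The search is
performed exactly over the finite candidate set $\{0\}$ plus the observed
$|\hat T_{ij}|$ within range — the rejection set only changes at observed
values, so scanning the jump points finds the same decisions as the
continuous infimum. When no candidate qualifies, the Bonferroni-flavoured
fallback $2\sqrt{\log p}$ is used (configurable), which at that point
rejects only overwhelming statistics. Ties ($|\hat T_{ij}| = \hat t$)
count as rejections. Thresholds are non-increasing and decision sets
nested in $\alpha$, which the property tests assert directly.

**GFC_L penalty selection.** The lasso statistics are computed along the
descending grid $\lambda_k = (k/20)\sqrt{\log(p)/n}$, $k = 40..1$, each
fit warm-started from the previous penalty. For each $\lambda$ the
selection criterion compares the observed exceedance counts with their
null expectation in the moderate tail,
$$\sum_{s=1}^{10}\Bigl(\frac{R(q_s)}{G(q_s)(p^2-p)/2} - 1\Bigr)^2,
  \qquad q_s = \Phi^{-1}\!\bigl(1 - \tfrac{s}{10}(1-\Phi(\sqrt{\log p}))\bigr),$$
and the minimizing $\lambda$ is kept. The idea: at a good penalty the bulk
of the statistics behaves like the null, so exceedance counts match their
theoretical frequency and the downstream FDR estimate is honest.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `lambda0` (scaled lasso) | $\sqrt{2\log(p)/n}$ | scale-free universal penalty; the effective penalty is `lambda0` times the estimated noise SD |
| `lambda` (graphical lasso) | $\sqrt{\log(p)/n}$ | tuning-free penalty; off-diagonal entries only |
| GFC_L grid | $(k/20)\sqrt{\log(p)/n},\ k=1..40$ | descending for warm starts |
| `alpha` | `c(0.05, 0.1)` | FDR level sequence for global inference |
| `ci_level` | 0.95 | entrywise confidence level |
| `tol` / `max_iter` | `1e-6` / `10000` | coordinate-descent stopping rule (max absolute coefficient change per sweep) |
| outer `tol` / iterations | `1e-6` / 100 | scaled-lasso noise-scale fixed point |
| `sigma_floor` | `1e-8` | below this residual scale a gene is reported as degenerate (near-duplicate) rather than producing infinite statistics |

The noise scale uses denominator $\sqrt{n}$ (no degrees-of-freedom
correction). This is deliberate: it makes the no-penalty, $n > p$ limit of
all three individual-inference methods collapse *exactly* onto the inverse
sample covariance, which the tests assert at `1e-8`.

## Numerical design

The coordinate-descent core works entirely in Gram form: $X^\top X/n$ is
computed once per data set and every nodewise problem reuses it, with
residual inner products maintained incrementally at each coefficient
update (covariance updates) — the raw data matrix is never rescanned.
Coordinates are visited in fixed ascending order, making runs
bit-reproducible. Between full verification sweeps the solver iterates
only over the currently active (non-zero) coefficients. De-sparsification
products $\Theta^\top \hat\Sigma \Theta$ iterate over the non-zero entries
of $\Theta$'s columns only, reducing the $O(p^3)$ dense cost to $O(sp^2)$;
an instrumented operation count verifies this in the tests. The graphical
lasso is solved by block coordinate descent over columns, each column a
lasso on the working covariance, with a duality-gap stopping rule
(`tr(S\Omega) - p + \lambda\|\Omega\|_{1,\mathrm{off}}`, zero at the
optimum).

Degenerate inputs are refused loudly: zero-variance genes are named when
standardizing; genes whose nodewise residual scale collapses below the
floor (duplicated columns) raise an error instead of producing infinite
z-scores; `p < 3` is rejected by the FDR machinery since there is no
multiplicity to control. Non-convergence of a lasso solve warns and
returns the flagged result rather than aborting — at the smallest
penalties of the GFC_L grid with $p > n$ the Gram matrix is singular and
the iteration cap can be reached without harming the selection, which
virtually never picks those penalties.

## The synthetic truth

`ggm_graph()` builds the four standard topologies: band
($\omega_{i,i\pm1} = 0.6$, $\omega_{i,i\pm2} = 0.3$), hub (disjoint groups
of 10, hub–member value 0.3), Erdős–Rényi (edge probability $5/p$ by
default, so the expected node degree is about 5, edge values $\pm 0.3$),
and scale-free (preferential-attachment tree, value 0.3). When a skeleton
is not positive definite the diagonal is shifted by
$|\lambda_{\min}| + 0.05$, which never changes the off-diagonal support; a
diagonal-dominance variant is available by flag. The band values 0.6/0.3
follow the settings used throughout the FDR-testing literature for this
model family; the hub and random-graph values are chosen so the skeletons
remain well-conditioned at the default sizes without a shift dominating
the spectrum.

What the generator deliberately does *not* emulate: single-cell count
noise (dropout, library-size variation), heavy-tailed marginals, or
sample dependence. The count transforms (`log2p1()`, `npn_transform()`)
model only the documented preprocessing endpoint — rank-based
Gaussianization preserves the copula and hence the network, which is the
property the tests check (exact invariance under monotone maps). Passing
tests on this generator therefore validate the *inferential machinery*
under its stated assumptions, not robustness to real scRNA-seq artefacts.

One implementation note on `npn_transform()`: the normal scores
$\Phi^{-1}(\mathrm{rank}/(n+1))$ are exactly mean-zero only for tie-free
columns, so the transform centers each column before scaling to unit
sample variance; with ties (common in counts) this keeps the output
exactly centered while changing nothing else.

## Validation protocol and problem sizes

The test suite recomputes, per method: interval coverage split by the
zero / non-zero partial-correlation sets, type-I/II error at level 0.05,
realized false discovery proportion and power of the global procedure,
Matthews correlation of edge recovery, and the log2–log2 degree
diagnostic (raw points plus a least-squares slope; the lowess smoothing
used for visual figures is intentionally omitted from the automated
check). The headline simulations run at n = 400, p = 200 with 20
replicates for coverage and type-I error, n = 100, p = 200 with 50
replicates for FDR control of GFC_L, and p = 1000 with 100 seeds for the
generator calibration — sizes chosen so the full suite completes in
minutes on one core while keeping Monte-Carlo error well inside the
asserted tolerances (about 0.005 for a coverage proportion at these
counts). `scripts/acceptance.R` reruns exactly these four studies from
scratch under a single seed and writes the summary numbers as JSON.

## Known limitations

* GFC_SL / GFC_L provide no confidence intervals, and no inference is
  offered on diagonal entries (the display matrices zero the diagonal;
  the diagonal precision estimates are retained in a separate field).
* The MLE baseline needs $n > p$ and grows unstable as $n \to p$; it
  exists for comparison, not use.
* The FDR guarantee is asymptotic and assumes the statistics are
  approximately standard normal under the null; heavy departures from
  Gaussianity should be handled with the nonparanormal transform first.
* Penalty defaults are the theory-backed tuning-free choices, not
  cross-validated; cross-validation is deliberately out of scope.

## A worked example

```{r example, eval = FALSE}
model <- ggm_graph("band", p = 50, seed = 1)
x <- sample_mvn(model, n = 300, seed = 2)
fit <- ggm_infer(x, method = "B_NW_SL", global = TRUE,
                 true_graph = model$adjacency)
fit
summary(fit)
ci_coverage(fit$individual, model)
as.data.frame(fit, sort_by_significance = TRUE)[1:5, ]
```
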