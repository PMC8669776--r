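---
title: "FDR estimation versus FDR control: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FDR estimation versus FDR control: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multifdr)
```

## The two quantities

Let $p_1,\dots,p_m$ be raw p-values for $m$ features, $p_{(1)} \le \dots \le
p_{(m)}$ their order statistics, and $\gamma$ an FDR threshold. The
Benjamini–Hochberg step-up procedure selects features of rank $1..k$ where
$k = \max\{i : p_{(i)} \le \gamma i/m\}$. Two distinct per-feature summaries
arise from this machinery:

* **Adjusted p-values** $\tilde p_{(i)} = \min_{j \ge i} p_{(j)} m / j$: the
  smallest $\gamma$ at which feature $i$ is selected. The running minimum
  (step-up smoothing) makes them monotone in rank; comparing $\tilde p_i \le
  \gamma$ reproduces the procedure's selections exactly. This is what
  `stats::p.adjust` returns.
* **FDR estimates** $\mathrm{FDR}_i = p_i \, m / \mathrm{rank}(p_i) \cdot
  \hat\pi_0$: the inversion of the selection criterion into an
  empirical-Bayes estimate of the propensity of feature $i$ itself to be a
  false discovery. No step smoothing is applied — smoothing belongs to
  control, not estimation — so the estimates need not be monotone, and the
  set $\{i : \mathrm{FDR}_i \le \gamma\}$ generally differs from the
  procedure's rejection set.

`pFDR()` returns both, plus rejection labels obtained by comparing the
*adjusted p-values* (never the FDR estimates) to the threshold.

The same split applies to each supported method. With $r_i =
\mathrm{rank}(p_i)$, the FDR estimates before capping are

| method | FDR estimate | adjusted p-value | step |
|---|---|---|---|
| BH | $p_i m/r_i \cdot \hat\pi_0$ | $\min_{j\ge i} p_{(j)} m/j$ | up |
| BY | $p_i m c(m)/r_i \cdot \hat\pi_0$ | $\min_{j\ge i} p_{(j)} m c(m)/j$ | up |
| Bonferroni | $p_i m \cdot \hat\pi_0$ | $p_i m$ | none |
| Sidák | $(1-(1-p_i)^m) \cdot \hat\pi_0$ | $1-(1-p_i)^m$ | none |
| Holm | $p_i (m{+}1{-}r_i) \cdot \hat\pi_0$ | $\max_{j\le i} p_{(j)}(m{+}1{-}j)$ | down |
| Hochberg | $p_i (m{+}1{-}r_i) \cdot \hat\pi_0$ | $\min_{j\ge i} p_{(j)}(m{+}1{-}j)$ | up |

All outputs are capped at 1 — for the FDR estimates, *after* the $\hat\pi_0$
multiplication. $\hat\pi_0$ enters the FDR estimates only; adjusted p-values
carry no $\hat\pi_0$ term, reading the displayed forms literally. For methods
without a step component (Bonferroni, Sidák) the two columns coincide
whenever $\hat\pi_0 = 1$.

The BY correction is the harmonic sum $c(m) = \sum_{j=1}^m 1/j$, valid under
flexible positive dependence. No published $c(m)$ exists for the "negative"
correlation option, so the same harmonic sum — the most conservative
published choice — is used there too; `fdrEstimate()`/`adjustPValues()`
expose a `cm` hook for callers who want a different factor (setting
`cm = 1` recovers BH exactly, which the tests assert).

## Ranks and ties

Ranks default to `ties.method = "random"`: tied blocks receive a random
permutation of their rank range. Randomness here is driven by a tie seed
stored in the `PValueSet` — an internal fixed seed when the caller supplies
none — so results are reproducible by default and the caller's RNG stream is
never disturbed. Step procedures order features consistently with these
resolved ranks, so rank-based formulas and threshold searches share one tie
resolution. NA p-values are removed by default and `m` counts only retained
values (counting NAs as viable features silently deflates every
`m`-dependent adjustment).

## Null proportion estimation

The mixing proportion $\pi_0$ (fraction of truly null features) scales the
FDR estimates. The conservative default is $\pi_0 = 1$. Estimators:

* **Last Histogram Height.** Null p-values are uniform on $[0,1]$, so in an
  equal-width $B$-bin histogram each bin is expected to hold $\pi_0 m / B$
  null values, while alternatives pile up near 0. The height $H_B$ of the
  bin adjacent to 1 gives $\hat\pi_0 = \min(1, H_B B / m)$. Bins default to
  Scott's normal reference rule, $h = 3.49\,\mathrm{sd}(p)\,m^{-1/3}$,
  translated to $B = \lceil 1/h \rceil$ bins anchored at 0 and 1 (the
  anchoring is this package's convention; the rule itself says nothing about
  it). When $\mathrm{sd}(p) = 0$ or $h \ge 1$ the rule degenerates to a
  single bin, so $B = \lceil\sqrt m\rceil$ is used instead. Bins are
  half-open $[a,b)$ with the final bin closed so $p = 1$ is counted.
* **Storey.** $\hat\pi_0(\lambda) = \#\{p_i > \lambda\}/(m(1-\lambda))$ on a
  grid of $\lambda$, smoothed by a natural cubic smoothing spline with 3
  effective degrees of freedom and read off at the largest $\lambda$. The
  grid $0.05, 0.10, \dots, 0.95$ and the spline settings follow the
  estimator's conventional published defaults; single-$\lambda$ grids (and
  grids of length 2–3, too short for a spline) return the raw tail-count
  estimate.
* **Pounds.** $\hat\pi_0 = \min(1, 2\bar p)$.

All estimates are capped into $[0,1]$ before use, since sampling noise can
push the raw ratios above 1.

## Lower bound on the FDR

For a single finding with Z-value $z$ (two-sided p-values transform as
$z = \Phi^{-1}(1 - p/2)$; $p = 0$ is clamped to the smallest positive double
so the transform stays finite), the posterior probability of the null under
a Gaussian model is bounded below by

$$\Big(1 + e^{z^2/2}\,\tfrac{\pi_1}{\pi_0}\Big)^{-1},$$

with default prior odds $\pi_1/\pi_0 = 1$. The bound uses the asymptotic
$\chi^2$ form of the likelihood ratio rather than the exact ratio, which a
p-value-only interface cannot know; this is also what makes the bound
computable from a single p-value. It peaks at $1/(1+\mathrm{odds})$ — exactly
$1/2$ at $z = 0$ with odds 1 — and decreases strictly in $|z|$ and in the
odds. It serves as a best-case benchmark: an FDR estimate *below* the bound
signals optimism of the estimation assumptions, and adjusted p-values
routinely fall below it, one more reason not to read them as FDRs.

The one-sided "less" convention $z = \Phi^{-1}(p)$ is the natural mirror of
the "greater" case; it is a package convention, chosen once, not a published
statement.

## Two-group model

`TwoGroupModel` represents $f(z) = \pi_0 f_0(z) + \pi_1 f_1(z)$ with both
components Gaussian (theoretical null $N(0,1)$; the alternative family is
restricted to Gaussians, matching the model's standard illustration
$f_1 = N(2,1)$). `fdrRegion()` evaluates the empirical-Bayes FDR of a tail
region by Bayes' theorem, $\mathrm{FDR}(\mathcal Z) = \pi_0
F_0(\mathcal Z)/F(\mathcal Z)$; regions are one- or two-tailed half-lines
(arbitrary Borel sets are out of scope). Plugging the empirical step CDF
$\hat F = \mathrm{rank}(p_i)/m$ and $F_0 = p$ into this formula with
$\pi_0 = 1$ recovers the BH per-feature estimate exactly — the identity that
ties the p-value and Z-value views together, asserted in the test suite.

## Simulation design

`simulatePValues()` generates the two-group data used throughout testing:
per replicate, $\mathrm{round}(m\,\pi_0)$ null features with
$p \sim U(0,1)$ and the rest from either $U(0, 0.01)$ (a sharply skewed
alternative) or a Gaussian shift $z \sim N(2,1)$ converted to p-values under
the stated sidedness. These two alternatives are the configurations the
benchmarked designs specify; both defaults (u = 0.01; mean 2, sd 1) are
kept fixed. Output is bit-reproducible under a seed, with labels fixed as
the leading block of each replicate.

Evaluation designs used by the test suite, at sizes chosen to keep a full
run within minutes on one CPU while leaving Monte-Carlo error well inside
the asserted margins:

* **Realized FDR**: 1,000 replicates of $m = 100$, $\pi_0 = 0.8$,
  $U(0,0.01)$ alternatives; BH at $\gamma = 0.05$ must keep the mean
  realized false discovery proportion (false selections / selections, 0 when
  nothing is selected — the standard convention) below $0.05 + 3$
  Monte-Carlo standard errors, with BY no less conservative on the same
  batches.
* **π0 recovery**: 200 replicates of $m = 1{,}000$ at true
  $\pi_0 \in \{0.5, 0.8, 1\}$; Last Histogram Height and Storey must land
  within 0.05 of the truth on average. Smaller-scale variants of both
  designs run in the regular unit tests.

What these simulations emulate is independent features with a clean null;
they do not probe correlated test statistics, composite or misspecified
nulls, or discretely supported p-values, so passing them says nothing about
robustness to dependence — BY's harmonic correction exists precisely for
that case and is exercised here only under independence, where it is simply
conservative.

## Numerical conventions and limitations

* Capping order: $\hat\pi_0$ multiplication first, then step smoothing
  (where applicable), then the cap at 1.
* `stepRejection()` implements the raw threshold searches (step-up for BH /
  BY / Hochberg, step-down for Holm) directly on ordered raw p-values; its
  selections provably equal `adjustPValues(...) <= gamma`, and the suite
  checks that equivalence on a thousand random vectors — the two code paths
  act as mutual oracles.
* Degenerate inputs: empty sets and out-of-range values fail loudly with the
  offending position; a single p-value reduces every method to the identity;
  zero-mass regions make the region FDR undefined and raise an error.
* `evaluatePi0Methods()` derives per-cell seeds from the base seed and keeps
  them below $2^{31}$.
* Known limitations: no dependent-feature simulation, no q-values or local
  fdr curves, no empirical-null estimation, and no confidence intervals for
  $\hat\pi_0$.
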