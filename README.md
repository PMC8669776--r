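# multifdr

False discovery rate **estimation** and FDR/FWER **control** for multiple
testing, kept distinct.

When many features are tested at once, two different quantities are routinely
conflated:

* the **adjusted p-value** `p~_i` — the smallest threshold γ at which feature
  *i* would be selected by a control procedure (e.g. Benjamini–Hochberg
  step-up). Adjusted p-values are monotone in raw-p rank by construction and
  are the right tool for *controlling* the group-wise FDR at γ.
* the **per-feature FDR estimate** `FDR_i` — the propensity of that specific
  finding to be a false discovery. For Benjamini–Hochberg this is the
  inversion `FDR_i = p_i · m / rank(p_i) · π̂0`, with no step smoothing, and
  it is **not** monotone in rank.

A feature can be selected by a procedure controlling the FDR at γ while its
own estimated FDR exceeds γ. `multifdr` computes both quantities, for six
adjustment methods (BH, BY with the harmonic correction `c(m) = Σ 1/j`,
Bonferroni, Sidák, Holm, Hochberg), for audiences ranging from genomics-scale
screens down to a single test.

Also included:

* **π0 (null proportion) estimation** — fixed value, *Last Histogram Height*
  (`π̂0 = H_B · B / m`, the occupancy of the p-value histogram bin adjacent
  to 1, with Scott's rule binning), Storey's smoothed-λ estimator, and the
  Pounds estimator `min(1, 2·p̄)`.
* a **univariate Gaussian lower bound** on the FDR of a single finding,
  `(1 + exp(z²/2)·π1/π0)⁻¹`, usable even when only one p-value exists.
* a **two-group Gaussian mixture model** on the Z scale with the
  empirical-Bayes FDR of tail regions, `FDR(Z) = π0·F0(Z)/F(Z)`.
* **simulation machinery**: labeled two-group p-value generation, realized
  FDR/power of the control procedures, and bias/MSE benchmarking of the π0
  estimators.
* plain-text I/O, diagnostic plots, and a command-line tool
  (`exec/multifdr`).

## Worked example

Five features with two-sided p-values:

```r
library(multifdr)
res <- pFDR(c(0.005, 0.049, 0.050, 0.051, 0.700))
res
#> FDRResult: BH adjustment, 5 feature(s)
#>   threshold: 0.05  pi0: 1 (set.pi0)
#>   rejections: 1 of 5
#>   feature raw_p adjusted_p     fdr lower_bound_fdr    reject
#> 1       1 0.005    0.02500 0.02500         0.01908 Reject.H0
#> 2       2 0.049    0.06375 0.12250         0.12590    FTR.H0
#> 3       3 0.050    0.06375 0.08333         0.12778    FTR.H0
#> 4       4 0.051    0.06375 0.06375         0.12964    FTR.H0
#> 5       5 0.700    0.70000 0.70000         0.48145    FTR.H0
```

Reading the table: controlling the FDR at 5% selects only feature 1 (its
adjusted p-value 0.025 is the only one ≤ 0.05). The FDR column is *not*
monotone — 0.1225 > 0.0833 > 0.0638 — because FDR estimation applies no
step-up smoothing. At γ = 0.07 the step-up procedure would select features
1–4, yet only features 1 and 4 have estimated FDRs below 0.07:

```r
stepRejection(c(0.005, 0.049, 0.050, 0.051, 0.700), gamma = 0.07)$k
#> [1] 4
which(fdrEstimate(c(0.005, 0.049, 0.050, 0.051, 0.700)) < 0.07)
#> [1] 1 4
```

The `lower_bound_fdr` column is the Gaussian lower bound at default prior
odds 1: feature 4's estimated FDR (0.064) sits *below* its best-case bound
(0.130), flagging the estimate as potentially optimistic.

The same computation from a shell:

```sh
Rscript exec/multifdr compute --input inst/extdata/example5_pvalues.txt \
    --method BH --threshold 0.05 --lower-bound
```

Estimating the null proportion instead of fixing it:

```r
pi0Value(getPi0(runif(1000), estimMethod = "last.hist"))   # ~1 on null data
res <- pFDR(p, estimMethod = "last.hist")                  # scales the FDRs
```

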