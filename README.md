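# netqdiag

Inconsistency diagnostics for fixed-effects network meta-analysis.

A network meta-analysis combines randomized trials that compare different
subsets of treatments, so that every pairwise contrast can be estimated by
pooling direct evidence with indirect evidence routed through the rest of
the network. The validity of those estimates rests on *consistency*:
direct and indirect evidence must agree. One deviating set of trials can
perturb many network estimates at once, producing a "hot spot" of
inconsistency that is hard to trace by eye. `netqdiag` is a diagnostic
toolkit for locating such hot spots, aimed at meta-analysts working with
contrast-level trial summaries (log odds ratios, mean differences, ...)
and their standard errors.

## The model and the diagnostics

Studies are grouped by *design* — the full set of treatments a study
compares. The fixed-effects analysis is done in two stages:

1. **Component meta-analyses.** The studies of each design *d* are pooled
   by inverse-variance weighting into a direct estimate with known
   covariance,
   θ̂ᵈⁱʳ_d = (Σₛ V⁻¹ₛ)⁻¹ Σₛ V⁻¹ₛ Yₛ, Vᵈⁱʳ_d = (Σₛ V⁻¹ₛ)⁻¹.
   Multi-arm studies enter as correlated contrast blocks, so the pooling
   is a matrix-weighted mean.
2. **Network GLS.** The stacked direct estimates follow the linear model
   θ̂ᵈⁱʳ = X_a θ + ε, Cov(ε) = V_a (block diagonal), and the T basic
   parameters (contrasts versus the network reference) are estimated by
   generalized least squares, θ̂ = (X_a′V_a⁻¹X_a)⁻¹X_a′V_a⁻¹θ̂ᵈⁱʳ.

Three diagnostics are built on this fit:

- **Hat matrix** H = X_a(X_a′V_a⁻¹X_a)⁻¹X_a′V_a⁻¹. Row d′ gives the
  linear weight of every direct estimate in the network estimate of d′ —
  the generalization of meta-analysis weights, revealing which designs
  *drive* which estimates. trace(H) = T; the diagonal entry is the weight
  of a design's own direct evidence.
- **Q decomposition.** The network Cochran statistic splits exactly as
  Qⁿᵉᵗ = Qʰᵉᵗ + Qⁱⁿᶜ into within-design heterogeneity (summed per-design
  Cochran statistics) and between-design inconsistency
  Qⁱⁿᶜ = (θ̂ᵈⁱʳ − X_aθ̂)′V_a⁻¹(θ̂ᵈⁱʳ − X_aθ̂), each approximately
  chi-squared under the respective null.
- **Design detaching.** Refitting with one design's effect freed from the
  consistency constraints (equivalent to holding its studies out) yields
  the residual statistic Q⁽ᵈ⁾ⁱⁿᶜ and the Q-difference matrix
  Q^diff_{d′,d} = Qⁱⁿᶜ_{d′} − Q⁽ᵈ⁾ⁱⁿᶜ_{d′}: how much detaching design d
  changes design d′'s squared standardized residual. The **net heat plot**
  shows this matrix as clustered colors (warm = detaching reduces
  inconsistency, blue = it increases it, saturating at |8|) with overlaid
  gray squares of area |H_{d′,d}|.

## Worked example

The built-in eight-design, six-treatment network has unit-variance direct
estimates, all zero except a shift of 5 on design 1:2:

```r
library(netqdiag)
fit <- netgls(make_scenario("fig1_a"))
fit
#> Fixed-effects network meta-analysis (two-stage GLS)
#> 8 studies, 8 designs, 6 treatments (reference: 1)
#>
#> Basic parameters (versus 1):
#>   estimate     se
#> 2   3.1667 0.7958
#> 3   1.3333 0.7303
#> 4   0.8333 0.9129
#> 5   0.6667 1.0646
#> 6   0.5000 0.8367
#>
#> Q_net = 9.17 (df 3, p 0.027); Q_het = 0.00 (df 0); Q_inc = 9.17 (df 3, p 0.027)
```

The perturbed contrast 1:2 is pulled from its direct value 5 to the
network estimate 3.17, and the between-design statistic Qⁱⁿᶜ = 9.17 on 3
degrees of freedom (p = 0.027) flags inconsistency. The hat matrix shows
that design 1:2 drives 63% of its own network estimate, with the rest
coming mainly from 2:3 and 1:3:

```r
hat_matrix(fit, percent = TRUE)[1:3, 1:3]
#>     1:2 1:3 1:6
#> 1:2  63  27  10
#> 1:3  27  53  20
#> 1:6  10  20  70
```

Detaching design 1:3 only drops the statistic to 5.36 (p = 0.069), while
detaching 1:2 (or 2:3) removes it entirely — so those two designs form
the plausible source:

```r
detach_design(fit, "1:3")
#> Detached design: 1:3
#> Deviation (direct minus indirect): dev:1:3 = -2.857
#> Remaining inconsistency: Q = 5.36 (df 2, p 0.069)

qd <- q_diff_matrix(fit)
round(qd[1:3, 1:3], 2)
#>      1:2   1:3   1:6
#> 1:2 3.36  2.21  0.58
#> 1:3 1.78  1.78 -1.00
#> 1:6 0.25 -0.90  0.25
cluster_order(qd)
#> [1] "1:6" "3:4" "4:6" "4:5" "5:6" "1:3" "1:2" "2:3"
```

The clustering puts the hot spot 1:3, 1:2, 2:3 in one contiguous block;
`netheat(fit, file = "netheat.svg")` renders the plot. For a one-shot
analysis of a CSV file (`study,treat1,treat2,effect,se`, optional
arm-variance sidecar for multi-arm studies), `run_pipeline("data.csv",
out_dir = "out")` writes `stats.json`, the labelled `qdiff.csv` and the
net heat image, or use the shell front end:

```sh
Rscript inst/scripts/netqdiag demo --scenario fig1_a --out demo.csv
Rscript inst/scripts/netqdiag fit --input demo.csv --out-dir out
```

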