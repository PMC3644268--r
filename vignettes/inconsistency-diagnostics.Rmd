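---
title: "Locating inconsistency in fixed-effects network meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating inconsistency in fixed-effects network meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netqdiag)
```

## The model

`netqdiag` analyses contrast-level summaries of randomized trials: each
study contributes the estimated effects of its non-reference arms against
a study reference (e.g. log odds ratios or mean differences) together
with a covariance block that is treated as known — the usual fixed-effects
idealization at the meta-analytic level. Studies are grouped by *design*,
the full set of treatments compared; a network with $T+1$ treatments has
$T$ *basic parameters*, the contrasts of each treatment against the
network reference, from which every other contrast follows under the
consistency assumption.

Estimation is performed in two stages that are algebraically equivalent
to a single generalized least squares fit on all study contrasts (an
equivalence the test suite checks to $10^{-8}$ on simulated networks):

1. the studies of each design are pooled by (matrix) inverse-variance
   weighting into a direct estimate $\hat\theta^{dir}_d$ with covariance
   $V^{dir}_d$;
2. the stacked direct estimates are regressed on the aggregated design
   matrix $X_a$ by GLS with block-diagonal covariance $V_a$.

Working at the design level is what makes the diagnostics sharp: a
deviating body of evidence is a *design*, whether it holds one study or
ten, and within-study correlations of multi-arm trials are carried along
as covariance blocks rather than being approximated away.

### Multi-arm covariance blocks

A study with $N_s$ arms contributes $N_s - 1$ correlated contrasts. The
package builds its covariance block from arm-level variances $v_t$ as
$\mathrm{Var}(Y_{0:i}) = v_0 + v_i$ and
$\mathrm{Cov}(Y_{0:i}, Y_{0:j}) = v_0$, which is positive definite for
any positive arm variances. When only the complete set of $n(n-1)/2$
pairwise standard errors is published, the arm variances are recovered by
least squares from $se_{ab}^2 = v_a + v_b$ (a non-positive solution is an
error, not silently clipped). A multi-arm study with only its
versus-reference standard errors is rejected: the pairwise correlations
are genuinely unidentified, and guessing them would silently change every
downstream statistic.

## The diagnostics

**Hat matrix.** $H = X_a(X_a'V_a^{-1}X_a)^{-1}X_a'V_a^{-1}$ is the
projection of the aggregated fit. Row $d'$ lists the linear coefficients
of all direct estimates in the network estimate of $d'$ — the natural
generalization of meta-analysis weights (they do not sum to one, and lie
in $[-1, 1]$). The diagonal entry is the weight of a design's own direct
evidence against the indirect evidence of the remaining network; for
networks of two-arm designs it equals the electrical-network weight
$w_d = (1/V_d^{dir}) \big/ (1/V_d^{dir} + 1/R_d)$ with $R_d$ the
effective resistance between the design's endpoints after deleting its
edge. The test suite verifies this identity by brute force on every
connected graph with up to five edges, using an independent
Laplacian-pseudoinverse oracle.

**Q decomposition.** The network Cochran statistic over all study
contrasts decomposes exactly as $Q^{net} = Q^{het} + Q^{inc}$:
within-design heterogeneity (per-design Cochran statistics, summed) and
between-design inconsistency. The implementation computes the three
statistics independently — $Q^{net}$ from study-level residuals,
$Q^{het}$ from the first stage, $Q^{inc}$ from the design-level
residuals — so that the additivity asserted by the tests is a real check
on the code, not an identity of the implementation. Degrees of freedom
follow the design-size inventory ($df^{inc} = \sum_d (N_d - 1) - T$,
etc.); $df^{inc} = 0$ means the network has no loops and inconsistency is
unassessable, which the package reports with $p = 1$ and a warning rather
than a misleading statistic.

**Detaching.** For each eligible design the model is refit with
$N_d - 1$ extra indicator columns that free the design's effect from the
consistency constraints; this equals fitting the consistency model with
the design's studies held out (an equivalence tested on simulated
networks). The change of each design's inconsistency summand,
$Q^{diff}_{d',d}$, forms the matrix behind the net heat plot.

**Eligibility rule.** A design is detachable only if at least two of its
treatments occur in other designs *and* removing its studies leaves all
of its treatments in one connected component of the remaining network.
This excludes bridge comparisons and comparisons that introduce a
treatment seen nowhere else; both are dropped from the net heat plot
entirely, since their deviation parameters would be confounded with the
basic parameters. The rule also excludes a multi-arm design with a
private treatment — detaching it would leave that treatment's basic
parameter unidentified — which keeps the extended design matrix full rank
by construction.

**Saturation.** Detaching a design of a single-loop network saturates the
extended model (as many parameters as design contrasts). The statistic is
then exactly zero with zero degrees of freedom and $p = 1$; the package
returns an exact 0 rather than accumulated rounding noise.

## The net heat plot

Cell $(d', d)$ is colored by $Q^{diff}_{d',d}$ on a discrete symmetric
diverging scale (13 bins; warm = detaching $d$ reduces the inconsistency
at $d'$, blue = it increases it) saturating at a configurable cap,
default 8 — beyond that the evidence for a hot spot is unambiguous and
finer gradation would only compress the rest of the scale. A centered
gray square of area proportional to $|H_{d',d}|$ overlays each cell, so
drivers and inconsistency are read together. Rows and columns are ordered
by complete-linkage clustering of the summed Manhattan distances between
rows and between columns; labels are pre-sorted so ties break
deterministically, and an all-zero matrix keeps its input order. A
multi-arm design appears once per contrast (labelled with an asterisk);
because detaching is defined per design, its rows and columns carry the
design-level value and the clustered matrix stays square with matching
labels. Rendering is a pure function of the layout: the same fit written
twice gives byte-identical SVG output.

## Synthetic networks

`make_scenario()` generates the illustrative unit-variance networks used
in the documentation and tests: one single-study design per edge,
standard error 1, all effects zero except a perturbation `delta`
(default 5 — five standard errors of a direct estimate, large enough to
give the diagnostics realistic power at desk scale) on one design. The
six-treatment edge sets are fixed: the eight-design double-triangle
network, the single six-cycle, and the complete 15-design network. The
six-cycle's edge set is the Hamiltonian cycle 1:2, 2:3, 3:4, 4:5, 5:6,
1:6 — the only single-loop arrangement consistent with one inconsistency
degree of freedom on six designs.

`simulate_network()` draws study-level data under the consistency model
with optional per-contrast between-study shifts of standard deviation
`het_sd`, using unit arm variances (so two-arm sampling variance 2, and
correlated blocks for multi-arm designs). It emulates sampling error,
heterogeneity and multi-arm correlation; it does *not* emulate the
messiness of real extraction — unequal and misreported variances,
missing covariance information, or effect measures on the wrong scale —
so passing tests demonstrate the algebra and the null calibration, not
robustness to dirty data.

Test and acceptance problem sizes were chosen to keep everything at desk
scale: the six-treatment scenarios (6–15 designs), simulated networks of
six designs with up to a few studies each, the exhaustive five-edge graph
family for the hat-matrix oracle, and 10,000 replicates for the null
calibration of $Q^{inc}$ against its chi-squared reference.

## Numerical choices

- Canonical orientation everywhere: treatments are sorted
  lexicographically; the design reference is the smallest treatment of
  the design, the network reference the smallest overall. All Q
  statistics are invariant to these choices (tested by relabelling); for
  multi-arm designs the *rows of $H$* do depend on the design reference,
  which is why the row labels spell it out rather than pretending to an
  invariance the quantity does not have.
- Linear systems are solved (`solve`, QR), never inverted explicitly
  except for the small per-design blocks; accumulated symmetric matrices
  are re-symmetrized by averaging with their transpose.
- The detached fits run in whitened coordinates (block Cholesky of
  $V_a$), turning the quadratic-form statistics into plain residual sums
  of squares and making rank decisions explicit via pivoted QR.
- Percent formatting of hat weights rounds half away from zero, for
  display only; raw values are kept everywhere else.
- p-values are printed to three decimals; full precision goes to the JSON
  export.

## Limitations

- Fixed effects only, by design: known variances and no random
  heterogeneity or inconsistency components. This is what makes the Q
  decomposition exact and the diagnostics sharp, but the statistics are
  conditional on the reported variances.
- One design is detached at a time; simultaneous multi-design detaching
  and the full design-by-treatment interaction model are out of scope, as
  are node-splitting, ranking summaries and study-level variants of the
  heat plot.
- Inputs are contrast-level; the package does not compute effects from
  raw arm data (2x2 tables, means and SDs).
- In a single-loop network inconsistency can be detected but not located;
  the package reports this honestly (zero remaining degrees of freedom
  after any detachment) instead of picking a design.
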