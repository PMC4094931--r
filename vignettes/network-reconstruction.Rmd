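---
title: "Information-theoretic reconstruction of input-output signaling networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-theoretic reconstruction of input-output signaling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdenet)
```

## The problem

High-throughput signaling screens measure a panel of upstream signaling
activities (e.g. 22 phosphoproteins quantified by western blot) together
with a panel of downstream responses (e.g. 7 secreted cytokines) across
tens of stimulation conditions. The reconstruction question is: which
inputs carry statistically real information about which outputs? Linear
methods (principal-component or partial-least-squares regression) answer
this under a linearity assumption; kdenet instead scores every input-output
pair by its **mutual information** (MI), which is zero exactly when the
pair is statistically independent, regardless of the functional form of the
dependency. The deliverable is a *parsimonious* network: the minimal edge
set whose MI survives a calibrated significance threshold, plus an optional
linear predictive model restricted to those edges.

## The estimator

For a pair of continuous variables the MI (in nats) is estimated by kernel
densities evaluated at the sample itself (a resubstitution estimate):

$$\hat I(X,Y) = \frac{1}{n}\sum_{j=1}^{n}
  \ln\frac{\hat f(x_j,y_j)}{\hat f(x_j)\hat f(y_j)},$$

with Gaussian kernel densities

$$\hat f(x)=\frac{1}{\sqrt{2\pi}\,nh}\sum_i e^{-(x-x_i)^2/2h^2},\qquad
  \hat f(x,y)=\frac{1}{2\pi nh^2}\sum_i
  e^{-[(x-x_i)^2+(y-y_i)^2]/2h^2}.$$

One bandwidth $h$ is shared by the joint and both marginals, and by every
pair in a dataset. For that to be meaningful the package standardizes every
column (zero mean, unit sd) after row deletion and before any density
computation; the data are assumed to be already log-transformed upstream.
Resubstitution makes the estimate positively biased at small $n$ and
occasionally slightly negative under independence; estimates are reported
raw, and clamped at zero only where they are compared to a threshold
(negative MI is indistinguishable from independence).

## Bandwidth selection

$h$ is chosen by **unbiased (least-squares) cross-validation**: minimizing

$$\mathrm{UCV}(h)=\int \hat f_h^2 - \frac{2}{n}\sum_i \hat f_{(-i),h}(x_i),$$

whose expectation differs from the mean integrated squared error by a
constant. Because the quantity of interest is a *bivariate* density ratio,
the package cross-validates the bivariate KDE per variable pair
(`ucv_objective_2d()`; the univariate objective is kept for diagnostics)
and uses the **mean of the per-pair optima** as the dataset bandwidth.
Numerical choices, all in `select_bandwidth()`:

* a coarse log-spaced grid (40 points in $[0.02, 2]$, sensible for
  standardized data) is scanned first and the *global* grid minimum taken —
  UCV objectives are notorious for spurious local minima;
* the winning grid cell is refined by golden-section search between its
  neighbouring grid points;
* by default all input-output pairs are cross-validated when there are at
  most 200, otherwise 100 seeded random pairs — the mean over pairs is
  stable long before that;
* zero-variance columns (after row deletion) cannot be standardized and are
  dropped with a warning.

For $n$ around 80-1000 standardized Gaussian-like columns this lands near
the Silverman reference $1.06\,n^{-1/5}$, i.e. roughly $0.15$-$0.45$.

## Threshold calibration

An MI estimate is never exactly zero, so edges must be filtered by a
threshold $I_0$ with a known false-positive meaning. Under the independence
null, large-deviation theory gives an exponentially decaying tail,
$P(\hat I > I_0) \sim e^{-cNI_0}$, hence $\ln P = a + bI_0$ with $b<0$
scaling with the number of observations $N$. The package:

1. builds the null by independently row-shuffling every column
   (`permutation_null()`, default 100 rounds), recomputing all MIM entries
   and pooling them — marginals are preserved, all dependencies destroyed.
   Pooling across pairs assumes exchangeability after standardization; a
   per-pair restriction is available by subsetting the data (this is what
   node-by-node reconstruction does per output);
2. computes the empirical survival function on 200 equally spaced points
   from 0 to the null's 99.9th percentile, keeps points whose survival
   probability lies in $[10/m,\,0.5]$ given $m$ pooled draws (tail points
   supported by fewer than 10 draws are excluded — the log of a tiny
   empirical probability is unstable), and fits
   $\ln P = a + bI_0$ by least squares (`fit_large_deviation()`);
3. inverts the fit at the requested p-value:
   $I_0 = (\ln p - a)/b$ (`threshold_for_pvalue()`), default $p = 0.005$.

A requested p-value below the smallest fitted survival probability is an
extrapolation of the linear tail — that is the point of the
large-deviation form. Calibration refuses to fit when fewer than three
distinct survival levels fall in the window and asks for more
permutations.

## Network assembly

`reconstruct()` keeps entries with MI **strictly greater** than $I_0$
(boundary ties are discarded — coefficients *below* threshold are
insignificant, and a conservative tie-break costs at most an edge that was
indistinguishable from noise). Isolated variables stay in the node list
with provenance `"none"`. Two modes exist:

* **bipartite** — input-output edges only (a rectangular MIM);
* **full** — all pairs; one shared threshold for input-input and
  input-output edges, with output-output edges computed but flagged
  (`edge_type`) and excluded from default rankings, which are input-centric.

`combine_networks()` unions two dataset-specific networks (e.g. Toll-like
receptor-stimulated and non-Toll conditions analysed separately so the
dominant stimulus does not mask the other), tagging nodes and edges
`"both"` when supported by the two datasets and keeping both MI weights for
shared edges. `node_by_node()` rebuilds the network one output at a time
with a per-output recalibrated threshold; disagreement with the jointly
thresholded network is confined to edges whose MI sits within calibration
noise of $I_0$, which is a useful robustness read-out.

## The predictive model

For each output, the significant inputs feed a least-squares linear model:
inputs standardized by *training-set* mean and sd, output mean-centred,
coefficients from a QR solve (equal to the normal-equations solution on
full-rank problems, without forming $X^TX$; rank deficiency is reported
with the collinear columns named). Evaluation is by RMSE and $R^2$, with
the $R^2$ denominator taken around the *test-set* mean. The default 0.25
test fraction reproduces an approximate 3:1 train:test ratio. The linear
model is a deliberate simplification — the MI step exists precisely because
the underlying biology is not linear — so moderate $R^2$ on real data is
expected and informative.

## The synthetic benchmark

Real signaling compendia are external and not redistributable, so the
package generates its own test beds (`synthetic` module):

* `gaussian_pair()` — bivariate Gaussians with correlation $\rho$, whose MI
  is exactly $-\tfrac12\ln(1-\rho^2)$: the estimator oracle.
* `generate_planted()` — a sparse planted input-output network emulating a
  phosphoprotein-cytokine screen: correlated Gaussian inputs, outputs built
  from `linear` ($z$), `quadratic` ($z^2-1$, mean-zero and Pearson-silent)
  and `saturating` ($\tanh 2z$) links plus Gaussian noise, outputs
  standardized post-generation so `noise_sd` reads as noise relative to
  unit signal scale, and an optional fraction of rows masked missing (one
  randomly chosen variable per affected row) to exercise the deletion
  policies. The default shape is 22 inputs, 7 outputs and 78 observations,
  the design of the motivating screens.

What the generator does *not* emulate: heavy-tailed or skewed marginals,
structured (non-exchangeable) input correlation, feedback between outputs,
and non-random missingness. Passing the planted-recovery tests therefore
demonstrates correctness of the machinery and its false-positive control,
not performance guarantees on arbitrary real data.

The quadratic link is the canonical demonstration that the pipeline does
not inherit a linearity assumption: its Pearson correlation with the input
is near zero, yet at $n = 500$ its MI clears the $p = 0.005$ threshold
essentially always.

## Reproducibility and problem sizes

Every stochastic step (pair sampling, permutations, train/test splits, the
generators) takes a seed; `run_pipeline()` derives per-stage seeds
deterministically from one master seed and records them, with all fitted
quantities, in a JSON manifest free of timestamps — two runs with the same
seed produce byte-identical artifacts. The bundled verification
(`scripts/acceptance.R` and the test suite) exercises the estimator at
$n = 1000$ with 20 replicates per correlation, false-positive control on
twenty independent $78 \times 29$ datasets, and planted-network recovery at
$n = 500$ with 20 mixed edges — sizes chosen so the entire battery
completes in minutes on a single core while keeping Monte-Carlo error well
inside the asserted tolerances.

## Known limitations

* Resubstitution bias: at $n \le 100$ the null MI is visibly positive;
  thresholds absorb this (the null is built with the same estimator), but
  raw MI values should not be compared across datasets of different size.
* A single shared bandwidth is a modelling choice; strongly multimodal
  variables would prefer per-variable bandwidths, which the method trades
  away for comparability of MI values within a dataset.
* MI is symmetric: edge direction in a bipartite network is a labelling of
  roles, not a causal inference.
* Listwise deletion discards information when missingness is concentrated
  in a few columns; the pairwise policy retains it at the cost of entries
  estimated on different row sets (and is therefore not the default).
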