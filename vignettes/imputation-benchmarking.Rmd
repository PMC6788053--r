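---
title: "Simulating missingness and benchmarking imputation for LC-MS feature tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating missingness and benchmarking imputation for LC-MS feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Untargeted LC-MS metabolomics produces a samples × features table of peak
intensities in which a large share of the entries — commonly 30–50% — is
missing. The missingness is not of one kind. Some values vanish for reasons
unrelated to the data (failed peak integration, alignment glitches): missing
completely at random (MCAR). Some are missing because of *other* measured
signals — for example, an abundant co-eluting compound suppressing the
ionization of another — so the probability of absence depends on observed
values: missing at random (MAR). And many are absent because the value
itself was too small to detect, a left truncation at the instrument's
effective detection limit: missing not at random (MNAR). Downstream
statistics require a complete matrix, so the entries must be imputed — and
the right imputation method depends on which of these processes produced
the holes.

This package provides the machinery to study that question empirically:
generate complete matrices with realistic structure, damage them with a
controlled, known mechanism, repair them with nine standard imputation
methods, and measure each method's error over repeated randomized trials.

## The evaluation design

One *trial* fixes a complete matrix $X^{\mathrm{comp}}$ and a missingness
specification (mechanism + total rate), simulates a single mask, and lets
every method impute the same masked matrix, so method comparisons are
paired. The score is the normalized root mean squared error over the
masked cells:

$$\mathrm{NRMSE} \;=\; \sqrt{\frac{\operatorname{mean}\!\big[(X^{\mathrm{comp}} - X^{\mathrm{imp}})^2\big]}{\operatorname{var}\!\big[X^{\mathrm{comp}}\big]}},$$

with mean and variance taken over the masked cells (unbiased, $n-1$,
variance). Zero means perfect recovery; values near 1 mean the method did
no better than the masked cells' own mean. Because every method in this
package preserves observed cells exactly, including observed cells in the
average would only dilute the signal; restricting to masked cells is the
convention of the missForest error measure. The formula is also sometimes
read per feature ("the error for every feature that contains missing
values"); both aggregations are implemented (`per_feature` in `nrmse()`),
the masked-cell-global one is the default, and neither is claimed to be
the only valid reading.

The full benchmark (`run_benchmark()`) repeats, by default 100 times: draw
one dataset from a pool, subsample 200 complete features, and for each of
the 7 mechanisms × 4 rates (5, 10, 20, 30%) × 9 methods compute one NRMSE.
`summarize_benchmark()` reduces the records to mean ± sd per method ×
mechanism × rate plus a pooled-across-rates row — the inputs of the usual
heatmap and error-bar displays. Every per-trial seed is derived by hashing
(master seed, permutation, mechanism, rate), so any single cell of the
grid can be replayed without rerunning the rest.

## The missingness simulators

**MCAR** removes exactly `round(rate × cells)` cells uniformly without
replacement.

**MAR** repeatedly picks an ordered pair of distinct features: a *driver*
$X_1$ and a *target* $X_2$. A cut-off fraction $c$ is drawn (below), and
the target is masked in the samples holding the top $\lceil c \cdot n
\rceil$ driver values — high abundance of one compound knocks out the
measurement of another in the same sample. Pairs are redrawn with
replacement until the requested total is reached.

**MNAR** repeatedly picks one feature, draws $c$, and masks the smallest
$\lceil c \cdot n_{\mathrm{obs}} \rceil$ of its *still-observed* values
(left truncation — the detection-limit analogue; right truncation exists
behind `truncation_side` but is not a benchmark default).

**Mixed mechanisms** (`MCAR_MAR`, `MCAR_MNAR`, `MAR_MNAR`,
`MCAR_MAR_MNAR`) run their components sequentially, each removing an equal
share of the total on top of the previous step's output: at 30% total,
each of the three steps removes exactly 10% of all cells.

The cut-off fraction is drawn from $\chi^2_1/30$, clipped to $[0,1]$. The
distribution has analytic mean $1/30 \approx 3.33\%$ and sd
$\sqrt{2}/30 \approx 4.71\%$ (clipping at 1 is a ~5σ event and is
negligible for the moments), so individual events typically remove a few
percent of a feature, with rare large wipe-outs. One degree of freedom is
the only choice whose scaled moments match those targets; it is fixed in
the package, and the acceptance script re-derives both moments by
simulation.

Three bookkeeping decisions, each recorded in the returned event
provenance, make the simulators exactly reproducible and exactly counted:

* driver ranks are computed on the complete original values (the simulator
  has them), while MNAR ranks only still-observed values;
* already-masked cells are never re-masked;
* the final event is trimmed to make the total `round(rate × cells)`
  exact. Trimming keeps the most extreme cells of that event (highest
  driver values for MAR, smallest values for MNAR-left) so that the
  per-event order properties — masked MNAR values never exceed a value
  still observed at that step — survive trimming.

Rates above 30% are allowed but warned about: heavy masking of any origin
starts to look like left truncation, which is also why the benchmark's
default grid stops at 30%.

## The nine imputation methods

*Single-value replacement.* `ZERO`, `MEAN`, `MIN`, `HALF_MIN` fill each
feature's missing cells with 0, its observed mean, its observed minimum,
or half the minimum. The per-feature (not global) statistic is the
convention of the LC-MS imputation packages, and respects the orders of
magnitude separating feature intensities. Minimum-based variants encode
the belief that the values are left-censored.

*Local structure.* `KNN` imputes each feature from its K = 10 most similar
features; similarity is root-mean-square Euclidean distance over mutually
observed samples (normalizing by overlap keeps distances comparable when
overlaps differ), votes are inverse-distance weighted, neighbours missing
at the needed sample abstain, and a cell with no voting neighbour falls
back to the feature mean (counted in the diagnostics). Ties break by
feature index, so KNN is deterministic. `RF` is the missForest scheme:
mean-initialize, visit features by ascending missingness, regress each on
all others with a random forest (100 trees, `mtry = floor(sqrt(p))`,
minimum node size 5 — grown by `ranger`) and predict its missing cells,
sweeping until the normalized squared change between sweeps rises, then
return the previous sweep.

*Global structure.* `SVD` starts from literal zeros at the missing cells
and alternates rank-r truncated SVD with reconstruction of the missing
cells until the relative change falls below `tol`. It deliberately runs on
the raw, uncentered matrix: the zero start *is* the method's documented
initialization, and on positive intensity data it is a crude guess — one
reason this method trails the probabilistic variants. `PPCA` fits
$x = Wz + \mu + \varepsilon$, $\varepsilon \sim N(0, \sigma^2 I)$, by EM:
data are column-centered on observed means, missing cells refilled each
sweep with their model reconstruction, loadings and $\sigma^2$ re-estimated
from the completed matrix; initialization is a deterministic SVD of the
mean-filled matrix. On complete data the fitted subspace converges to the
ordinary principal-component subspace (the PPCA maximum-likelihood
solution), which the tests verify to within $10^{-3}$ radians. `BPCA`
adds automatic relevance determination: each loading column carries its
own prior precision $\alpha_j$, re-estimated as $p / \lVert w_j\rVert^2$
each sweep, entering the loading update as a ridge penalty
$\sigma^2\,\mathrm{diag}(\alpha)$. Columns that do not earn their variance
are driven to zero, so a generous rank choice self-corrects — the tests
exercise this by fitting rank-8 to rank-2 data and checking that
superfluous axes collapse below 1% of the leading one.

Defaults for the iterative methods: rank 5 for SVD/PPCA/BPCA (small
relative to a 200-feature table; the right value is unknowable without
ground truth, and BPCA is the method designed to be insensitive to it),
`tol = 1e-5` relative change, and an iteration cap of 100, after which the
result is returned flagged `converged = FALSE` rather than discarded.

No transformation is applied before imputation — no log, no scaling. Many
LC-MS features are strongly skewed, and transforming a feature to look
Gaussian before imputing changes both its distribution and its
relationships with other features, risking bias that outlives the
imputation. Methods that internally need a location estimate (PPCA, BPCA)
center and uncenter internally; nothing else touches the scale.

## The synthetic-data generator

The real feature tables such a benchmark would use are typically not
shareable, so `generate_complete_matrix()` draws matrices with the three
properties the analysis needs: strict positivity, right skew, and low-rank
inter-feature correlation. The model is a log-scale factor model,
exponentiated:

$$\log X = \mu + F\Lambda + E,$$

where each feature loads primarily on one of `latent_rank = 5` factors
(features $j$ and $j + 5$ share a factor — a crude stand-in for metabolite
clusters, adducts and isotopologues), with primary loading
$U(0.6, 1.4)\cdot\texttt{sd\_log}$, weak cross-loadings, per-feature
baselines $\mu_j \sim N(\texttt{mean\_log} = 12,\, 1)$ (raw intensities
around $e^{12} \approx 1.6\times10^5$, a typical peak-height magnitude),
`sd_log = 1` and residual `noise_sd = 0.5` — i.e. the factors explain
roughly 80% of log-scale variance, enough structure for multivariate
imputers to be non-trivially testable and enough noise that they cannot be
perfect. The default per-trial size is 100 samples × 200 features; the
default `run_benchmark()` pool spans 12 shapes from cohort-style (258
samples) to intervention-style (47 samples) studies with 204–1152
features.

What the generator does *not* emulate: batch effects, retention-time
drift, heteroscedastic technical noise, feature-wise outliers, and — most
consequentially — the exact per-feature intensity distributions of any
real instrument. Results on this synthetic data replicate *qualitative*
method orderings, not absolute NRMSE levels. One ordering is visibly
sensitive to the distributional choice: under left-truncated MNAR, whether
`MIN` or `HALF_MIN` wins depends on how wide the censored left tail is.
With `sd_log = 1` the masked tail values are typically far below half the
observed minimum, which favours `HALF_MIN`; data with tighter per-feature
distributions favour `MIN`. The package reports both; see the test suite
for the orderings asserted at reduced scale.

## Numerical and degenerate-input policy

* Exact-count invariant: every simulator masks exactly
  `round(rate × cells)` cells, tested across all mechanisms and rates.
* A feature left with no observed values makes `MEAN`/`MIN`-type, KNN and
  the centered EM methods fail with an error naming the feature; inside a
  benchmark trial that failure is caught and recorded as a flagged record
  (`ok = FALSE`), excluded from summaries with a logged count, and the run
  continues.
* NRMSE requires at least two masked cells with non-constant truth;
  degenerate inputs raise errors rather than returning NaN.
* `n_reps`, seeds and all grouping keys ride along in the records, so any
  summary number can be traced to the trials that produced it.
* Determinism: identical (matrix, spec, seed) gives identical masks;
  identical configs and master seed give identical benchmark records
  (`runtime_s`, a wall-clock diagnostic, is the only column exempt).

## Problem sizes used in the shipped checks

The package's own test suite runs the design at reduced scale — 10
permutations of 100 × 200 matrices for the ranking checks (50-tree
forests), 1 to 5 permutations of smaller matrices for the exactness and
determinism checks — sizes chosen so the whole suite documents the
pipeline's behaviour at desk scale. The full 100-permutation design is a
single `run_benchmark(benchmark_config())` call away.

## A worked example

```{r, eval = FALSE}
library(lcimpute)

x <- generate_complete_matrix(datagen_config(seed = 1))     # 100 x 200
masked <- simulate_missingness(x, missingness_spec("MCAR_MAR_MNAR", 0.30),
                               seed = 7)
sum(masked$mask)                                            # 6000 cells

rec <- run_single_trial(x, missingness_spec("MNAR", 0.10), seed = 11)
rec[order(rec$nrmse), c("method", "nrmse")]

cfg <- benchmark_config(n_permutations = 10,
                        mechanisms = c("MCAR", "MNAR"),
                        rates = c(0.10, 0.30),
                        master_seed = 2)
summ <- summarize_benchmark(run_benchmark(cfg))
heatmap_matrix(summ, "MCAR")
```

## Known limitations

* Group structure (treatment arms, time points) is ignored: features are
  imputed across all samples jointly, which can blur group differences in
  real studies; group-wise imputation would need the methods re-run per
  stratum.
* The simulators cannot fully separate mechanisms at high rates: heavy
  MAR/MCAR masking incidentally produces MNAR-like patterns, which is why
  rates above 30% warn.
* No method here quantifies imputation uncertainty (single imputation
  only), and no significance testing is attached to method comparisons.
* Detecting which mechanism produced an observed dataset's missingness is
  out of scope; the simulators answer the converse question.
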