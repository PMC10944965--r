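---
title: "Benchmarking tissue-specific methylation age clocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking tissue-specific methylation age clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clockbench)
```

## The problem

DNA methylation age clocks are penalized linear models that predict
chronological age from CpG methylation. Their practical value depends on
questions that are rarely quantified together: how much does performance
improve with training-set size, does the choice of penalty (ridge, lasso,
elastic-net) matter, is there an advantage to training separately per sex,
and does a clock trained on the target tissue beat a generic clock trained
on blood? `clockbench` implements a complete benchmarking pipeline for
these questions — preprocessing, clock training, leave-one-dataset-out
(LODO) validation, an age-stratified subsampling ladder, and
random-intercept mixed-model meta-comparison — together with a synthetic
study generator with planted ground truth, so every stage can be tested
against known answers.

## The clock model

A clock is fit by penalized least squares of age on logit2-transformed
methylation (M-values), minimizing over intercept $\beta_0$ and weights $w$

$$\frac{1}{2n}\sum_i \big(\mathrm{age}_i-\beta_0-m_i^\top w\big)^2
  +\lambda\Big(\alpha\lVert w\rVert_1+\tfrac{1-\alpha}{2}\lVert w\rVert_2^2\Big),$$

with $\alpha=0$ (ridge), $1$ (lasso) or $0.5$ (elastic-net, equally
weighted L1/L2). The path of 50 logarithmically spaced $\lambda$ values
runs from $\lambda_{\max}$ (the smallest penalty that zeroes every
coefficient, computed from the standardized design) down to
$10^{-4}\lambda_{\max}$ ($10^{-2}$ when $p>n$). $\lambda$ is selected at
the minimum mean held-out squared error of an internal cross-validation:
10 folds when $n\ge 10$, leave-one-out when $n<10$. Ages are used
untransformed: the pipeline restricts samples to the (20, 85] window
where the age–methylation relation is close to linear, so no log-age
warping is applied.

### Solver

The path is solved by cyclic coordinate descent with warm starts, working
on sufficient statistics ($X^\top X/n$, $X^\top y/n$) of the internally
standardized design (mean 0, variance 1 with the $1/n$ convention).
Convergence requires the largest standardized-coefficient change in a
full cyclic pass to fall below $10^{-7}$ (at most $10^5$ passes). Because
plain cyclic descent approaches such tight tolerances slowly when
predictors are correlated — and age-associated CpGs are correlated by
construction — full passes are alternated with an exact minimization over
the current active set (a Cholesky solve of the orthant-restricted
quadratic), accepted only when it does not increase the objective;
cyclic descent is the fallback, and a final full pass always re-checks
every coordinate, so the Karush–Kuhn–Tucker conditions of the stated
objective hold at the solution. The per-pass objective is recorded and
tested to be monotonically non-increasing. Coefficients are reported on
both the original and the standardized scale; the standardized scale is
used for coefficient thresholding in the selection analysis, because a
common absolute cutoff is only meaningful there (an original-scale option
is provided).

## Scoring a clock

Predicted "methylage" is evaluated through the calibration regression
$\mathrm{methylage}=\theta_1+\theta_2\,\mathrm{age}+\varepsilon$. Both
scores derive from this fitted line: RMSE is the root mean squared
residual about the line (not about the identity — a clock that is a
perfect affine function of age has RMSE 0), and adjusted $R^2$ uses the
parameter count $K=2$. Splits with fewer than three samples are skipped,
never scored.

## The experimental design

Within each tissue (samples aggregated by dot-boundary MeSH code
prefixes, with sorted-cell suffixes like `.CD4` foldable into their
parent), each dataset (GSE) is held out in turn; a clock is trained on
the remaining datasets pooled and validated on the held-out one, for
every penalty, training-sex configuration (joint, male, female;
validation always scored per sex and jointly) and every subsampling
ladder size available in the training set. Subsampling is stratified by
decade age bins with largest-remainder quotas, the excluded samples
forming a test split. A guard of three samples applies to every side of
every split. Per-cell seeds are derived by hashing the cell labels with
the master seed, so adding cells never perturbs existing ones. The
transfer experiment trains one clock per penalty on all blood samples and
scores it on every validation dataset of every other tissue
(`tissue_specific = 0` records).

## Meta-comparison

Each comparison is a linear mixed model on a score table with a random
intercept for the dataset of origin, fitted by REML. The response and
every covariate — the natural-log sample size and the contrast dummy —
are standardized, so the fixed-effect slope of the contrast is a partial
correlation. The REML criterion is profiled over the variance ratio
$\theta=\tau^2/\sigma^2$ and minimized by one-dimensional optimization on
the log scale with the $\theta=0$ boundary checked explicitly; with one
grouping factor all matrix inverses reduce to closed per-group forms.
Wald t-tests use the conservative degrees of freedom
$n_{\mathrm{obs}}-n_{\mathrm{fixed}}-n_{\mathrm{groups}}$ (finite-sample
corrections such as Satterthwaite are out of scope). P-values are
adjusted by Benjamini–Yekutieli within each (analysis, response) family;
the base of the log sample size is irrelevant after standardization.
The headline analyses pool tissues into a single model per contrast
(the dataset random intercept absorbs tissue-level baselines); fitting
per tissue is available through `compare_scores` on a filtered table.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
with known ground truth. For CpG $j$, sample $i$ in dataset $g$:

$$M_{ij}=b_j+s_j(\mathrm{tissue}_i,\mathrm{sex}_i)\,\mathrm{age}_i
  +u_{jg}+\varepsilon_{ij},\qquad
  u\sim N(0,\sigma_b^2),\ \varepsilon\sim N(0,\sigma_e^2),$$

and $\beta=2^M/(1+2^M)$. Planted CpG categories: *shared* (slope in every
tissue), *tissue-specific* (slope only in the native tissue), and
*sex-modulated* (slope in females only — the sex effect modulates the
age drift rather than adding a constant offset, because a constant
per-sex offset is absorbed exactly by the calibration regression when
validation is scored per sex and would make sex configuration
irrelevant by construction). Background, sex-chromosome and SNP-control
(`rs`) probes carry no age signal; the latter two exist to exercise the
probe filters. Baselines are clamped so that $\beta$ stays within
(0.01, 0.99) across the age range at three total noise SDs, avoiding
logit saturation.

Three forms of between-dataset heterogeneity are built in, because the
random-intercept meta-models exist precisely to absorb cohort-level
variation and would be vacuous without it: each dataset draws its ages
from a random sub-window of (20, 85] (cohorts differ in age
composition), multiplies the residual SD by a dataset-level factor
(technical quality), and jitters its sample count around the nominal
size (so the log-sample-size covariate is never degenerate).
Tissue-specific CpGs also carry inflated inter-individual noise outside
their native tissue (default twice `noise_sd`), emulating
tissue-specific regulatory variability; without it, a transferred blood
clock loses correlation with age but not calibration-line RMSE, since
pure slope attenuation is invisible to a regression-line residual.

Defaults describe a three-tissue study (blood, a nervous-system code, a
digestive-system code), four datasets per tissue of a nominal 120
samples, residual SD 0.5 M-units, batch SD 0.2, 1% missing entries, and
a sparse, strong planted signal: 6 shared plus 3 tissue-specific clock
CpGs per tissue with absolute slopes of 0.04–0.08 M-units/year among
~100 background CpGs. The signal is deliberately sparse relative to the
smallest subsampling ladder size (25), the regime in which lasso and
elastic-net recover the same support and differ only negligibly — with a
dense or weak planted signal the elastic-net's grouping advantage at
$n=25$ becomes systematic and detectable, which is a statement about
that generator regime rather than about the penalties in general. A few
hundred CpGs keep full end-to-end runs tractable on a laptop; the
analysis logic is dimension-agnostic and the solver handles the
450K-scale case through the same interface.

The generator draws one RNG substream per dataset from the master seed,
so adding a dataset leaves existing ones bit-identical.

What the generator does **not** emulate: cell-composition heterogeneity,
probe-level measurement artifacts (type I/II chemistry, batch dye
effects), non-linear pediatric/geriatric age effects (the pipeline's age
window excludes them), genuine 450K manifests, and any non-Gaussian
residual structure. Passing tests therefore demonstrate correctness of
the pipeline's statistics on data satisfying its assumptions, not
performance claims about real arrays.

## Preprocessing choices

Samples: keep controls with age in (20, 85] (bounds read as "remove
$\le 20$ and $>85$"), and one random representative per family
(twins/repeats), drawn under the run seed recorded in the filter report.
Probes, per train/validation pair: the intersection of probe sets, minus
probes with any missing value remaining *after* imputation, minus `rs`
control probes, X/Y probes, and probes flagged unreliable or blacklisted
(a published unreliable-probe list can be supplied as a plain id list).
Imputation is a documented stand-in: per-probe means within each dataset
(model-based methylation imputation is an external concern, as is
between-dataset normalization, for which an identity hook with a
pluggable interface is provided). The pipeline order is impute →
probe-filter → logit2, and the logit2 transform clamps $\beta$ to
$[\varepsilon,1-\varepsilon]$ with $\varepsilon=10^{-6}$ — real pipelines
never meet $\beta\in\{0,1\}$ but synthetic or degenerate inputs can.
Retained probes are sorted by id so results are invariant to input
probe order.

## Selection analysis

From the full-size elastic-net clocks of each tissue, coefficients with
$|c|\le 0.1$ (closed interval, standardized scale) are zeroed, CpGs with
non-zero coefficients in fewer than 10% of a tissue's clocks are
dropped, and two consensus sets are formed per tissue: CpGs selected by
*all* clocks and by *at least one* clock. Three-tissue overlaps are
counted over the 7 Venn regions at both the CpG and the gene level
(genes via the annotation's symbol lists, case-insensitive matching
against reference clock gene lists supplied by the user).

## A small run

```{r, eval = FALSE}
cfg <- default_config(seed = 1)
res <- run_report(cfg, out_dir = "clockbench_out")
res$summary
```

`run_report` chains simulate → preprocess → benchmark → compare → select
and writes every artifact (study tables, ground truth, score table,
comparison table, selection/Venn tables, YAML summary). With the default
configuration it reproduces the four qualitative findings: validation
adjusted $R^2$ rises with training-set size; lasso and elastic-net do
not differ significantly on the sparse planted signal; sex-specific
training brings no advantage when no sex effect is planted; and
tissue-trained clocks beat the transferred blood clock on both scores
when tissue-specific CpGs dominate.

## Problem sizes used by the test-suite

The acceptance checks run the full pipeline at desk scale: 20 replicates
of the three-tissue study (four datasets per tissue, nominal 120 samples
each, ladder 25/50/75/100/full, elastic-net and lasso) for the size and
penalty findings; 20 replicates with joint, male and
female training across the same ladder for the sex contrast (the ladder
gives joint and sex-specific clocks overlapping training-size ranges,
without which the sex dummy is nearly collinear with log sample size);
20 replicates of a variant with
2 shared and 8 tissue-specific CpGs per tissue for the blood-transfer
contrast; 50 random $20\times 5$ problems against an accelerated
proximal-gradient minimizer and the ridge closed form; 200 simulated score
tables for mixed-model recovery and 500 for permutation calibration.

## Known limitations

* Mixed-model degrees of freedom are conservative; borderline p-values
  differ slightly from Satterthwaite-corrected implementations.
* The REML profile assumes a single grouping factor; crossed or nested
  designs are out of scope.
* The coordinate-descent solver keeps the $p\times p$ Gram matrix in
  memory; for $p$ beyond a few tens of thousands a streaming residual
  update would be preferable.
* The imputation stand-in ignores correlation between CpGs; probes fully
  missing within a dataset remain missing and are removed by the probe
  filter.
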