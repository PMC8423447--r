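---
title: "Models and design choices in dietfx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in dietfx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietfx)
```

dietfx implements the statistical core of a diet-intervention study in
group-housed primates: whole-diet manipulation (Western vs Mediterranean) with
monocyte RNA-seq and focal behavioral observation on 35 animals (20 Western,
15 Mediterranean). This vignette explains each model, its assumptions, the
parameters that matter, and the choices we made where the design was open.

## The kinship linear mixed model

Differential expression is tested per gene with

$$y = X\beta + u + \varepsilon,\qquad
u \sim N(0,\, \sigma_g^2 K),\qquad
\varepsilon \sim N(0,\, \sigma_e^2 I),$$

where $y$ is residual log2 expression across animals, $X$ contains an
intercept and the diet indicator (Western = 1, so positive $\beta_{diet}$
means higher expression under the Western diet), and $K$ is the animal-by-
animal kinship matrix. Related animals share expression variation through the
polygenic term $u$; ignoring it would overstate the effective sample size.

`fit_lmm()` solves the model by the eigendecomposition trick: with
$K = USU'$, rotating $y$ and $X$ by $U'$ diagonalizes the covariance to
$\sigma_g^2(S + \delta I)$ with $\delta = \sigma_e^2/\sigma_g^2$. The REML
(default) or ML criterion is profiled over $\log_{10}\delta$ on a 100-point
grid on $[-5, 5]$ and refined by Brent search between the best grid point's
neighbours; $\beta$ follows by generalized least squares. Fits at the grid
edge are flagged as boundary fits. Inference uses a Wald $t$ with
$df = n - \mathrm{rank}(X)$ rather than a normal reference because $n = 35$.
When $K = I$ the fit reduces exactly to ordinary least squares for any
$\delta$, which the test suite exploits as an oracle.

Two numerical floors matter for degenerate inputs: the weighted residual sum
of squares is floored so constant responses return $\beta_{diet} = 0$,
$p = 1$ rather than 0/0, and rank-deficient designs fall back to a pseudo-
inverse with a warning.

At $n = 35$ the Wald $t$ p-values are slightly anti-conservative (about 5.4%
of null p-values fall below 0.05). We do not correct this analytically
because the error control downstream never uses the nominal scale alone: the
empirical FDR compares observed p-values to permuted p-values that carry the
same miscalibration, so it cancels.

## Permutation empirical FDR

`permutation_pvalues()` refits every gene after shuffling the diet labels;
crucially, one shuffle is shared by all genes within a permutation, which
preserves the inter-gene correlation structure under the null — the
empirical-FDR estimator assumes exchangeable replicates of the whole matrix,
not gene-wise independence. Diet can be shuffled per animal (default) or per
social group, since diet was assigned at the pen level. The default is 100
permutations, configurable.

`empirical_fdr()` estimates, for each observed p-value $p_i$,

$$\widehat{FDR}(p_i) =
\frac{\tfrac1B\sum_b \#\{p^{(b)} \le p_i\}}{\#\{p^{obs} \le p_i\}},$$

with monotonicity enforced by a cumulative minimum from the largest observed
p-value downward and clipping to $[0,1]$. Permuted refits use a coarser
21-point variance-ratio grid without Brent refinement: p-values are
insensitive to the $\delta$ resolution, and the savings keep hundreds of
whole-matrix refits tractable.

This estimator is deliberately stringent. Under a global null fewer than 1%
of genes fall below FDR 0.05, but its effective per-gene p cutoff is far
smaller than 0.05 ($\approx G^{-1}\times$ the number of acceptable false
positives), so moderate effects (one residual SD at $n=35$) are recovered at
roughly 30% sensitivity, not the ~80% that a nominal $p<0.05$ threshold
would give. Users planning studies should power against the FDR-thresholded
sensitivity, not nominal power.

## Differential co-expression (CILP)

For the top-$k$ differentially expressed genes (default $k = 140$, giving
$\binom{140}{2} = 9730$ pairs), each gene is standardized to mean 0 and unit
variance *within each diet group* (sample SD, $n-1$), and each pair's
per-animal product $z_i z_j$ is formed. The identity
$\sum z_i z_j/(n-1) = r$ within a group means a diet effect on the product
vector is exactly a diet difference in Pearson correlation; the product
vector is therefore tested with the same kinship LMM and permutation FDR
machinery (default significance at 20% empirical FDR). "Top" is defined as:
significant genes ranked by empirical FDR ascending, ties broken by
$|\beta_{diet}|$ descending, then gene id — the ranking is reported so it can
be audited.

Pairs containing a gene with zero within-group variance are dropped rather
than imputed. The product test's type-I error at nominal $p<0.05$ is close
to nominal (measured 0.059 over 10,000 null pairs) — products of standardized
Gaussians are heavier-tailed than Gaussian, which the Wald $t$ absorbs
reasonably at these sample sizes.

## Hub genes

Hubs are genes participating in more significant differentially co-expressed
pairs than chance allows. The null resamples $|sig|$ pairs uniformly without
replacement from all tested pairs (default 1000 draws), records per-gene
partner counts from every draw, pools them, and thresholds at the ceiling of
the 95th percentile (floored at one partner so genes with no significant
pairs can never be hubs). Under this uniform null a gene's partner count is
hypergeometric — $(N{=}9730, K{=}139, n{=}445)$ gives a 95th percentile of
11, which the Monte-Carlo threshold reproduces within $\pm 1$. Note that a
published analysis of this design reports a threshold of 13 with the same
stated construction; that value is not derivable from the pooled reading of
the null, and we surface the pooled result rather than matching the printed
number. Transcription-factor enrichment among hubs uses an upper-tail
hypergeometric test against the $k$ tested genes.

## Behavior and the DAB composite

Focal observations (default 600 s sessions) are summarized per animal:
event behaviors as events per observed hour, state behaviors as the fraction
of observed time. Raw codes map to summary behaviors through a configurable
table; by default contact and non-contact aggression combine into
`aggression`, and the self-directed behaviors (self-grooming, scratching)
form the `anxiety` index. Rates use observed time, not nominal session time,
so truncated sessions aggregate correctly.

Diet contrasts per behavior use the Mann-Whitney U test (exact enumeration
when both groups have at most 8 animals and no ties; otherwise the normal
approximation with tie and continuity corrections) with Holm-Bonferroni
adjustment across behaviors.

The diet-altered behavior (DAB) composite is built by PCA on the standardized
animal-by-behavior matrix. Rather than hard-coding the second component —
which is what this study design happened to find — the DAB is chosen
algorithmically: the component most strongly associated with diet (Welch $t$)
among those significant after Holm adjustment, with the chosen index
reported. The axis is oriented so the anchor behavior (body contact by
default) loads positively, putting affiliative, Mediterranean-typical
behavior at the positive end. Per-behavior correlations with DAB use Pearson
$r$ with Holm adjustment.

## Bootstrap mediation

For each gated gene, two OLS models are fit: outcome on diet (total effect
$\beta_{diet}$) and outcome on diet plus mediator (direct effect
$\beta'_{diet}$). The indirect effect is their difference, which for linear
models equals the product of path coefficients exactly — the suite asserts
this identity at machine precision. Animals are resampled with replacement
(10,000 draws by default; resamples containing a single diet group, or
producing singular fits, are redrawn and counted), and mediation is called
when the 90% percentile interval of the bootstrapped difference excludes
zero. The forward direction treats expression as outcome and DAB as
mediator; the reverse direction swaps them. Gating first — genes must show a
univariate kinship-LMM association with the DAB score at 5% empirical FDR —
matches the study design and concentrates the scan on genes where mediation
is estimable.

Choices worth knowing: the bootstrap uses OLS without the kinship term
(resampling animals breaks the kinship structure anyway; a kinship-aware
variant exists behind a flag), the interval is percentile rather than BCa,
and the proportion mediated is reported from the point estimates with the
bootstrap-mean version alongside. Two calibration facts from the test suite:
the 90% interval covers a planted indirect effect of 0.48 at $n=200$ about
90% of the time, but when the mediator is independent of both diet and
outcome the interval contains zero essentially always (~100%, not 90%) — the
doubly-null difference-of-coefficients test is conservative, a well-known
property of product-type mediation tests, so null mediators are rarely
flagged but the test is not exact under that null.

## The synthetic-study generator

`simulate_study()` emulates the study conditions so the whole pipeline is
testable with known ground truth: 35 animals (20 Western) in social groups
of 3-4 with diet constant within groups; a block-family kinship matrix
(within-family relatedness 0.25, 12 families); ~12,000 genes (desk-scale
runs use a few hundred) with negative-binomial counts.

Per-gene log2 means are `baseline + beta*diet + covariate loadings +
polygenic + Gaussian noise`, with:

* baseline log2 expression uniform on [4, 11] — median depth of a few
  hundred reads per gene, typical of filtered monocyte RNA-seq;
* gene-wise NB dispersions log-normal around size 20;
* diet effects in 40% of genes, magnitudes exponential with mean 0.48 log2
  (Western-direction) vs 0.30 (Mediterranean-direction) — the 1.6-fold
  magnitude asymmetry the design reproduces — and a 45.6/54.4 direction
  split;
* total Gaussian log2 noise SD 0.35 (~27% between-animal CV), of which 20%
  is polygenic (kinship-correlated). These two values were fixed once so the
  default study meets the generator's stated recovery contract (estimated
  vs true $\beta$ correlate at $r \ge 0.9$);
* four technical covariates (CD14, CD3, RIN, concentration) loading on 10%
  of genes; the first two gene columns are `CD14` and `CD3E` marker genes
  tracking their covariates, so the contamination flagging rule is
  exercisable (`n_contaminated` plants CD3-high samples);
* differentially co-expressed pairs sharing a latent factor active under one
  diet only, amplitude set to hit the target within-diet correlation in the
  Gaussian part (NB counting noise attenuates the realized correlation
  slightly);
* a latent DAB score `-1.2*diet + 0.5*(reverse-gene noise) + N(0, 0.5)` —
  Mediterranean animals higher — that feeds forward-mediated genes
  (mediated proportion uniform on [0.3, 0.7]). The reverse-path channel
  injects only the diet-independent fluctuations of the reverse genes'
  expression: because each such gene's expression also carries its own diet
  effect, conditioning DAB on the gene recovers a genuine indirect component
  while leaving the DAB diet separation stable across seeds. Pair genes for
  differential co-expression are reserved before the mediation pools are
  drawn, so shared-DAB loadings cannot masquerade as co-expression;
* an ethogram with 8 state and 10 event behaviors, several loading on the
  DAB latent during the experimental phase only; the baseline phase is fixed
  at 12 sessions x 600 s = 2 h per animal and carries no diet signal.

What the generator does *not* emulate: sequencing-level artifacts (GC,
length bias beyond the RPKM filter), dominance hierarchies, non-exchangeable
within-group behavioral dependence, count-level outliers, or the mosaic of
partially correlated diet responses seen in real data. Passing tests on
synthetic data therefore demonstrate correctness of the statistics under the
stated model, not field realism of any particular biological conclusion.

## Problem sizes and reproducibility

Test and example runs use reduced sizes chosen as the smallest that leave
the statistical properties measurable: studies of 300-400 genes, 30-50
permutations, bootstrap depth 200-1000, and Monte-Carlo checks of 100-200
replicates; the acceptance script uses 2,000-gene null matrices with 100
permutations and 10 seeds for FDR calibration. All randomness flows through
explicit seeds; stage seeds derive from the global seed by fixed offsets, so
pipeline stages are reproducible in isolation, and rerunning the pipeline
with the same configuration produces byte-identical tables (asserted by
hash in the suite).

## Known limitations

* The Wald-$t$/grid REML approach does not propagate variance-component
  uncertainty into the fixed-effect tests; the permutation FDR is the
  intended inferential layer.
* The CILP product test assumes the within-group standardization removes
  all distributional differences between diets; strong mean-variance
  coupling surviving residualization could still masquerade as differential
  correlation.
* Bootstrap mediation is associational: forward and reverse scans can both
  flag the same genes, and the package deliberately offers no formal
  adjudication between the two directions.
* With 35 animals, enrichment CIs from the gene-level bootstrap are wide;
  fold-enrichment point estimates below ~1.3 should not be over-read.
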