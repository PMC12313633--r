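---
title: "Models and methods behind droughtmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind droughtmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtmet)
```

`droughtmet` analyses augmented randomized complete block (ARCBD)
multi-environment germplasm trials: hundreds of unreplicated test
accessions anchored by replicated reference checks, evaluated under an
irrigated control and one or more drought-stress environments. This
vignette documents the models, the simulated world used to validate
them, the numerical choices, and what a passing test suite does and does
not establish.

## The two-stage mixed-model analysis

### Stage 1: single-trial BLUEs and heritability

For one environment and one trait, the plot value of genotype $i$ in
block $k$ is modelled as

$$ y_{ik} = g_i + b_k + \varepsilon_{ik}, \qquad
   b_k \sim N(0, \sigma_b^2), \;
   \varepsilon_{ik} \sim N(0, \sigma_e^2). $$

With genotype **fixed**, the generalized-least-squares estimates of the
$g_i$ are the design-adjusted genotype means (BLUEs): replicated checks
estimate the block effects, and each unreplicated entry's single plot is
corrected by its block's estimated effect. Standard errors come from the
inverse of the mixed-model coefficient matrix, so check BLUEs (10 plots)
are more precise than entry BLUEs (1 plot) — an invariant the tests
assert.

Broad-sense heritability on a plot basis is
$H^2 = \sigma_g^2/(\sigma_g^2 + \sigma_e^2)$, which requires a genetic
*variance* — something the genotype-fixed fit cannot supply. The trial
is therefore refit with genotype **random** and block **fixed**. A
reasonable alternative would have been two sequential one-random-term
fits (absorb blocks, then fit genotype on the adjusted data), but
plugging pre-adjusted data into a second REML fit understates the
block-estimation uncertainty; the single genotype-random/block-fixed fit
is the standard augmented-design formulation and needs no data surgery.
The identification of $\sigma_e^2$ rests almost entirely on the
replicated checks — with 7 checks × 10 blocks there are ~63 residual
degrees of freedom within check levels, which is why $H^2$ recovery at
the full trial size lands within ±0.05 of the target (an acceptance
criterion).

The trial CV (%) is computed on raw plot values by default (a
descriptive statistic of the trial, not of the adjusted means);
`cv_on = "blue"` switches to BLUEs.

### Stage 2: multi-environment BLUPs

Stage-1 BLUEs $\hat y_{ij}$ (genotype $i$, environment $j$) feed

$$ \hat y_{ij} = e_j + u_i + \varepsilon_{ij}, \qquad
   u_i \sim N(0, \sigma_u^2), $$

with environment fixed and genotype random. The BLUP $\hat u_i$ shrinks
each genotype toward the across-environment mean in proportion to its
replication and the signal-to-noise ratio
$\sigma_u^2/\sigma_\varepsilon^2$; the reported *predicted value* is
`grand mean + BLUP` (grand mean = unweighted mean of the fitted
environment means), so predictions stay on the trait scale.

The stage-2 fit is **unweighted** by default — the two-stage literature
often carries stage-1 precisions forward, but the baseline method this
package reproduces does not, and on a balanced augmented trial the
stage-1 SEs are nearly constant within entries anyway. Inverse-variance
weighting (`weight = "inv_var"`, residual variance $\propto 1/w_i$ with
$w_i = 1/\mathrm{se}_i^2$) is available and handled exactly in the
engine, not by approximation.

A trait observed in a single environment (the drought-reaction scores)
leaves genotype and environment confounded: no shrinkage is identified
and stage-1 BLUEs pass through unshrunk, with a warning.

### The REML engine

Both models share one structure: one categorical fixed factor (cell
means), at most one categorical random factor, i.i.d. residuals. The
engine exploits it:

* Both design matrices are single-factor indicators, so $X'X$ and $Z'Z$
  are diagonal and every cross-product is a contingency table or grouped
  sum — likelihood evaluations cost $O(n)$ plus a $q \times q$ solve via
  the Woodbury identity ($q$ = random levels appearing through
  $M = D^{-1} - U' D_x^{-1} U \succeq \lambda^{-1} I$, always positive
  definite).
* The restricted likelihood is profiled analytically over the fixed
  effects and $\sigma_e^2$, leaving a 1-D criterion in
  $\lambda = \sigma_u^2/\sigma_e^2$, maximized by Brent search on
  $\log\lambda \in [-30, 30]$. Non-negativity is built into the
  parameterization; a maximum pressed against either end of the interval
  is reported as a boundary fit (`v_random = 0`, or a degenerate
  residual), never silently.
* The response is centered before forming sufficient statistics: the
  constant lies in the cell-means column space, so REML is unchanged
  while the quadratic forms avoid catastrophic cancellation (translation
  invariance then holds to ~1e-6 even for large offsets; bit-exactness
  is impossible once the shifted data themselves lose mantissa bits).
* Effects and standard errors come from a dense solve of Henderson's
  mixed-model equations at the estimated components — at most a few
  hundred equations for these models.

The tests hold this engine against independent dense oracles (explicit
$V = \sigma_u^2 ZZ' + \sigma_e^2 W^{-1}$, textbook GLS and
conditional-mean formulas), the closed-form balanced one-way ANOVA
estimators, lme4 spot checks during development, and closed-form
shrinkage limits.

## The simulated world

`sim_config()` describes the generator; its defaults *are* the published
trial: 500 test accessions and 7 checks (4 tolerant: Apo, Norungan,
CO 53, Anna (R) 4; 3 susceptible: IR 64, Jaya, Pusa 44) replicated in 10
blocks, under Control, ROS (rainout shelter) and TPE (rainfed target
environment), with 10 agronomic and 4 physiological traits. Trait means,
heritabilities and plot CVs per environment are fixed at the published
trial-level values (e.g. grain yield 4.57/1.55/1.37 t/ha with
$H^2$ 0.88/0.85/0.80 and CV 31.5/61.1/43.1%).

Only $H^2$ and the CV are published, not the variance components, so the
generator back-solves them: the plot phenotypic variance $v_p$ implied
by the CV is split as $v_{block} = 0.01\,v_p$ (a small but nonzero block
variance; field blocks in levelled paddies are homogeneous) and
$v_g = H^2 (v_p - v_{block})$, $v_e = (1 - H^2)(v_p - v_{block})$. This
reproduces all three published summaries simultaneously.

Genetic effects are multivariate normal — the distributional assumption
of the mixed models being validated. Correlation enters in two layers:
a between-trait correlation matrix (grain yield's published
multi-environment associations — panicle weight 0.50, spikelet fertility
0.34, … negative with flowering time — plus field-typical secondary
structure, projected once to the nearest unit-diagonal PSD matrix), and
a per-trait 3×3 cross-environment genetic correlation matrix taken from
the published between-environment trait correlations (0.00–0.89). The
construction draws trait-correlated innovations independently per
environment and then mixes environments through each trait's Cholesky
factor: per-trait environment correlations are honored exactly, and when
all traits share one environment matrix the structure reduces to the
Kronecker product. When they differ, same-environment between-trait
correlations are attenuated by a factor
$(L_t L_{t'}')_{ee} \le 1$ — a deliberate trade-off that keeps the
covariance PSD by construction while matching the better-documented
marginal structures exactly.

Checks carry fixed, role-based genetic effects for grain yield and
spikelet fertility (tolerant checks hold yield under stress at
+1.5…+0.7 genetic SDs; susceptible checks collapse to −0.8…−1.2 while
performing well irrigated), so check-anchored classification has
realistic anchors: roughly 7–10% of simulated accessions clear every
tolerant check under managed stress, as in the study this emulates. For
all other traits the checks behave as ordinary genotypes.

Score-type traits (panicle exsertion, leaf rolling, leaf tip drying) are
generated by rounding and clamping a latent normal onto the 1–9 scale;
leaf rolling and tip drying exist under ROS only, relative water content
and the chlorophyll index under Control and ROS only.

What the generator does **not** emulate: spatial field trend, non-normal
tails (plot values can go slightly negative under the high-CV stress
environments, where real yields truncate at zero), weather-driven stress
dynamics, genotype-specific stress sensitivity beyond the configured
correlations, and the mild mean shift that clamping induces in score
traits near the scale ends. A green recovery test therefore establishes
that the estimators recover the parameters of a correctly specified
world — not robustness to these field realities.

## Downstream statistics

**Reductions.** `reduction_metrics()` offers two definitions, because
published summaries rarely say which was used: *of-means*
(difference/ratio of group means — reproduces all worked-example
differences exactly; note the panicle-length means imply a 0.62 cm
reduction under ROS although 0.60 is sometimes printed) and
*mean-of-per-genotype* (average of per-genotype percent reductions,
paired by name). Both are always emitted by `reduction_table()`.

**Correlations.** Pairwise-complete Pearson $r$ with two-sided p from
the $t$ transform; a Benjamini–Hochberg column is added because
published stars rarely name an adjustment. Zero-variance cells are
reported missing, not zero. Observed between-environment BLUE
correlations are attenuated relative to the configured *genetic*
correlations when $H^2 < 1$; the recovery tests use high-$H^2$ traits
and a ±0.1 band for exactly that reason.

**Stepwise regression.** Bidirectional search by AIC from the
intercept-only model (`stats::step`), after pre-filtering candidates to
$|r| \ge 0.1$ with the response; the selected model is refit by OLS. AIC
is the default because it is deterministic and oracle-checkable — the
acceptance suite demands agreement with exhaustive best-subset AIC over
all $2^6$ subsets across 50 datasets. A p-value enter/remove variant
(0.05/0.10) is available. AIC admits a pure-noise predictor with
probability $P(\chi^2_1 > 2) \approx 0.16$ per candidate; the noise test
is calibrated to that known rate rather than to an idealized zero.

**Classification.** Boundaries are the empirical check yields in the
same data: the top band above the *maximum* tolerant check (which
reproduces the published per-environment phrasings without hard-coding
which tolerant check is best where), then the upper anchor
(Anna (R) 4) and lower anchor (IR 64). Ties go to the better category —
the source is silent, and upward resolution is the deterministic choice
favourable to the accession. "Below the lower anchor" is interpreted as
below IR 64 specifically (both configurable). Checks are excluded from
summary denominators. When the observed check ordering contradicts the
tolerance labels (possible in any finite trial), a note is logged and
the empirical boundaries are used as-is — hiding the violation would
misrepresent the data.

**Selection index.** With z-scored traits, $G$ is the sample correlation
matrix of the index traits over the scored panel (test accessions plus
checks, on multi-environment predicted values — checks must be scorable
for the beats-all-checks comparison); whether the published $G$ was a
phenotypic or genetic covariance is unstated, and the phenotypic choice
is the one computable from the same predictions being scored.
$b = G^{-1} d$ is obtained by Cholesky solve, never an explicit inverse,
with the residual $\max|Gb - d|$ verified below $10^{-8}$ and
ill-conditioning ($\kappa > 10^{10}$) reported with the most collinear
trait pair. Setting $d_j = 0$ does *not* zero $b_j$ under correlation —
that is the point of carrying flowering time in the index (it guards
against inadvertent phenology selection), and a test asserts it.

## Pipeline, configuration, determinism

`run_pipeline()` executes the stages in order and writes every table as
CSV plus a JSON run log (seed, package and R versions, input MD5). All
randomness flows from one seed through a private RNG stream that is
restored afterwards; two runs with the same config and seed produce
byte-identical CSVs (asserted). Config and log use JSON rather than a
YAML-style format because the package deliberately keeps its import list
to `stats`, `utils`, `jsonlite`.

Scaling notes for the shipped test suite: the LMM oracle battery runs at
its specified sizes; the parameter-recovery criterion runs the full
500-accession trial for all 20 seeds (grain yield only is analysed —
the criterion measures nothing else); the end-to-end determinism
criterion uses a 150-accession panel with the full 14-trait set, since
doubling a full-size run adds minutes without changing what is being
asserted (structure and determinism).

## Known limitations

* One random factor only: no spatial/row–column adjustment, pedigree or
  marker kinship, heterogeneous residuals (beyond observation weights),
  or factor-analytic G×E models; stability indices (AMMI/GGE, STI/SSI)
  are out of scope.
* Stage-wise (two-stage) estimation, not a single-stage joint fit; the
  default stage-2 fit ignores stage-1 precision (see above).
* $H^2$ is plot-basis `vg/(vg+ve)`; line-mean or Cullis-type
  heritabilities are not computed.
* The generator's score traits are rounded latent normals, not a
  threshold model with estimated cutpoints.
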