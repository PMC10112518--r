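---
title: "Genomic prediction with deleterious mutation load: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction with deleterious mutation load: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`loadgp` studies a question that matters for clonally propagated crops such
as cassava: when does knowing which mutations are deleterious improve
genomic prediction of clone performance? Clonal propagation lets recessive
deleterious mutations accumulate sheltered in heterozygous state, so a
candidate set of such mutations — derived alleles at evolutionarily
conserved, protein-damaging, rare sites — is both a plausible source of
trait variation and a plausible set of markers to emphasize in prediction.
The package provides the full simulation-and-prediction machinery to test
this: a synthetic two-population genotype generator, a dominance-aware QTL
trait simulator, additive and dominance genomic relationship matrices with
optional functional weights, a multi-kernel REML/GBLUP engine, deleterious
load annotation, and cross-population / k-fold evaluation.

## The prediction model

All predictions come from a multi-kernel linear mixed model. For a vector
of clone phenotypes $y$,

$$ y = X\beta + Z_A a + Z_D d + \varepsilon, \qquad
   a \sim N(0, G_A \sigma^2_a),\;
   d \sim N(0, G_D \sigma^2_d),\;
   \varepsilon \sim N(0, I \sigma^2_\varepsilon), $$

where $X\beta$ holds the mean and, in the `+Load` model variants, the two
per-clone load covariates (homozygous and heterozygous derived burden at
deleterious sites). $G_A$ is the VanRaden additive relationship matrix:
with dosages centered by twice the allele frequency into $M$,

$$ G_A = \frac{M M'}{\sum_i 2 p_i (1 - p_i)}. $$

$G_D$ is the dominance relationship matrix built from the zero-mean
heterozygosity coding: per site, $-2p_i^2$ for the reference homozygote,
$2p_iq_i$ for the heterozygote and $-2q_i^2$ for the alternate homozygote
($q_i = 1 - p_i$), with denominator $\sum_i (2 p_i q_i)^2$. This coding has
zero expectation under Hardy–Weinberg proportions, which is what makes
$\sigma^2_d$ interpretable as dominance variance. A sign convention that
assigns $+2q_i^2$ to the alternate homozygote circulates in some pipelines;
it is not zero-mean, and `dominance_grm(..., zero_mean = FALSE)` reproduces
it only for comparison.

Functionally weighted kernels place per-site weights $w_i \in [0, 1]$
(conservation-classifier probabilities, or normalized absolute QTL effects
in the simulation study) on the sites:

$$ G_{AW} = \frac{M W M'}{\sum_i 2 p_i q_i w_i}, \qquad
   G_{DW} = \frac{D W D'}{\sum_i (2 p_i q_i w_i)^2}, $$

with $W = \mathrm{diag}(w)$. Unit weights recover the unweighted kernels
exactly (the same BLAS path is used, so the reduction is bitwise). The
weighted dominance denominator sums the *squared* per-site terms, matching
the structure of the unweighted denominator.

Variance components are estimated by REML — direct Nelder–Mead
maximization of the restricted log-likelihood over log variance components,
with a polishing restart; convergence is declared when the restart improves
the criterion by less than `tol` (default $10^{-6}$). BLUEs and BLUPs at
the optimum come from generalized least squares, which is equivalent to
solving Henderson's mixed-model equations (the test suite checks this
equivalence against an independently assembled MME solver). Masked clones
are predicted through the kernel covariance between masked and observed
units:
$\hat u_k = \sigma^2_k K_k Z_k' V^{-1} (y - X\hat\beta)$ evaluated on the
training rows, so a clone with no relatives in the training set (identity
kernel) predicts exactly zero. Predicted genetic value is the sum of the
additive and dominance BLUPs, plus the load fixed-effect contribution when
load covariates are in the model; intercepts are excluded as
rank-invariant.

### Numerical choices

* Variance components are floored at $10^{-8} \mathrm{Var}(y)$; a ridge of
  $10^{-8}$ is added to every kernel diagonal so singular kernels remain
  usable in the equations.
* Kernels that are indefinite beyond $-10^{-8}$ are bent by eigenvalue
  clipping with a warning; callers passing cross-product kernels (PSD by
  construction) can skip the check with `bend_kernels = FALSE`.
* Aliased fixed-effect columns are detected by pivoted QR and dropped with
  a warning; their coefficients are reported as `NA`.
* With one free variance component the optimizer is Brent on a bounded log
  scale; otherwise Nelder–Mead (relative tolerance $10^{-13}$) with one
  polishing restart.
* Top-k ties are broken by stable position order, making the overlap
  metric deterministic.

## The trait simulator

A simulated architecture draws, per site independently, QTL status with
probability `prob_qtl` (so e.g. $10^{-3}$ over 66k sites yields ~66 QTL),
an additive effect $a_i \sim \Gamma(\text{shape}=1, \text{scale}=1)$
attached to the *ancestral* allele (so ancestral alleles are always
favourable, the deleterious-derived framing), and a dominance degree $d_i$
from $N(2, 0.3^2)$ truncated above at 2 by rejection sampling — clipping
would create a point mass at complete dominance. The genotype-to-value map
at a QTL with ancestral-allele dosage $g \in \{0, 1, 2\}$ is

$$ v_i(g) = \begin{cases} a_i\, g & g \in \{0, 2\} \\ a_i\, d_i & g = 1,
\end{cases} $$

so $d_i = 1$ is pure additivity and $d_i = 2$ makes the derived allele
fully recessive (heterozygote equals ancestral homozygote). The truncation
bound guarantees the heterozygote never exceeds the ancestral homozygote,
consistent with recessive-to-additive deleterious action; the published
description of this simulator leaves the genotype-to-value map implicit,
and this is the reading we adopt (and document) — with the cap at the
normal mean, the dominance distribution is an upper-half truncation whose
mean $\mu - \sigma\sqrt{2/\pi}$ the test suite verifies by Monte Carlo.

Residuals are i.i.d. normal with variance
$\mathrm{Var}(g)\,(1 - h^2)/h^2$ targeting the *realized* genetic variance
of the panel at hand (default $h^2 = 0.3$), not an expected variance under
idealized equilibrium — each simulated trait is calibrated to its own
panel, and the mean realized heritability across replicates recovers the
target (the acceptance script recomputes this).

## What the synthetic panel emulates — and what it does not

`simulate_population_pair()` produces a two-population diploid panel under
the Balding–Nichols model: per site an ancestral frequency
$p \sim U(0.05, 0.95)$, population frequencies
$p_k \sim \mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, binomial(2) dosages,
and redraws for sites with pooled MAF below `maf_min`. Defaults emulate
the study system this package was built around: two African cassava
breeding panels of 524 clones each (the published total of 1048 does not
state the per-population split, so an even split is our choice), ~66k
coding sites, and $F_{ST} = 0.1$, a plausible divergence for two related
breeding pools; the realized Hudson-estimator divergence is checked
against the parameter in the tests. The ancestral allele is assigned at
simulation time (a fair coin per site) so derived-allele orientation is
known ground truth rather than inferred from an outgroup.

Two deliberate unrealisms matter for interpreting results:

* **No linkage disequilibrium beyond population structure.** Sites are
  independent given their ancestral frequencies. In real breeding panels,
  dense genome-wide markers tag causal sites through LD, which is exactly
  why genome-wide kernels catch up with causal-site kernels for polygenic
  traits. On a no-LD panel, a kernel built from the exact causal sites
  retains an advantage even for highly polygenic architectures (the
  genome-wide kernel is a diluted estimate of the causal relatedness);
  passing or failing the "no gain at many QTL" pattern is therefore
  informative about this structural difference, not only about the code.
* **No imputation error.** Genotypes are complete by construction; the
  imputation stage of the real pipeline is replaced by the generator.

The annotation generator produces per-site evolutionary rates from a
three-component mixture so both the conserved ($< 0.3$) and non-conserved
($> 2$) tails used for classifier training are populated, protein-impact
scores negatively associated with conservation, and a configurable block
of generic numeric predictors carrying a tunable conservation signal — a
stand-in for the ~500-dimensional feature sets (impact scores, embedding
units, GC content) used in practice; the classifier code is
dimension-agnostic, and the default of 16 features keeps tests fast.
About 3.3% of sites are drawn from the "deleterious-like" corner (rate
$< 0.5$, impact $< 0.05$, MAF $< 0.2$), emulating the observed ~2.2k of
66k. Deleterious classification uses strict inequalities on all three
thresholds, so boundary sites are not flagged. MAF for the filter is the
pooled-panel frequency (the published pipeline uses a reference panel
frequency; the pooled panel is our approximation).

Functional weights come from a probability random forest (via `ranger`,
500 trees by default) trained to separate conserved from non-conserved
sites, fit once per held-out chromosome: a site's weight is always
produced by a model whose training data excluded that site's chromosome,
`excluded`-band sites (rate in $[0.3, 2]$) never train but are always
scored, and the held-out chromosome is recorded per site so leakage is
auditable.

The trial-table generator nests replicates in trials and incomplete blocks
in replicates, with trial effects fixed and rep/block/plot effects
independent normals; the BLUE stage fits the matching model (mean, trial,
plants-harvested covariate and germplasm id fixed; rep-in-trial and
block-in-rep random) with the package's own REML engine and re-centers
germplasm estimates by evaluating the non-clone fixed effects at their
plot average — in a single-trial, constant-covariate design this reduces
exactly to clone plot means.

## Evaluation design

Four schemes mirror the study layout: within-population 10-fold
cross-validation for each population and both cross-population directions
(train on one population, mask every phenotype of the other). Fold
assignment is simple randomization with remainders spread round-robin;
fold draws are made once per replicate and shared across model variants,
so variants with identical kernels produce identical results under one
seed (the unit-weight reduction test exploits this). Accuracy is the
Pearson correlation between predicted and reference values of masked
clones only — the bookkeeping never lets a masked phenotype into a
training set, and variance components are re-estimated within every fold.
In simulation the reference is the clone's *total* simulated genetic value
(additive plus dominance): the evaluation targets overall clone
performance, which is what matters for selecting clonally propagated
material; additive-only breeding values are available via
`genetic_value(..., type = "additive")` for users who want the
transmission-oriented definition. The reported confidence half-width is
$\mathrm{SD}/\sqrt{n} \cdot t_{0.975, n-1}$ with $n$ = folds ×
replications, the convention used with replicated cross-validation; since
fold replicates are not independent this indicates variability rather
than a calibrated interval.

The simulation study sweeps QTL probabilities
$\{10^{-1}, 10^{-2}, 10^{-3}, 10^{-4}\}$ (50 replicates by default) and
compares three variants: genome-wide kernels (`Baseline`), causal-site
kernels (`QTL`), and causal-site kernels weighted by absolute additive
effect normalized to a maximum of 1 (`WeightedQTL` — the published
description says "weighted by effect size" without giving the map; the
normalized absolute effect is the minimal consistent choice and is
overridable). Replicates with zero sampled QTL are resampled with a
message. The empirical-style study computes clone BLUEs from plot data and
compares six variants (`Marker_G`, `Imputed_G`, `Nonsyn`, `Nonsyn+Load`,
`Weighted_Nonsyn`, `Weighted_Nonsyn+Load`) distinguished by marker subset,
functional weighting and load covariates; it predicts on BLUEs (one
record per clone), matching the two-stage description.

## Problem sizes in the tests

The shipped test suite exercises the study's operating points at sizes
chosen to keep a full run comfortable on a laptop: the heritability
recovery uses a 1000-clone panel with 10k sites and 200 simulated traits;
QTL-count calibration uses the full 66k-site dimension; the
architecture-sweep pattern check uses a 400-clone, 66k-site panel with 30
replicates and the two cross-population schemes; variance-component
recovery uses a 500-clone, 2k-site panel with 50 replicates. The
acceptance script regenerates its panel at 1000 clones × 66k sites. These
sizes are the package's own choices; every threshold they are checked
against is stated in the corresponding test.

## Known limitations

* REML by dense Cholesky scales as $O(n^3)$ per likelihood evaluation;
  panels beyond a few thousand clones need a different backend.
* The dominance variance component is weakly identified on panels of
  near-unrelated clones: the dominance kernel's off-diagonals shrink
  toward zero as sites grow, leaving $\sigma^2_d$ and
  $\sigma^2_\varepsilon$ nearly collinear at the observation level.
  Estimates are correspondingly noisy (the recovery test tracks the
  median over replicates, and its tolerance reflects this).
* No epistasis, no QTL-by-environment interaction, no spatial field
  trends, no Bayesian whole-genome regression comparators.
* The generator makes no attempt at coalescent or recombination realism;
  see the no-LD caveat above for how that shapes which published patterns
  a synthetic panel can reproduce.

## A minimal run

```{r, eval = FALSE}
library(loadgp)
g <- simulate_population_pair(n1 = 60, n2 = 60, m = 2000, seed = 1)
study <- run_simulation_study(g, prob_qtl_grid = c(1e-2, 1e-1), reps = 5,
                              seed = 2, k = 5, top_k = 10)
study$summary
```
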