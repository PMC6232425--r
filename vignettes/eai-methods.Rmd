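---
title: "Quantifying the aggregated impact of compounded disturbances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the aggregated impact of compounded disturbances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eaimpact)
```

## The problem

Soil microcosm experiments that apply pulse disturbances — heat, freeze–thaw,
anoxia, singly or in different chronological orders — produce many response
variables per microcosm: N-cycle process rates (potential nitrification and
denitrification, potential N~2~O emissions), mineral and total N pools,
qPCR gene-copy abundances of N-cycle guilds (*amoA* of AOA and AOB, *nirK*,
*nirS*, *nosZ* clades I and II, total 16S rRNA), and community diversity
indices. The question "how much did the ecosystem change, all variables
considered?" needs a single, comparable number per treatment and timepoint.
`eaimpact` answers it with an *Ecosystem Aggregated Impact* (EAI) built from
standardized effect sizes, and surrounds it with the univariate and
community-composition analyses such experiments use.

## Effect sizes: Hedges' g

For one variable, treatment, and timepoint, with treated replicates
$x_T$ ($n_T$) and control replicates $x_C$ ($n_C$):

$$ g = J \cdot \frac{\bar x_T - \bar x_C}{s_p}, \qquad
   s_p = \sqrt{\frac{(n_T-1)s_T^2 + (n_C-1)s_C^2}{n_T+n_C-2}}, \qquad
   J = 1 - \frac{3}{4m-1},\ m = n_T+n_C-2 $$

$$ \widehat{var}(g) = \frac{n_T+n_C}{n_T\,n_C} + \frac{g^2}{2(n_T+n_C)},
   \qquad CI_{95\%} = g \pm 1.96\sqrt{\widehat{var}(g)} $$

Choices worth making explicit:

* **Bias correction.** We use the $1 - 3/(4m-1)$ approximation of the
  small-sample correction rather than the exact gamma-function form. At the
  design's group sizes ($n = 4$ per group) the two differ in the third
  decimal of $g$; the approximation is the form conventionally used in
  ecological effect-size work, and the variance uses the matching
  large-sample expression.
* **Sign convention** is treated minus control; only $|g|$ enters the EAI,
  so the convention matters only for per-variable interpretation.
* **Normal 95% quantile** (1.96, not a t quantile): the interval is used
  downstream on a variance-propagated *sum* of effect sizes, where the
  normal approximation is the coherent choice.
* **Degenerate spread.** Two groups with identical values and equal means
  are a well-defined "no effect": $g = 0$ with variance reduced to the
  sample-size term. Zero pooled spread with unequal means has no finite
  standardized difference and raises an error rather than returning an
  infinity that would silently dominate an aggregate.
* **Transforms are configuration.** Gene-copy abundances are typically
  log~10~-transformed before analysis; which variables to transform is an
  analysis decision recorded in the run configuration, not something
  inferred from the data. $g$ is computed on the transformed (analysis)
  scale.

## The Ecosystem Aggregated Impact

For the configured variable set $V$ (26 variables in the default design):

$$ EAI = \sum_{v \in V} |g_v|, \qquad
   var(EAI) = \sum_{v \in V} var(g_v), \qquad
   CI_{95\%} = EAI \pm 1.96\sqrt{var(EAI)} $$

The absolute value deliberately drops any a-priori notion of "better" or
"worse" performance: the index measures displacement from the control, not
its direction. Two further decisions:

* **Variance propagation.** $var(EAI)$ is the plain sum of the
  per-variable effect-size variances — valid for approximately normally
  distributed variables — not the folded-normal variance of $|g|$. The sum
  of folded effect sizes is strictly positive in expectation even under a
  global null (about 15 for 26 null variables at $n = 4/4$), so EAI values
  are compared *between treatments*, never against zero.
* **CI-overlap inference.** Two cells are called significantly different
  when their 95% CIs do not overlap. Intervals are treated as closed
  (touching endpoints overlap), the conservative reading. Letters are
  assigned so that two cells share a letter *iff* their intervals overlap:
  because CIs are intervals on the line, the overlap graph is an interval
  graph whose maximal cliques all occur at interval start points; a sweep
  in ascending-EAI order collects those cliques and absorbs subsets, which
  guarantees the displayed relation is exactly the overlap relation. The
  letter *labels* are therefore deterministic but arbitrary; the tested
  surface is the relation they encode.
* **Letter scope.** Displays group bars per timepoint panel, so letters
  are assigned within timepoint by default; `assign_letters(within = NULL)`
  compares all cells jointly when a single cross-timepoint display is
  wanted.

## Community composition

OTU count tables with a rooted, branch-length-bearing phylogeny are
processed with the conventions of QIIME-era pipelines, fixed as follows:

* **Singletons** are OTUs with a *dataset-wide* total count of one, and are
  removed before rarefaction. The alternative readings (per-sample
  singletons; removal after rarefaction) are defensible; this package fixes
  one and documents it.
* **Rarefaction** draws once per sample, without replacement, to a common
  depth (default 2200 reads — a typical minimum sample depth), via
  `vegan::rrarefy` under a caller-supplied seed. Means per OTU follow the
  hypergeometric expectation; samples below depth are excluded with a
  warning, mirroring standard practice.
* **Alpha diversity**: observed species, Simpson's reciprocal
  $1/\sum p_i^2$ (plug-in form, matching common pipeline defaults rather
  than the $n(n-1)$ bias-corrected form), and Faith's PD including the path
  to the root, so a one-taxon sample has PD equal to its root-to-tip
  distance (computed through `picante::pd(include.root = TRUE)`).
* **UniFrac** is computed in-package from a single postorder
  branch-proportion traversal, because the two weighted conventions needed
  — the raw $\sum_i b_i |p_i^A - p_i^B|$ and the normalized
  $\big(\sum_i b_i |p_i^A - p_i^B|\big) / \big(\sum_i b_i (p_i^A + p_i^B)\big)$
  — are not both exposed by any single installed implementation. The
  default weighted variant is the raw one (the historical
  `weighted_unifrac` of QIIME 1); unweighted defaults to the standard
  unique/union branch-length ratio. The implementation is cross-checked in
  the test suite against a naive per-branch enumeration built on
  `phangorn::Descendants`, and against `picante::unifrac` for the
  unweighted variant.
* **PCoA** is classical metric scaling (Gower double-centring through
  `stats::cmdscale`). Negative eigenvalues — expected for non-Euclidean
  dissimilarities — are reported but their axes dropped; no
  Cailliez/Lingoes correction is applied by default. Axis signs, which are
  arbitrary, are fixed by making each axis's largest-magnitude coordinate
  positive so outputs are reproducible.

## Inference

* **Per-timepoint ANOVA** fits $Y_{ij} = \mu + treatment_i + residual_{ij}$
  (via `stats::lm`/`anova`), with the exact-fit degeneracy (zero residual
  mean square) reported as an infinite F with p = 0. **Tukey HSD** uses the
  studentized range with the Tukey–Kramer standard error for unbalanced
  groups; with two groups $q = \sqrt 2\,|t|$.
* **PERMANOVA** uses the one-factor pseudo-F computed directly from the
  distance matrix. It is implemented in-package rather than through
  `vegan::adonis2` because small pairwise designs ($n = 4$ vs 4) benefit
  from an exhaustive-enumeration mode that permutation software does not
  expose; `adonis2` serves as an independent cross-check in the tests.
  Monte-Carlo p-values use $(b+1)/(m+1)$ so p is never zero; the default
  permutation count is 999 with free permutation of raw labels. Pairwise
  PERMANOVAs are unadjusted by default (Benjamini–Hochberg optional),
  matching the common practice of reporting raw pairwise outcomes.
* **Variance partitioning** is sequential (Type-I) least squares in the
  configured term order, each single-df term tested against the residual
  mean square and expressed as a percentage of the total sum of squares.
  The observational unit is one (treatment, timepoint) cell: the response
  is the cell's EAI; a variable-named predictor contributes the cell's
  $|g|$ for that variable; a distance-metric predictor contributes the
  mean distance between the cell's samples and the control samples of the
  same timepoint. With correlated predictors the attribution is
  order-dependent by construction — the order is part of the analysis
  configuration, with the composition predictor first by default.

## The synthetic generator

The generator exists so the entire chain is testable without sequence
archives. It emulates the *statistical structure* the analysis assumes:

* **Measurements**: i.i.d. Normal on the analysis scale,
  $N(\mu_v + \delta\,\sigma_v,\ \sigma_v)$ for treated cells, so the
  declared $\delta$ *is* the true standardized effect; variables flagged
  log~10~ are emitted as $10^x$ so ingestion must re-transform them.
  Destructive sampling in the emulated design means timepoints are
  independent, which the generator reproduces by drawing cells
  independently.
* **Communities**: Dirichlet-multinomial counts (log-normal base alphas,
  total concentration 50) with depths uniform on 2500–6000 (safely above
  the 2200 rarefaction depth), and composition shifts that multiply the
  alphas of a treatment-specific random OTU subset by $10^{\text{log-fold}}$.
  The Dirichlet-multinomial is the minimal overdispersed count model that
  supports such shifts; it is a stand-in, not a mechanistic claim.
* **Defaults mirror the emulated design**: one control, three repeated
  single-disturbance treatments (F, H, A), six chronology treatments (FHA,
  FAH, HFA, HAF, AFH, AHF), 4 replicates, timepoints T0–T4, 26 variables
  named for the measured quantities, 300 OTUs.

What the generator does **not** emulate: sequencing error and chimeras,
taxon-specific disturbance responses, correlations between functional
variables and community composition beyond what the planted effects induce,
and any mechanistic N-cycle kinetics. Passing tests therefore demonstrate
the statistical machinery is correct under its stated assumptions — not
that those assumptions hold in any particular soil.

## Problem sizes and numerical choices in the checks

The shipped checks run at sizes chosen to give stable Monte-Carlo
estimates on a single CPU: 2000 simulated 4-vs-4 experiments for
effect-size recovery and for the null-EAI comparison against an
independently coded oracle (5% relative tolerance); 500 random interval
sets for the letter-display relation; 200 random trees of up to 8 leaves
for the branch-metric oracles (1e-9 tolerance); 1000 rarefaction draws
against the hypergeometric mean (3 standard errors); 1000 structureless
datasets at 199 permutations for PERMANOVA null calibration (rejection
rate in [0.03, 0.07]); and 100 repetitions of a scaled-down
chronology-ordering recovery in which adjacent true aggregate effects are
spaced by at least three CI half-widths (12 variables, true per-variable
effects 0.3 / 2.0 / 3.7). Exact comparisons use 1e-9–1e-12 tolerances;
comparisons against printed hand examples use the precision of those
examples (1e-4).

## Limitations

* The EAI inherits the CI-overlap decision rule: it is conservative
  relative to a formal test of equality, and its variance propagation
  assumes approximate normality of the underlying variables.
* Equal weighting of variables means the index depends on the configured
  variable set; adding near-duplicate variables inflates it.
* Type-I partitioning answers "how much does each predictor explain, in
  this order" — not an order-free attribution.
* The letter display encodes pairwise CI overlap only; it is not a
  simultaneous inference procedure.
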