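# eaimpact

Quantifying the aggregated impact of single and compounded (sequential)
disturbances on ecosystem properties and functions in replicated microcosm
experiments — the statistical toolkit for designs where soil microcosms
receive pulse disturbances (heat, freeze–thaw, anoxia, in different
chronological orders) and are destructively sampled over time for N-cycle
rates, N pools, gene-copy abundances of N-cycle guilds, and 16S community
composition.

## The core statistic

For each response variable, treatment and timepoint, the package computes
Hedges' g — the small-sample-corrected standardized mean difference of the
treated replicates against the control replicates:

    g = J (x̄_T − x̄_C) / s_p,   J = 1 − 3/(4m − 1),  m = n_T + n_C − 2
    var(g) = (n_T + n_C)/(n_T n_C) + g² / (2 (n_T + n_C))

and aggregates the variables into an **Ecosystem Aggregated Impact**:

    EAI = Σ_v |g_v|,   var(EAI) = Σ_v var(g_v),   CI95 = EAI ± 1.96 √var(EAI)

The absolute value measures how much the system changed without judging
direction; non-overlapping 95% confidence intervals between cells are read
as significant differences and summarized as compact letters. Around the
index, the package provides per-timepoint ANOVA + Tukey HSD, OTU-table
rarefaction, alpha diversity (observed species, Simpson's reciprocal,
Faith's PD), unweighted/weighted UniFrac, PCoA, pairwise PERMANOVA, and
sequential (Type-I) variance partitioning of the EAI against composition
predictors. A synthetic experiment generator with known true effects makes
the whole chain testable end to end.

## Worked example

```r
library(eaimpact)

hedges_g(control = c(10, 12, 11, 13), treated = c(14, 16, 15, 17))
#>       g  var_g ci_low ci_high n_treated n_control
#> 1 2.694 0.9537 0.7802   4.608         4         4
```

The treated group sits 2.69 pooled standard deviations above the control;
the CI excludes zero, so this variable alone signals a clear effect.

A miniature experiment with three disturbance chronologies whose planted
per-variable effects grow from 0.6 to 2.1 standard deviations:

```r
d <- experiment_design(
  treatments = c("control", "HAF", "AFH", "AHF"),
  timepoints = c("T0", "T1"), n_replicates = 4,
  variables = default_variables())
eff <- rbind(effect_spec(d, "HAF", delta = 0.6),
             effect_spec(d, "AFH", delta = 1.4),
             effect_spec(d, "AHF", delta = 2.1))
m   <- simulate_measurements(d, eff, seed = 101)
es  <- effect_size_table(m, control = "control",
        transforms = setNames(d$variables$transform, d$variables$name))
eai_table(es)
#>   treatment timepoint   eai var_eai ci_low ci_high n_variables letter
#> 1       AFH        T0 15.59   14.04  8.244   22.93          26      a
#> 2       AFH        T1 36.61   16.78 28.580   44.64          26      b
#> 3       AHF        T0 15.55   13.93  8.235   22.86          26      a
#> 4       AHF        T1 57.34   22.60 48.020   66.66          26      c
#> 5       HAF        T0 12.80   13.59  5.578   20.03          26      a
#> 6       HAF        T1 19.15   14.22 11.763   26.54          26      a
```

At T0 (before any disturbance) all treatments share letter `a`: their CIs
overlap, as they should under no effect — note the EAI is still ~15, not 0,
because a sum of |g| over 26 null variables is positive in expectation; EAI
values are compared between cells, never against zero. At T1 the three
chronologies separate exactly in the planted order (letters `a`, `b`, `c`),
with the weakest (HAF) not distinguishable from its own baseline.

The full pipeline — effect sizes, EAI with letters, ANOVA/Tukey,
rarefaction, diversity, UniFrac/PCoA, pairwise PERMANOVA, variance
partitioning, and a JSON manifest — runs from a YAML configuration:

```r
run_pipeline(paper_like_config(), "out_dir")
```

and from the shell via the thin CLI (`inst/cli/eaimpact.R`), with
subcommands `simulate`, `effect-sizes`, `eai`, `diversity`, `permanova`,
`varpart`, `run-all`.

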