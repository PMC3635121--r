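# blastovar

Positional variability analysis of *Drosophila* blastoderm expression
profiles.

During cleavage cycle 14A, gap genes position the seven
*even-skipped* (Eve) stripes with high embryo-to-embryo precision —
the expression patterns are *canalised*. Mutants of the terminal gap
gene *tailless* (*tll*) lose this precision in the posterior: Eve
stripe 7 forms late and only in a stochastic subset of embryos, and
the positions of the posterior stripes and gap domains vary far more
from embryo to embryo than in wild-type. `blastovar` implements the
quantitative pipeline that turns per-nucleus expression records into
that conclusion:

* **Profile processing** — lateral-strip extraction, background
  removal, bounded affine registration, integration into 100 one-%EL
  bins, Gaussian smoothing, cross-genotype intensity scaling.
* **Feature extraction** — penalised quadratic-spline fits; domain
  peaks (window argmax, refined to 0.01 %EL), half-maximum boundaries
  (bisection, censored when domains fuse), widths, t3→t8 anterior
  shifts, total Eve extent, and the three stripe-7 pattern classes
  (six / partial seventh / full seven).
* **Variability statistics** — for each cell of a domain × feature ×
  time-class grid, directional pooled t-tests on mean position and
  directional Brown–Forsythe tests on positional variance,

      W = (N − 2) · Σᵢ nᵢ (Z̄ᵢ − Z̄)² / Σᵢⱼ (Zᵢⱼ − Z̄ᵢ)²,  Zᵢⱼ = |xᵢⱼ − medianᵢ|,

  Bonferroni-corrected over the family (the default Eve grid has
  7 × 3 × 8 = 168 cells) with significance at corrected p < 0.005;
  plus SD summaries, pattern-class frequency tables and
  embryo-paired boundary correlations.
* **Synthetic cohorts** — a seeded generator with wild-type-like and
  *tll*-like presets (Gaussian domains with per-embryo positional
  jitter, class-linear anterior shifts, stochastic delayed stripe 7,
  shared-jitter coupling between the abdominal Kni and Eve stripe 6
  borders) so the entire pipeline runs and is tested with no external
  data, against analytically known ground truth.

Intended users: quantitative developmental biologists and
computational groups working with FlyEx-style per-nucleus expression
tables who need reproducible domain-feature extraction and
variance-comparison statistics.

## Worked example

Generate a small *tll*-like cohort, classify stripe-7 patterns, and
test stripe-6 positional variance against a wild-type-like cohort:

```r
library(blastovar)

cohort  <- generate_cohort(preset_tll(), c(t7 = 30, t8 = 30),
                           seed = 7, genes = "eve")
classes <- classify_cohort_stripe7(cohort)
pattern_class_frequencies(classes)
#>   time_class         class count   fraction
#> 1         t7           six    14 0.46666667
#> 2         t7 partial_seven    12 0.40000000
#> 3         t7    full_seven     4 0.13333333
#> 4         t8           six     1 0.03333333
#> 5         t8 partial_seven    14 0.46666667
#> 6         t8    full_seven    15 0.50000000
```

The seventh stripe appears progressively: about half of these mutant
embryos show it (partially or fully) at t7, and nearly all do at t8 —
the embryo-to-embryo heterogeneity itself is the phenotype. Positional
variance of the neighbouring stripe 6 tells the same story:

```r
feats <- extract_features(cohort)
s6    <- feats[feats$domain == "eve_stripe_6" & feats$time_class == "t8", ]
mean(s6$peak, na.rm = TRUE); sd(s6$peak, na.rm = TRUE)
#> stripe-6 peak at t8: 75.59 +/- 2.16 %EL over 29 embryos

wt  <- generate_cohort(preset_wildtype(), c(t8 = 30), seed = 8, genes = "eve")
fwt <- extract_features(wt)
brown_forsythe(fwt$peak[fwt$domain == "eve_stripe_6"], s6$peak, "less")
#>                 test direction statistic df1 df2        p_raw
#> 1 brown_forsythe_var      less  19.69505   1  56 2.154712e-05
bonferroni(2.154712e-05, 168)
#> [1] 0.00362
```

The wild-type cohort's stripe-6 peaks are significantly *less*
variable than the mutant's even after correcting for all 168 grid
cells (corrected p = 0.0036 < 0.005). `run_pipeline()` drives the
whole chain (generation or loading, processing, features,
classification, the full test grid) and writes provenance-stamped
tab-delimited tables; `inst/scripts/blastovar.R` exposes
`generate` / `process` / `features` / `stats` / `run` subcommands for
shell use.

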