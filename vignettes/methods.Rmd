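---
title: "Measuring positional variability in blastoderm expression profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring positional variability in blastoderm expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastovar)
```

## The problem

During the late syncytial blastoderm of *Drosophila* (cleavage cycle
14A, subdivided here into time classes `c13`, `t1`–`t8` of roughly 6–7
minutes each), segmentation genes lay down the antero-posterior (A–P)
body plan. Gap genes (*hb*, *Kr*, *kni*, *gt*, terminal *tll*) form
broad domains that position the seven stripes of the pair-rule gene
*even-skipped* (Eve) with remarkable embryo-to-embryo precision — the
developmental-biology sense of *canalisation*. Loss-of-function of the
terminal gap gene *tailless* (*tll*) disturbs the posterior of this
system: the posterior Hb domain is missing, the posterior Gt domain is
expanded and retracts late from the pole, and Eve stripe 7 fails to
form on schedule, appearing only in a stochastic subset of embryos at
the very end of the blastoderm stage.

`blastovar` provides the quantitative machinery to measure these
effects from per-nucleus expression records: it reduces each embryo to
a 1-D A–P intensity profile, extracts positional features of every
expression domain from a quadratic-spline approximation, and compares
genotypes with a Bonferroni-corrected grid of directional tests on
means (Student's *t*) and variances (median-centred Levene, i.e.
Brown–Forsythe). Increased embryo-to-embryo positional variance in the
mutant is the statistical signature of lost canalisation.

Positions throughout are percent egg length (%EL), 0 % at the anterior
pole; intensities are arbitrary 8-bit units (0–255); time-class
indices are `c13` = 0, `t1`–`t8` = 1–8, and temporal shifts are
treated as linear in this index, consistent with the near-linear
time–space trajectories of blastoderm domains.

## From nuclei to profiles

A cohort table holds one row per nucleus (`embryo_id`, `genotype`,
`time_class`, `x`, `y`, one intensity column per gene). Processing per
embryo and gene follows the classical quantification chain:

1. **Lateral strip extraction** (`extract_strip`): keep nuclei within
   a band of 10 % of embryo height around the lateral midline
   (`|y − 50| ≤ 5`) and sort by `x`. This turns the 2-D nuclear cloud
   into a 1-D profile at roughly one nucleus per %EL.
2. **Background removal** (`remove_background`): non-specific staining
   is estimated from the low envelope of the profile — within 10-%EL
   windows the lowest ⌈q·n⌉ samples (default q = 0.1) are baseline
   candidates; a robust outlier drop discards candidates that sit on
   domain flanks (windows fully covered by signal), and a polynomial
   (degree ≤ 2, default 2) is least-squares fitted and subtracted,
   clamping at zero. Rank-based candidate selection makes the step
   exactly invariant under constant intensity offsets, and re-running
   it on a corrected profile is a no-op to within one intensity unit.
3. **Registration** (`register_profiles`): each profile may be mapped
   by a bounded affine transform of the A–P coordinate
   (`x' = a·x + b`, `a ∈ [0.9, 1.1]`, `|b| ≤ 5`), chosen to minimise
   the mean squared difference to the cohort's binwise mean on a
   common grid, iterated twice with the reference re-derived after the
   first pass. Offsets are re-centred to cohort mean zero, so
   registration corrects egg-length and mounting differences without
   moving the cohort. The fit is a deterministic two-stage grid search
   over the bounded box — a quasi-Newton optimiser proved unreliable
   on this objective because the overlap region (and hence the
   support of the loss) changes with the parameters. The affine
   model is a deliberate small surrogate for spline-based registration
   used on scanned embryos; it is the smallest model that corrects the
   relevant geometric nuisances.
4. **Integration** (`integrate_profiles`): samples of all embryos of a
   genotype × gene × time class are pooled into 100 half-open 1-%EL
   bins `[b, b+1)` and averaged; empty bins are filled by linear
   interpolation (with ~100 nuclei per profile and 100 bins, sporadic
   empty bins are expected at small cohort sizes).
5. **Smoothing** (`smooth_gaussian`): discrete Gaussian filter,
   default σ = 1 bin, reflective boundaries — the minimal smoothing
   consistent with averaged 8-bit data.
6. **Intensity scaling** (`scale_to_reference`): to compare genotypes
   on one intensity scale, the target profile is multiplied by the
   ratio of 95th-percentile bin values (reference/target). The
   direction is per-gene configurable (`scaling$flip_genes`, default
   `hkb`) for channels where the mutant staining is the more reliable
   intensity reference.

## Spline-based feature extraction

All positional features come from a penalised quadratic B-spline fit
(`fit_quadratic_spline`): knots every 1 %EL on the fixed axis
[0, 100], degree 2 (continuous first derivative), and a
second-difference penalty on the coefficients. The smoothing parameter
defaults to 0.5, calibrated on synthetic data to balance two regimes:
densely sampled broad domains are tracked to < 2 intensity units under
noise of sd 5, while the narrow inter-stripe valleys of per-embryo Eve
profiles (sampled at ≈ 1 nucleus per %EL) are not filled in — stronger
smoothing raises the 6/7-%EL-spaced stripe valleys above half maximum
and censors the inner boundaries. At the default, stripe-peak
positional noise is ≈ 0.06 %EL and stripe widths broaden by
≈ 0.6 %EL on a half-max width of 4.2 %EL; the broadening cancels in
genotype comparisons made with the same extractor but should be
remembered when reading absolute widths. For noise-free inputs
`smoothing = 0` reproduces the data to within interpolation error.

Features per domain (`extract_features`):

* **Peak**: argmax of the spline inside the domain's search window,
  located on a 0.01-%EL grid and refined by local quadratic
  interpolation; ties resolve to the most anterior position. An
  argmax sitting on a window edge is interpreted as the flank of the
  neighbouring domain and the domain is reported absent — without
  this rule the posterior tail of Eve stripe 6 reads as a spurious
  stripe 7. Peaks below a fraction (default 0.1) of the profile's
  global maximum are also reported absent; absence is a value, not an
  error.
* **Half-maximum boundaries**: the nearest crossings of half the peak
  intensity on either flank, found by scanning from the peak and
  refined by bisection to better than 1e-4 %EL. The half-max level is
  relative to the zero baseline (after background removal), not to the
  local valley. If a flank never drops below half maximum before the
  window edge (fused domains), that side is *censored* with reason
  `no-half-max-crossing`; censored values are excluded from statistics
  and counted in reports, never extrapolated.
* **Width**: posterior minus anterior boundary; censored if either
  side is.
* **Shift**: peak at the earlier class minus peak at the later class;
  positive values are anterior movement. The headline shifts are taken
  between `t3` and `t8` (five class steps).
* **Extent**: last minus first stripe peak of the Eve pattern.

Search windows give peaks their identity ("which stripe is this?").
On real embryos identity is assigned by inspection and reporter
evidence, which 1-D data cannot reproduce, so `search_windows` derives
default windows from a genotype preset's expected class-shifted
centres — interior limits midway between adjacent centres, outer
limits four Gaussian scales beyond the outermost centre — and any
user-supplied `gene`/`domain`/`lo`/`hi` table can replace them.

**Stripe-7 pattern classes** (`classify_stripe7`): late *tll* embryos
fall into three classes — six stripes, six plus a partial seventh, or
seven fully formed stripes. With `A7` the stripe-7 window peak
relative to the stripe-6 peak and `V` the 6/7 valley minimum relative
to the smaller peak, the rule is `six` if `A7 < 0.15`, `full_seven` if
`A7 ≥ 0.50` and `V ≤ 0.50`, else `partial_seven`. On embryo images
"partial" also covers incomplete dorso-ventral extent; that criterion
is unavailable in a 1-D profile, so reduced relative amplitude stands
in for it — a documented limitation, and the reason the partial class
of the synthetic generator is rendered at reduced amplitude.

## The statistical grid

For each cell of a comparison grid (domain × feature × time class) the
package runs, in both directions ("smaller than" and "greater than"):

* a pooled-variance two-sample **Student t-test** on mean position
  (`t_test_directional`; pooled rather than Welch deliberately), and
* a **Brown–Forsythe test** on positional variance
  (`brown_forsythe`): with `Z_ij = |x_ij − median_i|`,

  `W = (N − 2) · Σ n_i (Z̄_i − Z̄)² / Σ_ij (Z_ij − Z̄_i)²`

  against F(1, N − 2). Median centring makes the test robust to small
  samples and mild non-normality; the price is mild conservatism at
  very small n (measured rejection ≈ 0.041 at nominal 0.05 with
  n = 20 per group, converging to nominal by n ≈ 100). The F test is
  one-tailed in W, so directional p-values halve the two-sided p when
  the ordering of the group Z-means matches the requested direction
  and take the complement otherwise.

Raw p-values are Bonferroni-corrected with the grid's family size and
flagged significant below α = 0.005 (corrected). The default Eve grid
is 7 stripes × {peak, anterior, posterior} × 8 time classes = **168**
cells; the two directions of one test are treated as one corrected
family member. The composition of the family is configurable
(`test_grid`), since grids of this kind admit several consistent
accountings; this one reproduces the canonical family size from the
cell count alone. Cells with fewer than three uncensored values on
either side are skipped with a recorded reason. Degenerate inputs use
fixed conventions: zero pooled variance with equal means gives t-test
p = 0.5 (p ∈ {0, 1} by sign otherwise); all-zero absolute deviations
give Brown–Forsythe p = 1 with a degenerate flag.

`sd_summary` (sample SD, n − 1), `pattern_class_frequencies`, and
`boundary_correlation` (Pearson, paired by embryo, for e.g. the
abdominal Kni posterior border against the Eve stripe 6 anterior
border) complete the analysis surface.

## The synthetic cohort generator

Because quantified mutant cohorts are not generally redistributable,
the package ships a seeded generator (`generate_embryo`,
`generate_cohort`) whose presets encode the study conditions, so every
downstream stage is exercisable with no external data.

Each expression domain is a Gaussian bump: amplitude × exp(−(x −
c)²/2σ²), with c = `center − shift_per_class × class index` plus one
per-embryo jitter draw per domain. Gaussians are not a claim about
biology; they are smooth, and analytically invertible, so the true
half-maximum boundaries (`c ± σ√(2 ln 2)`) are known exactly and
parameter recovery can be tested against closed-form ground truth.
Jitter is drawn once per embryo per domain — it models embryo-to-embryo
positional variability, the quantity under test, not nuclear noise.
Domains may share a jitter draw (`jitter_group`), producing the
correlated boundaries expected when one domain positions another (the
built-in presets couple the abdominal Kni domain and Eve stripe 6).
Amplitude varies with a Gaussian coefficient of variation (a modelling
choice; no distributional information exists for it), a constant-plus-
quadratic background and i.i.d. Gaussian nucleus noise are added, and
intensities are clipped to [0, 255]. Stochastic domains carry a
per-class presence probability, and present domains may be "partial"
(amplitude reduced to 30 %) with a per-class probability.

Nuclei sit at quasi-regular A–P positions with small scatter;
dorso-ventral heights are stratified (a golden-ratio sequence plus
jitter) rather than i.i.d. uniform, because real blastoderm nuclei
tile the surface — i.i.d. heights leave multi-%EL gaps in a 10 %
lateral strip that no real embryo shows, and such gaps break any
profile-based extractor. The default 1000 nuclei yield ≈ 100 strip
nuclei, the nuclear resolution of quantified blastoderm data.

The **wild-type-like preset** carries seven Eve stripes (t8 positions
spanning 47 %EL from stripe 1 to stripe 7), uniform positional jitter
of 0.75 %EL, per-class shift rates chosen so the t3→t8 shifts of Eve
stripe 6, Eve stripe 7 and the posterior Gt domain are 2.62, 4.36 and
4.34 %EL, and the principal gap domains. The **tailless-like preset**
removes the posterior Hb domain, widens and posteriorises the
posterior Gt domain (t3→t8 shift 5.92 %EL), dislocates stripes 4–6
posteriorly (stripe 6 shifting 4.16 %EL), inflates jitter on the
posterior stripes (1.6–2.0 %EL), and makes stripe 7 stochastic and
delayed: absent through t6, present in 45 % of embryos at t7
(33 % partial / 12 % full) and 92 % at t8, positioned so that embryos
with a seventh stripe span ≈ 57 %EL. All preset numbers are the
generator's definition of the study conditions, not measurements; the
tests and the acceptance script measure what the pipeline recovers
from them.

What the generator does **not** emulate: 2-D nuclear geometry and D–V
patterning; early broad pair-rule domains that only later resolve into
stripes (presets are stripe-resolved at every class, so early-class
synthetic patterns are cleaner than real ones); gene-circuit dynamics
(shifts are kinematic, linear in class index); non-Gaussian stripe
shapes and asymmetric flanks; spatially correlated staining artefacts.
Passing tests therefore demonstrate that the *pipeline* measures
faithfully under controlled conditions — not that real embryos obey
the generator's assumptions.

## Numerical choices and degenerate inputs

* Spline: ridge 1e-8 alongside the smoothing penalty for rank safety;
  evaluation clamps to [0, 100]; fits require ≥ 6 samples.
* Peak refinement: parabola through the three grid points around the
  argmax; tie-breaks anterior; refinement is validated against a
  dense-grid argmax oracle to 0.02 %EL.
* Boundary bisection: `uniroot` to 1e-6 on a 0.01-%EL bracket.
* Duplicate strip positions are separated by a stable 1e-9 jitter to
  keep profiles strictly increasing.
* Numbers in tab-delimited outputs are rendered at 6 significant
  digits, making repeated runs byte-identical; every output carries a
  provenance header (package version, configuration hash, master
  seed).
* Per-embryo seeds derive deterministically from the master seed
  (master + running embryo index).

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen
to keep sampling error well inside the asserted bounds: 200 embryos
per condition for jitter/frequency recovery, 100–250 per time class
for shift recovery, 40 embryos per class and genotype (t1–t8) for the
end-to-end canalisation comparison, 10⁴ replicates for test-level
calibration and 2000 for power. The statistical grid's family size
(168) and α (0.005, corrected) follow the canonical Eve analysis.

## Known limitations

* Stripe identity is window-based; grossly mispositioned domains
  (beyond the window half-spacing) would be mislabelled. Windows are
  user-overridable.
* The affine registration surrogate cannot correct non-linear axis
  distortions.
* Widths carry a smoothing-dependent broadening; compare widths only
  across cohorts processed with identical settings.
* The partial-stripe criterion is amplitude-based in 1-D; image-based
  D–V assessment is out of scope.
* The Brown–Forsythe test is conservative at n ≲ 30 per group; with
  the additional Bonferroni correction, reported variance differences
  are if anything understated.
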