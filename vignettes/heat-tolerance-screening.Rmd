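---
title: "Screening heat tolerance from pollen viability: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening heat tolerance from pollen viability: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heattol)
```

## The screening problem

Terminal heat stress around anthesis sterilises wheat pollen; genotypes
differ widely in how much viability they retain. A screening trial grows a
diversity panel twice — under normal conditions and under imposed terminal
heat — in a randomized complete block design repeated over seasons, and
scores percent pollen viability (darkly stained fertile grains over total,
Alexander stain) per plot. `heattol` turns those plot records into three
linked analyses: a per-genotype susceptibility index, a variance
decomposition for the whole factorial, and genetic parameters that say
whether selection on the trait would be effective.

## The susceptibility index

For genotype $g$ in one season, with $X$ the genotype mean over replicates,

$$\mathrm{HSI}_g \;=\; \frac{1 - X_{\text{stress},g}/X_{\text{normal},g}}
                           {1 - \bar X_{\text{stress}}/\bar X_{\text{normal}}},$$

the genotype's relative viability loss divided by the panel-mean relative
loss $\bar D$. The denominator's grand means are **unweighted means of
genotype means**, taken over the genotypes with both treatment means in
that season — the standard Fischer–Maurer usage. Genotypes with an
undefined index (zero normal-side mean, or a missing treatment) are
excluded from the grand means and reported in an exclusion list, never
silently dropped.

Conventions, each of which was a genuinely open choice:

* **Replicate means enter the formula**, not plot-level values: the index
  is a property of the genotype's expected response, and means over the
  (three) blocks are its natural estimate.
* **Per-season computation.** Each season is screened against its own
  $\bar D$; cross-season stability is then assessed by intersecting the
  per-season tolerant sets (`stable_tolerant()`), which is how two-year
  tolerant lines are reported in this literature.
* **Class boundaries.** Published cut-offs in this field ("tolerant
  < 0.5, moderately tolerant 0.5–0.99, susceptible > 1.0") leave
  $[0.99, 1)$ unassigned. `classify_hsi()` uses half-open intervals —
  tolerant $(-\infty, 0.5)$, moderate $[0.5, 1)$, susceptible
  $[1, \infty)$ — so the three classes partition the line while agreeing
  with the published labels everywhere they are defined. Both cuts are
  arguments, not constants.
* **Negative index values** (viability higher under stress than control)
  are retained and classify as tolerant; dropping them would bias class
  counts, and they carry real information about measurement noise at
  small panel reductions.
* Full precision is kept throughout; rounding (2 decimals in published
  tables) is display-only.

Two exact properties follow from the algebra and are enforced by tests:
the index is invariant to rescaling all viabilities by a positive
constant, and a genotype losing viability at exactly the panel-mean rate
has index 1. A caution follows from the second: an index of *exactly* 1
sits on the susceptible boundary, and floating-point arithmetic can place
a mathematically-boundary genotype on either side by one ulp. The package
does not fuzz the boundary; users comparing counts near the boundary
should compare indices, not classes.

## The factorial ANOVA

`anova_combined()` fits the fixed-effects decomposition

$$y = \mu + \text{Treatment} + \text{Year} + \text{Genotype}
      + \text{Treatment}\times\text{Genotype} + \varepsilon$$

with sums of squares that, on the balanced designs the function accepts,
equal the orthogonal mean decomposition (the tests verify this against an
explicit brute-force implementation on random designs up to
$6 \times 3 \times 4$). Deliberately **no** block term and no
Year-interaction terms are modelled: replicate-to-replicate and
year-interaction variation pool into the residual. This is the model under
which a $G \times 2 \times S \times r$ panel has df
$1,\; S-1,\; G-1,\; G-1$ and the remainder of $N-1$ — for the reference
design of 200 genotypes, two seasons and three replicates:
1, 1, 199, 199, 1999. All F tests are against the residual mean square.

Unbalanced panels are refused with the offending cells named rather than
approximated: the expected-mean-square algebra below is exact only under
balance, and silently switching to approximate sums of squares would
change the meaning of the downstream genetic parameters. A panel with
identical replicates (zero residual variance) is legal; its F statistics
are reported as `+Inf` rather than `NaN`.

## Variance components and genetic parameters

From the one-way genotype ANOVA within one condition (balanced, $r$
observations per genotype),

$$\hat\sigma^2_e = MS_E, \qquad
  \hat\sigma^2_g = \frac{MS_G - MS_E}{r} \;\;(\text{truncated at } 0),$$

and then

$$\mathrm{PCV}\% = \frac{100\sqrt{\sigma^2_p}}{\bar X}, \quad
  \mathrm{GCV}\% = \frac{100\sqrt{\sigma^2_g}}{\bar X}, \quad
  h^2_{bs} = \frac{100\,\sigma^2_g}{\sigma^2_p}, \quad
  \mathrm{GA} = k\,\sqrt{\sigma^2_p}\; \frac{\sigma^2_g}{\sigma^2_p},$$

with $k = 2.06$ (5% selection intensity) by default and GA in trait units
(percent viability); GA as a percent of the mean is provided as an extra
column.

Open choices and their resolutions:

* **Phenotypic-variance basis.** Whether $\sigma^2_p = \sigma^2_g +
  \sigma^2_e$ (plot basis) or $\sigma^2_g + \sigma^2_e/r$ (genotype-mean
  basis) is rarely stated in PCV/GCV papers; both are common. The default
  is the plot basis — the more conservative (lower heritability) and the
  more frequent in the Allard-citing literature — with
  `phenotypic_basis = "mean"` available everywhere.
* **Season pooling.** `genetics_report()` pools the seasons by default,
  so each genotype contributes seasons × replicates observations and one
  value per condition is reported (matching how single per-condition
  estimates are usually presented); a `season` argument restricts to one
  season. Note that pooling folds season-to-season variance into the
  error term, shrinking heritability relative to the single-season latent
  value — visible in the package's own simulations, and a reason the
  recovery tests below use single-season panels, where the latent value
  is exact.
* **Truncation.** $\hat\sigma^2_g < 0$ (genotype MS below error MS) is
  clamped to zero and flagged. Under a true null this happens with
  probability approaching one half at large df; a simulation test checks
  the 40–60% band.

## The trial simulator

`simulate_panel()` draws balanced panels from

$$y = \mu + \text{year}_s - \delta\,\mathbf 1[\text{stress}] + g_i
      + gt_i\,\mathbf 1[\text{stress}] + \varepsilon,$$

Gaussian effects on the percent scale, clipped to $[0,100]$ with clip
events counted (a warning above 5%). Defaults: 200 genotypes, two
seasons, three replicates, $\mu = 92$%, stress decrement $\delta = 8$% —
the design and magnitudes of the reference field screen. The variance
defaults $\sigma^2_e = 3$, $\sigma^2_g = 6.2$, $\sigma^2_{gt} = 3.1$,
$\sigma^2_{year} = 1$ (percent²) were fixed once, by two requirements:
the latent plot-basis heritabilities equal the values reported for this
trait in the field (67.3% normal; 75.6% stress, where the stress-side
genetic variance is $\sigma^2_g + \sigma^2_{gt}$), and draws at
$\mu = 92$ stay essentially inside the percent scale (default clipping
< 1%, so moment estimators are unbiased in practice).

What the generator emulates and what it does not: it reproduces the
design, the variance architecture, and the genotype × treatment
interaction that drives index-based re-ranking. It does **not** reproduce
the strong left skew of real viability data (most genotypes near 95% with
a long tail toward zero), spatial field autocorrelation, or
weather-driven season effects. One consequence: under a Gaussian
architecture calibrated to the reported heritabilities, the tolerant
class is rarer (≈ 5% of genotypes) than in the skewed real data (≈ 25%),
because a wide tolerant class requires interaction variance far exceeding
what those heritabilities permit. Passing recovery tests therefore
validate the estimators, not distributional realism. The latent truth
(`$truth`) defines genotype indices from noise-free expected means, so
recovery tests compare estimated against latent quantities.

Randomness is consumed in a fixed order — season effects, genotype
effects, interaction effects, registry, residuals — so changing the
replicate count does not reshuffle genotype effects, and a seed fully
determines the panel (byte-identical CSV).

## The reference fixture

Twelve published reference lines tolerant in both seasons of a two-year
screen ship with the package (`reference_tolerant_lines()`), with their
printed per-season index values. `fixture_reference_panel()` inverts the
index formula into a noise-free panel: all genotypes share a normal-side
mean (95%), each line's stress mean is $x_n(1 - \mathrm{HSI}\cdot\bar D)$
for a chosen $\bar D$ (0.25 per season).

A subtlety dictated the fixture's shape: a panel containing *only* the 12
tolerant lines cannot be internally consistent, because with a common
normal mean the panel mean reduction equals the mean genotype reduction,
forcing the average index to be exactly 1 — impossible when all values
are below 0.5. The fixture therefore adds four susceptible context
genotypes per season whose common reduction is solved exactly so the
panel $\bar D$ hits its target; they stand in for the susceptible bulk of
a real diversity panel, and the 12 reference lines remain the complete
tolerant intersection.

```{r fixture}
sc <- screen_panel(fixture_reference_panel())
stable_tolerant(sc)$stable_tolerant
```

## Descriptive reports

* **Viability bins** (`viability_bins()`): decade bins 100, 90–99, …,
  < 60. Because the published bin labels are integer ranges, genotype
  means are rounded to integer percent before binning by default; with
  `round_means = FALSE` the bins become half-open up to the next bin so
  they stay exhaustive on the continuous scale.
* **Era trends** (`era_trend()`): release years map to
  pre-green-revolution (< 1965), post-green-revolution (1965–2000) and
  modern (≥ 2001) eras; the cuts are configuration since era definitions
  vary between programmes. Genotypes without a release year (advanced
  lines) are listed as unassigned. The cross-season mean index per
  genotype is summarised per era and returned raw for violin plots.
* **Correlations** (`hsi_correlations()`): Pearson r of the index with
  normal- and stress-side viability, paired by genotype and season. A
  degenerate pair (zero variance) is an error, not an NA.

## Validation strategy and problem sizes

The test suite validates every stage against independent oracles:
brute-force group-and-average for means and indices, the explicit
orthogonal mean decomposition for ANOVA (200 random balanced designs with
$G \le 6$, $S \le 3$, $r \le 4$), textbook covariance sums for
correlations. Statistical properties are checked by simulation: genotype-F
null calibration at $\alpha = 0.05$ over 1000 panels of 20 genotypes ×
3 replicates (99% binomial band), heritability recovery at the full
200-genotype × 3-replicate size — the median estimate over 500
single-season panels must fall within 3 percentage points of the latent
truth at $h^2 \in \{30\%, 50\%, 75.5\%\}$ — and null truncation frequency
over 200 panels. These sizes give the tests stable verdicts while keeping
a full run around a minute on one core.

## Limitations

* Balanced designs only; no REML/mixed-model path for unbalanced data.
* Fixed-effects ANOVA with a single pooled residual; no narrow-sense
  heritability, and no multi-environment variance partitioning beyond the
  plot/mean-basis switch.
* Single-trait: no yield-based indices (STI, GMP) — the per-season
  screening structure would admit them, but they are out of scope.
* The Gaussian-with-clipping generator is a tool for estimator
  validation, not a distributional model of real viability data (see
  above).
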