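---
title: "Quantifying gravitaxis and culture-age expression changes in Euglena gracilis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gravitaxis and culture-age expression changes in Euglena gracilis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(euglenaGravitax)
```

## The problem

*Euglena gracilis* orients its swimming relative to the gravity vector,
and the sign of that orientation flips with the age of a batch culture:
young cells swim downward (positive gravitaxis), around day 6 the
population loses any preferred direction, and older cells swim upward
with increasing precision (negative gravitaxis). This package implements
the two computational legs of a study of that switch:

1. **Behaviour**: turning tracked cell trajectories from 20 fps
   recordings into population movement parameters — circular histogram,
   velocity, motility, alignment, direction index, the 120° upward
   fraction, form factor, and the r-value (mean resultant length).
2. **Transcriptome**: a microarray analysis chain — quantile
   normalization, empirical-Bayes moderated *t*-tests against the day-6
   reference with Benjamini–Hochberg FDR, fold-change binning, Venn
   decomposition of the significant sets, ANOVA-filtered Ward clustering
   on uncentered (absolute) Pearson distance, and GO-term
   overrepresentation with coverage percentages.

Because the raw videos and array scans are not available, a synthetic
data module generates inputs with exactly the statistical structure the
two chains assume, so every stage can be validated against known truth.
The numbered scripts under `analysis/` run the whole study end to end on
that synthetic data; they are thin drivers over the package functions,
which are the programmatic interface.

## Movement model and statistics

Headings are degrees clockwise from the upward axis: 0° is up, 180°
down, 90°/270° sideward. The simulator gives each motile cell one fixed
heading drawn from a von Mises(μ, κ) distribution plus small per-frame
angular jitter (default SD 5°). A fixed-heading-plus-jitter model is the
simplest generative process consistent with how vectors are extracted:
each object is followed for 5 frame transitions, so within-window paths
are nearly straight anyway. Per-cell speeds are Gaussian (default
50 ± 10 µm/s, truncated at 0) with 5% per-frame jitter; immotile cells
wobble with SD 0.5 µm/frame, far below the default 10 µm/s motility
threshold. Positions reflect at the arena walls with mirrored headings;
reflecting rather than periodic boundaries avoids spurious long vectors
jumping across the field. All geometry is in µm; pixels appear only when
frames are rasterized, so calibration enters in exactly one place.

Tracking links each object greedily to the nearest unclaimed object in
the next frame (ties to the lowest index), repeated over a 5-transition
window; a vector is emitted only when all five links succeed, because
the pooled statistics assume fixed-length vectors — broken tracks are
dropped, not truncated. "Followed for 5 subsequent frames" is read as 5
transitions (frames *t*…*t*+5). Greedy nearest-neighbour matching is
exact when cells are sparse; an exhaustive-assignment oracle guards the
small cases in the tests. The vector is the *net* displacement over the
window, and raster y-down coordinates are converted to the 0°-up
convention once, at vector construction.

The population statistics, for headings θ₁…θₙ of the motile vectors:

* **r-value** = ‖(mean cos θ, mean sin θ)‖ ∈ [0, 1]; 1 when all cells
  swim identically, 0 for symmetric spread. For a von Mises sample it
  converges to I₁(κ)/I₀(κ), which the simulator tests exploit.
* **alignment** = mean cos 2θ. Only the sign contract is prescribed
  (positive vertical, negative horizontal, ≈0 unoriented); mean cos 2θ
  is the standard axial second-moment statistic that satisfies it
  exactly.
* **direction** = (fraction up) − (fraction down), with "up" the open
  quadrants around 0° and the horizontal boundary (exactly 90°/270°)
  counting as neither — a measure-zero tie-break that avoids sign bias.
* **120° upward** = fraction within ±60° of up, boundary included.
* **form factor** = P²/(4πA), 1 for a circle; traced contours of
  discretized shapes can dip a few percent either way.
* **velocity** averages speed over motile *vectors* (not unique cells),
  and **motility** is the percentage of vectors at or above the speed
  threshold. The threshold (10 µm/s) is configuration, not doctrine.
* Pooling replicate measurements concatenates their vectors before
  computing statistics (per-replicate averaging is available but not
  the default).

Orientation statistics use the motile subset only — immotile jitter has
meaningless headings; motility uses the full vector set.

## Expression model and statistics

The simulator plants, per transcript, a baseline log2 intensity
~ N(8, 1.5²) and a residual variance σ²_g ~ d₀s₀²/χ²_{d₀} (defaults
d₀ = 4, s₀² = 0.05). Differential transcripts (10% per non-reference
group by default) receive additive log2 shifts of random sign with
|log2 FC| ∈ [log2 1.5, 2]. The matrix is returned on the linear scale,
20,396 × 16 at default size.

Tests run on log2 intensities; fold changes are ratios of linear group
means folded to ≥ 1 — the convention that keeps a "1.5-fold" cutoff
interpretable. The moderated *t* shrinks each pooled variance toward a
prior, s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g), with (d₀, s₀²) estimated
by moment matching on log variances (trigamma inversion); the statistic
is referred to a *t* distribution with d₀ + d_g df, or the normal when
d₀ = ∞ (the asymptotic case, which also arises when the observed log
variances spread no more than sampling noise — then s₀² is the mean
variance). Setting d₀ = 0 disables moderation. The estimation is
unit-tested by parameter recovery on the simulator's planted
(d₀, s₀²), and the whole path is cross-checked against an independent
empirical-Bayes implementation.

Significance combines FC ≥ 1.5 and p ≤ 0.05; BH-adjusted values are
always reported and can be used as an additional gate
(`fdr_cut`). Fold-change bins are cumulative (FC ≥ 1.5/2/3/5) with an
up/down split at the loosest bin. The Venn decomposition reports totals,
per-set specifics, the triple overlap, and pairwise overlaps both
including and excluding the triple region, so either reading of a
"shared between two days" count is computable.

Clustering uses d = 1 − |r_u| with the uncentered correlation
r_u = Σxy/√(Σx²Σy²); the absolute variant is the default, with a switch
for the signed one. Ward agglomeration applies the Lance–Williams update
to squared dissimilarities (`ward.D2`), switchable to `ward.D` — the
original software's internal choice cannot be determined, so both are
exposed. Samples enter after a one-way ANOVA filter (default p ≤ 0.05;
the filter threshold is not prescribed anywhere, so it is
configuration). Dendrograms export to Newick with branch lengths equal
to merge-height increments.

Enrichment is one-sided hypergeometric overrepresentation,
p = P(X ≥ k) for a term of size n containing k of the K differentially
expressed transcripts in an N-transcript universe — the standard
operationalization of correlating per-term DEG counts with term sizes.
Terms below 5 members are excluded before testing; BH runs across tested
terms; the default gates are p ≤ 0.05 and FDR ≤ 0.25. Coverage,
100·k/n, is rounded half-up at 2 decimals (1-decimal display optional);
the bundled `culture_age_go_counts()` table carries the published
per-term (k, n) pairs from which the reported percentages are
reproduced. No GO-hierarchy propagation is applied: term sizes are taken
as given flat counts. Transcripts may carry many terms.

```{r coverage}
go <- culture_age_go_counts()
head(cbind(go[, c("age", "term_id", "n_de", "n_term")],
           coverage = coverage_percent(go$n_de, go$n_term)))
```

## Worked example

```{r motion}
cfg <- track_sim_config(n_cells = 100, duration_s = 5, mu_deg = 180,
                        kappa = 4, seed = 7)
sim <- simulate_tracks(cfg)
vectors <- link_tracks(split_frames(sim$frames), window = 5,
                       max_disp = 10, fps = 20)
summarize_motion(vectors)
```

A downward-oriented population (μ = 180°) shows negative direction,
positive alignment and a mean heading near 180° — the positive-gravitaxis
signature of a young culture.

```{r de}
ecfg <- expr_sim_config(n_transcripts = 2000, seed = 7)
esim <- simulate_expression(ecfg)
de <- run_de_contrasts(esim$matrix, esim$groups, reference_group = "6d")
de$bins[["9d"]]
```

## What the synthetic data does and does not show

The generators reproduce the *statistical* structure the methods assume:
von Mises headings, log-normal intensities, inverse-chi-square variance
heterogeneity, planted effect sizes. They do not reproduce optical
segmentation artifacts, cell–cell occlusion, chemotactic or phototactic
components of real swimming, array spatial effects, or annotation bias.
Passing tests therefore demonstrate that the pipeline recovers truth
under its own model assumptions — correctness of the computations, not
of the biology. The published absolute DEG counts depend on the
unavailable raw arrays and are deliberately not targets; the published
coverage percentages, which are pure functions of printed counts, are.

## Numerical choices and problem sizes

Empty heading sets raise errors rather than returning NaN; histogram
bins are half-open with edge angles assigned upward; the r-value is
clamped at 1 against floating-point overshoot; equidistant link
candidates break ties deterministically; quantile normalization resolves
within-column ties by averaging (a fully constant column receives the
mean of the target distribution); zero sample variances are dropped from
the prior fit with a warning; zero within-group variance with distinct
means yields ANOVA p = 0, flagged. The test suite and the acceptance
script use deliberately modest problem sizes — 2,000-heading samples for
moment recovery, 5,000-transcript experiments for parameter recovery, 20
seeds for cluster-purity rates — chosen so the full validation runs in
well under a minute while keeping Monte-Carlo error far below the
asserted tolerances; the `analysis/` scripts run the study-scale
20,396-transcript design.

## Known limitations

Greedy linking can mis-assign at high cell densities (the exhaustive
oracle covers only sparse cases); the alignment/direction definitions
satisfy the documented sign contracts but may differ numerically from
legacy video-analysis systems whose formulas were never published;
whether the original array software computed fold changes on normalized
linear or log values is unknowable, and this package's convention
(linear means, log tests) is one defensible reading; wall reflections
mirror headings and therefore attenuate population orientation
statistics in long simulated recordings, exactly as they would in a real
cuvette.
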