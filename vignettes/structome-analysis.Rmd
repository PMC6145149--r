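---
title: "Structome analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structome analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structome)
```

## The measurement problem

Structome analysis is the quantitative structural profiling of a whole
single cell from a complete stack of serial ultrathin sections (about
40 nm thick) imaged by transmission electron microscopy. For a rod-shaped
bacterium every section shows two traced boundaries — the outer membrane
(OM), which delimits the whole cell, and the plasma membrane (PM), which
delimits the cytoplasm — and, with cryo-fixation and freeze-substitution,
individually countable cytoplasmic ribosomes. From the per-section
perimeters, cross-sectional areas, axis lengths and ribosome counts this
package computes the per-cell profile: length, OM/PM diameters, aspect
ratio, OM/PM surface areas, the volumes of the whole cell and of its four
compartments (OM shell, periplasm, PM shell, cytoplasm), the total
ribosome count and the cytoplasmic ribosome density per 0.1 fl
(1 fl = 1 µm³). Ribosome density is the species-characteristic statistic:
it varies little between cells of one strain while total counts track cell
size.

## Estimators and their conventions

**Length.** `cell_length()` defaults to `n_sections × thickness`. The
bundled reference dataset of seven *M. smegmatis* cells
(`msmegmatis_profiles()`) carries per-cell lengths that are *not* equal to
section count times any single nominal thickness (e.g. 38 sections but a
reported 3.90 µm), so a `supplied` mode passes an externally measured
length through unchanged, and the fixture stores the reported values
verbatim.

**Diameter.** One diameter per cell must be distilled from dozens of
sections whose apparent size shrinks toward the poles.
`cell_diameter()`'s default, `median_central`, takes the median minor axis
over the central 50% of sections, which on an ideal spherocylinder sits
entirely in the cylindrical mid-segment and is therefore exact;
`mean_all` and `max` are provided for sensitivity analyses.

**Surface area.** `surface_area()` stacks trapezoids: consecutive
perimeters are the parallel sides, section thickness the height, so
`S = Σ (p_i + p_{i-1})/2 · t`. No end-cap correction is applied. This
matters: over a hemispherical cap the integral of the perimeter is
`π²r²/2` while the true cap area is `2πr²`, so each cap is underestimated
by the factor π/4 and the whole-cell relative error is `(4 − π) r / (2L)`
— about 3.5% for a typical cell (r = 0.29 µm, L = 3.54 µm) but rising
above 10% for nearly spherical cells (r = 0.45 µm, L = 2 µm). The test
suite asserts that the observed error tracks this closed form to within
one percentage point; the bias is documented rather than corrected
because the downstream comparisons are between cells measured with the
same convention.

**Volumes.** `compartment_volume()` is the Cavalieri estimator
`V = Σ a_i · t` over OM-lined (whole cell) or PM-lined (cytoplasm) areas.
Evaluated at section mid-planes this is a midpoint rule; since the
cross-sectional area of a spherocylinder is piecewise quadratic in the
axial coordinate, the discretisation error at 40-nm sections is below
0.1% everywhere in the tested geometry range. Membrane shell volumes
(`shell_volume()`) use the thin-shell product perimeter × membrane
thickness × section thickness. The periplasm is obtained by subtraction;
the default `table_consistent` mode (whole − cytoplasm − OM − PM) keeps
the four compartments exactly additive, which the reference tables obey,
while `text_literal` (whole − cytoplasm) is retained as an option.
Noise-induced negative periplasm values clamp to zero with a warning.

**Ribosomes.** `ribosome_total()` sums per-section counts;
`ribosome_density()` is `total / V_cytoplasm × 0.1`. Report tables round
half-away-from-zero: 2 decimals for lengths, diameters, areas, volumes
and aspect ratios; nearest 10 for ribosome totals and densities
(`round_profile_table()`). All internal computation is full precision;
rounding happens only at report time. A consequence worth knowing when
checking published tables against themselves: quantities recomputed from
*rounded* inputs can land one rounding unit away from values originally
computed from unrounded data (2-dp cytoplasm volumes propagate to ±10 on
a density near 1,000), and the tests treat such one-unit discrepancies as
consistent.

## The synthetic generator

No raw micrographs accompany the reference data, so estimator validation
uses `spherocylinder_model()`: a straight cylinder with hemispherical
caps, circular cross-sections, the PM set inward of the OM by the
envelope width, and closed-form truth for every profile metric
(`analytic_truth()`). `slice_model()` cuts it into mid-plane-evaluated
sections at a chosen thickness and offset; `place_ribosomes()` draws the
cell total from a Poisson law with mean `density × V_cytoplasm / 0.1` and
spreads it multinomially in proportion to exact per-section cytoplasmic
slab volumes — equivalent to independent homogeneous placement, matching
the evenly distributed ribosomes seen in 3D reconstructions of real
cells. Optional measurement noise is multiplicative lognormal
(unit mean, chosen coefficient of variation), independent per section and
per measured quantity, which keeps all measurements positive; real
tracing error is likely correlated across neighbouring sections, so
noise-based tests are conservative about that structure.

Defaults are fixed at the reference study's conditions: OM radius
0.29 µm, length 3.54 µm, envelope width 0.015 µm (PM diameter 0.55 µm),
OM/PM thicknesses 0.002/0.006 µm (chosen to reproduce the ~0.01 and
~0.03 fl shell volumes of the reference cells), density 1,170 per 0.1 fl,
section thickness 0.040 µm. What the generator does **not** emulate —
bent or branching cells, septation, elliptic cross-sections, section
compression, correlated tracing error — bounds what passing tests show:
they validate the estimators' numerics and conventions, not robustness to
every artefact of real microscopy.

Randomness always flows through one explicit integer seed per call
(restored afterwards, so the caller's RNG stream is untouched);
`simulate_section_stacks()` derives per-cell sub-seeds from a single
master seed.

## Statistics

Group rows are mean and sample SD (n − 1). Cross-species comparisons use
two-sample two-sided t-tests that accept summary statistics alone
(`t_test_from_summaries()`), because several comparison species are
available only as published (n, mean, SD). The default variant is Welch
(robust to the unequal SDs and group sizes involved); the classical
pooled test is available, and for one published bound (total ribosomes,
*M. smegmatis* vs *M. tuberculosis*, p < 0.0002) only the pooled variant
reproduces the bound — Welch gives p = 3.1 × 10⁻⁴ — so the variant used
is worth reporting alongside any bound. `one_way_anova()` wraps the
classical fixed-effects F-test. No multiplicity correction is applied by
default, matching the source tables' convention; Bonferroni is available
through `compare_profiles(p_adjust = "bonferroni")`. p-values below
10⁻¹⁵ print as "< 1e-15" but are stored at full precision.

## Growth calibration

`structome_calibration()` returns the reference exponential
`y = 4998.5 · e^(−0.002 x)` (x = ribosome density per 0.1 fl, y =
doubling time in minutes). `fit_doubling_model()` refits (a, b) by
log-linear least squares — ordinary `lm()` on `log(y)` — chosen over
nonlinear least squares because no error model or weighting scheme
accompanies the reference presentation of the curve; with two points the
fit interpolates exactly. `invert_doubling()` is the algebraic inverse,
defined for `0 < y ≤ a`. The anchor doubling times behind the reference
parameters are not published, so the constants ship as constants and
refitting is left to user-supplied pairs; no confidence intervals are
offered for the reference curve.

## Problem sizes used in the shipped checks

The package's own verification runs use: a 5 × 5 noise-free geometry
sweep (r ∈ [0.25, 0.45] µm, L ∈ [2, 8] µm, t = 0.04 µm) for deterministic
recovery; 200 seeded synthetic cells at density 1,170/0.1 fl for
stochastic density recovery (mean within 3 standard errors of truth); and
10,000 null replicates (n = 10 per group) for t-test type-I error
calibration. These sizes make the checks statistically meaningful while
keeping a full run fast on a laptop.

## Known limitations

- The trapezoid surface estimator's pole-cap bias `(4 − π) r / (2L)` is
  inherent to the method and uncorrected; for cells with aspect ratio
  below about 4.3 it exceeds 5%.
- Straight-axis geometry only: bent cells are measured as if straight,
  which matches the section-stack convention (sections are perpendicular
  to the cutting axis, not the cell's centerline) but underestimates the
  arc length of strongly curved cells.
- `supplied` lengths are taken on trust; the package cannot reconcile a
  supplied length with the stack's section count.
- Shell volumes assume thin membranes of locally constant thickness.
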