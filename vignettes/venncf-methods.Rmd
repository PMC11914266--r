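---
title: "Area-based colocalization factors: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Area-based colocalization factors: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venncf)
```

## The measurement problem

Superresolution immunofluorescence of three cytoplasmic proteins (the
package's running example: ACC1, COP1 and KIF12 in hepatocyte-like cells)
shows each protein as fields of ~100-nm microdroplets. Whether the droplets
of different proteins co-assemble — and which protein bridges the other two —
is an inference about *spatial association between binary point patterns*,
and the area-overlap statistic used here deliberately avoids
intensity-based coefficients (Pearson, Manders): after binarization, only
pixel membership matters.

## Model and statistic

Let the k binary masks cover fractions $p_i$ of the ROI. A Venn region $R$
is given by included channels $I$ and excluded channels $E$. Its observed
fraction is the exact pixel count of $\bigcap_{i \in I} M_i \setminus
\bigcup_{j \in E} M_j$ over the ROI area (integer arithmetic throughout the
partition; floating point enters only at the final ratio). Under the
independence null — every channel's pixels placed at random — the expected
fraction factorizes:

$$\mathbb{E}_0[f_R] \;=\; \prod_{i \in I} p_i \prod_{j \in E} (1 - p_j),$$

and the Colocalization Factor is $CF(R) = f_R / \mathbb{E}_0[f_R]$, with
$CF = 1$ the control level.

**Two expectation conventions.** The phrase "multiply the percentages of
each color area" is unambiguous for the all-channels region but ambiguous
for exclusive regions such as $A \cap B \setminus C$: one may or may not
multiply by $(1 - p_C)$. `exclusion_aware` (the default) includes the
$(1-p_j)$ factors and is the exact independence null for the exclusive
region — it is the convention under which the package's null calibration
gives mean CF = 1 for *every* region. `paper_literal` multiplies only the
included fractions; because it overstates the expected area of exclusive
regions by $1/\prod_{j\in E}(1-p_j)$, its CFs are conservatively biased low
for exclusive regions (by ~5–8% at the few-percent cover fractions typical
here). Both conventions coincide on the triple region, and the convention is
recorded in every CF record so results are auditable.

**Undefined CFs.** When an included channel's mask is empty the expected
fraction is 0 and the observed fraction is necessarily 0; the CF is reported
as `NaN` with `defined = FALSE` rather than dropped silently. Cohort
summaries use defined records only and report the exclusion count. An
observed area over a zero expectation cannot occur (the observed fraction is
bounded by $\min_{i \in I} p_i$); the code asserts this.

## Binarization

In practice this analysis is usually run on images binarized interactively
in ImageJ/Fiji, with no single canonical algorithm; the threshold rule is
therefore configurable and recorded with every result. The
default is per-channel Otsu computed *within the ROI only* (a bright
structure outside the ROI must not move the threshold), implemented on the
ROI intensity vector with a 256-bin histogram; tied maximizing cuts resolve
to the median tie, so an exactly bimodal histogram thresholds midway between
the modes. Fixed and quantile thresholds are available; all methods use
`intensity >= threshold` and never mark pixels outside the ROI. The ROI
defaults to the whole frame — deriving per-cell outlines (segmentation) is
out of scope, but any mask supplied as TIFF/PNG is honoured.

## The droplet simulator

The simulator emulates sparse fields of diffraction-limited-style spots:
per channel, `droplets_per_channel` centres on a torus, each rendered as an
isotropic Gaussian of width `psf_sigma` and amplitude `peak_intensity` on a
constant `background_level`, plus i.i.d. Gaussian read noise, clipped to
[0, 1]. Placement is uniform, except that with a `scaffold_channel` set, a
fraction `tether_fraction` of each other channel's droplets is displaced
from a uniformly chosen scaffold droplet centre by an isotropic Gaussian of
sd `tether_distance_sd` (toroidally wrapped). With `tether_fraction = 0` all
channels are independent — and because placement and wrapping are toroidal,
area fractions are translation invariant and the independence null is exact,
with no edge correction needed.

Defaults (chosen once as the package's study conditions): 256×256 px at
30 nm/px, 150 droplets per channel, `psf_sigma` 60 nm, peak 0.8 on
background 0.1 with noise sd 0.02, `tether_distance_sd` 30 nm. Under Otsu
binarization these give per-channel cover fractions around 5–7% — the sparse
regime of superresolution droplet fields. No droplet density or intensity
statistics were available to match, so these are calibration choices, not
measured values. Droplet radius parameters are retained in the
configuration but do not affect rendering (single Gaussian per droplet);
they exist for forward compatibility.

What the simulator does *not* emulate: 3D structure, drift and chromatic
aberration, Poisson shot noise and camera gain, SIM reconstruction
artefacts, and spatially varying background. Tests passing on simulated data
therefore validate the *statistics* (calibration of CF, conservation,
inference behaviour), not robustness to those instrument effects.

**Seeds.** A cell is a pure function of (config, seed). Cohorts derive
per-cell seeds from the cohort seed by a fixed counter-based step
(`derive_cell_seed`, one LCG iteration of seed + cell index, kept below
2^31), so cohorts are reproducible without seed reuse across cells.

**Storage.** Stacks are written as multi-page 32-bit TIFF; this
environment's TIFF writer stores 32-bit samples on an integer grid, so
intensities round-trip to within 2^-32 per pixel (tested), not bit-exactly.
Channel names travel in the JSON ground-truth/config sidecars, not in TIFF
tags.

## Cohort inference

Cells are the replicate unit; no within-cell pixel correlation is modelled.
Per region the package reports mean CF, SEM and n over defined records. The
omnibus test is a classic one-way ANOVA across regions; comparisons "against"
the reference region are pairwise Welch t-tests with Holm familywise
correction — chosen over Dunnett because cohorts are small (typically 5
cells) with no variance-homogeneity guarantee; the method string is stored in
the output rather than assumed. Degenerate inputs: all values identical is an
error; zero within-group variance with differing means yields $F = \infty$,
$p = 0$, and the Welch wrapper returns p ∈ {0, 1} for constant pairs.

**Scaffold call.** With three channels, the candidate scaffold is the
channel excluded from the exclusive-pair region with the minimum mean CF;
the call is made only when both other pair regions reject against that
minimum region at the chosen alpha (Holm over the two comparisons), and a
relative tie within 1e-9 between the two smallest means yields no call.
Because the minimum region is selected from the data, the null rate of
significant calls is not exactly alpha; requiring *both* comparisons to
reject keeps it below the familywise level in the package's calibration
(tested at ≤ 10% for alpha 0.05).

The default ANOVA reference in `run_config()` is the exclusive pair of the
first two channels excluding the third (for the default channel order:
ACC1 & COP1 without KIF12), matching the convention of reporting enrichment
against the pair region that excludes the putative scaffold.

## Numerical and design choices

- Areas are integer pixel counts; the Venn partition is computed by exact
  bit-code tabulation, so conservation (exclusive areas sum to the union;
  marginals reconstruct exactly) holds as integer identities.
- Canonical region labels sort channel names, so regions match across cells
  regardless of construction order.
- The toroidal-shift Monte-Carlo estimator (`toroidal_null_fraction`) is the
  model-free check of the analytic expectation: uniform random translations
  with wrap-around preserve each channel's internal structure while
  destroying cross-channel association; on a torus its expectation equals
  the analytic product exactly.
- Quantile thresholds use R's default (type 7) sample quantile.

## Problem sizes used by the shipped checks

Null calibration: 800 cells in the test suite and 1000 in
`scripts/acceptance.R` (256×256, defaults), giving a standard error on the
mean triple-region CF of ~0.02 against the ±0.05 tolerance the calibration
tests assert. Oracle
agreement: 20 simulated cells × 500 toroidal shifts, 3-SE criterion per
region. Scaffold recovery: 100 cohorts of 5 cells at tether fraction 0.8
(and 100 null cohorts for the false-call rate). ANOVA calibration: 1000
synthetic null cohorts. These sizes are the package's documented study
conditions; all are seeded and deterministic.

## Known limitations

- Area-based only: no Pearson/Manders coefficients, no Costes-style pixel
  scrambling, no object-based nearest-neighbour analysis.
- The independence null treats pixels, not droplets, as the random unit at
  analysis time; droplet-scale clustering within a channel widens the
  per-cell CF distribution (it does not bias its mean under the null), which
  is why calibration statements are about means over cells.
- 2D only; no registration or SIM reconstruction.
- Scaffold inference assumes exactly three channels and that one protein is
  a candidate bridge; it reports orderings, not mechanism.
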