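---
title: "Quantifying biofilm pH, matrix biovolume, and paired community shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biofilm pH, matrix biovolume, and paired community shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmph)
```

## Scope

`biofilmph` implements the quantitative core of a split-mouth (within-patient
paired) in situ biofilm study: the same mouth carries arginine-treated (ARG)
biofilms on one side and placebo-treated (NoARG) biofilms on the other, and
three read-outs are compared within patient — microscale extracellular pH
under a sucrose challenge, lectin-stained carbohydrate matrix biovolume, and
16S community composition at the ASV level. The package starts from images
and count tables; growing biofilms, acquiring images, and processing reads
into an ASV table are upstream of it.

## Ratiometric pH: model and assumptions

C-SNARF-4 shifts its fluorescence emission with pH, so the ratio r of green
to red channel intensity is a dye-concentration-free pH reporter. The
calibration relation is the four-parameter log-logistic

$$r(\mathrm{pH}) = d + \frac{a}{1 + \mathrm{pH}^{\,b}/c},$$

with amplitude $a$ (ratio units), offset $d$ (the high-pH asymptote), Hill
exponent $b$, and scale $c$; the half-point of the transition sits at
$\mathrm{pH} = c^{1/b}$. This form is adopted because the pixel-wise
conversion used on images,

$$\mathrm{pH}(r) = \left(\left(\frac{a}{r-d}-1\right) \times c\right)^{1/b},$$

is its exact algebraic inverse, so forward simulation and inverse analysis
are consistent by construction. The packaged constants
($a = 2.249$, $d = 0.171$, $c = 1.36911 \times 10^{11}$, $b = 14.53178$,
`csnarf4_curve()`) place the half-point at pH 5.839, inside the dye's
sensitive range, and are valid on the titrated buffer domain [4, 8].

Numerical choices:

* **Conversion first, averaging second.** A field of view (FOV) is
  summarized as the arithmetic mean and SD of the per-pixel pH values.
  Averaging ratios before conversion is *not* equivalent under the
  nonlinear curve, and the suite asserts the two orders disagree.
* **Out-of-domain pixels are excluded, not clamped.** A pixel converting to
  pH outside [4, 8] is unsupported by the calibration; clamping would bias
  FOV means invisibly, so such pixels are dropped and their fraction is
  reported (`out_of_domain_fraction`). Ratios at or beyond the curve's pole
  ($r \le d$ or $r \ge d + a$) have no pre-image and are flagged invalid.
* **Fitting.** `fit_calibration()` uses deterministic Levenberg-Marquardt
  least squares with the scale parameter estimated on the log scale for
  conditioning. Initialization is fixed (offset = min ratio, amplitude =
  ratio range, $b = 10$, $c$ = midpoint$^b$); there are no random restarts,
  so a fit is reproducible given the table. At least 5 distinct pH levels
  are required for the 4 free parameters; non-monotone tables fit with a
  recorded warning.

## Segmentation and the cell/extracellular partition

Both pipelines share intensity-threshold segmentation (`threshold_mask()`):
Otsu's method on a 256-bin histogram by default, or a fixed manual value;
the threshold used is recorded on every mask. "Associated with microbial
cells" is operationalized as overlap with the cell mask dilated by a
4-connected disc of configurable radius (default 1 px) — the dilation
radius is a named knob because adjacency is not otherwise defined. The
lectin partition (`partition_lectin()`) is a true partition:
cell-associated and intercellular pixels are disjoint and their union is
the lectin mask, so areas are conserved exactly.

## Biovolumes from z-stacks

A stack of $n$ slices (study layout: $n = 6$, slice 1 at the substratum) is
segmented per slice and per channel; pixel counts become areas through the
pixel size (default $101.61/512\ \mu m$) and volumes by multiplying with
the interslice distance $\Delta z$. Layers are contiguous thirds — slices
1–2 (bottom), 3–4 (middle), 5–6 (top) for six slices. The interslice
distance is a required acquisition parameter (default 2 µm) recorded in
every report; biovolumes are linear in it, so paired comparisons are
unaffected by the default. Normalized biovolumes express lectin volume as
percent of microbial volume; per-layer percentages use the layer-matched
microbial denominator by default, with the stack-total denominator emitted
alongside (`*_totaldenom`), since either convention is defensible.
Thickness is an operational measure: slices whose microbial area fraction
reaches 0.5% count as occupied, times $\Delta z$.

## Paired statistics

* **Differential abundance.** Counts are centered-log-ratio transformed per
  sample (pseudocount 0.5 by default; the clr is computed on the full
  composition before any filtering). Each ASV whose mean group relative
  abundance reaches 1% (the conventional display cutoff) is tested with a
  Wilcoxon signed-rank test on the within-patient clr differences — zeros
  dropped, exact null for $\le 25$ untied pairs, normal approximation with
  continuity correction otherwise — followed by Benjamini-Hochberg
  adjustment across the tested ASVs. Filtering before adjustment affects q
  and is deliberate. The reported `log2fc` is the log2 ratio of NoARG over
  ARG group mean relative abundances (positive = more abundant under
  placebo), with the mean paired clr difference reported alongside, because
  fold changes of compositional means and clr effects answer subtly
  different questions.
* **Hierarchical estimates.** Treatment effects on pH or biovolume are
  estimated by a linear mixed model with random intercepts for patient and
  biofilm-within-patient (REML), honoring FOVs nested in biofilms nested in
  patients; group means and 95% CIs come from the fitted model and the
  difference p-value uses Satterthwaite degrees of freedom. A transparent
  two-stage fallback (FOV → biofilm → patient means, then a paired t-test)
  is always available and is used automatically, with a warning, for
  designs with no within-cell replication.
* **Sample size.** `sample_size_paired()` implements the one-sample normal
  approximation $n = \lceil ((z_{1-\alpha/\mathrm{sides}} + z_{1-\beta})
  \sigma / \Delta)^2 \rceil$ with the sidedness exposed as a parameter.
  With $\Delta$ equal to the SD it gives 8; with the hydrogen-ion inputs
  $\Delta = 1.03\times10^{-7}$ mol/L and $\sigma = 1.39\times10^{-7}$ mol/L
  it gives 15 (two-sided) and 11 (one-sided). No standard one- or
  two-sample normal/t convention reproduces a value as small as 7 from
  these inputs, so the convention is left explicit rather than resolved.

## What the synthetic generators emulate

Every pipeline input can be generated with ground truth attached, under a
single seed fanned out through named substreams (`substream_seed()`), so
identical specs regenerate bit-identical data.

* **Calibration sets** (`gen_calibration_set()`): 21 buffer levels
  (pH 4.0–8.0 by 0.2) × 3 FOVs; constant red raster, green = (true ratio +
  Gaussian noise) × red.
* **Ratio FOVs** (`gen_snarf_fov()`): a known pH field (constant,
  two-region, or gradient) encoded through the forward relation; cell
  objects as random ellipses bright in both channels with a one-pixel
  4-connected smoothed rim — so the thresholding route removes them, and a
  one-pixel dilation margin provably covers the rim; Poisson shot noise
  plus Gaussian read noise (SD 2), quantized to 8 bits. With noise off the
  image is continuous and the pipeline recovers the field to $10^{-9}$,
  which the suite asserts.
* **Z-stacks** (`gen_flba_stack()`): smooth random fields thresholded at
  exact pixel counts give blob-like masks whose per-slice area fractions
  match the request to within one pixel; intensities are two-mode (40 vs
  200) under the same noise model. Default cohort fractions impose a
  bottom-heavy microbial gradient, a fucose-lectin signal halved by
  treatment at all layers, and a galactose-lectin signal redistributed
  from bottom to top — the qualitative patterns the pipeline must detect.
* **ASV tables** (`gen_asv_table()`): log-normal baseline (SD 1.5), a
  patient effect shared by both sides (SD 2.0, making patient identity the
  dominant factor, as oral microbiota show), per-sample log noise (SD 0.3)
  and mild Dirichlet overdispersion (concentration 5000) on top of
  multinomial sampling at depth 20 000. Designated treatment-shifted ASVs
  are drawn from the top decile of baseline abundance so that they are
  observable after the 1% display filter, mirroring the fact that the
  detectable shifts in such cohorts occur among abundant taxa.
* **pH cohorts** (`gen_ph_cohort()`): a hierarchical Gaussian model at the
  FOV-summary level with imposed effects +0.19 (10 min) and +0.16 (35 min)
  pH units over placebo means 5.87 and 5.68, and SD components patient
  0.3, biofilm 0.1, FOV 0.15 — the within-biofilm FOV spread this implies
  (largest differences of ~0.5–0.8 pH units across 9 FOVs) matches the
  variability such studies report.

What the generators do *not* emulate: real biofilm texture and optical
sectioning (no PSF, no depth attenuation), dye photophysics, chimeras or
contamination in sequencing, and any coupling between a patient's pH
response and their community composition (effects are imposed
independently). Passing tests therefore demonstrate that the computations
are correct and well-calibrated, not that the biological effect sizes are
rediscoverable from real images.

## Verification strategy and problem sizes

The test suite checks, among others: exact recount equivalence — every
pixel count, area, and biovolume the pipeline reports equals a brute-force
recount of the emitted rasters (independent dilation and counting code) —
run over the full per-patient study layout (2 × 2 sides × 2 biofilms ×
9 FOVs × 2 timepoints ratio images and 2 × 2 × 2 lectins × 9 z-stacks at
512 × 512) for a two-patient slice of the cohort, a problem size chosen to
keep the default suite fast while exercising identical per-image
conditions; conservation of layer additivity and the lectin partition on
1 000 random mask instances; recovery of each draw's realized cohort pH
effect (the ground truth the generator attaches) within 0.05 in at least
95 of 100 seeded draws, together with unbiasedness of the estimator for
the imposed +0.19 across those draws — the two readings differ because
the biofilm-effect draws alone move a realized cohort mean by SD ≈ 0.035
around the imposed value — with the mixed-model and two-stage estimators
agreeing in sign on every draw; null calibration of the
clr-Wilcoxon-BH pipeline over 10 000 simulated null cohorts (40 ASVs at
depth 5 000 per replicate, a size set for the suite's runtime budget);
agreement of the exact signed-rank p-value at n = 10 with full $2^{10}$
enumeration; and patient-dominant ordination structure (silhouette by
patient exceeding silhouette by treatment on the first two components).

## Worked example

```{r example}
curve <- csnarf4_curve()

# a noisy field of view at pH 5.5 with 15% cell cover
g <- gen_snarf_fov("constant", mean_ph = 5.5, cell_density = 0.15,
                   dim = c(256, 256), seed = 7)
out <- process_fov(g$fov, curve)
out$summary[, c("mean_ph", "sd_ph", "n_pixels", "out_of_domain_fraction")]

# a z-stack with a bottom-heavy lectin gradient
st <- gen_flba_stack(rep(0.35, 6), c(0.14, 0.14, 0.09, 0.09, 0.04, 0.04),
                     dim = c(128, 128), seed = 12)
rep <- normalize_biovolumes(stack_biovolumes(st$stack))
rep
```

## Known limitations

* The Otsu threshold assumes a bimodal histogram; FOVs dominated by one
  class segment poorly, which is why the threshold value is recorded and a
  fixed manual override exists.
* Per-pixel shot noise propagates nonlinearly through the conversion
  curve, biasing noisy FOV means slightly acid-ward (about 0.03 pH units
  at the default noise settings and 8-bit quantization); the effect
  cancels in within-patient comparisons, which is what the design
  estimates.
* The mixed model treats pH as Gaussian at the FOV level and ignores
  spatial correlation between FOVs of one biofilm beyond the shared random
  intercept.
* Biovolumes inherit the usual stereological simplification of multiplying
  segmented area by interslice distance; no axial PSF correction is
  attempted.
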