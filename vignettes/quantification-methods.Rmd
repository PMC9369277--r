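---
title: "Quantifying uterine vasculature from multiplex immunofluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying uterine vasculature from multiplex immunofluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselquant)
```

## The measurement problem

Adenomyosis — endometrial glands and stroma ectopically present inside the
myometrium — is associated with abnormal uterine bleeding and subfertility,
and angiogenesis and lymphangiogenesis are suspected drivers. The
measurements this package implements come from multiplex immunofluorescence
of hysterectomy tissue: six markers imaged per field (DAPI for nuclei, CD31
for all endothelium, podoplanin/D2-40 for lymphatic endothelium, α-SMA for
smooth muscle and pericytes, CD10 for endometrial stroma, and VEGF), with
five multispectral fields of 0.9 × 0.7 mm analyzed per tissue sample.

Four outcomes are computed per tissue compartment:

* **Blood vessel density (BVD)** — CD31⁺ vessel count per mm² of
  compartment area. The compartment area is the CD10-stained area for
  endometrial stroma and the α-SMA-stained area for myometrium. Every
  endothelial cell or cluster counts as one vessel.
* **Lymph vessel density (LVD)** — the same for podoplanin⁺ vessels.
* **Percent stained area** — %CD31⁺ (or %podoplanin⁺) pixels per
  compartment, a consistency check on the count-based densities that is
  insensitive to how clusters are delimited.
* **Mature:total vessel ratio** — the fraction of CD31⁺ blood vessels with
  α-SMA double staining (a mural/pericyte ring). A low ratio marks tissue
  rich in new, immature vessels, i.e. ongoing angiogenesis. It is only
  meaningful in endometrial stroma: in myometrium every vessel is embedded
  in smooth muscle.

VEGF expression is summarized by the immunohistochemical score (IHS): the
percentage of immunoreactive cells binned to 0–4 (below 1% → 0, 1–10% → 1,
11–50% → 2, 51–80% → 3, 81–100% → 4) multiplied by a staining intensity
score 0–4, giving 0–16. Group comparisons use the Kruskal–Wallis test across
tissue types with pairwise Mann–Whitney U post hoc tests, two-tailed at
α = 0.05, reported as median (range) and stratified by menstrual cycle phase.

## Pipeline

`run_pipeline()` chains the stages: ingest (or simulate) → per-channel
binary layers → compartment masks → vessel objects → densities → IHS →
comparison report. Each stage is exported on its own
(`binarize_channel()`, `clean_mask()`, `label_objects()`,
`build_compartment_masks()`, `extract_vessels()`, `classify_maturity()`,
`compute_densities()`, `aggregate_specimen()`, `score_field()`,
`compare_tissues()`), so any intermediate is inspectable.

### Binary layers

Each channel is thresholded (pixel positive iff intensity ≥ threshold) with
Otsu's method by default and the applied threshold recorded for audit; a
fixed threshold can be forced per channel. Otsu assumes a bimodal
histogram, which fails in two real situations, so `quantify_field()` adds
two guards around it:

* a **contrast guard**: when the class means are separated by less than
  `min_contrast` (default 0.15 on the [0, 1] scale), Otsu has split a
  unimodal histogram. A **background-floored rescue** threshold (5th
  intensity percentile + 0.3) is then tried, which recovers genuinely
  sparse staining such as a single lymphatic in a field;
* a **uniform-staining branch**: if the rescue also fails and the mean
  intensity is above 0.4, the field is uniformly stained with no background
  present (bulk α-SMA in pure myometrium) and the whole plane is positive;
  otherwise the channel carries no specific signal and the layer is empty.

Masks are cleaned by morphological closing (disc radius 0.5 µm) and removal
of components below 5 µm² (20 px at 0.5 µm/px) — smaller than any capillary
cross-section. Connected components are labeled with 8-connectivity so that
ring-shaped vessel walls do not fragment at diagonals; 4-connectivity is
available for comparison.

### Compartments

The field is partitioned into four mutually exclusive, jointly exhaustive
masks. Stroma is the cleaned CD10 area. Glands are enclosed CD10-negative
holes inside the endometrial tissue that contain nuclei (gland detection is
geometric because glands are defined morphologically). Myometrium is the
cleaned α-SMA area minus endometrial tissue: stroma takes precedence on
overlap, so the α-SMA rings of mature vessels inside the endometrium are
never misread as myometrium, while bulk myometrial α-SMA (which includes
vessel walls) is kept whole, matching how myometrial area is measured from
bulk staining. Everything else is background.

### Vessels and maturity

Each CD31 component ≥ 5 µm² becomes a vessel object and is assigned the
compartment holding the majority of its pixels (background- or
gland-majority objects are dropped). It is classed lymphatic when ≥ 50% of
its pixels are podoplanin-positive; podoplanin components without
substantial CD31 overlap are appended as lymphatics, so a double-stained
lymphatic is counted exactly once. Because published protocols rarely state
whether CD31⁺/podoplanin⁺ objects were excluded from blood-vessel counts,
the 0.5 overlap cut is an explicit, configurable decision.

A blood vessel is **mature** when at least 10% of its dilated outer
boundary band (width 4.5 µm, spanning the endothelium-to-mural gap) is
α-SMA-positive. The low cut reflects that any visible mural coverage reads
as "double staining" to an observer; the measured overlap fraction is kept
on each vessel object so other cuts can be applied post hoc.

### Aggregation and statistics

Specimens are pooled per compartment as total count / total area over their
fields (and area-weighted means for percent areas) rather than a mean of
per-field densities — robust to unequal compartment areas per field.
Medians and ranges are computed on the unrounded specimen-level values.

`compare_tissues()` reproduces the study layout per outcome and cycle-phase
stratum: Kruskal–Wallis omnibus over {control endometrium, eutopic,
ectopic}, all pairwise Mann–Whitney U post hoc, and the
adenomyosis-vs-control myometrium pairwise test, with significance flags at
the configured two-tailed α. No multiple-testing correction is applied by
default, mirroring the original analysis; Holm adjustment is available
(`adjust = "holm"`). The Mann–Whitney implementation uses midranks; the
p-value is exact (full enumeration) when both groups have ≤ 8 tie-free
observations, and otherwise a tie-corrected normal approximation with
continuity correction; two-tailed exact p is twice the smaller tail, capped
at 1. Degenerate all-tied input makes the tie-corrected Kruskal–Wallis
statistic 0/0; the package returns H = 0, p = 1 with a warning. The
medication subgroup analysis (`medication_subgroup()`) compares
eutopic-endometrium BVD and LVD between anti-angiogenic medication users
(NSAIDs, tranexamic acid) and the rest, pooled over phases.

## The synthetic-tissue generator

No imaging data are deposited with the study this design emulates, so
validation uses rendered fields with fully known ground truth
(`generate_field()`, `generate_cohort()`).

**Geometry.** Eutopic/control endometrium fields are stroma-filled with ~13
elliptical glands per mm² (semi-axes 30–80 µm) lined by epithelial nuclei;
ectopic fields embed three CD10⁺ islands (semi-axes 110–220 µm, with small
glands) in an α-SMA⁺ myometrial bed; myometrium fields are uniformly α-SMA⁺.
Vessels are annuli: blood vessels with outer radius 4–15 µm and wall
2–3 µm (CD31), lymphatics 8–20 µm (podoplanin). The planted mature fraction
of blood vessels receives a concentric α-SMA ring 1–2 µm outside the
endothelium. Placement is rejection-sampled inside the target compartment
with no overlap; a field that cannot host its planted count fails loudly.
Nuclei are disks (radius 2.5 µm) at ~2000/mm² in stroma and ~1500/mm² in
myometrium with a minimum spacing that keeps them resolvable; VEGF is
painted over the planted fraction of cells per compartment at intensity
`level/4`.

**Scale.** The default pixel size is 0.5 µm/px, giving 1800 × 1400 px for
the fixed 0.9 × 0.7 mm field — sub-micron, as ×200 multispectral scans are.
Planted densities are exact by construction: the ground-truth BVD equals
planted count ÷ compartment area.

**Noise.** Additive background (0.05) plus Gaussian noise (σ = 0.02) on the
[0, 1] scale, quantized to 16 bits; optional spectral bleed-through adds a
fixed fraction of each channel to its spectral neighbours (default 0, since
spectral unmixing is upstream of this pipeline's scope). The generator does
*not* emulate nucleus texture, autofluorescence, uneven illumination,
section folds or out-of-focus blur — passing recovery tests therefore
demonstrates correctness of the measurement definitions and their
implementation, not robustness to every real-world artefact.

**Cohort preset.** `adenomyosis_study_design()` reproduces the emulated
study's structure: 19 cases (7 proliferative / 12 secretory) and 19 matched
controls (6/13); eutopic endometrium analyzable for 14 cases and 17
controls, ectopic for 16 cases, myometrium for all 38; 4 cases and 5
controls flagged as anti-angiogenic medication users; case lesion depths
planted well above the 2.5 mm invasion threshold that defines adenomyosis
(strict inequality). Planted effect medians encode the reported pattern —
ectopic BVD at twice the control endometrium (60 vs 28–36 vessels/mm²),
eutopic LVD elevated in the proliferative phase (16 vs 8 vessels/mm²),
eutopic BVD higher in the secretory than the proliferative phase, mature
fraction 0.60 in control endometrium vs 0.35 in eutopic/ectopic tissue, and
VEGF planted so the median IHS is 1 in stroma, 3 in glands and 4 in
myometrium with no case–control difference. Between-specimen biological
variability is lognormal with sdlog 0.25 (~25% CV) on densities — typical
of matched histology cohorts and consistent with effects of this size being
detectable at n ≈ 6 per phase stratum, as reported — plus Gaussian jitter
(SD 0.06) on the mature fraction. Specimen seeds derive from the master
seed via a polynomial string hash, so any specimen regenerates in
isolation. `simulate_outcome_table()` draws specimen-level outcomes from
the same variability model without rendering images; it is the desk-scale
route for calibration checks (type-I error, power) that need thousands of
replicate cohorts.

## Numerical and design choices

* **Intensity calibration.** IHS intensity cutpoints default to
  `c(0.125, 0.375, 0.625, 0.875)` — midpoints between the quarters of the
  background-subtracted dynamic range — so staining rendered at level *k*/4
  scores *k* with maximal noise margin. Real assays should calibrate these
  against control tissue.
* **Sub-1% staining** is scored 0: the printed bins start at 1%, and 0 is
  part of the intensity scale, so IHS 0 for essentially unstained tissue is
  the consistent completion.
* **Cells** are proxied by DAPI connected components; a cell is
  VEGF-positive iff the mean VEGF intensity in a 2.5 µm disk around its
  nucleus centroid is ≥ 0.15 (above background, below the lowest rendered
  level). Compartments with no detected cells report NA, never 0%.
* **Exact-test switch** at ≤ 8 per group: enumeration cost is at worst
  `choose(16, 8)` labelings.
* **Ring rasterization** enforces a minimum wall of 1.4 px so annuli stay
  8-connected at coarse pixel sizes.
* **Coordinates** are row/column pixel indices; all reported sizes are µm
  or mm, never pixels.

## Problem sizes used in the validation suite

The test suite exercises full-size 0.9 × 0.7 mm fields at 1 µm/px for
count, density and maturity recovery (20 fields spanning 10–60 vessels;
pooled five-field specimens at 5–40 vessels/mm²; the mature-fraction sweep
0–1), and runs the complete 19 + 19 preset end-to-end at 2 µm/px — the
package's chosen balance between spatial fidelity and a test suite that
runs in minutes. Statistical calibration uses specimen-level simulation:
2000 null replicates for the type-I error of the omnibus test at the
cohort's group sizes (5–13), and 200 replicates for the power of the 2×
ectopic BVD effect at n = 6 vs 6. The qualitative pattern of the preset
(which comparisons flag, and in which direction) is stable across seeds;
individual p-values are not, as expected at these group sizes.

## Known limitations

* The generator's vessels are circular annuli; real vessels are tortuous
  and sectioned obliquely. Count-based outcomes are insensitive to this;
  percent-area outcomes inherit the idealized wall geometry.
* Otsu-with-guards assumes staining is either well-separated from
  background, uniformly present, or absent; heavy autofluorescence
  gradients would need the fixed-threshold override.
* The IHS intensity score depends on its calibration vector; cross-study
  comparability requires a shared calibration, exactly as visual scoring
  requires a shared observer rubric.
* Phase and disease labels are metadata here; morphological cycle-phase
  dating and histopathological diagnosis are out of scope.
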