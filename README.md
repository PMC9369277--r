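# vesselquant

Quantification of blood and lymphatic microvasculature, vessel maturity and
VEGF expression from multiplex immunofluorescence images of endo-myometrial
tissue, with the nonparametric group-comparison report used in adenomyosis
case–control studies — plus a seeded synthetic-tissue generator with full
ground truth for validating every stage.

## What it measures

For each 0.9 × 0.7 mm multispectral field (channels DAPI, CD31, α-SMA,
podoplanin/D2-40, CD10, VEGF), the pipeline builds cleaned binary layers,
partitions the field into endometrial stroma (CD10⁺), glands, myometrium
(α-SMA⁺) and background, and computes per compartment:

- **BVD / LVD** — CD31⁺ / podoplanin⁺ vessel count per mm² of compartment
  area (every endothelial cell or cluster counts as one vessel);
- **% stained area** — percent CD31⁺ (podoplanin⁺) pixels per compartment,
  the count-free consistency check on the densities;
- **mature:total ratio** — fraction of blood vessels with an α-SMA mural
  ring (CD31/α-SMA double staining); low values indicate immature, newly
  formed vessels, i.e. ongoing angiogenesis (endometrial stroma only);
- **VEGF IHS** — immunohistochemical score: percentage-of-immunoreactive-
  cells bin (below 1% → 0, 1–10% → 1, 11–50% → 2, 51–80% → 3, 81–100% → 4)
  × intensity score (0–4), range 0–16.

Specimens pool their five fields as total count / total area. Group
comparisons follow the study layout: Kruskal–Wallis omnibus across tissue
types, pairwise Mann–Whitney U post hoc (exact by enumeration for small
tie-free groups), median (range) summaries, cycle-phase and medication
stratification, two-tailed α = 0.05.

## Worked example

Render one synthetic eutopic-endometrium field with known ground truth
(30 blood vessels/mm², 8 lymphatics/mm², half the blood vessels muralized),
then quantify it:

```r
library(vesselquant)

cfg <- specimen_config(tissue_type = "eutopic_endometrium", pixel_um = 1,
                       planted_bvd = 30, planted_lvd = 8,
                       planted_mature_fraction = 0.5, seed = 7)
field <- generate_field(cfg, 1)
q <- quantify_field(field$stack)
q$records[, c("compartment", "compartment_area_mm2", "blood_count",
              "lymph_count", "bvd_per_mm2", "lvd_per_mm2", "mature_ratio")]
#>   compartment compartment_area_mm2 blood_count lymph_count bvd_per_mm2
#> 1      stroma               0.5607          17           4       30.32
#>   lvd_per_mm2 mature_ratio
#> 1       7.135       0.4706

score_field(field$stack, q$compartments)[
  , c("compartment", "n_cells", "immunoreactive_pct", "pct_score",
      "intensity_score", "ihs")]
#>   compartment n_cells immunoreactive_pct pct_score intensity_score ihs
#> 1      stroma    1121              4.996         1               1   1
#> 2      glands     246             64.228         3               1   3
```

The 0.56 mm² of stroma held exactly 17 planted blood vessels and 4
lymphatics; the detected densities (30.3 and 7.1 vessels/mm²) and the
mature ratio (8/17 = 0.47) equal the planted ground truth
(`field$truth$summary`). The VEGF scores recover the planted
immunoreactive fractions (5% of stromal cells → bin 1, 65% of gland cells
→ bin 3) at intensity level 1, giving IHS 1 and 3.

A full study — the built-in 19 + 19 case–control preset with planted group
effects, five fields per specimen — runs end to end with:

```r
res <- run_pipeline(pipeline_config(simulate = "adenomyosis_study",
                                    preset_pixel_um = 2, seed = 1,
                                    out_dir = "out"))
res$report          # per-outcome, per-stratum tests with significance flags
```

which writes `fields.csv`, `specimens.csv`, `ihs.csv`, `outcomes.csv`,
`comparisons.csv`/`.json`, `group_summaries.csv` and the resolved
`config.yaml` into `out/`. Identical configuration and seed reproduce every
tabular artifact byte for byte.

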