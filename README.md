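# octbiofilm

Quantitative structural analysis of biofilms imaged by optical coherence
tomography (OCT), for labs running automated flow-cell monitoring rigs.
The package turns raw C-scan volumes (multi-page TIFF stacks) into the
standard structural parameters, evaluates the positioning accuracy of the
scanning stage from calibration-target images, and provides the replicate
statistics (Grubbs outlier testing, per-day summaries, heat-map tables)
needed to compare dozens of flow cells over a cultivation experiment. A
synthetic phantom generator with exactly known ground truth makes the
whole pipeline testable without instrument hardware.

## The quantities it computes

For a binarized C-scan with N A-scan columns and effective axial voxel
height Δz = Δz_air / n (refractive-index correction):

- **Mean biofilm thickness** L̄_F = (1/N) Σᵢ L_F,i, with the local
  thickness L_F,i = (Σ_z b_i,z) · Δz / 255 — the biomass voxel count of a
  column times the voxel height (b ∈ {0, 255}).
- **Substratum coverage** SC = 100 · A_biofilm / (A_biofilm +
  A_background), from the z-direction maximum intensity projection
  (every pixel ≥ 1 is biomass).
- **Intrinsic porosity** Φ_intrinsic = 100 · A_voids / (A_biofilm +
  A_voids), with voids labeled per A-scan column beneath the topmost
  biomass voxel (three-class labeling 150/50/0, background excluded),
  plus a **global porosity** over the whole sub-interface envelope.
- **Textural entropy** TE = −Σ_{a,b} p(a,b) ln p(a,b), the Shannon
  entropy (nats) of the gray-level co-occurrence table of the projection
  image — 0 for a homogeneous (biofilm-free) image.
- **Height maps** of the bulk–biofilm interface, in µm.

Positioning accuracy: the printed 1 mm target disc is detected by mean
filter (r = 2 px) → grayscale → threshold 120 → connected components with
particle-size gating → unweighted centroid; per-axis deviations from the
series mean (Δx_i = x_i − x̄, Δy_i = y_i − ȳ) are summarized with 1.5·IQR
outlier fences and checked against the 8 µm optical-resolution tolerance.

## Worked example

Simulate a four-day growth series on a small grid, analyze it, and compare
with the generator's ground truth:

```r
library(octbiofilm)

params <- growth_params(extent_x_mm = 1.2, extent_y_mm = 1.2,
                        voxel = voxel_spec(15, 15, 10, 1),
                        channel_height_um = 450, seeding_rate_mm2_day = 2,
                        lateral_rate_um_day = 90, vertical_rate_um_day = 40,
                        void_fraction = 0.2, noise_sd = 8, seed = 42)
series <- synth_biofilm_series(params, days = 4)
reports <- do.call(rbind, lapply(series, function(s)
  structure_report(s$volume, threshold = 90)))
print(reports, digits = 4)
#>   flow_cell day n_columns sc_percent mean_thickness_um phi_intrinsic_percent
#> 1        NA   1      6400      7.688             1.761                 16.77
#> 2        NA   2      6400     28.453            13.134                 17.14
#> 3        NA   3      6400     53.641            36.842                 17.93
#> 4        NA   4      6400     77.891            72.245                 18.23
#>   phi_global_percent textural_entropy
#> 1              16.77            3.535
#> 2              17.14            4.639
#> 3              17.93            5.163
#> 4              18.23            5.079
```

Coverage climbs from 8% to 78% as colonies spread, mean thickness grows to
72 µm, the measured porosity tracks the constructed 20% void fraction
within two points, and the textural entropy rises as the interface gets
patchier. The day-4 ground truth for comparison: SC 78.3%, L̄_F 71.1 µm,
void fraction 20.0% — the pipeline recovers coverage within 0.5 points and
thickness within one voxel height.

Positioning, on a synthetic target image with a known sub-pixel center and
five dust specks:

```r
tg <- synth_target_image(offset_um = c(3.1, -2.4), dust = 5, seed = 7)
rec <- detect_target(tg$image)
rec[, c("x_com_um", "y_com_um", "area_px")]
#>   x_com_um y_com_um area_px
#> 1     3351  2495.57   44610
round(tg$true_center_um, 2)
#>       x       y
#> 3351.01 2495.52
```

The detected center of mass lands within 0.05 µm of the true center
(about 0.01 px) despite the dust, which the particle-size gate discards.

The worked example for the flow-cell operating point:
`flow_rate(6, 5, 0.45)` (mean velocity 6 mm/s in a 5 × 0.45 mm channel)
returns **0.81 mL/min**.

## Command line

A thin dispatcher over the same functions ships in
`inst/scripts/octbiofilm.R`:

```sh
Rscript inst/scripts/octbiofilm.R simulate --output_dir sim --dx 15 --dy 15 --dz_air 15 --refractive_index 1
Rscript inst/scripts/octbiofilm.R analyze  --input sim/manifest.csv --output_dir out --dx 15 --dy 15 --dz_air 15 --refractive_index 1
Rscript inst/scripts/octbiofilm.R summarize --input out/structure_reports.csv --output_dir summary
```

`analyze` writes one CSV row and one height-map PNG per flow cell × day;
`summarize` produces per-parameter heat-map CSVs (outliers annotated `o`,
missing cells blank) and figures. Settings can also live in a plain
`key = value` config file (`--config FILE`), with flags taking precedence.

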