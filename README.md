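# ivhypoxia

Quantitative analysis of multichannel intravital microscopy of tumors
carrying a hypoxia-response-element (HRE)/GFP reporter: spectral unmixing,
tumor-ROI hypoxia metrics, vascular-distance gradients, peritumoral collagen
orientation from SHG, serial-section colocalization — plus a synthetic scene
generator with exact ground truth so the whole pipeline is testable without
a microscope.

## Who this is for

Imaging groups quantifying tumor hypoxia and its microenvironment from
four-channel intravital data (DsRed tumor cells, HRE-driven GFP hypoxia
reporter, APC-CD31 vessels, second-harmonic-generation collagen), and
methodologists who want every stage of such a pipeline backed by oracles.

## The models at the core

* **Linear unmixing** — per pixel, channel signals S relate to fluorophore
  abundances A through a control-derived coefficient matrix R:
  `S = A × R`. Solved by least squares with non-negativity (clip or NNLS).
* **Hypoxia gradient** — cells sampled on a 20-µm grid in the tumor ROI;
  each gets its exact Euclidean distance to the nearest vessel, testing
  whether reporter intensity rises with distance from oxygen supply.
* **Vascular density** — vessel-positive fraction of the tumor ROI dilated
  by 100 µm (the nominal O₂ diffusion limit), vessels segmented by SLIC +
  adaptive thresholding.
* **Collagen alignment** — per 100-µm peritumoral ROI, the 2D FFT power
  spectrum is binned into angular power, an ellipse is fitted by second
  moments, and `Alignment score = (1 − b/a) × 100` (0 = isotropic,
  100 = perfectly aligned); fiber orientation is reported relative to the
  local tumor edge.
* **Colocalization** — stain images coarsely downsampled (bicubic) to
  absorb registration error, then pixel-intensity Pearson r between
  hypoxia markers; positive-stain fraction at the pooled top-decile
  threshold within viable (DsRed⁺) tumor.
* **Reporter kinetics** — half-life of
  `I(t) = baseline + amplitude · 2^(−t/t½)` by profiled least squares.

See `vignettes/quantitative-intravital-hypoxia.Rmd` for assumptions,
parameter defaults, and numerical choices.

## Worked example

```r
library(ivhypoxia)

p <- scene_params(image_size_px = c(192L, 192L), pixel_size_um = 2,
                  tumor_radius_um = 130, n_vessels = 4, n_fibers = 300,
                  seed = 1L)
scene <- generate_scene(p)                      # 4-channel image + truth
A <- unmix(scene$image, p$mixing_matrix)        # solve S = A x R

tumor   <- segment_tumor_roi(A$DsRed, 2)
vessels <- segment_vessels(A$APC, 2)
dmap    <- vessel_distance_map(vessels)
cells   <- sample_cells(tumor, A$GFP, dmap)

tumor
#> <region_mask:tumor_roi> 192 x 192 px, 13409 positive (36.4%)
pearson_cor(cells$gfp_intensity, cells$distance_um)
#> r = 0.990, p = 2.68e-117, n = 136
str(gfp_metrics(A$GFP, tumor, 50))
#> List of 3
#>  $ gfp_positive_fraction: num 0.292
#>  $ mean_gfp_intensity   : num 31.1
#>  $ n_tumor_pixels       : int 13409
vascular_density(vessels, expand_roi(tumor, 100))
#> [1] 0.1578
```

The reporter intensity of the sampled "cells" rises steeply with distance
to the nearest vessel (r = 0.99 on this noiseless scene — the generator
planted a saturating-exponential gradient), 29.2 % of tumor pixels are
GFP-positive at threshold 50, and vessels cover 15.8 % of the expanded ROI.

Peritumoral collagen along the tumor–collagen interface:

```r
lines <- extract_interface(tumor, A$SHG, collagen_search_um = 30)
main  <- lines[[which.max(vapply(lines, `[[`, 0, "arc_length_um"))]]
main
#> <interface_line> 390 vertices, 912.5 um, closed
img <- spectral_image(list(GFP = A$GFP, SHG = A$SHG), 2, c("GFP", "SHG"))
head(peritumoral_table(img, tumor, main)[, c("mean_gfp", "mean_shg",
     "orientation_deg", "alignment_score", "relative_orientation_deg")], 4)
#>   mean_gfp mean_shg orientation_deg alignment_score relative_orientation_deg
#> 1    48.00   10.669           33.29           49.90                  62.4685
#> 2    46.88   10.448           11.53           47.77                  32.1731
#> 3    59.01    9.446           42.10           69.81                   0.7435
#> 4    30.66    4.718           42.56           68.95                  17.6735
```

Each row is one 100-µm ROI stepped 100 µm along the 912-µm interface: local
mean reporter intensity (tumor-overlapping pixels only), mean SHG, dominant
fiber direction, Eq.-style alignment score, and fiber angle relative to the
local tumor edge.

In vitro reporter decay:

```r
tc <- generate_timecourse(2, 1, 10, seq(0, 12, 0.5))
fit_halflife(tc$time_h, tc$intensity)
#> <decay_fit> half-life 2.000 h, baseline 1, amplitude 10
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/ivhypoxia.R", package="ivhypoxia"))')
Rscript $CLI simulate --out scene --seed 1 --size 256
Rscript $CLI quantify --scene scene --out metrics
Rscript $CLI collagen --scene scene --out rois.csv
Rscript $CLI coloc    --seed 1 --out coloc
```

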