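# muos

Transport simulation and collective-migration analysis for a
micro-optic-stalk (μOS) microfluidic gradient device.

The μOS mimics the developing *Drosophila* eye–brain complex: a sink
reservoir (eye imaginal disc, left) and a source reservoir (brain lobe,
right), both 50 μm deep, joined by eight tapered microchannels 90 μm long
and 10 μm deep that stand in for the optic stalk. Continuously flushing the
source with a chemoattractant (FGF, or a dextran tracer) sets up a
quasi-linear gradient along each channel, within which retinal neuroblast
(RNB) clusters chemotax collectively. The package is for quantitative
biologists and microfluidics designers who want to reproduce and probe the
device's concentration fields and the cluster-migration statistics measured
in it — without access to the original cells or raw images.

It provides:

* **Transport**: a depth-averaged finite-volume solver for steady and
  transient diffusion–advection, ∂(hc)/∂t = D ∇·(h∇c) − h u ∂c/∂x, with the
  thickness map h encoding the two-layer device; axial profiles, the L/M/H
  gradient-region partition, OLS gradient-linearity R², and RMSE. Unequal
  inlet flow ratios R = Q_R/Q_L enter through a channel Péclet number
  Pe = pe_alpha·(R − 1).
* **Migration metrics**: per-track total path length L_T, net displacement
  D_N, and the directionality ratio DR = Σcos(θ)/n (one net-displacement
  angle per track against the gradient axis), summarized by cluster size
  class (single 1–2 cells / small 3–5 / large >5).
* **Disaggregation**: fission-event detection with cell-count conservation,
  localization into gradient regions, and the small-cluster-fraction
  timeline among motile clusters.
* **Synthetic experiments**: a seeded Gamma/von-Mises biased-random-walk
  generator with concentration-gated fission, plus calibration routines
  that invert the reported statistics (step means from L_T, heading
  concentration κ from DR, fission hazard and initial mix from the
  timeline).

## Worked example

```r
library(muos)

mask    <- build_domain_mask(device_geometry(), grid_spec(dx = 1))
field   <- solve_steady(mask, transport_params())        # balanced inlets, R = 1
profile <- extract_axial_profile(field, channel_index = 4)
partition_regions(profile, device_geometry())
#>   label x_min x_max c_min c_max
#> 1     L   150   180 0.134 0.384
#> 2     M   180   210 0.384 0.630
#> 3     H   210   240 0.630 0.867
linearity_r2(profile, c(150, 240))
#> [1] 0.999807
```

The channel span [150, 240] μm carries an almost perfectly linear gradient
(R² → 0.9999 as the grid is refined); its thirds hold low (≈0.13–0.38),
medium (≈0.38–0.63) and high (≈0.63–0.87) normalized concentrations, the
three microenvironments the device exposes cells to within one gradient.

```r
cal <- calibrate_generator(lt = 17.7, dr = 0.72, dn = 10.1)  # small-cluster row
cal$kappa
#> [1] 0.877
ex <- generate_tracks(generator_config(seed = 42, n_tracks = 300))
summarize_by_class(ex$tracks)
#> Per-class migration summary (mean +/- SE per track)
#>   class   n percent         L_T_um        D_N_um             DR
#>  SINGLE  51   17.0%  2.70 +/- 0.10 1.09 +/- 0.08 -0.06 +/- 0.10
#>   SMALL 176   58.7% 17.70 +/- 0.34 9.38 +/- 0.34  0.74 +/- 0.03
#>   LARGE  73   24.3% 14.79 +/- 0.34 8.58 +/- 0.40  0.85 +/- 0.02
```

A 300-track synthetic experiment at the calibrated defaults recovers the
reported structure: singles barely move (≈2.7 μm total, no directionality),
small clusters dominate and migrate farthest (L_T ≈ 17.7 μm, DR ≈ 0.72–0.74),
large clusters are directional but less displaced.

See `vignettes/muos-methods.Rmd` for the model details, calibrations and
limitations, and `inst/scripts/muos.R` for a command-line front end
(`simulate`, `synth`, `analyze`, `pipeline`, `sweep-ratio`).

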