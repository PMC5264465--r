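# ilxpct

Simulation and quantification of **in-line X-ray phase-contrast CT
(IL-XPCT)** of tumor neovascularization.

## What this package is for

Propagation-based (in-line) phase-contrast imaging turns phase gradients
into intensity fringes by letting the beam propagate freely between the
specimen and the detector: with the X-ray refractive index
`n = 1 - delta + i*beta`, every interface between materials of
different `delta` acquires a bright/dark fringe pair whose strength
grows with the object-to-detector distance in the near field.  At a
synchrotron this resolves micrometre-scale vasculature in fixed liver
specimens *without a contrast agent*, and has been used to follow tumor
neovascularization in hepatoma xenografts over four weekly growth
stages: tumor vascular density (vessel volume / tumor volume) rises to
a peak of about 4.3 % at week 2 and then falls as necrosis outpaces
angiogenesis, with the smallest detectable vessels around 20 um at a
9 um detector pixel.

`ilxpct` re-implements that entire quantification chain as a tested,
reusable R package, replacing the animal specimens with a synthetic
phantom generator of known ground truth:

* **Phantoms** — liver lobe + staged tumor with branching hepatic and
  tortuous tumor vessel trees (cluster motifs, avascular cores, a
  low-transmittance suture), rasterized to `delta`/`beta`/label voxel
  grids with exact ground-truth volumes and densities.
* **Forward optics** — line-integral phase/attenuation maps
  (`phase = -(2*pi/lambda) * integral(delta dl)`), Fresnel free-space
  propagation, Poisson noise, detector-gain (ring artifact) injection.
* **Reconstruction** — parallel-beam filtered back projection
  (band-limited Ram-Lak, Shepp-Logan / Hann options), slice-wise over
  the rotation axis.
* **Contrast statistics** — the vessel-wall edge contrast
  `C = (Imax - Imin) / (Imax + Imin)` from line profiles, and the
  local-window contrast map
  `C(x,y) = sd_W(I) / mean_W(I)` (windowed coefficient of variation).
* **Vessel quantification** — suture/transmittance masking, threshold
  vessel extraction (fringe-robust Otsu + hysteresis), vascular volume
  and density, local-thickness vessel diameters, ring-artifact gray
  profiles.
* **Reporting** — week-series mean +- SD tables, simple linear
  regression trend tests, CSV/JSON artifacts via `run_pipeline()`.

## Worked example

Simulate one week-2 specimen at the default beamline settings
(15 keV, 1 m object-to-detector distance, 9 um pixels) and recover its
vascular density:

```r
library(ilxpct)

spec <- phantom_spec(week_stage = 2, seed = 1)   # 128^3 at 9 um
ph   <- build_phantom(spec)
tidy(ph)
#> # A tibble: 1 x 6
#>    week tumor_volume_mm3 vascular_volume_mm3 vascular_density_pct
#>   <int>            <dbl>               <dbl>                <dbl>
#> 1     2           0.0593             0.00255                 4.29
#> # i 2 more variables: min_diameter_um <dbl>, sub_resolution <lgl>

g    <- beam_geometry(energy_kev = 15, distance_m = 1, n_angles = 400,
                      photons = 1e4)
sino <- acquire_sinogram(ph, g, seed = 1)
vol  <- reconstruct_volume(sino)
rec  <- quantify_specimen(vol, ph$masks$tumor, week = 2,
                          suture_mask = dilate_mask(ph$masks$suture, 2))
rec$vascular_density_pct
#> [1] 4.052826
```

The phantom's exact ground-truth density is 4.29 % (the week-2 target);
the end-to-end chain — edge-enhanced projections, Poisson noise at
10^4 photons/pixel, FBP, threshold segmentation — recovers 4.05 %,
within about 6 % relative, and reports an 18 um minimum vessel diameter
(the 2-voxel resolution floor).  Over the full staged series (weeks 1-4,
three seeds per week) the recovered densities reproduce the
rise-to-week-2-then-fall pattern; see
`recover_week_series()` and the methods vignette
(`vignettes/methods.Rmd`).

The whole pipeline, including CSV/JSON reporting, runs from a single
config:

```r
res <- run_pipeline(list(phantom = list(grid_n = 64, seed = 1),
                         optics = list(n_angles = 200)),
                    out_dir = "out")
res$week_series
```

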