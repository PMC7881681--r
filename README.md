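# molliT1

Pixel-wise T1 relaxometry and ECV mapping for cardiac MOLLI (modified
Look-Locker inversion recovery) series.

Cardiac T1 mapping quantifies the longitudinal relaxation time of the
myocardium from a handful of inversion-time (TI) images acquired in one
breath-hold — N = 8 for the pre-contrast 5(3)3 scheme, N = 9 for the
post-contrast 4(1)3(1)2 scheme. Each pixel's samples are fit with the
three-parameter inversion-recovery model

    S(t) = a (1 − e^(−b·t)) + c,        T1* = 1/b,

and the apparent T1\* is converted to T1 by the Look-Locker correction
`T1 = T1* (a/(a+c) − 1)`. From co-registered pre- and post-contrast T1 maps,
blood-pool T1 values and the hematocrit, the extracellular volume fraction
map follows as `ECV = (1 − Hct) · ΔR1_myo / ΔR1_blood` with
`ΔR1 = 1/T1_post − 1/T1_pre`.

The package is aimed at quantitative-MRI researchers and tool builders who
need a scriptable, testable MOLLI pipeline:

* **Two fitters.** A Levenberg–Marquardt path (`fit_lm`, via `minpack.lm`)
  with incremental polarity flipping for magnitude data, and a
  reduced-dimension nonlinear least-squares path (`fit_rd`) that solves
  (a, c) in closed form for every candidate rate and searches over the rate
  alone — initialisation-free and the faster of the two.
* **Robust polarity restoration.** Magnitude images lose the sign of
  early-TI samples; the restoration window around the minimum-magnitude
  sample covers noise displacement in either direction, which matters when
  two TIs nearly coincide (as MOLLI schedules structurally produce).
* **Map layer.** `compute_t1_map` fits every above-threshold pixel, with
  invalid-pixel masking (never value clipping), optional T1 clamp limits,
  and worker-count-invariant parallel execution. `fit_pixel_report` exports
  a per-pixel fitted-curve plot.
* **ECV, evaluation, I/O.** `compute_ecv_map`, ROI means and Bland–Altman
  agreement (`roi_mean`, `bland_altman`), DICOM series reading (standard
  InversionTime attribute), NIfTI/CSV/PNG export with JSON sidecars.
* **Synthetic phantom.** `cardiac_phantom` / `generate_phantom` render
  MOLLI stacks with exported ground truth and Rician noise, so every stage
  is testable without clinical data.

## Worked example

```r
library(molliT1)

# a 64x64 digital cardiac phantom: blood disk (T1 = 1500 ms) inside a
# myocardial annulus (950 ms), 5(3)3 scheme, Rician noise at 2% of amplitude
ph  <- cardiac_phantom("pre", shape = c(64, 64), noise_sigma = 6, seed = 42)
map <- compute_t1_map(ph$stack, method = "RD", clamp_limit = 3000)
map
#> parameter_map [RD]: 64 x 64, 3151 valid pixels, T1 11..2962 ms

roi_mean(map, phantom_mask(ph, 1))   # myocardium: 949.4 ms (truth 950)
roi_mean(map, phantom_mask(ph, 2))   # blood:     1491.8 ms (truth 1500)

# post-contrast companion and the ECV map
post <- cardiac_phantom("post", shape = c(64, 64), noise_sigma = 6, seed = 43)
pmap <- compute_t1_map(post$stack, method = "RD", clamp_limit = 1500)
ecv  <- compute_ecv_map(map, pmap,
                        blood_t1_pre  = roi_mean(map,  phantom_mask(ph, 2)),
                        blood_t1_post = roi_mean(pmap, phantom_mask(post, 2)),
                        hct = 0.45)
roi_mean(ecv, phantom_mask(ph, 1))   # myocardial ECV: 0.218
```

The fitted ROI means sit within a few tenths of a percent of the phantom
truth; air pixels and fits beyond the clamp limit are invalid (`NA`), so
they never contaminate ROI statistics. The ECV of 0.218 matches the value
implied by the phantom's ground-truth relaxation rates (0.2215) to the
phantom's noise level.

A command-line tool wraps the same pipeline (installed at
`exec/molli-t1` inside the package library):

```sh
molli-t1 phantom --contrast pre --shape 96,72 --noise-sigma 6 --seed 1 --output pre_dicom
molli-t1 fit --input pre_dicom --method rd --output pre_t1
molli-t1 inspect --input pre_dicom --row 48 --col 36 --output fitplot
molli-t1 ecv --pre pre_t1.nii.gz --post post_t1.nii.gz \
         --blood-pre 1491.8 --blood-post 279.9 --hct 0.45 --output ecv
```

## Documentation

See the package help pages (`?fit_rd`, `?compute_t1_map`, …) and the
methods vignette `vignettes/molli-t1-mapping.Rmd` for the model, the
candidate-window design, numerical tolerances and known limitations.
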