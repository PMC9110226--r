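# ctprestore

Sinogram-domain restoration for low-dose dynamic brain CT perfusion (CTP),
with an end-to-end, fully synthetic evaluation pipeline.

CTP imaging repeats a head scan every couple of seconds while a contrast
bolus passes, so radiation dose is a first-order concern — but lowering the
tube output floods the projection data with noise that propagates into the
CBV/CBF/MTT/TTP perfusion maps clinicians read. This package implements and
evaluates the projection-domain answer: model the noise where it arises (in
the sinogram), restore it there, and only then reconstruct. It is aimed at
medical-imaging researchers who want a compact, dependency-light R testbed
for penalized weighted least-squares (PWLS) sinogram restoration.

## What it implements

1. **Noise model.** Post-log projection variance
   σ² = (1/P₀)·exp(a)·[1 + (1/P₀)·exp(a)·(σₑ² − 1.25)] — photon statistics
   plus electronic noise, growing exponentially with attenuation
   (`noise_variance()`, `add_noise()`).
2. **PWLS restoration.** Minimize
   Φ(p) = Σ (yᵢ−pᵢ)²/σᵢ² + β Σ (pᵢ − med(Nᵢ))², a variance-weighted data
   term plus a 4-neighborhood **median** penalty, via a modified
   Gauss–Seidel sweep with the closed-form update
   pᵢ ← (yᵢ + βσᵢ²·med(Nᵢ)) / (1 + βσᵢ²)  (`pwls_restore()`).
3. **Adaptive weighting.** Keep the measured ray where σᵢ² ≤ λ, use the
   restored ray where σᵢ² > λ; λ defaults to the 75th percentile of the
   variance map (`adaptive_weight()`, `restore()`).
4. **Tomography.** Parallel-beam forward projection, its exact adjoint, and
   FBP reconstruction with ramp/Hann/Shepp–Logan filters, in Rcpp
   (`forward_project()`, `fbp_reconstruct()`).
5. **Perfusion maps.** CBV (AUC ratio), CBF (maximum slope / AIF peak),
   MTT (central volume), TTP (`compute_maps()`).
6. **Metrics.** PSNR, RMSE and the universal quality index (UQI)
   against a noise-free reference arm (`evaluate()`).
7. **Phantom.** A dynamic elliptical head phantom with normal tissue,
   penumbra, infarct core and artery, each following an analytic
   gamma-variate bolus — so ground truth is exact (`build_phantom()`).

See the methods vignette (`vignettes/ctp-restoration.Rmd`) for the model
details, parameter rationale and limitations.

## Worked example

One call runs the whole study: phantom → projections → shared noise
realization → an `unrestored` and a `restored` arm → maps → metrics versus
the clean reference.

```r
library(ctprestore)
report <- run_pipeline(run_config(seed = 1))
print(report)
```

```
CTP pipeline run (seed 1, grid 64, 20 frames)
arms: clean_reference, unrestored, restored 
restoration: beta = 1.121e+04, lambda = 0.0002905, mean 22.4 sweeps
metrics vs clean reference:
        arm map n_pixels      psnr         rmse          uqi
 unrestored cbv     2264  3.115870  78.04322340  0.015093194
 unrestored cbf     2264 14.466694   0.09701549  0.358692095
 unrestored mtt     1472  6.448359 474.06618022 -0.006464852
 unrestored ttp     2264  2.030301  10.68608764  0.079793451
   restored cbv     2264  4.531001  66.30994273  0.024387338
   restored cbf     2264 17.499280   0.06842452  0.508230738
   restored mtt     1576  6.155290 490.33446938  0.019801384
   restored ttp     2264  5.064991   7.53501653  0.149366978
```

On this seed, restoration gains +1.4 dB (CBV), +3.0 dB (CBF) and +3.0 dB
(TTP); MTT — a ratio of two noisy estimates and the hardest map — happens
to lose 0.3 dB here but gains on average across seeds (note its larger
valid-pixel count: restoration recovers perfused pixels that noise had
pushed below the CBF floor). The region summary confirms the phantom's
ischemic contrast survives the low-dose chain:

```r
print(report$region_reports$restored, digits = 3)
```

```
 tissue_class n_pixels   cbv   cbf mtt   ttp rel_cbv rel_cbf rel_mtt rel_ttp
       normal     1973  58.6 0.151 579  9.14   1.000   1.000   1.000    1.00
     penumbra      211  57.0 0.135 693 16.08   0.972   0.899   1.197    1.76
         core       54  39.4 0.141 547 22.21   0.672   0.936   0.944    2.43
       artery       26 103.3 0.464 268  4.85   1.762   3.077   0.463    0.53
```

Passing `out_dir =` writes `report.json`, multi-page TIFF frame stacks and
pseudocolor PNG maps. The lower-level pieces compose directly, e.g.:

```r
gt   <- build_phantom(phantom_spec(64L))
sino <- forward_project(unclass(gt$frames)[, , 10] * 1.9e-5,
                        pixel_size = 180 / 64)
nz   <- add_noise(sino, noise_params(seed = 7))
res  <- restore(nz$sinogram, nz$variance)
img  <- fbp_reconstruct(res$weighted, recon_params(output_size = 64L))
```

## Command line

A thin CLI wraps the pipeline:

```sh
Rscript inst/scripts/ctprestore run --config cfg.yaml --out run1 --seed 1
Rscript inst/scripts/ctprestore compare run1/report.json run2/report.json
```

The YAML config mirrors `run_config()` arguments (with nested `noise`,
`restoration`, `recon` blocks); omitted fields take package defaults.

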