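# thyroseg

Benchmarking two operator-light segmentation algorithms — Otsu's global
threshold and an adapted Chan–Vese active-contour model — for
determining the *active* thyroid volume from 99mTc-pertechnetate SPECT,
on fully synthetic, seeded image data.

Radioiodine therapy planning needs the tracer-avid gland volume, and
SPECT is the modality that measures it; but SPECT volumes are blurry
(≈7.5 mm system resolution at 4.42 mm voxels) and count-noisy, so the
segmentation algorithm materially changes the volume estimate. This
package builds the whole experiment in code: digital thyroid phantoms,
a simplified SPECT image-formation model, the clinical pre-processing
chain, both segmentation algorithms implemented from scratch, and the
evaluation statistics.

## The two algorithms

**Otsu's method** picks the global threshold *t* on the 256-bin image
histogram minimizing the weighted within-class variance

    σ_w²(t) = ω_b(t) σ_b²(t) + ω_f(t) σ_f²(t),

with class weights ω from the normalized histogram; voxels at or above
*t* are the gland.

**The adapted Chan–Vese model** segments by minimizing the two-phase
piecewise-constant Mumford–Shah energy

    F(c1, c2, C) = λ1 ∫_in |f − c1|² + λ2 ∫_out |f − c2|² + μ·area(C),

solved by 3-D iterative convolution-thresholding (ICTM): alternate
(a) region means c1, c2, (b) Gaussian convolution of the region
indicator (kernel variance 2τ), (c) voxel-wise re-thresholding. The
user sets only the step length τ (default 0.3) and a fidelity scale k,
with λ1(k, τ) = k·√(π/τ); the energy is provably non-increasing across
iterations.

The pipeline around them: parametric butterfly phantom (two ellipsoidal
lobes + isthmus around an air trachea in a water tank, volume-matched
to the nearest voxel), parallel-beam projector with attenuation and a
Gaussian PSF whose back projection is the exact adjoint, Poisson count
noise scaled to 100,000 counts/projection, OSEM (6 subsets × 12
iterations, no post-filter) plus a calibrated fast image-domain
surrogate, background-mean subtraction / hotspot capping / 8-bit
quantization, and evaluation by relative volume, MAE, SD and the Dice
similarity coefficient with a paired t-test between methods.

## Worked example

```r
library(thyroseg)

ph <- place_hotspot(build_phantom(35), 0.10)
print(ph)
#> thyroid phantom: 34.97 ml gland on a 128x128x128 grid, 4.42 mm voxels
#>     AIR   WATER THYROID TRACHEA HOTSPOT
#> 2085536   10923     365     288      40

case <- case_spec(35, 0.10, 2.0, seed = case_seed(1, 35, 0.10, 2))
cfg  <- benchmark_config(noise_scale = 25.48297)  # pre-calibrated scale
r <- run_case(case, cfg, phantom = ph)
r[, c("method", "est_volume_ml", "relative_volume", "dsc", "otsu_threshold", "k")]
#>     method est_volume_ml relative_volume    dsc otsu_threshold    k
#>       otsu         35.14           1.005 0.9901             90   NA
#>  chan_vese         35.14           1.005 0.9901             NA 0.03
```

A 35 ml gland with a 200 % hotspot over 10 % background: both methods
recover the volume within 0.5 % and overlap the truth at DSC 0.990;
the Otsu threshold (90 of 255) and the Chan–Vese fidelity scale
(k = 3·10⁻², from the per-condition default table) are recorded per
case. `run_grid(benchmark_config(seed = 1))` runs the full 48-case
protocol (3 gland volumes × 4 background levels × 4 hotspot contrasts),
prints per-volume and pooled MAE / mean relative volume / SD for both
methods, and reports the paired t-test on the 48 DSC pairs. When
`noise_scale` is not supplied, the surrogate is first calibrated
against a full projector + OSEM reconstruction of the reference case
(about 3 minutes extra).

## Learning more

The methods vignette (`vignettes/thyroid-spect-benchmark.Rmd`) explains
the phantom geometry, the image-formation model and its noise
calibration, every numerical choice (kernel conventions, bisection
tolerances, tie-breaks), and what the synthetic benchmark does and does
not say about clinical images.
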