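# hosvdmri

Rician noise removal for 3D magnitude MR volumes by nonlocal cube
matching and higher-order SVD with adaptive multilinear rank selection.

## Who this is for

Researchers working with 3D magnitude MRI (structural brain imaging,
phantom studies, preprocessing for segmentation/CAD pipelines) who need a
self-contained, reproducible volumetric denoiser with a known noise model
— and a reference implementation of log-penalty singular-value shrinkage
for tensor groups.

## The method in brief

Magnitude MR data follow a Rician distribution: each voxel is
`y = sqrt((x + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma_n^2)`. The
denoiser:

1. applies a **variance-stabilizing transform** (VST) built from
   closed-form Rician moments, making the noise approximately N(0, 1);
2. for each reference cube (edge `p`, stride 3) finds the `m` most
   similar cubes in a 13^3 window and stacks them into a 4th-order tensor
   `Y` (p x p x p x m);
3. estimates the multilinear rank of each group adaptively: for each mode
   `n`, the singular values of the unfolding `Y_(n)` pass through the
   threshold operator `theta(y; lambda, a)` of the parameterized
   logarithmic penalty `lambda * (1/a) * log(1 + a|x|)` — strictly convex
   proximal objective for `a*lambda = 0.5 < 1` — and `r_n` is the number
   of survivors. With `tau = 2*log(p^3*m)` and unit stabilized noise, the
   default threshold `lambda = tau` sits at the Marchenko–Pastur edge of
   the pure-noise mode-4 spectrum;
4. reconstructs each group as the orthogonal projection onto the retained
   factors (`S = Y x1 U1' .. x4 U4'`, `X = S x1 U1 .. x4 U4`) and
   aggregates all cubes by uniform averaging;
5. iterates with **iterative regularization** (`Y_t = X_{t-1} +
   beta*(Y - X_{t-1})`, noise level shrunk by `gamma`), then applies the
   exact-unbiased inverse VST.

Defaults follow the published calibration: `L = 13`, `beta = 0.65`,
`gamma = 0.2`, `T = 2`, and `(p, m)` from the noise level (3/50 at 1%,
3/75 at 3%, 4/75 at 5–7%, 5/90 at 9–15%).

## Worked example

```r
library(hosvdmri)

clean <- make_phantom(seed = 1)                 # 64^3 phantom, max = 255
sigma <- 0.05 * max(clean)                      # 5% Rician noise
noisy <- add_rician_noise(clean, sigma, seed = 100)

res <- denoise_volume(noisy, sigma)             # defaults pick p = 4, m = 75
print(res)
#> Denoised volume: 64 x 64 x 64  (sigma_n = 12.75 )
#>   iter 1: sigma = 1.0000, groups = 9261, mean ranks = 4.00, 4.00, 4.00, 1.60
#>   iter 2: sigma = 0.1912, groups = 9261, mean ranks = 4.00, 4.00, 4.00, 40.53

psnr(clean, noisy, 255)                         # 23.908 dB
psnr(clean, res$volume, 255)                    # 28.887 dB  (+5.0 dB)
ssim_paper(clean, res$volume, 255)              # 0.9917 (vs 0.9362 noisy)
```

The diagnostics show the adaptive rank at work: the first pass keeps on
average 1.6 of 75 mode-4 components (strong truncation at full noise);
the second, running at the `gamma`-shrunk threshold, keeps ~41 and acts
as a gentle detail-restoration pass. A single pass (`T = 1`) reaches
40.87 dB on this phantom.

Command line (same pipeline):

```sh
Rscript inst/cli/hosvdmri simulate --shape 64 --level 5 --seed 0 \
    --out-clean clean.nii.gz --out-noisy noisy.nii.gz
Rscript inst/cli/hosvdmri denoise --input noisy.nii.gz --output den.nii.gz \
    --sigma-percent 5
Rscript inst/cli/hosvdmri evaluate --ref clean.nii.gz --test den.nii.gz
# PSNR          29.2052
# SSIM_global    0.9817
# SSIM_windowed  0.4350
```

(`--sigma-percent` is taken relative to the maximum of the *noisy*
volume — the convention for real data, where no clean reference exists —
so the effective sigma is slightly above the simulated one. The low
windowed SSIM is dominated by the zero background, where the clean
variance is 0; the global variant matches the published formula.)

Real volumes in NIfTI-1 format (`.nii` / `.nii.gz`) are read and written
directly; the affine is passed through untouched.

## Package layout

- `R/tensor.R` — mode-n unfold/fold, n-mode product, full HOSVD
- `R/shrinkage.R` — log-penalty threshold operator, adaptive rank, group denoiser
- `R/blockmatch.R` — reference grid, cube matching, aggregation (reference R path)
- `src/denoise_pass.cpp` — compiled inner pass used by the pipeline
- `R/rician.R` — Rician simulation/moments, forward/inverse VST, sigma update
- `R/pipeline.R` — configuration, calibration table, outer loop
- `R/evaluation.R` — PSNR, global and windowed SSIM, phantom generator
- `R/nifti.R`, `R/cli.R`, `inst/cli/hosvdmri` — NIfTI-1 I/O and CLI
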