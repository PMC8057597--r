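# htvogs

Restoration of single-channel images degraded by blur and Poisson
(photon-counting) noise — the situation in fluorescence microscopy,
low-dose radiography and other photon-limited modalities, where each
recorded pixel is a Poisson draw with mean equal to the blurred clean
intensity and the noise level is set by the peak photon count
MAX<sub>f</sub>.

The estimate minimises a hybrid variational model,

```
min_f  λ·D_KL(Hf ‖ g) + φ_O(∇₁f) + φ_O(∇₂f) + η·‖∇²f‖ₚᵖ ,   0 < p < 1,
```

where `D_KL` is the generalised Kullback–Leibler divergence (the Poisson
negative log-likelihood up to constants), `φ_O` is the
overlapping-group-sparsity functional — the sum of Euclidean norms of all
K×K windows of each first-difference channel — and the last term is a
nonconvex entrywise ℓp penalty on all four second-difference channels. The
group-sparse TV term removes noise without the staircase artifacts of plain
TV; the near-ℓ0 curvature term prevents over-smoothing at edges.

The objective is solved by a multi-block ADMM whose subproblems are: a
closed-form per-pixel Poisson data update; a majorization–minimization
solver for the overlapping-group proximal problem; iteratively reweighted
least squares for the ℓp proximal problem; and an exact FFT-diagonalised
image update under periodic boundary conditions.

The package also ships the forward degradation model (peak scaling,
periodic blur, seeded Poisson sampling), named blur kernels (Gaussian,
linear motion, text-file kernels), synthetic phantoms, the PSNR and
global-statistics SSIM metrics used to evaluate such restorations, and a
command-line front end.

## Worked example

Degrade a synthetic piecewise-constant phantom with a 9×9 Gaussian PSF
(σ = 1) at peak 100 photons, then restore it with the published deblurring
presets:

```r
library(htvogs)

f      <- make_phantom(64, "disks", seed = 3)
kernel <- make_gaussian_kernel(9, 1)
g      <- degrade(f, degradation_spec(max_f = 100, kernel, seed = 3))
clean  <- attr(g, "clean")           # the scaled clean image, for scoring

quality_report(clean, unclass(g), max_f = 100)
#> PSNR 22.64 dB, SSIM 0.9598 (peak 100)

params <- default_params("deblur", max_f = 100, "gaussian")
params
#> solver_params:
#>   lam = 300, eta = 2, delta = (0.01, 0.1, 0.01)
#>   p = 0.1, K = 3, n_in = 5, n_irls = 5
#>   n_out = 50, eps_tol = 0.001, max_f = 100

res <- restore(unclass(g), kernel, params, truth = clean)
res
#> htvogs restoration: 64 x 64 image, 38 outer iterations (converged)
#>   final relative change: 9.868e-04
#>   final PSNR 25.68 dB, SSIM 0.9800
```

The restoration recovers about 3 dB of PSNR over the degraded input (22.64
→ 25.68 dB) and raises SSIM from 0.960 to 0.980: the Poisson noise is
suppressed and the Gaussian blur largely inverted while the disk edges stay
sharp. `res$f` holds the restored image (unclipped floating point);
`res$history` logs per-iteration relative change, objective and — because
`truth` was supplied — PSNR/SSIM.

For pure denoising use `identity_kernel()` and
`default_params("denoise", max_f)`; the second-order weight `eta` has no
published value for denoising and should be tuned to the noise level
(start near 1).

### Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "htvogs.R", package = "htvogs"))')
Rscript $CLI phantom  --n 64 --seed 3 --output-dir out
Rscript $CLI degrade  --input out/phantom_disks.png --kernel gaussian \
                      --kernel-size 9 --sigma 1 --max-f 100 --seed 3 --output-dir out
Rscript $CLI restore  --input out/degraded.png --kernel gaussian \
                      --kernel-size 9 --sigma 1 --max-f 100 \
                      --truth out/phantom_disks.png --output-dir out
Rscript $CLI evaluate --truth out/phantom_disks.png --estimate out/restored.png --max-f 100
```

Every subcommand writes a resolved-config JSON snapshot next to its outputs
so a run can be reproduced exactly.

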