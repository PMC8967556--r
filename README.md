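# tvsense

Total-variation regularized SENSE reconstruction for undersampled
multi-coil (parallel) MRI, with synthetic phantom acquisitions and
reference image-quality metrics.

## The problem

Parallel MRI shortens scans by sampling only part of k-space with K
receiver coils; each coil j measures `f_j = M F S_j u`, where `u` is the
image, `S_j` the coil's sensitivity map, `F` the 2-D Fourier transform and
`M` the binary sampling mask. The undersampled inversion is ill-posed, so
the package reconstructs by solving the TV-regularized SENSE model

    min_u  ||u||_TV + lambda * sum_j || M F S_j u - f_j ||_2^2

whose total-variation prior favors the piecewise-constant, sharp-edged
structure of anatomical cross-sections. Two alternating-direction solvers
are provided:

* **Coil-splitting ADMM** (default): auxiliary variables `X_j = S_j u`
  make the per-coil data subproblem exactly solvable by an elementwise
  k-space division (`F^H (M^T M + (alpha/lambda) I) F` is
  Fourier-diagonal for a binary mask), while the image subproblem is a
  weighted TV denoise solved by a warm-started primal-dual hybrid
  gradient (PDHG) inner loop.
* **Penalty splitting**: a quadratic penalty relaxes `v = u`, alternating
  a TV denoise with a linearized (majorized) data step, with a
  continuation schedule on the penalty weight.

The package is aimed at method developers and students who need a small,
fully testable reconstruction chain with known ground truth: every
operator has an exact adjoint, solver optimality is pinned against an
independent dense convex solver in the test suite, and all inputs can be
simulated (`make_phantom()`, `make_sensitivities()`, `make_mask()`,
`simulate_acquisition()`).

## A worked example

```r
library(tvsense)

acq <- demo_problem()   # 64 x 64 phantom, 8 coils, 4x undersampling, sigma 0.01
fit <- tvsense(acq$problem$data, acq$problem$sens, acq$problem$mask,
               lambda = 100, alpha = 1, solver = "admm", truth = acq$truth)
summary(fit)
```

prints (numbers from this exact run):

```
Call: tvsense(data = acq$problem$data, sens = acq$problem$sens, mask = acq$problem$mask,
    lambda = 100, alpha = 1, solver = "admm", truth = acq$truth)
Solver: admm (100 iterations, iteration limit)
Final objective: 3.136560e+02   primal residual: 4.564e-01
Against ground truth:   PSNR 36.08 dB   SSIM 0.9825   MSE 0.000246
Zero-filled baseline:   PSNR 23.58 dB   SSIM 0.6880   MSE 0.00439
```

The reconstruction gains about 12 dB PSNR and lifts SSIM from 0.69 to 0.98
over the unregularized zero-filled baseline (`zero_filled_recon()`), i.e.
the TV-SENSE model removes most aliasing and noise while keeping the
lesion edges. `plot(fit)` shows truth, reconstruction and error maps;
`iteration_history(fit)` exports the objective/residual trace.

A command-line interface wraps the same pipeline:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/tvsense.R", package = "tvsense"))')
Rscript $CLI simulate    --out sim/ --seed 7
Rscript $CLI reconstruct --in sim/acquisition.rds --solver admm --out rec/
Rscript $CLI evaluate    --recon rec/reconstruction.rds --truth sim/acquisition.rds
Rscript $CLI demo        --seed 20220323
```

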