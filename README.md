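# capria

Simulation and reconstruction toolkit for **4D combined angiography and
perfusion imaging with arterial spin labeling (CAPRIA)** — an MRI technique
that follows magnetically labeled arterial blood with a continuous 3D
golden-means radial ("koosh-ball") readout, so that a single non-contrast
scan yields both time-resolved angiograms (short temporal windows, full
matrix) and tissue perfusion images (long windows, low matrix from central
k-space), reconstructed retrospectively from the same raw label/control
k-space.

The package is aimed at MR physicists and methods researchers who want to
study this class of acquisition numerically: how flip-angle schedules trade
angiographic against perfusion SNR, how undersampled radial data behave under
conventional and low-rank-regularized reconstruction, and how split-scan
repeatability quantifies the result.

## What it implements

* **Trajectory** — 3D multi-dimensional golden-means spoke schedules
  ($\theta_m = \arccos\{m\phi_1\}$, $\varphi_m = 2\pi\{m\phi_2\}$ with
  $\phi_2^3 + \phi_2 = 1$, $\phi_1 = \phi_2^2$, every other spoke reversed for
  even partial-Fourier coverage), interleaved label/control preparations,
  retrospective frame binning, and radial undersampling accounting
  $R = (\pi\,\mathrm{matrix}^2/2)/n_\mathrm{spokes}$.
* **Kinetics** — the PCASL angiographic difference signal
  $S_{angio,i} = 2M_{0b}\alpha_{inv}v\sin(\alpha_i)e^{-\delta_t/T_{1b}}R_i$
  and the Buxton single-compartment perfusion signal
  $S_{perf,i} = \Delta M_B(t_i)R_i\sin\alpha_i$, under constant or quadratic
  variable flip-angle (VFA) schedules with cumulative RF attenuation
  $R_i = \prod_{j<i}\cos\alpha_j$.
* **Flip-angle optimization** — mean-signal metric grids over
  $(\alpha_1, \alpha_N)$, averaged across physiological transit-time ranges,
  combined with weight ½ on angiography; selection of the optimal constant
  flip angle (diagonal argmax) and VFA pair (within 95% of peak, closest to
  the origin).
* **Phantom** — a seeded dynamic digital head phantom (vessel tubes with
  transit delays and blood volumes, perfused tissue ellipsoids, static
  background) with smooth complex coil sensitivities and an exact multi-coil
  non-Cartesian forward simulation along the acquisition trajectory,
  including per-preparation noise streams (so split halves are bit-identical
  to shorter scans) and optional label/control phase drift.
* **Reconstruction** — Kaiser–Bessel gridding NUFFT (Rcpp kernels, exact
  adjoint), coil sensitivity estimation, SVD coil compression, phase-aligned
  complex subtraction, CG-SENSE with L2 gradient regularization, and a
  locally-low-rank solver (POGM, patchwise singular-value thresholding,
  cycle spinning), plus direct low-resolution perfusion reconstruction from
  central k-space.
* **Assessment** — dilated vessel masks, split-scan repeatability (Pearson r
  per frame, Fisher z), and the shortened-scan quadratic correction
  utilities.

## Worked example

Simulate a desk-scale scan (48³ phantom, 8 coils, 16 label/control pairs),
reconstruct angiography and perfusion from each half of the data, and score
split-scan repeatability:

```r
library(capria)

rc <- run_config(matrix = 48L, n_pairs = 16L, n_coils = 8L, n_virtual = 4L,
                 solver = "cg-sense", n_iters = 12L, seed = 11L)
raw <- capria_simulate(rc)
halves <- split_halves(raw)
rec1 <- capria_recon(halves$first, rc)
rec2 <- capria_recon(halves$second, rc)
tbl <- capria_assess(rec1, rec2,
                     brain_mask = phantom_brain_mask(raw$spec, rc$matrix),
                     brain_mask_low = phantom_brain_mask(raw$spec, rc$perf_matrix),
                     voxel_size = raw$config$voxel_size)
print(tbl, n = 6)
#> # A tibble: 15 x 6
#>   image frame   pld mask               r     z
#>   <chr> <int> <dbl> <chr>          <dbl> <dbl>
#> 1 angio     1 0.108 dilated-vessel 0.368 0.386
#> 2 angio     2 0.323 dilated-vessel 0.153 0.154
#> 3 angio     3 0.539 dilated-vessel 0.180 0.182
#> 4 angio     4 0.754 dilated-vessel 0.171 0.173
#> 5 angio     5 0.970 dilated-vessel 0.299 0.309
#> 6 angio     6 1.19  dilated-vessel 0.289 0.297
#> # i 9 more rows
```

Each row is one reconstructed frame: `pld` is its post-labeling delay in
seconds (window-center convention), `r` the Pearson correlation between the
two half-scan reconstructions over the mask, and `z = atanh(r)` its
variance-stabilized value — higher means a more stable, less noise-dominated
image. Perfusion rows (brain mask, 16³ matrix) behave like the low-SNR tissue
signal they measure: under a constant-flip-angle schedule their repeatability
collapses at late delays, which the quadratic VFA schedule (the default,
`alpha1 = 2, alphaN = 9`) largely restores, and the locally-low-rank solver
(`solver = "llr"`) raises further at every delay.

The flip-angle study itself is two lines:

```r
grid <- metric_grid(acquisition_config(), step = 1)
glance(grid)
#> # A tibble: 1 x 5
#>   cfa_opt vfa_alpha1 vfa_alphaN  step weight
#>     <dbl>      <dbl>      <dbl> <dbl>  <dbl>
#> 1       6          2          9     1    0.5
#> the constant-flip-angle optimum is 6 deg; the VFA operating point is (2, 9) deg
autoplot(grid)   # the three metric surfaces with both optima marked
```

A thin CLI over the same functions ships in `inst/cli/capria.R`
(`simulate`, `optimize-fa`, `recon`, `assess`, `sweep-lambda`).

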