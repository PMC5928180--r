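# unmixr

Physically constrained linear unmixing of hyperspectral images in R.

Hyperspectral instruments — imaging mass spectrometers (e.g. ToF-SIMS),
scanning transmission electron and scanning tunneling microscopes in
spectroscopic modes, X-ray diffraction microscopes — record a full spectrum
at every pixel. In many materials the spectrum at pixel *x* is well
approximated by a linear mixture

> S(x, R) = Σᵢ aᵢ(x) wᵢ(R) + noise,

where the *wᵢ* are a small number of constituent (*endmember*) spectra and
the *aᵢ(x)* are their spatial *abundance maps*. In matrix form, the
channels-by-pixels data matrix factorizes as **X ≈ U V** with endmembers in
the columns of **U** (m × k) and abundances in the rows of **V** (k × n).
Recovering **U** and **V** under physical constraints — non-negativity,
sparsity, spatial smoothness, per-pixel sum-to-one — turns a raw spectral
cube into interpretable chemical or structural phase maps.

unmixr provides:

- **Data model and I/O** — `hyper_cube()` / `data_matrix()` containers with
  a single raster-order contract, lossless cube↔matrix reshaping
  (`cube_to_matrix()`, `matrix_to_cube()`, `abundances_to_maps()`), and
  readers/writers for an RDS array container, per-channel TIFF stacks, and
  delimited text (`read_cube()`, `write_cube()`, `write_results()`).
- **Solvers** — `nmf_unmix()` (multiplicative updates for Frobenius and
  generalized Kullback–Leibler losses, plus a HALS solver), with L1
  sparsity (`lambda1`), graph-Laplacian spatial smoothness (`lambda2`), and
  sum-to-one abundance constraints; `pca_unmix()` and `svd_truncated()` as
  unconstrained baselines. Objective traces are recorded and monotone for
  the multiplicative updates.
- **Spatial graphs** — `build_grid_adjacency()` (4/8-neighbor) and
  `build_feature_similarity()` (Gaussian-kernel, dense or chunked knn that
  scales to 16,384-pixel images), with `edge_roughness()` to quantify map
  smoothness.
- **Rank selection** — `scan_k()` combining an elbow criterion on
  reconstruction error, a consensus dispersion coefficient over random
  restarts, and component-similarity saturation.
- **Preprocessing** — mean centering, normalization, log transform, and a
  sliding-window FFT (`sliding_fft()`) that turns lattice images into
  feature stacks for structural phase mapping.
- **Synthetic generator** — `make_ground_truth()` / `make_cube()` produce
  seeded cubes with peak-shaped endmembers, smooth/sparse abundance fields,
  and Gaussian or Poisson noise, plus `recovery_report()` for
  permutation-aware comparison against the truth.
- **Command line** — `unmix_cli()` (also installed as
  `inst/scripts/unmixr`) with subcommands `unmix`, `pca`, `scan-k`,
  `synth`, and `slidefft`, JSON run reports, and exit codes 0/1/2 for
  success/runtime failure/usage error.

Tidyverse-native where it fits: results are plain lists with `tidy()`,
`glance()`, and `autoplot()` methods, and tabular outputs are tibbles.

## Worked example

Generate a synthetic 32 × 32 × 200 cube with three endmembers and 30 dB
Gaussian noise, unmix it on the simplex, and compare against the ground
truth:

```r
library(unmixr)

truth <- make_ground_truth(k = 3, seed = 0)      # 32 x 32 grid, 200 channels
cube  <- make_cube(truth)                        # adds 30 dB Gaussian noise
dm    <- cube_to_matrix(cube)
dm
#> <data_matrix> 200 channels x 1024 pixels (grid 32 x 32, row-major)

fit <- nmf_unmix(dm, unmixing_config(k = 3, seed = 0, sum_to_one = TRUE))
fit
#> <factor_model> nmf: 200 channels x 1024 pixels, k = 3
#>   objective 25.0503 after 500 iterations (converged: FALSE)

glance(fit)
#> # A tibble: 1 × 6
#>   method     k objective iterations converged n_warnings
#>   <chr>  <int>     <dbl>      <int> <lgl>          <int>
#> 1 nmf        3      25.1        500 FALSE              0

recovery_report(fit, truth)[c("cosines", "abundance_rmse")]
#> $cosines
#> [1] 0.9987837 0.9999861 0.9999549
#>
#> $abundance_rmse
#> [1] 0.009038333
```

All three endmembers are recovered with cosine similarity above 0.998 and
the abundance maps with RMSE below 0.01. (`converged: FALSE` only means
the relative-change tolerance was not reached within the default 500
iterations; the trace has long since flattened.) Rank selection on the
same cube:

```r
scan <- scan_k(dm, 2:5, config = unmixing_config(k = 2, max_iter = 400),
               n_restarts = 3, seed = 1)
scan
#> # A tibble: 4 × 4
#>       k reconstruction_error dispersion max_cosine
#> * <int>                <dbl>      <dbl>      <dbl>
#> 1     2               0.257       1          0.174
#> 2     3               0.0310      0.979      0.383
#> 3     4               0.0310      0.652      0.998
#> 4     5               0.0309      0.699      0.962
#> chosen k -- elbow: 3  dispersion: 2  saturation: 4
```

The elbow lands on the true rank 3, and at k = 4 two fitted endmembers
become near-duplicates (cosine 0.998), the saturation signature of an
overfit rank. The same pipeline is available from the shell:

```sh
Rscript inst/scripts/unmixr synth --preset default --seed 0 --out cube.rds
Rscript inst/scripts/unmixr unmix cube.rds --k 3 --sum-to-one --seed 0 --out run/
```

which writes `endmembers.csv`, per-endmember abundance TIFFs/PNGs, a
residual map, and a JSON run report into `run/`.

Methods details — the update rules, the design of the sum-to-one
projection, the choice of spatial penalty, rank-selection diagnostics, and
the generator's realism limits — are in the vignette source
`vignettes/unmixing-methods.Rmd`.

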