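# evr

3D backbone reconstruction of bacterial chromosomes from 3C/Hi-C
interaction-frequency matrices, by iterative **error-vector resultant**
optimization — plus the full synthetic benchmark harness (toroidal-spiral
standard structures, uniform matrix noise, scale-optimal superposition
RMSD, noise sweeps, marker-distance correlation) needed to validate such
reconstructions without any external download.

## Who this is for

Microbial 3D-genomics groups with a normalized Hi-C contact matrix of a
bacterial (usually circular) chromosome who want a fast, reproducible
backbone model — one 3D coordinate per genomic bin — and a way to quantify
how trustworthy that model is.

## The method

Given a symmetric, non-negative interaction-frequency matrix `F`, expected
spatial distances follow a power law

```
D_ij = (1 / F_ij)^alpha          (alpha = 0.5; D undefined where F_ij = 0)
```

Starting from a random conformation, every informative pair contributes an
error vector to bin j,

```
e_ij = (P_i − P_j)/‖P_i − P_j‖ · (‖P_i − P_j‖ − D_ij),
```

with genomically adjacent bins (including the first/last pair on a
circular chromosome) clamped to a chain-integrity band `[d_min, d_max]`.
Each bin's vectors are averaged into a resultant `E_j = (1/N) Σ_i e_ij`,
all bins move synchronously by their resultants, and the iteration stops
when the objective `F = Σ_j ‖E_j‖` changes by less than `1e-5` between
steps. Reconstructions are scored against references with scale-optimal
least-squares superposition (rotation, translation, global scale, optional
reflection — a contact matrix cannot determine chirality).

## Worked example

Simulate a 100-bin toroidal-spiral benchmark, reconstruct from its exact
power-law contact matrix, and score the result against the known truth:

```r
library(evr)

bench <- make_benchmark(spiral_spec(n_bins = 100))   # matrix + ground truth
fit   <- evr_reconstruct(bench$matrix, evr_config(seed = 1))
fit
#> <evr_fit> 100 bins, circular topology
#>   iterations: 377 (converged)
#>   final F: 0.0003411136, final dF: 9.750489e-06

glance(fit)
#> # A tibble: 1 × 8
#>   n_bins topology n_iter converged  f_final delta_f_final d_min d_max
#>    <int> <chr>     <int> <lgl>        <dbl>         <dbl> <dbl> <dbl>
#> 1    100 circular    377 TRUE      0.000341    0.00000975 0.406  6.49

aln <- superpose(fit, bench$truth)   # scale + reflection allowed
glance(aln)
#> # A tibble: 1 × 3
#>       rmsd scale reflected
#>      <dbl> <dbl> <lgl>
#> 1 0.000142 1.000 TRUE
```

The aligned RMSD of 0.000142 is 1.4e-05 of the structure's radius of
gyration (10.4): the noise-free benchmark is recovered essentially
exactly, up to the mirror ambiguity (`reflected = TRUE`) that contact data
cannot resolve. `d_min`/`d_max` in the glance are the adjacency band
resolved from the data scale. Per-bin coordinates come from `tidy(fit)`:

```r
tidy(fit)
#> # A tibble: 100 × 4
#>     bin      x     y     z
#>   <int>  <dbl> <dbl> <dbl>
#> 1     1 -10.5  -2.41 -7.68
#> 2     2  -9.90 -3.95 -7.34
#> 3     3  -8.78 -4.97 -6.63
#> # ℹ 97 more rows
```

`autoplot(fit)` draws the convergence trajectory, `plot_structure(fit)`
the backbone projections, and `write_xyz()` / `write_pdb_like()` export
structures for molecular viewers. Robustness to matrix noise is measured
with `noise_sweep()`, and agreement with fluorescence-microscopy distances
with `read_marker_set()` + `distance_correlation()`.

Real matrices enter through `read_if_matrix("matrix.tsv")` (the dense
text dialect of public bacterial Hi-C deposits). A command-line front end
covering the same workflows (`reconstruct`, `simulate`, `compare`,
`benchmark`) is installed at
`system.file("scripts", "evr", package = "evr")`.

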