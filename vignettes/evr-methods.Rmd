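---
title: "Error-vector resultant reconstruction of bacterial chromosome backbones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-vector resultant reconstruction of bacterial chromosome backbones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evr)
```

## The problem

Chromosome conformation capture assays (3C/Hi-C) measure, genome-wide, how
often pairs of genomic segments ("bins") are cross-linked in the cell. After
normalization, the data arrive as a symmetric, non-negative
interaction-frequency (IF) matrix: element $F_{ij}$ is the contact propensity
of bins $i$ and $j$. Because spatially close loci cross-link more often,
the IF matrix carries distance information, and a 3D backbone model of the
chromosome — one coordinate per bin — can be inferred from it. Most
prokaryotic chromosomes are circular, so the model must honour a closed
chain: the first and last bins are genomic neighbours.

`evr` reconstructs such backbones by iterative error-vector resultant
optimization, and ships the complete synthetic evaluation harness needed to
validate the method without any external data: standard-structure
generation, matrix simulation, noise injection, scale-optimal superposition
scoring, noise sweeps, and marker-distance correlation.

## The model

**Frequencies to distances.** For every pair with $F_{ij} \neq 0$ the
expected spatial distance is a power law,
$D_{ij} = (1/F_{ij})^{\alpha}$, with $\alpha = 0.5$ by default — the
exponent commonly used for bacterial Hi-C. Pairs with $F_{ij} = 0$ carry no
distance information; they are kept as an explicit *undefined* mask rather
than a large sentinel value, so that they can be excluded exactly from all
error-vector sums (a sentinel would leak into the optimization).

**Error vectors.** Given current positions $P_i$, each informative pair
contributes to bin $j$ the displacement

$$ e_{ij} \;=\; \frac{P_i - P_j}{\lVert P_i - P_j \rVert}\,
   \bigl(\lVert P_i - P_j \rVert - D_{ij}\bigr), $$

which pulls $j$ toward $i$ when the pair is too far apart and pushes it
away when too close. Genomically adjacent pairs ($|i-j| = 1$, plus the
$(1, N)$ pair for circular topology) instead obey a chain-integrity band
$[D_{\min}, D_{\max}]$: the target distance is clamped to the nearest band
edge when the current distance falls outside the band, equals $D_{ij}$
inside it, and, when an adjacent pair has $F_{ij} = 0$, the band interior
is a free region with zero error. Boundary ties go to the in-band branch;
all branches agree in value at the boundary, so this only fixes
determinism.

**Resultants and the objective.** Each bin's moves are averaged into a
resultant $E_j = w \sum_{i \neq j} e_{ij}$ with the uniform weight
$w = 1/N$, and the scalar objective is the total resultant length
$F = \sum_j \lVert E_j \rVert$. One iteration moves every bin by its
resultant, *synchronously*: all $E_j$ are evaluated on the previous
conformation before any move. The synchronous (Jacobi-style) update is what
makes the iteration trivially parallelizable per bin and keeps runs
order-independent and reproducible.

**Stopping.** Iteration stops when $\Delta F = |F_t - F_{t-1}|$ falls
below `tol` (default $10^{-5}$) or after `max_iter` (default 10000)
iterations. The full $F$ history is retained on the fitted object, so the
stop rule and convergence diagnostics are directly inspectable.

## Tunable parameters

| parameter  | default              | units             | role |
|------------|----------------------|-------------------|------|
| `alpha`    | 0.5                  | —                 | distance power law exponent |
| `d_min`    | $0.25\,m$            | expected-distance | adjacent-bin lower clamp |
| `d_max`    | $4\,m$               | expected-distance | adjacent-bin upper clamp |
| `weight`   | $1/N$                | —                 | resultant step size |
| `tol`      | $10^{-5}$            | objective units   | stop threshold on $\Delta F$ |
| `max_iter` | 10000                | iterations        | hard cap |
| `init_box` | $2\,m\,N^{1/3}$      | expected-distance | initialization cube side |

Here $m$ is the median defined adjacent-pair expected distance. The band
and the initialization cube are tied to this data scale so that the chain
can neither collapse nor tear regardless of how the IF matrix was
normalized, and so the initial random cloud has roughly the density of the
final structure; both resolved values are echoed on the fitted object and
in the CLI config echo, making every run reproducible from its config
alone. `weight` is exposed for experimentation but the uniform $1/N$ is
the reference behaviour — there is no adaptive step size or annealing.

Coordinates are reported in expected-distance units. A contact matrix
carries no absolute length scale, so only shape is meaningful;
`rescale = TRUE` normalizes the mean adjacent distance to 1 for viewers.

## Numerical choices and degenerate inputs

* **Asymmetric input matrices** (rounding asymmetry occurs in public matrix
  dumps) are averaged with their transpose, with a warning carrying the
  maximum asymmetry magnitude. Negative or NaN entries are errors.
* **Zero rows** (bins with no interactions) are permitted: such bins are
  positioned by the adjacency band alone, and a warning lists them. A
  linear-topology end bin with no information beyond its single neighbour
  is warned about too.
* **Coincident bins** have no defined error-vector direction. The pair is
  assigned a unit direction hashed deterministically from
  (seed, iteration, i, j) — reproducible, and never touching the session
  RNG — with magnitude equal to the full target distance, so coincident
  bins separate instead of sticking.
* **Self-pairs and undefined pairs** contribute nothing to the resultant:
  the sum runs over $i \neq j$ with a defined (or adjacency-clamped)
  target.
* The randomized initialization draws from a cube using an isolated seeded
  generator (`withr::with_seed`), so identical seeds give bitwise-identical
  trajectories and the caller's RNG state is never disturbed.

## The synthetic benchmark

`toroidal_spiral()` samples a closed curve winding `n_winds` times around
a torus (defaults $R = 10$, $r = 3$, 8 winds — an arbitrary but recorded
choice giving distinct large- and small-scale geometry) at equal parameter
increments. `structure_to_if()` converts it to an exact power-law IF
matrix with no distance cutoff, and `add_noise()` perturbs every
off-diagonal pair with an independent uniform draw from
$[-0.5\,P\,\mathrm{IF}_{\max},\, +0.5\,P\,\mathrm{IF}_{\max}]$, mirrored
across the diagonal to preserve symmetry. Perturbed frequencies below zero
are clamped to 0 — a negative frequency is physically meaningless and the
power law cannot map it — which routes such pairs into the undefined-
distance branch the optimizer already handles. The diagonal is left
untouched (it is unused downstream).

What this emulates is the *geometric* difficulty of the problem: an exact
distance-derived signal corrupted by bounded, mean-zero noise. What it
does **not** emulate are the count statistics of real Hi-C (Poisson
sampling, coverage and mappability biases, distance-decay interacting with
genomic features, normalization artifacts). Passing the benchmark
therefore demonstrates that the optimizer inverts the stated generative
model accurately and degrades gracefully with noise; it does not by itself
certify accuracy on real matrices, which is why the marker-correlation
protocol below exists.

## Scoring

A reconstruction is compared to a reference with a scale-optimal
least-squares superposition (`superpose()`): closed-form rotation from the
SVD of the cross-covariance, analytic optimal scale, and an explicit
evaluation of the mirror-image branch. Reflection must be allowed when
scoring reconstructions, because an IF matrix is invariant under
reflection and cannot determine chirality. Bin correspondence is by index
— reconstruction preserves bin identity, so no circular-shift search is
performed. RMSD uses per-bin mean normalization,
$\sqrt{\tfrac1N \sum_j \lVert \hat p_j - p_j \rVert^2}$, and is reported
in the units of the *target* conformation.

`noise_sweep()` repeats simulate → perturb → reconstruct → superpose per
noise level and replicate; replicate $k$ uses seed
$\texttt{base\_seed} + k - 1$ for both the noise draws and the
initialization, shared across levels (common random numbers), so tables
are exactly reproducible.

For validation against microscopy, `map_loci_to_bins()` places 1-based
genomic marker positions into bins (`floor((pos - 1)/bin_size)`), and
`distance_correlation()` computes the Pearson correlation (two-sided
t-test p-value, via `stats::cor.test`) between structure-based and
measured inter-locus distances. Correlation, not absolute agreement, is
the metric, because the model has arbitrary global scale. Marker pairs
spanning the origin of a circular genome are mapped by position only —
fluorescence distances are spatial, not genomic, so no arc-aware
adjustment applies.

## Convergence behaviour and known limitations

On noise-free matrices simulated from 100–500-bin spirals the run
typically converges in 350–500 iterations, with final objective around
$3 \times 10^{-4}$ and recovery RMSD below $10^{-4}$ of the structure
size.

The stop rule compares successive objective values only. On a minority of
initializations the trajectory traverses a slow saddle — the structure is
still partially folded, but $F$ momentarily changes by less than `tol`
per iteration — and the run stops early with a final $F$ two to three
orders of magnitude above the usual converged value. These are premature
stops, not true local optima: tightening `tol` (e.g. $10^{-9}$) lets the
same seed escape the plateau and reach near-exact recovery. The practical
diagnostic is `glance(fit)$f_final`: a value far above comparable runs
flags a plateau stop; re-run with a tighter `tol` or a different seed.

Other limitations, deliberate in scope:

* one consensus backbone per matrix — no ensemble or population modelling,
  and no polymer physics below bin resolution;
* `alpha` is a single global exponent, not fitted from data;
* input matrices are assumed normalized upstream (no ICE/KR here);
* binary Hi-C container formats (cooler/hic) are not read — dense text
  matrices only;
* the PDB-like writer targets tolerant viewer parsers (CA pseudo-atoms,
  CONECT chain records, fixed-width columns, auto-rescale into the 8.3
  coordinate field with the factor recorded in a REMARK); compatibility
  with any particular third-party tool's dialect is not promised.

## Problem sizes used by the test suite

The shipped tests and the acceptance script run entirely on synthetic
benchmarks chosen to exercise every code path at desk scale: unit oracles
at $N \le 50$, end-to-end recovery at $N = 100$ over 5 seeds, and the
noise sweep at $N = 100$ with 20 replicates per level at
$P \in \{0, 0.25, 0.5\}$. The field-vs-oracle equivalence is checked on
100 random instances mixing circular and linear topologies and sparse
(zero-frequency) masks.

## Reproducing the external validation

Correlating a real *E. coli* reconstruction against published fluorescence
distances requires the public 5-kb IF matrix (GEO accession GSE107301) and
the corresponding marker table; neither ships with the package. The
recipe: `read_if_matrix()` on the matrix dump, `evr_reconstruct()` with
defaults, `read_marker_set()` on the marker/distance tables, then
`distance_correlation(fit, markers, bin_size = 5000)`. The package makes
no claim about the resulting coefficient; the synthetic analogue of this
protocol is part of the test suite.
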