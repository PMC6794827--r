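#' Specification of a toroidal-spiral standard structure
#'
#' Toroidal spirals (closed curves winding `n_winds` times around a torus)
#' are the standard benchmark structures for circular-chromosome
#' reconstruction: they are closed, non-self-intersecting and have distinct
#' large- and small-scale geometry. Defaults (`R = 10`, `r = 3`,
#' `n_winds = 8`) give a visually distinct major/minor structure.
#'
#' @param n_bins Number of bins to cut the curve into (>= 3).
#' @param major_radius Torus major radius `R`.
#' @param minor_radius Torus minor radius `r`, with `r < R`.
#' @param n_winds Number of minor-circle turns per major revolution.
#' @return A list of class `"spiral_spec"`.
#' @export
spiral_spec <- function(n_bins = 100L, major_radius = 10, minor_radius = 3,
                        n_winds = 8L) {
  stopifnot(is.numeric(n_bins), length(n_bins) == 1, n_bins >= 3,
            is.numeric(major_radius), major_radius > 0,
            is.numeric(minor_radius), minor_radius > 0,
            is.numeric(n_winds), n_winds >= 0)
  if (minor_radius >= major_radius) {
    stop("`minor_radius` must be smaller than `major_radius` ",
         "(non-self-intersecting torus)", call. = FALSE)
  }
  structure(list(n_bins = as.integer(n_bins), major_radius = major_radius,
                 minor_radius = minor_radius, n_winds = as.integer(n_winds)),
            class = "spiral_spec")
}

#' Sample a toroidal spiral into a circular conformation
#'
#' Evaluates the closed curve
#' `x = (R + r cos(k t)) cos t`, `y = (R + r cos(k t)) sin t`,
#' `z = r sin(k t)` (with `k = n_winds`) at equal parameter increments
#' `t = 2 pi m / n_bins`, `m = 0, ..., n_bins - 1`. The curve closes on
#' itself, so the returned conformation has circular topology.
#'
#' @param spec A [spiral_spec()].
#' @return A [conformation()] with `spec$n_bins` bins.
#' @examples
#' truth <- toroidal_spiral(spiral_spec(n_bins = 100))
#' @export
toroidal_spiral <- function(spec = spiral_spec()) {
  stopifnot(inherits(spec, "spiral_spec"))
  t <- 2 * pi * (seq_len(spec$n_bins) - 1) / spec$n_bins
  k <- spec$n_winds
  rad <- spec$major_radius + spec$minor_radius * cos(k * t)
  conformation(cbind(rad * cos(t), rad * sin(t),
                     spec$minor_radius * sin(k * t)),
               topology = "circular")
}

#' Specification of uniform matrix noise
#'
#' Noise is injected into an interaction-frequency matrix by adding, to
#' each bin pair, an independent uniform draw from
#' `[-0.5 * P * IF_max, +0.5 * P * IF_max]`, where `P` is the noise level
#' and `IF_max` the largest matrix entry.
#'
#' @param level Noise level `P` in `[0, 1]`.
#' @param seed Integer seed for the draws.
#' @return A list of class `"noise_spec"`.
#' @export
noise_spec <- function(level = 0, seed = 1L) {
  if (!is.numeric(level) || length(level) != 1 || level < 0 || level > 1) {
    stop("noise `level` must be a single number in [0, 1]", call. = FALSE)
  }
  structure(list(level = level, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Add uniform noise to an interaction-frequency matrix
#'
#' Each off-diagonal upper-triangle entry receives an independent uniform
#' perturbation in `[-0.5 * P * IF_max, +0.5 * P * IF_max]`; the
#' perturbation is mirrored to the lower triangle so symmetry is preserved,
#' and entries pushed below zero are clamped to 0 (they become undefined
#' distances downstream, the same branch as a structural zero). The
#' diagonal is untouched. Deterministic under the given seed; the session
#' RNG state is not disturbed.
#'
#' @param m A [contact_matrix()].
#' @param noise A [noise_spec()].
#' @return A [contact_matrix()] of the same size.
#' @export
add_noise <- function(m, noise = noise_spec()) {
  stopifnot(inherits(m, "contact_matrix"), inherits(noise, "noise_spec"))
  if (noise$level == 0) return(m)
  n <- n_bins(m)
  vals <- unclass(m)
  attributes(vals) <- list(dim = dim(vals))
  if_max <- max(vals)
  half <- 0.5 * noise$level * if_max
  up <- upper.tri(vals)
  eps <- withr::with_seed(noise$seed,
                          stats::runif(sum(up), min = -half, max = half))
  vals[up] <- vals[up] + eps
  vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
  vals[vals < 0] <- 0
  suppressWarnings(
    contact_matrix(vals, bin_size = attr(m, "bin_size"),
                   labels = attr(m, "labels"))
  )
}

#' Build a benchmark: noisy matrix plus ground-truth structure
#'
#' Composes [toroidal_spiral()] -> [structure_to_if()] -> [add_noise()]
#' and returns both the (noisy) interaction matrix and the generating
#' conformation, so reconstructions can be scored against the truth.
#'
#' @param spec A [spiral_spec()].
#' @param alpha Power exponent of the distance model (default 0.5).
#' @param noise A [noise_spec()]; the default injects no noise.
#' @return A list with elements `matrix` (a [contact_matrix()]) and
#'   `truth` (a [conformation()]).
#' @examples
#' bench <- make_benchmark(spiral_spec(n_bins = 50))
#' @export
make_benchmark <- function(spec = spiral_spec(), alpha = 0.5,
                           noise = noise_spec()) {
  truth <- toroidal_spiral(spec)
  m <- structure_to_if(truth, alpha = alpha)
  list(matrix = add_noise(m, noise), truth = truth)
}
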