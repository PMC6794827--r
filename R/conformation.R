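#' Construct a conformation (ordered 3D bin coordinates)
#'
#' A conformation is the package's structure container: a tibble with one
#' row per genomic bin, columns `bin` (1-based index in genomic order),
#' `x`, `y`, `z`, and a `topology` attribute saying whether the chromosome
#' is closed (`"circular"`, first and last bins adjacent) or open
#' (`"linear"`).
#'
#' @param coords Numeric `N x 3` matrix, or a data frame with columns
#'   `x`, `y`, `z`.
#' @param topology `"circular"` (default; bacterial chromosomes) or
#'   `"linear"`.
#'
#' @return A tibble of class `"conformation"` with attribute `topology`.
#' @examples
#' conformation(matrix(rnorm(30), 10, 3))
#' @export
conformation <- function(coords, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (is.data.frame(coords)) {
    stopifnot(all(c("x", "y", "z") %in% names(coords)))
    coords <- as.matrix(coords[, c("x", "y", "z")])
  }
  if (!is.matrix(coords) || ncol(coords) != 3) {
    stop("`coords` must be an N x 3 matrix or a data frame with x, y, z",
         call. = FALSE)
  }
  if (nrow(coords) < 3) stop("a conformation needs at least 3 bins", call. = FALSE)
  if (any(!is.finite(coords))) {
    stop("conformation contains non-finite coordinates", call. = FALSE)
  }
  out <- tibble::tibble(bin = seq_len(nrow(coords)),
                        x = coords[, 1], y = coords[, 2], z = coords[, 3])
  class(out) <- c("conformation", class(out))
  attr(out, "topology") <- topology
  out
}

#' Extract the coordinate matrix of a conformation
#'
#' @param conf A [conformation()] (or any data frame with `x`, `y`, `z`).
#' @return Numeric `N x 3` matrix.
#' @export
coords <- function(conf) {
  if (is.matrix(conf) && ncol(conf) == 3) return(conf)
  stopifnot(is.data.frame(conf), all(c("x", "y", "z") %in% names(conf)))
  cbind(x = conf$x, y = conf$y, z = conf$z)
}

#' Topology of a conformation
#'
#' @param conf A [conformation()].
#' @return `"circular"` or `"linear"`.
#' @export
topology <- function(conf) {
  top <- attr(conf, "topology")
  if (is.null(top)) "circular" else top
}

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation> ", nrow(x), " bins, ", topology(x), " topology\n", sep = "")
  NextMethod()
}

#' Random initial conformation
#'
#' Draws `n_bins` points uniformly inside a cube of side `box` centered at
#' the origin, from a seeded generator that leaves the session RNG state
#' untouched. Identical seeds give identical conformations.
#'
#' @param n_bins Number of bins (>= 3).
#' @param seed Integer seed.
#' @param box Side length of the initialization cube.
#' @param topology Passed to [conformation()].
#' @return A [conformation()].
#' @export
init_conformation <- function(n_bins, seed = 1L, box = 1,
                              topology = c("circular", "linear")) {
  if (!is.numeric(n_bins) || length(n_bins) != 1 || n_bins < 3) {
    stop("`n_bins` must be a single integer >= 3", call. = FALSE)
  }
  stopifnot(is.numeric(box), length(box) == 1, box > 0)
  p <- withr::with_seed(as.integer(seed), {
    matrix(stats::runif(3 * n_bins, min = -box / 2, max = box / 2),
           ncol = 3)
  })
  conformation(p, topology = match.arg(topology))
}

#' Radius of gyration of a conformation
#'
#' Root-mean-square distance of the bins from their centroid; the natural
#' size scale against which reconstruction RMSD is judged.
#'
#' @param conf A [conformation()].
#' @return Non-negative scalar.
#' @export
radius_of_gyration <- function(conf) {
  p <- coords(conf)
  pc <- sweep(p, 2, colMeans(p))
  sqrt(mean(rowSums(pc^2)))
}
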