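#' Convert interaction frequencies to expected spatial distances
#'
#' Applies the power-law transform `D_ij = (1 / F_ij)^alpha` to every
#' off-diagonal pair with `F_ij != 0`. Pairs with `F_ij == 0` carry no
#' distance information (the infinite-distance branch of the model) and are
#' marked *undefined* rather than given a sentinel value, so that they can
#' be excluded exactly from the error-vector sums. The diagonal is always
#' undefined.
#'
#' @param m A [contact_matrix()].
#' @param alpha Positive power exponent; 0.5 by default, the value used for
#'   bacterial Hi-C reconstructions.
#'
#' @return A `distance_matrix`: list with `values` (`N x N` numeric,
#'   `NA` where undefined), `defined` (`N x N` logical mask) and `alpha`.
#'
#' @examples
#' m <- contact_matrix(matrix(c(0, 4, 1, 4, 0, 1, 1, 1, 0), 3, 3))
#' d <- if_to_distance(m)
#' d$values[1, 2]  # (1/4)^0.5 = 0.5
#' @export
if_to_distance <- function(m, alpha = 0.5) {
  stopifnot(inherits(m, "contact_matrix"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) {
    stop("`alpha` must be a single positive number", call. = FALSE)
  }
  f <- unclass(m)
  attributes(f) <- list(dim = dim(f))
  defined <- f != 0
  diag(defined) <- FALSE
  values <- matrix(NA_real_, nrow(f), ncol(f))
  values[defined] <- (1 / f[defined])^alpha
  structure(list(values = values, defined = defined, alpha = alpha),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  n <- nrow(x$values)
  n_def <- sum(x$defined[upper.tri(x$defined)])
  cat("<distance_matrix> ", n, " bins, alpha = ", x$alpha, ", ",
      n_def, "/", n * (n - 1) / 2, " pairs defined\n", sep = "")
  invisible(x)
}

#' Simulate an interaction-frequency matrix from a known structure
#'
#' Inverse of [if_to_distance()]: every bin pair receives
#' `F_ij = d_ij^(-1/alpha)` where `d_ij` is the Euclidean distance between
#' the bins, with a zero diagonal. Used to turn synthetic standard
#' structures into benchmark inputs; no distance cutoff is applied, so the
#' round trip `if_to_distance(structure_to_if(c))` recovers the true
#' distances exactly.
#'
#' @param conf A [conformation()] with pairwise-distinct points.
#' @param alpha Positive power exponent (default 0.5).
#' @param bin_size Optional bin width metadata for the output matrix.
#'
#' @return A [contact_matrix()].
#' @export
structure_to_if <- function(conf, alpha = 0.5, bin_size = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) {
    stop("`alpha` must be a single positive number", call. = FALSE)
  }
  p <- coords(conf)
  d <- as.matrix(stats::dist(p))
  dimnames(d) <- NULL
  off <- d[upper.tri(d)]
  if (any(off == 0)) {
    stop("coincident bins (zero pairwise distance); cannot form frequencies",
         call. = FALSE)
  }
  f <- d^(-1 / alpha)
  diag(f) <- 0
  contact_matrix(f, bin_size = bin_size)
}
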