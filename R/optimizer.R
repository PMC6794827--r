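#' Optimizer configuration for error-vector resultant reconstruction
#'
#' Collects every tunable of [evr_reconstruct()]. Parameters left `NULL`
#' are resolved from the data when the run starts and echoed back on the
#' fitted object so every run is reproducible from its config alone:
#'
#' * `d_min`, `d_max` — allowed distance band between genomically adjacent
#'   bins; defaults `0.25 * m_adj` and `4 * m_adj` where `m_adj` is the
#'   median defined adjacent-pair expected distance.
#' * `weight` — error-vector weight `w = 1/N`.
#' * `init_box` — side of the random initialization cube,
#'   `2 * m_adj * N^(1/3)` (a cloud at roughly the expected structure
#'   density).
#'
#' @param alpha Power exponent of the frequency-to-distance transform
#'   (default 0.5).
#' @param d_min,d_max Adjacent-bin distance band (expected-distance units);
#'   must satisfy `d_min < d_max` when given.
#' @param weight Scalar weight applied to every error vector in the
#'   resultant sum.
#' @param tol Stop threshold on `|F_t - F_(t-1)|` (default 1e-5).
#' @param max_iter Maximum number of iterations (default 10000).
#' @param seed Integer seed for the random initial conformation and for any
#'   degeneracy tie-breaks.
#' @param topology `"circular"` (first and last bins adjacent) or `"linear"`.
#' @param init_box Side of the initialization cube.
#'
#' @return A list of class `"evr_config"`.
#' @export
evr_config <- function(alpha = 0.5, d_min = NULL, d_max = NULL,
                       weight = NULL, tol = 1e-5, max_iter = 10000L,
                       seed = 1L, topology = c("circular", "linear"),
                       init_box = NULL) {
  topology <- match.arg(topology)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0,
            is.numeric(tol), tol > 0,
            is.numeric(max_iter), max_iter >= 1)
  if (!is.null(d_min)) stopifnot(is.numeric(d_min), d_min > 0)
  if (!is.null(d_max)) stopifnot(is.numeric(d_max), d_max > 0)
  if (!is.null(d_min) && !is.null(d_max) && d_min >= d_max) {
    stop("`d_min` must be strictly smaller than `d_max`", call. = FALSE)
  }
  if (!is.null(weight)) stopifnot(is.numeric(weight), weight > 0)
  if (!is.null(init_box)) stopifnot(is.numeric(init_box), init_box > 0)
  structure(list(alpha = alpha, d_min = d_min, d_max = d_max,
                 weight = weight, tol = tol,
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 topology = topology, init_box = init_box),
            class = "evr_config")
}

#' @export
print.evr_config <- function(x, ...) {
  cat("<evr_config>\n")
  for (nm in names(x)) {
    cat("  ", nm, ": ", if (is.null(x[[nm]])) "<auto>" else format(x[[nm]]),
        "\n", sep = "")
  }
  invisible(x)
}

# Fill the data-dependent defaults of a config from a distance matrix.
resolve_config <- function(cfg, d) {
  n <- nrow(d$values)
  adj <- adjacency_pairs(n, cfg$topology)
  idx <- cbind(adj$i, adj$j)
  adj_d <- d$values[idx][d$defined[idx]]
  if (length(adj_d) == 0) {
    stop("no adjacent bin pair has a defined expected distance; ",
         "cannot derive the adjacency band (set d_min/d_max explicitly)",
         call. = FALSE)
  }
  m_adj <- stats::median(adj_d)
  if (is.null(cfg$d_min)) cfg$d_min <- 0.25 * m_adj
  if (is.null(cfg$d_max)) cfg$d_max <- 4 * m_adj
  if (cfg$d_min >= cfg$d_max) {
    stop("resolved d_min >= d_max (", cfg$d_min, " >= ", cfg$d_max, ")",
         call. = FALSE)
  }
  if (is.null(cfg$weight)) cfg$weight <- 1 / n
  if (is.null(cfg$init_box)) cfg$init_box <- 2 * m_adj * n^(1 / 3)
  cfg
}

# Index pairs (i < j) that are genomically adjacent under the topology.
adjacency_pairs <- function(n, topology) {
  i <- seq_len(n - 1)
  j <- i + 1
  if (topology == "circular") {
    i <- c(i, 1L)
    j <- c(j, n)
  }
  list(i = i, j = j)
}

#' Error vector between two non-adjacent bins
#'
#' The displacement assigned to bin `j` from its pairing with bin `i`:
#' `((p_i - p_j) / r) * (r - d_ij)` with `r = |p_i - p_j|`. It pulls bin
#' `j` toward bin `i` when the pair is too far apart and pushes it away
#' when too close; it vanishes when the expected distance is met.
#'
#' @param p_i,p_j Numeric 3-vectors, current positions of bins i and j.
#' @param d_ij Positive expected distance.
#' @return Numeric 3-vector (the move contribution for bin `j`, before
#'   weighting).
#' @examples
#' pair_error_vector(c(0, 0, 0), c(3, 0, 0), 1)  # (-2, 0, 0)
#' @export
pair_error_vector <- function(p_i, p_j, d_ij) {
  stopifnot(length(p_i) == 3, length(p_j) == 3, d_ij > 0)
  diff <- p_i - p_j
  r <- sqrt(sum(diff^2))
  if (r == 0) stop("coincident points; no direction defined", call. = FALSE)
  diff / r * (r - d_ij)
}

#' Error vector between two genomically adjacent bins
#'
#' Adjacent bins obey a chain-integrity band: with `r = |p_i - p_j|`,
#' the target distance is `d_min` when `r < d_min`, `d_max` when
#' `r > d_max`, and the expected distance `d_ij` when `r` lies inside the
#' band. When `d_ij` is undefined (zero interaction frequency) and `r` is
#' inside the band, the band acts as a free region and the error is zero.
#' Boundary ties (`r == d_min` or `r == d_max`) take the in-band branch;
#' all branches are continuous there, so this only fixes determinism.
#'
#' @param p_i,p_j Numeric 3-vectors.
#' @param d_ij Expected distance, or `NA` when undefined.
#' @param d_min,d_max Adjacency band, `d_min < d_max`.
#' @return Numeric 3-vector.
#' @export
adjacent_error_vector <- function(p_i, p_j, d_ij, d_min, d_max) {
  stopifnot(d_min < d_max)
  diff <- p_i - p_j
  r <- sqrt(sum(diff^2))
  if (r == 0) stop("coincident points; no direction defined", call. = FALSE)
  target <- if (r < d_min) {
    d_min
  } else if (r > d_max) {
    d_max
  } else if (!is.na(d_ij)) {
    d_ij
  } else {
    r  # free region: zero error
  }
  diff / r * (r - target)
}

# Deterministic pseudo-random unit vectors for coincident pairs, hashed
# from (seed, iteration, i, j); touches no RNG state.
degenerate_directions <- function(seed, iter, i, j) {
  frac <- function(x) x - floor(x)
  base <- seed * 12.9898 + iter * 78.233 + i * 37.719 + j * 4.581
  u <- cbind(frac(sin(base + 93.989) * 43758.5453),
             frac(sin(base + 67.345) * 24634.6345),
             frac(sin(base + 13.579) * 56445.2357)) * 2 - 1
  nrm <- sqrt(rowSums(u^2))
  bad <- nrm < 1e-12
  if (any(bad)) {
    u[bad, ] <- matrix(c(1, 0, 0), sum(bad), 3, byrow = TRUE)
    nrm[bad] <- 1
  }
  u / nrm
}

#' Resultant field: per-bin sums of weighted error vectors
#'
#' For every bin `j` computes the error-vector resultant
#' `E_j = w * sum_i e_ij` over all partner bins `i != j`, where adjacent
#' pairs (|i - j| = 1, plus the first/last pair under circular topology)
#' use [adjacent_error_vector()] and non-adjacent pairs with a defined
#' expected distance use [pair_error_vector()]; undefined non-adjacent
#' pairs contribute nothing. The scalar objective is
#' `F = sum_j |E_j|`.
#'
#' All pairwise terms are evaluated on the input conformation
#' (synchronous/Jacobi update), matching a per-bin parallel implementation.
#'
#' @param conf A [conformation()].
#' @param d A `distance_matrix` from [if_to_distance()].
#' @param cfg An [evr_config()]; `NULL` entries are resolved from `d`.
#' @param iter Iteration counter, only used to derandomize coincident-point
#'   tie-breaks.
#'
#' @return List of class `"resultant_field"` with `vectors` (`N x 3`
#'   matrix of `E_j`) and `objective` (`F`).
#' @export
resultant_field <- function(conf, d, cfg = evr_config(), iter = 0L) {
  p <- coords(conf)
  n <- nrow(p)
  if (nrow(d$values) != n) {
    stop("conformation has ", n, " bins but distance matrix has ",
         nrow(d$values), call. = FALSE)
  }
  cfg$topology <- topology(conf)
  cfg <- resolve_config(cfg, d)

  dx <- outer(p[, 1], p[, 1], "-")   # dx[i, j] = x_i - x_j
  dy <- outer(p[, 2], p[, 2], "-")
  dz <- outer(p[, 3], p[, 3], "-")
  r <- sqrt(dx^2 + dy^2 + dz^2)

  # target distance per contributing pair; NA = no contribution
  target <- d$values
  target[!d$defined] <- NA_real_
  adj <- adjacency_pairs(n, cfg$topology)
  ai <- c(adj$i, adj$j)
  aj <- c(adj$j, adj$i)
  aidx <- cbind(ai, aj)
  ra <- r[aidx]
  ta <- ifelse(ra < cfg$d_min, cfg$d_min,
        ifelse(ra > cfg$d_max, cfg$d_max,
        ifelse(d$defined[aidx], d$values[aidx], ra)))
  target[aidx] <- ta
  diag(target) <- NA_real_

  contrib <- !is.na(target)
  degen <- contrib & r == 0
  coef <- matrix(0, n, n)
  ok <- contrib & !degen
  coef[ok] <- (r[ok] - target[ok]) / r[ok]

  # E_j = w * sum_i coef[i,j] * (p_i - p_j); coef is symmetric
  w <- cfg$weight
  cs <- colSums(coef)
  e <- w * cbind(coef %*% p[, 1] - p[, 1] * cs,
                 coef %*% p[, 2] - p[, 2] * cs,
                 coef %*% p[, 3] - p[, 3] * cs)

  if (any(degen)) {
    # coincident pair: move bin j along a reproducible pseudo-random
    # direction by the full target distance (e_ij = -target * u_ij)
    which_d <- which(degen & upper.tri(degen), arr.ind = TRUE)
    if (nrow(which_d) > 0) {
      u <- degenerate_directions(cfg$seed, iter, which_d[, 1], which_d[, 2])
      tgt <- target[which_d]
      for (k in seq_len(nrow(which_d))) {
        i <- which_d[k, 1]; j <- which_d[k, 2]
        e[j, ] <- e[j, ] - w * tgt[k] * u[k, ]
        e[i, ] <- e[i, ] + w * tgt[k] * u[k, ]
      }
    }
  }

  structure(list(vectors = e, objective = sum(sqrt(rowSums(e^2)))),
            class = "resultant_field")
}

#' Apply one synchronous optimization step
#'
#' Moves every bin by its resultant vector: `coords[j] <- coords[j] + E_j`.
#' All resultants were computed on the input conformation, so the update is
#' order-independent.
#'
#' @param conf A [conformation()].
#' @param field A `"resultant_field"` for `conf`.
#' @return The moved [conformation()].
#' @export
evr_step <- function(conf, field) {
  p <- coords(conf)
  if (nrow(field$vectors) != nrow(p)) {
    stop("field and conformation sizes differ", call. = FALSE)
  }
  conformation(p + field$vectors, topology = topology(conf))
}

#' Reconstruct a 3D chromosome backbone from a contact matrix
#'
#' The full pipeline: converts the interaction-frequency matrix to expected
#' distances with the power law, draws a random initial conformation, and
#' iterates synchronous resultant-field moves until the objective
#' stabilizes (`|F_t - F_(t-1)| < tol`) or `max_iter` is reached. The run
#' is fully deterministic given the matrix and config.
#'
#' Coordinates are reported in expected-distance units; set
#' `rescale = TRUE` to normalize the mean adjacent-bin distance to 1
#' (contact data carries no absolute length scale).
#'
#' @param m A [contact_matrix()] (or a plain symmetric non-negative
#'   matrix, coerced).
#' @param cfg An [evr_config()].
#' @param rescale Normalize mean adjacent distance to 1 after convergence?
#'
#' @return An object of class `"evr_fit"`: list with `conformation`
#'   (a [conformation()]), `f_history` (objective per iteration, starting
#'   at the initial conformation), `n_iter`, `converged`, `delta_f_final`,
#'   and the fully resolved `config`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#'
#' @examples
#' truth <- toroidal_spiral(spiral_spec(n_bins = 40))
#' fit <- evr_reconstruct(structure_to_if(truth), evr_config(seed = 7))
#' glance(fit)
#' @export
evr_reconstruct <- function(m, cfg = evr_config(), rescale = FALSE) {
  if (!inherits(m, "contact_matrix")) m <- contact_matrix(m)
  n <- n_bins(m)
  d <- if_to_distance(m, alpha = cfg$alpha)
  cfg <- resolve_config(cfg, d)

  if (cfg$topology == "linear") {
    end_rows <- c(1L, n)
    lonely <- end_rows[!apply(d$defined[end_rows, , drop = FALSE], 1, any)]
    if (length(lonely) > 0) {
      warning("linear end bin(s) with no defined distances, constrained ",
              "only by one neighbor: ", paste(lonely, collapse = ", "),
              call. = FALSE)
    }
  }

  conf <- init_conformation(n, seed = cfg$seed, box = cfg$init_box,
                            topology = cfg$topology)
  field <- resultant_field(conf, d, cfg, iter = 0L)
  f_hist <- numeric(cfg$max_iter + 1)
  f_hist[1] <- field$objective
  delta <- Inf
  t <- 0L
  while (t < cfg$max_iter) {
    t <- t + 1L
    conf <- evr_step(conf, field)
    field <- resultant_field(conf, d, cfg, iter = t)
    f_hist[t + 1] <- field$objective
    delta <- abs(f_hist[t + 1] - f_hist[t])
    if (delta < cfg$tol) break
  }
  f_hist <- f_hist[seq_len(t + 1)]

  scale_applied <- 1
  if (rescale) {
    p <- coords(conf)
    adj <- adjacency_pairs(n, cfg$topology)
    mean_adj <- mean(sqrt(rowSums((p[adj$i, , drop = FALSE] -
                                   p[adj$j, , drop = FALSE])^2)))
    if (mean_adj > 0) {
      scale_applied <- 1 / mean_adj
      conf <- conformation(p * scale_applied, topology = cfg$topology)
    }
  }

  structure(list(conformation = conf,
                 f_history = f_hist,
                 n_iter = t,
                 converged = delta < cfg$tol,
                 delta_f_final = delta,
                 rescale_factor = scale_applied,
                 config = cfg),
            class = "evr_fit")
}

#' @export
print.evr_fit <- function(x, ...) {
  cat("<evr_fit> ", n_bins(x$conformation), " bins, ",
      topology(x$conformation), " topology\n", sep = "")
  cat("  iterations: ", x$n_iter,
      if (x$converged) " (converged)" else " (max_iter reached)", "\n",
      sep = "")
  cat("  final F: ", format(x$f_history[length(x$f_history)]),
      ", final dF: ", format(x$delta_f_final), "\n", sep = "")
  invisible(x)
}
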