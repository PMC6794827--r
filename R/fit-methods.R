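#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an EVR fit into a per-bin coordinate table
#'
#' @param x An `evr_fit` from [evr_reconstruct()].
#' @param ... Unused.
#' @return A tibble with one row per bin: `bin`, `x`, `y`, `z`.
#' @export
tidy.evr_fit <- function(x, ...) {
  out <- tibble::as_tibble(x$conformation)
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of an EVR fit
#'
#' @param x An `evr_fit`.
#' @param ... Unused.
#' @return A one-row tibble: bin count, topology, iterations, convergence
#'   flag, final objective `F` and final `delta F`, and the resolved
#'   adjacency band.
#' @export
glance.evr_fit <- function(x, ...) {
  tibble::tibble(
    n_bins = n_bins(x$conformation),
    topology = topology(x$conformation),
    n_iter = x$n_iter,
    converged = x$converged,
    f_final = x$f_history[length(x$f_history)],
    delta_f_final = x$delta_f_final,
    d_min = x$config$d_min,
    d_max = x$config$d_max
  )
}

#' Objective trajectory plot for an EVR fit
#'
#' Plots the objective `F` (sum of resultant lengths) against iteration on
#' a log10 y scale — the standard convergence diagnostic.
#'
#' @param object An `evr_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evr_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$f_history) - 1,
                       f = object$f_history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$f)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "objective F",
                  title = "EVR convergence") +
    ggplot2::theme_minimal()
}

#' Orthographic projections of a reconstructed backbone
#'
#' Draws the bin chain in the xy, xz and yz planes, colored by genomic
#' position, closing the chain when the topology is circular.
#'
#' @param conf A [conformation()] or an `evr_fit`.
#' @return A ggplot (faceted by projection plane).
#' @export
plot_structure <- function(conf) {
  if (inherits(conf, "evr_fit")) conf <- conf$conformation
  p <- coords(conf)
  n <- nrow(p)
  ord <- if (topology(conf) == "circular") c(seq_len(n), 1L) else seq_len(n)
  df <- dplyr::bind_rows(
    tibble::tibble(plane = "xy", h = p[ord, 1], v = p[ord, 2], bin = ord),
    tibble::tibble(plane = "xz", h = p[ord, 1], v = p[ord, 3], bin = ord),
    tibble::tibble(plane = "yz", h = p[ord, 2], v = p[ord, 3], bin = ord)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$v,
                                   color = .data$bin)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~plane) +
    ggplot2::scale_color_viridis_c(name = "bin") +
    ggplot2::labs(x = NULL, y = NULL, title = "Reconstructed backbone") +
    ggplot2::theme_minimal()
}
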