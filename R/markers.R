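#' Construct a marker set: genomic loci with measured pairwise distances
#'
#' Fluorescence-microscopy validation data: named genomic loci (1-based bp
#' positions) and experimentally measured spatial distances between pairs
#' of them. Used to correlate structure-based distances of a reconstruction
#' with independent measurements.
#'
#' @param positions Data frame with columns `name` and `position`
#'   (1-based bp).
#' @param measured_pairs Data frame with columns `name_a`, `name_b`,
#'   `distance` (and optionally `units`).
#'
#' @return A list of class `"marker_set"` with tibbles `positions` and
#'   `measured_pairs`.
#' @export
marker_set <- function(positions, measured_pairs) {
  positions <- tibble::as_tibble(positions)
  measured_pairs <- tibble::as_tibble(measured_pairs)
  stopifnot(all(c("name", "position") %in% names(positions)),
            all(c("name_a", "name_b", "distance") %in% names(measured_pairs)))
  if (any(positions$position < 1)) {
    stop("marker positions must be >= 1 (1-based bp)", call. = FALSE)
  }
  if (any(measured_pairs$distance <= 0)) {
    stop("measured distances must be positive", call. = FALSE)
  }
  missing <- setdiff(c(measured_pairs$name_a, measured_pairs$name_b),
                     positions$name)
  if (length(missing) > 0) {
    stop("measured pairs reference unknown markers: ",
         paste(unique(missing), collapse = ", "), call. = FALSE)
  }
  structure(list(positions = positions, measured_pairs = measured_pairs),
            class = "marker_set")
}

#' Read a marker set from two delimited text tables
#'
#' `positions_path` is a 2-column table (name, bp position);
#' `pairs_path` a 3- or 4-column table (name_a, name_b, measured distance,
#' optional units). Tab- or whitespace-delimited, `#` comments allowed,
#' no header.
#'
#' @param positions_path,pairs_path File paths.
#' @return A [marker_set()].
#' @export
read_marker_set <- function(positions_path, pairs_path) {
  pos <- utils::read.table(positions_path, header = FALSE,
                           comment.char = "#",
                           col.names = c("name", "position"),
                           colClasses = c("character", "numeric"))
  pr <- utils::read.table(pairs_path, header = FALSE, comment.char = "#",
                          fill = TRUE, stringsAsFactors = FALSE)
  if (ncol(pr) < 3) stop("pairs table needs >= 3 columns", call. = FALSE)
  names(pr)[1:3] <- c("name_a", "name_b", "distance")
  if (ncol(pr) >= 4) names(pr)[4] <- "units"
  pr$distance <- as.numeric(pr$distance)
  marker_set(pos, pr[, seq_len(min(ncol(pr), 4))])
}

#' Map genomic positions onto bin indices
#'
#' Positions are 1-based inclusive bp; bins are fixed-width, so position
#' `p` falls into bin `floor((p - 1) / bin_size)` (0-based internal,
#' returned 1-based to match [conformation()] rows). Positions past
#' `n_bins * bin_size` but within `genome_length` (a trailing partial bin)
#' map to the last bin with a warning; anything further is an error.
#'
#' @param positions Numeric vector of 1-based bp positions.
#' @param bin_size Bin width in bp.
#' @param n_bins Number of bins in the structure.
#' @param genome_length Optional true genome length (>= `n_bins * bin_size`)
#'   allowing a trailing partial bin.
#' @return Integer vector of 1-based bin indices.
#' @examples
#' map_loci_to_bins(c(1, 10000, 10001), bin_size = 10000, n_bins = 5)
#' @export
map_loci_to_bins <- function(positions, bin_size, n_bins,
                             genome_length = NULL) {
  stopifnot(bin_size > 0, n_bins >= 1)
  if (any(positions < 1)) {
    stop("positions must be >= 1 (1-based bp)", call. = FALSE)
  }
  limit <- if (is.null(genome_length)) n_bins * bin_size else genome_length
  if (any(positions > limit)) {
    stop("positions beyond the genome end: ",
         paste(positions[positions > limit], collapse = ", "), call. = FALSE)
  }
  bins <- floor((positions - 1) / bin_size) + 1L
  over <- bins > n_bins
  if (any(over)) {
    warning(sum(over), " position(s) in the trailing partial bin mapped to ",
            "the last bin", call. = FALSE)
    bins[over] <- n_bins
  }
  as.integer(bins)
}

#' Correlate structure-based and measured inter-locus distances
#'
#' Maps each marker onto its bin, reads that bin's 3D coordinate off the
#' reconstruction, computes the Euclidean distance for every measured pair,
#' and correlates those structure-based distances with the measured ones
#' (Pearson, two-sided t-test p-value). Because the reconstruction has an
#' arbitrary global scale, the correlation — not the absolute agreement —
#' is the accuracy measure.
#'
#' @param conf A [conformation()] or `evr_fit`.
#' @param markers A [marker_set()].
#' @param bin_size Bin width in bp.
#' @param genome_length Optional, see [map_loci_to_bins()].
#'
#' @return A list of class `"evr_distance_cor"`: `pcc`, `p_value`, `n_pairs`
#'   and `pairs`, a tibble with one row per measured pair
#'   (`name_a`, `name_b`, `measured`, `structure`).
#' @export
distance_correlation <- function(conf, markers, bin_size,
                                 genome_length = NULL) {
  if (inherits(conf, "evr_fit")) conf <- conf$conformation
  stopifnot(inherits(markers, "marker_set"))
  pairs <- markers$measured_pairs
  if (nrow(pairs) < 3) {
    stop("need at least 3 measured pairs for a correlation test",
         call. = FALSE)
  }
  p <- coords(conf)
  pos <- markers$positions
  bins <- map_loci_to_bins(pos$position, bin_size, nrow(p), genome_length)
  bin_of <- stats::setNames(bins, pos$name)
  d_struct <- sqrt(rowSums((p[bin_of[pairs$name_a], , drop = FALSE] -
                            p[bin_of[pairs$name_b], , drop = FALSE])^2))
  tab <- tibble::tibble(name_a = pairs$name_a, name_b = pairs$name_b,
                        measured = pairs$distance, structure = d_struct)
  ct <- stats::cor.test(tab$structure, tab$measured, method = "pearson",
                        alternative = "two.sided")
  structure(list(pcc = unname(ct$estimate), p_value = ct$p.value,
                 n_pairs = nrow(tab), pairs = tab),
            class = "evr_distance_cor")
}

#' @export
print.evr_distance_cor <- function(x, ...) {
  cat("<evr_distance_cor> PCC = ", format(x$pcc), ", p = ",
      format(x$p_value), " (", x$n_pairs, " pairs)\n", sep = "")
  invisible(x)
}

#' One-row summary of a distance correlation
#'
#' @param x An `evr_distance_cor`.
#' @param ... Unused.
#' @return A one-row tibble with `pcc`, `p_value`, `n_pairs`.
#' @export
glance.evr_distance_cor <- function(x, ...) {
  tibble::tibble(pcc = x$pcc, p_value = x$p_value, n_pairs = x$n_pairs)
}

#' Scatterplot of measured vs structure-based distances
#'
#' @param object An `evr_distance_cor` from [distance_correlation()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evr_distance_cor <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$measured, y = .data$structure)) +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "grey40", linewidth = 0.5) +
    ggplot2::labs(x = "measured distance", y = "structure-based distance",
                  subtitle = sprintf("PCC = %.3f, p = %.3g",
                                     object$pcc, object$p_value)) +
    ggplot2::theme_minimal()
}
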