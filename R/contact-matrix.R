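#' Construct a validated interaction-frequency (contact) matrix
#'
#' A contact matrix holds normalized 3C/Hi-C interaction frequencies for
#' `N` equal-length genomic bins. It is the sole input of
#' [evr_reconstruct()]. Entries must be non-negative and the matrix square
#' and symmetric; the diagonal is carried along but never used downstream.
#'
#' @param values Square numeric matrix of interaction frequencies
#'   (`N x N`, `N >= 3`). Mild asymmetry (as found in some GEO text dumps)
#'   is averaged with the transpose and reported via a warning.
#' @param bin_size Optional bin width in base pairs; only used when mapping
#'   genomic marker positions onto bins.
#' @param labels Optional character vector of per-bin identifiers.
#'
#' @return A `contact_matrix`: a numeric matrix with class
#'   `"contact_matrix"` and attributes `bin_size` and `labels`.
#'
#' @examples
#' m <- contact_matrix(matrix(c(0, 2, 1, 2, 0, 4, 1, 4, 0), 3, 3))
#' n_bins(m)
#' @export
contact_matrix <- function(values, bin_size = NULL, labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(values) != ncol(values)) {
    stop("contact matrix must be square, got ", nrow(values), " x ",
         ncol(values), call. = FALSE)
  }
  n <- nrow(values)
  if (n < 3) stop("contact matrix needs at least 3 bins, got ", n, call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("contact matrix contains NA or non-finite entries", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("contact matrix contains negative interaction frequencies", call. = FALSE)
  }
  asym <- max(abs(values - t(values)))
  if (asym > 0) {
    warning("asymmetric input (max |F_ij - F_ji| = ", format(asym),
            "); averaging with the transpose", call. = FALSE)
    values <- (values + t(values)) / 2
  }
  off <- values
  diag(off) <- 0
  zero_rows <- which(rowSums(off) == 0)
  if (length(zero_rows) > 0) {
    warning("bins with no off-diagonal interactions (constrained only by ",
            "chain adjacency): ", paste(zero_rows, collapse = ", "),
            call. = FALSE)
  }
  if (!is.null(bin_size)) {
    stopifnot(length(bin_size) == 1, is.numeric(bin_size), bin_size > 0)
    bin_size <- as.integer(bin_size)
  }
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    labels <- as.character(labels)
  }
  dimnames(values) <- NULL
  structure(values, class = c("contact_matrix", class(matrix())),
            bin_size = bin_size, labels = labels)
}

#' Number of bins of a contact matrix or conformation
#'
#' @param x A `contact_matrix` or `conformation`.
#' @return Integer bin count.
#' @export
n_bins <- function(x) {
  if (inherits(x, "contact_matrix")) return(nrow(x))
  if (inherits(x, "conformation") || is.data.frame(x)) return(nrow(x))
  stop("cannot determine bin count for class ", paste(class(x), collapse = "/"),
       call. = FALSE)
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix> ", nrow(x), " x ", ncol(x), " bins", sep = "")
  bs <- attr(x, "bin_size")
  if (!is.null(bs)) cat(", bin size ", bs, " bp", sep = "")
  cat("\n  IF range: [", format(min(x)), ", ", format(max(x)), "]\n", sep = "")
  invisible(x)
}

#' Read an interaction-frequency matrix from dense text
#'
#' Reads the whitespace/tab-delimited dense matrix dialect used by
#' bacterial Hi-C GEO deposits: `N` rows of `N` numeric columns, optionally
#' preceded by a header row and a leading label column
#' (`dialect = "dense_text_with_header"`). The dialect is never sniffed;
#' silently mis-reading a label row as data would corrupt the matrix.
#'
#' @param path Path to the text file.
#' @param dialect `"dense_text"` (numbers only) or
#'   `"dense_text_with_header"` (first row and first column are bin labels).
#' @param bin_size Optional bin width in bp, attached as metadata.
#'
#' @return A validated [contact_matrix()]; asymmetric inputs are averaged
#'   with the transpose (with a warning), negative or NA entries are errors.
#'
#' @seealso [write_if_matrix()]
#' @export
read_if_matrix <- function(path,
                           dialect = c("dense_text", "dense_text_with_header"),
                           bin_size = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty matrix file: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  labels <- NULL
  if (dialect == "dense_text_with_header") {
    header <- fields[[1]]
    fields <- fields[-1]
    # header may or may not carry a stub over the label column
    labels <- vapply(fields, `[`, character(1), 1)
    fields <- lapply(fields, `[`, -1)
  }
  widths <- lengths(fields)
  if (length(unique(widths)) != 1) {
    stop("ragged matrix file: rows have ", paste(sort(unique(widths)),
         collapse = ", "), " columns", call. = FALSE)
  }
  if (widths[1] != length(fields)) {
    stop("non-square matrix: ", length(fields), " rows x ", widths[1],
         " columns", call. = FALSE)
  }
  vals <- suppressWarnings(vapply(fields, as.numeric, numeric(widths[1])))
  if (anyNA(vals)) {
    stop("non-numeric or NaN entries in matrix file", call. = FALSE)
  }
  # vapply over rows gives columns; transpose back to row-major reading
  contact_matrix(t(vals), bin_size = bin_size, labels = labels)
}

#' Write an interaction-frequency matrix as dense tab-delimited text
#'
#' Full-precision (`%.17g`) formatting so `read_if_matrix(write_if_matrix(m))`
#' reproduces `m` exactly. Labels, when present, are written in the
#' `dense_text_with_header` dialect.
#'
#' @param m A [contact_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_if_matrix <- function(m, path) {
  stopifnot(inherits(m, "contact_matrix"))
  labels <- attr(m, "labels")
  body <- apply(m, 1, function(row) paste(sprintf("%.17g", row), collapse = "\t"))
  if (!is.null(labels)) {
    body <- paste(labels, body, sep = "\t")
    body <- c(paste(c("bin", labels), collapse = "\t"), body)
  }
  writeLines(body, path)
  invisible(path)
}
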