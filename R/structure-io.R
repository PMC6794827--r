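#' Write a conformation as an xyz table
#'
#' One tab-delimited data line per bin — 1-based bin index, x, y, z at full
#' precision — preceded by `#`-prefixed header lines carrying topology and
#' any provenance metadata, so [read_xyz()] inverts the file exactly.
#'
#' @param conf A [conformation()] or `evr_fit`.
#' @param path Output file path.
#' @param provenance Optional named list (seed, source matrix path, config
#'   hash, ...) recorded in the header as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(conf, path, provenance = NULL) {
  if (inherits(conf, "evr_fit")) {
    if (is.null(provenance)) {
      provenance <- list(seed = conf$config$seed,
                         alpha = conf$config$alpha,
                         converged = conf$converged,
                         n_iter = conf$n_iter)
    }
    conf <- conf$conformation
  }
  p <- coords(conf)
  if (any(!is.finite(p))) {
    stop("non-finite coordinates; refusing to write", call. = FALSE)
  }
  header <- c("# evr xyz structure", paste0("# topology: ", topology(conf)))
  for (nm in names(provenance)) {
    header <- c(header, paste0("# ", nm, ": ", format(provenance[[nm]])))
  }
  lines <- sprintf("%d\t%.17g\t%.17g\t%.17g",
                   seq_len(nrow(p)), p[, 1], p[, 2], p[, 3])
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a conformation from an xyz table
#'
#' Inverse of [write_xyz()]. Topology is recovered from the
#' `# topology:` header line; when absent, circular is assumed (the tool
#' targets prokaryotes, whose chromosomes are mostly closed) with a
#' warning.
#'
#' @param path Path to an xyz file.
#' @return A [conformation()]; header metadata is attached as attribute
#'   `"provenance"` (named character vector).
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^#", lines)
  meta <- lines[hdr]
  body <- lines[!hdr & nzchar(trimws(lines))]
  kv <- regmatches(meta, regexec("^#\\s*([^:]+):\\s*(.*)$", meta))
  kv <- kv[lengths(kv) == 3]
  prov <- stats::setNames(vapply(kv, `[`, character(1), 3),
                          trimws(vapply(kv, `[`, character(1), 2)))
  top <- if ("topology" %in% names(prov)) prov[["topology"]] else NULL
  if (is.null(top) || is.na(top)) {
    warning("xyz header carries no topology; assuming circular",
            call. = FALSE)
    top <- "circular"
  }
  fields <- strsplit(trimws(body), "[ \t]+")
  if (any(lengths(fields) != 4)) {
    bad <- which(lengths(fields) != 4)[1]
    stop("malformed xyz data line ", bad, " (expected 4 fields)",
         call. = FALSE)
  }
  mat <- do.call(rbind, lapply(fields, as.numeric))
  if (anyNA(mat)) stop("non-numeric field in xyz data", call. = FALSE)
  idx <- mat[, 1]
  if (anyDuplicated(idx)) {
    stop("duplicate bin index in xyz file: ",
         idx[duplicated(idx)][1], call. = FALSE)
  }
  if (!identical(as.integer(idx), seq_len(nrow(mat)))) {
    mat <- mat[order(idx), , drop = FALSE]
    if (!identical(as.integer(mat[, 1]), seq_len(nrow(mat)))) {
      stop("bin indices are not 1..N", call. = FALSE)
    }
  }
  out <- conformation(mat[, 2:4, drop = FALSE], topology = top)
  attr(out, "provenance") <- prov
  out
}

#' Write a conformation as a PDB-like file for molecular viewers
#'
#' Renders each bin as the CA atom of a sequential residue on one chain,
#' with CONECT records joining consecutive bins (including the last-to-
#' first closure when the topology is circular) so viewers draw a closed
#' tube. Coordinates are uniformly rescaled when needed so the largest
#' absolute value fits the fixed-width 8.3 coordinate field; the scale
#' factor is recorded in a REMARK line. Shape is preserved exactly (a pure
#' similarity), so superposition against the original gives RMSD 0.
#'
#' @param conf A [conformation()] or `evr_fit`.
#' @param path Output file path.
#' @return `path`, invisibly; attribute `"scale"` carries the factor
#'   applied.
#' @export
write_pdb_like <- function(conf, path) {
  if (inherits(conf, "evr_fit")) conf <- conf$conformation
  p <- coords(conf)
  n <- nrow(p)
  if (n > 99999) {
    stop("PDB fixed-width serial field cannot hold more than 99999 bins ",
         "(got ", n, "); use write_xyz()", call. = FALSE)
  }
  if (any(!is.finite(p))) {
    stop("non-finite coordinates; refusing to write", call. = FALSE)
  }
  scale <- 1
  max_abs <- max(abs(p))
  if (max_abs > 999.999) {     # widest value, sign included, in 8 columns
    scale <- 999.999 / max_abs
    p <- p * scale
  } else if (max_abs > 0 && max_abs < 0.01) {
    scale <- 100 / max_abs
    p <- p * scale
  }
  lines <- c(
    "REMARK   3D chromosome backbone model (one pseudo-atom per bin)",
    sprintf("REMARK   topology: %s", topology(conf)),
    sprintf("REMARK   coordinate scale factor applied: %.6g", scale)
  )
  atoms <- sprintf(
    "ATOM  %5d  CA  BIN A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), ((seq_len(n) - 1) %% 9999) + 1, p[, 1], p[, 2], p[, 3])
  ij <- cbind(seq_len(n - 1), seq_len(n - 1) + 1)
  if (topology(conf) == "circular") ij <- rbind(ij, c(n, 1L))
  conect <- sprintf("CONECT%5d%5d", ij[, 1], ij[, 2])
  writeLines(c(lines, atoms, conect, "END"), path)
  out <- invisible(path)
  attr(out, "scale") <- scale
  out
}
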