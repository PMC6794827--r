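# Independent scalar-loop reference for the resultant field: plain double
# loop over ordered pairs with the error-vector formulas written out from
# scratch (no calls into the package's field code).
oracle_resultant_field <- function(p, d_values, d_defined, topo,
                                   d_min, d_max, w) {
  n <- nrow(p)
  is_adjacent <- function(i, j) {
    abs(i - j) == 1 || (topo == "circular" && abs(i - j) == n - 1)
  }
  e <- matrix(0, n, 3)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i == j) next
      diff <- p[i, ] - p[j, ]
      r <- sqrt(sum(diff^2))
      if (is_adjacent(i, j)) {
        target <- if (r < d_min) d_min
                  else if (r > d_max) d_max
                  else if (d_defined[i, j]) d_values[i, j]
                  else r
      } else {
        if (!d_defined[i, j]) next
        target <- d_values[i, j]
      }
      e[j, ] <- e[j, ] + w * diff / r * (r - target)
    }
  }
  list(vectors = e, objective = sum(sqrt(rowSums(e^2))))
}

# Random conformation with pairwise-distinct points.
random_conformation <- function(n, seed, topology = "circular", spread = 5) {
  withr::with_seed(seed,
    conformation(matrix(stats::runif(3 * n, -spread, spread), ncol = 3),
                 topology = topology))
}

# Random sparse-ish contact matrix built from a random structure, with a
# fraction of off-diagonal pairs zeroed out (undefined distances).
random_contact_matrix <- function(n, seed, zero_frac = 0.2) {
  conf <- random_conformation(n, seed)
  m <- structure_to_if(conf)
  vals <- matrix(as.numeric(m), n, n)
  withr::with_seed(seed + 1000L, {
    up <- which(upper.tri(vals))
    drop <- sample(up, size = floor(zero_frac * length(up)))
    vals[drop] <- 0
  })
  vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
  suppressWarnings(contact_matrix(vals))
}
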