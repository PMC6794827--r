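test_that("random initialization is seeded, bounded, and seed-sensitive", {
  a <- init_conformation(100, seed = 1, box = 10)
  b <- init_conformation(100, seed = 1, box = 10)
  c <- init_conformation(100, seed = 2, box = 10)
  expect_identical(coords(a), coords(b))
  expect_false(identical(coords(a), coords(c)))
  expect_true(all(abs(coords(a)) <= 5))
  expect_error(init_conformation(2, seed = 1), ">= 3")
})

test_that("pair error vectors match hand-computed values", {
  # too far: pulled toward p_i by (r - d)
  expect_equal(pair_error_vector(c(0, 0, 0), c(3, 0, 0), 1), c(-2, 0, 0))
  # satisfied constraint: zero vector
  expect_equal(pair_error_vector(c(0, 0, 0), c(2, 0, 0), 2), c(0, 0, 0))
  # too close: pushed away from p_i
  expect_equal(pair_error_vector(c(0, 0, 0), c(0.5, 0, 0), 1), c(0.5, 0, 0))
  # general position: r = 5, d = 10, too close -> pushed away from p_i
  expect_equal(pair_error_vector(c(1, 2, 3), c(4, 6, 3), 10), c(3, 4, 0))
})

test_that("adjacent error vectors follow the three-branch band rule", {
  # below the band: target d_min, bins pushed apart
  e <- adjacent_error_vector(c(0, 0, 0), c(0.05, 0, 0), d_ij = 0.5,
                             d_min = 0.1, d_max = 2)
  expect_equal(e, c(0.05, 0, 0))  # away from p_i, magnitude |r - d_min|
  expect_equal(sqrt(sum(e^2)), 0.05)
  # inside the band: expected distance rules
  e2 <- adjacent_error_vector(c(0, 0, 0), c(1, 0, 0), d_ij = 0.5,
                              d_min = 0.1, d_max = 2)
  expect_equal(e2, c(-0.5, 0, 0))
  # inside the band, undefined expected distance: free region, zero error
  e3 <- adjacent_error_vector(c(0, 0, 0), c(1, 0, 0), d_ij = NA,
                              d_min = 0.1, d_max = 2)
  expect_equal(e3, c(0, 0, 0))
  # above the band: target d_max
  e4 <- adjacent_error_vector(c(0, 0, 0), c(5, 0, 0), d_ij = 0.5,
                              d_min = 0.1, d_max = 2)
  expect_equal(e4, c(-3, 0, 0))
  # boundary tie goes to the middle branch
  e5 <- adjacent_error_vector(c(0, 0, 0), c(0.1, 0, 0), d_ij = 0.15,
                              d_min = 0.1, d_max = 2)
  expect_equal(e5, c(0.05, 0, 0))  # middle branch, target d_ij = 0.15
})

test_that("resultant field matches the scalar double-loop oracle", {
  cases <- expand.grid(n = c(3, 5, 17, 50), topo = c("circular", "linear"),
                       stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cases))) {
    n <- cases$n[k]
    topo <- cases$topo[k]
    m <- random_contact_matrix(n, seed = 100 + k)
    d <- if_to_distance(m)
    conf <- random_conformation(n, seed = 200 + k, topology = topo)
    cfg <- evr_config(d_min = 0.2, d_max = 8, weight = 1 / n,
                      topology = topo)
    field <- resultant_field(conf, d, cfg)
    ref <- oracle_resultant_field(coords(conf), d$values, d$defined,
                                  topo, 0.2, 8, 1 / n)
    expect_lt(max(abs(field$vectors - ref$vectors)), 1e-9)
    expect_equal(field$objective, ref$objective, tolerance = 1e-9)
    # the stored objective is the sum of resultant norms by definition
    expect_equal(field$objective, sum(sqrt(rowSums(field$vectors^2))))
  }
})

test_that("linear topology leaves the first/last pair non-adjacent", {
  n <- 5
  m <- random_contact_matrix(n, seed = 7, zero_frac = 0)
  d <- if_to_distance(m)
  conf_lin <- random_conformation(n, seed = 8, topology = "linear")
  cfg <- evr_config(d_min = 0.01, d_max = 100, topology = "linear")
  field <- resultant_field(conf_lin, d, cfg)
  # oracle with the (1, n) pair forced through the non-adjacent formula
  ref <- oracle_resultant_field(coords(conf_lin), d$values, d$defined,
                                "linear", 0.01, 100, 1 / n)
  expect_lt(max(abs(field$vectors - ref$vectors)), 1e-12)
  # under a band that clamps the first/last pair, only the topology flag
  # decides whether bins 1 and n feel the wraparound adjacency
  tight <- evr_config(d_min = 0.01, d_max = 0.02)
  conf_circ <- conformation(coords(conf_lin), topology = "circular")
  f_lin <- resultant_field(conf_lin, d, tight)
  f_circ <- resultant_field(conf_circ, d, tight)
  expect_equal(f_lin$vectors[2:(n - 1), ], f_circ$vectors[2:(n - 1), ])
  expect_gt(max(abs(f_circ$vectors[c(1, n), ] - f_lin$vectors[c(1, n), ])), 0)
})

test_that("a conformation realizing all distances is a fixed point", {
  conf <- random_conformation(20, seed = 5)
  m <- structure_to_if(conf)
  d <- if_to_distance(m)
  cfg <- evr_config()  # band resolved from data brackets true distances
  field <- resultant_field(conf, d, cfg)
  expect_lt(field$objective, 1e-10)
  moved <- evr_step(conf, field)
  expect_lt(max(abs(coords(moved) - coords(conf))), 1e-10)
})

test_that("the resultant field is equivariant under rigid motions", {
  n <- 15
  m <- random_contact_matrix(n, seed = 31)
  d <- if_to_distance(m)
  conf <- random_conformation(n, seed = 32)
  cfg <- evr_config(d_min = 0.2, d_max = 8)
  f0 <- resultant_field(conf, d, cfg)

  theta <- 0.7
  rot <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0),
               c(0, 0, 1))
  shift <- c(3, -2, 11)
  conf2 <- conformation(sweep(coords(conf) %*% t(rot), 2, shift, "+"))
  f1 <- resultant_field(conf2, d, cfg)
  expect_lt(max(abs(f1$vectors - f0$vectors %*% t(rot))), 1e-9)
  expect_equal(f1$objective, f0$objective, tolerance = 1e-9)
})

test_that("coincident bins get a finite, reproducible tie-break move", {
  p <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(0, 2, 0))
  conf <- conformation(p)
  m <- random_contact_matrix(4, seed = 77, zero_frac = 0)
  d <- if_to_distance(m)
  cfg <- evr_config(d_min = 0.1, d_max = 5, seed = 3)
  f1 <- resultant_field(conf, d, cfg, iter = 2L)
  f2 <- resultant_field(conf, d, cfg, iter = 2L)
  expect_true(all(is.finite(f1$vectors)))
  expect_identical(f1$vectors, f2$vectors)
  # a different iteration breaks the tie along a different direction
  f3 <- resultant_field(conf, d, cfg, iter = 3L)
  expect_false(identical(f1$vectors[1, ], f3$vectors[1, ]))
})

test_that("synchronous step moves every bin by its resultant", {
  conf <- random_conformation(6, seed = 9)
  zero <- structure(list(vectors = matrix(0, 6, 3), objective = 0),
                    class = "resultant_field")
  expect_identical(coords(evr_step(conf, zero)), coords(conf))
  fld <- zero
  fld$vectors[4, ] <- c(1, 0, 0)
  moved <- evr_step(conf, fld)
  expect_equal(coords(moved)[4, ], coords(conf)[4, ] + c(1, 0, 0),
               ignore_attr = TRUE)
  expect_equal(coords(moved)[-4, ], coords(conf)[-4, ], ignore_attr = TRUE)
})

test_that("a free bin approaches its sphere-constraint target over iterations", {
  # two-anchor toy: bins 1 and 2 satisfy their mutual distance exactly;
  # bin 3 starts away from the intersection of the two target spheres
  p <- rbind(c(0, 0, 0), c(4, 0, 0), c(6, 5, 0))
  d_vals <- matrix(NA_real_, 3, 3)
  d_vals[1, 2] <- d_vals[2, 1] <- 4
  d_vals[1, 3] <- d_vals[3, 1] <- 3
  d_vals[2, 3] <- d_vals[3, 2] <- 3
  d <- structure(list(values = d_vals, defined = !is.na(d_vals), alpha = 0.5),
                 class = "distance_matrix")
  cfg <- evr_config(d_min = 0.5, d_max = 10, weight = 1 / 3,
                    topology = "linear")
  conf <- conformation(p, topology = "linear")
  resid <- function(cf) {
    q <- coords(cf)
    sqrt((sqrt(sum((q[3, ] - q[1, ])^2)) - 3)^2 +
         (sqrt(sum((q[3, ] - q[2, ])^2)) - 3)^2)
  }
  r <- resid(conf)
  for (it in 1:10) {
    conf <- evr_step(conf, resultant_field(conf, d, cfg, iter = it))
    r_new <- resid(conf)
    expect_lt(r_new, r)
    r <- r_new
  }
})
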