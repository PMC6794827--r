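test_that("superposition recovers rigid motions and global scale exactly", {
  target <- toroidal_spiral(spiral_spec(n_bins = 30))
  rot90 <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  moved <- conformation(sweep(coords(target) %*% t(rot90), 2, c(1, -2, 3), "+"))
  aln <- superpose(moved, target)
  expect_lt(aln$rmsd, 1e-10)
  expect_equal(aln$scale, 1, tolerance = 1e-10)
  expect_false(aln$reflected)
  expect_equal(crossprod(aln$rotation), diag(3), tolerance = 1e-12)
  expect_equal(det(aln$rotation), 1, tolerance = 1e-12)

  doubled <- conformation(coords(target) * 2)
  aln2 <- superpose(doubled, target, allow_scaling = TRUE)
  expect_lt(aln2$rmsd, 1e-10)
  expect_equal(aln2$scale, 0.5, tolerance = 1e-10)

  # stored rmsd matches the rmsd of the stored transform
  check <- sqrt(mean(rowSums(
    (coords(apply_alignment(aln2, doubled)) - coords(target))^2)))
  expect_equal(check, aln2$rmsd, tolerance = 1e-10)
})

test_that("reflection branch resolves chirality mismatches", {
  set.seed(14)
  target <- conformation(matrix(rnorm(30), 10, 3))
  mirror <- conformation(coords(target) %*% diag(c(1, 1, -1)))
  no_ref <- superpose(mirror, target, allow_reflection = FALSE)
  with_ref <- superpose(mirror, target, allow_reflection = TRUE)
  expect_gt(no_ref$rmsd, 0.1)
  expect_lt(with_ref$rmsd, 1e-10)
  expect_true(with_ref$reflected)
  expect_equal(det(with_ref$rotation), 1, tolerance = 1e-12)
})

test_that("more transform freedoms never increase the RMSD", {
  set.seed(3)
  a <- conformation(matrix(rnorm(60), 20, 3))
  b <- conformation(matrix(rnorm(60), 20, 3))
  r_rigid <- superpose(a, b, allow_scaling = FALSE,
                       allow_reflection = FALSE)$rmsd
  r_scale <- superpose(a, b, allow_scaling = TRUE,
                       allow_reflection = FALSE)$rmsd
  r_all <- superpose(a, b, allow_scaling = TRUE,
                     allow_reflection = TRUE)$rmsd
  expect_lte(r_scale, r_rigid + 1e-12)
  expect_lte(r_all, r_scale + 1e-12)
})

test_that("scale-normalized superposition is symmetric between directions", {
  set.seed(8)
  a <- conformation(matrix(rnorm(45), 15, 3))
  b <- conformation(matrix(rnorm(45), 15, 3))
  ab <- superpose(a, b)
  ba <- superpose(b, a)
  # normalize by the target's size in each direction
  size <- function(conf) sqrt(mean(rowSums(
    sweep(coords(conf), 2, colMeans(coords(conf)))^2)))
  expect_equal(ab$rmsd / size(b), ba$rmsd / size(a), tolerance = 1e-8)
})

test_that("superposition agrees with vegan's Procrustes on proper cases", {
  library(vegan)
  set.seed(21)
  x <- matrix(rnorm(36), 12, 3)
  y <- matrix(rnorm(36), 12, 3)
  ours <- superpose(conformation(x), conformation(y),
                    allow_scaling = TRUE, allow_reflection = TRUE)
  ref <- vegan::procrustes(y, x, scale = TRUE, symmetric = FALSE)
  ref_rmsd <- sqrt(mean(rowSums((stats::fitted(ref) - y)^2)))
  expect_equal(ours$rmsd, ref_rmsd, tolerance = 1e-8)
})

test_that("superposition rejects mismatched or degenerate inputs", {
  a <- conformation(matrix(rnorm(30), 10, 3))
  b <- conformation(matrix(rnorm(15), 5, 3))
  expect_error(superpose(a, b), "different bin counts")
  line <- conformation(cbind(1:10, 0, 0))
  expect_error(superpose(a, line), "degenerate")
})

test_that("noise sweeps are reproducible tables with one row per level", {
  spec <- spiral_spec(n_bins = 30)
  cfg <- evr_config()
  s1 <- noise_sweep(spec, levels = c(0, 0.5), replicates = 2,
                    base_seed = 3, cfg = cfg)
  s2 <- noise_sweep(spec, levels = c(0, 0.5), replicates = 2,
                    base_seed = 3, cfg = cfg)
  expect_equal(nrow(s1), 2)
  expect_named(s1, c("level", "mean_rmsd", "sd_rmsd", "n"))
  expect_identical(s1$mean_rmsd, s2$mean_rmsd)
  expect_identical(s1$sd_rmsd, s2$sd_rmsd)
  runs <- attr(s1, "runs")
  expect_equal(nrow(runs), 4)
  expect_true(all(runs$rmsd >= 0))
  expect_s3_class(autoplot(s1), "ggplot")
})
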