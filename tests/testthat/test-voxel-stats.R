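flat_mask <- function(dim = c(6, 5, 4)) array(TRUE, dim)

gauss_maps <- function(n, dim, sd = 1, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) array(rnorm(prod(dim), sd = sd), dim))
}

test_that("paired test on identical conditions is identically zero", {
  m <- flat_mask()
  maps <- gauss_maps(6, dim(m), seed = 1)
  res <- paired_t_map(maps, maps, m, n_perm = 50, seed = 1)
  expect_true(all(res$stat[m] == 0))
  expect_equal(nrow(res$clusters), 0L)
})

test_that("paired t equals the closed-form statistic of the injected
          differences", {
  m <- flat_mask()
  n <- 6
  base <- gauss_maps(n, dim(m), seed = 2)
  delta <- c(0.8, 1.1, 0.9, 1.3, 0.7, 1.0)
  maps_a <- lapply(seq_len(n), function(i) {
    x <- base[[i]]
    x[3, 2, 2] <- x[3, 2, 2] + delta[i]
    x
  })
  res <- paired_t_map(maps_a, base, m, n_perm = 200, seed = 3)
  d <- delta  # the difference maps are exactly delta at the injected voxel
  want <- mean(d) / (sd(d) / sqrt(n))
  expect_equal(res$stat[3, 2, 2], want, tolerance = 1e-12)
  ## identity permutation is included: corrected p never drops below 1/n_perm
  expect_gte(min(res$p[m]), 1 / res$n_perm)
})

test_that("paired test rejects unpaired input and enumerates small samples", {
  m <- flat_mask()
  maps <- gauss_maps(4, dim(m), seed = 4)
  expect_error(paired_t_map(maps, maps[1:3], m), "unpaired")
  expect_error(paired_t_map(maps[1:2], maps[1:2], m), "at least 3")
  expect_message(paired_t_map(maps, gauss_maps(4, dim(m), seed = 5), m,
                              n_perm = 500, seed = 1), "fully enumerated")
})

test_that("maxT threshold grows as alpha shrinks", {
  m <- flat_mask()
  a <- gauss_maps(8, dim(m), seed = 6)
  b <- gauss_maps(8, dim(m), seed = 7)
  r1 <- paired_t_map(a, b, m, alpha = 0.05, n_perm = 300, seed = 11)
  r2 <- paired_t_map(a, b, m, alpha = 0.01, n_perm = 300, seed = 11)
  expect_gte(r2$threshold, r1$threshold)
  ## same seed, same result
  r3 <- paired_t_map(a, b, m, alpha = 0.05, n_perm = 300, seed = 11)
  expect_identical(r1$stat, r3$stat)
  expect_identical(r1$threshold, r3$threshold)
})

test_that("interaction statistic vanishes when groups share the change maps", {
  m <- flat_mask()
  one <- array(rnorm(prod(dim(m))), dim(m))
  maps <- rep(list(one), 10)
  res <- group_time_anova(maps, rep(c("training", "control"), each = 5), m,
                          n_perm = 60, var_fwhm = 0, seed = 1)
  expect_true(all(res$stat[m] == 0))
  expect_equal(nrow(res$clusters), 0L)
})

test_that("group relabelings are enumerated when few and the test is
          deterministic under a seed", {
  m <- flat_mask()
  maps <- gauss_maps(8, dim(m), seed = 8)
  g <- rep(c("training", "control"), each = 4)
  expect_message(res <- group_time_anova(maps, g, m, n_perm = 5000,
                                         var_fwhm = 0, seed = 2),
                 "fully enumerated")
  expect_equal(res$n_perm, choose(8, 4))
  expect_gte(min(res$p[m]), 1 / res$n_perm)
  expect_error(group_time_anova(maps, rep("training", 8), m), "two levels")
  expect_error(group_time_anova(maps[1:3], c("a", "a", "b"), m), "at least 2")
})

test_that("permutation p-values are uniform under an exchangeable null", {
  m <- flat_mask(c(5, 5, 3))
  pvals <- vapply(1:200, function(r) {
    maps <- gauss_maps(12, dim(m), seed = 5000 + r)
    res <- group_time_anova(maps, rep(c("training", "control"), each = 6), m,
                            n_perm = 199, var_fwhm = 0, seed = r)
    min(res$p[m])
  }, numeric(1))
  ## permutation p-values are discrete (multiples of 1/n_perm), so ties are
  ## expected; the KS comparison remains a conservative uniformity check
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("variance smoothing produces a pseudo-t that differs from the raw
          t but keeps the same sign pattern", {
  m <- flat_mask(c(8, 8, 4))
  maps <- gauss_maps(12, dim(m), seed = 13)
  g <- rep(c("training", "control"), each = 6)
  raw <- group_time_anova(maps, g, m, n_perm = 50, var_fwhm = 0, seed = 3)
  smo <- group_time_anova(maps, g, m, n_perm = 50, var_fwhm = 6,
                          voxel_size = 2, seed = 3)
  expect_false(isTRUE(all.equal(raw$stat[m], smo$stat[m])))
  expect_equal(sign(raw$stat[m]), sign(smo$stat[m]))
})

test_that("cluster extent rule: strictly more than five voxels survive", {
  d <- c(12, 6, 5)
  stat <- array(0, d)
  supra <- array(FALSE, d)
  ## isolated voxel
  supra[1, 1, 1] <- TRUE
  ## a 5-voxel line (dropped) and a 6-voxel line (kept)
  supra[3:7, 3, 2] <- TRUE
  supra[1:6, 5, 4] <- TRUE
  stat[supra] <- 1
  stat[2, 5, 4] <- 7  # peak of the 6-voxel component
  out <- cluster_filter(stat, supra, min_extent = 5)
  expect_equal(nrow(out), 1L)
  expect_equal(out$size, 6L)
  expect_equal(out$peak_stat, 7)
  expect_equal(c(out$peak_i, out$peak_j, out$peak_k), c(1, 4, 3))
  ## with min_extent 4 the 5-voxel line also survives
  out4 <- cluster_filter(stat, supra, min_extent = 4)
  expect_equal(sort(out4$size), c(5L, 6L))
})

test_that("component sizes match an independent graph-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(21)
  d <- c(8, 7, 6)
  supra <- array(runif(prod(d)) < 0.25, d)
  stat <- array(rnorm(prod(d)), d)
  for (conn in c(6L, 26L)) {
    got <- sort(cluster_filter(stat, supra, min_extent = 0,
                               connectivity = conn)$size, decreasing = TRUE)
    want <- oracle_components(supra, conn)
    expect_equal(as.integer(got), as.integer(want))
  }
})

test_that("cluster peaks are reported in both voxel and world coordinates", {
  d <- c(6, 6, 4)
  stat <- array(0, d); supra <- array(FALSE, d)
  supra[2:4, 2:4, 2] <- TRUE
  stat[supra] <- seq_len(sum(supra))
  aff <- lssrm:::phantom_affine(c(1.5, 1.5, 1.5))
  out <- cluster_filter(stat, supra, min_extent = 5, affine = aff)
  expect_equal(nrow(out), 1L)
  expect_equal(out$peak_x, (out$peak_i + 0.5) * 1.5)
  expect_equal(out$peak_z, (out$peak_k + 0.5) * 1.5)
})
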