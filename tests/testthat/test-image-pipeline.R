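make_mask <- function(dim = c(9, 8, 7)) {
  set.seed(31)
  m <- array(FALSE, dim)
  m[2:8, 2:7, 2:6] <- TRUE
  ## carve an irregular boundary
  m[sample(which(m), 40)] <- FALSE
  m
}

test_that("masked smoothing preserves constants and ignores outside voxels", {
  m <- make_mask()
  img <- array(rnorm(prod(dim(m)), sd = 100), dim(m))
  img[m] <- 5
  out <- masked_gaussian_smooth(img, m, fwhm = 6, voxel_size = 2)
  expect_equal(out[m], rep(5, sum(m)))
  expect_true(all(is.nan(out[!m])))
})

test_that("fwhm = 0 is the identity inside the mask", {
  m <- make_mask()
  img <- array(rnorm(prod(dim(m))), dim(m))
  out <- masked_gaussian_smooth(img, m, fwhm = 0)
  expect_identical(out[m], img[m])
  expect_true(all(is.nan(out[!m])))
})

test_that("masked smoothing equals the brute-force normalized-convolution
          oracle", {
  m <- make_mask()
  set.seed(5)
  img <- array(rnorm(prod(dim(m))), dim(m))
  for (fwhm in c(3, 10)) {
    got <- masked_gaussian_smooth(img, m, fwhm, voxel_size = c(2, 2.5, 2))
    want <- oracle_masked_smooth(img, m, fwhm, voxel_size = c(2, 2.5, 2))
    expect_lt(max(abs(got[m] - want[m])), 1e-10)
  }
})

test_that("smoothing never propagates information across the mask boundary", {
  m <- make_mask()
  set.seed(6)
  img <- array(rnorm(prod(dim(m))), dim(m))
  base <- masked_gaussian_smooth(img, m, 8, voxel_size = 2)
  poked <- img
  poked[!m] <- 1e9
  alt <- masked_gaussian_smooth(poked, m, 8, voxel_size = 2)
  expect_identical(base[m], alt[m])
  nanpoked <- img; nanpoked[!m] <- NaN
  alt2 <- masked_gaussian_smooth(nanpoked, m, 8, voxel_size = 2)
  expect_identical(base[m], alt2[m])
})

test_that("4D input is smoothed frame by frame and empty masks error", {
  m <- make_mask()
  set.seed(7)
  img4 <- array(rnorm(prod(dim(m)) * 3), c(dim(m), 3))
  out <- masked_gaussian_smooth(img4, m, 5, voxel_size = 2)
  for (k in 1:3)
    expect_equal(out[, , , k],
                 masked_gaussian_smooth(img4[, , , k], m, 5, voxel_size = 2))
  expect_error(masked_gaussian_smooth(img4, array(FALSE, dim(m)), 5), "empty")
})

test_that("masked-vector smoother matches the array smoother", {
  m <- make_mask()
  set.seed(8)
  img <- array(rnorm(prod(dim(m))), dim(m))
  sm <- lssrm:::make_masked_smoother(m, 7, c(2, 2, 2))
  got <- sm(img[which(m)])
  want <- masked_gaussian_smooth(img, m, 7, voxel_size = 2)[which(m)]
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("motion screening counts split frames and flags heavy sessions", {
  sched <- default_frame_schedule()
  quiet <- simulate_motion_trace(duration_s = 4794, base_amplitude = 1.0,
                                 seed = 2)
  s <- screen_motion(quiet, sched)
  expect_equal(s$extra_subframes, 0L)
  expect_false(s$excluded)
  expect_lt(s$max_excursion, 2.5)
  ## one 3-mm spike inside a single frame -> exactly one extra subframe
  spike <- simulate_motion_trace(duration_s = 4794, base_amplitude = 0,
                                 spike_times = 660, spike_amplitude = 3,
                                 seed = 2)
  s1 <- screen_motion(spike, sched)
  expect_equal(s1$extra_subframes, 1L)
  expect_false(s1$excluded)
  ## many spiking frames exceed the tolerated count and flag the session
  wild <- simulate_motion_trace(duration_s = 4794, base_amplitude = 0,
                                spike_times = c(300, 900, 1500, 2100, 2700),
                                spike_amplitude = 4, seed = 2)
  expect_true(screen_motion(wild, sched)$excluded)
  ## trace must cover the scan
  expect_error(screen_motion(quiet[1:100, ], sched), "shorter")
})

test_that("cohort motion report prints the clean-session percentage", {
  sched <- default_frame_schedule()
  mk <- function(n, spike) replicate(n, screen_motion(
    simulate_motion_trace(duration_s = 4794, base_amplitude = 0.5,
                          spike_times = if (spike) 1000 else numeric(),
                          spike_amplitude = 4, seed = sample.int(1e6, 1)),
    sched), simplify = FALSE)
  set.seed(99)
  screens <- c(mk(89, FALSE), mk(17, TRUE))
  rep <- motion_cohort_report(screens)
  expect_equal(rep$n_sessions, 106L)
  expect_equal(rep$n_clean, 89L)
  expect_equal(rep$clean_percent, 84)
  expect_output(print(rep), "84% (89/106)", fixed = TRUE)
})

test_that("region TAC extraction equals the brute-force mean", {
  spec <- small_spec()
  set.seed(12)
  img <- array(rnorm(prod(spec$dim) * 20, mean = 10), c(spec$dim, 20))
  got <- extract_region_tac(img, spec$reference, spec$schedule)
  idx <- which(spec$reference)
  want <- vapply(1:20, function(k) {
    fr <- img[, , , k]
    mean(fr[idx])
  }, numeric(1))
  expect_equal(got$values, want)
  ## single-voxel mask returns that voxel's TAC
  m1 <- array(FALSE, spec$dim); m1[7, 7, 7] <- TRUE
  expect_equal(extract_region_tac(img, m1, spec$schedule)$values,
               img[7, 7, 7, ])
  ## uniform image: any mask gives the same TAC
  u <- array(3, c(spec$dim, 20))
  expect_equal(extract_region_tac(u, spec$striatum, spec$schedule)$values,
               rep(3, 20))
  expect_error(extract_region_tac(img, array(FALSE, spec$dim),
                                  spec$schedule), "empty")
})

test_that("noise-free voxelwise fit recovers analytic binding potentials and
          confines the effect to the blob", {
  spec <- small_spec(noise_scale = 0)
  scan <- simulate_phantom_scan(spec, "training", "post", "letter_memory",
                                seed = 1)
  ref <- extract_region_tac(scan$img, spec$reference, spec$schedule)
  fit <- fit_voxelwise(scan$img, ref, spec$striatum, spec$profile)
  expect_equal(fit$flagged_fraction, 0)
  p <- spec$striatum_params
  bp0_true <- p$k2 / p$k2a - 1
  expect_equal(unname(fit$bp0$data[spec$striatum]),
               rep(bp0_true, sum(spec$striatum)), tolerance = 0.01)
  ## delta-BP change is strictly negative in the blob, identical elsewhere
  d <- fit$delta$data
  expect_true(all(d[spec$effect] < -0.2))
  outside <- spec$striatum & !spec$effect
  pre <- simulate_phantom_scan(spec, "training", "pre", "letter_memory",
                               seed = 1)
  fit_pre <- fit_voxelwise(pre$img,
                           extract_region_tac(pre$img, spec$reference,
                                               spec$schedule),
                           spec$striatum, spec$profile)
  chg <- d - fit_pre$delta$data
  expect_lt(max(abs(chg[outside])), 1e-10)
  expect_true(all(chg[spec$effect] < -0.1))
  ## the delta map is exactly BP1 - BP0
  expect_equal(fit$delta$data[spec$striatum],
               fit$bp1$data[spec$striatum] - fit$bp0$data[spec$striatum])
})

test_that("voxelwise fit handles single-voxel masks and flags bad voxels", {
  spec <- small_spec(noise_scale = 0)
  scan <- simulate_phantom_scan(spec, "control", "pre", "letter_memory",
                                seed = 2)
  ref <- extract_region_tac(scan$img, spec$reference, spec$schedule)
  m1 <- array(FALSE, spec$dim)
  m1[which(spec$striatum)[1]] <- TRUE
  fit1 <- fit_voxelwise(scan$img, ref, m1, spec$profile)
  expect_equal(sum(is.finite(fit1$bp0$data)), 1L)
  ## a voxel with corrupt data is flagged, not fatal
  img <- scan$img
  bad <- which(spec$striatum)[3]
  img[bad + prod(spec$dim) * (0:19)] <- NaN
  fit2 <- fit_voxelwise(img, ref, spec$striatum, spec$profile)
  expect_gt(fit2$flagged_fraction, 0)
  expect_true(is.na(fit2$bp0$data[bad]))
  ## an all-zero image cannot be fit anywhere
  expect_error(fit_voxelwise(array(0, c(spec$dim, 20)),
                             tac(spec$schedule, rep(1, 20), "reference"),
                             spec$striatum, spec$profile), "all in-mask")
})

test_that("schedule JSON sidecars round-trip", {
  s <- default_frame_schedule()
  path <- withr::local_tempfile(fileext = ".json")
  write_schedule_json(s, path)
  s2 <- read_schedule_json(path)
  expect_equal(s2$start, s$start)
  expect_equal(s2$duration, s$duration)
})
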