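ref_default <- simulate_reference_tac()
prof_default <- activation_profile()

test_that("forward simulation: zero input gives zero output", {
  sched <- default_frame_schedule()
  zero <- tac(sched, rep(0, 20), role = "reference")
  ct <- simulate_target_tac(zero, kinetic_params(1, 0.3, 0.1, 0.02))
  expect_equal(ct$values, rep(0, 20))
})

test_that("forward simulation: BP0 = 0 tracks the reference at equilibrium", {
  ct <- simulate_target_tac(ref_default, kinetic_params(1, 0.3, 0.3, 0))
  late <- 17:20
  expect_equal(ct$values[late], ref_default$values[late], tolerance = 2e-3)
})

test_that("forward simulation agrees with an independent stiff ODE solver", {
  skip_if_not_installed("deSolve")
  prof <- prof_default
  params <- kinetic_params(1.0, 0.3, 0.1, 0.02)
  ct <- simulate_target_tac(ref_default, params, prof)
  ## independent solve of the same ODE with the same interpolated forcing
  crf <- approxfun(c(0, ref_default$schedule$mid),
                   c(0, ref_default$values), rule = 2)
  eps <- 1e-4
  dcrf <- function(t) (crf(t + eps) - crf(pmax(t - eps, 0))) /
    (t + eps - pmax(t - eps, 0))
  rhs <- function(t, y, p)
    list(p$r1 * dcrf(t) + p$k2 * crf(t) -
           (p$k2a + p$gamma * gamma_variate(t, prof)) * y)
  fine <- seq(0, 79.9, by = 1 / 60)
  sol <- deSolve::lsoda(c(ct = 0), fine, rhs, params,
                        rtol = 1e-10, atol = 1e-10)
  frames <- vapply(seq_len(20), function(i) {
    s <- ref_default$schedule
    i0 <- round(s$start[i] * 60) + 1
    i1 <- round((s$start[i] + s$duration[i]) * 60) + 1
    pracma::trapz(fine[i0:i1], sol[i0:i1, 2]) / s$duration[i]
  }, numeric(1))
  expect_equal(ct$values, frames, tolerance = 1e-3)
  ## a positive activation weight lowers the late-scan signal
  ct0 <- simulate_target_tac(ref_default, kinetic_params(1, 0.3, 0.1, 0), prof)
  expect_true(all(ct$values[18:20] < ct0$values[18:20]))
  expect_equal(ct$values[1:13], ct0$values[1:13], tolerance = 1e-10)
})

test_that("non-positive k2a warns about the unbounded horizon", {
  expect_warning(simulate_target_tac(ref_default, kinetic_params(1, 0.3, 0, 0)),
                 "unbounded")
})

test_that("design matrix: degenerate cases", {
  ct <- simulate_target_tac(ref_default, kinetic_params(1, 0.3, 0.1, 0.01))
  ## activation entirely after the scan: fourth column vanishes
  late_prof <- activation_profile(onset = 200, window_end = 240)
  X <- build_design_matrix(ct, ref_default, late_prof)
  expect_equal(unname(X[, 4]), rep(0, 20))
  ## constant reference: cumulative integral is ~ c * t at the frame level
  sched <- default_frame_schedule()
  cref <- tac(sched, rep(7, 20), role = "reference")
  Xc <- build_design_matrix(cref, cref, prof_default)
  expect_equal(unname(Xc[2:20, 2]), 7 * sched$mid[2:20], tolerance = 0.03)
  ## under-determined schedules are refused
  s4 <- frame_schedule(c(0, 2, 4, 6), rep(2, 4))
  t4 <- tac(s4, rep(1, 4)); r4 <- tac(s4, rep(1, 4), role = "reference")
  expect_error(build_design_matrix(t4, r4), "at least 5 frames")
  ## mismatched schedules are refused
  s5 <- frame_schedule(c(0, 2, 4, 6, 8), rep(2, 5))
  expect_error(
    build_design_matrix(tac(s5, rep(1, 5)), ref_default), "share")
})

test_that("design-matrix integrals agree with fine-grid quadrature of the
          true curves to < 0.5%", {
  prof <- prof_default
  params <- kinetic_params(1.0, 0.3, 0.1, 0.02)
  ct <- simulate_target_tac(ref_default, params, prof,
                            ref_fun = reference_curve())
  X <- build_design_matrix(ct, ref_default, prof)
  ## oracle: 1-s quadrature of the analytic reference curve and of the
  ## densely simulated target, averaged per frame
  sched <- ref_default$schedule
  fine <- seq(0, 79.9, by = 1 / 60)
  crf <- reference_curve()
  crfine <- crf(fine)
  half <- seq(0, 79.9, by = 1 / 120)
  y <- lssrm:::rk4_target(crf(half), lssrm:::grid_gradient(crf(half), 1 / 120),
                          gamma_variate(half, prof), 1 / 60,
                          matrix(unlist(params), 4, 1))[, 1]
  frame_avg_cumint <- function(v) {
    I <- pracma::cumtrapz(fine, v)
    vapply(seq_len(20), function(i) {
      i0 <- round(sched$start[i] * 60) + 1
      i1 <- round((sched$start[i] + sched$duration[i]) * 60) + 1
      pracma::trapz(fine[i0:i1], I[i0:i1]) / sched$duration[i]
    }, numeric(1))
  }
  o2 <- frame_avg_cumint(crfine)
  o3 <- -frame_avg_cumint(y)
  o4 <- -frame_avg_cumint(y * gamma_variate(fine, prof))
  expect_lt(max(abs(X[, 2] - o2)) / max(abs(o2)), 0.005)
  expect_lt(max(abs(X[, 3] - o3)) / max(abs(o3)), 0.005)
  expect_lt(max(abs(X[, 4] - o4)) / max(abs(o4)), 0.005)
})

test_that("noise-free simulate-then-fit recovers the parameters within 1%", {
  prof <- prof_default
  crf <- reference_curve()
  truth <- kinetic_params(1.0, 0.3, 0.1, 0.02)
  ct <- simulate_target_tac(ref_default, truth, prof, ref_fun = crf)
  fit <- fit_lssrm(ct, ref_default, prof)
  got <- unlist(fit$params)
  expect_equal(unname(got), unname(unlist(truth)), tolerance = 0.01)
  expect_lt(fit$rss, 0.1)
  expect_true(is.finite(fit$cond))
  ## duration weighting changes the estimator but not the answer materially
  fw <- fit_lssrm(ct, ref_default, prof,
                  weights = ref_default$schedule$duration)
  expect_equal(unname(unlist(fw$params)), unname(unlist(truth)),
               tolerance = 0.01)
})

test_that("model nesting: gamma = 0 data give the 3-parameter SRTM fit", {
  prof <- prof_default
  ct <- simulate_target_tac(ref_default, kinetic_params(1.1, 0.25, 0.08, 0),
                            prof, ref_fun = reference_curve())
  f4 <- fit_lssrm(ct, ref_default, prof)
  f3 <- fit_lssrm(ct, ref_default, prof, fit_activation = FALSE)
  expect_lt(abs(f4$params$gamma), 1e-4)
  expect_equal(unlist(f4$params)[1:3], unlist(f3$params)[1:3],
               tolerance = 1e-3)
  expect_equal(f3$params$gamma, 0)
  ## fitting with the activation column dropped is the exact 3-column LS
  X <- build_design_matrix(ct, ref_default, prof)[, 1:3]
  beta <- qr.coef(qr(X), ct$values)
  expect_equal(unname(unlist(f3$params)[1:3]), unname(beta),
               tolerance = 1e-10)
})

test_that("a curve with no specific binding (k2 = k2a) recovers BP0 = 0", {
  ## note R1 != 1: with R1 = 1 and k2 = k2a the target is identical to the
  ## reference, so the integral columns are exactly collinear and the fit is
  ## (correctly) refused as rank-deficient
  ct <- simulate_target_tac(ref_default, kinetic_params(0.9, 0.3, 0.3, 0),
                            ref_fun = reference_curve())
  fit <- fit_lssrm(ct, ref_default, prof_default)
  expect_equal(bp_baseline(fit$params), 0, tolerance = 0.01)
  ## and the degenerate identical-curve case is reported as collinear
  cteq <- simulate_target_tac(ref_default, kinetic_params(1, 0.3, 0.3, 0),
                              ref_fun = reference_curve())
  expect_error(fit_lssrm(cteq, ref_default, prof_default), "collinear")
})

test_that("degenerate fits fail loudly", {
  sched <- default_frame_schedule()
  ## a zero reference cannot be fit
  zero <- tac(sched, rep(0, 20), role = "reference")
  tgt <- tac(sched, rep(0, 20))
  expect_error(fit_lssrm(tgt, zero, prof_default), "identically zero")
  ## target == scaled reference with no activation makes columns 3 and 4
  ## proportional once h has no support -> rank-deficient, named
  cref <- tac(sched, rep(3, 20), role = "reference")
  ctgt <- tac(sched, rep(3, 20))
  late_prof <- activation_profile(onset = 200, window_end = 240)
  expect_error(fit_lssrm(ctgt, cref, late_prof), "collinear")
})

test_that("binding potentials follow the SRTM relations", {
  expect_equal(bp_baseline(kinetic_params(0.36 / 0.12, 0.36, 0.12)), 2)
  expect_equal(bp_baseline(kinetic_params(1, 0.2, 0.2)), 0)
  expect_true(is.na(bp_baseline(kinetic_params(1, 0.3, -0.1))))
  set.seed(42)
  for (i in 1:25) {
    k2 <- runif(1, 0.05, 0.6); k2a <- runif(1, 0.02, 0.4)
    expect_equal(bp_baseline(kinetic_params(1, k2, k2a)), k2 / k2a - 1)
  }
})

test_that("activation BP: gamma = 0 reduces exactly to BP0; displacement
          lowers binding", {
  prof <- prof_default
  p0 <- kinetic_params(1, 0.3, 0.1, 0)
  expect_identical(bp_activation(p0, prof), bp_baseline(p0))
  expect_identical(bp_activation(p0, prof, method = "pointwise"),
                   bp_baseline(p0))
  set.seed(7)
  for (i in 1:25) {
    g <- runif(1, 1e-4, 0.05) * sample(c(-1, 1), 1)
    p <- kinetic_params(1, 0.3, 0.1, g)
    b <- binding_potentials(p, prof)
    expect_equal(b$delta, b$bp1 - b$bp0)
    if (g > 0) expect_lt(b$delta, 0) else expect_gt(b$delta, 0)
  }
  ## non-positive averaged efflux is flagged, not raised
  expect_true(is.na(bp_activation(kinetic_params(1, 0.3, 0.01, -0.1), prof)))
})

test_that("rate and pointwise activation averaging agree for small gamma", {
  prof <- prof_default
  p <- kinetic_params(1, 0.3, 0.1, 0.01)
  expect_equal(bp_activation(p, prof, method = "pointwise"),
               bp_activation(p, prof, method = "rate"), tolerance = 0.02)
})
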