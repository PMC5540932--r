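#' Bolus-plus-infusion input-function parameters
#'
#' Parameters of the phenomenological reference-region curve for a
#' bolus-plus-infusion administration: a bolus component
#' A (exp(-beta t) - exp(-beta_uptake t)) -- continuous at injection, early
#' peak, washed out -- plus an approach-to-plateau infusion component
#' P (1 - exp(-alpha t)). The bolus amplitude A is set so that the curve
#' peaks at `bolus_peak_ratio` times the plateau, the modest overshoot of a
#' well-calibrated bolus-plus-infusion protocol. `bolus_fraction` and `kbol`
#' (the minutes of infusion to which the bolus is equivalent; the default
#' f = 0.5, Kbol = 80 min describes half the tracer given as bolus over an
#' 80-min infusion) are protocol metadata recorded with generated data.
#'
#' @param bolus_fraction fraction of the total dose given as bolus, in (0, 1).
#' @param kbol minutes of infusion to which the bolus is equivalent.
#' @param plateau_level kBq/mL, the equilibrium level of the reference curve.
#' @param alpha infusion approach rate, 1/min.
#' @param beta bolus washout rate, 1/min.
#' @param bolus_uptake bolus tissue uptake rate, 1/min (> beta).
#' @param bolus_peak_ratio peak-to-plateau ratio of the full curve.
#' @return An object of class `input_function_params`.
#' @export
input_function_params <- function(bolus_fraction = 0.5, kbol = 80,
                                  plateau_level = 30, alpha = 0.12,
                                  beta = 0.15, bolus_uptake = 0.6,
                                  bolus_peak_ratio = 1.5) {
  if (!(bolus_fraction > 0 && bolus_fraction < 1))
    stop("'bolus_fraction' must be in (0, 1)")
  if (kbol <= 0) stop("'kbol' must be > 0")
  if (plateau_level < 0) stop("'plateau_level' must be >= 0")
  if (alpha <= 0 || beta <= 0) stop("washout rates must be > 0")
  if (bolus_uptake <= beta) stop("'bolus_uptake' must exceed 'beta'")
  if (bolus_peak_ratio < 1) stop("'bolus_peak_ratio' must be >= 1")
  structure(list(bolus_fraction = bolus_fraction, kbol = kbol,
                 plateau_level = plateau_level, alpha = alpha, beta = beta,
                 bolus_uptake = bolus_uptake,
                 bolus_peak_ratio = bolus_peak_ratio),
            class = "input_function_params")
}

#' Continuous reference-region curve
#'
#' @param params [input_function_params()].
#' @return A function of time (min) returning activity (kBq/mL).
#' @export
reference_curve <- function(params = input_function_params()) {
  stopifnot(inherits(params, "input_function_params"))
  P <- params$plateau_level
  alpha <- params$alpha; beta <- params$beta; bu <- params$bolus_uptake
  base <- function(t, A) A * (exp(-beta * t) - exp(-bu * t)) +
    P * (1 - exp(-alpha * t))
  if (P == 0) return(function(t) 0 * t)
  tprobe <- seq(0, 20, by = 0.01)
  A <- if (params$bolus_peak_ratio > 1)
    stats::uniroot(function(a) max(base(tprobe, a)) -
                     params$bolus_peak_ratio * P,
                   c(0, 1e4 * P))$root
  else 0
  function(t) base(t, A)
}

#' Simulate a reference-region TAC
#'
#' Frame averages of the continuous bolus-plus-infusion curve, optionally with
#' additive Gaussian noise of standard deviation
#' `noise_scale * sqrt(value / frame_duration)`.
#'
#' @param params [input_function_params()].
#' @param schedule a [frame_schedule()].
#' @param seed integer seed (only used when `noise_scale > 0`).
#' @param noise_scale noise magnitude; 0 (default) gives the noise-free curve.
#' @return A reference [tac()].
#' @export
simulate_reference_tac <- function(params = input_function_params(),
                                   schedule = default_frame_schedule(),
                                   seed = NULL, noise_scale = 0) {
  crf <- reference_curve(params)
  dt <- 1 / 60
  tgrid <- fine_grid(schedule, dt)
  y <- matrix(crf(tgrid), ncol = 1L)
  vals <- bin_to_frames(y, dt, schedule)[, 1L]
  if (noise_scale > 0) {
    if (!is.null(seed)) set.seed(seed)
    vals <- vals + stats::rnorm(length(vals),
                                sd = noise_scale *
                                  sqrt(pmax(vals, 0) / schedule$duration))
  }
  tac(schedule, vals, role = "reference")
}

## ---- phantom geometry ----------------------------------------------------

## Logical 3D array marking voxels inside an axis-aligned ellipsoid given in
## world (mm) coordinates; voxel centers at (ijk - 0.5) * voxel_size with
## 1-based ijk, i.e. world = affine %*% (ijk0 + 0.5) for 0-based indices.
ellipsoid_mask <- function(dim, voxel_size, center, radii) {
  cx <- (seq_len(dim[1]) - 0.5) * voxel_size[1]
  cy <- (seq_len(dim[2]) - 0.5) * voxel_size[2]
  cz <- (seq_len(dim[3]) - 0.5) * voxel_size[3]
  dx2 <- ((cx - center[1]) / radii[1])^2
  dy2 <- ((cy - center[2]) / radii[2])^2
  dz2 <- ((cz - center[3]) / radii[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

phantom_affine <- function(voxel_size) {
  a <- diag(c(voxel_size, 1))
  ## voxel centers: world = (ijk0 + 0.5) * voxel_size for 0-based ijk0
  a[1:3, 4] <- voxel_size / 2
  a
}

#' Phantom specification
#'
#' Geometry, true kinetic parameters and noise model of a synthetic dynamic
#' PET phantom. The default grid (40 x 32 x 32 voxels of 1.5 mm) holds a
#' striatal ellipsoid of about 2934 voxels (~10 cm^3), matching the size of
#' the striatal search volume the analysis is restricted to, a disjoint
#' reference-region sphere, and an effect sub-region of ~200 voxels inside
#' the striatum where the activation weight gamma is incremented for
#' trained-group post-training sessions (the training-induced increase in
#' dopamine release).
#'
#' @param dim integer length-3 grid size (voxels).
#' @param voxel_size voxel edge length, mm (isotropic scalar or length 3).
#' @param striatum_center,striatum_radii ellipsoid spec of the striatal
#'   search mask, mm.
#' @param reference_center,reference_radii ellipsoid spec of the reference
#'   region, mm; must be disjoint from the striatal mask.
#' @param effect_center,effect_radii ellipsoid spec of the training-effect
#'   blob; its intersection with the striatal mask is the effect region.
#' @param striatum_params baseline [kinetic_params()] of striatal tissue
#'   (gamma component ignored; task gammas come from `gamma_base`).
#' @param gamma_base named list of task-induced activation weights (1/min)
#'   per task, applied striatum-wide during every scan of that task.
#' @param gamma_effect increment of gamma (1/min) inside the effect region
#'   for training-group post-training sessions.
#' @param noise_scale additive Gaussian noise magnitude; per-frame standard
#'   deviation is `noise_scale * sqrt(value / frame_duration)`.
#' @param input_params [input_function_params()] of the reference curve.
#' @param schedule a [frame_schedule()].
#' @param profile an [activation_profile()].
#' @return An object of class `phantom_spec` carrying the computed masks.
#' @export
phantom_spec <- function(dim = c(40L, 32L, 32L), voxel_size = 1.5,
                         striatum_center = c(30, 24, 30),
                         striatum_radii = c(20, 14, 8.5),
                         reference_center = c(30, 24, 9),
                         reference_radii = c(7.5, 7.5, 7.5),
                         effect_center = c(21, 24, 30),
                         effect_radii = c(7, 5.5, 4.5),
                         striatum_params = kinetic_params(1.0, 0.3, 0.1),
                         gamma_base = list(letter_memory = 0.010,
                                           nback = 0.008),
                         gamma_effect = 0.015,
                         noise_scale = 1,
                         input_params = input_function_params(),
                         schedule = default_frame_schedule(),
                         profile = activation_profile()) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(dim) == 3L, all(dim >= 1), length(voxel_size) == 3L,
            all(voxel_size > 0), noise_scale >= 0, gamma_effect >= 0)
  striatum <- ellipsoid_mask(dim, voxel_size, striatum_center, striatum_radii)
  reference <- ellipsoid_mask(dim, voxel_size, reference_center,
                              reference_radii)
  if (any(striatum & reference))
    stop("striatal and reference masks overlap")
  if (!any(striatum)) stop("empty striatal mask")
  if (!any(reference)) stop("empty reference mask")
  effect <- ellipsoid_mask(dim, voxel_size, effect_center, effect_radii) &
    striatum
  structure(list(dim = as.integer(dim), voxel_size = voxel_size,
                 affine = phantom_affine(voxel_size),
                 striatum = striatum, reference = reference, effect = effect,
                 striatum_params = striatum_params, gamma_base = gamma_base,
                 gamma_effect = gamma_effect, noise_scale = noise_scale,
                 input_params = input_params, schedule = schedule,
                 profile = profile),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "Phantom: %s grid, %.3g mm voxels; striatum %d vox, reference %d vox, effect %d vox\n",
    paste(x$dim, collapse = "x"), x$voxel_size[1],
    sum(x$striatum), sum(x$reference), sum(x$effect)))
  invisible(x)
}

## Noise-free truth curves for one task under a phantom spec; returns a list
## with the reference TAC and the striatal / effect-region target TACs.
## Computed through the same forward path as simulate_target_tac().
phantom_truth <- function(spec, task, with_effect) {
  ref <- simulate_reference_tac(spec$input_params, spec$schedule)
  crf <- reference_curve(spec$input_params)
  g0 <- spec$gamma_base[[task]]
  if (is.null(g0)) stop("no gamma_base entry for task '", task, "'")
  p <- spec$striatum_params
  base <- simulate_target_tac(ref, kinetic_params(p$r1, p$k2, p$k2a, g0),
                              spec$profile, ref_fun = crf)
  eff <- if (with_effect && spec$gamma_effect > 0)
    simulate_target_tac(
      ref, kinetic_params(p$r1, p$k2, p$k2a, g0 + spec$gamma_effect),
      spec$profile, ref_fun = crf)
  else base
  list(reference = ref, striatum = base, effect = eff)
}

#' Simulate one phantom scan
#'
#' Builds a 4D dynamic image for one session. Striatal voxels follow the
#' forward-simulated target TAC for the session's activation weight (with the
#' gamma increment inside the effect region for training-group post-training
#' sessions), reference-mask voxels follow the reference curve, background is
#' zero, and additive Gaussian noise with variance proportional to
#' signal / frame duration is applied inside the masks. Deterministic under
#' `seed`.
#'
#' @param spec a [phantom_spec()].
#' @param group `"training"` or `"control"`.
#' @param time `"pre"` or `"post"`.
#' @param task a name present in `spec$gamma_base`.
#' @param seed integer seed.
#' @param truth optional precomputed result of the internal truth-curve
#'   generator (used by cohort drivers to avoid recomputation).
#' @return A list of class `phantom_scan`: `img` (4D array), `affine`,
#'   `schedule`, masks, `motion` trace, session metadata and the noise-free
#'   `truth` curves.
#' @export
simulate_phantom_scan <- function(spec, group = c("training", "control"),
                                  time = c("pre", "post"), task = "letter_memory",
                                  seed = 1L, truth = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  group <- match.arg(group)
  time <- match.arg(time)
  with_effect <- group == "training" && time == "post"
  if (is.null(truth)) truth <- phantom_truth(spec, task, with_effect)
  set.seed(seed)
  nf <- n_frames(spec$schedule)
  img <- array(0, c(spec$dim, nf))
  nvox <- prod(spec$dim)
  stri <- which(spec$striatum & !spec$effect)
  effv <- which(spec$effect)
  refv <- which(spec$reference)
  for (k in seq_len(nf)) {
    off <- (k - 1L) * nvox
    img[off + stri] <- truth$striatum$values[k]
    img[off + effv] <- (if (with_effect) truth$effect else truth$striatum)$values[k]
    img[off + refv] <- truth$reference$values[k]
  }
  if (spec$noise_scale > 0) {
    inmask <- which(spec$striatum | spec$reference)
    for (k in seq_len(nf)) {
      off <- (k - 1L) * nvox
      v <- img[off + inmask]
      img[off + inmask] <- v + stats::rnorm(
        length(v), sd = spec$noise_scale *
          sqrt(pmax(v, 0) / spec$schedule$duration[k]))
    }
  }
  motion <- simulate_motion_trace(duration_s = round(spec$schedule$end * 60),
                                  seed = seed + 104729L)
  structure(list(img = img, affine = spec$affine, schedule = spec$schedule,
                 striatum = spec$striatum, reference = spec$reference,
                 effect = spec$effect, motion = motion,
                 session = list(group = group, time = time, task = task,
                                seed = seed),
                 truth = truth),
            class = "phantom_scan")
}

#' Cohort design
#'
#' Two groups (training, control) measured pre and post intervention on the
#' in-scanner tasks; behavioral score distributions default to the printed
#' group means and SDs of the letter-memory criterion task and the 3-back
#' transfer task.
#'
#' @param n_training,n_control subjects per group (default 14 + 14).
#' @param tasks character vector of task names.
#' @param behavior named list (per task) of lists with `training` and
#'   `control` entries, each `c(pre_mean, pre_sd, post_mean, post_sd)`.
#' @param correlation pre--post score correlation used by
#'   [simulate_behavior()] (default 0.5).
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_training = 14L, n_control = 14L,
                          tasks = c("letter_memory", "nback"),
                          behavior = list(
                            letter_memory = list(
                              training = c(51.54, 11.63, 83.33, 31.67),
                              control = c(47.57, 12.87, 56.28, 17.01)),
                            nback = list(
                              training = c(74.53, 18.24, 86.12, 14.51),
                              control = c(79.44, 20.66, 91.10, 7.30))),
                          correlation = 0.5) {
  if (n_training < 2L || n_control < 2L) stop("group sizes must be >= 2")
  if (abs(correlation) > 1) stop("'correlation' must be in [-1, 1]")
  for (task in tasks) {
    b <- behavior[[task]]
    if (is.null(b) || !all(c("training", "control") %in% names(b)))
      stop("behavior parameters missing for task '", task, "'")
    for (g in c("training", "control")) {
      if (length(b[[g]]) != 4L) stop("behavior entries must have 4 values")
      if (b[[g]][2] < 0 || b[[g]][4] < 0)
        stop("behavioral SDs must be non-negative")
    }
  }
  structure(list(n_training = as.integer(n_training),
                 n_control = as.integer(n_control),
                 tasks = tasks, behavior = behavior,
                 correlation = correlation),
            class = "cohort_design")
}

#' Session table of a cohort
#'
#' Enumerates every scan session of a design: subject x task x pre/post, with
#' a deterministic per-session seed offset.
#'
#' @param design a [cohort_design()].
#' @return A data frame with columns `subject`, `group`, `task`, `time`,
#'   `session_index`.
#' @export
cohort_sessions <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  subj <- data.frame(
    subject = sprintf("S%02d", seq_len(design$n_training + design$n_control)),
    group = rep(c("training", "control"),
                c(design$n_training, design$n_control)))
  out <- expand.grid(subject = subj$subject, task = design$tasks,
                     time = c("pre", "post"), stringsAsFactors = FALSE)
  out$group <- subj$group[match(out$subject, subj$subject)]
  out <- out[order(out$subject, out$task, out$time), ]
  out$session_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("subject", "group", "task", "time", "session_index")]
}

#' Simulate behavioral score tables
#'
#' Draws per-subject pre/post scores from a bivariate normal with the
#' configured marginal means/SDs and pre--post correlation, independently per
#' task. Defaults reproduce the printed group marginals of the letter-memory
#' and 3-back tasks.
#'
#' @param design a [cohort_design()].
#' @param seed integer seed.
#' @return Long-format data frame: `subject`, `group`, `task`, `time`,
#'   `score`.
#' @export
simulate_behavior <- function(design = cohort_design(), seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(seed)
  rho <- design$correlation
  ns <- design$n_training + design$n_control
  width <- max(2L, nchar(ns))
  subject <- sprintf(paste0("S%0", width, "d"), seq_len(ns))
  group <- rep(c("training", "control"),
               c(design$n_training, design$n_control))
  out <- lapply(design$tasks, function(task) {
    pars <- design$behavior[[task]]
    m1 <- vapply(group, function(g) pars[[g]][1], 0)
    s1 <- vapply(group, function(g) pars[[g]][2], 0)
    m2 <- vapply(group, function(g) pars[[g]][3], 0)
    s2 <- vapply(group, function(g) pars[[g]][4], 0)
    z1 <- stats::rnorm(ns); z2 <- stats::rnorm(ns)
    pre <- m1 + s1 * z1
    post <- m2 + s2 * (rho * z1 + sqrt(1 - rho^2) * z2)
    data.frame(subject = rep(subject, each = 2L),
               group = rep(group, each = 2L), task = task,
               time = rep(c("pre", "post"), ns),
               score = as.vector(rbind(pre, post)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate a head-motion trace
#'
#' Six channels (three translations in mm, three rotations in degrees) at
#' 1 Hz: smooth low-amplitude wander scaled to `base_amplitude`, plus
#' optional Gaussian-shaped spikes on the first translation channel.
#'
#' @param duration_s trace length in seconds (default one 79.9-min scan).
#' @param base_amplitude maximum wander excursion, mm (0 gives a flat trace).
#' @param spike_times seconds at which spikes occur.
#' @param spike_amplitude spike height, mm.
#' @param seed integer seed.
#' @return Data frame: `time_s`, `tx`, `ty`, `tz` (mm), `rx`, `ry`, `rz`
#'   (degrees).
#' @export
simulate_motion_trace <- function(duration_s = 4794, base_amplitude = 0.5,
                                  spike_times = numeric(),
                                  spike_amplitude = 3, seed = NULL) {
  if (base_amplitude < 0) stop("'base_amplitude' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, duration_s)
  n <- length(tt)
  wander <- function() {
    w <- cumsum(stats::rnorm(n))
    w <- stats::filter(w, rep(1 / 61, 61), sides = 2)
    w[is.na(w)] <- 0
    w <- w - w[1]
    m <- max(abs(w))
    if (m == 0) rep(0, n) else base_amplitude * w / m
  }
  tr <- data.frame(time_s = tt, tx = wander(), ty = wander(), tz = wander(),
                   rx = 0.2 * wander(), ry = 0.2 * wander(),
                   rz = 0.2 * wander())
  for (s in spike_times) {
    tr$tx <- tr$tx + spike_amplitude * exp(-((tt - s)^2) / (2 * 2.5^2))
  }
  tr
}
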