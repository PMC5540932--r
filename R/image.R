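#' Parametric image
#'
#' A 3D map of a fitted quantity (BP0, BP1, delta BP, R1 or a flag map) with
#' its affine and provenance. Values are `NaN` outside the analysis mask.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @param label one of `"BP0"`, `"BP1"`, `"dBP"`, `"R1"`, `"k2"`, `"k2a"`,
#'   `"gamma"`, `"flag"`.
#' @param provenance named list (session metadata, config hash, ...).
#' @return An object of class `parametric_image`.
#' @export
parametric_image <- function(data, affine = diag(4), label = "BP0",
                             provenance = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  label <- match.arg(label,
                     c("BP0", "BP1", "dBP", "R1", "k2", "k2a", "gamma", "flag"))
  structure(list(data = data, affine = affine, label = label,
                 provenance = provenance),
            class = "parametric_image")
}

#' @export
print.parametric_image <- function(x, ...) {
  v <- x$data[is.finite(x$data)]
  cat(sprintf("%s parametric image %s: %d defined voxels, range %.3g - %.3g\n",
              x$label, paste(dim(x$data), collapse = "x"),
              length(v), if (length(v)) min(v) else NA,
              if (length(v)) max(v) else NA))
  invisible(x)
}

## ---- NIfTI / sidecar I/O -------------------------------------------------

#' Write a 3D/4D array as NIfTI-1
#'
#' Data are stored as float64 so that written-then-read images round-trip
#' bit-identically.
#'
#' @param data 3D or 4D numeric array (or a [parametric_image()]).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size voxel edge lengths, mm.
#' @return `path`, invisibly.
#' @export
write_nifti_image <- function(data, path, voxel_size = c(1, 1, 1)) {
  if (inherits(data, "parametric_image")) data <- data$data
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- c(voxel_size, rep(1, length(dim(data)) - 3L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a NIfTI image as a plain array
#'
#' @param path NIfTI file.
#' @return Numeric array (attributes dropped).
#' @export
read_nifti_image <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}

#' Write / read a frame schedule JSON sidecar
#'
#' @param schedule a [frame_schedule()].
#' @param path JSON path.
#' @return `path` / a [frame_schedule()].
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(list(frame_start_min = schedule$start,
                            frame_duration_min = schedule$duration),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  frame_schedule(x$frame_start_min, x$frame_duration_min)
}

## ---- motion screening ----------------------------------------------------

#' Screen a head-motion trace against the acquisition frames
#'
#' Within each frame the translation amplitude is the maximum Euclidean
#' excursion from the frame's reference position (its first sample). Frames
#' whose amplitude reaches `threshold` cannot be reconstructed as one
#' motion-free frame and each spawns one additional acquisition subframe;
#' sessions with more than `max_extra_subframes` such frames are flagged as
#' candidates for exclusion (a reproducible proxy for visual review).
#' Rotations are reported but not thresholded: the threshold is a distance.
#'
#' @param trace data frame from [simulate_motion_trace()] (columns `time_s`,
#'   `tx`, `ty`, `tz` in mm at 1 Hz).
#' @param schedule the [frame_schedule()] of the scan.
#' @param threshold motion-free amplitude limit, mm (default 2.5).
#' @param max_extra_subframes tolerated number of split frames per session.
#' @return An object of class `motion_screen`: per-frame amplitudes,
#'   `extra_subframes`, `max_excursion` and the `excluded` flag.
#' @export
screen_motion <- function(trace, schedule = default_frame_schedule(),
                          threshold = 2.5, max_extra_subframes = 3L) {
  need <- c("time_s", "tx", "ty", "tz")
  if (!all(need %in% names(trace)))
    stop("trace must have columns ", paste(need, collapse = ", "))
  if (max(trace$time_s) < schedule$end * 60 - 1)
    stop("motion trace is shorter than the scan")
  nf <- n_frames(schedule)
  amp <- numeric(nf)
  for (i in seq_len(nf)) {
    s0 <- schedule$start[i] * 60
    s1 <- (schedule$start[i] + schedule$duration[i]) * 60
    rows <- which(trace$time_s >= s0 & trace$time_s < s1)
    d <- sqrt((trace$tx[rows] - trace$tx[rows[1]])^2 +
                (trace$ty[rows] - trace$ty[rows[1]])^2 +
                (trace$tz[rows] - trace$tz[rows[1]])^2)
    amp[i] <- max(d)
  }
  extra <- sum(amp >= threshold)
  structure(list(frame_amplitude = amp, max_excursion = max(amp),
                 extra_subframes = extra, threshold = threshold,
                 excluded = extra > max_extra_subframes),
            class = "motion_screen")
}

#' @export
print.motion_screen <- function(x, ...) {
  cat(sprintf(
    "motion screen: max excursion %.2f mm, %d extra subframe(s)%s\n",
    x$max_excursion, x$extra_subframes,
    if (x$excluded) " [flagged for exclusion]" else ""))
  invisible(x)
}

#' Cohort-level motion report
#'
#' Summarizes [screen_motion()] results over sessions: how many sessions
#' needed no additional subframes (all frames below the motion threshold),
#' reported as a whole-number percentage, and how many are flagged.
#'
#' @param screens list of `motion_screen` objects.
#' @return An object of class `motion_cohort_report` with `n_sessions`,
#'   `n_clean`, `clean_percent` (rounded to whole percent), `n_flagged`.
#' @export
motion_cohort_report <- function(screens) {
  stopifnot(length(screens) > 0,
            all(vapply(screens, inherits, TRUE, "motion_screen")))
  n <- length(screens)
  clean <- sum(vapply(screens, function(s) s$extra_subframes == 0L, TRUE))
  structure(list(n_sessions = n, n_clean = clean,
                 clean_percent = round(100 * clean / n),
                 n_flagged = sum(vapply(screens, function(s) s$excluded, TRUE))),
            class = "motion_cohort_report")
}

#' @export
print.motion_cohort_report <- function(x, ...) {
  cat(sprintf(
    "%d%% (%d/%d) of sessions required no additional subframes; %d flagged\n",
    x$clean_percent, x$n_clean, x$n_sessions, x$n_flagged))
  invisible(x)
}

## ---- region extraction and voxelwise fitting -----------------------------

#' Mean time--activity curve of a region
#'
#' @param img4d 4D dynamic image (x, y, z, frame).
#' @param mask logical 3D array.
#' @param schedule the [frame_schedule()] of the acquisition.
#' @param role `"reference"` (default: the usual use is supplying C_R) or
#'   `"target"`.
#' @return A [tac()] of per-frame in-mask means.
#' @export
extract_region_tac <- function(img4d, mask, schedule,
                               role = c("reference", "target")) {
  d <- dim(img4d)
  stopifnot(length(d) == 4L)
  if (!identical(as.integer(d[1:3]), as.integer(dim(mask))))
    stop("image and mask must share one grid")
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask")
  Y <- matrix(img4d, prod(d[1:3]), d[4])[idx, , drop = FALSE]
  tac(schedule, colMeans(Y), role = match.arg(role))
}

#' Voxelwise extended-SRTM fitting and BP mapping
#'
#' Runs the linearized fit at every in-mask voxel and maps BP0, BP1 and
#' delta BP = BP1 - BP0. Voxels with non-physical fits (k2a <= 0,
#' non-positive activation-phase efflux, BP0 <= -1 or non-finite data) are
#' flagged, set to `NaN` in the BP maps and counted, not raised as errors.
#'
#' @param img4d 4D dynamic image, already smoothed per protocol.
#' @param ref reference-region [tac()] supplying C_R.
#' @param mask logical 3D analysis mask (the striatal search volume).
#' @param profile an [activation_profile()].
#' @param weights optional per-frame weights passed to the linear fit.
#' @param bp_method `"rate"` or `"pointwise"`, see [bp_activation()].
#' @param window activation window, min.
#' @param affine 4x4 voxel-to-world matrix stored with the maps.
#' @param provenance named list stored with the maps.
#' @return An object of class `voxel_fit`: parametric images `bp0`, `bp1`,
#'   `delta`, `r1`, `flag`; the per-voxel parameter matrix; and
#'   `flagged_fraction`.
#' @export
fit_voxelwise <- function(img4d, ref, mask, profile = activation_profile(),
                          weights = NULL, bp_method = c("rate", "pointwise"),
                          window = profile$window, affine = diag(4),
                          provenance = list()) {
  bp_method <- match.arg(bp_method)
  d <- dim(img4d)
  stopifnot(length(d) == 4L, inherits(ref, "tac"))
  if (!identical(as.integer(d[1:3]), as.integer(dim(mask))))
    stop("image and mask must share one grid")
  if (d[4] != n_frames(ref$schedule))
    stop("frame count of image and reference schedule differ")
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask")
  V <- length(idx)
  Y <- matrix(img4d, prod(d[1:3]), d[4])[idx, , drop = FALSE]
  ops <- design_operators(ref$schedule, profile)
  c1 <- ref$values
  c2 <- as.numeric(ops$P_int %*% c1)
  C3 <- -(Y %*% t(ops$P_int))
  C4 <- -(Y %*% t(ops$P_inth))
  sw <- if (is.null(weights)) NULL else sqrt(weights)
  pars <- matrix(NA_real_, V, 4L,
                 dimnames = list(NULL, c("r1", "k2", "k2a", "gamma")))
  bad_data <- rowSums(!is.finite(Y)) > 0
  for (v in which(!bad_data)) {
    X <- cbind(c1, c2, C3[v, ], C4[v, ])
    y <- Y[v, ]
    if (!is.null(sw)) { X <- X * sw; y <- y * sw }
    fit <- stats::.lm.fit(X, y)
    pars[v, ] <- fit$coefficients
  }
  hbar <- mean_activation(profile, window)
  k2 <- pars[, "k2"]; k2a <- pars[, "k2a"]; g <- pars[, "gamma"]
  bp0 <- ifelse(is.finite(k2a) & k2a > 0, k2 / k2a - 1, NA_real_)
  if (bp_method == "rate") {
    den <- k2a + g * hbar
    bp1 <- ifelse(is.finite(den) & den > 0, k2 / den - 1, NA_real_)
  } else {
    tt <- seq(window[1], window[2], by = 1 / 60)
    hh <- gamma_variate(tt, profile)
    bp1 <- vapply(seq_len(V), function(v) {
      den <- k2a[v] + g[v] * hh
      if (any(!is.finite(den)) || any(den <= 0)) return(NA_real_)
      mean(k2[v] / den - 1)
    }, numeric(1))
  }
  flag <- bad_data | !is.finite(bp0) | !is.finite(bp1) | bp0 <= -1
  bp0[flag] <- NA_real_; bp1[flag] <- NA_real_
  if (all(flag))
    stop("all in-mask voxels failed to fit; check inputs")
  mk_map <- function(vals, label) {
    a <- array(NaN, d[1:3])
    a[idx] <- vals
    parametric_image(a, affine, label, provenance)
  }
  structure(list(bp0 = mk_map(bp0, "BP0"), bp1 = mk_map(bp1, "BP1"),
                 delta = mk_map(bp1 - bp0, "dBP"),
                 r1 = mk_map(pars[, "r1"], "R1"),
                 flag = mk_map(as.numeric(flag), "flag"),
                 params = pars, mask_index = idx,
                 flagged_fraction = mean(flag)),
            class = "voxel_fit")
}

#' @export
print.voxel_fit <- function(x, ...) {
  cat(sprintf("voxelwise fit: %d voxels, %.1f%% flagged\n",
              nrow(x$params), 100 * x$flagged_fraction))
  invisible(x)
}
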