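#' Run configuration
#'
#' A single nested configuration drives the three pipeline stages
#' ([run_simulate()], [run_fit()], [run_stats()]). Values can come from a
#' YAML file, an override list, or both (overrides win over the file, the
#' file over the defaults). An MD5 hash of the resolved configuration is
#' stamped into every output so results can be traced to their settings.
#'
#' Blocks: `paths` (`dataset`, `output`), `seed`, `phantom` (arguments of
#' [phantom_spec()] except schedule/profile), `cohort` (arguments of
#' [cohort_design()]), `kinetics` (`onset`, `time_to_peak`, `shape_lambda`,
#' `smooth_fwhm`, `weights` = `"uniform"` or `"duration"`, `bp_method`),
#' `stats` (`alpha_anova`, `alpha_paired`, `n_perm`, `var_fwhm`,
#' `min_extent`, `connectivity`, `motion_threshold`, `max_extra_subframes`).
#'
#' @param path optional YAML file.
#' @param overrides optional nested list of settings.
#' @return A list of class `run_config` with attribute-free plain values and
#'   an element `hash`.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    paths = list(dataset = "dataset", output = "output"),
    seed = 1L,
    phantom = list(),
    cohort = list(),
    kinetics = list(onset = 55, time_to_peak = 8 + 20 / 60,
                    shape_lambda = 3, smooth_fwhm = 10,
                    weights = "uniform", bp_method = "rate"),
    stats = list(alpha_anova = 0.05, alpha_paired = 0.01, n_perm = 5000,
                 var_fwhm = 10, min_extent = 5, connectivity = 26,
                 motion_threshold = 2.5, max_extra_subframes = 3))
  merge_lists <- function(base, new) {
    for (nm in names(new)) {
      base[[nm]] <- if (is.list(new[[nm]]) && is.list(base[[nm]]))
        merge_lists(base[[nm]], new[[nm]]) else new[[nm]]
    }
    base
  }
  cfg <- defaults
  if (!is.null(path)) cfg <- merge_lists(cfg, yaml::read_yaml(path))
  cfg <- merge_lists(cfg, overrides)
  cfg$hash <- config_hash(cfg[setdiff(names(cfg), "hash")])
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

cfg_profile <- function(config) {
  activation_profile(onset = config$kinetics$onset,
                     time_to_peak = config$kinetics$time_to_peak,
                     shape_lambda = config$kinetics$shape_lambda)
}

cfg_spec <- function(config) {
  args <- config$phantom
  args$profile <- cfg_profile(config)
  do.call(phantom_spec, args)
}

session_stub <- function(s) {
  sprintf("%s_task-%s_time-%s", s["subject"], s["task"], s["time"])
}

cfg_frame_weights <- function(config, schedule) {
  if (identical(config$kinetics$weights, "duration")) schedule$duration
  else NULL
}

#' Simulate a phantom cohort to disk
#'
#' Generates the full synthetic study of the configuration -- two groups,
#' pre/post sessions, the configured tasks -- as NIfTI dynamic images with a
#' frame-schedule JSON sidecar, per-session motion traces (CSV), masks, a
#' behavioral score table and a `manifest.json` listing every file with its
#' MD5 checksum and the config hash. Rerunning with the same configuration
#' reproduces the dataset bit for bit.
#'
#' @param config a [run_config()].
#' @param force overwrite an existing non-empty dataset directory.
#' @return The manifest, invisibly.
#' @export
run_simulate <- function(config, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  root <- config$paths$dataset
  if (dir.exists(root) && length(list.files(root)) > 0 && !force)
    stop("dataset directory exists and is not empty (use force = TRUE)")
  dir.create(file.path(root, "pet"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "motion"), showWarnings = FALSE)
  spec <- cfg_spec(config)
  design <- do.call(cohort_design, config$cohort)
  sessions <- cohort_sessions(design)
  write_schedule_json(spec$schedule, file.path(root, "schedule.json"))
  for (m in c("striatum", "reference", "effect"))
    write_nifti_image(array(as.numeric(spec[[m]]), spec$dim),
                      file.path(root, sprintf("mask_%s.nii", m)),
                      spec$voxel_size)
  truth_cache <- new.env(parent = emptyenv())
  files <- character(0)
  sessions$pet_file <- NA_character_
  for (i in seq_len(nrow(sessions))) {
    s <- sessions[i, ]
    with_effect <- s$group == "training" && s$time == "post"
    key <- paste(s$task, with_effect)
    truth <- get0(key, envir = truth_cache)
    if (is.null(truth)) {
      truth <- phantom_truth(spec, s$task, with_effect)
      assign(key, truth, envir = truth_cache)
    }
    scan <- simulate_phantom_scan(spec, s$group, s$time, s$task,
                                  seed = config$seed + 1009L * i,
                                  truth = truth)
    stub <- session_stub(c(subject = s$subject, task = s$task, time = s$time))
    pet <- file.path("pet", paste0(stub, ".nii"))
    write_nifti_image(scan$img, file.path(root, pet), spec$voxel_size)
    mot <- file.path("motion", paste0(stub, "_motion.csv"))
    utils::write.csv(scan$motion, file.path(root, mot), row.names = FALSE)
    sessions$pet_file[i] <- pet
    files <- c(files, pet, mot)
  }
  utils::write.csv(sessions, file.path(root, "sessions.csv"),
                   row.names = FALSE)
  behavior <- simulate_behavior(design, seed = config$seed + 7919L)
  utils::write.csv(behavior, file.path(root, "behavior.csv"),
                   row.names = FALSE)
  files <- c("schedule.json", "sessions.csv", "behavior.csv",
             sprintf("mask_%s.nii", c("striatum", "reference", "effect")),
             files)
  files <- sort(files)
  sums <- tools::md5sum(file.path(root, files))
  manifest <- list(config_hash = config$hash,
                   files = data.frame(file = files, md5 = unname(sums)))
  jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Fit parametric BP maps for every session of a dataset
#'
#' For each session: screens the motion trace, extracts the reference-region
#' TAC, applies edge-preserving masked smoothing to the dynamic frames
#' within the striatal mask, runs the voxelwise extended-SRTM fit and writes
#' BP0 / BP1 / delta-BP / flag maps plus a JSON fit report (per-session
#' flagged-voxel fraction, motion screen, cohort motion summary, config
#' hash).
#'
#' @param config a [run_config()].
#' @return The fit report, invisibly.
#' @export
run_fit <- function(config) {
  stopifnot(inherits(config, "run_config"))
  root <- config$paths$dataset
  out <- file.path(config$paths$output, "maps")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  schedule <- read_schedule_json(file.path(root, "schedule.json"))
  striatum <- read_nifti_image(file.path(root, "mask_striatum.nii")) > 0.5
  reference <- read_nifti_image(file.path(root, "mask_reference.nii")) > 0.5
  sessions <- utils::read.csv(file.path(root, "sessions.csv"))
  profile <- cfg_profile(config)
  spec_vs <- attr(RNifti::readNifti(file.path(root, "mask_striatum.nii")),
                  "pixdim")[1:3]
  weights <- cfg_frame_weights(config, schedule)
  screens <- list()
  per_session <- list()
  for (i in seq_len(nrow(sessions))) {
    s <- sessions[i, ]
    stub <- session_stub(c(subject = s$subject, task = s$task,
                           time = s$time))
    img <- read_nifti_image(file.path(root, s$pet_file))
    motion <- utils::read.csv(file.path(root, "motion",
                                        paste0(stub, "_motion.csv")))
    screen <- screen_motion(motion, schedule,
                            threshold = config$stats$motion_threshold,
                            max_extra_subframes =
                              config$stats$max_extra_subframes)
    screens[[stub]] <- screen
    ref <- extract_region_tac(img, reference, schedule, role = "reference")
    sm <- masked_gaussian_smooth(img, striatum,
                                 fwhm = config$kinetics$smooth_fwhm,
                                 voxel_size = spec_vs)
    fit <- fit_voxelwise(sm, ref, striatum, profile, weights = weights,
                         bp_method = config$kinetics$bp_method,
                         provenance = list(session = stub,
                                           config_hash = config$hash))
    for (m in c("bp0", "bp1", "delta", "flag"))
      write_nifti_image(fit[[m]],
                        file.path(out, sprintf("%s_%s.nii", stub,
                                               fit[[m]]$label)),
                        spec_vs)
    per_session[[stub]] <- list(
      flagged_fraction = fit$flagged_fraction,
      motion_max_excursion = screen$max_excursion,
      motion_extra_subframes = screen$extra_subframes,
      motion_excluded = screen$excluded)
  }
  report <- list(config_hash = config$hash,
                 motion_cohort = unclass(motion_cohort_report(screens)),
                 sessions = per_session)
  jsonlite::write_json(report,
                       file.path(config$paths$output, "fit_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Voxelwise and behavioral statistics for a fitted dataset
#'
#' Per task: (1) the pre-training task effect on BP -- a paired comparison of
#' BP1 vs BP0 maps across all non-excluded subjects with sign-flip maxT
#' correction at the paired alpha; (2) the training effect -- the
#' 2 (group) x 2 (time) permutation ANOVA on the per-subject change of
#' delta BP (post - pre) with variance smoothing and cluster-extent
#' filtering; (3) the behavioral mixed ANOVA with effect sizes after 3 x IQR
#' outlier screening of pre-training scores, and the pre-training group
#' comparison (pooled t). Cluster tables are written as CSV, statistic maps
#' as NIfTI, and everything is summarized in `stats_summary.json`.
#'
#' @param config a [run_config()].
#' @return The summary list, invisibly.
#' @export
run_stats <- function(config) {
  stopifnot(inherits(config, "run_config"))
  root <- config$paths$dataset
  outdir <- file.path(config$paths$output, "stats")
  mapdir <- file.path(config$paths$output, "maps")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  striatum <- read_nifti_image(file.path(root, "mask_striatum.nii")) > 0.5
  vs <- attr(RNifti::readNifti(file.path(root, "mask_striatum.nii")),
             "pixdim")[1:3]
  affine <- phantom_affine(vs)
  sessions <- utils::read.csv(file.path(root, "sessions.csv"))
  fitrep <- jsonlite::read_json(file.path(config$paths$output,
                                          "fit_report.json"))
  excluded <- vapply(fitrep$sessions, function(s) isTRUE(s$motion_excluded),
                     TRUE)
  st <- config$stats
  load_map <- function(stub, label)
    read_nifti_image(file.path(mapdir, sprintf("%s_%s.nii", stub, label)))
  summary_out <- list(config_hash = config$hash, tasks = list())
  for (task in unique(sessions$task)) {
    task_sessions <- sessions[sessions$task == task, ]
    stub_of <- function(subj, time)
      session_stub(c(subject = subj, task = task, time = time))
    ## (1) pre-training task effect: BP1 vs BP0, both groups combined
    pre <- task_sessions[task_sessions$time == "pre", ]
    ok <- !excluded[vapply(pre$subject, stub_of, "", time = "pre")]
    pre <- pre[ok, ]
    paired <- paired_t_map(
      lapply(pre$subject, function(su) load_map(stub_of(su, "pre"), "BP1")),
      lapply(pre$subject, function(su) load_map(stub_of(su, "pre"), "BP0")),
      striatum, alpha = st$alpha_paired, n_perm = st$n_perm,
      voxel_size = vs, min_extent = st$min_extent,
      connectivity = st$connectivity, affine = affine,
      seed = config$seed + 53L)
    ## (2) group x time ANOVA on delta-BP change
    subj <- unique(task_sessions$subject)
    keep <- vapply(subj, function(su)
      !excluded[stub_of(su, "pre")] && !excluded[stub_of(su, "post")], TRUE)
    subj <- subj[keep]
    group <- task_sessions$group[match(subj, task_sessions$subject)]
    change <- lapply(subj, function(su)
      load_map(stub_of(su, "post"), "dBP") -
        load_map(stub_of(su, "pre"), "dBP"))
    anova <- group_time_anova(change, group, striatum,
                              alpha = st$alpha_anova, n_perm = st$n_perm,
                              var_fwhm = st$var_fwhm, voxel_size = vs,
                              min_extent = st$min_extent,
                              connectivity = st$connectivity,
                              affine = affine, seed = config$seed + 97L)
    utils::write.csv(paired$clusters,
                     file.path(outdir, sprintf("%s_task_effect_clusters.csv",
                                               task)), row.names = FALSE)
    utils::write.csv(anova$clusters,
                     file.path(outdir, sprintf("%s_interaction_clusters.csv",
                                               task)), row.names = FALSE)
    write_nifti_image(anova$stat,
                      file.path(outdir, sprintf("%s_interaction_stat.nii",
                                                task)), vs)
    ## (3) behavioral statistics
    behavior <- utils::read.csv(file.path(root, "behavior.csv"))
    beh <- behavior[behavior$task == task, ]
    pre_scores <- beh[beh$time == "pre", ]
    screen <- remove_extreme_outliers(pre_scores$score)
    drop_subj <- pre_scores$subject[screen$removed]
    beh_kept <- beh[!(beh$subject %in% drop_subj), ]
    aov2 <- mixed_anova_2x2(beh_kept)
    grp_pre <- function(g) pre_scores$score[pre_scores$group == g &
                                              !(pre_scores$subject %in%
                                                  drop_subj)]
    a <- grp_pre("training"); b <- grp_pre("control")
    baseline <- two_sample_t_pooled(mean(a), stats::sd(a), length(a),
                                    mean(b), stats::sd(b), length(b))
    summary_out$tasks[[task]] <- list(
      task_effect = list(
        n = nrow(pre), threshold = paired$threshold,
        n_clusters = nrow(paired$clusters),
        clusters = paired$clusters),
      interaction = list(
        n = length(subj), threshold = anova$threshold,
        n_clusters = nrow(anova$clusters),
        clusters = anova$clusters),
      behavior = list(
        outliers_removed = length(screen$removed),
        interaction_F = aov2$interaction$F,
        interaction_df = c(aov2$interaction$df1, aov2$interaction$df2),
        interaction_p = aov2$interaction$p,
        eta_sq_partial = aov2$interaction$eta_sq_partial,
        cohens_d = aov2$interaction$cohens_d,
        baseline_t = baseline$t, baseline_df = baseline$df,
        baseline_p = baseline$p))
  }
  jsonlite::write_json(summary_out,
                       file.path(outdir, "stats_summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(summary_out)
}
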