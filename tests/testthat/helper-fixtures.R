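## Shared fixtures and independent oracles for the test suite.

## Small phantom used by pipeline-level tests: ~288-voxel striatal mask,
## 32-voxel reference sphere, 80-voxel effect blob on a 14 x 14 x 10 grid of
## 1.5 mm voxels. Smoothing kernels are scaled with the reduced geometry
## (5 mm instead of 10 mm at full scale).
small_spec <- function(...) {
  phantom_spec(dim = c(14L, 14L, 10L), voxel_size = 1.5,
               striatum_center = c(10.5, 10.5, 10.5),
               striatum_radii = c(7, 7, 4.5),
               reference_center = c(10.5, 10.5, 3),
               reference_radii = c(4, 4, 2),
               effect_center = c(7, 10.5, 10.5),
               effect_radii = c(4.5, 4.5, 3), ...)
}
small_fwhm <- 5

## Simulate one cohort of per-subject delta-BP change maps (post - pre)
## through the full scan -> smooth -> voxelwise-fit pipeline.
simulate_change_cohort <- function(spec, seed, n_per_group = 14L,
                                   task = "letter_memory",
                                   fwhm = small_fwhm, effect = TRUE) {
  sp <- spec
  if (!effect) sp$gamma_effect <- 0
  design <- cohort_design(n_training = n_per_group, n_control = n_per_group,
                          tasks = task)
  sess <- cohort_sessions(design)
  truth_cache <- new.env(parent = emptyenv())
  subs <- unique(sess$subject)
  groups <- sess$group[match(subs, sess$subject)]
  maps <- vector("list", length(subs))
  for (si in seq_along(subs)) {
    d <- list()
    for (tm in c("pre", "post")) {
      i <- which(sess$subject == subs[si] & sess$time == tm)
      we <- groups[si] == "training" && tm == "post" && effect
      key <- paste(task, we)
      tr <- get0(key, envir = truth_cache)
      if (is.null(tr)) {
        tr <- lssrm:::phantom_truth(sp, task, we)
        assign(key, tr, envir = truth_cache)
      }
      scan <- simulate_phantom_scan(sp, groups[si], tm, task,
                                    seed = seed * 100L + i, truth = tr)
      ref <- extract_region_tac(scan$img, sp$reference, sp$schedule)
      sm <- masked_gaussian_smooth(scan$img, sp$striatum, fwhm,
                                   sp$voxel_size)
      fit <- fit_voxelwise(sm, ref, sp$striatum, sp$profile)
      d[[tm]] <- fit$delta$data
    }
    maps[[si]] <- d$post - d$pre
  }
  list(maps = maps, groups = groups, spec = sp)
}

## Brute-force normalized-convolution oracle: O(N * K) triple loop over the
## same finite kernel support (|offset| <= ceiling(4 sigma) per axis,
## separable Gaussian weights).
oracle_masked_smooth <- function(img, mask, fwhm, voxel_size = c(1, 1, 1)) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  d <- dim(img)
  sig <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  r <- ceiling(4 * sig)
  w1 <- lapply(1:3, function(a) exp(-((-r[a]):r[a])^2 / (2 * sig[a]^2)))
  out <- array(NaN, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    num <- 0; den <- 0
    for (di in (-r[1]):r[1]) {
      ii <- i + di
      if (ii < 1 || ii > d[1]) next
      for (dj in (-r[2]):r[2]) {
        jj <- j + dj
        if (jj < 1 || jj > d[2]) next
        for (dk in (-r[3]):r[3]) {
          kk <- k + dk
          if (kk < 1 || kk > d[3]) next
          if (!mask[ii, jj, kk]) next
          w <- w1[[1]][di + r[1] + 1] * w1[[2]][dj + r[2] + 1] *
            w1[[3]][dk + r[3] + 1]
          num <- num + w * img[ii, jj, kk]
          den <- den + w
        }
      }
    }
    out[i, j, k] <- num / den
  }
  out
}

## Independent connected-component oracle built on igraph.
oracle_components <- function(supra, connectivity = 26L) {
  d <- dim(supra)
  idx <- which(supra)
  if (length(idx) == 0) return(integer(0))
  co <- arrayInd(idx, d)
  edges <- list()
  for (a in seq_along(idx)) for (b in seq_along(idx)) {
    if (a >= b) next
    dd <- abs(co[a, ] - co[b, ])
    if (all(dd <= 1)) {
      s <- sum(dd)
      ok <- switch(as.character(connectivity),
                   "6" = s == 1, "18" = s <= 2 && max(dd) == 1, s >= 1)
      if (ok) edges[[length(edges) + 1L]] <- c(a, b)
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, unlist(edges))
  sort(as.integer(table(igraph::components(g)$membership)),
       decreasing = TRUE)
}

## Direct sums-of-squares decomposition for the BALANCED 2 x 2 split-plot
## design (m subjects per group): between-subject stratum (group vs
## subject-within-group) and within-subject stratum (time, group:time vs the
## time-by-subject residual). Classical textbook formulas, computed from
## scratch.
oracle_split_plot <- function(tab) {
  tab$subject <- as.character(tab$subject)
  tab$group <- as.character(tab$group)
  tab$time <- as.character(tab$time)
  subj <- unique(tab[, c("subject", "group")])
  stopifnot(length(unique(table(subj$group))) == 1L)
  m <- unname(table(subj$group)[1])
  grand <- mean(tab$score)
  gmean <- tapply(tab$score, tab$group, mean)
  tmean <- tapply(tab$score, tab$time, mean)
  cell <- tapply(tab$score, list(tab$group, tab$time), mean)
  smean <- tapply(tab$score, tab$subject, mean)
  ss_group <- 2 * m * sum((gmean - grand)^2)
  ss_subj <- 2 * sum((smean[subj$subject] - gmean[subj$group])^2)
  ss_time <- 2 * m * sum((tmean - grand)^2)
  dev_int <- cell
  for (g in rownames(cell)) for (t in colnames(cell))
    dev_int[g, t] <- cell[g, t] - gmean[g] - tmean[t] + grand
  ss_int <- m * sum(dev_int^2)
  res <- tab$score - cell[cbind(tab$group, tab$time)] -
    smean[tab$subject] + gmean[tab$group]
  ss_res <- sum(res^2)
  df_b <- 2 * m - 2
  list(F_group = ss_group / (ss_subj / df_b),
       F_time = ss_time / (ss_res / df_b),
       F_int = ss_int / (ss_res / df_b),
       df2 = df_b, ss_int = ss_int, ss_res = ss_res)
}
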