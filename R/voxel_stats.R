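## Stack a list of 3D maps (or parametric_images) into a V x n matrix of
## in-mask values.
stack_maps <- function(maps, mask) {
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask")
  vals <- vapply(maps, function(m) {
    if (inherits(m, "parametric_image")) m <- m$data
    if (!identical(as.integer(dim(m)), as.integer(dim(mask))))
      stop("map and mask grids differ")
    m[idx]
  }, numeric(length(idx)))
  matrix(vals, nrow = length(idx))
}

## Empirical (1 - alpha) critical value and per-voxel corrected p-values of
## a max-statistic permutation null. Ties count against rejection (p uses
## >=) and the identity permutation is always the first column, so p >=
## 1/n_perm.
maxt_summary <- function(obs, max_null, alpha) {
  n_perm <- length(max_null)
  p <- vapply(obs, function(t) mean(max_null >= t), numeric(1))
  crit <- sort(max_null)[ceiling((1 - alpha) * n_perm)]
  list(p = p, crit = crit)
}

new_permutation_result <- function(type, stat3d, p3d, crit, alpha, n_perm,
                                   enumerated, clusters, extra = list()) {
  structure(c(list(type = type, stat = stat3d, p = p3d, threshold = crit,
                   alpha = alpha, n_perm = n_perm, enumerated = enumerated,
                   clusters = clusters), extra),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "%s permutation test: %d permutations%s, alpha = %g, maxT threshold = %.3f\n",
    x$type, x$n_perm, if (x$enumerated) " (full enumeration)" else "",
    x$alpha, x$threshold))
  if (nrow(x$clusters) == 0) cat("no suprathreshold clusters\n")
  else print(x$clusters)
  invisible(x)
}

#' Voxelwise paired t-test with sign-flip permutation correction
#'
#' Paired t statistics on per-subject difference maps A - B, with family-wise
#' error control by the permutation distribution of the maximum |t| over the
#' search volume under random sign flipping of the subject difference maps
#' (exchangeable under the null of no condition effect). The identity
#' flip is always included. Suprathreshold voxels (corrected p <= alpha) are
#' grouped into clusters and filtered by extent.
#'
#' @param maps_a,maps_b lists of 3D arrays (or [parametric_image()]s), one
#'   per subject, in matching order.
#' @param mask logical 3D search volume.
#' @param alpha corrected significance level (default 0.01, the task-effect
#'   threshold).
#' @param n_perm number of sign-flip permutations (identity included); if it
#'   reaches 2^n the flips are fully enumerated.
#' @param var_fwhm variance-smoothing FWHM in mm; 0 (default) gives the raw
#'   paired t, > 0 a pseudo-t with masked-smoothed variance.
#' @param voxel_size voxel size, mm.
#' @param min_extent clusters must exceed this many voxels (strictly).
#' @param connectivity cluster connectivity: 26 (default), 18 or 6.
#' @param affine 4x4 voxel-to-world matrix for peak coordinates.
#' @param seed integer seed for the permutation stream.
#' @return A `permutation_result` with the statistic map, corrected p map,
#'   maxT threshold and cluster table.
#' @export
paired_t_map <- function(maps_a, maps_b, mask, alpha = 0.01, n_perm = 2000,
                         var_fwhm = 0, voxel_size = c(1, 1, 1),
                         min_extent = 5L, connectivity = 26L,
                         affine = diag(4), seed = NULL) {
  if (length(maps_a) != length(maps_b))
    stop("unpaired input: maps_a and maps_b differ in length")
  n <- length(maps_a)
  if (n < 3L) stop("need at least 3 paired subjects")
  D <- stack_maps(maps_a, mask) - stack_maps(maps_b, mask)
  V <- nrow(D)
  if (!is.null(seed)) set.seed(seed)
  enumerated <- FALSE
  if (2^n <= n_perm) {
    S <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    S <- t(S[c(1, setdiff(seq_len(2^n), 1)), , drop = FALSE])
    n_perm <- 2^n
    enumerated <- TRUE
    message("sign flips fully enumerated (", n_perm, " <= n_perm)")
  } else {
    S <- matrix(sample(c(1, -1), n * (n_perm - 1L), replace = TRUE), n)
    S <- cbind(rep(1, n), S)
  }
  smoother <- make_masked_smoother(mask, var_fwhm, voxel_size)
  ss <- rowSums(D^2)
  M <- (D %*% S) / n
  Tm <- matrix(0, V, n_perm)
  for (k in seq_len(n_perm)) {
    vr <- (ss - n * M[, k]^2) / (n - 1)
    vr[vr < 0] <- 0
    if (var_fwhm > 0) vr <- smoother(vr)
    se <- sqrt(vr / n)
    tk <- M[, k] / se
    tk[se == 0] <- 0
    Tm[, k] <- tk
  }
  obs <- Tm[, 1L]
  mx <- apply(abs(Tm), 2, max)
  sm <- maxt_summary(abs(obs), mx, alpha)
  finish_permutation("paired_t", obs, sm, mask, alpha, n_perm, enumerated,
                     min_extent, connectivity, affine)
}

## Shared tail: embed statistic and p into 3D maps, threshold, cluster.
finish_permutation <- function(type, obs, sm, mask, alpha, n_perm,
                               enumerated, min_extent, connectivity, affine) {
  idx <- which(mask)
  stat3d <- array(NaN, dim(mask)); stat3d[idx] <- obs
  p3d <- array(NaN, dim(mask)); p3d[idx] <- sm$p
  supra <- array(FALSE, dim(mask)); supra[idx] <- sm$p <= alpha
  clusters <- cluster_filter(stat3d, supra, min_extent = min_extent,
                             connectivity = connectivity, affine = affine)
  new_permutation_result(type, stat3d, p3d, sm$crit, alpha, n_perm,
                         enumerated, clusters)
}

#' Permutation 2x2 group-by-time ANOVA on binding-potential change
#'
#' The group-by-time interaction on delta BP in a mixed 2 (group) x 2 (time)
#' design is equivalent to a two-sample comparison of the per-subject change
#' maps (post - pre), which makes label permutation exact under group
#' exchangeability. The statistic is a pseudo-t: the pooled-variance image is
#' smoothed with [masked_gaussian_smooth()] (FWHM `var_fwhm`; 0 gives the raw
#' t) before forming the denominator, stabilizing small-sample variance
#' estimates. Family-wise error is controlled by the max-|t| permutation
#' distribution over the search volume; surviving voxels are clustered and
#' filtered by extent.
#'
#' The statistic is signed as first group minus second group (alphabetically
#' by label unless `group` is a factor).
#'
#' @param change_maps list of per-subject change maps (3D arrays or
#'   [parametric_image()]s), post minus pre.
#' @param group group label per subject (two levels, each with >= 2
#'   subjects).
#' @param mask logical 3D search volume.
#' @param alpha corrected significance level (default 0.05).
#' @param n_perm permutations (default 5000); if the number of distinct
#'   relabelings is smaller, they are fully enumerated with a note.
#' @param var_fwhm variance-smoothing FWHM, mm (default 10).
#' @param voxel_size voxel size, mm.
#' @param min_extent,connectivity,affine,seed see [paired_t_map()].
#' @return A `permutation_result`.
#' @export
group_time_anova <- function(change_maps, group, mask, alpha = 0.05,
                             n_perm = 5000, var_fwhm = 10,
                             voxel_size = c(1, 1, 1), min_extent = 5L,
                             connectivity = 26L, affine = diag(4),
                             seed = NULL) {
  n <- length(change_maps)
  group <- as.factor(group)
  if (nlevels(group) != 2L || length(group) != n)
    stop("'group' must give one of two levels per subject")
  n1 <- sum(group == levels(group)[1L])
  n2 <- n - n1
  if (n1 < 2L || n2 < 2L) stop("need at least 2 subjects per group")
  X <- stack_maps(change_maps, mask)
  V <- nrow(X)
  if (!is.null(seed)) set.seed(seed)
  obs_idx <- which(group == levels(group)[1L])
  n_distinct <- choose(n, n1)
  enumerated <- FALSE
  if (n_distinct <= n_perm) {
    combos <- utils::combn(n, n1)
    first <- which(apply(combos, 2, function(cc) all(cc == sort(obs_idx))))
    ord <- c(first, setdiff(seq_len(ncol(combos)), first))
    G1 <- matrix(0, n, ncol(combos))
    for (k in seq_along(ord)) G1[combos[, ord[k]], k] <- 1
    n_perm <- ncol(combos)
    enumerated <- TRUE
    message("group relabelings fully enumerated (", n_perm, " <= n_perm)")
  } else {
    G1 <- matrix(0, n, n_perm)
    G1[obs_idx, 1L] <- 1
    for (k in 2:n_perm) G1[sample(n, n1), k] <- 1
  }
  G2 <- 1 - G1
  S1 <- X %*% G1; S2 <- X %*% G2
  X2 <- X^2
  Q1 <- X2 %*% G1; Q2 <- X2 %*% G2
  m1 <- S1 / n1; m2 <- S2 / n2
  varp <- (Q1 - n1 * m1^2 + Q2 - n2 * m2^2) / (n - 2)
  varp[varp < 0] <- 0
  smoother <- make_masked_smoother(mask, var_fwhm, voxel_size)
  Tm <- matrix(0, V, n_perm)
  sefac <- 1 / n1 + 1 / n2
  for (k in seq_len(n_perm)) {
    vr <- varp[, k]
    if (var_fwhm > 0) vr <- smoother(vr)
    se <- sqrt(vr * sefac)
    tk <- (m1[, k] - m2[, k]) / se
    tk[se == 0] <- 0
    Tm[, k] <- tk
  }
  obs <- Tm[, 1L]
  mx <- apply(abs(Tm), 2, max)
  sm <- maxt_summary(abs(obs), mx, alpha)
  finish_permutation("group_time_interaction", obs, sm, mask, alpha, n_perm,
                     enumerated, min_extent, connectivity, affine)
}

#' Connected-component cluster filtering of a thresholded map
#'
#' Groups suprathreshold voxels into connected components (26-connectivity
#' by default) and keeps components whose size strictly exceeds
#' `min_extent` — the "report only effects that exceed 5 voxels" rule. Peak
#' coordinates are reported both as 0-based voxel indices and in world
#' coordinates through the affine.
#'
#' @param stat 3D statistic map (used for peak values; may contain `NaN`).
#' @param supra logical 3D array of suprathreshold voxels.
#' @param min_extent clusters must have size > `min_extent` (default 5).
#' @param connectivity 26 (faces, edges, corners), 18 or 6.
#' @param affine 4x4 voxel-to-world matrix.
#' @return Data frame: `cluster`, `size`, `peak_stat`, `peak_i/j/k`
#'   (0-based), `peak_x/y/z` (world, mm).
#' @export
cluster_filter <- function(stat, supra, min_extent = 5L, connectivity = 26L,
                           affine = diag(4)) {
  stopifnot(identical(dim(stat), dim(supra)),
            connectivity %in% c(6L, 18L, 26L))
  d <- dim(supra)
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  ord <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  off <- off[ord <= c(`6` = 1L, `18` = 2L, `26` = 3L)[as.character(connectivity)], ]
  idx <- which(supra)
  lab <- array(0L, d)
  res <- list()
  cl <- 0L
  coords <- arrayInd(idx, d)
  pos <- array(0L, d); pos[idx] <- seq_along(idx)
  for (s in seq_along(idx)) {
    if (lab[idx[s]] != 0L) next
    cl <- cl + 1L
    queue <- s
    lab[idx[s]] <- cl
    members <- integer(0)
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      members <- c(members, v)
      here <- coords[v, ]
      for (r in seq_len(nrow(off))) {
        nb <- here + c(off$dx[r], off$dy[r], off$dz[r])
        if (any(nb < 1L) || any(nb > d)) next
        li <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        pv <- pos[li]
        if (pv != 0L && lab[li] == 0L) {
          lab[li] <- cl
          queue <- c(queue, pv)
        }
      }
    }
    vox <- idx[members]
    vals <- stat[vox]
    pk <- members[which.max(abs(vals))]
    res[[cl]] <- list(size = length(members), peak_stat = stat[idx[pk]],
                      ijk = coords[pk, ] - 1L)
  }
  keep <- Filter(function(r) r$size > min_extent, res)
  if (length(keep) == 0L)
    return(data.frame(cluster = integer(0), size = integer(0),
                      peak_stat = numeric(0), peak_i = integer(0),
                      peak_j = integer(0), peak_k = integer(0),
                      peak_x = numeric(0), peak_y = numeric(0),
                      peak_z = numeric(0)))
  keep <- keep[order(vapply(keep, function(r) -r$size, numeric(1)))]
  out <- do.call(rbind, lapply(seq_along(keep), function(i) {
    r <- keep[[i]]
    w <- as.numeric(affine %*% c(r$ijk, 1))
    data.frame(cluster = i, size = r$size, peak_stat = r$peak_stat,
               peak_i = r$ijk[1], peak_j = r$ijk[2], peak_k = r$ijk[3],
               peak_x = w[1], peak_y = w[2], peak_z = w[3])
  }))
  rownames(out) <- NULL
  out
}
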