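# --- 3D thinning -------------------------------------------------------------
# Sequential simple-point removal with endpoint preservation. A border voxel
# is deleted when removing it provably leaves local topology unchanged
# (Bertrand-Malandain characterisation): exactly one 26-connected foreground
# component in the 26-neighbourhood, and exactly one 6-connected background
# component in the 18-neighbourhood that touches a face neighbour. Deleting
# sequentially (not in parallel) keeps the test valid throughout a pass;
# six directional subiterations keep the skeleton centred.

# offsets and adjacency tables for the 27-cell neighbourhood, built once
.thin_env <- new.env(parent = emptyenv())

thin_tables <- function() {
  if (!is.null(.thin_env$tab)) return(.thin_env$tab)
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  centre <- which(rowSums(abs(g)) == 0L)
  man <- rowSums(abs(g))
  cheb <- apply(abs(g), 1L, max)
  adj26 <- vector("list", 27L)
  adj6 <- vector("list", 27L)
  for (p in 1:27) {
    dp <- outer(rep(1, 27), g[p, ], "*")
    dd <- abs(g - dp)
    adj26[[p]] <- setdiff(which(apply(dd, 1L, max) == 1L), centre)
    adj6[[p]] <- setdiff(which(rowSums(dd) == 1L), centre)
  }
  .thin_env$tab <- list(
    offsets = g, centre = centre,
    n26 = setdiff(which(cheb == 1L), centre),
    n18 = setdiff(which(man <= 2L & cheb == 1L), centre),
    n6 = setdiff(which(man == 1L), centre),
    adj26 = adj26, adj6 = adj6
  )
  .thin_env$tab
}

# count connected components of `cells` (indices into the 27-block) under the
# given adjacency lists
count_components_27 <- function(cells, adj) {
  if (length(cells) == 0L) return(0L)
  seen <- logical(27L)
  inset <- logical(27L)
  inset[cells] <- TRUE
  ncomp <- 0L
  for (s in cells) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue) > 0L) {
      cur <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      for (nb in adj[[cur]]) {
        if (inset[nb] && !seen[nb]) {
          seen[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
  }
  ncomp
}

is_simple_point <- function(nbhd, tab) {
  # nbhd: logical length-27 neighbourhood (centre included)
  fg <- intersect(tab$n26, which(nbhd))
  if (length(fg) == 0L) return(FALSE)
  if (count_components_27(fg, tab$adj26) != 1L) return(FALSE)
  bg18 <- intersect(tab$n18, which(!nbhd))
  # keep only the 6-connected background components touching a face neighbour
  if (length(intersect(bg18, tab$n6)) == 0L) return(FALSE)
  comps <- 0L
  seen <- logical(27L)
  inset <- logical(27L)
  inset[bg18] <- TRUE
  for (s in intersect(bg18, tab$n6)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue) > 0L) {
      cur <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      for (nb in tab$adj6[[cur]]) {
        if (inset[nb] && !seen[nb]) {
          seen[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
  }
  comps == 1L
}

neighbourhood27 <- function(pad, i, j, k) {
  # pad is the mask padded by one FALSE voxel on every side; (i,j,k) index
  # the padded array
  as.vector(pad[(i - 1L):(i + 1L), (j - 1L):(j + 1L), (k - 1L):(k + 1L)])
}

#' Skeletonize a 3D binary mask by topology-preserving thinning
#'
#' Iteratively deletes simple border voxels (six directional subiterations
#' per pass, sequential within a subiteration) until stable, preserving
#' curve endpoints (voxels with exactly one 26-neighbour). The result is a
#' one-voxel-wide centreline with the same number of connected components
#' and holes as the input.
#'
#' @param mask Logical 3D array, or a `bin_volume`.
#' @return Logical 3D array of skeleton voxels (same shape as the input).
#' @export
skeletonize_mask <- function(mask) {
  if (inherits(mask, "bin_volume")) mask <- mask$data
  tab <- thin_tables()
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)] <- mask
  dirs <- tab$n6  # one subiteration per face direction
  repeat {
    deleted_any <- FALSE
    for (dir in dirs) {
      off <- tab$offsets[dir, ]
      idx <- which(pad)
      if (length(idx) == 0L) break
      dp <- dim(pad)
      k <- (idx - 1L) %/% (dp[1L] * dp[2L]) + 1L
      rem <- (idx - 1L) %% (dp[1L] * dp[2L])
      j <- rem %/% dp[1L] + 1L
      i <- rem %% dp[1L] + 1L
      # border in this direction: the face neighbour along `off` is background
      nb_lin <- (k + off[3L] - 1L) * dp[1L] * dp[2L] + (j + off[2L] - 1L) * dp[1L] + (i + off[1L])
      cand <- which(!pad[nb_lin])
      for (c_i in cand) {
        ii <- i[c_i]; jj <- j[c_i]; kk <- k[c_i]
        nb <- neighbourhood27(pad, ii, jj, kk)
        if (sum(nb[tab$n26]) == 1L) next  # endpoint: keep
        if (is_simple_point(nb, tab)) {
          pad[ii, jj, kk] <- FALSE
          deleted_any <- TRUE
        }
      }
    }
    if (!deleted_any) break
  }
  pad[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)]
}

#' Topological precision, recall and clDICE
#'
#' Skeleton-in-mask overlap measures for tubular segmentations: precision
#' is the fraction of the predicted mask's skeleton voxels lying inside the
#' ground-truth mask, recall the fraction of the ground-truth skeleton
#' voxels lying inside the predicted mask, and clDICE their harmonic mean.
#' Swapping prediction and ground truth swaps precision and recall exactly.
#'
#' @param pred_mask,gt_mask `bin_volume`s of identical shape and voxel
#'   size.
#' @return Tibble with one row: `precision`, `recall`, `cl_dice`. Recall
#'   (and clDICE) are `NA` when the ground truth is empty.
#' @export
topo_precision_recall <- function(pred_mask, gt_mask) {
  if (!inherits(pred_mask, "bin_volume") || !inherits(gt_mask, "bin_volume")) {
    abort("both masks must be bin_volume objects")
  }
  if (!identical(dim(pred_mask$data), dim(gt_mask$data))) {
    abort("mask shapes differ")
  }
  if (!any(gt_mask$data)) {
    return(tibble::tibble(precision = NA_real_, recall = NA_real_, cl_dice = NA_real_))
  }
  skel_pred <- skeletonize_mask(pred_mask$data)
  skel_gt <- skeletonize_mask(gt_mask$data)
  precision <- if (any(skel_pred)) sum(skel_pred & gt_mask$data) / sum(skel_pred) else 0
  recall <- sum(skel_gt & pred_mask$data) / sum(skel_gt)
  cl_dice <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(precision = precision, recall = recall, cl_dice = cl_dice)
}

#' Detection rate of large vessels in a predicted mask
#'
#' A ground-truth segment with mean radius above the threshold counts as
#' detected when at least half of its centreline points fall on foreground
#' voxels of the predicted mask.
#'
#' @param gt_tree A `spatial_graph` with per-point radii (world µm).
#' @param pred_mask A `bin_volume`.
#' @param radius_threshold Minimum mean radius (µm) for a segment to
#'   qualify.
#' @return List: `rate` (detected / qualifying, `NA` when no segment
#'   qualifies), `per_segment` tibble (`segment`, `mean_radius`,
#'   `frac_on_foreground`, `detected`).
#' @export
detection_rate_by_radius <- function(gt_tree, pred_mask, radius_threshold) {
  stop_if_not_graph(gt_tree)
  geom <- segment_geometry(gt_tree)
  qualifying <- geom$segment[geom$mean_radius > radius_threshold]
  if (length(qualifying) == 0L) {
    return(list(rate = NA_real_, per_segment = tibble::tibble()))
  }
  d <- dim(pred_mask$data)
  per <- purrr::map_dfr(qualifying, function(sid) {
    p <- gt_tree$points[gt_tree$points$segment == sid, ]
    ijk <- world_to_voxel(pred_mask, as.matrix(p[, c("x", "y", "z")]))
    ok <- in_bounds(pred_mask, ijk)
    on_fg <- rep(FALSE, nrow(ijk))
    lin <- (ijk[ok, 3L] - 1L) * d[1L] * d[2L] + (ijk[ok, 2L] - 1L) * d[1L] + ijk[ok, 1L]
    on_fg[ok] <- pred_mask$data[lin]
    tibble::tibble(
      segment = sid,
      mean_radius = geom$mean_radius[geom$segment == sid],
      frac_on_foreground = mean(on_fg),
      detected = mean(on_fg) >= 0.5
    )
  })
  list(rate = mean(per$detected), per_segment = per)
}

#' Five-component skeleton super-metric
#'
#' Scores a candidate skeleton against the segmentation it was derived
#' from by projecting the discrepancy onto five components: relative volume
#' difference between the skeleton's tube reconstruction and the mask,
#' absolute difference in connected-component counts, absolute difference
#' in Euler characteristic, centreline sensitivity (fraction of skeleton
#' points on mask foreground) and bifurcation DICE (branch points matched
#' greedily within a capture radius). The combined score is the weighted
#' Euclidean norm of the component vector, with sensitivity and DICE
#' entering as (1 - value) so that 0 means perfect agreement; it is
#' homogeneous of degree 1 in the weights.
#'
#' @param skeleton A `spatial_graph` in the same µm frame as the mask.
#' @param seg_mask A non-empty `bin_volume`.
#' @param weights Non-negative length-5 vector (volume, components, Euler,
#'   sensitivity, bifurcation DICE); default all 1.
#' @param capture_radius_voxels Matching radius for branch points, in
#'   voxels (default 2).
#' @return List of class `supermetric_result`: `components` (named numeric,
#'   raw values), `deviations` (named numeric entering the norm), `score`.
#' @export
skeleton_supermetric <- function(skeleton, seg_mask, weights = rep(1, 5),
                                 capture_radius_voxels = 2) {
  stop_if_not_graph(skeleton)
  if (!inherits(seg_mask, "bin_volume")) abort("`seg_mask` must be a bin_volume")
  if (!any(seg_mask$data)) abort("segmentation mask is empty")
  if (length(weights) != 5L || any(weights < 0)) {
    abort("`weights` must be 5 non-negative values")
  }

  # tube reconstruction of the skeleton on the mask's grid
  recon <- voxelize_tree(skeleton,
    voxel_size = seg_mask$voxel_size,
    bounds = list(origin = seg_mask$origin, dim = dim(seg_mask$data))
  )
  vol_mask <- sum(seg_mask$data)
  vol_recon <- sum(recon$mask$data)
  vol_disc <- abs(vol_recon - vol_mask) / vol_mask

  cc_diff <- abs(n_components(recon$mask$data) - n_components(seg_mask$data))
  euler_diff <- abs(euler_characteristic(recon$mask$data) - euler_characteristic(seg_mask$data))

  d <- dim(seg_mask$data)
  ijk <- world_to_voxel(seg_mask, as.matrix(skeleton$points[, c("x", "y", "z")]))
  ok <- in_bounds(seg_mask, ijk)
  on_fg <- rep(FALSE, nrow(ijk))
  lin <- (ijk[ok, 3L] - 1L) * d[1L] * d[2L] + (ijk[ok, 2L] - 1L) * d[1L] + ijk[ok, 1L]
  on_fg[ok] <- seg_mask$data[lin]
  cl_sens <- mean(on_fg)

  bb_dice <- bifurcation_dice(skeleton, seg_mask,
    capture_radius = capture_radius_voxels * seg_mask$voxel_size
  )

  components <- c(
    volume = vol_disc, components = cc_diff, euler = euler_diff,
    cl_sensitivity = cl_sens, bifurcation_dice = bb_dice
  )
  deviations <- c(
    volume = vol_disc, components = as.numeric(cc_diff),
    euler = as.numeric(euler_diff),
    cl_sensitivity = 1 - cl_sens, bifurcation_dice = 1 - bb_dice
  )
  score <- sqrt(sum((weights * deviations)^2))
  structure(
    list(components = components, deviations = deviations, score = score,
         weights = weights),
    class = "supermetric_result"
  )
}

#' @export
print.supermetric_result <- function(x, ...) {
  cat(sprintf("<supermetric_result> score = %.4g\n", x$score))
  for (nm in names(x$components)) {
    cat(sprintf("  %-18s %.4g\n", nm, x$components[[nm]]))
  }
  invisible(x)
}

# 26-neighbour count of every voxel of a logical array, via shifted sums
neighbour_count26 <- function(mask) {
  d <- dim(mask)
  pad <- array(0L, d + 2L)
  pad[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)] <- mask
  out <- array(0L, d)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0L && dj == 0L && dk == 0L) next
    out <- out + pad[
      (2:(d[1L] + 1L)) + di, (2:(d[2L] + 1L)) + dj, (2:(d[3L] + 1L)) + dk
    ]
  }
  out
}

# remove skeleton spurs: peel endpoint voxels (<= 1 neighbour) `steps` times.
# Thinning a tube of inradius r voxels grows surface-bump spurs about r long,
# so callers peel by the mask's maximum inradius.
prune_spurs <- function(skel, steps) {
  for (s in seq_len(steps)) {
    nb <- neighbour_count26(skel)
    endpoints <- skel & nb <= 1L
    if (!any(endpoints)) break
    skel <- skel & !endpoints
  }
  skel
}

# branch points of the skeleton graph vs branch points of the thinned mask,
# matched greedily nearest-first within the capture radius; DICE of the match
bifurcation_dice <- function(skeleton, seg_mask, capture_radius) {
  segs <- skeleton$segments
  deg <- table(factor(c(segs$start_node, segs$end_node), levels = skeleton$nodes$node))
  branch_nodes <- skeleton$nodes[deg[as.character(skeleton$nodes$node)] >= 3L, ]
  skel_vox <- skeletonize_mask(seg_mask$data)
  inr_map <- distance_transform(!seg_mask$data, 1)  # inradius, voxel units
  inradius <- max(inr_map[seg_mask$data])
  skel_vox <- prune_spurs(skel_vox, ceiling(inradius) + 1L)
  mask_branch <- branch_voxels(skel_vox)
  if (nrow(branch_nodes) == 0L && nrow(mask_branch) == 0L) return(1)
  if (nrow(branch_nodes) == 0L || nrow(mask_branch) == 0L) return(0)
  a <- as.matrix(branch_nodes[, c("x", "y", "z")])
  b <- voxel_to_world(seg_mask, as.matrix(mask_branch))
  # a voxel skeleton localises a bifurcation only to where the child lumens
  # separate -- about one parent radius past the centreline junction -- so
  # the capture radius is floored at twice the local vessel inradius
  ijk_b <- matrix(pmax(round(mask_branch), 1L), ncol = 3L)
  d <- dim(inr_map)
  ijk_b[, 1L] <- pmin(ijk_b[, 1L], d[1L])
  ijk_b[, 2L] <- pmin(ijk_b[, 2L], d[2L])
  ijk_b[, 3L] <- pmin(ijk_b[, 3L], d[3L])
  thr_b <- pmax(capture_radius, 2 * inr_map[ijk_b] * seg_mask$voxel_size)
  dmat <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  dmat <- sqrt(pmax(dmat, 0))
  dmat[sweep(dmat, 2L, thr_b, `>`)] <- Inf
  matched <- 0L
  used_a <- logical(nrow(a))
  used_b <- logical(nrow(b))
  repeat {
    dmat_masked <- dmat
    dmat_masked[used_a, ] <- Inf
    dmat_masked[, used_b] <- Inf
    m <- which.min(dmat_masked)
    if (length(m) == 0L || !is.finite(dmat_masked[m])) break
    ia <- (m - 1L) %% nrow(a) + 1L
    ib <- (m - 1L) %/% nrow(a) + 1L
    used_a[ia] <- TRUE
    used_b[ib] <- TRUE
    matched <- matched + 1L
  }
  2 * matched / (nrow(a) + nrow(b))
}

# branch points of a voxel skeleton: voxels with 3+ foreground 26-neighbours,
# clustered (adjacent branch voxels arise at a single junction) and reduced to
# cluster centroids in voxel coordinates
branch_voxels <- function(skel) {
  if (!any(skel)) return(matrix(numeric(0), ncol = 3L))
  nb <- neighbour_count26(skel)
  branch <- skel & nb >= 3L
  if (!any(branch)) return(matrix(numeric(0), ncol = 3L))
  lab <- label_components(branch, connectivity = "full")
  idx <- which(branch, arr.ind = TRUE)
  grp <- lab[branch]
  out <- t(vapply(
    split(seq_len(nrow(idx)), grp),
    function(rows) colMeans(idx[rows, , drop = FALSE]),
    numeric(3)
  ))
  unname(out)
}
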