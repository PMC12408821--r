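#' Smoothing configuration for large-calibre centrelines
#'
#' Iterative weighted smoothing of centreline points: at each round every
#' interior point moves to the normalised convex combination of itself and
#' its two polyline neighbours. The neighbour weight (0.8) is split
#' symmetrically between the two neighbours and the triplet is normalised
#' by the weight sum, so the update is
#' p <- (0.4 p_prev + 0.1 p + 0.4 p_next) / 0.9. Endpoints never move and
#' radii are untouched. Only segments at or above the order threshold are
#' smoothed: large vessels accumulate centreline tortuosity from surface
#' noise during skeletonization, while small-vessel centrelines are already
#' at voxel scale.
#'
#' @param order_threshold Minimum truncated Strahler order smoothed
#'   (default 5).
#' @param w_neighbors Total weight of the two neighbour points (default 0.8).
#' @param w_current Weight of the current point (default 0.1).
#' @param iterations Number of smoothing rounds (default 15).
#' @return A `smoothing_config` list.
#' @export
smoothing_config <- function(order_threshold = 5L, w_neighbors = 0.8,
                             w_current = 0.1, iterations = 15L) {
  if (w_neighbors < 0 || w_current < 0) abort("weights must be non-negative")
  if (iterations < 0) abort("iterations must be >= 0")
  structure(
    list(
      order_threshold = order_threshold, w_neighbors = w_neighbors,
      w_current = w_current, iterations = iterations
    ),
    class = "smoothing_config"
  )
}

#' Smooth large-calibre centrelines
#'
#' @param tree A [root_tree()] result (any `spatial_graph` is accepted).
#' @param ordering Tibble `segment`, `order` from
#'   [assign_truncated_strahler()].
#' @param cfg A [smoothing_config()].
#' @return The graph with smoothed point coordinates on all segments whose
#'   order is at or above the threshold; segments with fewer than 3 points
#'   pass through unchanged. Node positions are endpoints and never move.
#' @export
smooth_centerlines <- function(tree, ordering, cfg = smoothing_config()) {
  stop_if_not_graph(tree)
  targets <- ordering$segment[ordering$order >= cfg$order_threshold]
  if (length(targets) == 0L || cfg$iterations == 0L) return(tree)
  wn <- cfg$w_neighbors / 2
  wc <- cfg$w_current
  denom <- cfg$w_neighbors + cfg$w_current
  pts <- tree$points
  for (sid in targets) {
    sel <- which(pts$segment == sid)
    if (length(sel) < 3L) next
    xyz <- as.matrix(pts[sel, c("x", "y", "z")])
    n <- nrow(xyz)
    for (it in seq_len(cfg$iterations)) {
      interior <- (wn * xyz[1:(n - 2L), , drop = FALSE] +
        wc * xyz[2:(n - 1L), , drop = FALSE] +
        wn * xyz[3:n, , drop = FALSE]) / denom
      xyz[2:(n - 1L), ] <- interior
    }
    pts[sel, c("x", "y", "z")] <- tibble::as_tibble(as.data.frame(xyz)) |>
      setNames(c("x", "y", "z"))
  }
  tree$points <- pts
  tree
}

#' Flag potentially collapsed segments
#'
#' All large-calibre segments (order at or above `order_threshold`) are
#' flagged `auto_large`: ex vivo, label-free imaging leaves every large
#' vessel suspect. Small-calibre segments are flagged `percentile_outlier`
#' when their mean radius falls below the given percentile of mean radii
#' within their own order; orders containing a single segment yield no
#' percentile flag.
#'
#' @param tree A `spatial_graph`.
#' @param ordering Tibble `segment`, `order`.
#' @param percentile Percentile threshold (default 10, i.e. the 10th
#'   percentile).
#' @param order_threshold Order at and above which segments are
#'   auto-flagged (default 5).
#' @return Tibble `segment`, `order`, `mean_radius`, `flag` with flag one
#'   of `"auto_large"`, `"percentile_outlier"`, `"none"`.
#' @export
flag_collapsed <- function(tree, ordering, percentile = 10, order_threshold = 5L) {
  stop_if_not_graph(tree)
  geom <- segment_geometry(tree)
  df <- dplyr::left_join(ordering, geom[, c("segment", "mean_radius")], by = "segment")
  df <- df |>
    dplyr::group_by(.data$order) |>
    dplyr::mutate(
      q = if (dplyr::n() > 1L) quantile(.data$mean_radius, percentile / 100) else NA_real_
    ) |>
    dplyr::ungroup()
  df$flag <- dplyr::case_when(
    df$order >= order_threshold ~ "auto_large",
    !is.na(df$q) & df$mean_radius < df$q ~ "percentile_outlier",
    TRUE ~ "none"
  )
  df[, c("segment", "order", "mean_radius", "flag")]
}

# sub-pixel perimeter of the TRUE region of a logical matrix, in pixel units.
# The binary raster is box-smoothed (3x3 mean) and the 0.5 level set traced by
# marching squares with linear edge interpolation; the smoothing anti-aliases
# the staircase so oblique boundaries measure at their true length instead of
# their Manhattan length. For pixels digitised centre-inside, the reconstructed
# boundary is unbiased for straight edges at any orientation.
marching_squares_perimeter <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 1L || nc < 1L || !any(m)) return(0)
  # pad by 2 so the smoothed field decays to 0 outside and contours close
  K <- matrix(0, nr + 4L, nc + 4L)
  K[3:(nr + 2L), 3:(nc + 2L)] <- m
  S <- matrix(0, nr + 4L, nc + 4L)
  for (di in -1:1) for (dj in -1:1) {
    S[2:(nr + 3L), 2:(nc + 3L)] <- S[2:(nr + 3L), 2:(nc + 3L)] +
      K[2:(nr + 3L) + di, 2:(nc + 3L) + dj]
  }
  S <- S / 9

  lvl <- 0.5
  per <- 0
  seg_len <- function(p, q) sqrt(sum((p - q)^2))
  for (j in seq_len(ncol(S) - 1L)) {
    for (i in seq_len(nrow(S) - 1L)) {
      a <- S[i, j]; b <- S[i + 1L, j]; c_ <- S[i + 1L, j + 1L]; d <- S[i, j + 1L]
      code <- (a >= lvl) + 2L * (b >= lvl) + 4L * (c_ >= lvl) + 8L * (d >= lvl)
      if (code == 0L || code == 15L) next
      # crossing points on the four cell edges (local cell coordinates)
      pAB <- c((lvl - a) / (b - a), 0)
      pBC <- c(1, (lvl - b) / (c_ - b))
      pCD <- c((lvl - d) / (c_ - d), 1)
      pDA <- c(0, (lvl - a) / (d - a))
      per <- per + switch(code,
        seg_len(pDA, pAB),                       #  1: A
        seg_len(pAB, pBC),                       #  2: B
        seg_len(pDA, pBC),                       #  3: A,B
        seg_len(pBC, pCD),                       #  4: C
        if ((a + b + c_ + d) / 4 >= lvl) {       #  5: A,C saddle
          seg_len(pAB, pBC) + seg_len(pCD, pDA)
        } else {
          seg_len(pDA, pAB) + seg_len(pBC, pCD)
        },
        seg_len(pAB, pCD),                       #  6: B,C
        seg_len(pCD, pDA),                       #  7: A,B,C
        seg_len(pCD, pDA),                       #  8: D
        seg_len(pAB, pCD),                       #  9: A,D
        if ((a + b + c_ + d) / 4 >= lvl) {       # 10: B,D saddle
          seg_len(pDA, pAB) + seg_len(pBC, pCD)
        } else {
          seg_len(pAB, pBC) + seg_len(pCD, pDA)
        },
        seg_len(pBC, pCD),                       # 11: A,B,D
        seg_len(pDA, pBC),                       # 12: C,D
        seg_len(pAB, pBC),                       # 13: A,C,D
        seg_len(pDA, pAB),                       # 14: B,C,D
        0
      )
    }
  }
  per
}

#' Extract a vessel cross-section from a binary volume
#'
#' Samples the plane normal to the centreline tangent at a point by
#' nearest-neighbour interpolation, keeps the in-plane connected component
#' containing the centre, and measures its perimeter with sub-pixel
#' (marching-squares) contour length. The equivalent radius is the radius
#' of the circle with that perimeter, perimeter / (2 pi) — the radius
#' estimate for a vessel whose lumen is patent in the mask even where the
#' skeleton under-reads it.
#'
#' @param volume A `bin_volume`.
#' @param point Centre of the plane, world µm (3-vector).
#' @param tangent Centreline direction at the point (nonzero 3-vector).
#' @param half_width Half-extent of the sampled plane, µm.
#' @param spacing In-plane sample spacing, µm (default: the voxel size).
#' @return A `cross_section` list: `raster` (logical matrix of the retained
#'   component), `spacing`, `perimeter` (µm), `area` (µm^2),
#'   `equivalent_radius` (µm), `empty` (TRUE when the centre lands on
#'   background, in which case the radius is `NA`).
#' @export
extract_cross_section <- function(volume, point, tangent, half_width,
                                  spacing = NULL) {
  if (!inherits(volume, "bin_volume")) abort("`volume` must be a bin_volume")
  if (vnorm(tangent) == 0) abort("`tangent` must be nonzero")
  spacing <- spacing %||% volume$voxel_size
  basis <- plane_basis(tangent)
  s <- seq(-half_width, half_width, by = spacing)
  grid <- expand.grid(a = s, b = s)
  coords <- outer(grid$a, basis$u) + outer(grid$b, basis$v)
  coords <- sweep(coords, 2L, point, `+`)
  ijk <- world_to_voxel(volume, coords)
  ok <- in_bounds(volume, ijk)
  vals <- rep(FALSE, nrow(ijk))
  d <- dim(volume$data)
  lin <- (ijk[ok, 3L] - 1L) * d[1L] * d[2L] + (ijk[ok, 2L] - 1L) * d[1L] + ijk[ok, 1L]
  vals[ok] <- volume$data[lin]
  raster <- matrix(vals, nrow = length(s))
  centre <- (length(s) + 1L) %/% 2L
  if (!raster[centre, centre]) {
    return(structure(
      list(
        raster = raster, spacing = spacing, perimeter = NA_real_,
        area = NA_real_, equivalent_radius = NA_real_, empty = TRUE
      ),
      class = "cross_section"
    ))
  }
  lab <- label_components(raster, connectivity = "face")
  keep <- lab == lab[centre, centre]
  per <- marching_squares_perimeter(keep) * spacing
  touches <- any(keep[1L, ]) || any(keep[nrow(keep), ]) ||
    any(keep[, 1L]) || any(keep[, ncol(keep)])
  structure(
    list(
      raster = keep, spacing = spacing, perimeter = per,
      area = sum(keep) * spacing^2,
      equivalent_radius = per / (2 * pi), empty = FALSE,
      touches_border = touches
    ),
    class = "cross_section"
  )
}

# central-difference tangents along a polyline (n x 3); endpoint one-sided
polyline_tangents <- function(xyz) {
  n <- nrow(xyz)
  t <- matrix(0, n, 3L)
  if (n == 1L) return(t)
  t[1L, ] <- xyz[2L, ] - xyz[1L, ]
  t[n, ] <- xyz[n, ] - xyz[n - 1L, ]
  if (n > 2L) t[2:(n - 1L), ] <- xyz[3:n, , drop = FALSE] - xyz[1:(n - 2L), , drop = FALSE]
  t
}

#' Correct collapsed-segment radii from a binary volume
#'
#' For each confirmed segment, a cross-section plane is extracted at every
#' centreline point and its equivalent radius computed; per-plane radii
#' outside the segment's 5th-95th percentile window are discarded (residual
#' centreline tortuosity produces oblique cuts with inflated perimeters),
#' and discarded or empty planes inherit the nearest valid plane's radius
#' along the polyline. Unconfirmed segments are untouched; topology is
#' never altered.
#'
#' @param tree A `spatial_graph`.
#' @param volume A `bin_volume` covering the flagged segments.
#' @param flags Tibble from [flag_collapsed()].
#' @param confirmations Tibble `segment`, `confirm` (logical) — the batch
#'   replacement for interactive review. Defaults to confirming every
#'   flagged segment.
#' @param window Percentile window for per-plane outlier removal (default
#'   `c(5, 95)`).
#' @param half_width_factor Plane half-width as a multiple of the segment's
#'   current mean radius (default 4).
#' @param per_segment_constant If `TRUE`, assign each corrected segment the
#'   mean of its valid plane radii instead of per-plane values.
#' @return The graph with corrected point radii; attribute `correction`
#'   holds a tibble `segment`, `n_planes`, `n_valid`, `corrected` (FALSE
#'   when no valid plane existed).
#' @export
correct_collapsed_radii <- function(tree, volume, flags,
                                    confirmations = NULL,
                                    window = c(5, 95),
                                    half_width_factor = 4,
                                    per_segment_constant = FALSE) {
  stop_if_not_graph(tree)
  flagged <- flags$segment[flags$flag != "none"]
  if (is.null(confirmations)) {
    confirmations <- tibble::tibble(segment = flagged, confirm = TRUE)
  }
  todo <- confirmations$segment[confirmations$confirm]
  todo <- intersect(todo, flagged)
  pts <- tree$points
  geom <- segment_geometry(tree)
  report <- purrr::map_dfr(todo, function(sid) {
    sel <- which(pts$segment == sid)
    xyz <- as.matrix(pts[sel, c("x", "y", "z")])
    hw0 <- half_width_factor * max(geom$mean_radius[geom$segment == sid], volume$voxel_size)
    tangents <- polyline_tangents(xyz)
    plane_r <- vapply(seq_len(nrow(xyz)), function(i) {
      # a collapsed skeleton under-reads the radius, so the initial window can
      # clip the true lumen; grow the plane until the retained component no
      # longer touches the window border
      hw <- hw0
      for (try in 1:8) {
        cs <- extract_cross_section(volume, xyz[i, ], tangents[i, ], hw)
        if (cs$empty || !cs$touches_border) break
        hw <- hw * 2
      }
      cs$equivalent_radius
    }, numeric(1))
    valid <- is.finite(plane_r)
    if (any(valid)) {
      lo <- quantile(plane_r[valid], window[1L] / 100)
      hi <- quantile(plane_r[valid], window[2L] / 100)
      valid <- valid & plane_r >= lo & plane_r <= hi
    }
    if (!any(valid)) {
      return(tibble::tibble(
        segment = sid, n_planes = nrow(xyz), n_valid = 0L, corrected = FALSE
      ))
    }
    vi <- which(valid)
    fill <- vapply(seq_len(nrow(xyz)), function(i) {
      plane_r[vi[which.min(abs(vi - i))]]
    }, numeric(1))
    new_r <- ifelse(valid, plane_r, fill)
    if (per_segment_constant) new_r <- rep(mean(plane_r[valid]), length(new_r))
    pts$radius[sel] <<- new_r
    tibble::tibble(
      segment = sid, n_planes = nrow(xyz), n_valid = sum(valid), corrected = TRUE
    )
  })
  tree$points <- pts
  attr(tree, "correction") <- report
  tree
}

#' Repair short collapsed stretches within a segment
#'
#' Pinch-point repair for a patent vessel with a short collapsed portion:
#' point radii below the segment's own 5th percentile are replaced by the
#' nearest (along the polyline) radius that is not itself below the
#' percentile. Positions are untouched.
#'
#' @param graph A `spatial_graph`.
#' @param percentile Percentile below which a point radius counts as
#'   collapsed (default 5).
#' @return The graph with repaired point radii.
#' @export
repair_short_collapses <- function(graph, percentile = 5) {
  stop_if_not_graph(graph)
  pts <- graph$points
  for (sid in unique(pts$segment)) {
    sel <- which(pts$segment == sid)
    if (length(sel) < 3L) next
    r <- pts$radius[sel]
    thr <- quantile(r, percentile / 100)
    bad <- r < thr
    if (!any(bad) || all(bad)) next
    good_idx <- which(!bad)
    r[bad] <- vapply(which(bad), function(i) {
      r[good_idx[which.min(abs(good_idx - i))]]
    }, numeric(1))
    pts$radius[sel] <- r
  }
  graph$points <- pts
  graph
}
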