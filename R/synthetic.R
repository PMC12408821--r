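#' Specification for a synthetic vascular tree
#'
#' Describes the statistical structure of a rooted arterial tree: number of
#' Strahler orders, branching ratio, root radius, the radial scaling rule
#' (child radius = parent radius x m^(-a) at a junction with m children,
#' which makes the scaling exponent exact by construction), per-order
#' length:diameter targets, branching-angle geometry and centreline
#' tortuosity noise. The defaults emulate the measured structure of a
#' whole human kidney arterial network: nine orders, branching ratio 2.9,
#' root radius 2900 µm, radial exponent 0.55, length:diameter falling from
#' ~57 at order 1 to ~10 at the root, branching angles around 140 degrees
#' and tortuosity close to 1.1.
#'
#' @param n_orders Number of truncated Strahler orders (root order).
#' @param branching_ratio Target branching ratio gamma (> 1). Junction
#'   child counts are drawn as 2 + Poisson(gamma - 2), so the expected
#'   per-order count ratio equals gamma; gamma = 2 gives a deterministic
#'   binary tree.
#' @param root_radius Root segment radius, µm.
#' @param radius_exponent Radial scaling exponent a: segment radius is
#'   r_root * (N_d / N_root)^a with N_d the segment's realized downstream
#'   endpoint count. This makes both the radial scaling law R ~ N_d^a and
#'   the generalized Murray relation r_p^(1/a) = sum r_c^(1/a) exact by
#'   construction for any topology (for a symmetric binary tree it reduces
#'   to the familiar halving rule r_c = r_p * 2^(-a)).
#' @param radius_noise SD of multiplicative log-normal radius scatter
#'   (0 = exact radii). The default 0.1 emulates the within-order radius
#'   dispersion seen in real whole-organ networks.
#' @param length_to_diameter Per-order length:diameter targets, indexed
#'   from order 1 upward; recycled/truncated to `n_orders`.
#' @param branching_angle Mean child-parent branching angle, degrees
#'   (straight continuation = 180).
#' @param angle_spread SD of the branching-angle deviation, degrees.
#' @param tortuosity_noise Amplitude of transverse centreline noise as a
#'   fraction of segment length (0 = perfectly straight polylines).
#' @param points_per_segment Polyline points per segment (>= 2).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @return A `tree_spec` list.
#' @export
tree_spec <- function(n_orders = 9L,
                      branching_ratio = 2.9,
                      root_radius = 2900,
                      radius_exponent = 0.55,
                      radius_noise = 0.1,
                      length_to_diameter = c(57, 32, 20, 15, 12, 8, 8.5, 9.6, 10),
                      branching_angle = 140,
                      angle_spread = 15,
                      tortuosity_noise = 0.02,
                      points_per_segment = 9L,
                      seed = 1L) {
  if (branching_ratio < 2) abort("branching_ratio must be >= 2 (each junction has >= 2 children)")
  if (n_orders < 1L) abort("n_orders must be >= 1")
  if (root_radius <= 0) abort("root_radius must be positive")
  ld <- rep_len(length_to_diameter, n_orders)
  # radii shrink by ~gamma^-a per order; reject specs that bottom out below 1 µm
  worst <- root_radius * (branching_ratio^-radius_exponent)^(n_orders - 1L)
  if (worst < 1) {
    abort(sprintf(
      "spec yields sub-micrometre radii at order 1 (%.3g um); increase root_radius or reduce n_orders",
      worst
    ))
  }
  if (radius_noise < 0) abort("radius_noise must be >= 0")
  structure(
    list(
      n_orders = as.integer(n_orders), branching_ratio = branching_ratio,
      root_radius = root_radius, radius_exponent = radius_exponent,
      radius_noise = radius_noise,
      length_to_diameter = ld, branching_angle = branching_angle,
      angle_spread = angle_spread, tortuosity_noise = tortuosity_noise,
      points_per_segment = as.integer(max(2L, points_per_segment)),
      seed = as.integer(seed)
    ),
    class = "tree_spec"
  )
}

#' Generate a synthetic rooted vascular tree
#'
#' Three deterministic passes given the seed. Topology: from the root order
#' down, each junction draws its child count m (2 + Poisson(gamma - 2));
#' all children take order one less than their parent. Radii: downstream
#' endpoint counts are tallied and each segment receives
#' r_root * (N_d / N_root)^a, optionally scattered by log-normal noise, so
#' the radial scaling exponent and the generalized Murray relation are
#' exact ground truth (up to the noise) whatever topology was realized.
#' Geometry: child directions deviate from the parent direction by the
#' branching angle with azimuths spread evenly around it, segment length is
#' the per-order length:diameter target times the diameter, and polylines
#' receive smooth transverse tortuosity noise with fixed endpoints.
#'
#' @param spec A [tree_spec()].
#' @return A `rooted_tree` whose segments table carries the generator's
#'   ground truth (`true_order`, `true_radius`).
#' @export
generate_tree <- function(spec) {
  if (!inherits(spec, "tree_spec")) abort("`spec` must be a tree_spec")
  set.seed(spec$seed)
  lambda <- spec$branching_ratio - 2

  # --- pass 1: topology (parent links, orders, child counts) ---------------
  parent <- integer(0)
  order <- integer(0)
  stack <- integer(0)
  add_seg <- function(p, o) {
    parent[length(parent) + 1L] <<- p
    order[length(order) + 1L] <<- o
    length(parent)
  }
  root_id <- add_seg(NA_integer_, spec$n_orders)
  stack <- c(stack, root_id)
  while (length(stack) > 0L) {
    sid <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    o <- order[sid]
    if (o == 1L) next
    m <- 2L + if (lambda > 0) rpois(1L, lambda) else 0L
    for (ci in seq_len(m)) {
      cid <- add_seg(sid, o - 1L)
      stack <- c(stack, cid)
    }
  }
  n_seg <- length(parent)
  kids <- split(seq_len(n_seg), factor(parent, levels = seq_len(n_seg)))

  # --- pass 2: downstream endpoint counts and radii -------------------------
  nd <- numeric(n_seg)
  for (sid in rev(seq_len(n_seg))) {  # children always have larger ids
    ch <- kids[[as.character(sid)]]
    nd[sid] <- if (length(ch) == 0L) 1 else sum(nd[ch])
  }
  radius <- spec$root_radius * (nd / nd[root_id])^spec$radius_exponent
  if (spec$radius_noise > 0) {
    radius <- radius * exp(rnorm(n_seg, 0, spec$radius_noise))
  }
  if (any(radius < 1)) {
    abort(sprintf(
      "spec yields sub-micrometre radii (min %.3g um); increase root_radius or reduce n_orders",
      min(radius)
    ))
  }

  # --- pass 3: geometry -----------------------------------------------------
  nodes_x <- numeric(n_seg + 1L)
  nodes_y <- numeric(n_seg + 1L)
  nodes_z <- numeric(n_seg + 1L)
  start_node <- integer(n_seg)
  end_node <- integer(n_seg)
  pt_rows <- vector("list", n_seg)
  # segment sid ends at node sid + 1; the root starts at node 1 (the origin)
  jobs <- list()
  jobs[[root_id]] <- list(start_node = 1L, start_pos = c(0, 0, 0), direction = c(0, 0, 1))
  for (sid in seq_len(n_seg)) {
    job <- jobs[[sid]]
    L <- spec$length_to_diameter[order[sid]] * 2 * radius[sid]
    end_pos <- job$start_pos + job$direction * L
    start_node[sid] <- job$start_node
    end_node[sid] <- sid + 1L
    nodes_x[sid + 1L] <- end_pos[1L]
    nodes_y[sid + 1L] <- end_pos[2L]
    nodes_z[sid + 1L] <- end_pos[3L]
    npts <- spec$points_per_segment
    tt <- seq(0, 1, length.out = npts)
    xyz <- outer(1 - tt, job$start_pos) + outer(tt, end_pos)
    if (spec$tortuosity_noise > 0 && npts > 2L) {
      basis <- plane_basis(job$direction)
      amp <- spec$tortuosity_noise * L
      ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
      w1 <- amp * sin(pi * tt) * sin(2 * pi * tt + ph1)
      w2 <- amp * sin(pi * tt) * cos(2 * pi * tt + ph2)
      xyz <- xyz + outer(w1, basis$u) + outer(w2, basis$v)
    }
    pt_rows[[sid]] <- tibble::tibble(
      segment = sid, x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
      radius = radius[sid]
    )
    ch <- kids[[as.character(sid)]]
    if (length(ch) > 0L) {
      m <- length(ch)
      dev <- (180 - spec$branching_angle) * pi / 180
      basis <- plane_basis(job$direction)
      az0 <- if (spec$angle_spread > 0) runif(1, 0, 2 * pi) else 0
      for (ci in seq_len(m)) {
        dev_i <- dev
        if (spec$angle_spread > 0) {
          dev_i <- abs(dev + rnorm(1, 0, spec$angle_spread * pi / 180))
        }
        az <- az0 + 2 * pi * (ci - 1L) / m
        axis <- cos(az) * basis$u + sin(az) * basis$v
        perp <- c(
          job$direction[2L] * axis[3L] - job$direction[3L] * axis[2L],
          job$direction[3L] * axis[1L] - job$direction[1L] * axis[3L],
          job$direction[1L] * axis[2L] - job$direction[2L] * axis[1L]
        )
        dir_c <- rotate_about(job$direction, perp, dev_i)
        jobs[[ch[ci]]] <- list(
          start_node = sid + 1L, start_pos = end_pos,
          direction = dir_c / vnorm(dir_c)
        )
      }
    }
  }

  nodes <- tibble::tibble(
    node = seq_len(n_seg + 1L),
    x = nodes_x, y = nodes_y, z = nodes_z
  )
  segments <- tibble::tibble(
    segment = seq_len(n_seg),
    start_node = start_node, end_node = end_node,
    true_order = order, true_radius = radius
  )
  g <- spatial_graph(
    nodes, segments, dplyr::bind_rows(pt_rows),
    provenance = sprintf("generate_tree(seed = %d)", spec$seed)
  )
  root_tree(g, root = 1L)
}

#' Perfect binary tree with a prescribed radius-halving exponent
#'
#' Convenience constructor for analytic checks: a noiseless symmetric
#' bifurcating tree over `n_orders` orders with child radius = parent
#' radius x 2^(-a). With a = 1/3 this is an exact Murray tree (cubed parent
#' radius equals the summed cubed child radii at every junction); with
#' a = 1/2 it is exactly area-preserving.
#'
#' @param n_orders Number of orders (root order).
#' @param radius_exponent Exponent a in the halving rule.
#' @param root_radius Root radius, µm.
#' @return A `rooted_tree`.
#' @export
example_binary_tree <- function(n_orders = 3L, radius_exponent = 1 / 3,
                                root_radius = 1000) {
  generate_tree(tree_spec(
    n_orders = n_orders, branching_ratio = 2, root_radius = root_radius,
    radius_exponent = radius_exponent, radius_noise = 0,
    length_to_diameter = rep(3, n_orders),
    branching_angle = 140, angle_spread = 0, tortuosity_noise = 0,
    points_per_segment = 5L, seed = 1L
  ))
}

#' Voxelize a vessel tree into a binary phantom volume
#'
#' A voxel is foreground exactly when its centre lies within the local
#' vessel radius of some subsegment: the centre must project onto the
#' subsegment (axial parameter within \[0, 1\], extended by half a voxel at
#' each end) with radial distance no greater than the linearly interpolated
#' point radius. Each subsegment is thus a finite cylinder without
#' spherical end caps, so a straight tube's voxel volume converges to
#' pi r^2 L (the half-voxel axial extension guarantees that every
#' centreline point, including vessel tips, lands on a foreground voxel,
#' at a volume cost of one voxel-length disc per free end).
#'
#' @param tree A `spatial_graph`.
#' @param voxel_size Isotropic voxel size, µm.
#' @param margin World-space margin added around the tree bounding box, µm.
#' @param voxel_budget Maximum voxel count permitted (default 512^3);
#'   exceeding it errors with advice to coarsen the voxel size.
#' @param bounds Optional list `origin`, `dim` to voxelize onto an existing
#'   grid instead of the tree's bounding box.
#' @return List: `mask` (a `bin_volume`), `graph` (the input tree, the
#'   phantom's ground truth).
#' @export
voxelize_tree <- function(tree, voxel_size, margin = NULL, voxel_budget = 512^3,
                          bounds = NULL) {
  stop_if_not_graph(tree)
  pts <- tree$points
  if (is.null(bounds)) {
    margin <- margin %||% (2 * max(pts$radius))
    lo <- c(min(pts$x), min(pts$y), min(pts$z)) - margin
    hi <- c(max(pts$x), max(pts$y), max(pts$z)) + margin
    dims <- pmax(as.integer(ceiling((hi - lo) / voxel_size)) + 1L, 1L)
    origin <- lo
  } else {
    origin <- bounds$origin
    dims <- as.integer(bounds$dim)
  }
  if (prod(as.numeric(dims)) > voxel_budget) {
    abort(sprintf(
      "requested volume is %s voxels, over the budget of %s; use a coarser voxel size",
      format(prod(as.numeric(dims)), big.mark = ","), format(voxel_budget, big.mark = ",")
    ))
  }
  mask <- array(FALSE, dims)

  ax_x <- origin[1L] + (seq_len(dims[1L]) - 1L) * voxel_size
  ax_y <- origin[2L] + (seq_len(dims[2L]) - 1L) * voxel_size
  ax_z <- origin[3L] + (seq_len(dims[3L]) - 1L) * voxel_size

  for (sid in unique(pts$segment)) {
    p <- pts[pts$segment == sid, ]
    xyz <- as.matrix(p[, c("x", "y", "z")])
    rr <- p$radius
    for (q in seq_len(nrow(xyz) - 1L)) {
      a <- xyz[q, ]; b <- xyz[q + 1L, ]
      r_max <- max(rr[q], rr[q + 1L])
      lo_i <- pmin(a, b) - r_max
      hi_i <- pmax(a, b) + r_max
      ix <- which(ax_x >= lo_i[1L] - voxel_size & ax_x <= hi_i[1L] + voxel_size)
      iy <- which(ax_y >= lo_i[2L] - voxel_size & ax_y <= hi_i[2L] + voxel_size)
      iz <- which(ax_z >= lo_i[3L] - voxel_size & ax_z <= hi_i[3L] + voxel_size)
      if (!length(ix) || !length(iy) || !length(iz)) next
      gx <- ax_x[ix]; gy <- ax_y[iy]; gz <- ax_z[iz]
      ab <- b - a
      len2 <- sum(ab^2)
      # projection parameter t of every local voxel centre onto the subsegment
      G <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
      t_par <- if (len2 > 0) {
        ((G[, 1L] - a[1L]) * ab[1L] + (G[, 2L] - a[2L]) * ab[2L] +
          (G[, 3L] - a[3L]) * ab[3L]) / len2
      } else {
        rep(0, nrow(G))
      }
      pad <- if (len2 > 0) voxel_size / (2 * sqrt(len2)) else 0
      in_slab <- t_par >= -pad & t_par <= 1 + pad
      t_cl <- pmin(pmax(t_par, 0), 1)
      cx <- a[1L] + t_cl * ab[1L]
      cy <- a[2L] + t_cl * ab[2L]
      cz <- a[3L] + t_cl * ab[3L]
      dist2 <- (G[, 1L] - cx)^2 + (G[, 2L] - cy)^2 + (G[, 3L] - cz)^2
      r_loc <- rr[q] + t_cl * (rr[q + 1L] - rr[q])
      inside <- in_slab & dist2 <= r_loc^2
      if (any(inside)) {
        idx_local <- as.matrix(expand.grid(i = ix, j = iy, k = iz))[inside, , drop = FALSE]
        mask[idx_local] <- TRUE
      }
    }
  }
  # the voxel holding each centreline point is always foreground, so vessel
  # tips are covered even when the nearest voxel centre falls just beyond the
  # cylinder end (at most one extra voxel per free end)
  vol <- bin_volume(mask, voxel_size, origin)
  ijk <- world_to_voxel(vol, as.matrix(pts[, c("x", "y", "z")]))
  ok <- in_bounds(vol, ijk)
  vol$data[ijk[ok, , drop = FALSE]] <- TRUE
  list(
    mask = vol,
    graph = tree
  )
}

#' Inject collapse artifacts into a phantom
#'
#' Emulates the skeleton under-reading patent lumens in ex vivo, label-free
#' imaging: a random fraction of segments has its graph (skeleton) radii
#' scaled down by `severity` while the mask keeps the true lumen, so the
#' correction machinery can be scored against ground truth. Optionally the
#' mask itself is thinned too.
#'
#' @param phantom A [voxelize_tree()] result.
#' @param fraction Fraction of segments to collapse, in \[0, 1\].
#' @param severity Radius scale factor applied to collapsed segments, in
#'   \[0, 1).
#' @param seed Integer seed.
#' @param thin_mask If `TRUE`, re-voxelize so the mask reflects the
#'   collapsed radii as well.
#' @return List: `phantom` (with modified graph and optionally mask),
#'   `collapsed` (tibble `segment`, `true_radius` of the altered
#'   segments).
#' @export
inject_collapse <- function(phantom, fraction, severity, seed = 1L,
                            thin_mask = FALSE) {
  if (fraction < 0 || fraction > 1) abort("`fraction` must be in [0, 1]")
  if (severity < 0 || severity >= 1) abort("`severity` must be in [0, 1)")
  g <- phantom$graph
  if (fraction == 0) {
    return(list(phantom = phantom, collapsed = tibble::tibble(
      segment = integer(0), true_radius = numeric(0)
    )))
  }
  set.seed(seed)
  segs <- g$segments$segment
  n_pick <- round(fraction * length(segs))
  pick <- sort(sample(segs, n_pick))
  geom <- segment_geometry(g)
  truth <- tibble::tibble(
    segment = pick,
    true_radius = geom$mean_radius[match(pick, geom$segment)]
  )
  sel <- g$points$segment %in% pick
  g$points$radius[sel] <- g$points$radius[sel] * severity
  phantom$graph <- g
  if (thin_mask) {
    phantom <- voxelize_tree(g, phantom$mask$voxel_size,
      bounds = list(origin = phantom$mask$origin, dim = dim(phantom$mask$data))
    )
  }
  list(phantom = phantom, collapsed = truth)
}

#' Generate a synthetic organ compartment label volume
#'
#' Concentric ellipsoidal shells emulating organ anatomy: an outer cortex
#' shell, a medulla shell, an inner hilum core, and pillar wedges crossing
#' the medulla (azimuthal sectors). Labels partition the organ ellipsoid
#' with no gaps or overlaps; voxels outside the organ are background.
#'
#' @param dims Voxel dimensions (length-3 integer).
#' @param voxel_size Voxel size, µm.
#' @param semi_axes Organ ellipsoid semi-axes, µm (default: fits the
#'   volume).
#' @param medulla_frac,hilum_frac Relative (linear) radii of the
#'   medulla-cortex and hilum-medulla interfaces, 0 < hilum < medulla < 1.
#'   The default medulla fraction 0.71 makes the cortex shell about 64% of
#'   the organ volume.
#' @param n_pillars Number of pillar wedges crossing the medulla.
#' @param pillar_halfwidth Angular half-width of each wedge, radians.
#' @return A `label_volume` with legend background/cortex/medulla/hilum/
#'   pillars, centred on the volume centre.
#' @export
generate_compartments <- function(dims = c(64L, 64L, 64L), voxel_size = 100,
                                  semi_axes = NULL,
                                  medulla_frac = 0.71, hilum_frac = 0.35,
                                  n_pillars = 4L, pillar_halfwidth = 0.15) {
  if (!(hilum_frac > 0 && hilum_frac < medulla_frac && medulla_frac < 1)) {
    abort("need 0 < hilum_frac < medulla_frac < 1 (nested shells)")
  }
  dims <- as.integer(dims)
  semi_axes <- semi_axes %||% ((dims - 2L) * voxel_size / 2)
  centre <- (dims - 1L) * voxel_size / 2
  ax <- (seq_len(dims[1L]) - 1L) * voxel_size - centre[1L]
  ay <- (seq_len(dims[2L]) - 1L) * voxel_size - centre[2L]
  az <- (seq_len(dims[3L]) - 1L) * voxel_size - centre[3L]
  X <- array(rep(ax, times = dims[2L] * dims[3L]), dims)
  Y <- array(rep(rep(ay, each = dims[1L]), times = dims[3L]), dims)
  Z <- array(rep(az, each = dims[1L] * dims[2L]), dims)
  rho <- sqrt((X / semi_axes[1L])^2 + (Y / semi_axes[2L])^2 + (Z / semi_axes[3L])^2)
  lab <- array(0L, dims)
  lab[rho <= 1] <- 1L                      # cortex
  lab[rho <= medulla_frac] <- 2L           # medulla
  lab[rho <= hilum_frac] <- 3L             # hilum
  if (n_pillars > 0L) {
    phi <- atan2(Y, X)
    in_medulla <- lab == 2L
    for (p in seq_len(n_pillars)) {
      phi0 <- -pi + (p - 0.5) * 2 * pi / n_pillars
      dphi <- atan2(sin(phi - phi0), cos(phi - phi0))
      lab[in_medulla & abs(dphi) <= pillar_halfwidth] <- 4L
    }
  }
  label_volume(lab, voxel_size,
    origin = c(0, 0, 0),
    legend = c(background = 0L, cortex = 1L, medulla = 2L, hilum = 3L, pillars = 4L)
  )
}
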