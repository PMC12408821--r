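# zig-zag polyline along the x axis with transverse amplitude `amp`
make_zigzag_graph <- function(n_points = 21, amp = 10, length_um = 1000, radius = 20) {
  x <- seq(0, length_um, length.out = n_points)
  y <- amp * rep_len(c(0, 1, 0, -1), n_points)
  y[c(1, n_points)] <- 0
  nodes <- tibble::tibble(node = 1:2, x = c(0, length_um), y = 0, z = 0)
  segs <- tibble::tibble(segment = 1L, start_node = 1L, end_node = 2L)
  pts <- tibble::tibble(segment = 1L, x = x, y = y, z = 0, radius = radius)
  spatial_graph(nodes, segs, pts)
}

ordering_all <- function(g, order = 5L) {
  tibble::tibble(segment = g$segments$segment, order = order)
}

test_that("smoothing reduces zig-zag tortuosity monotonically with fixed endpoints", {
  g <- make_zigzag_graph()
  tor <- tortuosity(g)$tortuosity
  prev <- g
  prev_tor <- tor
  for (k in 1:5) {
    cur <- smooth_centerlines(prev, ordering_all(g), smoothing_config(iterations = 1L))
    cur_tor <- tortuosity(cur)$tortuosity
    expect_lt(cur_tor, prev_tor)
    # endpoints pinned
    expect_equal(unlist(cur$points[1, c("x", "y", "z")]), c(x = 0, y = 0, z = 0))
    prev <- cur
    prev_tor <- cur_tor
  }
  # radii never touched by smoothing
  expect_identical(prev$points$radius, g$points$radius)
})

test_that("a straight segment is a fixed point of smoothing", {
  g <- make_tube_graph(n_points = 15)
  sm <- smooth_centerlines(g, ordering_all(g), smoothing_config())
  expect_equal(as.matrix(sm$points[, c("x", "y", "z")]),
    as.matrix(g$points[, c("x", "y", "z")]),
    tolerance = 1e-12, ignore_attr = TRUE
  )
  # 2-point segments pass through untouched
  g2 <- make_tube_graph(n_points = 2)
  sm2 <- smooth_centerlines(g2, ordering_all(g2), smoothing_config())
  expect_identical(sm2$points, g2$points)
})

test_that("smoothing only touches segments at or above the order threshold", {
  t <- example_binary_tree(3)
  ord <- assign_truncated_strahler(t)
  noisy <- t
  sel <- which(noisy$points$segment == 1L)
  mid <- sel[-c(1, length(sel))]
  noisy$points$y[mid] <- noisy$points$y[mid] + 5
  sm <- smooth_centerlines(noisy, ord, smoothing_config(order_threshold = 3L))
  # order-3 root segment smoothed, order-1 leaves identical
  leaf_ids <- ord$segment[ord$order == 1L]
  expect_identical(
    sm$points[sm$points$segment %in% leaf_ids, ],
    noisy$points[noisy$points$segment %in% leaf_ids, ]
  )
  expect_false(isTRUE(all.equal(
    sm$points$y[mid], noisy$points$y[mid]
  )))
})

test_that("smoothing matches a literal step-by-step recomputation", {
  # sinusoid-perturbed tube, default weights, 15 iterations
  n <- 41
  x <- seq(0, 2000, length.out = n)
  y <- 2 * sin(seq(0, 6 * pi, length.out = n))
  y[c(1, n)] <- 0
  nodes <- tibble::tibble(node = 1:2, x = c(0, 2000), y = 0, z = 0)
  segs <- tibble::tibble(segment = 1L, start_node = 1L, end_node = 2L)
  g <- spatial_graph(nodes, segs, tibble::tibble(
    segment = 1L, x = x, y = y, z = 0, radius = 50
  ))
  sm <- smooth_centerlines(g, ordering_all(g), smoothing_config())

  # oracle: literal loop over points and iterations
  P <- cbind(x, y, rep(0, n))
  for (it in 1:15) {
    Q <- P
    for (i in 2:(n - 1)) {
      Q[i, ] <- (0.4 * P[i - 1, ] + 0.1 * P[i, ] + 0.4 * P[i + 1, ]) / 0.9
    }
    P <- Q
  }
  expect_equal(as.matrix(sm$points[, c("x", "y", "z")]), P,
    tolerance = 1e-12, ignore_attr = TRUE
  )
  # tortuosity shrank toward 1
  expect_lt(tortuosity(sm)$tortuosity, tortuosity(g)$tortuosity)
})

test_that("collapse flagging combines the auto-large and percentile rules", {
  t <- generate_tree(tree_spec(
    n_orders = 6, branching_ratio = 3, root_radius = 1500, seed = 8
  ))
  ord <- assign_truncated_strahler(t)
  flags <- flag_collapsed(t, ord)
  expect_true(all(flags$flag[flags$order >= 5] == "auto_large"))
  expect_true(all(flags$flag[flags$order < 5] != "auto_large"))

  # identical radii within an order: no percentile outliers
  t0 <- example_binary_tree(4)
  ord0 <- assign_truncated_strahler(t0)
  flags0 <- flag_collapsed(t0, ord0, order_threshold = 99L)
  expect_true(all(flags0$flag == "none"))
})

test_that("planted collapses are recovered at the 10th percentile", {
  # collapse 10% of segments to a fifth of their radius; pooled over several
  # seeded replicates because single-tree recovery fluctuates with how the
  # 10%-per-order flag budget lands against the binomial planting counts
  planted_total <- 0L
  hit_total <- 0L
  for (s in 1:4) {
    t <- generate_tree(tree_spec(
      n_orders = 7, branching_ratio = 2.9, root_radius = 2900, seed = s
    ))
    ord <- assign_truncated_strahler(t)
    set.seed(100 + s)
    planted <- sample(t$segments$segment, round(0.1 * nrow(t$segments)))
    sel <- t$points$segment %in% planted
    t$points$radius[sel] <- t$points$radius[sel] * 0.2
    flags <- flag_collapsed(t, ord)
    hit <- flags$segment[flags$flag != "none"]
    planted_total <- planted_total + length(planted)
    hit_total <- hit_total + sum(planted %in% hit)
  }
  expect_gte(hit_total / planted_total, 0.9)
})

test_that("pinch points are repaired from the nearest patent radius", {
  g <- make_tube_graph(n_points = 20, radius = 50)
  g$points$radius[7] <- 5
  fixed <- repair_short_collapses(g)
  expect_equal(fixed$points$radius, rep(50, 20))
  # positions untouched
  expect_identical(fixed$points[, c("x", "y", "z")], g$points[, c("x", "y", "z")])

  # constant radii: nothing below the percentile, unchanged
  g2 <- make_tube_graph(n_points = 12, radius = 30)
  expect_identical(repair_short_collapses(g2)$points$radius, g2$points$radius)

  # monotone taper: at most the percentile-boundary point changes
  g3 <- make_tube_graph(n_points = 20)
  g3$points$radius <- seq(40, 20, length.out = 20)
  fixed3 <- repair_short_collapses(g3)
  expect_lte(sum(fixed3$points$radius != g3$points$radius), 1L)
})

test_that("cross-sections recover tube, prism and ellipse geometry", {
  # circular tube r = 100 um at 10 um voxels
  g <- make_tube_graph(length_um = 600, radius = 100, n_points = 7)
  ph <- voxelize_tree(g, 10)
  cs <- extract_cross_section(ph$mask, c(0, 0, 300), c(0, 0, 1), half_width = 200)
  expect_false(cs$empty)
  expect_lt(abs(cs$equivalent_radius - 100), 10)  # within one voxel
  expect_equal(cs$equivalent_radius, cs$perimeter / (2 * pi))

  # square prism, side 40 um: perimeter 4s, equivalent radius 2s/pi
  m <- array(FALSE, c(40, 40, 9))
  m[11:30, 11:30, ] <- TRUE
  vol <- bin_volume(m, 2)
  cs2 <- extract_cross_section(vol, c(40, 40, 8), c(0, 0, 1), half_width = 35)
  expect_equal(cs2$equivalent_radius, 2 * 40 / pi, tolerance = 0.05)

  # elliptical tube a = 60, b = 20: Ramanujan perimeter within 2%
  me <- array(FALSE, c(80, 40, 9))
  xs <- (seq_len(80) - 40.5) * 2
  ys <- (seq_len(40) - 20.5) * 2
  for (k in 1:9) {
    me[, , k] <- outer(xs, ys, function(x, y) (x / 60)^2 + (y / 20)^2 <= 1)
  }
  vole <- bin_volume(me, 2)
  # plane centre on the voxel lattice, as real centreline points are
  cs3 <- extract_cross_section(vole, c(78, 38, 8), c(0, 0, 1), half_width = 70)
  h <- ((60 - 20) / (60 + 20))^2
  p_ram <- pi * (60 + 20) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  expect_equal(cs3$perimeter, p_ram, tolerance = 0.02)

  # centre on background signals an empty section
  cs4 <- extract_cross_section(ph$mask, c(900, 900, 300), c(0, 0, 1), half_width = 50)
  expect_true(cs4$empty)
  expect_true(is.na(cs4$equivalent_radius))
})

test_that("collapsed radii are restored from the binary volume", {
  g <- make_tube_graph(length_um = 800, radius = 80, n_points = 17)
  ph <- voxelize_tree(g, 10)
  # skeleton under-reads the patent lumen: radii near zero
  collapsed <- ph$graph
  collapsed$points$radius <- 2
  flags <- tibble::tibble(segment = 1L, order = 5L, mean_radius = 2, flag = "auto_large")
  fixed <- correct_collapsed_radii(collapsed, ph$mask, flags)
  newr <- fixed$points$radius[fixed$points$segment == 1L]
  expect_lt(abs(mean(newr) - 80) / 80, 0.05)
  report <- attr(fixed, "correction")
  expect_true(report$corrected)

  # patent tube with correct radii: near-idempotent
  patent <- correct_collapsed_radii(ph$graph, ph$mask, flags)
  pr <- patent$points$radius[patent$points$segment == 1L]
  expect_lt(abs(mean(pr) - 80) / 80, 0.02)

  # per-segment-constant option assigns one radius
  fixed_const <- correct_collapsed_radii(collapsed, ph$mask, flags,
    per_segment_constant = TRUE
  )
  expect_equal(length(unique(fixed_const$points$radius)), 1L)

  # unconfirmed segments stay untouched
  skip_conf <- tibble::tibble(segment = 1L, confirm = FALSE)
  untouched <- correct_collapsed_radii(collapsed, ph$mask, flags, skip_conf)
  expect_identical(untouched$points$radius, collapsed$points$radius)
})

test_that("aberrant planes are excluded by the 5/95 percentile window", {
  # tube of radius 80 with two planted bulges (radius 160 at two interior
  # points): their planes fall above the 95th percentile and are replaced by
  # the nearest patent plane
  g <- make_tube_graph(length_um = 2000, radius = 80, n_points = 41)
  bulged <- g
  bulged$points$radius[c(15, 28)] <- 160
  ph <- voxelize_tree(bulged, 10)
  collapsed <- ph$graph
  collapsed$points$radius <- 2
  flags <- tibble::tibble(segment = 1L, order = 5L, mean_radius = 2, flag = "auto_large")
  fixed <- correct_collapsed_radii(collapsed, ph$mask, flags)
  rep <- attr(fixed, "correction")
  expect_lte(rep$n_valid, rep$n_planes - 2L)
  newr <- fixed$points$radius[fixed$points$segment == 1L]
  # the bulge planes were discarded and inherited patent-neighbour radii
  expect_true(all(newr < 120))
  expect_lt(abs(stats::median(newr) - 80) / 80, 0.05)

  # correction must never alter topology
  expect_identical(dim(fixed$points), dim(collapsed$points))
  expect_identical(fixed$segments, collapsed$segments)
  expect_identical(fixed$nodes, collapsed$nodes)
})
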