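test_that("tortuosity is 1 for straight segments and pi/2 for a semicircle", {
  expect_equal(tortuosity(make_tube_graph())$tortuosity, 1, tolerance = 1e-12)

  # semicircular arc of radius 100: arc pi*r over chord 2r
  theta <- seq(0, pi, length.out = 401)
  nodes <- tibble::tibble(node = 1:2, x = c(100, -100), y = 0, z = 0)
  segs <- tibble::tibble(segment = 1L, start_node = 1L, end_node = 2L)
  pts <- tibble::tibble(
    segment = 1L, x = 100 * cos(theta), y = 100 * sin(theta), z = 0, radius = 10
  )
  g <- spatial_graph(nodes, segs, pts)
  expect_equal(tortuosity(g)$tortuosity, pi / 2, tolerance = 1e-4)
})

test_that("tortuosity matches direct recomputation and rigid-motion invariance", {
  g <- random_tree_graph(20, seed = 12, n_mid = 3)
  expect_equal(tortuosity(g)$tortuosity, oracle_tortuosity(g), tolerance = 1e-12)

  # rotate + translate the whole graph: tortuosity and angles unchanged
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  shift <- c(1000, -500, 250)
  rot <- function(df) {
    m <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df$x <- m[, 1] + shift[1]; df$y <- m[, 2] + shift[2]; df$z <- m[, 3] + shift[3]
    df
  }
  g2 <- spatial_graph(rot(g$nodes), g$segments, rot(g$points))
  expect_equal(tortuosity(g2)$tortuosity, tortuosity(g)$tortuosity, tolerance = 1e-9)
  t1 <- root_tree(g, root = 1L)
  t2 <- root_tree(g2, root = 1L)
  expect_equal(
    branching_angles(t2)$angle, branching_angles(t1)$angle,
    tolerance = 1e-9
  )
})

test_that("branching angles follow the chord-vector construction", {
  # parent along +x from (0,0,0) to (100,0,0); children from there
  mk <- function(child_dirs) {
    n_child <- length(child_dirs)
    ends <- lapply(child_dirs, function(d) c(100, 0, 0) + 100 * d)
    nodes <- tibble::tibble(
      node = 1:(2 + n_child),
      x = c(0, 100, vapply(ends, `[`, numeric(1), 1L)),
      y = c(0, 0, vapply(ends, `[`, numeric(1), 2L)),
      z = c(0, 0, vapply(ends, `[`, numeric(1), 3L))
    )
    segs <- tibble::tibble(
      segment = 1:(1 + n_child),
      start_node = c(1L, rep(2L, n_child)),
      end_node = c(2L, 2L + seq_len(n_child))
    )
    pts <- purrr::map_dfr(seq_len(1 + n_child), function(s) {
      a <- unlist(nodes[segs$start_node[s], c("x", "y", "z")])
      b <- unlist(nodes[segs$end_node[s], c("x", "y", "z")])
      tibble::tibble(
        segment = s, x = c(a[1], b[1]), y = c(a[2], b[2]), z = c(a[3], b[3]),
        radius = 10
      )
    })
    root_tree(spatial_graph(nodes, segs, pts), root = 1L)
  }

  # collinear continuation: 180; orthogonal child: 90
  t <- mk(list(c(1, 0, 0), c(0, 1, 0)))
  cp <- branching_angles(t, "child_parent")
  expect_true(is.na(cp$angle[cp$segment == 1L]))  # root has no parent
  expect_equal(cp$angle[cp$segment == 2L], 180)
  expect_equal(cp$angle[cp$segment == 3L], 90)

  # symmetric Y at +/-60 degrees from the parent axis: child_child = 120
  s60 <- sin(pi / 3); c60 <- cos(pi / 3)
  ty <- mk(list(c(c60, s60, 0), c(c60, -s60, 0)))
  cc <- branching_angles(ty, "child_child")
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$angle, 120, tolerance = 1e-9)
  expect_equal(
    branching_angles(ty, "child_parent")$angle[-1], c(120, 120),
    tolerance = 1e-9
  )
})

test_that("segment volume follows the truncated-cone rule", {
  # cylinder r = 10, L = 100
  g <- make_tube_graph(length_um = 100, radius = 10, n_points = 5)
  expect_equal(segment_volume(g)$volume, pi * 100 * 100, tolerance = 1e-9)

  # linear taper 10 -> 20 over 100 um, 1000 subsegments vs exact frustum
  n <- 1001
  nodes <- tibble::tibble(node = 1:2, x = c(0, 100), y = 0, z = 0)
  segs <- tibble::tibble(segment = 1L, start_node = 1L, end_node = 2L)
  pts <- tibble::tibble(
    segment = 1L, x = seq(0, 100, length.out = n), y = 0, z = 0,
    radius = seq(10, 20, length.out = n)
  )
  g2 <- spatial_graph(nodes, segs, pts)
  frustum <- pi * 100 / 3 * (10^2 + 10 * 20 + 20^2)
  expect_equal(segment_volume(g2)$volume, frustum, tolerance = 1e-3)

  # zero radii give zero volume
  g3 <- g
  g3$points$radius <- 0
  expect_equal(segment_volume(g3)$volume, 0)
})

test_that("midpoint IVD matches constructions and brute force", {
  # two parallel aligned segments 500 um apart
  nodes <- tibble::tibble(
    node = 1:4,
    x = c(0, 1000, 0, 1000), y = c(0, 0, 500, 500), z = 0
  )
  segs <- tibble::tibble(segment = 1:2, start_node = c(1L, 3L), end_node = c(2L, 4L))
  pts <- purrr::map_dfr(1:2, function(s) {
    y <- if (s == 1L) 0 else 500
    tibble::tibble(segment = s, x = c(0, 1000), y = y, z = c(0, 0), radius = 10)
  })
  g <- spatial_graph(nodes, segs, pts)
  expect_equal(ivd_midpoint(g)$ivd, c(500, 500))

  # three collinear end-to-end segments of length L: middle IVD = L
  nodes2 <- tibble::tibble(node = 1:4, x = c(0, 300, 600, 900), y = 0, z = 0)
  segs2 <- tibble::tibble(segment = 1:3, start_node = 1:3, end_node = 2:4)
  pts2 <- purrr::map_dfr(1:3, function(s) {
    tibble::tibble(
      segment = s, x = c((s - 1) * 300, s * 300), y = c(0, 0), z = c(0, 0),
      radius = 10
    )
  })
  g2 <- spatial_graph(nodes2, segs2, pts2)
  expect_equal(ivd_midpoint(g2)$ivd[2], 300)

  # brute-force agreement on random graphs, and relabelling symmetry
  for (seed in c(5, 6, 7)) {
    gr <- random_tree_graph(15, seed = seed, n_mid = 2)
    expect_equal(ivd_midpoint(gr)$ivd, oracle_ivd(gr), tolerance = 1e-9)
  }

  # single-segment graph: null
  expect_true(is.na(ivd_midpoint(make_tube_graph())$ivd))
})

test_that("morphometry assembles the per-segment record table", {
  t <- generate_tree(tree_spec(n_orders = 5, branching_ratio = 3, root_radius = 600, seed = 3))
  rec <- morphometry(t)
  expect_equal(nrow(rec), nrow(t$segments))
  expect_true(all(c(
    "mean_radius", "length", "tortuosity", "length_diameter", "volume",
    "angle", "ivd", "order", "generation"
  ) %in% names(rec)))
  expect_true(all(rec$tortuosity >= 1 - 1e-9))
  expect_equal(rec$length_diameter, rec$length / (2 * rec$mean_radius))
  # root has no parent angle; all others defined
  expect_equal(sum(is.na(rec$angle)), 1L)
})

test_that("summaries group records by order with n, mean and SD", {
  t <- generate_tree(tree_spec(n_orders = 5, branching_ratio = 3, root_radius = 600, seed = 3))
  rec <- morphometry(t)
  tab <- summarize_morphometry(rec, "order")
  expect_equal(sum(tab$n), nrow(rec))
  expect_true(all(tab$mean_radius_sd >= 0, na.rm = TRUE))
  # radius grows with order by construction
  expect_true(all(diff(tab$mean_radius_mean) > 0))
  # single-group table covers everything
  rec$order <- 1L
  tab1 <- summarize_morphometry(rec, "order")
  expect_equal(tab1$n, nrow(rec))
})

test_that("per-order summaries reproduce the generator's radius structure", {
  spec <- tree_spec(
    n_orders = 5, branching_ratio = 3, root_radius = 810,
    radius_exponent = 0.5, seed = 14
  )
  t <- generate_tree(spec)
  rec <- morphometry(t)
  tab <- summarize_morphometry(rec, "order")
  # child radius = parent * m^-0.5 with m >= 2: each order's mean radius must
  # sit below its parent's by at least 2^-0.5, and ground-truth per-segment
  # radii match the recorded means exactly (radii are constant per segment)
  truth <- t$segments |>
    dplyr::left_join(rec[, c("segment", "order", "mean_radius")], by = "segment")
  expect_equal(truth$mean_radius, truth$true_radius, tolerance = 1e-9)
  ratio <- tab$mean_radius_mean[-1] / tab$mean_radius_mean[-nrow(tab)]
  expect_true(all(ratio >= sqrt(2) * 0.9))
})

test_that("segments are assigned to compartments and boundary-crossers excluded", {
  lab <- generate_compartments(dims = c(40L, 40L, 40L), voxel_size = 100)
  centre <- (c(40, 40, 40) - 1) * 100 / 2

  # wholly inside the cortex shell: a short segment near the organ edge
  r_cortex <- centre[1] + 1400  # between 0.71 and 1.0 of the semi-axis
  seg_in_cortex <- local({
    x0 <- centre[1] + 0.85 * (19 * 100)
    nodes <- tibble::tibble(node = 1:2, x = c(x0, x0), y = centre[2] + c(-50, 50), z = centre[3])
    segs <- tibble::tibble(segment = 1L, start_node = 1L, end_node = 2L)
    pts <- tibble::tibble(
      segment = 1L, x = x0, y = centre[2] + c(-50, 50), z = centre[3], radius = 20
    )
    spatial_graph(nodes, segs, pts)
  })
  res <- assign_compartments(seg_in_cortex, lab)
  expect_equal(res$segments$compartment, "cortex")

  # spanning hilum to cortex: excluded as multi-compartment
  spanning <- local({
    nodes <- tibble::tibble(
      node = 1:2, x = c(centre[1], centre[1] + 0.9 * 19 * 100),
      y = centre[2], z = centre[3]
    )
    segs <- tibble::tibble(segment = 1L, start_node = 1L, end_node = 2L)
    pts <- tibble::tibble(
      segment = 1L, x = seq(nodes$x[1], nodes$x[2], length.out = 20),
      y = centre[2], z = centre[3], radius = 20
    )
    spatial_graph(nodes, segs, pts)
  })
  res2 <- assign_compartments(spanning, lab)
  expect_true(is.na(res2$segments$compartment))
  excl <- attr(res2, "exclusion")
  expect_equal(excl$reason, "multi_compartment")

  # wholly outside the labelled space
  outside <- local({
    nodes <- tibble::tibble(node = 1:2, x = c(-5000, -4000), y = -5000, z = -5000)
    segs <- tibble::tibble(segment = 1L, start_node = 1L, end_node = 2L)
    pts <- tibble::tibble(
      segment = 1L, x = c(-5000, -4000), y = -5000, z = -5000, radius = 20
    )
    spatial_graph(nodes, segs, pts)
  })
  res3 <- assign_compartments(outside, lab)
  expect_equal(attr(res3, "exclusion")$reason, "outside_labels")
})

test_that("compartment exclusion matches an exhaustive per-point label audit", {
  lab <- generate_compartments(dims = c(32L, 32L, 32L), voxel_size = 120)
  t <- generate_tree(tree_spec(
    n_orders = 4, branching_ratio = 3, root_radius = 150,
    length_to_diameter = c(8, 6, 5, 4), seed = 6
  ))
  # centre the tree inside the organ
  centre <- (c(32, 32, 32) - 1) * 120 / 2
  shift <- centre - c(0, 0, 800)
  t$nodes[, c("x", "y", "z")] <- sweep(as.matrix(t$nodes[, c("x", "y", "z")]), 2, shift, `+`)
  t$points[, c("x", "y", "z")] <- sweep(as.matrix(t$points[, c("x", "y", "z")]), 2, shift, `+`)
  res <- assign_compartments(t, lab)
  excl <- attr(res, "exclusion")

  # oracle: per-point voxel lookup done longhand
  look <- function(p) {
    ijk <- round(unlist(p) / 120) + 1
    if (any(ijk < 1) || any(ijk > 32)) return(NA_integer_)
    lab$data[ijk[1], ijk[2], ijk[3]]
  }
  for (sid in t$segments$segment) {
    p <- t$points[t$points$segment == sid, ]
    labs <- unique(vapply(
      seq_len(nrow(p)),
      function(i) look(p[i, c("x", "y", "z")]), integer(1)
    ))
    labs <- labs[!is.na(labs) & labs != 0L]
    expected <- if (length(labs) == 1L) {
      names(lab$legend)[match(labs, lab$legend)]
    } else {
      NA_character_
    }
    got <- res$segments$compartment[res$segments$segment == sid]
    expect_identical(got, expected)
    if (length(labs) > 1L) {
      expect_true(sid %in% excl$segment[excl$reason == "multi_compartment"])
    }
  }
})
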