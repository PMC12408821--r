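test_that("a perfect binary tree gets textbook Strahler orders and generations", {
  t <- example_binary_tree(3)
  ord <- assign_truncated_strahler(t)
  expect_equal(as.integer(table(ord$order)), c(4L, 2L, 1L))
  gen <- assign_topological_generation(t)
  expect_equal(as.integer(table(gen$generation)), c(1L, 2L, 4L))
})

test_that("a chain through degree-2 nodes stays order 1, generation 1", {
  nodes <- tibble::tibble(node = 1:4, x = c(0, 1, 2, 3) * 100, y = 0, z = 0)
  segs <- tibble::tibble(segment = 1:3, start_node = 1:3, end_node = 2:4)
  pts <- purrr::map_dfr(1:3, function(s) {
    tibble::tibble(segment = s, x = c(s - 1, s) * 100, y = c(0, 0), z = c(0, 0), radius = 10)
  })
  t <- root_tree(spatial_graph(nodes, segs, pts), root = 1L)
  expect_true(all(assign_truncated_strahler(t)$order == 1L))
  expect_true(all(assign_topological_generation(t)$generation == 1L))
})

test_that("Strahler and generation match recursive oracles on random trees", {
  n_trees <- 200L
  for (seed in seq_len(n_trees)) {
    g <- random_tree_graph(sample(4:32, 1), seed = 1000 + seed)
    t <- root_tree(g, root = 1L)
    ord <- assign_truncated_strahler(t)
    expect_identical(ord$order, oracle_strahler(t))
    gen <- assign_topological_generation(t)
    expect_identical(gen$generation, oracle_generation(t))
    # order-1 segments always dominate every higher order
    oc <- order_counts(ord)
    expect_true(all(oc$n[oc$order == 1L] >= oc$n))
  }
})

test_that("Strahler orders survive segment re-indexing and chain subdivision", {
  g <- random_tree_graph(16, seed = 77)
  t <- root_tree(g, root = 1L)
  ord <- assign_truncated_strahler(t)

  # re-index segments (reverse ids); orders must follow the relabelling
  remap <- setNames(rev(g$segments$segment), g$segments$segment)
  segs2 <- g$segments
  segs2$segment <- remap[as.character(segs2$segment)]
  pts2 <- g$points
  pts2$segment <- remap[as.character(pts2$segment)]
  ord2 <- assign_truncated_strahler(root_tree(
    spatial_graph(g$nodes, segs2[order(segs2$segment), ], pts2), root = 1L
  ))
  expect_equal(
    ord2$order[match(remap[as.character(ord$segment)], ord2$segment)],
    ord$order
  )

  # subdivide one leaf segment by a degree-2 node: orders of others unchanged
  kids <- oracle_children(t)
  leaf <- as.integer(names(kids)[vapply(kids, length, integer(1)) == 0L])[1L]
  p <- g$points[g$points$segment == leaf, ]
  midpoint <- (unlist(p[1, c("x", "y", "z")]) + unlist(p[nrow(p), c("x", "y", "z")])) / 2
  new_node <- max(g$nodes$node) + 1L
  new_seg <- max(g$segments$segment) + 1L
  old_end <- g$segments$end_node[g$segments$segment == leaf]
  nodes3 <- dplyr::bind_rows(g$nodes, tibble::tibble(
    node = new_node, x = midpoint[1], y = midpoint[2], z = midpoint[3]
  ))
  segs3 <- g$segments
  segs3$end_node[segs3$segment == leaf] <- new_node
  segs3 <- dplyr::bind_rows(segs3, tibble::tibble(
    segment = new_seg, start_node = new_node, end_node = old_end
  ))
  first_half <- tibble::tibble(
    segment = leaf,
    x = c(p$x[1], midpoint[1]), y = c(p$y[1], midpoint[2]), z = c(p$z[1], midpoint[3]),
    radius = p$radius[1]
  )
  second_half <- tibble::tibble(
    segment = new_seg,
    x = c(midpoint[1], p$x[nrow(p)]), y = c(midpoint[2], p$y[nrow(p)]),
    z = c(midpoint[3], p$z[nrow(p)]), radius = p$radius[1]
  )
  pts3 <- dplyr::bind_rows(g$points[g$points$segment != leaf, ], first_half, second_half)
  t3 <- root_tree(spatial_graph(nodes3, segs3, pts3), root = 1L)
  ord3 <- assign_truncated_strahler(t3)
  common <- intersect(ord$segment, ord3$segment)
  expect_equal(
    ord3$order[match(common, ord3$segment)],
    ord$order[match(common, ord$segment)]
  )
})

test_that("max generation is 1 + branching nodes on the deepest root-leaf path", {
  for (seed in 1:20) {
    g <- random_tree_graph(sample(5:24, 1), seed = 300 + seed)
    t <- root_tree(g, root = 1L)
    gen <- assign_topological_generation(t)
    kids <- oracle_children(t)
    # enumerate root-leaf paths; count branching (>= 2 children) junctions
    segs <- t$segments
    paths_from <- function(sid) {
      ch <- kids[[as.character(sid)]]
      if (length(ch) == 0L) return(list(sid))
      unlist(lapply(ch, function(c2) {
        lapply(paths_from(c2), function(pth) c(sid, pth))
      }), recursive = FALSE)
    }
    roots <- segs$segment[is.na(segs$parent)]
    paths <- unlist(lapply(roots, paths_from), recursive = FALSE)
    deepest <- max(vapply(paths, function(pth) {
      1L + sum(vapply(
        pth[-length(pth)],
        function(sid) length(kids[[as.character(sid)]]) >= 2L, logical(1)
      ))
    }, integer(1)))
    expect_equal(max(gen$generation), deepest)
  }
})

test_that("branching ratio is exact on perfect counts and matches OLS on real tables", {
  # perfect binary counts: slope -ln 2 exactly
  fit <- fit_branching_ratio(tibble::tibble(order = 1:3, n = c(4, 2, 1)))
  expect_equal(fit$gamma, 2.0, tolerance = 1e-12)

  # counts generated exactly from the model N = N0 * gamma^(-O) recover
  # gamma/N0 to machine precision
  gamma_true <- 2.92
  N0_true <- 2e4
  counts <- tibble::tibble(order = 1:9, n = N0_true * gamma_true^(-(1:9)))
  fit2 <- fit_branching_ratio(counts)
  expect_equal(fit2$gamma, gamma_true, tolerance = 1e-10)
  expect_equal(fit2$N0, N0_true, tolerance = 1e-6)

  # whole-kidney per-order counts: all-order OLS, checked against a direct
  # closed-form least-squares evaluation
  kidney <- tibble::tibble(order = 1:9, n = c(5105, 3030, 1295, 516, 150, 69, 20, 8, 1))
  fit3 <- fit_branching_ratio(kidney)
  x <- kidney$order; y <- log(kidney$n)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit3$gamma, exp(-slope), tolerance = 1e-12)
  expect_equal(fit3$gamma, 2.825, tolerance = 1e-3)
  # restricting to orders 2-9 steepens the decay
  fit4 <- fit_branching_ratio(kidney, fit_range = 2:9)
  expect_equal(fit4$gamma, 2.993, tolerance = 1e-3)

  expect_error(fit_branching_ratio(tibble::tibble(order = 1, n = 5)), "at least 2")
  expect_warning(
    fit_branching_ratio(tibble::tibble(order = 1:3, n = c(4, 0, 1))),
    "zero"
  )
})

test_that("tidy and glance summarise a branching fit", {
  fit <- fit_branching_ratio(tibble::tibble(order = 1:3, n = c(9, 3, 1)))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "gamma"], 3, tolerance = 1e-10)
  gl <- glance(fit)
  expect_equal(gl$n_orders, 3L)
  expect_gt(gl$r.squared, 0.999)
})

test_that("anatomical mapping reports per-class counts and radii", {
  t <- generate_tree(tree_spec(n_orders = 6, branching_ratio = 3, root_radius = 1500, seed = 1))
  ord <- assign_truncated_strahler(t)
  geom <- segment_geometry(t)
  res <- map_orders_to_anatomy(ord, geom, tibble::tibble(
    class = c("large", "small", "everything", "absent"),
    order_min = c(4L, 1L, 1L, 9L),
    order_max = c(6L, 3L, 6L, 9L)
  ))
  oc <- order_counts(ord)
  expect_equal(res$n[res$class == "large"], sum(oc$n[oc$order >= 4]))
  expect_equal(res$n[res$class == "everything"], nrow(t$segments))
  expect_equal(res$n[res$class == "absent"], 0L)
  expect_true(is.na(res$mean_radius[res$class == "absent"]))
  # classes with larger orders have larger mean radii by construction
  expect_gt(
    res$mean_radius[res$class == "large"],
    res$mean_radius[res$class == "small"]
  )
})

test_that("missing-order estimation follows the log-ratio formula", {
  expect_equal(estimate_missing_orders(4, 2, 16), 2)
  expect_equal(estimate_missing_orders(500, 3, 500), 0)
  # whole-kidney scale: 5105 terminals, gamma 2.92, 1.2 million glomeruli
  expect_equal(estimate_missing_orders(5105, 2.92, 1.2e6), 5.095, tolerance = 1e-3)
  expect_error(estimate_missing_orders(10, 0.9, 100), "gamma")
  expect_error(estimate_missing_orders(-1, 2, 100), "positive")
})

test_that("glomerular extrapolation scales counts by cortex volume", {
  expect_equal(extrapolate_glomeruli(10, 5e8, 5e8)$pooled, 10)
  expect_equal(extrapolate_glomeruli(5, 2.5e8, 1e9)$pooled, 20)
  res <- extrapolate_glomeruli(c(10, 30), c(1e8, 2e8), 1e9)
  expect_equal(res$per_voi$estimate, c(100, 150))
  expect_equal(res$pooled, 125)
  expect_error(extrapolate_glomeruli(c(1, 2), 1e8, 1e9), "length")
})

test_that("pooled extrapolation recovers a Poisson field density", {
  # two VOIs sampled from a homogeneous Poisson field of known density
  set.seed(42)
  density <- 5e-9            # glomeruli per um^3
  total_volume <- 1e12
  voi_volumes <- c(2e10, 4e10)
  counts <- rpois(2, density * voi_volumes)
  res <- extrapolate_glomeruli(counts, voi_volumes, total_volume)
  truth <- density * total_volume
  se <- sqrt(mean((truth^2) / (density * voi_volumes)))  # delta-method scale
  expect_lt(abs(res$pooled - truth), 2 * se)
})
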