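# Independent oracle implementations and hand-built fixtures. Everything here
# works directly from node/segment tables by brute force, without calling the
# package's traversal code, so disagreements implicate the implementation.

# straight tube spatial graph along +z
make_tube_graph <- function(length_um = 1000, radius = 100, n_points = 11) {
  nodes <- tibble::tibble(node = 1:2, x = c(0, 0), y = c(0, 0), z = c(0, length_um))
  segs <- tibble::tibble(segment = 1L, start_node = 1L, end_node = 2L)
  pts <- tibble::tibble(
    segment = 1L, x = 0, y = 0,
    z = seq(0, length_um, length.out = n_points), radius = radius
  )
  spatial_graph(nodes, segs, pts)
}

# random tree: each new segment starts at a uniformly chosen existing node
# (creating pass-through chains and multifurcations) and ends at a fresh node
random_tree_graph <- function(n_segments, seed, n_mid = 0L) {
  set.seed(seed)
  nodes <- tibble::tibble(node = 1L, x = 0, y = 0, z = 0)
  segs <- tibble::tibble(
    segment = integer(0), start_node = integer(0), end_node = integer(0)
  )
  pts <- list()
  for (s in seq_len(n_segments)) {
    from <- sample(nodes$node, 1L)
    p0 <- unlist(nodes[nodes$node == from, c("x", "y", "z")])
    p1 <- p0 + runif(3, -100, 100)
    while (sum((p1 - p0)^2) == 0) p1 <- p0 + runif(3, -100, 100)
    nid <- nrow(nodes) + 1L
    nodes <- dplyr::bind_rows(nodes, tibble::tibble(
      node = nid, x = p1[1], y = p1[2], z = p1[3]
    ))
    k <- n_mid + 2L
    tt <- seq(0, 1, length.out = k)
    mid <- outer(1 - tt, p0) + outer(tt, p1)
    if (n_mid > 0L) {
      jitter <- matrix(runif(3L * n_mid, -5, 5), ncol = 3L)
      mid[2:(k - 1L), ] <- mid[2:(k - 1L), , drop = FALSE] + jitter
    }
    segs <- dplyr::bind_rows(segs, tibble::tibble(
      segment = s, start_node = from, end_node = nid
    ))
    pts[[s]] <- tibble::tibble(
      segment = s, x = mid[, 1], y = mid[, 2], z = mid[, 3],
      radius = runif(1, 5, 50)
    )
  }
  spatial_graph(nodes, segs, dplyr::bind_rows(pts))
}

# children-of-segment structure by brute force from an oriented rooted tree
oracle_children <- function(tree) {
  segs <- tree$segments
  lapply(setNames(segs$segment, segs$segment), function(sid) {
    end_n <- segs$end_node[segs$segment == sid]
    sort(segs$segment[segs$start_node == end_n & segs$segment != sid])
  })
}

# recursive textbook Strahler definition
oracle_strahler <- function(tree) {
  kids <- oracle_children(tree)
  memo <- new.env()
  rec <- function(sid) {
    key <- as.character(sid)
    if (!is.null(memo[[key]])) return(memo[[key]])
    ch <- kids[[key]]
    val <- if (length(ch) == 0L) {
      1L
    } else {
      os <- vapply(ch, rec, integer(1))
      m <- max(os)
      if (sum(os == m) >= 2L) m + 1L else m
    }
    memo[[key]] <- val
    val
  }
  vapply(tree$segments$segment, rec, integer(1))
}

# recursive generation: +1 below every node with >= 2 child segments
oracle_generation <- function(tree) {
  segs <- tree$segments
  kids <- oracle_children(tree)
  rec <- function(sid) {
    p <- segs$parent[segs$segment == sid]
    if (is.na(p)) return(1L)
    inc <- if (length(kids[[as.character(p)]]) >= 2L) 1L else 0L
    rec(p) + inc
  }
  vapply(segs$segment, rec, integer(1))
}

# per-segment leaf count by exhaustive subtree enumeration
oracle_tip_counts <- function(tree) {
  kids <- oracle_children(tree)
  rec <- function(sid) {
    ch <- kids[[as.character(sid)]]
    if (length(ch) == 0L) return(1L)
    sum(vapply(ch, rec, integer(1)))
  }
  vapply(tree$segments$segment, rec, integer(1))
}

# breadth-first orientation oracle: parent node of every node, from root
oracle_bfs_orientation <- function(graph, root) {
  segs <- graph$segments
  parent_node <- setNames(rep(NA_integer_, nrow(graph$nodes)), graph$nodes$node)
  visited <- setNames(logical(nrow(graph$nodes)), graph$nodes$node)
  visited[as.character(root)] <- TRUE
  queue <- root
  while (length(queue) > 0L) {
    n <- queue[[1L]]; queue <- queue[-1L]
    inc <- segs[segs$start_node == n | segs$end_node == n, ]
    for (i in seq_len(nrow(inc))) {
      other <- if (inc$start_node[i] == n) inc$end_node[i] else inc$start_node[i]
      if (!visited[as.character(other)]) {
        visited[as.character(other)] <- TRUE
        parent_node[as.character(other)] <- n
        queue <- c(queue, other)
      }
    }
  }
  parent_node
}

# direct arc/chord recomputation
oracle_tortuosity <- function(graph) {
  vapply(graph$segments$segment, function(sid) {
    p <- graph$points[graph$points$segment == sid, ]
    xyz <- as.matrix(p[, c("x", "y", "z")])
    arc <- sum(sqrt(rowSums(diff(xyz)^2)))
    chord <- sqrt(sum((xyz[nrow(xyz), ] - xyz[1, ])^2))
    arc / chord
  }, numeric(1))
}

# O(n^2) midpoint IVD with its own midpoint walker
oracle_ivd <- function(graph) {
  mids <- t(vapply(graph$segments$segment, function(sid) {
    p <- graph$points[graph$points$segment == sid, ]
    xyz <- as.matrix(p[, c("x", "y", "z")])
    steps <- sqrt(rowSums(diff(xyz)^2))
    cum <- c(0, cumsum(steps))
    half <- cum[length(cum)] / 2
    i <- max(which(cum <= half))
    i <- min(i, nrow(xyz) - 1L)
    f <- if (steps[i] > 0) (half - cum[i]) / steps[i] else 0
    xyz[i, ] + f * (xyz[i + 1L, ] - xyz[i, ])
  }, numeric(3)))
  n <- nrow(mids)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt(rowSums((mids[-i, , drop = FALSE] -
      matrix(mids[i, ], n - 1L, 3L, byrow = TRUE))^2))
    out[i] <- min(d)
  }
  out
}

# (radius, n_downstream) pairs for a rooted tree, via package accessors
scaling_pairs <- function(tree) {
  dplyr::left_join(
    segment_geometry(tree)[, c("segment", "mean_radius")],
    downstream_tip_counts(tree),
    by = "segment"
  ) |>
    dplyr::rename(radius = "mean_radius")
}
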