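#' Construct a vessel spatial graph
#'
#' A spatial graph is the skeleton representation of a vessel network:
#' `nodes` are 3D locations where vessels meet or end, `segments` connect
#' pairs of nodes, and each segment carries an ordered polyline of `points`
#' with a radius at every point. All coordinates and radii are in micrometres
#' (world space); voxel indices appear only inside volume operations.
#'
#' @param nodes Tibble with columns `node` (unique integer id), `x`, `y`, `z`.
#' @param segments Tibble with columns `segment` (unique integer id),
#'   `start_node`, `end_node` referencing `nodes$node`. Extra columns (e.g.
#'   `compartment`) are preserved.
#' @param points Tibble with columns `segment`, `x`, `y`, `z`, `radius`,
#'   ordered along each segment from its start node to its end node; the
#'   first/last point of a segment must coincide with its start/end node
#'   positions. Radii are per point and non-negative.
#' @param provenance Free-text provenance recorded in the metadata.
#'
#' @return An object of class `spatial_graph`: a list with tibbles `nodes`,
#'   `segments`, `points` and a `metadata` list (`units = "um"`).
#'
#' @details Segments must have at least two points, positive arc length and
#'   no repeated consecutive points; zero-length segments are rejected
#'   outright because they break tortuosity and branching-angle definitions.
#'   Multifurcations (more than two children meeting at a node) are allowed.
#'
#' @examples
#' g <- example_binary_tree(n_orders = 3)
#' g
#' validate_graph(g)
#' @export
spatial_graph <- function(nodes, segments, points, provenance = "") {
  nodes <- tibble::as_tibble(nodes)
  segments <- tibble::as_tibble(segments)
  points <- tibble::as_tibble(points)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0L) {
      abort(sprintf("%s table is missing column(s): %s", what, paste(miss, collapse = ", ")))
    }
  }
  need(nodes, c("node", "x", "y", "z"), "nodes")
  need(segments, c("segment", "start_node", "end_node"), "segments")
  need(points, c("segment", "x", "y", "z", "radius"), "points")

  if (anyDuplicated(nodes$node)) abort("node ids must be unique")
  if (anyDuplicated(segments$segment)) abort("segment ids must be unique")
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z")])))) {
    abort("node positions must be finite")
  }
  bad_ref <- !(segments$start_node %in% nodes$node) | !(segments$end_node %in% nodes$node)
  if (any(bad_ref)) {
    abort(sprintf(
      "segment(s) %s reference nodes that do not exist",
      paste(segments$segment[bad_ref], collapse = ", ")
    ))
  }
  if (any(points$radius < 0, na.rm = TRUE)) abort("point radii must be >= 0")
  if (!all(points$segment %in% segments$segment)) {
    abort("points reference unknown segment ids")
  }

  # per-segment geometry checks
  pts_split <- split(points, factor(points$segment, levels = segments$segment))
  node_pos <- as.matrix(nodes[, c("x", "y", "z")])
  rownames(node_pos) <- as.character(nodes$node)
  for (i in seq_len(nrow(segments))) {
    sid <- segments$segment[i]
    p <- pts_split[[i]]
    if (is.null(p) || nrow(p) < 2L) {
      abort(sprintf("segment %s has fewer than 2 points", sid))
    }
    xyz <- as.matrix(p[, c("x", "y", "z")])
    steps <- vnorm(diff(xyz))
    if (any(steps == 0)) {
      abort(sprintf("segment %s has repeated consecutive points", sid))
    }
    if (sum(steps) <= 0) {
      abort(sprintf("segment %s has zero arc length", sid))
    }
    a <- node_pos[as.character(segments$start_node[i]), ]
    b <- node_pos[as.character(segments$end_node[i]), ]
    tol <- 1e-6 * max(1, max(abs(xyz)))
    if (vnorm(xyz[1L, ] - a) > tol || vnorm(xyz[nrow(p), ] - b) > tol) {
      abort(sprintf("segment %s endpoints do not coincide with its start/end nodes", sid))
    }
  }

  structure(
    list(
      nodes = nodes,
      segments = segments,
      points = points,
      metadata = list(units = "um", provenance = provenance)
    ),
    class = "spatial_graph"
  )
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf(
    "<spatial_graph> %d nodes, %d segments, %d points (units: %s)\n",
    nrow(x$nodes), nrow(x$segments), nrow(x$points), x$metadata$units
  ))
  if (inherits(x, "rooted_tree")) {
    cat(sprintf("  rooted at node %d\n", x$root_node))
  }
  invisible(x)
}

#' Per-segment arc lengths and mean radii
#'
#' @param graph A `spatial_graph`.
#' @return Tibble with one row per segment: `segment`, `length` (arc length,
#'   µm), `mean_radius` (mean of all point radii, µm), `n_points`.
#' @export
segment_geometry <- function(graph) {
  stop_if_not_graph(graph)
  graph$points |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(
      length = polyline_length(cbind(.data$x, .data$y, .data$z)),
      mean_radius = mean(.data$radius),
      n_points = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$segment)
}

#' Integrity report for a spatial graph
#'
#' Reports (without erroring) orphan nodes, zero-length segments, duplicate
#' edges, cycles and disconnected components, together with the node, segment
#' and point counts. A clean tree reports zero defects and one component.
#'
#' @param graph A `spatial_graph`.
#' @return A list of class `graph_report`: `counts` (nodes, segments,
#'   points), `orphan_nodes`, `zero_length_segments`, `duplicate_edges`
#'   (segment ids beyond the first occurrence of each node pair),
#'   `n_components`, `components` (tibble node -> component), `cycles`
#'   (list of node-id vectors, one per independent cycle found), and
#'   `n_defects`.
#' @export
validate_graph <- function(graph) {
  stop_if_not_graph(graph)
  nodes <- graph$nodes
  segs <- graph$segments

  used <- unique(c(segs$start_node, segs$end_node))
  orphan <- setdiff(nodes$node, used)

  geom <- segment_geometry(graph)
  zero_len <- geom$segment[geom$length <= 0]

  key <- paste(pmin(segs$start_node, segs$end_node), pmax(segs$start_node, segs$end_node))
  dup <- segs$segment[duplicated(key)]

  # connected components by BFS over the node adjacency
  adj <- split(
    c(segs$end_node, segs$start_node),
    factor(c(segs$start_node, segs$end_node), levels = nodes$node)
  )
  comp <- setNames(rep(NA_integer_, nrow(nodes)), nodes$node)
  cid <- 0L
  for (start in nodes$node) {
    if (!is.na(comp[as.character(start)])) next
    cid <- cid + 1L
    queue <- start
    comp[as.character(start)] <- cid
    while (length(queue) > 0L) {
      n <- queue[[1L]]; queue <- queue[-1L]
      for (nb in adj[[as.character(n)]]) {
        if (is.na(comp[as.character(nb)])) {
          comp[as.character(nb)] <- cid
          queue <- c(queue, nb)
        }
      }
    }
  }

  cycles <- find_cycles(nodes$node, segs)

  rep <- list(
    counts = c(nodes = nrow(nodes), segments = nrow(segs), points = nrow(graph$points)),
    orphan_nodes = orphan,
    zero_length_segments = zero_len,
    duplicate_edges = dup,
    n_components = max(comp, 0L),
    components = tibble::tibble(node = nodes$node, component = unname(comp)),
    cycles = cycles
  )
  rep$n_defects <- length(orphan) + length(zero_len) + length(dup) +
    length(cycles) + max(rep$n_components - 1L, 0L)
  class(rep) <- "graph_report"
  rep
}

#' @export
print.graph_report <- function(x, ...) {
  cat(sprintf(
    "<graph_report> %d nodes, %d segments, %d points\n",
    x$counts[["nodes"]], x$counts[["segments"]], x$counts[["points"]]
  ))
  cat(sprintf(
    "  defects: %d (orphans %d, zero-length %d, duplicate edges %d, cycles %d, extra components %d)\n",
    x$n_defects, length(x$orphan_nodes), length(x$zero_length_segments),
    length(x$duplicate_edges), length(x$cycles), max(x$n_components - 1L, 0L)
  ))
  invisible(x)
}

# independent cycles via DFS spanning forest; returns list of node-id paths
find_cycles <- function(node_ids, segs) {
  parent <- setNames(rep(NA_integer_, length(node_ids)), node_ids)
  visited <- setNames(rep(FALSE, length(node_ids)), node_ids)
  edge_list <- Map(c, segs$start_node, segs$end_node)
  adj <- list()
  for (i in seq_along(edge_list)) {
    a <- as.character(edge_list[[i]][1L]); b <- as.character(edge_list[[i]][2L])
    adj[[a]] <- c(adj[[a]], list(c(edge_list[[i]][2L], i)))
    adj[[b]] <- c(adj[[b]], list(c(edge_list[[i]][1L], i)))
  }
  cycles <- list()
  used_edge <- rep(FALSE, nrow(segs))
  for (start in node_ids) {
    if (visited[as.character(start)]) next
    stack <- list(c(start, 0L))
    visited[as.character(start)] <- TRUE
    while (length(stack) > 0L) {
      top <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      n <- top[1L]
      for (e in adj[[as.character(n)]] %||% list()) {
        nb <- e[1L]; eid <- e[2L]
        if (used_edge[eid]) next
        used_edge[eid] <- TRUE
        if (!visited[as.character(nb)]) {
          visited[as.character(nb)] <- TRUE
          parent[as.character(nb)] <- n
          stack <- c(stack, list(c(nb, eid)))
        } else {
          # back edge: walk both endpoints to root collecting the cycle path
          path_a <- n
          while (!is.na(parent[as.character(path_a[length(path_a)])])) {
            path_a <- c(path_a, parent[as.character(path_a[length(path_a)])])
          }
          path_b <- nb
          while (!is.na(parent[as.character(path_b[length(path_b)])])) {
            path_b <- c(path_b, parent[as.character(path_b[length(path_b)])])
          }
          common <- intersect(path_a, path_b)
          meet <- common[which.min(match(common, path_a))]
          ia <- match(meet, path_a); ib <- match(meet, path_b)
          cyc <- c(path_a[seq_len(ia)], rev(path_b[seq_len(ib - 1L)]))
          cycles <- c(cycles, list(cyc))
        }
      }
    }
  }
  cycles
}

#' Orient a spatial graph as a rooted tree
#'
#' Directs every segment away from a root node so that downstream analyses
#' (ordering, tip counting, scaling) can traverse parent/child structure.
#' With `root = NULL` the root is chosen automatically as the degree-1 node
#' whose incident segment has the largest mean radius — appropriate for an
#' arterial network whose feeding artery was cut, leaving the widest stump
#' as a free end.
#'
#' @param graph A connected, acyclic `spatial_graph`.
#' @param root Node id to use as root, or `NULL` for automatic selection.
#' @return A `rooted_tree` (subclass of `spatial_graph`): segment rows gain a
#'   `parent` column (parent segment id, `NA` for segments incident to the
#'   root) and segments/points are re-oriented so `start_node` is proximal.
#'   Child lists are ordered by segment id.
#' @export
root_tree <- function(graph, root = NULL) {
  stop_if_not_graph(graph)
  rep <- validate_graph(graph)
  if (length(rep$cycles) > 0L) {
    abort(sprintf(
      "graph contains %d cycle(s) (first involves nodes %s); resolve cycles before rooting",
      length(rep$cycles), paste(rep$cycles[[1L]], collapse = ", ")
    ))
  }
  if (rep$n_components > 1L) {
    tab <- table(rep$components$component)
    abort(sprintf(
      "graph is disconnected (%d components with sizes %s)",
      rep$n_components, paste(tab, collapse = ", ")
    ))
  }

  segs <- graph$segments
  if (is.null(root)) {
    deg <- table(factor(c(segs$start_node, segs$end_node), levels = graph$nodes$node))
    leaves <- as.integer(names(deg)[deg == 1L])
    if (length(leaves) == 0L) abort("no degree-1 node available for auto-rooting")
    geom <- segment_geometry(graph)
    rad <- setNames(geom$mean_radius, geom$segment)
    best <- -Inf; root <- leaves[1L]
    for (lf in leaves) {
      inc <- segs$segment[segs$start_node == lf | segs$end_node == lf]
      r <- max(rad[as.character(inc)])
      if (r > best) { best <- r; root <- lf }
    }
  }
  if (!root %in% graph$nodes$node) abort(sprintf("root node %s not in graph", root))

  # BFS from root, orienting segments and recording parent segments
  inc_by_node <- split(
    rep(segs$segment, 2L),
    factor(c(segs$start_node, segs$end_node), levels = graph$nodes$node)
  )
  seg_idx <- setNames(seq_len(nrow(segs)), segs$segment)
  flip <- rep(FALSE, nrow(segs))
  parent <- rep(NA_integer_, nrow(segs))
  seen_seg <- rep(FALSE, nrow(segs))
  queue <- list(c(root, NA_integer_))  # node, incoming segment id
  while (length(queue) > 0L) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    n <- cur[1L]; in_seg <- cur[2L]
    out <- sort(inc_by_node[[as.character(n)]])
    for (sid in out) {
      i <- seg_idx[[as.character(sid)]]
      if (seen_seg[i]) next
      seen_seg[i] <- TRUE
      parent[i] <- in_seg
      if (segs$start_node[i] != n) flip[i] <- TRUE
      far <- if (flip[i]) segs$start_node[i] else segs$end_node[i]
      queue <- c(queue, list(c(far, sid)))
    }
  }

  if (any(flip)) {
    pts <- graph$points
    flipped_ids <- segs$segment[flip]
    keep <- !(pts$segment %in% flipped_ids)
    parts <- split(pts[!keep, ], pts$segment[!keep])
    parts <- lapply(parts, function(p) p[rev(seq_len(nrow(p))), ])
    graph$points <- dplyr::bind_rows(pts[keep, ], dplyr::bind_rows(parts)) |>
      dplyr::arrange(factor(.data$segment, levels = segs$segment))
    tmp <- segs$start_node[flip]
    segs$start_node[flip] <- segs$end_node[flip]
    segs$end_node[flip] <- tmp
  }
  segs$parent <- parent
  graph$segments <- segs
  graph$root_node <- root
  class(graph) <- c("rooted_tree", class(graph))
  graph
}

# children of each segment (list keyed by segment id as character), ordered by id
segment_children <- function(tree) {
  stop_if_not_rooted(tree)
  segs <- tree$segments
  kids <- split(segs$segment, factor(segs$parent, levels = segs$segment))
  lapply(kids, sort)
}

# segment ids in a root-to-leaf (topological) order
topo_order <- function(tree) {
  segs <- tree$segments
  roots <- segs$segment[is.na(segs$parent)]
  kids <- segment_children(tree)
  out <- integer(0)
  queue <- sort(roots)
  while (length(queue) > 0L) {
    s <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, s)
    queue <- c(queue, kids[[as.character(s)]])
  }
  out
}
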