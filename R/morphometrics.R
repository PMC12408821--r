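#' Per-segment tortuosity
#'
#' Arc length divided by chord length (Euclidean distance between the
#' segment's start and end node), so a straight vessel scores exactly 1 and
#' values grow with winding. Loop-back segments (coincident endpoints) have
#' no defined tortuosity and return `NA`.
#'
#' @param graph A `spatial_graph`.
#' @return Tibble `segment`, `tortuosity`.
#' @export
tortuosity <- function(graph) {
  stop_if_not_graph(graph)
  graph$points |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(
      tortuosity = {
        xyz <- cbind(.data$x, .data$y, .data$z)
        arc <- polyline_length(xyz)
        chord <- vnorm(xyz[nrow(xyz), ] - xyz[1L, ])
        if (chord > 0) arc / chord else NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$segment)
}

#' Branching angles at junctions
#'
#' Uses chord vectors (start node to end node of each segment), so the
#' angle is independent of centreline tortuosity. Two conventions:
#' `"child_parent"` reports, per child segment, the angle at the junction
#' between the vector pointing back up the parent chord and the child's
#' chord — a straight continuation scores 180 degrees; `"child_child"`
#' reports, per junction with exactly two children, the angle between the
#' two child chords.
#'
#' @param tree A [root_tree()] result.
#' @param mode `"child_parent"` (default; one row per non-root segment) or
#'   `"child_child"` (one row per two-child junction).
#' @return Tibble. `child_parent`: `segment`, `angle` (degrees, `NA` for
#'   root segments or zero-length chords). `child_child`: `parent`,
#'   `child_1`, `child_2`, `angle`.
#' @export
branching_angles <- function(tree, mode = c("child_parent", "child_child")) {
  stop_if_not_rooted(tree)
  mode <- match.arg(mode)
  segs <- tree$segments
  node_pos <- as.matrix(tree$nodes[, c("x", "y", "z")])
  rownames(node_pos) <- as.character(tree$nodes$node)
  chord <- function(sid) {
    i <- match(sid, segs$segment)
    node_pos[as.character(segs$end_node[i]), ] - node_pos[as.character(segs$start_node[i]), ]
  }
  ang <- function(u, v) {
    nu <- vnorm(u); nv <- vnorm(v)
    if (nu == 0 || nv == 0) return(NA_real_)
    acos(pmin(pmax(sum(u * v) / (nu * nv), -1), 1)) * 180 / pi
  }
  if (mode == "child_parent") {
    purrr::map_dfr(seq_len(nrow(segs)), function(i) {
      p <- segs$parent[i]
      a <- if (is.na(p)) NA_real_ else ang(-chord(p), chord(segs$segment[i]))
      tibble::tibble(segment = segs$segment[i], angle = a)
    })
  } else {
    kids <- segment_children(tree)
    purrr::map_dfr(segs$segment, function(sid) {
      ch <- kids[[as.character(sid)]]
      if (length(ch) != 2L) return(NULL)
      tibble::tibble(
        parent = sid, child_1 = ch[1L], child_2 = ch[2L],
        angle = ang(chord(ch[1L]), chord(ch[2L]))
      )
    })
  }
}

#' Per-segment vessel volume
#'
#' Truncated-cone midpoint rule: each subsegment contributes
#' pi * rbar^2 * l with rbar the mean of its two bounding point radii and l
#' its length; the segment volume is the sum over subsegments.
#'
#' @param graph A `spatial_graph`.
#' @return Tibble `segment`, `volume` (µm^3).
#' @export
segment_volume <- function(graph) {
  stop_if_not_graph(graph)
  graph$points |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(
      volume = {
        xyz <- cbind(.data$x, .data$y, .data$z)
        l <- vnorm(diff(xyz))
        rbar <- (head(.data$radius, -1L) + tail(.data$radius, -1L)) / 2
        sum(pi * rbar^2 * l)
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$segment)
}

# arc-length midpoint of each segment polyline (linear interpolation)
segment_midpoints <- function(graph) {
  graph$points |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(
      mx = midpoint_coord(cbind(.data$x, .data$y, .data$z))[1L],
      my = midpoint_coord(cbind(.data$x, .data$y, .data$z))[2L],
      mz = midpoint_coord(cbind(.data$x, .data$y, .data$z))[3L],
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$segment)
}

midpoint_coord <- function(xyz) {
  steps <- vnorm(diff(xyz))
  cum <- c(0, cumsum(steps))
  half <- cum[length(cum)] / 2
  i <- findInterval(half, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(xyz) - 1L)
  f <- if (steps[i] > 0) (half - cum[i]) / steps[i] else 0
  xyz[i, ] + f * (xyz[i + 1L, ] - xyz[i, ])
}

#' Midpoint inter-vessel distance
#'
#' For every segment, the Euclidean distance from its arc-length midpoint
#' to the nearest other segment's midpoint. Only the segment itself is
#' excluded (topological neighbours compete like any other segment); ties
#' resolve to the smaller segment id.
#'
#' @param graph A `spatial_graph` with at least 2 segments.
#' @return Tibble `segment`, `ivd` (µm), `nearest` (segment id).
#' @export
ivd_midpoint <- function(graph) {
  stop_if_not_graph(graph)
  mids <- segment_midpoints(graph)
  if (nrow(mids) < 2L) {
    return(tibble::tibble(segment = mids$segment, ivd = NA_real_, nearest = NA_integer_))
  }
  m <- as.matrix(mids[, c("mx", "my", "mz")])
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  nn <- apply(d, 1L, which.min)  # which.min takes the first (smallest id) on ties
  tibble::tibble(
    segment = mids$segment,
    ivd = d[cbind(seq_len(nrow(d)), nn)],
    nearest = mids$segment[nn]
  )
}

#' Full per-segment morphometry table
#'
#' Gathers the branching metrics into one tibble: mean radius, arc length,
#' tortuosity, length:diameter ratio, volume, branching angle
#' (child-parent convention by default), midpoint inter-vessel distance,
#' truncated Strahler order and topological generation.
#'
#' @param tree A [root_tree()] result.
#' @param ordering Optional precomputed [assign_truncated_strahler()] result.
#' @param angle_mode Passed to [branching_angles()]; the per-segment table
#'   uses `"child_parent"` by default.
#' @return Tibble with one row per segment.
#' @export
morphometry <- function(tree, ordering = NULL, angle_mode = "child_parent") {
  stop_if_not_rooted(tree)
  ordering <- ordering %||% assign_truncated_strahler(tree)
  geom <- segment_geometry(tree)
  angles <- branching_angles(tree, mode = angle_mode)
  if (angle_mode == "child_child") {
    # per-junction angle reported against the parent segment
    angles <- dplyr::select(angles, segment = "parent", "angle")
  }
  out <- geom |>
    dplyr::left_join(tortuosity(tree), by = "segment") |>
    dplyr::left_join(segment_volume(tree), by = "segment") |>
    dplyr::left_join(angles, by = "segment") |>
    dplyr::left_join(ivd_midpoint(tree)[, c("segment", "ivd")], by = "segment") |>
    dplyr::left_join(ordering, by = "segment") |>
    dplyr::left_join(assign_topological_generation(tree), by = "segment") |>
    dplyr::mutate(length_diameter = .data$length / (2 * .data$mean_radius))
  if ("compartment" %in% names(tree$segments)) {
    out <- dplyr::left_join(out,
      tree$segments[, c("segment", "compartment")],
      by = "segment"
    )
  }
  out
}

#' Summarise morphometry by order or compartment
#'
#' Emulates a per-order branching-metrics table (n, mean +/- SD of radius,
#' length, tortuosity, length:diameter, volume, branching angle, IVD) or a
#' per-compartment table; the compartment mode can additionally report
#' tissue volumes and percentages from a label volume.
#'
#' @param records A [morphometry()] tibble.
#' @param group_by `"order"` or `"compartment"`.
#' @param labels Optional `label_volume` for tissue volumes in compartment
#'   mode.
#' @return Tibble with one row per group: `n` plus `<metric>_mean` and
#'   `<metric>_sd` columns; in compartment mode with `labels`, also
#'   `tissue_volume` (µm^3) and `tissue_pct`, and `segment_pct`.
#' @export
summarize_morphometry <- function(records, group_by = c("order", "compartment"),
                                  labels = NULL) {
  group_by <- match.arg(group_by)
  if (!group_by %in% names(records)) {
    abort(sprintf("records have no `%s` column", group_by))
  }
  metrics <- intersect(
    c("mean_radius", "length", "tortuosity", "length_diameter", "volume", "angle", "ivd"),
    names(records)
  )
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(
        dplyr::all_of(metrics),
        list(
          mean = ~ mean(.x, na.rm = TRUE),
          sd = ~ if (sum(is.finite(.x)) > 1L) sd(.x, na.rm = TRUE) else NA_real_
        )
      ),
      .groups = "drop"
    )
  if (group_by == "compartment") {
    out$segment_pct <- 100 * out$n / sum(out$n)
    if (!is.null(labels)) {
      vol <- compartment_volumes(labels)
      out <- dplyr::left_join(out, vol, by = "compartment")
    }
  }
  out
}
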