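#' Read a vessel spatial graph from disk
#'
#' Supports two dialects. `"amira_ascii"` parses AmiraMesh ASCII spatial
#' graphs: a `define VERTEX/EDGE/POINT` header, parameter block, data-section
#' declarations (`VERTEX { float[3] VertexCoordinates } @1` etc.) and the
#' corresponding `@n` data blocks for vertex coordinates, edge connectivity,
#' points per edge, point coordinates and per-point thickness. `"tabular"`
#' reads the two delimited tables written by [write_spatial_graph()]
#' (`<stem>_segments.tsv`, `<stem>_points.tsv`).
#'
#' @param path File path. For the tabular dialect, either the segments table
#'   or the stem shared by both tables.
#' @param dialect `"amira_ascii"` or `"tabular"`.
#' @param thickness Interpretation of the AmiraMesh per-point thickness
#'   channel: `"radius"` (default) or `"diameter"` (halved on read). Vessel
#'   radii are reported throughout the morphometry, so radius is assumed
#'   unless the producing software is known to store diameters.
#' @return A validated [spatial_graph()].
#' @export
read_spatial_graph <- function(path, dialect = c("amira_ascii", "tabular"),
                               thickness = c("radius", "diameter")) {
  dialect <- match.arg(dialect)
  thickness <- match.arg(thickness)
  if (dialect == "amira_ascii") {
    read_amira_graph(path, thickness)
  } else {
    read_tabular_graph(path)
  }
}

read_amira_graph <- function(path, thickness = "radius") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("#\\s*AmiraMesh.*ASCII", lines[1L])) {
    abort(sprintf("malformed header in %s: expected '# AmiraMesh 3D ASCII' first line", path))
  }

  grab_count <- function(what) {
    m <- grep(sprintf("^\\s*define\\s+%s\\s+\\d+", what), lines, value = TRUE)
    if (length(m) != 1L) abort(sprintf("malformed header: missing 'define %s <n>'", what))
    as.integer(sub(sprintf(".*define\\s+%s\\s+(\\d+).*", what), "\\1", m))
  }
  n_vertex <- grab_count("VERTEX")
  n_edge <- grab_count("EDGE")
  n_point <- grab_count("POINT")

  # map data labels (@k) to their declared contents
  decl <- grep("@\\d+\\s*$", lines, value = TRUE)
  decl <- decl[grepl("\\{", decl)]
  label_of <- function(field) {
    m <- decl[grepl(field, decl)]
    if (length(m) != 1L) abort(sprintf("malformed header: field '%s' not declared exactly once", field))
    sub(".*@(\\d+)\\s*$", "\\1", m)
  }
  lab_coords <- label_of("VertexCoordinates")
  lab_conn <- label_of("EdgeConnectivity")
  lab_npts <- label_of("NumEdgePoints")
  lab_ptcoords <- label_of("EdgePointCoordinates")
  lab_thick <- label_of("[Tt]hickness|Radius")

  # split out each @k data block
  starts <- grep("^@\\d+\\s*$", lines)
  if (length(starts) == 0L) abort("malformed file: no data sections found")
  blocks <- list()
  for (i in seq_along(starts)) {
    lab <- sub("^@(\\d+)\\s*$", "\\1", lines[starts[i]])
    from <- starts[i] + 1L
    to <- if (i < length(starts)) starts[i + 1L] - 1L else length(lines)
    txt <- lines[from:to]
    txt <- txt[nzchar(trimws(txt))]
    blocks[[lab]] <- as.numeric(unlist(strsplit(trimws(txt), "\\s+")))
  }
  fetch <- function(lab, n, what) {
    b <- blocks[[lab]]
    if (is.null(b)) abort(sprintf("data section @%s (%s) missing", lab, what))
    if (length(b) != n) {
      abort(sprintf(
        "data section @%s (%s) has %d values, expected %d",
        lab, what, length(b), n
      ))
    }
    b
  }

  vc <- matrix(fetch(lab_coords, 3L * n_vertex, "VertexCoordinates"), ncol = 3L, byrow = TRUE)
  conn <- matrix(fetch(lab_conn, 2L * n_edge, "EdgeConnectivity"), ncol = 2L, byrow = TRUE)
  npts <- fetch(lab_npts, n_edge, "NumEdgePoints")
  pc <- matrix(fetch(lab_ptcoords, 3L * n_point, "EdgePointCoordinates"), ncol = 3L, byrow = TRUE)
  thick <- fetch(lab_thick, n_point, "thickness")
  if (sum(npts) != n_point) {
    abort(sprintf("NumEdgePoints sums to %d but %d points were defined", sum(npts), n_point))
  }
  if (any(conn < 0 | conn >= n_vertex)) {
    bad <- which(apply(conn, 1L, function(r) any(r < 0 | r >= n_vertex)))[1L]
    abort(sprintf("edge %d references a vertex outside 0..%d", bad, n_vertex - 1L))
  }

  radii <- if (thickness == "diameter") thick / 2 else thick
  nodes <- tibble::tibble(node = seq_len(n_vertex), x = vc[, 1L], y = vc[, 2L], z = vc[, 3L])
  segments <- tibble::tibble(
    segment = seq_len(n_edge),
    start_node = as.integer(conn[, 1L]) + 1L,  # Amira vertex indices are 0-based
    end_node = as.integer(conn[, 2L]) + 1L
  )
  points <- tibble::tibble(
    segment = rep(seq_len(n_edge), times = npts),
    x = pc[, 1L], y = pc[, 2L], z = pc[, 3L],
    radius = radii
  )
  spatial_graph(nodes, segments, points, provenance = paste0("amira_ascii:", path))
}

read_tabular_graph <- function(path) {
  stem <- sub("_segments\\.tsv$", "", path)
  seg_path <- paste0(stem, "_segments.tsv")
  pt_path <- paste0(stem, "_points.tsv")
  for (p in c(seg_path, pt_path)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  segs <- tibble::as_tibble(read.delim(seg_path))
  pts <- tibble::as_tibble(read.delim(pt_path))
  # nodes are recovered from segment endpoints and first/last point positions
  firsts <- pts |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(
      sx = dplyr::first(.data$x), sy = dplyr::first(.data$y), sz = dplyr::first(.data$z),
      ex = dplyr::last(.data$x), ey = dplyr::last(.data$y), ez = dplyr::last(.data$z),
      .groups = "drop"
    )
  segs2 <- dplyr::left_join(segs, firsts, by = "segment")
  nodes <- dplyr::bind_rows(
    tibble::tibble(node = segs2$start_node, x = segs2$sx, y = segs2$sy, z = segs2$sz),
    tibble::tibble(node = segs2$end_node, x = segs2$ex, y = segs2$ey, z = segs2$ez)
  ) |>
    dplyr::distinct(.data$node, .keep_all = TRUE) |>
    dplyr::arrange(.data$node)
  keep <- setdiff(names(segs), c("sx", "sy", "sz", "ex", "ey", "ez"))
  spatial_graph(nodes, segs[, keep], pts[, c("segment", "x", "y", "z", "radius")],
    provenance = paste0("tabular:", stem)
  )
}

#' Write a vessel spatial graph to disk
#'
#' The AmiraMesh ASCII dialect writes a file re-readable by
#' [read_spatial_graph()] with identical topology and radii within float
#' round-trip. The tabular dialect writes two delimited tables:
#' `<stem>_segments.tsv` (segment, start_node, end_node and any extra
#' segment columns) and `<stem>_points.tsv` (one row per point: segment, x,
#' y, z, radius).
#'
#' @param graph A [spatial_graph()].
#' @param path Output path (for tabular, the stem used for both tables).
#' @param dialect `"amira_ascii"` or `"tabular"`.
#' @return `path`, invisibly.
#' @export
write_spatial_graph <- function(graph, path, dialect = c("amira_ascii", "tabular")) {
  stop_if_not_graph(graph)
  dialect <- match.arg(dialect)
  if (dialect == "tabular") {
    stem <- sub("_segments\\.tsv$", "", path)
    seg_cols <- setdiff(names(graph$segments), "parent")
    write.table(graph$segments[, seg_cols], paste0(stem, "_segments.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    write.table(graph$points[, c("segment", "x", "y", "z", "radius")],
      paste0(stem, "_points.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    return(invisible(path))
  }

  nodes <- graph$nodes
  segs <- graph$segments
  pts <- graph$points[order(match(graph$points$segment, segs$segment)), ]
  node_index <- setNames(seq_len(nrow(nodes)) - 1L, nodes$node)  # 0-based on write
  npts <- as.integer(table(factor(pts$segment, levels = segs$segment)))

  fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "# AmiraMesh 3D ASCII 2.0",
    "",
    sprintf("define VERTEX %d", nrow(nodes)),
    sprintf("define EDGE %d", nrow(segs)),
    sprintf("define POINT %d", nrow(pts)),
    "",
    "Parameters {",
    "    ContentType \"HxSpatialGraph\"",
    "}",
    "",
    "VERTEX { float[3] VertexCoordinates } @1",
    "EDGE { int[2] EdgeConnectivity } @2",
    "EDGE { int NumEdgePoints } @3",
    "POINT { float[3] EdgePointCoordinates } @4",
    "POINT { float thickness } @5",
    "",
    "# Data section follows"
  ), con)
  writeLines("@1", con)
  writeLines(paste(fmt(nodes$x), fmt(nodes$y), fmt(nodes$z)), con)
  writeLines(c("", "@2"), con)
  writeLines(paste(
    node_index[as.character(segs$start_node)],
    node_index[as.character(segs$end_node)]
  ), con)
  writeLines(c("", "@3"), con)
  writeLines(as.character(npts), con)
  writeLines(c("", "@4"), con)
  writeLines(paste(fmt(pts$x), fmt(pts$y), fmt(pts$z)), con)
  writeLines(c("", "@5"), con)
  writeLines(fmt(pts$radius), con)
  invisible(path)
}
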