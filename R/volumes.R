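#' Construct a binary or labelled 3D volume
#'
#' Volumes are plain 3D arrays with isotropic voxel size metadata in µm.
#' A `bin_volume` is logical (foreground/background); a `label_volume` is
#' integer with a legend mapping label values to compartment names. World
#' coordinates (µm) map to voxel indices via the voxel size and an origin
#' (world position of the centre of voxel \[1,1,1\]).
#'
#' @param data 3D array (logical/numeric for `bin_volume`, integer for
#'   `label_volume`).
#' @param voxel_size Isotropic voxel edge length, µm (> 0).
#' @param origin World position (µm) of the centre of the first voxel.
#' @param legend Named integer vector for `label_volume`, e.g.
#'   `c(background = 0, cortex = 1, medulla = 2, hilum = 3, pillars = 4)`.
#' @return A `bin_volume` or `label_volume` object.
#' @export
bin_volume <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) abort("`data` must be a 3D array")
  if (voxel_size <= 0) abort("`voxel_size` must be positive")
  structure(
    list(data = array(as.logical(data), dim(data)), voxel_size = voxel_size, origin = origin),
    class = "bin_volume"
  )
}

#' @rdname bin_volume
#' @export
label_volume <- function(data, voxel_size, origin = c(0, 0, 0),
                         legend = NULL) {
  if (length(dim(data)) != 3L) abort("`data` must be a 3D array")
  if (voxel_size <= 0) abort("`voxel_size` must be positive")
  data <- array(as.integer(data), dim(data))
  if (is.null(legend)) {
    vals <- sort(unique(as.vector(data)))
    legend <- setNames(vals, paste0("label_", vals))
  }
  if (!all(as.vector(data) %in% legend)) abort("volume contains labels missing from the legend")
  structure(
    list(data = data, voxel_size = voxel_size, origin = origin, legend = legend),
    class = "label_volume"
  )
}

#' @export
print.bin_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<bin_volume> %d x %d x %d voxels at %.3g um, %d foreground\n",
    d[1L], d[2L], d[3L], x$voxel_size, sum(x$data)
  ))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<label_volume> %d x %d x %d voxels at %.3g um; labels: %s\n",
    d[1L], d[2L], d[3L], x$voxel_size,
    paste(sprintf("%s=%d", names(x$legend), x$legend), collapse = ", ")
  ))
  invisible(x)
}

# world (µm) -> voxel index (1-based, rounded); returns n x 3 integer matrix
world_to_voxel <- function(vol, xyz) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3L)
  idx <- sweep(xyz, 2L, vol$origin) / vol$voxel_size
  matrix(as.integer(round(idx)), ncol = 3L) + 1L
}

# voxel index (1-based) -> world µm of voxel centre
voxel_to_world <- function(vol, ijk) {
  if (!is.matrix(ijk)) ijk <- matrix(ijk, ncol = 3L)
  sweep((ijk - 1L) * vol$voxel_size, 2L, vol$origin, `+`)
}

in_bounds <- function(vol, ijk) {
  d <- dim(vol$data)
  ijk[, 1L] >= 1L & ijk[, 1L] <= d[1L] &
    ijk[, 2L] >= 1L & ijk[, 2L] <= d[2L] &
    ijk[, 3L] >= 1L & ijk[, 3L] <= d[3L]
}

#' Read and write volumes as multipage TIFF or raw text sidecar
#'
#' TIFF stacks hold one z-slice per page; the voxel size is carried in a
#' plain-text sidecar `<path>.meta` (key: value lines `voxel_size`,
#' `origin`, and for label volumes the legend entries), since baseline TIFF
#' has no standard 3D spacing tag.
#'
#' @param vol A `bin_volume` or `label_volume`.
#' @param path Output `.tif` path.
#' @return `path` invisibly (writer); a volume object (reader).
#' @export
write_volume <- function(vol, path) {
  d <- dim(vol$data)
  slices <- lapply(seq_len(d[3L]), function(k) {
    m <- matrix(as.numeric(vol$data[, , k]), d[1L], d[2L])
    # tiff images are row-major from the top; store x along rows as-is
    m / max(1, max(vol$legend %||% 1))
  })
  tiff::writeTIFF(slices, path, bits.per.sample = 16L)
  meta <- c(
    sprintf("voxel_size: %.17g", vol$voxel_size),
    sprintf("origin: %.17g %.17g %.17g", vol$origin[1L], vol$origin[2L], vol$origin[3L]),
    sprintf("type: %s", class(vol)[1L]),
    sprintf("max_label: %d", as.integer(max(1, max(vol$legend %||% 1))))
  )
  if (!is.null(vol$legend)) {
    meta <- c(meta, sprintf("label %s: %d", names(vol$legend), vol$legend))
  }
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(path) || !file.exists(meta_path)) {
    abort(sprintf("volume file or sidecar missing: %s(.meta)", path))
  }
  meta <- readLines(meta_path)
  grab <- function(key) sub(sprintf("^%s: ", key), "", grep(sprintf("^%s: ", key), meta, value = TRUE))
  voxel_size <- as.numeric(grab("voxel_size"))
  origin <- as.numeric(strsplit(grab("origin"), " ")[[1L]])
  type <- grab("type")
  max_label <- as.integer(grab("max_label"))
  slices <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(slices[[1L]]), length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]
  arr <- round(arr * max_label)
  if (identical(type, "label_volume")) {
    leg_lines <- grep("^label ", meta, value = TRUE)
    legend <- as.integer(sub(".*: ", "", leg_lines))
    names(legend) <- sub("^label (.*):.*", "\\1", leg_lines)
    label_volume(arr, voxel_size, origin, legend)
  } else {
    bin_volume(arr > 0, voxel_size, origin)
  }
}

# --- distance transform ------------------------------------------------------

# 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher)
dt1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# exact 3D Euclidean distance transform: distance (µm) of every voxel to the
# nearest TRUE voxel of `mask`
distance_transform <- function(mask, voxel_size) {
  d <- dim(mask)
  # 1e12 stands in for infinity: far larger than any attainable squared index
  # distance (<= 3 * 512^2), but finite so the envelope intersections stay
  # well-defined on background-only lines
  f <- array(ifelse(mask, 0, 1e12), d)
  for (k in seq_len(d[3L])) for (j in seq_len(d[2L])) f[, j, k] <- dt1d(f[, j, k])
  for (k in seq_len(d[3L])) for (i in seq_len(d[1L])) f[i, , k] <- dt1d(f[i, , k])
  for (j in seq_len(d[2L])) for (i in seq_len(d[1L])) f[i, j, ] <- dt1d(f[i, j, ])
  sqrt(f) * voxel_size
}

#' Voxel inter-vessel distance map
#'
#' Exact Euclidean distance transform of the complement of a vessel mask:
#' every non-vessel voxel gets its distance (µm) to the nearest vessel
#' voxel. Statistics are reported over non-vessel voxels, optionally per
#' compartment of a label volume.
#'
#' @param vessel_mask A `bin_volume` with at least one foreground voxel.
#' @param region_labels Optional `label_volume` of matching shape.
#' @return List: `distance` (3D array, µm), `stats` (tibble with `region`,
#'   `mean`, `sd`, `max`, `n_voxels`; one `all` row, plus one row per
#'   non-background label when `region_labels` is given).
#' @export
ivd_voxel <- function(vessel_mask, region_labels = NULL) {
  if (!inherits(vessel_mask, "bin_volume")) abort("`vessel_mask` must be a bin_volume")
  if (!any(vessel_mask$data)) abort("vessel mask is empty")
  dmap <- distance_transform(vessel_mask$data, vessel_mask$voxel_size)
  bg <- !vessel_mask$data
  stats_rows <- tibble::tibble(
    region = "all",
    mean = if (any(bg)) mean(dmap[bg]) else NA_real_,
    sd = if (sum(bg) > 1L) sd(dmap[bg]) else NA_real_,
    max = if (any(bg)) max(dmap[bg]) else NA_real_,
    n_voxels = sum(bg)
  )
  if (!is.null(region_labels)) {
    if (!identical(dim(region_labels$data), dim(vessel_mask$data))) {
      abort("region label volume shape does not match the vessel mask")
    }
    leg <- region_labels$legend
    leg <- leg[!names(leg) %in% "background" & leg != 0]
    per <- purrr::map_dfr(names(leg), function(nm) {
      sel <- bg & region_labels$data == leg[[nm]]
      tibble::tibble(
        region = nm,
        mean = if (any(sel)) mean(dmap[sel]) else NA_real_,
        sd = if (sum(sel) > 1L) sd(dmap[sel]) else NA_real_,
        max = if (any(sel)) max(dmap[sel]) else NA_real_,
        n_voxels = sum(sel)
      )
    })
    stats_rows <- dplyr::bind_rows(stats_rows, per)
  }
  list(distance = dmap, stats = stats_rows)
}

# --- connected components and Euler characteristic ---------------------------

# label connected components of a logical 2D/3D array; connectivity 6 or 26
# (3D) / 4 or 8 (2D). Returns integer array of labels, 0 = background.
label_components <- function(mask, connectivity = c("face", "full")) {
  connectivity <- match.arg(connectivity)
  d <- dim(mask)
  if (length(d) == 2L) {
    mask <- array(mask, c(d, 1L))
    d <- dim(mask)
    was2d <- TRUE
  } else {
    was2d <- FALSE
  }
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0 & offs$dk == 0), ]
  if (connectivity == "face") {
    offs <- offs[abs(offs$di) + abs(offs$dj) + abs(offs$dk) == 1L, ]
  }
  offs <- as.matrix(offs)
  lab <- array(0L, d)
  nxt <- 0L
  idx_fg <- which(mask)
  for (start in idx_fg) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0L) {
      cur <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      k <- (cur - 1L) %/% (d[1L] * d[2L]) + 1L
      rem <- (cur - 1L) %% (d[1L] * d[2L])
      j <- rem %/% d[1L] + 1L
      i <- rem %% d[1L] + 1L
      ni <- i + offs[, 1L]; nj <- j + offs[, 2L]; nk <- k + offs[, 3L]
      ok <- ni >= 1L & ni <= d[1L] & nj >= 1L & nj <= d[2L] & nk >= 1L & nk <= d[3L]
      lin <- (nk[ok] - 1L) * d[1L] * d[2L] + (nj[ok] - 1L) * d[1L] + ni[ok]
      lin <- lin[mask[lin] & lab[lin] == 0L]
      if (length(lin) > 0L) {
        lab[lin] <- nxt
        queue <- c(queue, lin)
      }
    }
  }
  if (was2d) lab <- lab[, , 1L]
  lab
}

n_components <- function(mask, connectivity = "full") {
  max(label_components(mask, connectivity), 0L)
}

# Euler characteristic of the union of closed unit cubes (foreground voxels):
# chi = V - E + F - C over the cubical complex. A k-cell is present when any
# incident voxel is foreground; presence arrays are built by shifted ORs.
euler_characteristic <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)] <- mask
  dp <- dim(pad)
  or_shift <- function(arr, axes) {
    # OR of arr over the 2^|axes| shifts by 0/-1 along each axis in `axes`
    out <- arr
    for (ax in axes) {
      shifted <- array(FALSE, dim(out))
      if (ax == 1L) shifted[1:(dp[1L] - 1L), , ] <- out[2:dp[1L], , ]
      if (ax == 2L) shifted[, 1:(dp[2L] - 1L), ] <- out[, 2:dp[2L], ]
      if (ax == 3L) shifted[, , 1:(dp[3L] - 1L)] <- out[, , 2:dp[3L]]
      out <- out | shifted
    }
    out
  }
  n_cells <- sum(pad)                                   # 3-cells (cubes)
  n_faces <- sum(or_shift(pad, 1L)) + sum(or_shift(pad, 2L)) + sum(or_shift(pad, 3L))
  n_edges <- sum(or_shift(pad, c(1L, 2L))) + sum(or_shift(pad, c(1L, 3L))) +
    sum(or_shift(pad, c(2L, 3L)))
  n_verts <- sum(or_shift(pad, c(1L, 2L, 3L)))
  n_verts - n_edges + n_faces - n_cells
}

#' Assign vessel segments to anatomical compartments
#'
#' Maps every polyline point of every segment to the compartment label at
#' its voxel, then labels each segment by the unique non-background
#' compartment its points visit. Segments whose points touch two or more
#' compartments are excluded (reported, not silently dropped), as are
#' segments lying wholly outside the labelled space.
#'
#' @param tree A `spatial_graph` (rooted or not).
#' @param labels A `label_volume` covering the tree's bounding box.
#' @return The graph with a `compartment` column added to `segments`
#'   (compartment name, or `NA` for excluded segments) and an
#'   `exclusion` attribute: tibble `segment`, `reason`
#'   (`"multi_compartment"` or `"outside_labels"`).
#' @export
assign_compartments <- function(tree, labels) {
  stop_if_not_graph(tree)
  if (!inherits(labels, "label_volume")) abort("`labels` must be a label_volume")
  leg <- labels$legend
  bg_val <- if ("background" %in% names(leg)) leg[["background"]] else 0L
  name_of <- setNames(names(leg), leg)
  pts <- tree$points
  ijk <- world_to_voxel(labels, as.matrix(pts[, c("x", "y", "z")]))
  ok <- in_bounds(labels, ijk)
  lab <- rep(NA_integer_, nrow(pts))
  lin <- (ijk[ok, 3L] - 1L) * prod(dim(labels$data)[1:2]) +
    (ijk[ok, 2L] - 1L) * dim(labels$data)[1L] + ijk[ok, 1L]
  lab[ok] <- labels$data[lin]
  per_seg <- tibble::tibble(segment = pts$segment, label = lab) |>
    dplyr::filter(!is.na(.data$label), .data$label != bg_val) |>
    dplyr::distinct(.data$segment, .data$label)
  counts <- dplyr::count(per_seg, .data$segment)
  single <- counts$segment[counts$n == 1L]
  multi <- counts$segment[counts$n > 1L]
  outside <- setdiff(tree$segments$segment, counts$segment)
  seg_lab <- per_seg$label[match(single, per_seg$segment)]
  comp <- rep(NA_character_, nrow(tree$segments))
  comp[match(single, tree$segments$segment)] <- name_of[as.character(seg_lab)]
  tree$segments$compartment <- comp
  attr(tree, "exclusion") <- dplyr::bind_rows(
    tibble::tibble(segment = multi, reason = "multi_compartment"),
    tibble::tibble(segment = outside, reason = "outside_labels")
  )
  tree
}

#' Tissue volume per compartment
#'
#' @param labels A `label_volume`.
#' @return Tibble `compartment`, `tissue_volume` (µm^3), `tissue_pct`
#'   (percent of non-background labelled volume).
#' @export
compartment_volumes <- function(labels) {
  if (!inherits(labels, "label_volume")) abort("`labels` must be a label_volume")
  leg <- labels$legend
  leg <- leg[!names(leg) %in% "background" & leg != 0]
  vvol <- labels$voxel_size^3
  counts <- vapply(leg, function(v) sum(labels$data == v), numeric(1))
  tibble::tibble(
    compartment = names(leg),
    tissue_volume = unname(counts * vvol),
    tissue_pct = unname(100 * counts / sum(counts))
  )
}
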