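#' Assign truncated Strahler orders
#'
#' Centripetal stream ordering for a vessel tree whose true terminal vessels
#' lie below imaging resolution: every observed terminal (leaf) segment is
#' assigned order 1 ("truncated" Strahler ordering). At a junction the
#' parent order is the maximum child order, incremented by one when that
#' maximum is attained by two or more children (the standard generalisation
#' of the pairwise rule to multifurcations). Pass-through (degree-2) nodes
#' never increment the order: they are geometry, not topology.
#'
#' @param tree A [root_tree()] result.
#' @return Tibble with columns `segment`, `order` (integer >= 1).
#' @export
assign_truncated_strahler <- function(tree) {
  stop_if_not_rooted(tree)
  kids <- segment_children(tree)
  ord <- setNames(rep(NA_integer_, nrow(tree$segments)), tree$segments$segment)
  for (sid in rev(topo_order(tree))) {  # leaves first
    ch <- kids[[as.character(sid)]]
    if (length(ch) == 0L) {
      ord[as.character(sid)] <- 1L
    } else {
      co <- ord[as.character(ch)]
      m <- max(co)
      ord[as.character(sid)] <- if (sum(co == m) >= 2L) m + 1L else m
    }
  }
  tibble::tibble(segment = tree$segments$segment, order = unname(ord[as.character(tree$segments$segment)]))
}

#' Assign topological generations
#'
#' Centrifugal ordering: the most proximal (root) segment is generation 1
#' and the generation increases by one at every branching node. A segment
#' continuing through a degree-2 (pass-through) node keeps its parent's
#' generation.
#'
#' @param tree A [root_tree()] result.
#' @return Tibble with columns `segment`, `generation` (integer >= 1).
#' @export
assign_topological_generation <- function(tree) {
  stop_if_not_rooted(tree)
  kids <- segment_children(tree)
  segs <- tree$segments
  gen <- setNames(rep(NA_integer_, nrow(segs)), segs$segment)
  for (sid in topo_order(tree)) {
    p <- segs$parent[match(sid, segs$segment)]
    if (is.na(p)) {
      gen[as.character(sid)] <- 1L
    } else {
      siblings <- kids[[as.character(p)]]
      inc <- if (length(siblings) >= 2L) 1L else 0L
      gen[as.character(sid)] <- gen[as.character(p)] + inc
    }
  }
  tibble::tibble(segment = segs$segment, generation = unname(gen[as.character(segs$segment)]))
}

#' Segment counts per order
#'
#' @param ordering Tibble with `segment` and `order` columns, as returned by
#'   [assign_truncated_strahler()].
#' @return Tibble `order`, `n`, sorted by order.
#' @export
order_counts <- function(ordering) {
  ordering |>
    dplyr::count(.data$order, name = "n") |>
    dplyr::arrange(.data$order)
}

#' Fit the branching ratio from per-order segment counts
#'
#' Segment count decays exponentially with order, N = N0 exp(-O / gamma);
#' the branching ratio gamma is recovered as the anti-log of the (negated)
#' slope of the ordinary least squares fit of ln N on order O.
#'
#' @param counts Tibble with columns `order` and `n` (see [order_counts()]),
#'   or a named numeric vector of counts keyed by order.
#' @param fit_range Integer vector of orders to include, or `NULL` for all
#'   orders with positive counts.
#' @return Object of class `branching_fit` with elements `gamma`, `N0`,
#'   `fit_range`, `residuals` (tibble order, n, fitted, residual on the log
#'   scale) and the underlying `lm` fit. Has [tidy()] and [glance()]
#'   methods and an [ggplot2::autoplot()] method.
#' @export
fit_branching_ratio <- function(counts, fit_range = NULL) {
  if (!is.data.frame(counts)) {
    counts <- tibble::tibble(order = as.integer(names(counts)), n = as.numeric(counts))
  }
  counts <- dplyr::arrange(tibble::as_tibble(counts), .data$order)
  if (!is.null(fit_range)) counts <- dplyr::filter(counts, .data$order %in% fit_range)
  zero <- counts$n <= 0
  if (any(zero)) {
    warn(sprintf("excluding %d order(s) with zero segments from the fit", sum(zero)))
    counts <- counts[!zero, ]
  }
  if (nrow(counts) < 2L) abort("need at least 2 orders with positive counts to fit the branching ratio")
  fit <- lm(log(n) ~ order, data = counts)
  slope <- coef(fit)[["order"]]
  out <- list(
    gamma = exp(-slope),
    N0 = exp(coef(fit)[["(Intercept)"]]),
    fit_range = range(counts$order),
    residuals = tibble::tibble(
      order = counts$order, n = counts$n,
      fitted = exp(fitted(fit)), residual = residuals(fit)
    ),
    fit = fit
  )
  class(out) <- "branching_fit"
  out
}

#' @export
print.branching_fit <- function(x, ...) {
  cat(sprintf(
    "<branching_fit> gamma = %.4g, N0 = %.4g (orders %d-%d, %d points)\n",
    x$gamma, x$N0, x$fit_range[1L], x$fit_range[2L], nrow(x$residuals)
  ))
  invisible(x)
}

#' @rdname fit_branching_ratio
#' @param x A `branching_fit`.
#' @param ... Unused.
#' @export
tidy.branching_fit <- function(x, ...) {
  tibble::tibble(
    term = c("gamma", "N0"),
    estimate = c(x$gamma, x$N0)
  )
}

#' @rdname fit_branching_ratio
#' @export
glance.branching_fit <- function(x, ...) {
  y <- log(x$residuals$n)
  r2 <- 1 - sum(residuals(x$fit)^2) / sum((y - mean(y))^2)
  tibble::tibble(
    gamma = x$gamma, N0 = x$N0,
    r.squared = r2,
    n_orders = nrow(x$residuals),
    order_min = x$fit_range[1L], order_max = x$fit_range[2L]
  )
}

#' Map Strahler orders to anatomical vessel classes
#'
#' Anatomical classes (e.g. hilar branches, interlobar, arcuate,
#' interlobular arteries) are defined as order ranges. Ranges may overlap,
#' so classes are reported independently rather than as a partition.
#'
#' @param ordering Tibble `segment`, `order`.
#' @param geometry Tibble `segment`, `mean_radius` (from
#'   [segment_geometry()]).
#' @param anatomy Tibble with columns `class`, `order_min`, `order_max`. The
#'   default mirrors the renal arterial tree: hilar branches (orders 7-9),
#'   interlobar (5-6), arcuate (2-4), interlobular (1-3).
#' @return Tibble per class: `class`, `order_min`, `order_max`, `n`,
#'   `mean_radius`, `sd_radius` (NA when `n` = 0).
#' @export
map_orders_to_anatomy <- function(ordering, geometry,
                                  anatomy = renal_anatomy_map()) {
  joined <- dplyr::left_join(ordering, geometry, by = "segment")
  purrr::pmap_dfr(anatomy, function(class, order_min, order_max, ...) {
    sel <- joined[joined$order >= order_min & joined$order <= order_max, ]
    tibble::tibble(
      class = class, order_min = order_min, order_max = order_max,
      n = nrow(sel),
      mean_radius = if (nrow(sel)) mean(sel$mean_radius) else NA_real_,
      sd_radius = if (nrow(sel) > 1L) sd(sel$mean_radius) else NA_real_
    )
  })
}

#' @rdname map_orders_to_anatomy
#' @export
renal_anatomy_map <- function() {
  tibble::tibble(
    class = c("hilar branches", "interlobar", "arcuate", "interlobular"),
    order_min = c(7L, 5L, 2L, 1L),
    order_max = c(9L, 6L, 4L, 3L)
  )
}

#' Estimate the number of unresolved Strahler orders
#'
#' A truncated network ends at observed terminal segments, but the true
#' terminal vessels (e.g. afferent arterioles feeding glomeruli) are more
#' numerous. Assuming the branching ratio persists below resolution, the
#' fractional number of missing orders is
#' `k = ln(n_endpoints_true / n_terminal) / ln(gamma)`.
#'
#' @param n_terminal Observed order-1 segment count.
#' @param gamma Branching ratio (> 1).
#' @param n_endpoints_true Estimated true terminal count (e.g. glomerular
#'   number).
#' @return Fractional order deficit `k` (0 when counts agree).
#' @export
estimate_missing_orders <- function(n_terminal, gamma, n_endpoints_true) {
  if (any(c(n_terminal, gamma, n_endpoints_true) <= 0)) {
    abort("all inputs must be positive")
  }
  if (gamma <= 1) abort("gamma must exceed 1")
  log(n_endpoints_true / n_terminal) / log(gamma)
}

#' Extrapolate whole-organ glomerular number from sampled volumes
#'
#' Each high-resolution volume of interest (VOI) yields a glomerular count
#' and a cortex volume; scaling each count by total over sampled cortex
#' volume gives a per-VOI whole-organ estimate, and the pooled estimate is
#' their mean.
#'
#' @param voi_counts Glomeruli counted per VOI.
#' @param voi_cortex_volumes Cortex volume within each VOI, µm^3.
#' @param total_cortex_volume Whole-organ cortex volume, µm^3.
#' @return List with `per_voi` (tibble voi, count, cortex_volume, estimate)
#'   and `pooled` (mean of the per-VOI estimates).
#' @export
extrapolate_glomeruli <- function(voi_counts, voi_cortex_volumes, total_cortex_volume) {
  if (length(voi_counts) != length(voi_cortex_volumes)) {
    abort("voi_counts and voi_cortex_volumes must have the same length")
  }
  if (any(voi_cortex_volumes <= 0) || total_cortex_volume <= 0) {
    abort("volumes must be positive")
  }
  est <- voi_counts * total_cortex_volume / voi_cortex_volumes
  list(
    per_voi = tibble::tibble(
      voi = seq_along(voi_counts),
      count = voi_counts,
      cortex_volume = voi_cortex_volumes,
      estimate = est
    ),
    pooled = mean(est)
  )
}
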