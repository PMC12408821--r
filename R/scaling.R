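#' Count downstream network endpoints per segment
#'
#' For each vessel segment, the number of terminal (leaf) segments in its
#' downstream subtree, itself included when it is a leaf. Conservation holds
#' at every junction: the parent count is the sum of its children's counts.
#'
#' @param tree A [root_tree()] result.
#' @return Tibble `segment`, `n_downstream` (>= 1).
#' @export
downstream_tip_counts <- function(tree) {
  stop_if_not_rooted(tree)
  kids <- segment_children(tree)
  nd <- setNames(rep(NA_real_, nrow(tree$segments)), tree$segments$segment)
  for (sid in rev(topo_order(tree))) {
    ch <- kids[[as.character(sid)]]
    nd[as.character(sid)] <- if (length(ch) == 0L) 1 else sum(nd[as.character(ch)])
  }
  tibble::tibble(
    segment = tree$segments$segment,
    n_downstream = unname(nd[as.character(tree$segments$segment)])
  )
}

#' Radial scaling exponent by standard major axis regression
#'
#' Vessel radius scales with the number of downstream endpoints as
#' R ~ N_d^a. Murray's law (energy balance between viscous dissipation and
#' metabolic maintenance of blood) predicts a = 1/3; the West-Brown-Enquist
#' fractal-network model predicts a = 0.5 in large vessels and 1/3 in small
#' ones. The exponent is the slope of log R on log N_d fitted by standard
#' major axis (SMA) regression, which accounts for measurement error in
#' both variables: slope = sign(r) * SD(log R) / SD(log N_d), with the
#' standard SMA confidence interval at the given alpha.
#'
#' @param pairs Tibble with columns `radius` (µm, > 0) and `n_downstream`
#'   (>= 1), e.g. [segment_geometry()] joined to
#'   [downstream_tip_counts()].
#' @param alpha Significance level for the confidence interval (default
#'   0.05, i.e. a 95% CI).
#' @return Object of class `scaling_fit`: `exponent`, `ci` (length-2),
#'   `intercept` (log10 scale), `r`, `n`, and the `pairs` used. Has
#'   [tidy()], [glance()] and [ggplot2::autoplot()] methods.
#' @export
radial_scaling_exponent <- function(pairs, alpha = 0.05) {
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("radius", "n_downstream") %in% names(pairs))) {
    abort("`pairs` needs columns `radius` and `n_downstream`")
  }
  pairs <- pairs[is.finite(pairs$radius) & pairs$radius > 0 & pairs$n_downstream >= 1, ]
  if (nrow(pairs) < 3L) abort("need at least 3 (radius, n_downstream) pairs")
  x <- log10(pairs$n_downstream)
  y <- log10(pairs$radius)
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in log radius or log endpoint count")
  r <- stats::cor(x, y)
  b <- sign(ifelse(r == 0, 1, r)) * sd(y) / sd(x)
  n <- length(x)
  # standard SMA interval: b * (sqrt(B + 1) +/- sqrt(B)), B = qf * (1 - r^2) / (n - 2)
  B <- qf(1 - alpha, 1, n - 2) * (1 - r^2) / (n - 2)
  ci <- sort(b * c(sqrt(B + 1) - sqrt(B), sqrt(B + 1) + sqrt(B)))
  out <- list(
    exponent = b,
    ci = ci,
    intercept = mean(y) - b * mean(x),
    r = r,
    n = n,
    alpha = alpha,
    pairs = pairs
  )
  class(out) <- "scaling_fit"
  out
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "<scaling_fit> a = %.4f (%d%% CI %.4f-%.4f), n = %d segments (SMA)\n",
    x$exponent, round(100 * (1 - x$alpha)), x$ci[1L], x$ci[2L], x$n
  ))
  invisible(x)
}

#' @rdname radial_scaling_exponent
#' @param x A `scaling_fit`.
#' @param ... Unused.
#' @export
tidy.scaling_fit <- function(x, ...) {
  tibble::tibble(
    term = c("exponent", "intercept"),
    estimate = c(x$exponent, x$intercept),
    conf.low = c(x$ci[1L], NA_real_),
    conf.high = c(x$ci[2L], NA_real_)
  )
}

#' @rdname radial_scaling_exponent
#' @export
glance.scaling_fit <- function(x, ...) {
  tibble::tibble(
    exponent = x$exponent, conf.low = x$ci[1L], conf.high = x$ci[2L],
    r = x$r, n = x$n, method = "SMA"
  )
}

#' Per-bifurcation Murray's-law table
#'
#' At every junction, compares the cubed parent radius with the sum of
#' cubed child radii (Murray's optimum r_p^3 = sum r_c^3; multifurcations
#' sum over all children). Radii are segment mean radii.
#'
#' @param tree A [root_tree()] result.
#' @param geometry Optional precomputed [segment_geometry()].
#' @return Tibble per junction: `parent` (segment id), `n_children`,
#'   `parent_cubed`, `children_cubed`, `deviation`
#'   (= (sum r_c^3 - r_p^3) / r_p^3), plus attributes `mean_abs_deviation`
#'   and `median_abs_deviation` summarising the table.
#' @export
murray_table <- function(tree, geometry = NULL) {
  stop_if_not_rooted(tree)
  geometry <- geometry %||% segment_geometry(tree)
  rad <- setNames(geometry$mean_radius, geometry$segment)
  kids <- segment_children(tree)
  rows <- purrr::map_dfr(tree$segments$segment, function(sid) {
    ch <- kids[[as.character(sid)]]
    if (length(ch) < 2L) return(NULL)
    rp3 <- rad[[as.character(sid)]]^3
    rc3 <- sum(rad[as.character(ch)]^3)
    tibble::tibble(
      parent = sid, n_children = length(ch),
      parent_cubed = rp3, children_cubed = rc3,
      deviation = (rc3 - rp3) / rp3
    )
  })
  if (nrow(rows) > 0L) {
    attr(rows, "mean_abs_deviation") <- mean(abs(rows$deviation))
    attr(rows, "median_abs_deviation") <- stats::median(abs(rows$deviation))
  }
  rows
}

#' Compare log-radius-vs-order fits between two networks
#'
#' Normalises each network's per-order mean radii to a shared anchor order,
#' fits log(radius) against order by ordinary least squares per network, and
#' tests the null hypothesis that one global slope and intercept fit both
#' (extra-sum-of-squares F test with 2 constrained parameters):
#' F = ((SS_pooled - SS_separate)/2) / (SS_separate/(n_a + n_b - 4)),
#' where n_a and n_b count the non-anchor orders. The anchor rows are
#' excluded from the regressions: after normalisation they are identically 1
#' in both networks — they define the scale, they are not evidence — and
#' keeping a forced-identical point in both fits would bias the test toward
#' agreement. Two 9-order networks therefore give F(2, 12).
#'
#' @param table_a,table_b Tibbles with columns `order` and `radius`
#'   (per-order mean radius, µm).
#' @param anchor_order Order whose radius is mapped to 1 in both networks;
#'   must be present in both tables.
#' @return Object of class `order_fit_comparison`: `f`, `df` (c(2, n_a +
#'   n_b - 4)), `p_value`, per-network slopes/intercepts, and the normalised
#'   data. Has [tidy()] and [glance()] methods.
#' @export
compare_order_radius_fits <- function(table_a, table_b, anchor_order) {
  norm1 <- function(tab, label) {
    tab <- dplyr::arrange(tibble::as_tibble(tab), .data$order)
    if (!anchor_order %in% tab$order) {
      abort(sprintf("anchor order %s missing from table %s", anchor_order, label))
    }
    if (nrow(tab) < 3L) abort("each table needs at least 3 orders")
    anchor <- tab$radius[tab$order == anchor_order][1L]
    dplyr::mutate(tab, network = label, norm_radius = .data$radius / anchor)
  }
  a <- norm1(table_a, "a")
  b <- norm1(table_b, "b")
  both <- dplyr::bind_rows(a, b)
  a_fit <- a[a$order != anchor_order, ]
  b_fit <- b[b$order != anchor_order, ]
  if (nrow(a_fit) < 3L || nrow(b_fit) < 3L) {
    abort("each table needs at least 3 non-anchor orders")
  }
  fit_a <- lm(log(norm_radius) ~ order, data = a_fit)
  fit_b <- lm(log(norm_radius) ~ order, data = b_fit)
  fit_p <- lm(log(norm_radius) ~ order, data = rbind(a_fit, b_fit))
  ss_sep <- sum(residuals(fit_a)^2) + sum(residuals(fit_b)^2)
  ss_pool <- sum(residuals(fit_p)^2)
  df2 <- nrow(a_fit) + nrow(b_fit) - 4L
  # residual sums at float-noise scale are exact fits
  tiny <- .Machine$double.eps^0.5 * sum(log(both$norm_radius)^2 + 1)
  if (ss_sep < tiny) ss_sep <- 0
  if (ss_pool < tiny) ss_pool <- 0
  if (ss_sep == 0) {
    f <- if (ss_pool == 0) 0 else Inf
  } else {
    f <- ((ss_pool - ss_sep) / 2) / (ss_sep / df2)
  }
  p <- if (is.infinite(f)) 0 else pf(f, 2, df2, lower.tail = FALSE)
  out <- list(
    f = f, df = c(2L, df2), p_value = p,
    slopes = c(a = unname(coef(fit_a)[2L]), b = unname(coef(fit_b)[2L])),
    intercepts = c(a = unname(coef(fit_a)[1L]), b = unname(coef(fit_b)[1L])),
    data = both
  )
  class(out) <- "order_fit_comparison"
  out
}

#' @export
print.order_fit_comparison <- function(x, ...) {
  cat(sprintf(
    "<order_fit_comparison> F(%d, %d) = %.4g, p = %.4g\n",
    x$df[1L], x$df[2L], x$f, x$p_value
  ))
  invisible(x)
}

#' @rdname compare_order_radius_fits
#' @param x An `order_fit_comparison`.
#' @param ... Unused.
#' @export
tidy.order_fit_comparison <- function(x, ...) {
  tibble::tibble(
    network = c("a", "b"),
    slope = unname(x$slopes),
    intercept = unname(x$intercepts)
  )
}

#' @rdname compare_order_radius_fits
#' @export
glance.order_fit_comparison <- function(x, ...) {
  tibble::tibble(
    statistic = x$f, df1 = x$df[1L], df2 = x$df[2L], p.value = x$p_value
  )
}
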