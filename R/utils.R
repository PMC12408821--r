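#' @importFrom rlang %||% abort warn .data
#' @importFrom stats quantile sd lm coef qf pf setNames rpois runif rnorm fitted residuals median cor dist
#' @importFrom utils head tail read.delim write.table
NULL

# Euclidean norm of a 3-vector (or rowwise for a matrix)
vnorm <- function(v) {
  if (is.matrix(v)) sqrt(rowSums(v^2)) else sqrt(sum(v^2))
}

# arc length of a polyline given an n x 3 coordinate matrix
polyline_length <- function(xyz) {
  if (nrow(xyz) < 2L) return(0)
  sum(vnorm(diff(xyz)))
}

# orthonormal basis (u, v) perpendicular to a nonzero 3-vector t
plane_basis <- function(tangent) {
  t_hat <- tangent / vnorm(tangent)
  ref <- if (abs(t_hat[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * t_hat) * t_hat
  u <- u / vnorm(u)
  v <- c(
    t_hat[2L] * u[3L] - t_hat[3L] * u[2L],
    t_hat[3L] * u[1L] - t_hat[1L] * u[3L],
    t_hat[1L] * u[2L] - t_hat[2L] * u[1L]
  )
  list(u = u, v = v, t = t_hat)
}

# rotate vector x about unit axis k by angle theta (Rodrigues)
rotate_about <- function(x, k, theta) {
  k <- k / vnorm(k)
  cross <- c(
    k[2L] * x[3L] - k[3L] * x[2L],
    k[3L] * x[1L] - k[1L] * x[3L],
    k[1L] * x[2L] - k[2L] * x[1L]
  )
  x * cos(theta) + cross * sin(theta) + k * sum(k * x) * (1 - cos(theta))
}

stop_if_not_graph <- function(x, arg = "graph") {
  if (!inherits(x, "spatial_graph")) {
    abort(sprintf("`%s` must be a spatial_graph (see `spatial_graph()`).", arg))
  }
}

stop_if_not_rooted <- function(x, arg = "tree") {
  if (!inherits(x, "rooted_tree")) {
    abort(sprintf("`%s` must be a rooted tree; call `root_tree()` first.", arg))
  }
}
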