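#' Parametric ellipse for robust clump fitting
#'
#' An ellipse is parameterized by its center `(cx, cy)`, a scale `r`
#' (the radius of the equal-area circle; for `eps = 0` the ellipse *is* a
#' circle of radius `r`), a non-negative eccentricity parameter `eps`, and the
#' major-axis orientation `theta`. The shape matrix is constrained to
#' `A = R(theta) diag(m, 1/m) R(theta)'` with
#' `m = ratio_min + (1 - ratio_min) / (1 + eps)`, so the minor/major axis
#' ratio equals `m` and is bounded below by `ratio_min` for every parameter
#' value: hyperbolae and degenerate lines cannot be produced.
#'
#' @param cx,cy Center, in pixel units.
#' @param r Scale parameter (px), must be positive.
#' @param eps Eccentricity parameter, `>= 0`; 0 gives a circle.
#' @param theta Major-axis angle in radians; reduced to `[0, pi)`.
#' @param ratio_min Lower bound on the minor/major axis ratio (default 0.5).
#' @return An object of class `ellipse_params`.
#' @examples
#' e <- ellipse_params(50, 40, r = 15, eps = 0.3, theta = pi / 4)
#' ellipse_axes(e)
#' @export
ellipse_params <- function(cx, cy, r, eps = 0, theta = 0, ratio_min = 0.5) {
  if (!is.finite(r) || r <= 0) bp_abort("`r` must be positive.")
  if (!is.finite(eps) || eps < 0) bp_abort("`eps` must be >= 0.")
  if (ratio_min <= 0 || ratio_min >= 1) bp_abort("`ratio_min` must be in (0, 1).")
  structure(
    list(cx = cx, cy = cy, r = r, eps = eps,
         theta = theta %% pi, ratio_min = ratio_min),
    class = "ellipse_params"
  )
}

# minor/major axis ratio implied by eps
axis_ratio <- function(e) e$ratio_min + (1 - e$ratio_min) / (1 + e$eps)

#' Semi-axes of a parametric ellipse
#'
#' @param e An [ellipse_params()] object.
#' @return Named numeric vector with major semi-axis `a` and minor `b`
#'   (`a * b = r^2`, the equal-area property of the parameterization).
#' @export
ellipse_axes <- function(e) {
  m <- axis_ratio(e)
  c(a = e$r / sqrt(m), b = e$r * sqrt(m))
}

#' Algebraic error of points relative to an ellipse
#'
#' The algebraic error is `(p - c)' A (p - c) - r^2`: exactly 0 on the
#' ellipse, negative inside, positive outside. For `eps = 0` it reduces to the
#' circle form `|p - c|^2 - r^2`.
#'
#' @param e An [ellipse_params()] object.
#' @param x,y Point coordinates (vectorized).
#' @return Numeric vector of algebraic errors.
#' @examples
#' e <- ellipse_params(0, 0, r = 1)
#' algebraic_error(e, c(1, 2), c(0, 0)) # 0, 3
#' @export
algebraic_error <- function(e, x, y) {
  m <- axis_ratio(e)
  ct <- cos(e$theta); st <- sin(e$theta)
  # rotate into the ellipse frame: u along the major axis
  u <- (x - e$cx) * ct + (y - e$cy) * st
  v <- -(x - e$cx) * st + (y - e$cy) * ct
  m * u^2 + v^2 / m - e$r^2
}

# Signed near-boundary geometric residual: e / (2 r) is the first-order
# distance to the curve for near-circular ellipses; used as the working
# residual of the robust regression so the px-unit scale sigma applies.
geometric_residual <- function(e, x, y) algebraic_error(e, x, y) / (2 * e$r)

#' Sample points on an ellipse boundary
#'
#' @param e An [ellipse_params()] object.
#' @param n Number of points.
#' @return A tibble with columns `x`, `y`.
#' @export
ellipse_boundary <- function(e, n = 100) {
  ax <- ellipse_axes(e)
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ct <- cos(e$theta); st <- sin(e$theta)
  u <- ax[["a"]] * cos(t); v <- ax[["b"]] * sin(t)
  tibble::tibble(x = e$cx + u * ct - v * st, y = e$cy + u * st + v * ct)
}

# Circumcircle through 3 points; NULL when (nearly) collinear.
circle_through <- function(x, y) {
  ax <- x[1]; ay <- y[1]; bx <- x[2]; by <- y[2]; cx <- x[3]; cy <- y[3]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-9) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(cx = ux, cy = uy, r = sqrt((ax - ux)^2 + (ay - uy)^2))
}

#' @export
print.ellipse_params <- function(x, ...) {
  ax <- ellipse_axes(x)
  cat(sprintf(
    "<ellipse_params> center (%.2f, %.2f), r %.2f, axes %.2f x %.2f, theta %.3f\n",
    x$cx, x$cy, x$r, ax[["a"]], ax[["b"]], x$theta))
  invisible(x)
}
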