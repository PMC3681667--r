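#' Closed-form moment ellipse fit of an arbitrary pixel shape
#'
#' Matches the first and second moments of the pixel coordinates to those of
#' a uniform-density ellipse: the center is the centroid, the semi-axes are
#' `2 * sqrt(eigenvalue)` of the second central moment matrix, and the
#' density `D` is the pixel count over the fitted ellipse area. Shapes with
#' fewer than 5 pixels or `D >= 1` are routed to the artifact class.
#'
#' @param x,y Pixel coordinates of the shape.
#' @return A list of class `moment_fit`: `n`, `cx`, `cy`, `a`, `b` (major /
#'   minor semi-axes), `theta`, `density`, `artifact` (logical),
#'   `artifact_reason`.
#' @export
moment_ellipse_fit <- function(x, y) {
  n <- length(x)
  if (n < 5) {
    return(structure(list(n = n, cx = mean(x), cy = mean(y), a = NA_real_,
                          b = NA_real_, theta = NA_real_, density = NA_real_,
                          artifact = TRUE, artifact_reason = "too_small"),
                     class = "moment_fit"))
  }
  cx <- mean(x); cy <- mean(y)
  sxx <- mean((x - cx)^2); syy <- mean((y - cy)^2)
  sxy <- mean((x - cx) * (y - cy))
  M <- matrix(c(sxx, sxy, sxy, syy), 2, 2)
  ev <- eigen(M, symmetric = TRUE)
  a <- 2 * sqrt(max(ev$values[1], 1e-12))
  b <- 2 * sqrt(max(ev$values[2], 1e-12))
  theta <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) %% pi
  density <- n / (pi * a * b)
  structure(list(n = n, cx = cx, cy = cy, a = a, b = b, theta = theta,
                 density = density, artifact = density >= 1,
                 artifact_reason = if (density >= 1) "density" else NA_character_),
            class = "moment_fit")
}

#' Ramanujan's first approximation to an ellipse perimeter
#'
#' `pi * (3 (a + b) - sqrt((3a + b)(a + 3b)))`; exact in the circle limit.
#'
#' @param a,b Semi-axes, both positive.
#' @return Approximate perimeter length.
#' @examples
#' ramanujan_perimeter(10, 10) # 2 * pi * 10
#' @export
ramanujan_perimeter <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) bp_abort("semi-axes must be positive")
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Quality measures for an identified shape
#'
#' Four per-object quality measures drive the cell-confidence mixture:
#' \describe{
#'   \item{q_density}{`log(1 - D)` where `D` is the moment-fit density;
#'     bitmap-drawn cells have `D` just under 1.}
#'   \item{q_perimeter}{log ratio of the count of perimeter pixels (pixels
#'     with 3+ background pixels among their 8 neighbors) to the Ramanujan
#'     perimeter of the moment-fit ellipse.}
#'   \item{q_circular}{log coefficient of variation of the per-pixel sum of
#'     distance to the fitted center and distance to the edge; exactly the
#'     radius (zero variance) for an ideal circle, so the CV is floored at
#'     `cv_floor` before the log.}
#'   \item{mean_rfp}{mean RFP intensity over the shape.}
#' }
#'
#' @param x,y Pixel coordinates of the shape.
#' @param fit The shape's [moment_ellipse_fit()].
#' @param edge_distance Per-pixel edge distances for the shape's pixels.
#' @param rfp_values Per-pixel RFP intensities for the shape's pixels.
#' @param background Logical matrix marking background pixels (used for the
#'   perimeter-pixel rule).
#' @param cv_floor Floor applied to the CV before taking the log (default 1e-3).
#' @return Named numeric vector `c(q_density, q_perimeter, q_circular,
#'   mean_rfp)`.
#' @export
quality_vector <- function(x, y, fit, edge_distance, rfp_values, background,
                           cv_floor = 1e-3) {
  if (isTRUE(fit$artifact)) bp_abort("shape was routed to the artifact class")
  q_density <- log(max(1 - fit$density, 1e-12))
  n_perim <- count_perimeter_pixels(x, y, background)
  q_perimeter <- log(max(n_perim, 1) / ramanujan_perimeter(fit$a, fit$b))
  s <- sqrt((x - fit$cx)^2 + (y - fit$cy)^2) + edge_distance
  cv <- sd(s) * sqrt((length(s) - 1) / length(s)) / mean(s)
  q_circular <- log(max(cv, cv_floor))
  c(q_density = q_density, q_perimeter = q_perimeter,
    q_circular = q_circular, mean_rfp = mean(rfp_values))
}

count_perimeter_pixels <- function(x, y, background) {
  nr <- nrow(background); nc <- ncol(background)
  n_bg <- vapply(seq_along(x), function(i) {
    cnt <- 0L
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      yy <- y[i] + dy; xx <- x[i] + dx
      if (yy < 1 || yy > nr || xx < 1 || xx > nc || background[yy, xx]) {
        cnt <- cnt + 1L
      }
    }
    cnt
  }, integer(1))
  sum(n_bg >= 3L)
}

#' Fit the size-interpolated Normal cell-quality model
#'
#' Labeled cells are split into 7 size bins at equal-quantile anchors; each
#' bin gets a diagonal Normal (mean and sd per quality measure). At
#' evaluation time parameters are linearly interpolated between the two
#' bracketing bin anchors. The uniform (non-cell) alternative spans the
#' extremes of each measure over the complete object collection.
#'
#' @param training A data frame of labeled cells with columns `q_density`,
#'   `q_perimeter`, `q_circular`, `mean_rfp`, `size`.
#' @param all_objects A data frame of the complete object collection with the
#'   four measure columns; defaults to `training`.
#' @param n_bins Number of size bins (default 7).
#' @param sd_floor_frac sd floor per measure as a fraction of the measure's
#'   training range (default 1e-3).
#' @return An object of class `confidence_model`.
#' @export
fit_confidence_model <- function(training, all_objects = training,
                                 n_bins = 7, sd_floor_frac = 1e-3) {
  measures <- c("q_density", "q_perimeter", "q_circular", "mean_rfp")
  if (nrow(training) < 20) bp_abort("need at least 20 training cells")
  anchors <- unname(quantile(training$size,
                             probs = seq(0, 1, length.out = n_bins)))
  if (length(unique(anchors)) < 2) bp_abort("training sizes span fewer than 2 bins")
  # assign each training cell to its nearest anchor's bin
  bin <- pmax(1L, pmin(n_bins, findInterval(training$size, anchors,
                                            all.inside = TRUE)))
  # nearest anchor of the bracketing pair
  d_lo <- abs(training$size - anchors[bin])
  d_hi <- abs(anchors[pmin(bin + 1L, n_bins)] - training$size)
  bin <- ifelse(d_hi < d_lo, pmin(bin + 1L, n_bins), bin)
  rng <- vapply(measures, function(m) diff(range(training[[m]])), numeric(1))
  sd_floor <- pmax(rng * sd_floor_frac, 1e-9)
  mu <- matrix(NA_real_, n_bins, 4, dimnames = list(NULL, measures))
  sig <- matrix(NA_real_, n_bins, 4, dimnames = list(NULL, measures))
  flagged <- logical(n_bins)
  for (b in seq_len(n_bins)) {
    rows <- training[bin == b, , drop = FALSE]
    if (nrow(rows) == 0) { flagged[b] <- TRUE; next }
    for (k in seq_along(measures)) {
      mu[b, k] <- mean(rows[[measures[k]]])
      s <- if (nrow(rows) > 1) sd(rows[[measures[k]]]) else 0
      if (!is.finite(s) || s < sd_floor[k]) { s <- sd_floor[k]; flagged[b] <- TRUE }
      sig[b, k] <- s
    }
  }
  # borrow nearest fitted bin for empty bins
  fitted_bins <- which(!is.na(mu[, 1]))
  for (b in which(is.na(mu[, 1]))) {
    nb <- fitted_bins[which.min(abs(fitted_bins - b))]
    mu[b, ] <- mu[nb, ]; sig[b, ] <- sig[nb, ]
  }
  lo <- vapply(measures, function(m) min(all_objects[[m]]), numeric(1))
  hi <- vapply(measures, function(m) max(all_objects[[m]]), numeric(1))
  structure(list(anchors = anchors, mu = mu, sigma = sig,
                 uniform_lo = lo, uniform_hi = hi,
                 measures = measures, flagged = flagged,
                 rho = NA_real_),
            class = "confidence_model")
}

# Interpolated Normal parameters at a given size: linear blend of the two
# bracketing bins, clamped outside the anchor range.
interp_params <- function(model, size) {
  a <- model$anchors
  n <- length(a)
  if (size <= a[1]) return(list(mu = model$mu[1, ], sigma = model$sigma[1, ]))
  if (size >= a[n]) return(list(mu = model$mu[n, ], sigma = model$sigma[n, ]))
  i <- findInterval(size, a, rightmost.closed = TRUE)
  w <- (size - a[i]) / (a[i + 1] - a[i])
  list(mu = (1 - w) * model$mu[i, ] + w * model$mu[i + 1, ],
       sigma = (1 - w) * model$sigma[i, ] + w * model$sigma[i + 1, ])
}

# log density of q under the cell model at a size, and under the uniform
# alternative (support-edge density outside the support, flagged upstream)
cell_loglik <- function(model, q, size) {
  p <- interp_params(model, size)
  sum(dnorm(q, p$mu, p$sigma, log = TRUE))
}

uniform_loglik <- function(model, q) {
  -sum(log(pmax(model$uniform_hi - model$uniform_lo, 1e-12)))
}

#' Posterior probability that an object is a cell
#'
#' Two-component mixture posterior: size-interpolated diagonal Normal for
#' the cell class against a uniform alternative over the collection-wide
#' extremes, with mixing parameter `rho` as the cell-class prior.
#'
#' @param q Named quality vector ([quality_vector()]).
#' @param size Object size in pixels.
#' @param model A fitted [fit_confidence_model()].
#' @param rho Mixing parameter (cell prior); defaults to the model's
#'   estimate.
#' @return Posterior probability in `[0, 1]`.
#' @examples
#' # with equal component likelihoods and rho = 0.5 the posterior is 0.5
#' @export
cell_posterior <- function(q, size, model, rho = model$rho) {
  if (!is.finite(rho)) bp_abort("mixing parameter `rho` is not set")
  q <- q[model$measures]
  out_of_support <- any(q < model$uniform_lo | q > model$uniform_hi)
  if (out_of_support) {
    warn("quality vector outside the uniform support; using support-edge density")
  }
  lc <- cell_loglik(model, q, size)
  lu <- uniform_loglik(model, q)
  m <- max(lc, lu)
  num <- rho * exp(lc - m)
  den <- num + (1 - rho) * exp(lu - m)
  num / den
}

#' Estimate the mixing parameter by soft EM
#'
#' All component parameters are fixed; only the cell-class prior `rho` is
#' updated as the mean posterior over the collection, iterated to a fixed
#' point.
#'
#' @param objects Data frame with the four measure columns and `size`.
#' @param model A fitted [fit_confidence_model()].
#' @param rho_init Starting value (default 0.5).
#' @param tol Convergence tolerance on `rho` (default 1e-6).
#' @param max_iter Iteration cap.
#' @return The model with `rho` set and attribute `iterations`.
#' @export
estimate_mixing <- function(objects, model, rho_init = 0.5, tol = 1e-6,
                            max_iter = 500) {
  if (nrow(objects) == 0) bp_abort("empty object collection")
  lcs <- vapply(seq_len(nrow(objects)), function(i) {
    cell_loglik(model, unlist(objects[i, model$measures]), objects$size[i])
  }, numeric(1))
  lu <- uniform_loglik(model, NULL)
  rho <- rho_init
  iter <- 0L
  repeat {
    iter <- iter + 1L
    m <- pmax(lcs, lu)
    num <- rho * exp(lcs - m)
    post <- num / (num + (1 - rho) * exp(lu - m))
    rho_new <- mean(post)
    if (abs(rho_new - rho) < tol || iter >= max_iter) { rho <- rho_new; break }
    rho <- rho_new
  }
  model$rho <- rho
  attr(model, "iterations") <- iter
  model
}

#' Mother-bud pair probability and lone-cell weight
#'
#' The probability that a mother-bud pair is correctly identified is the
#' product of the two cell probabilities; a paired cell is partially
#' assigned to the lone class with weight `cell_p * (1 - partner_p)`.
#'
#' @param mother_p,bud_p Cell probabilities in `[0, 1]`.
#' @return `pair_probability`: the product.
#' @export
pair_probability <- function(mother_p, bud_p) {
  stopifnot(all(mother_p >= 0 & mother_p <= 1), all(bud_p >= 0 & bud_p <= 1))
  mother_p * bud_p
}

#' @param cell_p,partner_p Cell probabilities in `[0, 1]`.
#' @rdname pair_probability
#' @export
lone_weight <- function(cell_p, partner_p) {
  stopifnot(all(cell_p >= 0 & cell_p <= 1),
            all(partner_p >= 0 & partner_p <= 1))
  cell_p * (1 - partner_p)
}

#' @export
tidy.confidence_model <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x$mu)), function(b) {
    tibble::tibble(bin = b, size_anchor = x$anchors[b],
                   measure = x$measures,
                   mean = unname(x$mu[b, ]), sd = unname(x$sigma[b, ]),
                   flagged = x$flagged[b])
  })
}

#' @export
glance.confidence_model <- function(x, ...) {
  tibble::tibble(n_bins = nrow(x$mu), rho = x$rho,
                 n_flagged_bins = sum(x$flagged))
}

#' @export
print.confidence_model <- function(x, ...) {
  cat(sprintf("<confidence_model> %d size bins (%.0f..%.0f px), rho = %s\n",
              nrow(x$mu), min(x$anchors), max(x$anchors),
              ifelse(is.finite(x$rho), sprintf("%.3f", x$rho), "unset")))
  invisible(x)
}
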