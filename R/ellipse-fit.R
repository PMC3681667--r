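#' Extract clump contour pixels from an edge-distance map
#'
#' Contour pixels are foreground pixels within `thickness` (expected)
#' pixels of some background pixel, i.e. pixels with a positive edge
#' distance no greater than the contour thickness. Contours are grouped
#' into clumps by 8-connectivity.
#'
#' @param edge_map An [edge_distance_map()] result.
#' @param thickness Contour thickness in pixels (default 5).
#' @param foreground Optional logical foreground mask; defaults to pixels
#'   with a positive edge distance (exact in the deterministic limit; pass
#'   the thresholded segmentation posterior for soft maps).
#' @return A tibble with columns `x`, `y` (pixel coordinates, 1-based),
#'   `clump` (integer clump id) and `removed` (logical, all `FALSE`).
#' @export
extract_contour_pixels <- function(edge_map, thickness = 5, foreground = NULL) {
  d <- edge_map$distance
  if (is.null(foreground)) foreground <- d > 0
  sel <- foreground & d <= thickness
  if (!any(sel)) {
    return(tibble::tibble(x = integer(0), y = integer(0),
                          clump = integer(0), removed = logical(0)))
  }
  clump_lab <- label_connected(foreground)
  px <- pixel_coords(sel)
  px$clump <- clump_lab[cbind(px$y, px$x)]
  px$depth <- d[cbind(px$y, px$x)]
  px$removed <- FALSE
  px
}

# 8-connected component labelling by label propagation (vectorized).
label_connected <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0, nr, nc)
  lab[mask] <- which(mask)
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  repeat {
    new <- lab
    for (k in seq_len(nrow(offs))) {
      s <- shift_matrix(lab, offs$dy[k], offs$dx[k], fill = 0)
      new <- pmax(new, s * mask)
    }
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, nr, nc)
  ids <- sort(unique(lab[lab > 0]))
  out[mask] <- match(lab[mask], ids)
  out
}

# Damped Gauss-Newton IRLS minimization of the robust ellipse objective on
# one contour; returns the refined ellipse and its objective value. The fit
# targets the mid-line of the contour band; accepted ellipses are expanded
# to the cell boundary afterwards using the consumed pixels' edge depths.
refine_ellipse <- function(e, x, y, sigma = 5, max_iter = 100,
                           tol = 1e-4) {
  par <- c(e$cx, e$cy, e$r, e$eps, e$theta)
  ratio_min <- e$ratio_min
  par_to_e <- function(p) {
    ellipse_params(p[1], p[2], max(p[3], 0.5), max(p[4], 0), p[5],
                   ratio_min = ratio_min)
  }
  resid <- function(ee) geometric_residual(ee, x, y)
  # redescending (Geman-McClure) loss: contributions saturate at sigma^2/2,
  # so pixels belonging to *other* ellipses of the clump stop pulling the fit
  objective <- function(p) {
    res2 <- resid(par_to_e(p))^2
    sum(sigma^2 / 2 * res2 / (sigma^2 + res2))
  }
  obj <- objective(par)
  lambda <- 1e-3
  for (it in seq_len(max_iter)) {
    ee <- par_to_e(par)
    res <- resid(ee)
    w <- 1 / (1 + (res / sigma)^2)^2
    # numerical Jacobian of the residual wrt the 5 parameters
    J <- matrix(0, length(x), 5)
    h <- c(1e-4, 1e-4, 1e-4, 1e-5, 1e-5)
    for (j in 1:5) {
      pj <- par; pj[j] <- pj[j] + h[j]
      J[, j] <- (resid(par_to_e(pj)) - res) / h[j]
    }
    g <- crossprod(J, w * res)
    Hm <- crossprod(J, w * J)
    step <- tryCatch(solve(Hm + lambda * diag(diag(Hm) + 1e-8)),
                     error = function(e) NULL)
    if (is.null(step)) break
    delta <- as.numeric(step %*% g)
    cand <- par - delta
    cand[3] <- max(cand[3], 0.5)
    cand[4] <- max(cand[4], 0)
    obj_cand <- objective(cand)
    if (obj_cand <= obj) {
      moved <- max(abs(cand - par))
      par <- cand
      obj <- obj_cand
      lambda <- max(lambda / 3, 1e-8)
      if (moved < tol) break
    } else {
      lambda <- lambda * 5
      if (lambda > 1e8) break
    }
  }
  list(e = par_to_e(par), objective = obj)
}

#' Robust multi-ellipse regression on clump contours
#'
#' Fits one or more ellipses to the contour pixels of each clump using
#' iteratively-reweighted robust regression of the algebraic error
#' (redescending Geman-McClure weights `1 / (1 + (e/sigma)^2)^2` on the
#' scale-normalized residual, expected error `sigma` matching the contour
#' thickness; the loss saturates so contour pixels belonging to other cells
#' of the clump stop influencing the fit).
#' Candidates are initialized from circles through 3 randomly sampled
#' contour points (rejected when the circle escapes the clamping rectangle
#' of the contour or is centered on background), the best local minimum is
#' kept, contour pixels explained by it are removed, and the process repeats
#' until no further pixels can be removed. Ellipses narrower than 3 px or
#' explaining less than 10% of their expected contour pixels are rejected.
#'
#' @param contour A contour tibble from [extract_contour_pixels()] (a single
#'   clump, or use the pipeline which splits by clump).
#' @param seed Integer seed for the candidate sampler.
#' @param sigma Robust residual scale, px; defaults to half the contour
#'   thickness, since band pixels lie within half a thickness of the
#'   mid-contour curve.
#' @param thickness Contour thickness, px (default 5); sets the expected
#'   per-ellipse pixel count and the removal band.
#' @param ratio_min Lower bound on the minor/major axis ratio (default 0.5).
#' @param background_mask Optional logical matrix; candidate circles centered
#'   on `TRUE` pixels are rejected.
#' @param r_typical Typical cell radius used to budget candidates (default 15).
#' @param removal_factor Pixels with absolute normalized residual below this
#'   value are consumed by an accepted ellipse (default `sigma`).
#' @param max_ellipses Safety cap (default 50).
#' @return A tibble with one row per fitted ellipse: `cx`, `cy`, `r`, `eps`,
#'   `theta`, `a`, `b`, `objective`, `n_pixels` (contour pixels consumed).
#' @export
fit_ellipses_robust <- function(contour, seed = 1L, sigma = thickness / 2,
                                thickness = 5,
                                ratio_min = 0.5, background_mask = NULL,
                                r_typical = 15, removal_factor = thickness,
                                max_ellipses = 50) {
  empty <- tibble::tibble(cx = numeric(0), cy = numeric(0), r = numeric(0),
                          eps = numeric(0), theta = numeric(0),
                          a = numeric(0), b = numeric(0),
                          objective = numeric(0), n_pixels = integer(0))
  if (nrow(contour) < 3) return(empty)
  with_seed(seed, fit_ellipses_impl(contour, sigma, thickness, ratio_min,
                                    background_mask, r_typical,
                                    removal_factor, max_ellipses, empty))
}

fit_ellipses_impl <- function(contour, sigma, thickness, ratio_min,
                              background_mask, r_typical, removal_factor,
                              max_ellipses, empty) {
  x <- contour$x; y <- contour$y
  depth <- if ("depth" %in% names(contour)) contour$depth else
    rep(0.5, nrow(contour))
  active <- !contour$removed
  out <- list()
  # small initial eccentricity giving axis ratio 0.95
  eps_init <- eps_for_ratio(0.95, ratio_min)
  while (sum(active) >= 3 && length(out) < max_ellipses) {
    xa <- x[active]; ya <- y[active]; da <- depth[active]
    rect <- c(min(xa), max(xa), min(ya), max(ya))
    n_expected <- max(1, round(length(xa) / (2 * pi * r_typical * thickness)))
    n_cand <- 10 * n_expected
    best <- NULL
    for (k in seq_len(max(n_cand, 10))) {
      idx <- sample.int(length(xa), 3)
      circ <- circle_through(xa[idx], ya[idx])
      if (is.null(circ)) next
      # clamping-rectangle and non-background-center checks on the circle
      if (circ$cx - circ$r < rect[1] - thickness ||
          circ$cx + circ$r > rect[2] + thickness ||
          circ$cy - circ$r < rect[3] - thickness ||
          circ$cy + circ$r > rect[4] + thickness) next
      if (!is.null(background_mask) && center_on_background(
            background_mask, circ$cx, circ$cy)) next
      e0 <- ellipse_params(circ$cx, circ$cy, circ$r, eps_init,
                           runif(1, 0, pi), ratio_min = ratio_min)
      fit <- refine_ellipse(e0, xa, ya, sigma = sigma)
      # post-convergence candidate checks: bounded by the clamping rectangle
      # and not centered on background
      ext <- ellipse_extents(fit$e)
      if (fit$e$cx - ext[1] < rect[1] - thickness ||
          fit$e$cx + ext[1] > rect[2] + thickness ||
          fit$e$cy - ext[2] < rect[3] - thickness ||
          fit$e$cy + ext[2] > rect[4] + thickness) next
      if (!is.null(background_mask) && center_on_background(
            background_mask, fit$e$cx, fit$e$cy)) next
      # selection score: contour completeness = fraction of the ellipse's
      # expected contour band actually covered by low-residual pixels; this
      # prefers an ellipse matching one cell's arc over a clump-envelope
      # ellipse grazing many arcs
      inl <- sum(abs(geometric_residual(fit$e, xa, ya)) < sigma)
      fit$completeness <- inl / (2 * pi * fit$e$r * thickness)
      if (is.null(best) || fit$completeness > best$completeness) best <- fit
    }
    if (is.null(best)) break
    e <- best$e
    ok <- TRUE
    res_all <- abs(geometric_residual(e, x, y))
    consume <- active & res_all < removal_factor
    expected_px <- 2 * pi * e$r * thickness
    if (sum(consume) < 0.1 * expected_px) ok <- FALSE
    # expand the mid-band fit to the cell boundary: consumed pixels at edge
    # depth d sit about d - 1/2 px inside the boundary curve
    if (any(consume)) e$r <- e$r + max(mean(depth[consume]) - 0.5, 0)
    ax <- ellipse_axes(e)
    if (2 * ax[["b"]] < 3) ok <- FALSE
    if (!ok) {
      # reject the ellipse but still drop its pixels so iteration terminates
      if (!any(consume)) break
      active <- active & !consume
      next
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      cx = e$cx, cy = e$cy, r = e$r, eps = e$eps, theta = e$theta,
      a = ax[["a"]], b = ax[["b"]], objective = best$objective,
      n_pixels = sum(consume))
    if (!any(consume)) break
    active <- active & !consume
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out)
}

# half-extents of the ellipse bounding box along x and y
ellipse_extents <- function(e) {
  ax <- ellipse_axes(e)
  a <- ax[["a"]]; b <- ax[["b"]]
  ct <- cos(e$theta); st <- sin(e$theta)
  c(sqrt(a^2 * ct^2 + b^2 * st^2), sqrt(a^2 * st^2 + b^2 * ct^2))
}

# eccentricity parameter giving a target axis ratio under ratio_min
eps_for_ratio <- function(ratio, ratio_min) {
  (1 - ratio_min) / (ratio - ratio_min) - 1
}

center_on_background <- function(mask, cx, cy) {
  yy <- round(cy); xx <- round(cx)
  if (yy < 1 || yy > nrow(mask) || xx < 1 || xx > ncol(mask)) return(TRUE)
  mask[yy, xx]
}
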