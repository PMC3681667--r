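#' Fit the 3-segment model of expected mean RFP versus cell area
#'
#' Continuous piecewise-linear least squares with two free interior
#' breakpoints: for fixed breakpoints the fit is linear in a hinge basis
#' `(1, area, max(0, area - b1), max(0, area - b2))`, and the breakpoints
#' are optimized by Nelder-Mead over a quantile-anchored start. End segments
#' extrapolate, so the model is defined for any positive area.
#'
#' @param cells Data frame with columns `area` and `mean_rfp`.
#' @param min_cells Minimum number of cells (default 100).
#' @return Object of class `rfp_size_model`: `breakpoints`, `coef` (hinge
#'   basis coefficients), `single_segment` flag, `rss`.
#' @export
fit_rfp_size_model <- function(cells, min_cells = 100) {
  if (nrow(cells) < min_cells) {
    bp_abort(sprintf("need at least %d cells to fit the RFP size model",
                     min_cells))
  }
  a <- cells$area; yv <- cells$mean_rfp
  qs <- quantile(a, c(0.05, 0.95))
  spread_ok <- diff(qs) > 0.1 * max(a)
  hinge_fit <- function(bp) {
    X <- cbind(1, a, pmax(0, a - bp[1]), pmax(0, a - bp[2]))
    fit <- tryCatch(lm.fit(X, yv), error = function(e) NULL)
    if (is.null(fit)) return(list(rss = Inf))
    co <- fit$coefficients
    co[is.na(co)] <- 0
    list(rss = sum(fit$residuals^2), coef = co)
  }
  if (!spread_ok) {
    co <- lm.fit(cbind(1, a), yv)$coefficients
    return(structure(list(breakpoints = c(NA_real_, NA_real_),
                          coef = c(co, 0, 0), single_segment = TRUE,
                          rss = sum((yv - co[1] - co[2] * a)^2)),
                     class = "rfp_size_model"))
  }
  start <- unname(quantile(a, c(1 / 3, 2 / 3)))
  obj <- function(p) {
    bp <- sort(p)
    if (bp[1] <= min(a) || bp[2] >= max(a) || diff(bp) < 1e-6) return(1e30)
    hinge_fit(bp)$rss
  }
  # multi-start Nelder-Mead over breakpoint placements
  starts <- list(start,
                 unname(quantile(a, c(0.2, 0.5))),
                 unname(quantile(a, c(0.5, 0.8))),
                 unname(quantile(a, c(0.25, 0.75))))
  best <- NULL
  for (s in starts) {
    o <- optim(s, obj, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  bp <- sort(best$par)
  hf <- hinge_fit(bp)
  structure(list(breakpoints = bp, coef = hf$coef, single_segment = FALSE,
                 rss = hf$rss),
            class = "rfp_size_model")
}

#' Expected mean RFP at a given cell area
#'
#' @param object A fitted [fit_rfp_size_model()].
#' @param newdata Data frame with column `area`, or a numeric vector of areas.
#' @param ... Unused.
#' @return Numeric vector of expected mean RFP values.
#' @export
predict.rfp_size_model <- function(object, newdata, ...) {
  a <- if (is.data.frame(newdata)) newdata$area else newdata
  if (any(a <= 0)) bp_abort("areas must be positive")
  co <- object$coef
  b1 <- object$breakpoints[1]; b2 <- object$breakpoints[2]
  out <- co[1] + co[2] * a
  if (!is.na(b1)) out <- out + co[3] * pmax(0, a - b1)
  if (!is.na(b2)) out <- out + co[4] * pmax(0, a - b2)
  unname(out)
}

#' @export
tidy.rfp_size_model <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope", "hinge1", "hinge2"),
                 estimate = unname(x$coef),
                 breakpoint = c(NA, NA, x$breakpoints))
}

#' @export
glance.rfp_size_model <- function(x, ...) {
  tibble::tibble(breakpoint1 = x$breakpoints[1], breakpoint2 = x$breakpoints[2],
                 rss = x$rss, single_segment = x$single_segment)
}

#' Size-normalized GFP/RFP intensity ratio
#'
#' Total GFP over the size-expected total RFP: the observed RFP sum is
#' replaced by `area * E[mean RFP | area]` from the 3-segment model, making
#' the ratio comparable across cell sizes.
#'
#' @param gfp_sum Total GFP intensity within the cell.
#' @param rfp_sum Total RFP intensity within the cell (checked against the
#'   ruptured-cell signature of zero RFP).
#' @param area Cell area, px.
#' @param model A fitted [fit_rfp_size_model()].
#' @return The dimensionless intensity ratio.
#' @export
intensity_ratio <- function(gfp_sum, rfp_sum, area, model) {
  if (any(rfp_sum <= 0)) {
    bp_abort("zero RFP sum (ruptured-cell signature)",
             class = "budprofiler_ruptured_error")
  }
  expected <- predict(model, area)
  gfp_sum / (area * expected)
}

#' Morphological log-ratio distances for one cell
#'
#' Treating normalized pixel intensity in a channel as a probability
#' distribution over pixel coordinates, five expected geometric distances
#' are computed for the GFP-tagged protein and normalized by the same
#' quantity under the RFP marker distribution, reported as natural-log
#' ratios:
#' to the cell center (mean pixel coordinate), to the channel's own mass
#' center, to the cell periphery (edge-distance map), to the bud neck, and
#' between proteins (GFP-GFP pair expectation over the GFP-RFP cross
#' expectation). All five are 0 when the GFP and RFP spatial distributions
#' coincide, and invariant to scaling either channel by a positive
#' constant.
#'
#' @param x,y Pixel coordinates of the cell shape.
#' @param gfp,rfp Per-pixel intensities (non-negative; negative
#'   background-subtracted values should be clipped to 0 upstream).
#' @param edge_distance Per-pixel edge distances.
#' @param neck Optional bud-neck coordinate `c(x, y)`; `NULL` for lone
#'   cells, whose neck feature is recorded missing.
#' @param pair_method `"exact"` for the O(N^2) double sum of the
#'   between-protein expectations.
#' @return Named numeric vector: `d_between`, `d_mass_center`, `d_center`,
#'   `d_periphery`, `d_neck` (NA when `neck` is NULL).
#' @export
morphological_distances <- function(x, y, gfp, rfp, edge_distance,
                                    neck = NULL, pair_method = "exact") {
  if (sum(gfp) <= 0) {
    bp_abort("all-zero GFP over the cell: morphological distances undefined",
             class = "budprofiler_zero_channel_error")
  }
  if (sum(rfp) <= 0) {
    bp_abort("all-zero RFP over the cell",
             class = "budprofiler_zero_channel_error")
  }
  pg <- gfp / sum(gfp)
  pr <- rfp / sum(rfp)
  cellc <- c(mean(x), mean(y))
  mg <- c(sum(pg * x), sum(pg * y))
  mr <- c(sum(pr * x), sum(pr * y))
  dist_to <- function(p, pt) sum(p * sqrt((x - pt[1])^2 + (y - pt[2])^2))
  # expected pairwise distances (exact double sums)
  dmat_weighted <- function(pa, pb) {
    dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
    sum(outer(pa, pb) * sqrt(dx^2 + dy^2))
  }
  e_gg <- dmat_weighted(pg, pg)
  e_gr <- dmat_weighted(pg, pr)
  out <- c(
    d_between = log(e_gg / e_gr),
    d_mass_center = log(dist_to(pg, mg) / dist_to(pr, mr)),
    d_center = log(dist_to(pg, cellc) / dist_to(pr, cellc)),
    d_periphery = log(sum(pg * edge_distance) / sum(pr * edge_distance)),
    d_neck = NA_real_
  )
  if (!is.null(neck) && all(is.finite(neck))) {
    out[["d_neck"]] <- log(dist_to(pg, neck) / dist_to(pr, neck))
  }
  out
}
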