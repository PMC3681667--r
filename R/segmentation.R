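#' Background image from a collection of RFP micrographs
#'
#' The background image is the pixel-wise mean over the collection; pixels
#' whose variance across images is exactly zero (the signature of a defective
#' CCD pixel that systematically reports the same value) are flagged.
#'
#' @param images A list of numeric matrices of identical shape.
#' @return A list with `background` (matrix), `defective` (logical matrix,
#'   only meaningful for 3+ images) and `n_images`.
#' @export
compute_background_image <- function(images) {
  if (!length(images)) bp_abort("need at least one image")
  dims <- dim(images[[1]])
  for (i in seq_along(images)) {
    if (!identical(dim(images[[i]]), dims)) {
      bp_abort(sprintf("image %d has shape %s, expected %s", i,
                       paste(dim(images[[i]]), collapse = "x"),
                       paste(dims, collapse = "x")),
               class = "budprofiler_shape_error")
    }
  }
  n <- length(images)
  s <- Reduce(`+`, images)
  bg <- s / n
  defective <- matrix(FALSE, dims[1], dims[2])
  if (n >= 3) {
    s2 <- Reduce(`+`, lapply(images, function(m) m^2))
    v <- s2 / n - bg^2
    defective <- v <= 0
  }
  list(background = bg, defective = defective, n_images = n)
}

#' Subtract a background image, flooring at zero
#'
#' @param image Numeric matrix.
#' @param background Background matrix of the same shape.
#' @return Corrected matrix with negative values floored at 0.
#' @export
subtract_background <- function(image, background) {
  if (!identical(dim(image), dim(background))) {
    bp_abort("image and background shapes differ",
             class = "budprofiler_shape_error")
  }
  pmax(image - background, 0)
}

# --- Pseudo-2D HMM -----------------------------------------------------------

# Vectorized Baum-Welch for a 2-state Normal-emission HMM applied to every
# row of a matrix simultaneously (rows are independent sequences sharing
# parameters). Returns posteriors and fitted parameters.
hmm_em_rows <- function(m, mu, sigma, trans, max_iter = 200, tol = 1e-6) {
  nr <- nrow(m); nc <- ncol(m)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  pi0 <- c(0.5, 0.5)
  gamma1 <- NULL
  for (iter in seq_len(max_iter)) {
    # emission log-densities, nr x nc x 2
    ld1 <- dnorm(m, mu[1], sigma[1], log = TRUE)
    ld2 <- dnorm(m, mu[2], sigma[2], log = TRUE)
    # scaled forward-backward across columns, vectorized over rows
    alpha1 <- matrix(0, nr, nc); alpha2 <- matrix(0, nr, nc)
    cscale <- matrix(0, nr, nc)
    e1 <- exp(ld1 - pmax(ld1, ld2)); e2 <- exp(ld2 - pmax(ld1, ld2))
    a1 <- pi0[1] * e1[, 1]; a2 <- pi0[2] * e2[, 1]
    cs <- a1 + a2
    alpha1[, 1] <- a1 / cs; alpha2[, 1] <- a2 / cs
    cscale[, 1] <- log(cs) + pmax(ld1[, 1], ld2[, 1])
    for (t in 2:nc) {
      p1 <- alpha1[, t - 1] * trans[1, 1] + alpha2[, t - 1] * trans[2, 1]
      p2 <- alpha1[, t - 1] * trans[1, 2] + alpha2[, t - 1] * trans[2, 2]
      a1 <- p1 * e1[, t]; a2 <- p2 * e2[, t]
      cs <- a1 + a2
      cs[cs == 0] <- .Machine$double.xmin
      alpha1[, t] <- a1 / cs; alpha2[, t] <- a2 / cs
      cscale[, t] <- log(cs) + pmax(ld1[, t], ld2[, t])
    }
    ll <- sum(cscale)
    beta1 <- matrix(0, nr, nc); beta2 <- matrix(0, nr, nc)
    beta1[, nc] <- 1; beta2[, nc] <- 1
    # expected transition counts
    xi <- matrix(0, 2, 2)
    g1 <- matrix(0, nr, nc)
    g1[, nc] <- alpha1[, nc]
    for (t in (nc - 1):1) {
      b1n <- beta1[, t + 1] * e1[, t + 1]
      b2n <- beta2[, t + 1] * e2[, t + 1]
      nb1 <- trans[1, 1] * b1n + trans[1, 2] * b2n
      nb2 <- trans[2, 1] * b1n + trans[2, 2] * b2n
      norm <- alpha1[, t] * nb1 + alpha2[, t] * nb2
      norm[norm == 0] <- .Machine$double.xmin
      beta1[, t] <- nb1 / norm; beta2[, t] <- nb2 / norm
      g1[, t] <- alpha1[, t] * nb1 / norm
      xi[1, 1] <- xi[1, 1] + sum(alpha1[, t] * trans[1, 1] * b1n / norm)
      xi[1, 2] <- xi[1, 2] + sum(alpha1[, t] * trans[1, 2] * b2n / norm)
      xi[2, 1] <- xi[2, 1] + sum(alpha2[, t] * trans[2, 1] * b1n / norm)
      xi[2, 2] <- xi[2, 2] + sum(alpha2[, t] * trans[2, 2] * b2n / norm)
    }
    gamma1 <- g1
    g2 <- 1 - g1
    # M-step
    w1 <- sum(g1); w2 <- sum(g2)
    mu <- c(sum(g1 * m) / w1, sum(g2 * m) / w2)
    sigma <- c(sqrt(sum(g1 * (m - mu[1])^2) / w1),
               sqrt(sum(g2 * (m - mu[2])^2) / w2))
    sigma <- pmax(sigma, 1e-6)
    trans <- xi / pmax(rowSums(xi), .Machine$double.xmin)
    trans <- pmax(trans, 1e-12)
    trans <- trans / rowSums(trans)
    pi0 <- c(mean(g1[, 1]), mean(g2[, 1]))
    pi0 <- pi0 / sum(pi0)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(posterior1 = gamma1, mu = mu, sigma = sigma, trans = trans,
       loglik = ll_old, converged = converged, iterations = iter)
}

#' Foreground segmentation with a pseudo-2D hidden Markov model
#'
#' Background and foreground RFP levels are modeled as Normal emissions of a
#' 2-state HMM. Expectation-maximization is run twice: once treating image
#' rows as independent chains and once treating columns as independent
#' chains; the per-pixel foreground posterior is the average of the two. The
#' foreground state is the higher-mean state by convention.
#'
#' @param rfp Numeric matrix (background-corrected RFP channel).
#' @param max_iter EM iteration cap (default 200).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param self_init Initial self-transition probability (default 0.95).
#' @return An object of class `segmentation`: list with `posterior`
#'   (foreground probability matrix), `background` and `foreground`
#'   (mean/sd), `trans` (2x2 row-stochastic matrix, state 1 = background),
#'   `loglik`, `converged`.
#' @export
segment_foreground <- function(rfp, max_iter = 200, tol = 1e-6,
                               self_init = 0.95) {
  if (diff(range(rfp)) == 0) {
    bp_abort("constant image: segmentation is degenerate",
             class = "budprofiler_degenerate_error")
  }
  med <- median(rfp)
  lo <- rfp[rfp <= med]; hi <- rfp[rfp > med]
  if (!length(hi)) hi <- max(rfp)
  mu0 <- c(mean(lo), mean(hi))
  sigma0 <- pmax(c(sd(lo), sd(hi)), 1e-3)
  if (any(!is.finite(sigma0))) sigma0 <- rep(sd(rfp) / 2, 2)
  trans0 <- matrix(c(self_init, 1 - self_init, 1 - self_init, self_init), 2, 2,
                   byrow = TRUE)
  fit_r <- hmm_em_rows(rfp, mu0, sigma0, trans0, max_iter, tol)
  fit_c <- hmm_em_rows(t(rfp), mu0, sigma0, trans0, max_iter, tol)
  if (!fit_r$converged || !fit_c$converged) {
    warn("EM did not converge within the iteration cap; using best estimate")
  }
  # orient each fit so state 2 = foreground (higher mean)
  orient <- function(fit) {
    if (fit$mu[1] <= fit$mu[2]) {
      list(post_fg = 1 - fit$posterior1, mu = fit$mu, sigma = fit$sigma,
           trans = fit$trans)
    } else {
      list(post_fg = fit$posterior1, mu = rev(fit$mu), sigma = rev(fit$sigma),
           trans = fit$trans[2:1, 2:1])
    }
  }
  or <- orient(fit_r); oc <- orient(fit_c)
  posterior <- (or$post_fg + t(oc$post_fg)) / 2
  mu <- (or$mu + oc$mu) / 2
  sigma <- (or$sigma + oc$sigma) / 2
  trans <- (or$trans + oc$trans) / 2
  structure(
    list(posterior = posterior,
         background = c(mean = mu[1], sd = sigma[1]),
         foreground = c(mean = mu[2], sd = sigma[2]),
         trans = trans,
         loglik = c(rows = fit_r$loglik, cols = fit_c$loglik),
         converged = fit_r$converged && fit_c$converged),
    class = "segmentation"
  )
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf(
    "<segmentation> %d x %d; bg N(%.1f, %.1f), fg N(%.1f, %.1f), fg fraction %.3f\n",
    nrow(x$posterior), ncol(x$posterior),
    x$background[["mean"]], x$background[["sd"]],
    x$foreground[["mean"]], x$foreground[["sd"]], mean(x$posterior)))
  invisible(x)
}

#' @export
glance.segmentation <- function(x, ...) {
  tibble::tibble(
    bg_mean = x$background[["mean"]], bg_sd = x$background[["sd"]],
    fg_mean = x$foreground[["mean"]], fg_sd = x$foreground[["sd"]],
    self_trans_bg = x$trans[1, 1], self_trans_fg = x$trans[2, 2],
    fg_fraction = mean(x$posterior), converged = x$converged
  )
}
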