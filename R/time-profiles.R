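#' Cell stage from bud area
#'
#' Under constant bud-volume growth, time scales linearly with the bud
#' volume; for an isotropically scaled 2-D section this is `area^(3/2)`.
#' The exponent is configurable.
#'
#' @param bud_area Bud area, px (positive).
#' @param exponent Power applied to the area (default 1.5).
#' @return Stage covariate, monotone in bud area.
#' @export
cell_stage <- function(bud_area, exponent = 1.5) {
  if (any(bud_area <= 0)) bp_abort("bud area must be positive")
  bud_area^exponent
}

#' Equidistant stage keypoints for a run
#'
#' @param stage Stage covariate values.
#' @param n_keypoints Number of keypoints (default 10).
#' @param probs Quantile range spanned (default 1st-99th percentile).
#' @return Numeric vector of keypoint stage values.
#' @export
stage_keypoints <- function(stage, n_keypoints = 10, probs = c(0.01, 0.99)) {
  rng <- quantile(stage, probs, names = FALSE)
  seq(rng[1], rng[2], length.out = n_keypoints)
}

# Kernel-weighted mean and variance of one feature column at the keypoints.
kernel_estimates <- function(stage, values, weights, keypoints, bandwidth,
                             min_mass = 1e-8) {
  vapply(keypoints, function(t0) {
    k <- dnorm((stage - t0) / bandwidth)
    w <- weights * k
    sw <- sum(w)
    if (sw < min_mass) return(c(NA_real_, NA_real_, 0))
    mu <- sum(w * values) / sw
    c(mu, sum(w * (values - mu)^2) / sw, sw)
  }, numeric(3))
}

#' Confidence-weighted LOESS time profile
#'
#' At each of the stage keypoints, the mean and variance of every feature
#' are estimated by a Gaussian-kernel weighted average over mother-bud
#' pairs, with weights equal to the pair weight (product of the two cell
#' probabilities) times the kernel evaluated at the stage distance. The 6
#' features for bud and mother cells at 10 keypoints concatenate into the
#' 120-value time profile.
#'
#' @param series A data frame with columns `stage`, `weight`, and one column
#'   per feature (any columns other than `stage` and `weight` are treated as
#'   features; the pipeline supplies 12: 6 per cell role).
#' @param keypoints Keypoint stage values; default computed from the data
#'   with [stage_keypoints()].
#' @param bandwidth Gaussian kernel bandwidth in stage units (default 1700).
#' @param min_mass Keypoints where the total kernel mass falls below this
#'   tolerance are flagged unreliable (`NA` mean/variance).
#' @return Object of class `time_profile`: a tibble with columns `keypoint`,
#'   `stage`, `feature`, `mean`, `variance`, `kernel_mass`, `reliable`;
#'   attributes `n_pairs`, `bandwidth`, `keypoints`.
#' @export
loess_profile <- function(series, keypoints = NULL, bandwidth = 1700,
                          min_mass = 1e-8) {
  feats <- setdiff(names(series), c("stage", "weight", "protein"))
  if (!length(feats)) bp_abort("no feature columns in `series`")
  if (nrow(series) < 2 || sum(series$weight > 0) < 2) {
    bp_abort("need at least 2 pairs with positive weight")
  }
  if (is.null(keypoints)) keypoints <- stage_keypoints(series$stage)
  rows <- purrr::map_dfr(feats, function(f) {
    est <- kernel_estimates(series$stage, series[[f]], series$weight,
                            keypoints, bandwidth, min_mass)
    tibble::tibble(keypoint = seq_along(keypoints), stage = keypoints,
                   feature = f, mean = est[1, ], variance = est[2, ],
                   kernel_mass = est[3, ], reliable = est[3, ] >= min_mass)
  })
  structure(rows, class = c("time_profile", class(rows)),
            n_pairs = nrow(series), bandwidth = bandwidth,
            keypoints = keypoints)
}

#' Flatten a time profile into mean and variance vectors
#'
#' @param profile A [loess_profile()] result.
#' @return List with `mean` and `variance` vectors (feature-major, keypoint
#'   order within feature) named `feature.k`.
#' @export
profile_vector <- function(profile) {
  nm <- paste(profile$feature, profile$keypoint, sep = ".")
  list(mean = setNames(profile$mean, nm),
       variance = setNames(profile$variance, nm))
}

#' Jackknife sampling-variance fraction of the profile
#'
#' Leave-one-pair-out recomputation of every keypoint mean; the jackknife
#' variance of the mean is reported as a fraction of the total
#' (weight-weighted) cell-to-cell variance of the corresponding feature.
#'
#' @inheritParams loess_profile
#' @return A tibble `keypoint`, `feature`, `jackknife_variance`,
#'   `total_variance`, `fraction`.
#' @export
jackknife_profile_variance <- function(series, keypoints = NULL,
                                       bandwidth = 1700) {
  n <- nrow(series)
  if (n < 3) bp_abort("jackknife needs at least 3 pairs")
  if (is.null(keypoints)) keypoints <- stage_keypoints(series$stage)
  feats <- setdiff(names(series), c("stage", "weight", "protein"))
  full <- loess_profile(series, keypoints, bandwidth)
  loo <- lapply(seq_len(n), function(i) {
    loess_profile(series[-i, , drop = FALSE], keypoints, bandwidth)$mean
  })
  loo_mat <- do.call(cbind, loo) # (keypoints*features) x n
  theta_bar <- rowMeans(loo_mat)
  jk_var <- (n - 1) / n * rowSums((loo_mat - theta_bar)^2)
  tot <- vapply(feats, function(f) {
    weighted_moments(series[[f]], series$weight)[["var"]]
  }, numeric(1))
  tibble::tibble(
    keypoint = full$keypoint, feature = full$feature,
    jackknife_variance = jk_var,
    total_variance = tot[match(full$feature, feats)],
    fraction = jk_var / pmax(tot[match(full$feature, feats)], 1e-300))
}

#' Cell-stage permutation test for a time profile
#'
#' Permutes the stage covariate across pairs (features and weights stay
#' attached to their pair), recomputes the kernel estimates at each
#' keypoint, and reports two-sided empirical tail probabilities with the
#' add-one rule. Deterministic given `seed`; `n_perm = "exact"` enumerates
#' all permutations (small n only).
#'
#' @inheritParams loess_profile
#' @param n_perm Number of permutations (>= 100), or `"exact"`.
#' @param seed Integer seed.
#' @param alternative `"two.sided"` (default, 2.5% per tail at level 5%) or
#'   `"greater"` / `"less"`.
#' @return A tibble `keypoint`, `feature`, `observed`, `null_mean`,
#'   `null_sd`, `p_value`.
#' @export
stage_permutation_test <- function(series, keypoints = NULL, bandwidth = 1700,
                                   n_perm = 1000, seed = 1L,
                                   alternative = "two.sided") {
  exact <- identical(n_perm, "exact")
  if (!exact && n_perm < 100) bp_abort("n_perm must be >= 100 (or \"exact\")")
  if (is.null(keypoints)) keypoints <- stage_keypoints(series$stage)
  obs <- loess_profile(series, keypoints, bandwidth)
  n <- nrow(series)
  perms <- if (exact) {
    all_permutations(n)
  } else {
    with_seed(seed, replicate(n_perm, sample.int(n), simplify = FALSE))
  }
  feats <- setdiff(names(series), c("stage", "weight", "protein"))
  null_mat <- vapply(perms, function(p) {
    st <- series$stage[p]
    unlist(lapply(feats, function(f) {
      kernel_estimates(st, series[[f]], series$weight, keypoints,
                       bandwidth)[1, ]
    }))
  }, numeric(nrow(obs)))
  B <- length(perms)
  ge <- rowSums(null_mat >= obs$mean, na.rm = TRUE)
  le <- rowSums(null_mat <= obs$mean, na.rm = TRUE)
  p <- switch(alternative,
    two.sided = pmin(1, 2 * (pmin(ge, le) + 1) / (B + 1)),
    greater = (ge + 1) / (B + 1),
    less = (le + 1) / (B + 1),
    bp_abort("unknown alternative"))
  tibble::tibble(keypoint = obs$keypoint, feature = obs$feature,
                 observed = obs$mean,
                 null_mean = rowMeans(null_mat),
                 null_sd = apply(null_mat, 1, sd),
                 p_value = p)
}

all_permutations <- function(n) {
  if (n > 7) bp_abort("exact enumeration limited to n <= 7")
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

#' @export
autoplot.time_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean - sqrt(.data$variance),
      ymax = .data$mean + sqrt(.data$variance)), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~ .data$feature, scales = "free_y") +
    ggplot2::labs(x = "cell stage (bud-size transform)",
                  y = "feature value",
                  title = "confidence-weighted time profile")
}

#' @export
glance.time_profile <- function(x, ...) {
  tibble::tibble(n_pairs = attr(x, "n_pairs"),
                 bandwidth = attr(x, "bandwidth"),
                 n_keypoints = length(attr(x, "keypoints")),
                 n_unreliable = sum(!x$reliable))
}
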