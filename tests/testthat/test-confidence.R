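test_that("moment fit recovers a rasterized disk", {
  d <- raster_disk(50, 50, 20, 100, 100)
  fit <- moment_ellipse_fit(d$x, d$y)
  expect_equal(fit$cx, 50)  # exact by symmetry
  expect_equal(fit$cy, 50)
  expect_equal(fit$a, 20, tolerance = 0.02)
  expect_equal(fit$b, 20, tolerance = 0.02)
  expect_equal(fit$density, 1, tolerance = 0.02)
})

test_that("moment identity: semi-axis equals 2 sqrt(second central moment)", {
  # uniform continuous ellipse: E[(x - cx)^2] = a^2 / 4 along the major axis
  d <- raster_disk(60, 60, 25, 120, 120)
  sxx <- mean((d$x - mean(d$x))^2)
  fit <- moment_ellipse_fit(d$x, d$y)
  expect_equal(fit$a, 2 * sqrt(sxx), tolerance = 0.01)
})

test_that("degenerate shapes are routed to the artifact class", {
  # a 1-px wide line: density >= 1 or sub-minimal axis
  fit <- moment_ellipse_fit(1:100, rep(5, 100))
  expect_true(fit$artifact)
  # fewer than 5 pixels
  expect_true(moment_ellipse_fit(1:4, 1:4)$artifact)
  expect_equal(moment_ellipse_fit(1:4, 1:4)$artifact_reason, "too_small")
})

test_that("Ramanujan perimeter is exact for circles and accurate at ratio 2", {
  expect_equal(ramanujan_perimeter(10, 10), 2 * pi * 10)
  # numerical arc length oracle by quadrature for a = 20, b = 10
  t <- seq(0, pi / 2, length.out = 200001)
  integrand <- sqrt(20^2 * sin(t)^2 + 10^2 * cos(t)^2)
  arc <- 4 * sum((integrand[-1] + integrand[-length(t)]) / 2 * diff(t))
  expect_equal(ramanujan_perimeter(20, 10), arc, tolerance = 0.001)
  # degenerate limit b -> 0 approaches pi * a * (3 - sqrt(3)), not the true 4a
  lim <- ramanujan_perimeter(10, 1e-9)
  expect_equal(lim, pi * 10 * (3 - sqrt(3)), tolerance = 1e-6)
  # known approximation gap against the true degenerate perimeter 4a = 40
  expect_gt(abs(lim - 40), 0.1)
  expect_error(ramanujan_perimeter(10, 0))
})

test_that("quality measures separate a disk from an elongated blob", {
  nr <- 120
  bg <- matrix(TRUE, nr, nr)
  d <- raster_disk(40, 40, 18, nr, nr)
  bg[cbind(d$y, d$x)] <- FALSE
  # non-elliptical blob of comparable area: dumbbell of two tangent disks
  d1 <- raster_disk(75, 85, 13, nr, nr)
  d2 <- raster_disk(99, 85, 13, nr, nr)
  bx <- c(d1$x, d2$x); by <- c(d1$y, d2$y)
  keep <- !duplicated(cbind(bx, by))
  bx <- bx[keep]; by <- by[keep]
  bg[cbind(by, bx)] <- FALSE

  fgm <- !bg
  em <- edge_distance_map(binary_seg(fgm))
  fit_d <- moment_ellipse_fit(d$x, d$y)
  fit_b <- moment_ellipse_fit(bx, by)
  rfp <- matrix(50, nr, nr)
  q_d <- quality_vector(d$x, d$y, fit_d, em$distance[cbind(d$y, d$x)],
                        rfp[cbind(d$y, d$x)], bg)
  q_b <- quality_vector(bx, by, fit_b, em$distance[cbind(by, bx)],
                        rfp[cbind(by, bx)], bg)
  # the 3-of-8 exposure rule counts about 2/3 of the digitized perimeter on
  # any smooth boundary, so the disk sits near log(2/3), not 0; shapes whose
  # true boundary exceeds their moment-ellipse perimeter score higher
  expect_lt(abs(q_d[["q_perimeter"]] - log(2 / 3)), 0.25)
  expect_gt(q_b[["q_perimeter"]], q_d[["q_perimeter"]])
  expect_lt(q_d[["q_circular"]], q_b[["q_circular"]])
  expect_equal(q_d[["mean_rfp"]], 50)
})

test_that("center distance plus edge distance is constant on an ideal circle", {
  # for a continuous circle the sum is the radius everywhere; on the
  # rasterized disk the CV is small and the flooring keeps the log finite
  nr <- 100
  d <- raster_disk(50, 50, 20, nr, nr)
  bg <- matrix(TRUE, nr, nr); bg[cbind(d$y, d$x)] <- FALSE
  em <- edge_distance_map(binary_seg(!bg))
  s <- sqrt((d$x - 50)^2 + (d$y - 50)^2) + em$distance[cbind(d$y, d$x)]
  expect_lt(sd(s) / mean(s), 0.1)
})

test_that("confidence model interpolation hits bin parameters at anchors", {
  set.seed(8)
  n <- 140
  training <- tibble::tibble(
    q_density = rnorm(n, -0.1, 0.02), q_perimeter = rnorm(n, 0, 0.05),
    q_circular = rnorm(n, -3, 0.5), mean_rfp = rnorm(n, 900, 100),
    size = runif(n, 100, 1500))
  m <- fit_confidence_model(training)
  p <- interp_params_for_test(m, m$anchors[3])
  expect_equal(unname(p$mu), unname(m$mu[3, ]))
  expect_equal(unname(p$sigma), unname(m$sigma[3, ]))
  # outside the anchor range: clamped to the end bins
  p_lo <- interp_params_for_test(m, 0)
  expect_equal(unname(p_lo$mu), unname(m$mu[1, ]))
})

test_that("constant measures are floored and flagged", {
  n <- 60
  training <- tibble::tibble(
    q_density = rep(-0.1, n), q_perimeter = rnorm(n, 0, 0.05),
    q_circular = rnorm(n, -3, 0.5), mean_rfp = rnorm(n, 900, 100),
    size = runif(n, 100, 1500))
  m <- fit_confidence_model(training)
  expect_true(any(m$flagged))
  expect_true(all(m$sigma > 0))
})

test_that("bin means are recovered from normal simulations within 2 SE", {
  set.seed(9)
  n_per <- 400
  small <- tibble::tibble(
    q_density = rnorm(n_per, -0.2, 0.05), q_perimeter = rnorm(n_per, 0.1, 0.05),
    q_circular = rnorm(n_per, -2, 0.3), mean_rfp = rnorm(n_per, 700, 50),
    size = runif(n_per, 100, 200))
  large <- tibble::tibble(
    q_density = rnorm(n_per, -0.05, 0.05), q_perimeter = rnorm(n_per, 0, 0.05),
    q_circular = rnorm(n_per, -3, 0.3), mean_rfp = rnorm(n_per, 1000, 50),
    size = runif(n_per, 1000, 1100))
  m <- fit_confidence_model(dplyr::bind_rows(small, large), n_bins = 2)
  se <- 0.05 / sqrt(n_per)
  expect_lt(abs(m$mu[1, "q_density"] - (-0.2)), 4 * se)
  expect_lt(abs(m$mu[2, "q_density"] - (-0.05)), 4 * se)
})

test_that("cell posterior follows Bayes arithmetic", {
  m <- fake_model()
  # equal component likelihoods at the uniform density, rho = 0.5 -> 0.5
  q_mid <- m$mu[1, ]
  # construct a quality vector whose cell likelihood equals the uniform one
  lu <- -sum(log(m$uniform_hi - m$uniform_lo))
  # adjust: find offset along q_density so that loglik matches lu
  f <- function(d) {
    q <- q_mid; q["q_density"] <- q["q_density"] + d
    sum(dnorm(q, m$mu[1, ], m$sigma[1, ], log = TRUE)) - lu
  }
  d_star <- uniroot(f, c(0, 5), tol = 1e-12)$root
  q_eq <- q_mid; q_eq["q_density"] <- q_eq["q_density"] + d_star
  expect_equal(cell_posterior(q_eq, size = 150, m, rho = 0.5), 0.5,
               tolerance = 1e-6)
  # likelihood ratio 100 at rho = 0.099 -> 9.9 / 10.801
  lr_target <- log(100)
  f2 <- function(d) {
    q <- q_mid; q["q_density"] <- q["q_density"] + d
    sum(dnorm(q, m$mu[1, ], m$sigma[1, ], log = TRUE)) - (lu + lr_target)
  }
  d2 <- uniroot(f2, c(0, 1), tol = 1e-12)$root
  q_lr <- q_mid; q_lr["q_density"] <- q_lr["q_density"] + d2
  expect_equal(cell_posterior(q_lr, 150, m, rho = 0.099), 9.9 / 10.801,
               tolerance = 1e-6)
  # vanishing cell likelihood -> posterior 0 (and the out-of-support case
  # is flagged)
  q_far <- q_mid + c(30, 0, 0, 0)
  expect_warning(p_far <- cell_posterior(q_far, 150, m, rho = 0.5),
                 "outside the uniform support")
  expect_lt(p_far, 1e-6)
})

test_that("posterior is monotone in the cell-model likelihood at fixed rho", {
  m <- fake_model()
  qs <- seq(0, 3, by = 0.5)
  post <- vapply(qs, function(d) {
    q <- m$mu[1, ]; q["q_circular"] <- q["q_circular"] + d
    cell_posterior(q, 150, m, rho = 0.3)
  }, numeric(1))
  expect_true(all(diff(post) < 0))
})

test_that("soft-EM recovers the mixing parameter from a synthetic mixture", {
  m <- fake_model()
  set.seed(10)
  n <- 2000
  rho_true <- 0.7
  from_cell <- runif(n) < rho_true
  qs <- matrix(NA_real_, n, 4, dimnames = list(NULL, m$measures))
  for (k in 1:4) {
    qs[from_cell, k] <- rnorm(sum(from_cell), m$mu[1, k], m$sigma[1, k])
    qs[!from_cell, k] <- runif(sum(!from_cell), m$uniform_lo[k],
                               m$uniform_hi[k])
  }
  objects <- tibble::as_tibble(qs)
  objects$size <- runif(n, 100, 1500)
  m2 <- estimate_mixing(objects, m)
  expect_lt(abs(m2$rho - rho_true), 0.05)
})

test_that("soft-EM fixed points: single object and flat likelihood ratio", {
  m <- fake_model()
  q1 <- tibble::as_tibble(as.list(m$mu[1, ]))
  q1$size <- 200
  m1 <- estimate_mixing(q1, m, rho_init = 0.3)
  # with one object, rho converges to that object's posterior
  p <- cell_posterior(unlist(q1[, m$measures]), 200, m, rho = m1$rho)
  expect_equal(m1$rho, p, tolerance = 1e-4)
})

test_that("pair probability and lone weight follow the stated forms", {
  expect_equal(pair_probability(1, 1), 1)
  expect_equal(pair_probability(0.9, 0.5), 0.45)
  expect_equal(lone_weight(1, 1), 0)
  expect_equal(lone_weight(0.9, 0), 0.9)
  expect_error(pair_probability(1.2, 0.5))
})

test_that("confidence model serializes through JSON losslessly", {
  m <- fake_model()
  m$rho <- 0.42
  path <- tempfile(fileext = ".json")
  write_confidence_model(m, path)
  m2 <- read_confidence_model(path)
  expect_equal(m2$mu, m$mu, tolerance = 1e-12)
  expect_equal(m2$sigma, m$sigma, tolerance = 1e-12)
  expect_equal(m2$rho, 0.42)
  expect_equal(m2$anchors, m$anchors)
})
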