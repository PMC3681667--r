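# Shared fixtures and independent oracles used across test files.

# Rasterize a disk: linear indices and coordinates of pixels inside.
raster_disk <- function(cx, cy, r, nr = 128, nc = 128) {
  g <- expand.grid(y = seq_len(nr), x = seq_len(nc))
  inside <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
  list(x = g$x[inside], y = g$y[inside])
}

# A deterministic "segmentation" stand-in: binary posterior, identity
# transitions (the deterministic limit of the edge-distance recursion).
binary_seg <- function(fg_mask) {
  list(posterior = ifelse(fg_mask, 1, 0), trans = diag(2))
}

# Independent Dijkstra shortest-path oracle on the {1, sqrt2, sqrt5} move
# set with the image border as background. O(V^2), for small grids only.
dijkstra_edge_distance <- function(fg_mask) {
  nr <- nrow(fg_mask); nc <- ncol(fg_mask)
  fb <- fg_mask
  fb[1, ] <- FALSE; fb[nr, ] <- FALSE; fb[, 1] <- FALSE; fb[, nc] <- FALSE
  moves <- rbind(
    expand.grid(dy = -1:1, dx = -1:1),
    data.frame(dy = c(-2, -2, -1, -1, 1, 1, 2, 2),
               dx = c(-1, 1, -2, 2, -2, 2, -1, 1)))
  moves <- moves[!(moves$dy == 0 & moves$dx == 0), ]
  moves$d <- sqrt(moves$dy^2 + moves$dx^2)
  dist <- matrix(Inf, nr, nc)
  dist[!fb] <- 0
  done <- matrix(FALSE, nr, nc)
  repeat {
    u <- which(!done & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    uy <- ((u - 1) %% nr) + 1; ux <- ((u - 1) %/% nr) + 1
    for (k in seq_len(nrow(moves))) {
      vy <- uy + moves$dy[k]; vx <- ux + moves$dx[k]
      if (vy < 1 || vy > nr || vx < 1 || vx > nc) next
      if (!fb[vy, vx]) next
      nd <- dist[u] + moves$d[k]
      if (nd < dist[vy, vx]) dist[vy, vx] <- nd
    }
  }
  dist
}

# Direct kernel-weighted mean/variance oracle (plain loops, no shared code).
direct_kernel_moments <- function(stage, values, weights, t0, bandwidth) {
  k <- exp(-0.5 * ((stage - t0) / bandwidth)^2) / sqrt(2 * pi)
  w <- weights * k
  mu <- sum(w * values) / sum(w)
  c(mean = mu, var = sum(w * (values - mu)^2) / sum(w))
}

# Smooth random field for watershed tests.
smooth_field <- function(nr, nc, seed) {
  set.seed(seed)
  m <- matrix(rnorm(nr * nc), nr, nc)
  k <- dnorm(-4:4, sd = 1.5); k <- k / sum(k)
  for (i in seq_len(nr)) m[i, ] <- as.numeric(stats::filter(m[i, ], k,
    circular = TRUE))
  for (j in seq_len(nc)) m[, j] <- as.numeric(stats::filter(m[, j], k,
    circular = TRUE))
  m
}

# Build a simple profile table row-block for clustering tests.
make_class_defs <- function(k, sep = 10, sd = 1, size = 10, seed = 1) {
  set.seed(seed)
  lapply(seq_len(k), function(i) {
    list(mean = rnorm(120, mean = i * sep, sd = 1), sd = sd, size = size)
  })
}

interp_params_for_test <- function(m, size) budprofiler:::interp_params(m, size)

as_profile_list_for_test <- function(x) budprofiler:::as_profile_list(x)
write_table_tsv_for_test <- function(...) budprofiler:::write_table_tsv(...)
read_table_tsv_for_test <- function(...) budprofiler:::read_table_tsv(...)

# A hand-built confidence model with size-constant parameters, so posterior
# arithmetic can be checked without a fitting step.
fake_model <- function() {
  measures <- c("q_density", "q_perimeter", "q_circular", "mean_rfp")
  mu <- matrix(rep(c(-0.1, 0, -3, 900), each = 7), 7, 4,
               dimnames = list(NULL, measures))
  sigma <- matrix(rep(c(0.05, 0.1, 0.5, 100), each = 7), 7, 4,
                  dimnames = list(NULL, measures))
  structure(list(
    anchors = seq(100, 1500, length.out = 7),
    mu = mu, sigma = sigma,
    uniform_lo = setNames(c(-2, -1.5, -6, 0), measures),
    uniform_hi = setNames(c(0.5, 1.5, 1, 2000), measures),
    measures = measures, flagged = rep(FALSE, 7), rho = 0.5),
    class = "confidence_model")
}

# Adjusted Rand index (independent implementation for label agreement).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}
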