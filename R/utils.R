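# Internal helpers shared across modules.

# Stop with a classed condition so tests can assert on error class.
bp_abort <- function(msg, class = "budprofiler_error", ...) {
  rlang::abort(msg, class = class, ...)
}

# Matrix of pixel coordinates (row = y, col = x), 1-based internally;
# exported tables use 0-based coordinates per the package's I/O convention.
pixel_coords <- function(mask) {
  idx <- which(mask)
  nr <- nrow(mask)
  tibble::tibble(
    y = ((idx - 1L) %% nr) + 1L,
    x = ((idx - 1L) %/% nr) + 1L
  )
}

# Shift a matrix by (dy, dx), padding with `fill`.
shift_matrix <- function(m, dy, dx, fill = Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- max(1, 1 + dy):min(nr, nr + dy)
  xs <- max(1, 1 + dx):min(nc, nc + dx)
  if (length(ys) < 1 || length(xs) < 1) return(out)
  out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  out
}

# Weighted mean and plug-in weighted variance (weights need not sum to 1).
weighted_moments <- function(x, w) {
  sw <- sum(w)
  if (sw <= 0) return(c(mean = NA_real_, var = NA_real_))
  mu <- sum(w * x) / sw
  c(mean = mu, var = sum(w * (x - mu)^2) / sw)
}

# Deterministic child seed derived from a user seed, kept below 2^31.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 2654435761 + k * 40503) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
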