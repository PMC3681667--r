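# Move set for the expected-distance recursion: 8-neighborhood plus knight
# moves, with geometric step lengths 1, sqrt(2) and sqrt(5).
edge_move_set <- function() {
  m8 <- expand.grid(dy = -1:1, dx = -1:1)
  m8 <- m8[!(m8$dy == 0 & m8$dx == 0), ]
  kn <- expand.grid(dy = c(-2L, -1L, 1L, 2L), dx = c(-2L, -1L, 1L, 2L))
  kn <- kn[abs(kn$dy) != abs(kn$dx), ]
  mv <- rbind(m8, kn)
  mv$d <- sqrt(mv$dy^2 + mv$dx^2)
  mv
}

# Non-integer power of a 2x2 row-stochastic matrix via eigendecomposition.
matrix_power <- function(m, p) {
  e <- eigen(m)
  v <- e$vectors
  Re(v %*% diag(as.complex(e$values)^p) %*% solve(v))
}

#' Expected edge-distance map
#'
#' For each pixel, the expected length of the shortest path to background
#' over the move set of unit, diagonal and knight steps (lengths 1, sqrt(2),
#' sqrt(5)). Foreground/background uncertainty enters in two ways: a pixel's
#' own foreground posterior scales its distance (a certain-background pixel
#' has distance 0), and the onward distance through a neighbor at step
#' length `d` is discounted by the probability of remaining in the
#' foreground state over that step, taken from the segmentation HMM
#' transition matrix raised to the power `d` (eigendecomposition for the
#' non-integer powers). The recursion
#' `E(p) = f(p) * min_q [ d(p,q) + (T^d)_ff * E(q) ]`
#' is a monotone fixed point solved by value sweeps; in the deterministic
#' limit (posterior in \{0,1\}, transitions at identity) it reduces exactly to
#' Dijkstra shortest-path distance under the same move set. The image border
#' is treated as certain background.
#'
#' @param seg A [segment_foreground()] result, or a list with elements
#'   `posterior` (foreground-probability matrix) and `trans` (2x2 HMM
#'   transition matrix; identity gives the deterministic limit).
#' @param max_sweeps Cap on value-iteration sweeps (default 4 * image
#'   diagonal in knight steps, generous).
#' @return An object of class `edge_map`: list with `distance` (matrix) and
#'   `moves` (the move table used).
#' @export
edge_distance_map <- function(seg, max_sweeps = NULL) {
  f <- seg$posterior
  trans <- seg$trans %||% diag(2)
  nr <- nrow(f); nc <- ncol(f)
  mv <- edge_move_set()
  # foreground persistence probability per step length
  persist <- vapply(unique(mv$d), function(d) {
    p <- matrix_power(trans, d)[2, 2]
    min(max(p, 0), 1)
  }, numeric(1))
  names(persist) <- as.character(unique(mv$d))
  # border as certain background
  fb <- f
  fb[1, ] <- 0; fb[nr, ] <- 0; fb[, 1] <- 0; fb[, nc] <- 0
  big <- 2 * (nr + nc)
  E <- matrix(0, nr, nc)
  E[fb > 0] <- big
  if (is.null(max_sweeps)) max_sweeps <- 2L * (nr + nc)
  for (s in seq_len(max_sweeps)) {
    best <- matrix(Inf, nr, nc)
    for (k in seq_len(nrow(mv))) {
      cand <- mv$d[k] + persist[[as.character(mv$d[k])]] *
        shift_matrix(E, mv$dy[k], mv$dx[k], fill = 0)
      best <- pmin(best, cand)
    }
    Enew <- fb * best
    if (max(abs(Enew - E)) < 1e-9) { E <- Enew; break }
    E <- Enew
  }
  structure(list(distance = E, moves = mv), class = "edge_map")
}
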