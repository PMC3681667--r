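test_that("two intensity bumps split into two basins at the dim valley", {
  g <- expand.grid(y = 1:40, x = 1:60)
  img <- matrix(exp(-((g$x - 20)^2 + (g$y - 20)^2) / 60) +
                  exp(-((g$x - 42)^2 + (g$y - 20)^2) / 60), 40, 60)
  fgm <- img > 0.05
  lab <- watershed_basins(img, fgm)
  expect_equal(max(lab), 2)
  # the two bump peaks are in different basins
  expect_true(lab[20, 20] != lab[20, 42])
  # every foreground pixel is labeled
  expect_true(all(lab[fgm] > 0))
  expect_true(all(lab[!fgm] == 0))
})

test_that("a single bump yields one basin covering the mask", {
  g <- expand.grid(y = 1:30, x = 1:30)
  img <- matrix(exp(-((g$x - 15)^2 + (g$y - 15)^2) / 40), 30, 30)
  fgm <- img > 0.1
  lab <- watershed_basins(img, fgm)
  expect_equal(max(lab), 1)
  expect_true(all(lab[fgm] == 1))
})

test_that("basin labels equal a per-pixel steepest-ascent oracle", {
  img <- smooth_field(32, 32, seed = 21)
  fgm <- matrix(TRUE, 32, 32)
  lab <- watershed_basins(img, fgm)
  # oracle: from each pixel, repeatedly step to the brightest 8-neighbor
  # (with the same lowest-index plateau tie-break) until at a local max
  v <- img - matrix(seq_len(32 * 32), 32, 32) * 1e-9
  climb <- function(y, x) {
    repeat {
      best <- c(y, x); bv <- v[y, x]
      for (dy in -1:1) for (dx in -1:1) {
        yy <- y + dy; xx <- x + dx
        if (yy < 1 || yy > 32 || xx < 1 || xx > 32) next
        if (v[yy, xx] > bv) { bv <- v[yy, xx]; best <- c(yy, xx) }
      }
      if (best[1] == y && best[2] == x) return(c(y, x))
      y <- best[1]; x <- best[2]
    }
  }
  roots <- matrix(0, 32, 32)
  for (y in 1:32) for (x in 1:32) {
    r <- climb(y, x)
    roots[y, x] <- (r[2] - 1) * 32 + r[1]
  }
  # same partition: labels agree up to renaming
  expect_equal(length(unique(as.vector(roots))), max(lab))
  expect_true(all(tapply(as.vector(roots), as.vector(lab),
                         function(z) length(unique(z))) == 1))
})

test_that("basins are assigned to the ellipse nearest their maximum", {
  # two well-separated ellipse interiors as basins
  img <- matrix(0, 50, 90)
  e1 <- ellipse_params(25, 25, 12)
  e2 <- ellipse_params(62, 25, 14)
  g <- expand.grid(y = 1:50, x = 1:90)
  in1 <- algebraic_error(e1, g$x, g$y) <= 0
  in2 <- algebraic_error(e2, g$x, g$y) <= 0
  img[cbind(g$y[in1], g$x[in1])] <- 100 - algebraic_error(e1, g$x[in1], g$y[in1]) / 10
  img[cbind(g$y[in2], g$x[in2])] <- 100 - algebraic_error(e2, g$x[in2], g$y[in2]) / 10
  fgm <- img > 0
  basins <- watershed_basins(img, fgm)
  ells <- tibble::tibble(cx = c(25, 62), cy = c(25, 25), r = c(12, 14),
                         eps = 0, theta = 0)
  asm <- assemble_shapes(basins, ells, img)
  expect_equal(sort(unique(asm$label[asm$label > 0])), c(1L, 2L))
  expect_true(all(asm$label[cbind(g$y[in1], g$x[in1])] == 1L))
  expect_true(all(asm$label[cbind(g$y[in2], g$x[in2])] == 2L))
})

test_that("assignment equals the exhaustive minimum-error oracle", {
  set.seed(31)
  img <- smooth_field(40, 40, seed = 5) + 2
  fgm <- matrix(TRUE, 40, 40)
  basins <- watershed_basins(img, fgm)
  ells <- tibble::tibble(cx = c(10, 30, 20), cy = c(10, 12, 32),
                         r = c(8, 9, 10), eps = c(0, 0.4, 0.1),
                         theta = c(0, 1, 2))
  asm <- assemble_shapes(basins, ells, img)
  # oracle: per basin, evaluate |algebraic error| at the brightest pixel
  for (b in seq_len(max(basins))) {
    idx <- which(basins == b)
    peak <- idx[which.max(img[idx])]
    py <- ((peak - 1) %% 40) + 1; px <- ((peak - 1) %/% 40) + 1
    errs <- vapply(1:3, function(i) {
      e <- ellipse_params(ells$cx[i], ells$cy[i], ells$r[i], ells$eps[i],
                          ells$theta[i])
      abs(algebraic_error(e, px, py))
    }, numeric(1))
    expect_equal(unique(asm$label[idx]), which.min(errs))
  }
})

test_that("basins with no ellipse available are flagged unassigned", {
  img <- matrix(1, 10, 10); img[5, 5] <- 2
  basins <- watershed_basins(img, matrix(TRUE, 10, 10))
  asm <- assemble_shapes(basins, tibble::tibble(cx = numeric(0),
                                                cy = numeric(0),
                                                r = numeric(0),
                                                eps = numeric(0),
                                                theta = numeric(0)), img)
  expect_true(all(asm$label == 0L))
  expect_true(all(asm$unassigned[basins > 0L]))
})

# helper: label matrix with rectangular shapes in a horizontal chain
chain_label <- function(areas) {
  # each shape is a block of height 10 and width area/10, sharing vertical
  # boundaries with its neighbor
  widths <- vapply(areas, function(a) a %/% 10L, integer(1))
  lab <- matrix(0L, 14, sum(widths) + 4)
  x0 <- 2L
  for (i in seq_along(widths)) {
    lab[3:12, x0:(x0 + widths[i] - 1L)] <- i
    x0 <- x0 + widths[i]
  }
  lab
}

test_that("mother-bud typing follows the reciprocal-extremum rules", {
  # isolated shape -> lone
  lab1 <- chain_label(c(500L))
  t1 <- assign_cell_types(lab1)
  expect_equal(t1$type, "lone")

  # chain 500-120-90: pair (mother 120's? no: B=120 pairs with C=90); A lone
  lab2 <- chain_label(c(500L, 120L, 90L))
  t2 <- assign_cell_types(lab2)
  expect_equal(t2$type, c("lone", "mother", "bud"))
  expect_equal(t2$partner, c(NA_integer_, 3L, 2L))

  # two shapes 500-120 -> pair (mother A, bud B)
  lab3 <- chain_label(c(500L, 120L))
  t3 <- assign_cell_types(lab3)
  expect_equal(t3$type, c("mother", "bud"))
  expect_equal(t3$partner, c(2L, 1L))
})

test_that("bud neck lies between the paired shapes", {
  lab <- chain_label(c(500L, 120L))
  t <- assign_cell_types(lab)
  # boundary between block 1 (cols 2..51) and block 2 (cols 52..63)
  expect_true(all(abs(t$neck_x - 51.5) <= 1))
  expect_equal(t$neck_y, c(7.5, 7.5))
  expect_equal(t$bud_area, c(120, 120))
})

test_that("typing is invariant to shape enumeration order", {
  lab <- chain_label(c(500L, 120L, 90L, 300L))
  base <- assign_cell_types(lab)
  # relabel shapes in reversed order
  perm <- c(4L, 3L, 2L, 1L)
  lab2 <- lab
  lab2[lab > 0L] <- perm[lab[lab > 0L]]
  t2 <- assign_cell_types(lab2)
  t2 <- t2[match(perm[base$id], t2$id), ]
  expect_equal(t2$type, base$type)
})

test_that("shapes partition the assigned foreground exactly", {
  sim <- simulate_micrograph(scene_config(seed = 29))
  res <- process_micrograph(sim$micrograph, pipeline_config(), "x")
  lab <- res$label
  areas <- res$cells$area
  expect_equal(sum(areas), sum(lab > 0L))
  expect_equal(unname(c(table(lab[lab > 0L]))[as.character(res$cells$id)]),
               areas)
})

test_that("typing on simulated clumps matches the generator's pairing", {
  # clean regime: isolated mother-bud pairs and lone cells only (no random
  # clumping), buds clearly smaller than mothers and above the artifact
  # pre-filter, so typing errors cannot hide behind clump merge errors
  hits <- 0; tot <- 0
  for (s in c(41, 43, 47)) {
    sim <- simulate_micrograph(scene_config(
      seed = s, n_cells = 10, clump_fraction = 0, bud_fraction = 0.7,
      cell_area_range = c(700, 1600), bud_radius_range = c(0.45, 0.75)))
    res <- process_micrograph(sim$micrograph, pipeline_config(), "x")
    tr <- sim$truth$cells
    det <- res$cells[!res$cells$artifact, ]
    for (i in seq_len(nrow(det))) {
      d <- sqrt((tr$cx - det$cx[i])^2 + (tr$cy - det$cy[i])^2)
      j <- which.min(d)
      if (d[j] > 6) next
      tot <- tot + 1
      if (tr$type[j] == det$type[i]) hits <- hits + 1
    }
  }
  expect_gte(tot, 30)
  expect_gte(hits / tot, 0.95)
})
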