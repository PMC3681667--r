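#' Configuration for a synthetic two-channel yeast scene
#'
#' Describes a simulated micrograph: ellipsoidal cells with per-cell RFP
#' levels and a dome-shaped intensity profile (so each cell holds exactly one
#' intensity maximum), 1-px dim gaps between touching cells, mother-attached
#' buds, optional vacuole dimming, structured GFP patterns, background noise
#' and artifact objects. Defaults emulate a small field of a high-resolution
#' 12-bit yeast micrograph at desk scale.
#'
#' @param width,height Image size in pixels.
#' @param n_cells Number of primary cells (mothers and lone cells).
#' @param cell_area_range Range of primary-cell areas, px.
#' @param clump_fraction Fraction of primary cells placed touching an
#'   existing cell.
#' @param bud_fraction Probability each primary cell carries an attached bud.
#' @param bud_radius_range Bud radius as a fraction of the mother radius;
#'   the wide default spans the full bud-size (cell-stage) range.
#' @param rfp_level_mean,rfp_level_sd Per-cell RFP plateau level distribution
#'   (12-bit camera units).
#' @param vacuole_prob,vacuole_depth Probability a cell carries a dim vacuole
#'   and the fractional intensity drop inside it.
#' @param noise_mean,noise_sd Additive Gaussian background noise.
#' @param n_artifacts Number of artifact objects.
#' @param artifact_kinds Kinds sampled for artifacts; subset of
#'   `"edge_noise"`, `"ruptured"`, `"dim"`, `"defective_pixel"`.
#' @param gfp_pattern GFP pattern kind, one of `"uniform"`, `"nuclear"`,
#'   `"peripheral"`, `"bud_neck"`, `"punctate"`, `"stage_switching"`.
#' @param gfp_amplitude Peak GFP pattern level above the cytoplasmic base.
#' @param gfp_base Dim uniform cytoplasmic GFP level.
#' @param stage_switch_quantile For `"stage_switching"`: pairs with bud area
#'   below this quantile show the nuclear pattern, others uniform.
#' @param seed Integer random seed; identical config + seed gives a
#'   bit-identical scene.
#' @return A validated `scene_config` list.
#' @export
scene_config <- function(width = 256, height = 256,
                         n_cells = 8,
                         cell_area_range = c(500, 1500),
                         clump_fraction = 0.5,
                         bud_fraction = 0.5,
                         bud_radius_range = c(0.25, 0.8),
                         rfp_level_mean = 1500, rfp_level_sd = 250,
                         vacuole_prob = 0.3, vacuole_depth = 0.35,
                         noise_mean = 100, noise_sd = 12,
                         n_artifacts = 2,
                         artifact_kinds = c("edge_noise", "ruptured", "dim"),
                         gfp_pattern = "uniform",
                         gfp_amplitude = 800,
                         gfp_base = 150,
                         stage_switch_quantile = 0.5,
                         seed = 1L) {
  cfg <- list(width = as.integer(width), height = as.integer(height),
              n_cells = as.integer(n_cells),
              cell_area_range = cell_area_range,
              clump_fraction = clump_fraction, bud_fraction = bud_fraction,
              bud_radius_range = bud_radius_range,
              rfp_level_mean = rfp_level_mean, rfp_level_sd = rfp_level_sd,
              vacuole_prob = vacuole_prob, vacuole_depth = vacuole_depth,
              noise_mean = noise_mean, noise_sd = noise_sd,
              n_artifacts = as.integer(n_artifacts),
              artifact_kinds = artifact_kinds,
              gfp_pattern = gfp_pattern, gfp_amplitude = gfp_amplitude,
              gfp_base = gfp_base,
              stage_switch_quantile = stage_switch_quantile,
              seed = as.integer(seed))
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  stopifnot_cfg <- function(ok, field, what) {
    if (!ok) bp_abort(sprintf("scene_config field `%s` %s", field, what),
                      class = "budprofiler_config_error")
  }
  stopifnot_cfg(cfg$width > 0 && cfg$height > 0, "width/height", "must be positive")
  stopifnot_cfg(cfg$n_cells >= 0, "n_cells", "must be >= 0")
  stopifnot_cfg(cfg$n_artifacts >= 0, "n_artifacts", "must be >= 0")
  stopifnot_cfg(cfg$noise_sd > 0, "noise_sd", "must be > 0")
  for (f in c("clump_fraction", "bud_fraction", "vacuole_prob")) {
    stopifnot_cfg(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must be in [0, 1]")
  }
  stopifnot_cfg(all(cfg$cell_area_range > 0) && diff(cfg$cell_area_range) >= 0,
                "cell_area_range", "must be positive and increasing")
  kinds <- c("uniform", "nuclear", "peripheral", "bud_neck", "punctate",
             "stage_switching")
  stopifnot_cfg(cfg$gfp_pattern %in% kinds, "gfp_pattern",
                paste("must be one of", paste(kinds, collapse = ", ")))
  invisible(cfg)
}

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Separable Gaussian blur with reflective-ish (renormalized) edges.
gaussian_blur <- function(m, sigma = 2) {
  if (sigma <= 0) return(m)
  rad <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-rad:rad, sd = sigma)
  k <- k / sum(k)
  blur_1d <- function(mm, along_rows) {
    acc <- matrix(0, nrow(mm), ncol(mm))
    wacc <- matrix(0, nrow(mm), ncol(mm))
    for (i in seq_along(k)) {
      off <- i - rad - 1L
      s <- if (along_rows) shift_matrix(mm, off, 0L, fill = NA) else
        shift_matrix(mm, 0L, off, fill = NA)
      ok <- !is.na(s)
      acc[ok] <- acc[ok] + k[i] * s[ok]
      wacc[ok] <- wacc[ok] + k[i]
    }
    acc / wacc
  }
  blur_1d(blur_1d(m, TRUE), FALSE)
}

# Rasterize ellipse interior within its bounding box; returns linear indices.
rasterize_ellipse <- function(e, width, height, shrink = 0) {
  ax <- ellipse_axes(e)
  amax <- ax[["a"]]
  xs <- max(1L, floor(e$cx - amax)):min(width, ceiling(e$cx + amax))
  ys <- max(1L, floor(e$cy - amax)):min(height, ceiling(e$cy + amax))
  if (!length(xs) || !length(ys)) return(integer(0))
  g <- expand.grid(y = ys, x = xs)
  r_eff <- max(e$r - shrink, 1)
  e2 <- e; e2$r <- r_eff
  inside <- algebraic_error(e2, g$x, g$y) <= 0
  (g$x[inside] - 1L) * height + g$y[inside]
}

#' Simulate a two-channel micrograph with ground truth
#'
#' Renders the scene described by a [scene_config()]: cells are filled
#' ellipses with a dome-shaped RFP profile and a smooth 2-px roll-off at
#' edges, touching cells are separated by a 1-px dim gap (so watershed basins
#' split clumps at dim boundaries), buds are drawn attached to their mothers,
#' and the GFP channel renders the configured localization pattern per cell.
#' Values are clipped to the 12-bit range `[0, 4095]`.
#'
#' @param config A [scene_config()].
#' @return A list with elements `micrograph` (list of matrices `rfp`, `gfp`),
#'   and `truth`: a list with `cells` (tibble of per-cell ground truth:
#'   ellipse parameters, type, partner, mask area, bud area, neck
#'   coordinates, GFP pattern), `label` (integer matrix of cell ids, 0 =
#'   background) and `artifact_mask` (logical matrix).
#' @export
simulate_micrograph <- function(config) {
  validate_scene_config(config)
  with_seed(config$seed, simulate_micrograph_impl(config))
}

simulate_micrograph_impl <- function(cfg) {
  W <- cfg$width; H <- cfg$height
  cells <- list()
  margin <- 4

  place_ok <- function(cx, cy, r, touching_id = NA) {
    if (cx - r < margin || cx + r > W - margin ||
        cy - r < margin || cy + r > H - margin) return(FALSE)
    for (cl in cells) {
      d <- sqrt((cx - cl$cx)^2 + (cy - cl$cy)^2)
      # non-touching cells stay at least 12 px apart: the 2-px blur halos
      # plus the HMM's run-length smoothing can bridge smaller gaps and
      # would turn nominally isolated cells into de-facto clumps
      gap <- if (!is.na(touching_id) && cl$id == touching_id) 1 else 12
      if (d < r + cl$rmax + gap) return(FALSE)
    }
    TRUE
  }

  next_id <- 1L
  add_cell <- function(cx, cy, r, eps, theta, type, partner = NA_integer_) {
    e <- ellipse_params(cx, cy, r, eps, theta)
    cl <- list(id = next_id, cx = cx, cy = cy, r = r, eps = eps,
               theta = theta, rmax = ellipse_axes(e)[["a"]],
               type = type, partner = partner,
               level = max(200, rnorm(1, cfg$rfp_level_mean, cfg$rfp_level_sd)),
               vacuole = runif(1) < cfg$vacuole_prob)
    cells[[next_id]] <<- cl
    next_id <<- next_id + 1L
    cl$id
  }

  # primary cells (lone or mother), optionally clumped
  if (cfg$n_cells > 0) {
    for (i in seq_len(cfg$n_cells)) {
      area <- runif(1, cfg$cell_area_range[1], cfg$cell_area_range[2])
      r <- sqrt(area / pi)
      eps <- runif(1, 0, 0.25)
      theta <- runif(1, 0, pi)
      clumped <- length(cells) > 0 && runif(1) < cfg$clump_fraction
      placed <- FALSE
      for (try in 1:300) {
        if (clumped) {
          anchor <- cells[[sample.int(length(cells), 1)]]
          phi <- runif(1, 0, 2 * pi)
          d <- anchor$rmax + r + 1
          cx <- anchor$cx + d * cos(phi); cy <- anchor$cy + d * sin(phi)
          ok <- place_ok(cx, cy, r, touching_id = anchor$id)
        } else {
          cx <- runif(1, r + margin, W - r - margin)
          cy <- runif(1, r + margin, H - r - margin)
          ok <- place_ok(cx, cy, r)
        }
        if (ok) { add_cell(cx, cy, r, eps, theta, "lone"); placed <- TRUE; break }
      }
      if (!placed) {
        bp_abort("could not place all cells; reduce `n_cells` or `clump_fraction`",
                 class = "budprofiler_placement_error")
      }
    }
  }

  # buds attached to a subset of primary cells
  n_primary <- length(cells)
  if (n_primary > 0 && cfg$bud_fraction > 0) {
    budded <- which(runif(n_primary) < cfg$bud_fraction)
    # spread bud sizes over the configured range so the stage axis is covered
    fracs <- if (length(budded))
      seq(cfg$bud_radius_range[1], cfg$bud_radius_range[2],
          length.out = length(budded))[order(runif(length(budded)))]
    else numeric(0)
    for (j in seq_along(budded)) {
      m_id <- budded[j]
      m <- cells[[m_id]]
      rb <- fracs[j] * m$r
      if (rb < 3.5) rb <- 3.5
      placed <- FALSE
      for (try in 1:60) {
        phi <- runif(1, 0, 2 * pi)
        d <- m$rmax + rb + 1
        cx <- m$cx + d * cos(phi); cy <- m$cy + d * sin(phi)
        if (place_ok(cx, cy, rb, touching_id = m$id)) {
          b_id <- add_cell(cx, cy, rb, 0, 0, "bud", partner = m$id)
          cells[[m_id]]$type <- "mother"
          cells[[m_id]]$partner <- b_id
          placed <- TRUE
          break
        }
      }
      # an unplaceable bud simply leaves the mother as a lone cell
    }
  }

  # rasterize full ellipses; the 1-px placement gap plus the dome intensity
  # profile keeps inter-cell boundary pixels dimmer than both interiors
  label <- matrix(0L, H, W)
  areas <- integer(length(cells))
  for (cl in cells) {
    e <- ellipse_params(cl$cx, cl$cy, cl$r, cl$eps, cl$theta)
    idx <- rasterize_ellipse(e, W, H, shrink = 0)
    idx <- idx[label[idx] == 0L]
    label[idx] <- cl$id
    areas[cl$id] <- length(idx)
  }

  # RFP: per-cell dome profile level * (1 - 0.35 * rho^2), rho = ellipse radius
  rfp <- matrix(0, H, W)
  for (cl in cells) {
    idx <- which(label == cl$id)
    if (!length(idx)) next
    ys <- ((idx - 1L) %% H) + 1L
    xs <- ((idx - 1L) %/% H) + 1L
    e <- ellipse_params(cl$cx, cl$cy, cl$r, cl$eps, cl$theta)
    rho2 <- pmax(0, (algebraic_error(e, xs, ys) + cl$r^2) / cl$r^2)
    val <- cl$level * (1 - 0.35 * pmin(rho2, 1))
    if (cl$vacuole && cl$r > 8) {
      vr <- 0.35 * cl$r
      vphi <- runif(1, 0, 2 * pi)
      vx <- cl$cx + 0.3 * cl$r * cos(vphi); vy <- cl$cy + 0.3 * cl$r * sin(vphi)
      inside_v <- (xs - vx)^2 + (ys - vy)^2 < vr^2
      val[inside_v] <- val[inside_v] * (1 - cfg$vacuole_depth)
    }
    rfp[idx] <- val
  }
  rfp <- gaussian_blur(rfp, sigma = 2)

  # ground-truth typing follows the reciprocal-extremum rule on the
  # generative geometry: independent cells that happen to touch form a
  # de-facto pair, exactly as the identification heuristic defines one
  nC <- length(cells)
  adj <- matrix(FALSE, nC, nC)
  if (nC > 1) {
    for (i in 1:(nC - 1)) for (j in (i + 1):nC) {
      d <- sqrt((cells[[i]]$cx - cells[[j]]$cx)^2 +
                  (cells[[i]]$cy - cells[[j]]$cy)^2)
      adj[i, j] <- adj[j, i] <- d <= cells[[i]]$rmax + cells[[j]]$rmax + 2.5
    }
  }
  type <- rep("lone", nC)
  partner <- rep(NA_integer_, nC)
  for (i in seq_len(nC)) {
    nb <- which(adj[i, ])
    if (!length(nb)) next
    b <- nb[which.min(areas[nb])]
    if (areas[b] >= areas[i]) next
    nb_b <- which(adj[b, ])
    if (nb_b[which.max(areas[nb_b])] != i) next
    if (any(areas[nb_b] < areas[b])) next
    type[i] <- "mother"; type[b] <- "bud"
    partner[i] <- b; partner[b] <- i
  }
  # neck coordinates per pair (midpoint of the touching gap)
  truth <- purrr::map_dfr(cells, function(cl) {
    i <- cl$id
    neck <- c(NA_real_, NA_real_)
    bud_area <- NA_real_
    if (!is.na(partner[i])) {
      p <- cells[[partner[i]]]
      w <- cl$rmax / (cl$rmax + p$rmax)
      neck <- c(cl$cx + w * (p$cx - cl$cx), cl$cy + w * (p$cy - cl$cy))
      bud_area <- if (type[i] == "bud") areas[i] else areas[partner[i]]
    }
    tibble::tibble(id = i, type = type[i], partner = partner[i],
                   cx = cl$cx, cy = cl$cy, r = cl$r, eps = cl$eps,
                   theta = cl$theta, level = cl$level,
                   area = areas[i], bud_area = bud_area,
                   neck_x = neck[1], neck_y = neck[2])
  })

  # GFP channel
  gfp <- render_gfp(cfg, cells, label, truth, H, W)

  # artifacts (rendered into RFP so the identification stages see them)
  artifact_mask <- matrix(FALSE, H, W)
  if (cfg$n_artifacts > 0 && length(cfg$artifact_kinds)) {
    for (k in seq_len(cfg$n_artifacts)) {
      kind <- sample(cfg$artifact_kinds, 1)
      am <- render_artifact(kind, rfp, label, W, H, cfg)
      rfp <- am$rfp
      artifact_mask <- artifact_mask | am$mask
    }
  }

  rfp <- rfp + matrix(rnorm(H * W, cfg$noise_mean, cfg$noise_sd), H, W)
  gfp <- gfp + matrix(rnorm(H * W, cfg$noise_mean, cfg$noise_sd), H, W)
  clip12 <- function(m) pmin(pmax(m, 0), 4095)

  list(
    micrograph = list(rfp = clip12(rfp), gfp = clip12(gfp)),
    truth = list(cells = truth, label = label, artifact_mask = artifact_mask)
  )
}

render_gfp <- function(cfg, cells, label, truth, H, W) {
  gfp <- matrix(0, H, W)
  if (!length(cells)) return(gfp)
  pattern_of <- function(cl) {
    if (cfg$gfp_pattern != "stage_switching") return(cfg$gfp_pattern)
    ba <- truth$bud_area[truth$id == cl$id]
    if (is.na(ba)) return("uniform")
    thr <- quantile(truth$bud_area[truth$type == "bud"],
                    cfg$stage_switch_quantile, na.rm = TRUE)
    if (ba < thr) "nuclear" else "uniform"
  }
  for (cl in cells) {
    idx <- which(label == cl$id)
    if (!length(idx)) next
    ys <- ((idx - 1L) %% H) + 1L
    xs <- ((idx - 1L) %/% H) + 1L
    base <- rep(cfg$gfp_base, length(idx))
    pat <- pattern_of(cl)
    amp <- cfg$gfp_amplitude
    add <- switch(pat,
      uniform = rep(amp * 0.5, length(idx)),
      nuclear = {
        nr <- 0.3 * cl$r
        off <- 0.2 * cl$r
        nx <- cl$cx + off; ny <- cl$cy
        amp * exp(-((xs - nx)^2 + (ys - ny)^2) / (2 * (nr / 1.5)^2))
      },
      peripheral = {
        e <- ellipse_params(cl$cx, cl$cy, cl$r, cl$eps, cl$theta)
        rho <- sqrt(pmax(0, (algebraic_error(e, xs, ys) + cl$r^2) / cl$r^2))
        amp * exp(-((1 - rho) * cl$r)^2 / (2 * 1.5^2))
      },
      bud_neck = {
        nx <- truth$neck_x[truth$id == cl$id]
        ny <- truth$neck_y[truth$id == cl$id]
        if (is.na(nx)) rep(amp * 0.15, length(idx)) else
          amp * exp(-((xs - nx)^2 + (ys - ny)^2) / (2 * 2.5^2))
      },
      punctate = {
        npts <- max(1L, round(length(idx) / 250))
        pk <- sample(seq_along(idx), npts)
        v <- numeric(length(idx))
        for (p in pk) {
          v <- v + amp * exp(-((xs - xs[p])^2 + (ys - ys[p])^2) / (2 * 1.8^2))
        }
        v
      },
      rep(amp * 0.5, length(idx))
    )
    gfp[idx] <- base + add
  }
  gaussian_blur(gfp, sigma = 1)
}

render_artifact <- function(kind, rfp, label, W, H, cfg) {
  mask <- matrix(FALSE, H, W)
  free <- function(cx, cy, r) {
    xs <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
    ys <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
    all(label[ys, xs] == 0L)
  }
  if (kind == "edge_noise") {
    corner <- sample(1:4, 1)
    cx <- if (corner %in% c(1, 3)) 6 else W - 5
    cy <- if (corner %in% c(1, 2)) 6 else H - 5
    xs <- max(1, cx - 8):min(W, cx + 8)
    ys <- max(1, cy - 8):min(H, cy + 8)
    g <- expand.grid(y = ys, x = xs)
    keep <- (g$x - cx)^2 + (g$y - cy)^2 < 64 & runif(nrow(g)) < 0.7
    idx <- (g$x[keep] - 1L) * H + g$y[keep]
    idx <- idx[label[idx] == 0L]
    rfp[idx] <- rfp[idx] + runif(length(idx), 0.5, 1.5) * cfg$rfp_level_mean
    mask[idx] <- TRUE
  } else if (kind %in% c("ruptured", "dim")) {
    for (try in 1:100) {
      r <- runif(1, 8, 14)
      cx <- runif(1, r + 2, W - r - 2); cy <- runif(1, r + 2, H - r - 2)
      if (free(cx, cy, r + 4)) break
    }
    e <- ellipse_params(cx, cy, r)
    idx <- rasterize_ellipse(e, W, H)
    idx <- idx[label[idx] == 0L]
    if (kind == "ruptured") {
      ys <- ((idx - 1L) %% H) + 1L; xs <- ((idx - 1L) %/% H) + 1L
      rho2 <- ((xs - cx)^2 + (ys - cy)^2) / r^2
      ring <- rho2 > 0.55
      # keep only a partial arc: a ruptured envelope
      ang <- atan2(ys - cy, xs - cx)
      ring <- ring & (ang > -2.2)
      idx <- idx[ring]
      rfp[idx] <- rfp[idx] + 0.8 * cfg$rfp_level_mean
    } else {
      rfp[idx] <- rfp[idx] + 0.12 * cfg$rfp_level_mean
    }
    mask[idx] <- TRUE
  } else if (kind == "defective_pixel") {
    idx <- sample.int(W * H, 1)
    rfp[idx] <- 4095
    mask[idx] <- TRUE
  }
  list(rfp = rfp, mask = mask)
}
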