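#' Pipeline configuration
#'
#' Validated container for every stage parameter. Unknown keys are rejected
#' by name; the configuration round-trips through YAML/JSON and its hash is
#' stamped into every output table.
#'
#' @param scene A [scene_config()] (or list of them, one per image) for
#'   simulated runs; `NULL` when reading TIFF inputs via `image_paths`.
#' @param image_paths Character vector of micrograph path prefixes
#'   (see [read_micrograph_tiff()]); ignored when `scene` is given.
#' @param n_images Number of scenes to simulate from `scene` (seeds derived
#'   from `seed`).
#' @param contour_thickness Contour thickness, px.
#' @param sigma Robust-regression residual scale, px (half the contour
#'   thickness by default).
#' @param ratio_min Ellipse axis-ratio lower bound.
#' @param min_area,min_axis Artifact pre-filter: minimum shape area (px) and
#'   minimum moment-fit minor semi-axis (px).
#' @param n_bins Confidence-model size bins.
#' @param stage_exponent Bud-area exponent of the stage transform.
#' @param bandwidth LOESS kernel bandwidth in stage units.
#' @param n_keypoints Stage keypoints per time series.
#' @param metric Clustering metric (`"ml"`, `"euclidean"`, `"correlation"`).
#' @param n_perm Permutations for the enrichment null.
#' @param seed Integer master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = scene_config(), image_paths = NULL,
                            n_images = 4, contour_thickness = 5, sigma = 2.5,
                            ratio_min = 0.5, min_area = 50, min_axis = 1.5,
                            n_bins = 7, stage_exponent = 1.5,
                            bandwidth = 1700, n_keypoints = 10,
                            metric = "ml", n_perm = 200, seed = 1L) {
  cfg <- list(scene = scene, image_paths = image_paths,
              n_images = as.integer(n_images),
              contour_thickness = contour_thickness, sigma = sigma,
              ratio_min = ratio_min, min_area = min_area, min_axis = min_axis,
              n_bins = as.integer(n_bins), stage_exponent = stage_exponent,
              bandwidth = bandwidth, n_keypoints = as.integer(n_keypoints),
              metric = metric, n_perm = as.integer(n_perm),
              seed = as.integer(seed), schema = "budprofiler-config-1")
  structure(cfg, class = "pipeline_config")
}

#' Validate a raw configuration list against the schema
#'
#' @param x A named list (e.g. parsed from YAML).
#' @return A `pipeline_config`; unknown keys raise an error naming the key.
#' @export
as_pipeline_config <- function(x) {
  if (inherits(x, "pipeline_config")) return(x)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(x), c(known, "schema"))
  if (length(extra)) {
    bp_abort(sprintf("unknown configuration key(s): %s",
                     paste(extra, collapse = ", ")),
             class = "budprofiler_config_error")
  }
  if (!is.null(x$scene) && !inherits(x$scene, "scene_config")) {
    x$scene <- do.call(scene_config, x$scene)
  }
  do.call(pipeline_config, x[setdiff(names(x), "schema")])
}

config_hash <- function(cfg) substr(rlang::hash(unclass(cfg)), 1, 12)

#' Identify cells in one two-channel micrograph
#'
#' Runs the identification stages on a single image: P2DHMM segmentation,
#' edge-distance map, per-clump robust ellipse regression, watershed basin
#' assembly, mother/bud/lone typing, moment fits and quality measures.
#'
#' @param micrograph List with `rfp` and `gfp` matrices.
#' @param config A [pipeline_config()].
#' @param image_id Identifier stamped into the cell table.
#' @return List with `cells` (tibble: id, clump, type, partner, area, cx,
#'   cy, neck, bud area, quality measures, artifact routing), `label` (shape
#'   id matrix), `segmentation`, `edge_map`, `ellipses`.
#' @export
process_micrograph <- function(micrograph, config = pipeline_config(),
                               image_id = "img") {
  rfp <- micrograph$rfp
  seg <- segment_foreground(rfp)
  em <- edge_distance_map(seg)
  fg <- seg$posterior >= 0.5
  bg_mask <- !fg
  contours <- extract_contour_pixels(em, thickness = config$contour_thickness,
                                     foreground = fg)
  # per-clump ellipse fitting
  ellipses <- list()
  if (nrow(contours)) {
    for (cl in sort(unique(contours$clump))) {
      sub <- contours[contours$clump == cl, , drop = FALSE]
      fit <- fit_ellipses_robust(sub, seed = derive_seed(config$seed, cl),
                                 sigma = config$sigma,
                                 thickness = config$contour_thickness,
                                 ratio_min = config$ratio_min,
                                 background_mask = bg_mask)
      if (nrow(fit)) {
        fit$clump <- cl
        ellipses[[length(ellipses) + 1L]] <- fit
      }
    }
  }
  ellipses <- if (length(ellipses)) dplyr::bind_rows(ellipses) else
    tibble::tibble(cx = numeric(0), cy = numeric(0), r = numeric(0),
                   eps = numeric(0), theta = numeric(0), clump = integer(0))
  label <- matrix(0L, nrow(rfp), ncol(rfp))
  if (any(fg) && nrow(ellipses)) {
    basins <- watershed_basins(rfp, fg)
    clump_lab <- label_connected(fg)
    # assemble shapes clump by clump so basins in clumps without an
    # acceptable ellipse stay in the artifact pool
    for (cl in sort(unique(ellipses$clump))) {
      erows <- which(ellipses$clump == cl)
      bc <- basins
      bc[clump_lab != cl] <- 0L
      if (!any(bc > 0L)) next
      asm <- assemble_shapes(bc, ellipses[erows, , drop = FALSE], rfp,
                             ratio_min = config$ratio_min)
      sel <- asm$label > 0L
      label[sel] <- erows[asm$label[sel]]
    }
  }
  typed <- assign_cell_types(label)
  cells <- compute_shape_qualities(typed, label, em, rfp, bg_mask, config)
  cells$image <- image_id
  if (nrow(cells) && nrow(ellipses)) {
    cells$clump <- ellipses$clump[cells$id]
  } else {
    cells$clump <- NA_integer_
  }
  list(cells = cells, label = label, segmentation = seg, edge_map = em,
       ellipses = ellipses)
}

# Moment fits, artifact pre-filter and quality measures for typed shapes.
compute_shape_qualities <- function(typed, label, em, rfp, bg_mask, config) {
  if (!nrow(typed)) {
    typed$artifact <- logical(0)
    typed$q_density <- typed$q_perimeter <- typed$q_circular <-
      typed$mean_rfp <- numeric(0)
    return(typed)
  }
  nr <- nrow(label)
  qs <- purrr::map_dfr(seq_len(nrow(typed)), function(i) {
    idx <- which(label == typed$id[i])
    ys <- ((idx - 1L) %% nr) + 1L
    xs <- ((idx - 1L) %/% nr) + 1L
    fit <- moment_ellipse_fit(xs, ys)
    artifact <- fit$artifact || fit$n < config$min_area ||
      (is.finite(fit$b) && fit$b < config$min_axis)
    if (artifact) {
      return(tibble::tibble(artifact = TRUE, q_density = NA_real_,
                            q_perimeter = NA_real_, q_circular = NA_real_,
                            mean_rfp = mean(rfp[idx])))
    }
    q <- quality_vector(xs, ys, fit, em$distance[idx], rfp[idx], bg_mask)
    tibble::tibble(artifact = FALSE, q_density = q[["q_density"]],
                   q_perimeter = q[["q_perimeter"]],
                   q_circular = q[["q_circular"]],
                   mean_rfp = q[["mean_rfp"]])
  })
  dplyr::bind_cols(typed, qs)
}

#' Run the full pipeline on simulated scenes
#'
#' Simulates (or reads) a set of two-channel micrographs — one GFP-tagged
#' protein per image — identifies cells, fits the confidence and RFP-size
#' models across the collection, computes the six expression features per
#' cell, builds confidence-weighted time profiles per protein, clusters the
#' profiles and scores annotation enrichment over the hierarchy. All tables
#' are written under `out_dir` with the config hash in their metadata and a
#' provenance log.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param patterns Optional character vector recycled over images giving
#'   each simulated protein's GFP pattern (overrides the scene's).
#' @return Invisibly, a list with `cells`, `features`, `profiles` (list of
#'   `time_profile`), `dendrogram`, `enrichment`, `detection`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         patterns = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  log_lines <- c(sprintf("budprofiler run, config %s, seed %d", hash,
                         config$seed))
  scenes <- NULL
  if (!is.null(config$scene)) {
    scenes <- lapply(seq_len(config$n_images), function(i) {
      sc <- config$scene
      sc$seed <- as.integer(derive_seed(config$seed, 1000 + i) %% 2147483646)
      if (!is.null(patterns)) {
        sc$gfp_pattern <- patterns[((i - 1) %% length(patterns)) + 1]
      }
      validate_scene_config(sc)
      simulate_micrograph(sc)
    })
    images <- lapply(scenes, `[[`, "micrograph")
    ids <- sprintf("sim%02d", seq_along(images))
  } else {
    images <- lapply(config$image_paths, read_micrograph_tiff)
    ids <- basename(config$image_paths)
  }
  # background correction across the collection (RFP channel)
  if (length(images) > 1) {
    bg <- compute_background_image(lapply(images, `[[`, "rfp"))
    # the mean image includes the cells themselves at desk-scale n; subtract
    # the collection floor instead of the full mean to keep signal
    floor_bg <- matrix(quantile(bg$background, 0.05), nrow(bg$background),
                       ncol(bg$background))
    images <- lapply(images, function(im) {
      im$rfp <- subtract_background(im$rfp, floor_bg)
      im$gfp <- subtract_background(im$gfp, floor_bg)
      im
    })
  }
  runs <- purrr::map2(images, seq_along(images), function(im, i) {
    process_micrograph(im, config, image_id = ids[i])
  })
  cells <- dplyr::bind_rows(lapply(runs, `[[`, "cells"))
  log_lines <- c(log_lines, sprintf(
    "identified %d objects (%d mothers, %d buds, %d lone, %d artifacts)",
    nrow(cells), sum(cells$type == "mother" & !cells$artifact),
    sum(cells$type == "bud" & !cells$artifact),
    sum(cells$type == "lone" & !cells$artifact), sum(cells$artifact)))

  detection <- NULL
  training <- NULL
  if (!is.null(scenes)) {
    detection <- purrr::map2_dfr(runs, scenes, function(r, s) {
      det <- r$cells[!r$cells$artifact, c("cx", "cy", "area")]
      evaluate_detection(det, s$truth)
    })
    # objects matched to ground-truth cells act as the labeled training set
    training <- purrr::map2_dfr(runs, scenes, function(r, s) {
      ok <- r$cells[!r$cells$artifact, , drop = FALSE]
      if (!nrow(ok)) return(NULL)
      d <- sqrt(outer(ok$cx, s$truth$cells$cx, "-")^2 +
                  outer(ok$cy, s$truth$cells$cy, "-")^2)
      ok[apply(d, 1, min) <= 10, , drop = FALSE]
    })
  }
  good <- cells[!cells$artifact, , drop = FALSE]
  if (is.null(training) || nrow(training) < 20) training <- good
  model <- fit_confidence_model(
    tibble::tibble(q_density = training$q_density,
                   q_perimeter = training$q_perimeter,
                   q_circular = training$q_circular,
                   mean_rfp = training$mean_rfp, size = training$area),
    all_objects = good, n_bins = min(config$n_bins,
                                     max(2, nrow(training) %/% 10)))
  model <- estimate_mixing(
    tibble::tibble(q_density = good$q_density, q_perimeter = good$q_perimeter,
                   q_circular = good$q_circular, mean_rfp = good$mean_rfp,
                   size = good$area), model)
  log_lines <- c(log_lines, sprintf("mixing parameter rho = %.3f", model$rho))
  cells$cell_p <- NA_real_
  for (i in which(!cells$artifact)) {
    q <- c(q_density = cells$q_density[i], q_perimeter = cells$q_perimeter[i],
           q_circular = cells$q_circular[i], mean_rfp = cells$mean_rfp[i])
    cells$cell_p[i] <- cell_posterior(q, cells$area[i], model)
  }
  # RFP size model and per-cell features
  rfp_model <- fit_rfp_size_model(
    tibble::tibble(area = good$area, mean_rfp = good$mean_rfp),
    min_cells = min(100, nrow(good)))
  features <- compute_features(runs, images, cells, rfp_model)
  # per-protein time profiles from mother-bud pairs
  profiles <- list()
  all_stage <- c()
  series_by_img <- list()
  for (i in seq_along(runs)) {
    ser <- pair_series(cells[cells$image == ids[i], , drop = FALSE],
                       features, config)
    series_by_img[[ids[i]]] <- ser
    if (!is.null(ser)) all_stage <- c(all_stage, ser$stage)
  }
  keypoints <- if (length(all_stage) >= 2) {
    stage_keypoints(all_stage, config$n_keypoints)
  } else NULL
  for (id in names(series_by_img)) {
    ser <- series_by_img[[id]]
    if (is.null(ser) || nrow(ser) < 2) next
    profiles[[id]] <- loess_profile(ser, keypoints, config$bandwidth)
  }
  dend <- NULL
  enrich <- NULL
  if (length(profiles) >= 2) {
    plist <- lapply(names(profiles), function(id) {
      v <- profile_vector(profiles[[id]])
      vmean <- v$mean
      vvar <- v$variance
      vvar[!is.finite(vvar) | vvar <= 0] <- mean(vvar[is.finite(vvar) &
                                                        vvar > 0]) %||% 1
      vmean[!is.finite(vmean)] <- mean(vmean[is.finite(vmean)])
      cluster_profile(vmean, vvar, members = id)
    })
    dend <- agglomerate(plist, metric = config$metric)
    if (!is.null(scenes)) {
      ann <- tibble::tibble(
        protein = names(profiles),
        term = vapply(match(names(profiles), ids), function(i) {
          if (!is.null(patterns)) patterns[((i - 1) %% length(patterns)) + 1]
          else config$scene$gfp_pattern
        }, character(1)))
      if (length(unique(ann$term)) >= 2) {
        enrich <- s_statistic(dend, ann)
      }
    }
  }
  out <- list(cells = cells, features = features, profiles = profiles,
              dendrogram = dend, enrichment = enrich, detection = detection,
              confidence_model = model, rfp_model = rfp_model,
              config_hash = hash, log = log_lines)
  if (!is.null(out_dir)) write_run_outputs(out, out_dir, config)
  invisible(out)
}

# GFP/RFP features for every non-artifact cell.
compute_features <- function(runs, images, cells, rfp_model) {
  rows <- list()
  for (ri in seq_along(runs)) {
    r <- runs[[ri]]
    if (!nrow(r$cells)) next
    im <- images[[ri]]
    nr <- nrow(r$label)
    img_cells <- cells[cells$image == r$cells$image[1] & !cells$artifact, ,
                       drop = FALSE]
    for (i in seq_len(nrow(img_cells))) {
      idx <- which(r$label == img_cells$id[i])
      ys <- ((idx - 1L) %% nr) + 1L
      xs <- ((idx - 1L) %/% nr) + 1L
      gfp <- pmax(im$gfp[idx], 0)
      rfp <- pmax(im$rfp[idx], 0)
      if (sum(gfp) <= 0 || sum(rfp) <= 0) next
      neck <- if (!is.na(img_cells$neck_x[i])) {
        c(img_cells$neck_x[i], img_cells$neck_y[i])
      } else NULL
      md <- morphological_distances(xs, ys, gfp, rfp, r$edge_map$distance[idx],
                                    neck = neck)
      ir <- intensity_ratio(sum(gfp), sum(rfp), length(idx), rfp_model)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        image = img_cells$image[i], id = img_cells$id[i],
        type = img_cells$type[i], bud_area = img_cells$bud_area[i],
        cell_p = img_cells$cell_p[i], intensity = ir,
        d_between = md[["d_between"]], d_mass_center = md[["d_mass_center"]],
        d_center = md[["d_center"]], d_periphery = md[["d_periphery"]],
        d_neck = md[["d_neck"]])
    }
  }
  if (!length(rows)) return(NULL)
  dplyr::bind_rows(rows)
}

feature_cols <- c("intensity", "d_between", "d_mass_center", "d_center",
                  "d_periphery", "d_neck")

# Mother-bud pair series for one image: stage, pair weight, 12 features.
pair_series <- function(img_cells, features, config) {
  if (is.null(features)) return(NULL)
  mothers <- img_cells[img_cells$type == "mother" & !img_cells$artifact, ,
                       drop = FALSE]
  if (!nrow(mothers)) return(NULL)
  rows <- list()
  for (i in seq_len(nrow(mothers))) {
    m <- mothers[i, ]
    fm <- features[features$image == m$image & features$id == m$id, ]
    fb <- features[features$image == m$image & features$id == m$partner, ]
    if (!nrow(fm) || !nrow(fb)) next
    bp <- img_cells$cell_p[img_cells$id == m$partner]
    w <- pair_probability(m$cell_p, bp)
    row <- tibble::tibble(stage = cell_stage(m$bud_area,
                                             config$stage_exponent),
                          weight = w)
    for (f in feature_cols) {
      row[[paste0("bud_", f)]] <- fb[[f]]
      row[[paste0("mother_", f)]] <- fm[[f]]
    }
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) return(NULL)
  out <- dplyr::bind_rows(rows)
  # neck feature can be missing only for lone cells; pairs always have one,
  # but guard against degenerate necks
  out[complete.cases(out[, c("stage", "weight")]), , drop = FALSE]
}

write_run_outputs <- function(out, out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(sprintf("config_hash %s", out$config_hash),
            sprintf("seed %d", config$seed))
  write_table_tsv(out$cells, file.path(out_dir, "cells.tsv"), meta)
  if (!is.null(out$features)) {
    write_table_tsv(out$features, file.path(out_dir, "features.tsv"), meta)
  }
  if (length(out$profiles)) {
    pm <- do.call(rbind, lapply(out$profiles, function(p) profile_vector(p)$mean))
    pv <- do.call(rbind, lapply(out$profiles, function(p) profile_vector(p)$variance))
    ptab <- tibble::tibble(protein = names(out$profiles))
    ptab <- dplyr::bind_cols(ptab, tibble::as_tibble(pm),
                             tibble::as_tibble(setNames(
                               as.data.frame(pv),
                               paste0("var_", colnames(pv)))))
    write_table_tsv(ptab, file.path(out_dir, "profiles.tsv"), meta)
    if (!is.null(out$dendrogram)) {
      write_treeview(out$dendrogram, pm, file.path(out_dir, "clusters"))
      jsonlite::write_json(
        list(merge = out$dendrogram$merge, score = out$dendrogram$score,
             labels = out$dendrogram$labels),
        file.path(out_dir, "dendrogram.json"), digits = NA)
    }
  }
  if (!is.null(out$enrichment) && nrow(out$enrichment$per_term)) {
    write_table_tsv(out$enrichment$per_term,
                    file.path(out_dir, "enrichment.tsv"), meta)
  }
  if (!is.null(out$detection)) {
    write_table_tsv(out$detection, file.path(out_dir, "detection.tsv"), meta)
  }
  write_confidence_model(out$confidence_model,
                         file.path(out_dir, "confidence_model.json"))
  writeLines(out$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
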