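#' Watershed catchment basins by steepest ascent
#'
#' Every foreground pixel is assigned to the local intensity maximum it
#' reaches by repeatedly stepping to its brightest 8-neighbor (steepest
#' ascent); the set of pixels draining to one maximum is a catchment basin,
#' equivalently the set reachable from the maximum by monotonically
#' decreasing intensities. Plateaus are merged by resolving ties toward the
#' earliest pixel in column-major order, so each basin holds exactly one
#' (plateau-merged) maximum.
#'
#' @param rfp Intensity matrix.
#' @param foreground Logical mask of foreground pixels.
#' @return Integer matrix of basin labels (0 = background), labels numbered
#'   from 1 in order of their maxima.
#' @export
watershed_basins <- function(rfp, foreground) {
  if (!any(foreground)) bp_abort("foreground mask is empty")
  nr <- nrow(rfp); nc <- ncol(rfp)
  n <- nr * nc
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  # value used for comparisons: foreground intensity, background at -Inf
  v <- ifelse(foreground, rfp, -Inf)
  # tie-break on plateaus: add a tiny index-based perturbation so steepest
  # ascent is deterministic and plateaus drain to one representative
  vt <- v
  vt[foreground] <- vt[foreground] - seq_len(n)[foreground] * 1e-9
  parent <- seq_len(n)
  best_val <- vt
  for (k in seq_len(nrow(offs))) {
    sv <- shift_matrix(vt, offs$dy[k], offs$dx[k], fill = -Inf)
    sidx <- shift_matrix(matrix(seq_len(n), nr, nc),
                         offs$dy[k], offs$dx[k], fill = 0)
    better <- foreground & (sv > best_val)
    parent[which(better)] <- sidx[which(better)]
    best_val <- pmax(best_val, ifelse(foreground, sv, -Inf))
  }
  # pointer jumping to the root (the local maximum)
  repeat {
    gp <- parent[parent]
    if (identical(gp, parent)) break
    parent <- gp
  }
  lab <- matrix(0L, nr, nc)
  roots <- sort(unique(parent[foreground]))
  lab[foreground] <- match(parent[foreground], roots)
  lab
}

#' Assemble cell shapes by assigning watershed basins to ellipses
#'
#' Each basin is assigned to the ellipse whose algebraic error at the
#' basin's maximum-intensity pixel is smallest in absolute value; the union
#' of basins assigned to one ellipse forms that cell's shape.
#'
#' @param basins Integer basin label matrix from [watershed_basins()].
#' @param ellipses A tibble of ellipses (columns `cx`, `cy`, `r`, `eps`,
#'   `theta`) as returned by [fit_ellipses_robust()].
#' @param rfp Intensity matrix used to locate each basin's maximum pixel.
#' @param ratio_min Axis-ratio bound used to rebuild ellipse objects.
#' @return A list with `label`: integer matrix of shape ids (row index into
#'   `ellipses`; 0 = background), and `unassigned`: logical matrix of basin
#'   pixels with no ellipse available (empty ellipse table).
#' @export
assemble_shapes <- function(basins, ellipses, rfp, ratio_min = 0.5) {
  nb <- max(basins)
  out_label <- matrix(0L, nrow(basins), ncol(basins))
  unassigned <- matrix(FALSE, nrow(basins), ncol(basins))
  if (nb == 0L) return(list(label = out_label, unassigned = unassigned))
  if (nrow(ellipses) == 0L) {
    unassigned[basins > 0L] <- TRUE
    return(list(label = out_label, unassigned = unassigned))
  }
  es <- purrr::pmap(ellipses[, c("cx", "cy", "r", "eps", "theta")],
                    ellipse_params, ratio_min = ratio_min)
  nr <- nrow(basins)
  for (b in seq_len(nb)) {
    idx <- which(basins == b)
    if (!length(idx)) next
    peak <- idx[which.max(rfp[idx])]
    py <- ((peak - 1L) %% nr) + 1L
    px <- ((peak - 1L) %/% nr) + 1L
    errs <- vapply(es, function(e) abs(algebraic_error(e, px, py)),
                   numeric(1))
    out_label[idx] <- which.min(errs)
  }
  list(label = out_label, unassigned = unassigned)
}

# Pairs of shape labels sharing >= 1 pair of 8-connected cross-boundary
# pixels, plus the boundary pixels between each pair.
shape_adjacency <- function(label) {
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  pairs <- list()
  for (k in seq_len(nrow(offs))) {
    s <- shift_matrix(label, offs$dy[k], offs$dx[k], fill = 0L)
    sel <- label > 0L & s > 0L & s != label
    if (!any(sel)) next
    pairs[[length(pairs) + 1L]] <- tibble::tibble(
      i = pmin(label[sel], s[sel]), j = pmax(label[sel], s[sel]),
      pixel = which(sel))
  }
  if (!length(pairs)) {
    return(tibble::tibble(i = integer(0), j = integer(0), pixel = integer(0)))
  }
  dplyr::distinct(dplyr::bind_rows(pairs))
}

#' Assign mother/bud/lone types to cell shapes
#'
#' Mother-bud pairs are reciprocally the largest and smallest adjacent
#' cells: B is M's smallest neighbor, M is B's largest neighbor, and B has
#' no neighbor smaller than itself. All other cells are lone. The bud neck
#' is the set of boundary pixels separating the paired shapes; its position
#' is their mean coordinate.
#'
#' @param label Shape label matrix from [assemble_shapes()].
#' @param residuals Optional named numeric vector of per-shape ellipse-fit
#'   residuals used to break exact size ties (smaller residual wins), then
#'   lower shape id.
#' @return A tibble with one row per shape: `id`, `area`, `cx`, `cy`, `type`
#'   (`"mother"`, `"bud"`, `"lone"`), `partner`, `neck_x`, `neck_y`,
#'   `bud_area` (the pair's bud area, for both members), `tie_flagged`.
#' @export
assign_cell_types <- function(label, residuals = NULL) {
  ids <- sort(unique(label[label > 0L]))
  if (!length(ids)) {
    return(tibble::tibble(id = integer(0), area = integer(0), cx = numeric(0),
                          cy = numeric(0), type = character(0),
                          partner = integer(0), neck_x = numeric(0),
                          neck_y = numeric(0), bud_area = numeric(0),
                          tie_flagged = logical(0)))
  }
  nr <- nrow(label)
  areas <- tabulate(label[label > 0L], nbins = max(ids))
  cent <- lapply(ids, function(i) {
    idx <- which(label == i)
    c(cx = mean(((idx - 1L) %/% nr) + 1L), cy = mean(((idx - 1L) %% nr) + 1L))
  })
  adj <- shape_adjacency(label)
  # sort key: area, residual tie-break, id
  res <- rep(0, max(ids))
  if (!is.null(residuals)) res[as.integer(names(residuals))] <- residuals
  tie_flag <- rep(FALSE, length(ids))
  size_rank <- function(i, j) {
    # TRUE if shape i "smaller" than j under the deterministic tie-break
    if (areas[i] != areas[j]) return(areas[i] < areas[j])
    tie_flag[match(c(i, j), ids)] <<- TRUE
    if (res[i] != res[j]) return(res[i] < res[j])
    i < j
  }
  neighbors <- function(i) {
    unique(c(adj$j[adj$i == i], adj$i[adj$j == i]))
  }
  extreme_neighbor <- function(i, smallest) {
    nb <- neighbors(i)
    if (!length(nb)) return(NA_integer_)
    best <- nb[1]
    for (k in nb[-1]) {
      if (smallest == size_rank(k, best)) best <- k
    }
    best
  }
  type <- setNames(rep("lone", length(ids)), ids)
  partner <- setNames(rep(NA_integer_, length(ids)), ids)
  for (i in ids) {
    b <- extreme_neighbor(i, smallest = TRUE)   # i's smallest neighbor
    if (is.na(b)) next
    if (!size_rank(b, i)) next                   # bud must be smaller
    m_of_b <- extreme_neighbor(b, smallest = FALSE)
    if (!identical(m_of_b, i)) next              # reciprocity
    # bud may not have any smaller neighboring object
    nb_b <- neighbors(b)
    if (any(vapply(nb_b, function(k) size_rank(k, b), logical(1)))) next
    type[as.character(i)] <- "mother"
    type[as.character(b)] <- "bud"
    partner[as.character(i)] <- b
    partner[as.character(b)] <- i
  }
  # neck contours for pairs
  neck <- matrix(NA_real_, length(ids), 2)
  for (k in seq_along(ids)) {
    i <- ids[k]
    p <- partner[[as.character(i)]]
    if (is.na(p)) next
    sel <- adj[(adj$i == min(i, p) & adj$j == max(i, p)), ]
    if (!nrow(sel)) next
    ys <- ((sel$pixel - 1L) %% nr) + 1L
    xs <- ((sel$pixel - 1L) %/% nr) + 1L
    neck[k, ] <- c(mean(xs), mean(ys))
  }
  bud_area <- vapply(seq_along(ids), function(k) {
    i <- ids[k]
    p <- partner[[as.character(i)]]
    if (is.na(p)) return(NA_real_)
    if (type[[as.character(i)]] == "bud") areas[i] else areas[p]
  }, numeric(1))
  tibble::tibble(
    id = ids, area = areas[ids],
    cx = vapply(cent, `[[`, numeric(1), "cx"),
    cy = vapply(cent, `[[`, numeric(1), "cy"),
    type = unname(type), partner = unname(partner),
    neck_x = neck[, 1], neck_y = neck[, 2],
    bud_area = bud_area, tie_flagged = tie_flag)
}
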