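#' Evaluate cell identification against ground truth
#'
#' Matches each ground-truth cell to the nearest detected object center
#' within `radius` pixels, greedily by increasing center distance with a
#' one-to-one constraint, and summarizes recall, center-error statistics,
#' the Pearson correlation of matched areas, and the fraction of detections
#' that fall on artifact objects.
#'
#' @param detected A data frame with columns `cx`, `cy` and optionally
#'   `area` for detected objects.
#' @param truth The `truth` element of [simulate_micrograph()] output, or any
#'   list with a `cells` tibble (columns `cx`, `cy`, `area`) and optionally
#'   an `artifact_mask` matrix.
#' @param radius Match radius in pixels (default 10).
#' @return A one-row tibble: `recall`, `n_truth`, `n_detected`, `n_matched`,
#'   `mean_center_distance`, `area_correlation`, `false_positive_rate`
#'   (fraction of unmatched detections centered on an artifact pixel, NA
#'   without an artifact mask).
#' @export
evaluate_detection <- function(detected, truth, radius = 10) {
  if (radius <= 0) bp_abort("`radius` must be > 0")
  tcells <- truth$cells
  if (is.null(tcells) || nrow(tcells) == 0) {
    warn("empty ground truth: recall undefined")
    return(tibble::tibble(recall = NA_real_, n_truth = 0L,
                          n_detected = nrow(detected), n_matched = 0L,
                          mean_center_distance = NA_real_,
                          area_correlation = NA_real_,
                          false_positive_rate = NA_real_))
  }
  nd <- nrow(detected); nt <- nrow(tcells)
  if (nd == 0) {
    return(tibble::tibble(recall = 0, n_truth = nt, n_detected = 0L,
                          n_matched = 0L, mean_center_distance = NA_real_,
                          area_correlation = NA_real_,
                          false_positive_rate = NA_real_))
  }
  dmat <- sqrt(outer(tcells$cy, detected$cy, "-")^2 +
                 outer(tcells$cx, detected$cx, "-")^2)
  # greedy one-to-one matching by increasing distance
  ord <- order(dmat)
  match_t <- rep(NA_integer_, nt)
  used_d <- rep(FALSE, nd)
  for (o in ord) {
    if (dmat[o] > radius) break
    ti <- ((o - 1L) %% nt) + 1L
    di <- ((o - 1L) %/% nt) + 1L
    if (is.na(match_t[ti]) && !used_d[di]) {
      match_t[ti] <- di
      used_d[di] <- TRUE
    }
  }
  matched <- which(!is.na(match_t))
  n_matched <- length(matched)
  mean_dist <- if (n_matched) {
    mean(dmat[cbind(matched, match_t[matched])])
  } else NA_real_
  area_cor <- if (n_matched >= 3 && "area" %in% names(detected) &&
                  "area" %in% names(tcells)) {
    ta <- tcells$area[matched]; da <- detected$area[match_t[matched]]
    if (sd(ta) > 0 && sd(da) > 0) cor(ta, da) else NA_real_
  } else NA_real_
  fpr <- NA_real_
  if (!is.null(truth$artifact_mask) && any(!used_d)) {
    am <- truth$artifact_mask
    un <- which(!used_d)
    on_artifact <- vapply(un, function(i) {
      y <- round(detected$cy[i]); x <- round(detected$cx[i])
      y >= 1 && y <= nrow(am) && x >= 1 && x <= ncol(am) && am[y, x]
    }, logical(1))
    fpr <- sum(on_artifact) / nd
  } else if (!is.null(truth$artifact_mask)) {
    fpr <- 0
  }
  tibble::tibble(recall = n_matched / nt, n_truth = nt, n_detected = nd,
                 n_matched = n_matched, mean_center_distance = mean_dist,
                 area_correlation = area_cor, false_positive_rate = fpr)
}
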