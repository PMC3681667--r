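#' Diagonal-Gaussian cluster profile
#'
#' A cluster of time profiles is summarized by member count `n`, a mean
#' vector and a diagonal variance vector; merging is moment matching of the
#' size-weighted pooled Gaussian.
#'
#' @param mean Mean vector.
#' @param variance Variance vector (same length); floored at `var_floor`.
#' @param n Member count (default 1).
#' @param members Member protein ids.
#' @param var_floor Variance floor (default 1e-9).
#' @return Object of class `cluster_profile`.
#' @export
cluster_profile <- function(mean, variance, n = 1, members = NULL,
                            var_floor = 1e-9) {
  if (length(mean) != length(variance)) {
    bp_abort("mean and variance dimension mismatch",
             class = "budprofiler_dimension_error")
  }
  structure(list(n = n, mean = as.numeric(mean),
                 variance = pmax(as.numeric(variance), var_floor),
                 members = members %||% character(0)),
            class = "cluster_profile")
}

#' Merge two cluster profiles (size-weighted pooled moments)
#'
#' The merged Gaussian matches the moments of the pooled membership: the
#' size-weighted mean, and the per-dimension pooled variance including the
#' between-means term. Associative over any merge order of the same total
#' membership.
#'
#' @param c1,c2 [cluster_profile()] objects of equal dimension.
#' @return The merged `cluster_profile` with `n = n1 + n2`.
#' @export
merge_profiles <- function(c1, c2) {
  if (length(c1$mean) != length(c2$mean)) {
    bp_abort("profile dimension mismatch", class = "budprofiler_dimension_error")
  }
  n <- c1$n + c2$n
  mu <- (c1$n * c1$mean + c2$n * c2$mean) / n
  ex2 <- (c1$n * (c1$variance + c1$mean^2) +
            c2$n * (c2$variance + c2$mean^2)) / n
  cluster_profile(mu, pmax(ex2 - mu^2, 0), n = n,
                  members = c(c1$members, c2$members))
}

#' Maximum-likelihood merge score
#'
#' Log-likelihood ratio of modeling two clusters as two diagonal-covariance
#' Gaussians versus the single merged Gaussian, via the log-determinants:
#' `(n/2) sum log var_merged - (n1/2) sum log var1 - (n2/2) sum log var2`.
#' Non-negative, 0 iff the components have identical mean and variance;
#' smaller is a better merge.
#'
#' @param c1,c2 [cluster_profile()] objects.
#' @param var_floor Variance floor applied before the logs.
#' @return Scalar merge score.
#' @export
ml_merge_score <- function(c1, c2, var_floor = 1e-9) {
  m <- merge_profiles(c1, c2)
  n <- c1$n + c2$n
  (n / 2) * sum(log(pmax(m$variance, var_floor))) -
    (c1$n / 2) * sum(log(pmax(c1$variance, var_floor))) -
    (c2$n / 2) * sum(log(pmax(c2$variance, var_floor)))
}

#' Agglomerative hierarchical clustering of time profiles
#'
#' With `metric = "ml"`, repeatedly merges the pair of clusters with the
#' smallest maximum-likelihood merge score until one cluster remains
#' (greedy; ties broken toward the lowest index pair). `"euclidean"` and
#' `"correlation"` provide the complete-linkage robustness checks behind
#' the same interface (via [stats::hclust()] on the mean vectors).
#'
#' @param profiles A list of [cluster_profile()] objects, or a profile table
#'   from [simulate_profile_collection()] (converted automatically).
#' @param metric `"ml"`, `"euclidean"` or `"correlation"`.
#' @return Object of class `profile_dendrogram`: `merge` (hclust-style merge
#'   matrix), `height` (per-merge score, shifted to be increasing for
#'   display when needed), `score` (raw per-merge score), `labels`,
#'   `members` (list of leaf index sets per internal node), `metric`.
#' @export
agglomerate <- function(profiles, metric = c("ml", "euclidean", "correlation")) {
  metric <- match.arg(metric)
  profiles <- as_profile_list(profiles)
  K <- length(profiles)
  if (K < 2) bp_abort("need at least 2 profiles")
  labels <- vapply(seq_len(K), function(i) {
    if (length(profiles[[i]]$members)) profiles[[i]]$members[1] else
      sprintf("P%04d", i)
  }, character(1))
  if (metric != "ml") {
    M <- do.call(rbind, lapply(profiles, `[[`, "mean"))
    d <- if (metric == "euclidean") dist(M) else
      stats::as.dist(1 - stats::cor(t(M)))
    hc <- hclust(d, method = "complete")
    merge <- hc$merge
    height <- hc$height
    score <- hc$height
  } else {
    clus <- profiles
    merge <- matrix(0L, K - 1, 2)
    score <- numeric(K - 1)
    # pairwise score cache (upper triangle)
    S <- matrix(Inf, K, K)
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      S[i, j] <- ml_merge_score(clus[[i]], clus[[j]])
    }
    codes <- -(seq_len(K))
    for (step in seq_len(K - 1)) {
      alive <- which(!is.na(codes))
      # lowest-index tie break: which.min on the row-major upper triangle
      best <- c(NA, NA); best_s <- Inf
      for (ii in seq_along(alive)) {
        i <- alive[ii]
        if (ii == length(alive)) break
        js <- alive[(ii + 1):length(alive)]
        svals <- S[i, js]
        m <- min(svals)
        # strict < keeps the earliest (i, j) pair on ties; which.min picks
        # the lowest j within the row
        if (m < best_s) {
          best_s <- m
          best <- c(i, js[which.min(svals)])
        }
      }
      i <- best[1]; j <- best[2]
      merge[step, ] <- c(codes[i], codes[j])
      score[step] <- best_s
      clus[[i]] <- merge_profiles(clus[[i]], clus[[j]])
      codes[i] <- step
      codes[j] <- NA
      for (k in alive) {
        if (k == i || k == j) next
        lo <- min(i, k); hi <- max(i, k)
        S[lo, hi] <- ml_merge_score(clus[[i]], clus[[k]])
      }
      S[j, ] <- Inf; S[, j] <- Inf
    }
    height <- cummax(score) + seq_len(K - 1) * 1e-9
  }
  members <- vector("list", K - 1)
  for (s in seq_len(nrow(merge))) {
    kids <- merge[s, ]
    members[[s]] <- unlist(lapply(kids, function(k) {
      if (k < 0) -k else members[[k]]
    }))
  }
  structure(list(merge = merge, height = height, score = score,
                 labels = labels, members = members, metric = metric,
                 n_leaves = K),
            class = "profile_dendrogram")
}

as_profile_list <- function(profiles) {
  if (is.list(profiles) && length(profiles) &&
      inherits(profiles[[1]], "cluster_profile")) {
    return(profiles)
  }
  if (is.data.frame(profiles) && !is.null(profiles$profile)) {
    return(lapply(seq_len(nrow(profiles)), function(i) {
      cluster_profile(profiles$profile[i, ],
                      if (!is.null(profiles$variance))
                        profiles$variance[i, ] else rep(1, ncol(profiles$profile)),
                      members = profiles$protein[i])
    }))
  }
  bp_abort("cannot interpret `profiles`")
}

#' Convert a profile dendrogram to an hclust object
#'
#' @param x A [agglomerate()] result.
#' @return An object of class `hclust`.
#' @export
as_hclust <- function(x) {
  structure(list(merge = x$merge, height = x$height,
                 order = dendrogram_leaf_order(x),
                 labels = x$labels, method = x$metric,
                 call = match.call(), dist.method = x$metric),
            class = "hclust")
}

# display order: larger child first
dendrogram_leaf_order <- function(x) {
  size_of <- function(k) if (k < 0) 1L else length(x$members[[k]])
  walk <- function(k) {
    if (k < 0) return(-k)
    kids <- x$merge[k, ]
    kids <- kids[order(-vapply(kids, size_of, integer(1)))]
    c(walk(kids[1]), walk(kids[2]))
  }
  walk(nrow(x$merge))
}

#' Cut a profile dendrogram into k clusters
#'
#' @param x A [agglomerate()] result.
#' @param k Number of clusters.
#' @return Integer cluster labels per leaf.
#' @export
cut_dendrogram <- function(x, k) {
  unname(cutree(as_hclust(x), k = k))
}

#' @export
glance.profile_dendrogram <- function(x, ...) {
  tibble::tibble(n_leaves = x$n_leaves, metric = x$metric,
                 total_score = sum(x$score))
}

#' @export
tidy.profile_dendrogram <- function(x, ...) {
  tibble::tibble(step = seq_len(nrow(x$merge)),
                 left = x$merge[, 1], right = x$merge[, 2],
                 score = x$score,
                 size = vapply(x$members, length, integer(1)))
}

#' @export
autoplot.profile_dendrogram <- function(object, ...) {
  hc <- as_hclust(object)
  dd <- as.dendrogram(hc)
  # simple segment plot
  xy <- dendro_segments(dd)
  ggplot2::ggplot(xy) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = seq_along(hc$order),
                                labels = hc$labels[hc$order]) +
    ggplot2::labs(y = "merge score (monotonized)", x = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

dendro_segments <- function(dd) {
  segs <- list()
  pos <- new.env()
  counter <- new.env(); counter$i <- 0
  walk <- function(node) {
    if (is.leaf(node)) {
      counter$i <- counter$i + 1
      return(c(counter$i, 0))
    }
    l <- walk(node[[1]]); r <- walk(node[[2]])
    h <- attr(node, "height")
    segs[[length(segs) + 1]] <<- data.frame(
      x = c(l[1], l[1], r[1]), y = c(h, h, h),
      xend = c(r[1], l[1], r[1]), yend = c(h, l[2], r[2]))
    c((l[1] + r[1]) / 2, h)
  }
  walk(dd)
  do.call(rbind, segs)
}

#' Class profiles from exact localization label sets
#'
#' Proteins sharing an identical localization label set form a class; class
#' members are merged with [merge_profiles()] into one diagonal-Gaussian
#' class profile.
#'
#' @param profiles A list of [cluster_profile()] objects or a profile table.
#' @param label_sets A list (one element per profile) of character vectors
#'   of localization labels.
#' @return A named list of `cluster_profile` objects, one per distinct
#'   label set (name = sorted labels joined by `"+"`).
#' @export
class_profile <- function(profiles, label_sets) {
  profiles <- as_profile_list(profiles)
  if (!length(profiles)) bp_abort("empty profile collection")
  if (length(label_sets) != length(profiles)) {
    bp_abort("one label set per profile required")
  }
  key <- vapply(label_sets, function(s) paste(sort(unique(s)), collapse = "+"),
                character(1))
  out <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    merged <- profiles[[idx[1]]]
    for (i in idx[-1]) merged <- merge_profiles(merged, profiles[[i]])
    out[[k]] <- merged
  }
  out
}

#' Bhattacharyya distance between diagonal-Gaussian profiles
#'
#' `1/8 sum (dmu^2 / vbar) + 1/2 sum log( vbar / sqrt(v1 v2) )` with
#' `vbar = (v1 + v2)/2`; symmetric, 0 iff identical parameters, and
#' independent of member counts.
#'
#' @param c1,c2 [cluster_profile()] objects.
#' @param var_floor Variance floor.
#' @return Non-negative distance.
#' @examples
#' a <- cluster_profile(0, 1); b <- cluster_profile(2, 1)
#' bhattacharyya(a, b) # 0.5
#' @export
bhattacharyya <- function(c1, c2, var_floor = 1e-9) {
  if (length(c1$mean) != length(c2$mean)) {
    bp_abort("profile dimension mismatch", class = "budprofiler_dimension_error")
  }
  v1 <- pmax(c1$variance, var_floor); v2 <- pmax(c2$variance, var_floor)
  vbar <- (v1 + v2) / 2
  sum((c1$mean - c2$mean)^2 / vbar) / 8 +
    0.5 * sum(log(vbar / sqrt(v1 * v2)))
}

#' Within- versus between-group class-profile distances
#'
#' Compares the mean Bhattacharyya distance within groups of biologically
#' related classes to the mean distance from group members to classes
#' outside the group; significance of the difference (within minus between)
#' by permutation of the class-to-group assignment.
#'
#' @param class_profiles Named list of class profiles ([class_profile()]).
#' @param groups A list of character vectors of class names (groups of
#'   related classes); classes in no group contribute only "between"
#'   distances.
#' @param n_perm Number of permutations, or `"exact"` for full enumeration.
#' @param seed Integer seed.
#' @return A one-row tibble: `mean_within`, `mean_between`, `difference`,
#'   `p_value`, `n_perm`.
#' @export
group_distance_test <- function(class_profiles, groups, n_perm = 1000,
                                seed = 1L) {
  if (length(groups) < 2) bp_abort("need at least 2 groups")
  nm <- names(class_profiles)
  K <- length(nm)
  D <- matrix(0, K, K, dimnames = list(nm, nm))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    D[i, j] <- D[j, i] <- bhattacharyya(class_profiles[[i]],
                                        class_profiles[[j]])
  }
  group_id <- setNames(rep(NA_integer_, K), nm)
  for (g in seq_along(groups)) {
    found <- intersect(groups[[g]], nm)
    if (length(found) < 2) {
      warn(sprintf("group %d has fewer than 2 present classes; no within-distance", g))
    }
    group_id[found] <- g
  }
  stat <- function(gid) {
    w <- c(); b <- c()
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      if (is.na(gid[i]) && is.na(gid[j])) next
      if (!is.na(gid[i]) && !is.na(gid[j]) && gid[i] == gid[j]) {
        w <- c(w, D[i, j])
      } else {
        b <- c(b, D[i, j])
      }
    }
    c(within = mean(w), between = mean(b))
  }
  obs <- stat(group_id)
  d_obs <- obs[["within"]] - obs[["between"]]
  perms <- if (identical(n_perm, "exact")) {
    all_permutations(K)
  } else {
    with_seed(seed, replicate(n_perm, sample.int(K), simplify = FALSE))
  }
  null_d <- vapply(perms, function(p) {
    s <- stat(group_id[p])
    s[["within"]] - s[["between"]]
  }, numeric(1))
  B <- length(perms)
  p <- (sum(null_d <= d_obs) + 1) / (B + 1)
  tibble::tibble(mean_within = obs[["within"]], mean_between = obs[["between"]],
                 difference = d_obs, p_value = p, n_perm = B)
}
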