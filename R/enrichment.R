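#' Upper-tail hypergeometric log probability
#'
#' Log probability of observing at least `k` annotated proteins in a cluster
#' of size `n` drawn from a universe of `N` proteins of which `K` carry the
#' annotation; computed in log space via [stats::phyper()].
#'
#' @param N Universe size.
#' @param K Annotated proteins in the universe.
#' @param n Cluster size.
#' @param k Overlap.
#' @param base Logarithm base (default 10, matching the log-scale Bonferroni
#'   reporting).
#' @return log-base `P(X >= k)`; 0 when `k = 0`.
#' @examples
#' exp(hypergeom_logp(20, 4, 5, 4, base = exp(1))) * 15504 # 16
#' @export
hypergeom_logp <- function(N, K, n, k, base = 10) {
  if (k < 0 || K > N || n > N || k > min(K, n)) {
    bp_abort("inconsistent hypergeometric counts")
  }
  if (k == 0) return(0)
  lp <- phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  lp / log(base)
}

#' Most enriched cluster for one annotation term
#'
#' Scans every internal node of the dendrogram (size >= `min_size`) and
#' returns the node minimizing the upper-tail hypergeometric log P for the
#' term, with Bonferroni correction reported in log10 scale
#' (`log10 P + log10 m` for `m` hypotheses).
#'
#' @param dendrogram A [agglomerate()] result.
#' @param term_proteins Character vector of protein ids carrying the term.
#' @param n_hypotheses Bonferroni hypothesis count `m` (default 1).
#' @param min_size Minimum cluster size scanned (default 2).
#' @return One-row tibble: `node`, `cluster_size`, `term_size`, `overlap`,
#'   `universe`, `log10_p`, `log10_p_bonferroni`; or a zero-row tibble when
#'   the term has fewer than 2 proteins in the universe.
#' @export
best_cluster_scan <- function(dendrogram, term_proteins, n_hypotheses = 1,
                              min_size = 2) {
  labels <- dendrogram$labels
  N <- length(labels)
  in_term <- labels %in% term_proteins
  K <- sum(in_term)
  empty <- tibble::tibble(node = integer(0), cluster_size = integer(0),
                          term_size = integer(0), overlap = integer(0),
                          universe = integer(0), log10_p = numeric(0),
                          log10_p_bonferroni = numeric(0))
  if (K < 2) return(empty)
  best_node <- NA_integer_; best_lp <- Inf; best_n <- 0L; best_k <- 0L
  for (node in seq_along(dendrogram$members)) {
    mem <- dendrogram$members[[node]]
    n <- length(mem)
    if (n < min_size || n >= N) next
    k <- sum(in_term[mem])
    if (k == 0L) next
    lp <- hypergeom_logp(N, K, n, k)
    if (lp < best_lp) {
      best_node <- node; best_lp <- lp; best_n <- n; best_k <- k
    }
  }
  if (!is.finite(best_lp)) best_lp <- 0
  if (is.na(best_node)) return(empty)
  tibble::tibble(node = best_node, cluster_size = best_n, term_size = K,
                 overlap = best_k, universe = N, log10_p = best_lp,
                 log10_p_bonferroni = best_lp + log10(n_hypotheses))
}

#' Annotation-family enrichment summary statistic S
#'
#' For each eligible term (>= 2 annotated proteins in the universe) the
#' best-cluster log10 P is found with [best_cluster_scan()]; S is the sum
#' of these log P values. More negative S means stronger enrichment of the
#' family in the hierarchy.
#'
#' @param dendrogram A [agglomerate()] result.
#' @param annotations A data frame with columns `protein` and `term`.
#' @param min_size Minimum cluster size scanned.
#' @return List with `S` (scalar) and `per_term` (tibble with one row per
#'   eligible term, Bonferroni count = number of eligible terms).
#' @export
s_statistic <- function(dendrogram, annotations, min_size = 2) {
  terms <- split(annotations$protein, annotations$term)
  eligible <- names(terms)[vapply(terms, function(p) {
    sum(dendrogram$labels %in% p) >= 2
  }, logical(1))]
  m <- length(eligible)
  rows <- purrr::map_dfr(eligible, function(tm) {
    r <- best_cluster_scan(dendrogram, terms[[tm]], n_hypotheses = m,
                           min_size = min_size)
    if (nrow(r)) r$term <- tm
    r
  })
  list(S = if (nrow(rows)) sum(rows$log10_p) else 0, per_term = rows,
       n_terms = m)
}

#' Permutation null for the S statistic
#'
#' Preserves the tree topology and permutes the leaf-to-protein assignment:
#' globally (`constraint = "none"`) or only within groups of proteins
#' sharing an identical subcellular-localization label set
#' (`constraint = "localization"`), which preserves any localization-driven
#' enrichment under the null. Reports the Z score of the observed S against
#' the permutation distribution and the add-one empirical p-value.
#'
#' @param dendrogram A [agglomerate()] result.
#' @param annotations Data frame (`protein`, `term`) for the tested family.
#' @param constraint `"none"` or `"localization"`.
#' @param localization_sets Named list or character vector keyed by protein
#'   giving the exact localization label-set key (required for the
#'   constrained mode).
#' @param n_perm Number of permutations (default 200).
#' @param seed Integer seed.
#' @param min_size Minimum cluster size scanned.
#' @return One-row tibble: `S_obs`, `null_mean`, `null_sd`, `z`, `p_value`,
#'   `n_perm`, `degenerate` (constrained groups all singletons).
#' @export
permutation_null_S <- function(dendrogram, annotations,
                               constraint = c("none", "localization"),
                               localization_sets = NULL,
                               n_perm = 200, seed = 1L, min_size = 2) {
  constraint <- match.arg(constraint)
  labels <- dendrogram$labels
  obs <- s_statistic(dendrogram, annotations, min_size = min_size)
  groups <- if (constraint == "localization") {
    if (is.null(localization_sets)) {
      bp_abort("localization_sets required for the constrained null")
    }
    keys <- localization_sets[labels]
    if (is.list(keys)) {
      keys <- vapply(keys, function(s) paste(sort(unique(s)), collapse = "+"),
                     character(1))
    }
    split(seq_along(labels), unname(unlist(keys)))
  } else {
    list(seq_along(labels))
  }
  degenerate <- all(lengths(groups) <= 1)
  if (degenerate) {
    warn("all constrained groups are singletons: the null is degenerate")
  }
  null_S <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    perm <- seq_along(labels)
    for (g in groups) {
      if (length(g) > 1) perm[g] <- g[sample.int(length(g))]
    }
    d2 <- dendrogram
    d2$labels <- labels[perm]
    s_statistic(d2, annotations, min_size = min_size)$S
  }, numeric(1)))
  mu <- mean(null_S); s <- sd(null_S)
  tibble::tibble(S_obs = obs$S, null_mean = mu, null_sd = s,
                 z = if (s > 0) (obs$S - mu) / s else NA_real_,
                 p_value = (sum(null_S <= obs$S) + 1) / (n_perm + 1),
                 n_perm = n_perm, degenerate = degenerate)
}
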