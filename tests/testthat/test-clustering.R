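test_that("merging matches pooled-moment oracles", {
  # self-merge: same mean and variance, doubled n
  c1 <- cluster_profile(c(1, 2), c(0.5, 0.8), n = 4, members = "a")
  m <- merge_profiles(c1, c1)
  expect_equal(m$mean, c1$mean)
  expect_equal(m$variance, c1$variance)
  expect_equal(m$n, 8)

  # 1-D worked example: (10, 0, 1) + (10, 10, 1) -> mu 5, var 26
  a <- cluster_profile(0, 1, n = 10)
  b <- cluster_profile(10, 1, n = 10)
  ab <- merge_profiles(a, b)
  expect_equal(ab$mean, 5)
  expect_equal(ab$variance, 26)

  # fold-merging equals one-shot pooled moments of raw members
  set.seed(22)
  xs <- matrix(rnorm(30), 10, 3)
  singles <- lapply(seq_len(10), function(i) cluster_profile(xs[i, ], rep(0, 3)))
  folded <- Reduce(merge_profiles, singles)
  expect_equal(folded$mean, colMeans(xs), tolerance = 1e-9)
  # singleton variances are floored at 1e-9, which carries into the pool
  expect_equal(folded$variance,
               apply(xs, 2, function(v) mean((v - mean(v))^2)),
               tolerance = 1e-7)
  # associativity up to tolerance: different merge order, same result
  folded2 <- Reduce(merge_profiles, singles[c(5, 1, 9, 2, 10, 3, 8, 4, 7, 6)])
  expect_equal(folded$mean, folded2$mean, tolerance = 1e-9)
  expect_equal(folded$variance, folded2$variance, tolerance = 1e-9)
})

test_that("merge dimension mismatch errors", {
  expect_error(merge_profiles(cluster_profile(1, 1), cluster_profile(c(1, 2), c(1, 1))),
               class = "budprofiler_dimension_error")
})

test_that("ML merge score: identity, monotonicity and log-density oracle", {
  c1 <- cluster_profile(c(0, 1), c(1, 2), n = 5)
  expect_equal(ml_merge_score(c1, c1), 0)
  # strictly increasing in |mu1 - mu2| at fixed variances
  sc <- vapply(seq(0, 5, by = 0.5), function(d) {
    ml_merge_score(cluster_profile(0, 1, n = 6), cluster_profile(d, 1, n = 6))
  }, numeric(1))
  expect_true(all(diff(sc) > 0))
  # oracle: difference of plug-in Gaussian log-likelihood sums for the
  # 1-D worked example
  a <- cluster_profile(0, 1, n = 10); b <- cluster_profile(10, 1, n = 10)
  m <- merge_profiles(a, b)
  ll <- function(n, s2) -n / 2 * (log(2 * pi * s2) + 1)
  oracle <- (ll(10, 1) + ll(10, 1)) - ll(20, m$variance)
  expect_equal(ml_merge_score(a, b), oracle, tolerance = 1e-9)
})

test_that("merge scores are non-negative on random profile pairs", {
  set.seed(23)
  for (i in 1:200) {
    c1 <- cluster_profile(rnorm(8), runif(8, 0.1, 2), n = sample(1:20, 1))
    c2 <- cluster_profile(rnorm(8), runif(8, 0.1, 2), n = sample(1:20, 1))
    expect_gte(ml_merge_score(c1, c2), 0)
  }
})

test_that("identical profiles merge first and trees match brute force", {
  p1 <- cluster_profile(rep(0, 4), rep(1, 4), members = "a")
  p2 <- cluster_profile(rep(5, 4), rep(1, 4), members = "b")
  p3 <- cluster_profile(rep(0, 4), rep(1, 4), members = "c")
  d <- agglomerate(list(p1, p2, p3))
  expect_equal(sort(d$merge[1, ]), c(-3, -1))
  expect_equal(d$score[1], 0)

  # 5 profiles: tree equals an exhaustive greedy oracle
  set.seed(24)
  ps <- lapply(1:5, function(i) {
    cluster_profile(rnorm(6, i), runif(6, 0.5, 1.5), members = letters[i])
  })
  d5 <- agglomerate(ps)
  # oracle: recompute all pair scores each step, lowest-index tie break
  clus <- ps; codes <- -(1:5); merges <- NULL
  for (step in 1:4) {
    alive <- which(!is.na(codes))
    best <- NULL
    for (ii in seq_along(alive)[-length(alive)]) {
      for (jj in (ii + 1):length(alive)) {
        i <- alive[ii]; j <- alive[jj]
        s <- ml_merge_score(clus[[i]], clus[[j]])
        if (is.null(best) || s < best$s) best <- list(i = i, j = j, s = s)
      }
    }
    merges <- rbind(merges, c(codes[best$i], codes[best$j]))
    clus[[best$i]] <- merge_profiles(clus[[best$i]], clus[[best$j]])
    codes[best$i] <- step; codes[best$j] <- NA
  }
  expect_equal(d5$merge, merges, ignore_attr = TRUE)
})

test_that("well-separated classes are recovered by cutting the tree", {
  defs <- make_class_defs(4, sep = 12, sd = 1, size = 12, seed = 25)
  sim <- simulate_profile_collection(defs, seed = 26)
  d <- agglomerate(sim$profiles)
  labs <- cut_dendrogram(d, 4)
  expect_gt(adjusted_rand(labs, sim$labels), 0.95)
})

test_that("merge conservation: member counts sum through every node", {
  set.seed(27)
  ps <- lapply(1:8, function(i) cluster_profile(rnorm(5), runif(5, 0.5, 1),
                                                members = paste0("p", i)))
  d <- agglomerate(ps)
  sizes <- vapply(d$members, length, integer(1))
  expect_equal(sizes[length(sizes)], 8)
  for (s in seq_len(nrow(d$merge))) {
    kid_size <- function(k) if (k < 0) 1L else sizes[k]
    expect_equal(sizes[s], kid_size(d$merge[s, 1]) + kid_size(d$merge[s, 2]))
  }
})

test_that("euclidean and correlation metrics run behind the same interface", {
  defs <- make_class_defs(3, sep = 8, sd = 1, size = 6, seed = 28)
  sim <- simulate_profile_collection(defs, seed = 29)
  for (m in c("euclidean", "correlation")) {
    d <- agglomerate(sim$profiles, metric = m)
    expect_s3_class(d, "profile_dendrogram")
    expect_equal(d$n_leaves, 18)
    labs <- cut_dendrogram(d, 3)
    expect_gt(adjusted_rand(labs, sim$labels), 0.9)
  }
})

test_that("class profiles group by exact label-set equality", {
  ps <- lapply(1:3, function(i) cluster_profile(rep(i, 4), rep(1, 4),
                                                members = paste0("p", i)))
  cp <- class_profile(ps, list(c("A"), c("A"), c("A", "B")))
  expect_setequal(names(cp), c("A", "A+B"))
  expect_equal(cp[["A"]]$n, 2)
  expect_equal(cp[["A+B"]]$n, 1)
  expect_equal(cp[["A"]]$mean, rep(1.5, 4))

  # order of labels within a set does not matter
  cp2 <- class_profile(ps, list("A", "A", c("B", "A")))
  expect_setequal(names(cp2), names(cp))

  # fold over members equals pooled moments in any order
  set.seed(30)
  xs <- matrix(rnorm(24), 8, 3)
  singles <- lapply(seq_len(8), function(i) cluster_profile(xs[i, ], rep(0.5, 3)))
  cpa <- class_profile(singles, as.list(rep("Z", 8)))[["Z"]]
  cpb <- class_profile(rev(singles), as.list(rep("Z", 8)))[["Z"]]
  expect_equal(cpa$mean, cpb$mean, tolerance = 1e-9)
  expect_equal(cpa$variance, cpb$variance, tolerance = 1e-9)
})

test_that("Bhattacharyya distance: closed forms, symmetry, n-independence", {
  a <- cluster_profile(0, 1); b <- cluster_profile(2, 1)
  expect_equal(bhattacharyya(a, b), 0.5)   # dmu^2 / (8 sigma^2)
  expect_equal(bhattacharyya(a, a), 0)
  set.seed(31)
  for (i in 1:20) {
    c1 <- cluster_profile(rnorm(6), runif(6, 0.2, 2), n = sample(1:30, 1))
    c2 <- cluster_profile(rnorm(6), runif(6, 0.2, 2), n = sample(1:30, 1))
    expect_equal(bhattacharyya(c1, c2), bhattacharyya(c2, c1))
    expect_gte(bhattacharyya(c1, c2), 0)
    # independent of member counts
    c1b <- c1; c1b$n <- 999
    expect_equal(bhattacharyya(c1b, c2), bhattacharyya(c1, c2))
  }
})

test_that("group distance test separates structured from random groupings", {
  # four well-separated blocks of two nearby classes each (with fewer
  # groups the permutation null cannot reach p < 0.05 at all)
  block_means <- c(0, 3, 40, 43, 80, 83, 120, 123)
  defs <- lapply(block_means, function(m) {
    list(mean = rep(m, 120), sd = 0.8, size = 8)
  })
  sim <- simulate_profile_collection(defs, seed = 33)
  cps <- class_profile(as_profile_list_for_test(sim$profiles),
                       as.list(paste0("class", sim$labels)))
  related <- list(paste0("class", 1:2), paste0("class", 3:4),
                  paste0("class", 5:6), paste0("class", 7:8))
  res <- group_distance_test(cps, related, n_perm = 300, seed = 2)
  expect_lt(res$mean_within, res$mean_between)
  expect_lt(res$p_value, 0.05)

  # 3 classes, exhaustive permutations equal exact enumeration
  cps3 <- cps[1:3]
  g3 <- list(names(cps3)[1:2], names(cps3)[3])
  expect_warning(r_exact <- group_distance_test(cps3, g3, n_perm = "exact"),
                 "fewer than 2")
  # oracle: all 6 assignments of 3 classes to the group pattern
  D <- matrix(0, 3, 3)
  for (i in 1:2) for (j in (i + 1):3) {
    D[i, j] <- D[j, i] <- bhattacharyya(cps3[[i]], cps3[[j]])
  }
  gid <- c(1, 1, 2)
  stat <- function(g) {
    w <- c(); b <- c()
    for (i in 1:2) for (j in (i + 1):3) {
      if (g[i] == g[j]) w <- c(w, D[i, j]) else b <- c(b, D[i, j])
    }
    mean(w) - mean(b)
  }
  perms <- budprofiler:::all_permutations(3)
  nulls <- vapply(perms, function(p) stat(gid[p]), numeric(1))
  obs <- stat(gid)
  expect_equal(r_exact$p_value, (sum(nulls <= obs) + 1) / (length(perms) + 1))
})

test_that("TreeView CDT/GTR files are written and consistent", {
  defs <- make_class_defs(2, sep = 6, sd = 1, size = 4, seed = 34)
  sim <- simulate_profile_collection(defs, seed = 35)
  d <- agglomerate(sim$profiles)
  dir <- tempfile(); dir.create(dir)
  paths <- write_treeview(d, sim$profiles$profile, file.path(dir, "out"))
  expect_true(all(file.exists(file.path(dir, c("out.cdt", "out.gtr")))))
  cdt <- readLines(file.path(dir, "out.cdt"))
  expect_equal(length(cdt), 2 + 8)         # header + eweight + 8 leaves
  gtr <- read.table(file.path(dir, "out.gtr"), sep = "\t")
  expect_equal(nrow(gtr), 7)               # n - 1 merges
  expect_true(all(grepl("^(GENE|NODE)", c(gtr$V1, gtr$V2, gtr$V3))))
})
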