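test_that("noise-free archetypes are recovered exactly with zero objective", {
  ap <- archetype_profiles(n_per = 20, noise_sd = 0)
  cl <- kmeans_profiles(ap$profiles, k = 5, restarts = 10, seed = 1)
  expect_equal(adjusted_rand_index(cl$labels[names(ap$labels)], ap$labels), 1)
  expect_lt(cl$objective, 1e-9)
})

test_that("assignment is invariant to per-gene positive affine transforms", {
  ap <- archetype_profiles(n_per = 10, noise_sd = 0.25, seed = 2)
  cl1 <- kmeans_profiles(ap$profiles, k = 5, restarts = 5, seed = 3)
  cl2 <- kmeans_profiles(3 * ap$profiles + 7, k = 5, restarts = 5, seed = 3)
  expect_identical(cl1$labels, cl2$labels)
  expect_equal(cl1$objective, cl2$objective, tolerance = 1e-9)
})

test_that("k equal to the number of genes gives singleton clusters", {
  ap <- archetype_profiles(n_per = 1, noise_sd = 0.1, seed = 4)
  cl <- kmeans_profiles(ap$profiles, k = 5, restarts = 3, seed = 4)
  expect_equal(sort(unname(table(cl$labels))), rep(1L, 5), ignore_attr = TRUE)
  expect_lt(cl$objective, 1e-9)
})

test_that("clustering is order-invariant given a fixed seed and reports drops", {
  ap <- archetype_profiles(n_per = 8, noise_sd = 0.25, seed = 5)
  perm <- sample(nrow(ap$profiles))
  cl1 <- kmeans_profiles(ap$profiles, k = 5, restarts = 5, seed = 6)
  cl2 <- kmeans_profiles(ap$profiles[perm, ], k = 5, restarts = 5, seed = 6)
  expect_identical(cl1$labels, cl2$labels)

  flat <- ap$profiles
  flat[1, ] <- 3                      # zero variance: correlation undefined
  cl3 <- kmeans_profiles(flat, k = 5, restarts = 3, seed = 6)
  expect_true(rownames(flat)[1] %in% cl3$dropped)
  expect_false(rownames(flat)[1] %in% names(cl3$labels))
  expect_error(kmeans_profiles(ap$profiles[1:3, ], k = 5), "exceeds")
})

test_that("the k-means objective is non-increasing within the winning run", {
  ap <- archetype_profiles(n_per = 15, noise_sd = 0.4, seed = 7)
  cl <- kmeans_profiles(ap$profiles, k = 5, restarts = 10, seed = 7)
  expect_true(all(diff(cl$objective_trace) <= 1e-9))
})

test_that("cluster matching recovers a planted permutation exactly", {
  ap <- archetype_profiles(n_per = 12, noise_sd = 0.2, seed = 8)
  cl_a <- kmeans_profiles(ap$profiles, k = 5, restarts = 5, seed = 8)
  pi <- c(3, 5, 1, 2, 4)
  cl_b <- cl_a
  cl_b$labels <- setNames(pi[cl_a$labels], names(cl_a$labels))
  cl_b$centroids <- cl_a$centroids[order(pi), ]
  mt <- match_clusters(cl_a, cl_b)
  expect_equal(mt$cluster_b, pi)
  expect_equal(mt$score, rep(1, 5), tolerance = 1e-12)

  mt_id <- match_clusters(cl_a, cl_a)
  expect_equal(mt_id$cluster_b, 1:5)
  expect_equal(attr(mt_id, "total_score"), 5, tolerance = 1e-12)
})

test_that("cluster length enrichment matches the hypergeometric oracles", {
  # N=10 universe, K=4 category, one cluster of 5 with 3 hits: p = 66/252
  g <- make_ann(seq(0, 9000, 1000),
                seq(0, 9000, 1000) +
                  c(2500, 2500, 2500, 300, 300, 2500, 300, 300, 300, 300))
  labels <- setNames(rep(c(1L, 2L), each = 5), g$gene_id)
  assign <- structure(list(labels = labels, k = 2L,
                           centroids = matrix(0, 2, 3)),
                      class = "cluster_assignment")
  res <- cluster_length_enrichment(assign, g, function(l) l > 2000)
  expect_equal(res$x[1], 3)   # first cluster holds genes 1-5: 3 long genes...
  expect_equal(res$p[1], hyper_upper_enum(res$x[1], 5, 4, 10), tolerance = 1e-12)
  resU <- cluster_length_enrichment(assign, g, g$gene_id)
  expect_equal(resU$p, c(1, 1))
  expect_error(cluster_length_enrichment(assign, g, function(l) l > 1e9), "empty")

  # strong planted enrichment: cluster 1 = exactly the long genes
  p_strong <- hypergeom_upper(200, n = 200, K = 200, N = 600)
  expect_lt(p_strong, 1e-10)
  expect_rel_error(p_strong, hyper_upper_lgamma(200, 200, 200, 600), 1e-10)
})

test_that("redistribution summary reconciles flows, changes and body shift", {
  ap <- archetype_profiles(n_per = 10, noise_sd = 0.1, seed = 9)
  cl_a <- kmeans_profiles(ap$profiles, k = 5, restarts = 5, seed = 9)
  mt <- match_clusters(cl_a, cl_a)
  scheme <- profile_scheme(flank_bins = 10, body_bins = 40)
  rs <- redistribution_summary(cl_a, cl_a, mt, ap$profiles, ap$profiles,
                               scheme = scheme)
  expect_equal(sum(diag(rs$flow)), length(cl_a$labels))
  expect_equal(rs$association_change$mean_change, rep(0, 5))
  expect_equal(rs$body_shift_a, rs$body_shift_b)
  expect_equal(unname(rowSums(rs$flow)),
               unname(as.vector(table(factor(cl_a$labels, levels = 1:5)))))

  # planted reassignment: genes moved between clusters land off-diagonal
  cl_b <- cl_a
  movers <- names(cl_a$labels)[cl_a$labels == 2][1:5]
  cl_b$labels[movers] <- 4L
  rs2 <- redistribution_summary(cl_a, cl_b, mt, ap$profiles, ap$profiles,
                                scheme = scheme)
  expect_equal(unname(rs2$flow[2, 4]), 5)
  expect_equal(sum(rs2$flow) - sum(diag(rs2$flow)), 5)
})

test_that("body shift equals the planted amplitude on body-only noise-free data", {
  scheme <- profile_scheme(flank_bins = 10, body_bins = 40)
  prof <- c(rep(0, 10), rep(2, 40), rep(0, 10))
  m <- matrix(rep(prof, each = 4), nrow = 4)
  rownames(m) <- paste0("g", 1:4)
  labels <- setNames(rep(c(1L, 2L), 2), rownames(m))
  asg <- structure(list(labels = labels, k = 2L, centroids = rbind(prof, prof)),
                   class = "cluster_assignment")
  mt <- match_clusters(asg, asg)
  rs <- redistribution_summary(asg, asg, mt, m, m, scheme = scheme)
  expect_equal(rs$body_shift_a, 2)
})

test_that("adjusted Rand index agrees with the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(10)
  for (i in 1:5) {
    a <- sample(1:4, 50, replace = TRUE)
    b <- sample(1:3, 50, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, rep(1:5, 2)),
               mclust::adjustedRandIndex(1:10, rep(1:5, 2)))
})
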