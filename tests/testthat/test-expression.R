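make_expr <- function(values, intensity = NULL, contrast = "c1") {
  # values: genes x reps matrix
  x <- list(values)
  names(x) <- contrast
  expression_matrix(x, mean_intensity = intensity)
}

test_that("median centering zeroes constant replicates and is idempotent", {
  m <- matrix(0.7, 5, 3, dimnames = list(paste0("g", 1:5), NULL))
  x <- make_expr(m)
  out <- normalize_ratios(x, "median_center")
  expect_equal(unname(out$contrasts$c1), matrix(0, 5, 3))

  set.seed(2)
  m2 <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("g", 1:10), NULL))
  m2 <- sweep(m2, 2, apply(m2, 2, median))  # already median-0
  x2 <- make_expr(m2)
  out2 <- normalize_ratios(x2, "median_center")
  expect_equal(out2$contrasts$c1, m2, tolerance = 1e-9)
})

test_that("lowess normalization removes a planted intensity trend", {
  set.seed(3)
  n <- 400
  intensity <- sort(rlnorm(n, 7, 1))
  ids <- sprintf("g%04d", seq_len(n))
  names(intensity) <- ids
  rank_scaled <- 2 * (rank(intensity) - 1) / (n - 1) - 1   # [-1, 1]
  trend <- 0.5 * rank_scaled
  m <- matrix(trend + rnorm(n * 3, 0, 0.05), n, 3,
              dimnames = list(ids, NULL))
  x <- make_expr(m, intensity = intensity)
  out <- normalize_ratios(x, "lowess_ma", span = 0.3)
  for (j in 1:3) {
    fit <- lm(out$contrasts$c1[, j] ~ rank_scaled)
    expect_lt(abs(coef(fit)[2]), 0.05)
  }
  expect_error(normalize_ratios(make_expr(m), "lowess_ma"), "mean_intensity")
})

test_that("response-set calling follows the SD-and-p rule with an unchanged band", {
  ids <- paste0("g", 1:6)
  m <- rbind(c(3, 3.1, 2.9), c(-3, -3.1, -2.9), c(0.1, 0.1, 0.1),
             c(0.5, 0.6, 0.4), c(0.05, -0.05, 0.02), c(1.0, -1.0, 0.1))
  rownames(m) <- ids
  x <- make_expr(m)
  rs <- call_response_sets(x, "c1")
  expect_true("g1" %in% rs$induced)
  expect_true("g2" %in% rs$repressed)
  # |mean log2fc| = 0.1 -> fold 1.07 < 1.2 -> unchanged
  expect_true("g3" %in% rs$unchanged)
  expect_length(intersect(rs$induced, rs$repressed), 0)
  expect_length(intersect(rs$induced, rs$unchanged), 0)

  z <- make_expr(matrix(0, 5, 3, dimnames = list(paste0("g", 1:5), NULL)))
  expect_error(call_response_sets(z, "c1"), "SD")
})

test_that("null data yield the oracle-calibrated fraction of regulated calls", {
  g <- simulate_genome(10000, seed = 3)
  tr <- simulate_truth(g, frac_induced = 0, frac_repressed = 0, seed = 3)
  x <- simulate_expression(g, tr, noise_sd = 0.25, n_replicates = 4, seed = 3)
  rs <- call_response_sets(x, "wt_kcl")
  frac_ind <- length(rs$induced) / length(rs$universe)
  expect_gt(frac_ind, 0.02)
  expect_lt(frac_ind, 0.10)
})

test_that("calling is invariant to gene order and monotone in effect size", {
  g <- simulate_genome(300, seed = 8)
  tr <- simulate_truth(g, seed = 8)
  x <- simulate_expression(g, tr, seed = 8)
  rs <- call_response_sets(x, "wt_kcl")
  perm <- sample(nrow(x$contrasts$wt_kcl))
  xp <- expression_matrix(lapply(x$contrasts, function(m) m[perm, , drop = FALSE]),
                          mean_intensity = x$mean_intensity[perm])
  rsp <- call_response_sets(xp, "wt_kcl")
  expect_setequal(rs$induced, rsp$induced)
  expect_setequal(rs$repressed, rsp$repressed)

  # raising an induced gene's ratios keeps it induced (thresholds recomputed)
  gene <- rs$induced[1]
  x2 <- x
  x2$contrasts$wt_kcl[gene, ] <- x$contrasts$wt_kcl[gene, ] + 1
  rs2 <- call_response_sets(expression_matrix(x2$contrasts, x2$mean_intensity),
                            "wt_kcl")
  expect_true(gene %in% rs2$induced)
})

test_that("dependency classes are the stated intersections", {
  ids <- paste0("g", 1:8)
  wt <- structure(list(induced = ids[1:3], repressed = ids[4:5],
                       unchanged = ids[6:8], universe = ids),
                  class = "response_sets")
  dep <- structure(list(induced = ids[c(4, 6)], repressed = ids[c(1, 2, 7)],
                        unchanged = ids[3], universe = ids),
                   class = "response_sets")
  dc <- select_gcn5_dependent(wt, dep)
  expect_setequal(dc$dependent_induced, c("g1", "g2"))   # induced & lower in mutant
  expect_setequal(dc$dependent_repressed, "g4")          # repressed & higher in mutant
  expect_false("g3" %in% unlist(dc))                     # induced but unchanged in mutant

  dep_bad <- dep; dep_bad$universe <- ids[1:7]
  expect_error(select_gcn5_dependent(wt, dep_bad), "universe")
})

test_that("noise-free dependency recovery is exact", {
  g <- simulate_genome(200, seed = 12)
  tr <- simulate_truth(g, frac_induced = 0.2, frac_repressed = 0.1,
                       frac_dependent = 0.5, seed = 12)
  # exact planted memberships
  planted_di <- tr$gene_id[tr$dependency_class == "dependent_induced"]
  planted_dr <- tr$gene_id[tr$dependency_class == "dependent_repressed"]
  x <- simulate_expression(g, tr, noise_sd = 0, n_replicates = 3, seed = 12)
  # zero noise makes unchanged genes all-zero; add negligible jitter so the
  # population SD threshold is defined, without moving any call
  xj <- expression_matrix(lapply(x$contrasts, function(m)
    m + matrix(rnorm(length(m), 0, 1e-6), nrow(m))), x$mean_intensity)
  wt <- call_response_sets(xj, "wt_kcl")
  dep <- call_response_sets(xj, "mut_vs_wt_kcl")
  dc <- select_gcn5_dependent(wt, dep)
  expect_setequal(dc$dependent_induced, planted_di)
  expect_setequal(dc$dependent_repressed, planted_dr)
})

test_that("dependency spread statistics behave as scale measures", {
  ids <- sprintf("g%03d", 1:50)
  set.seed(4)
  base <- matrix(rnorm(150), 50, 3, dimnames = list(ids, NULL))
  x <- expression_matrix(list(minus = base, plus = base))
  sp <- dependency_spread(x, "minus", "plus")
  expect_equal(sp$ratio, 1)
  x2 <- expression_matrix(list(minus = base, plus = 2 * base))
  sp2 <- dependency_spread(x2, "minus", "plus")
  expect_equal(sp2$ratio, 2, tolerance = 1e-12)
  x3 <- expression_matrix(list(minus = base[1:5, ], plus = base[1:5, ]))
  expect_error(dependency_spread(x3, "minus", "plus"), "10 genes")
})

test_that("planted stress-specific dependency broadens the spread", {
  g <- simulate_genome(1000, seed = 21)
  tr <- simulate_truth(g, frac_induced = 0.15, frac_repressed = 0.15,
                       frac_dependent = 0.7, seed = 21)
  x <- simulate_expression(g, tr, noise_sd = 0.25, seed = 21)
  sp <- dependency_spread(x, "mut_vs_wt_ctrl", "mut_vs_wt_kcl")
  expect_gt(sp$ratio, 1)
  expect_equal(colnames(sp$histogram), c("mid", "freq_minus", "freq_plus"))
})

test_that("reference overlap matches the enumeration oracle", {
  u <- paste0("g", 1:10)
  ov <- overlap_with_reference(u[1:5], u, u)
  expect_equal(ov$fraction_of_a, 1)
  expect_equal(ov$p, 1)
  expect_equal(overlap_with_reference(u[1:3], u[4:6], u)$n_overlap, 0)
  # |U|=10, |A|=5, |R|=4, overlap 3: p = 66/252
  ov3 <- overlap_with_reference(u[1:5], c(u[3:5], u[10]), u)
  expect_equal(ov3$n_overlap, 3)
  expect_equal(ov3$p, 66 / 252, tolerance = 1e-12)
  expect_error(overlap_with_reference(character(0), u[1:2], u), "empty")
})
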