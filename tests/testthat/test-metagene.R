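test_that("windowed enrichment averages log ratios within the bandwidth", {
  pos <- seq(0, 1000, 50)
  ip <- signal_track(rep("chr1", length(pos)), pos, rep(4, length(pos)))
  input <- signal_track(rep("chr1", length(pos)), pos, rep(4, length(pos)))
  enr <- window_enrichment(ip, input, bandwidth = 250)
  expect_equal(enr$value, rep(0, length(pos)))

  # probes at 0/100/200 with log2 ratios 1/2/3: score at 100 is their mean
  ip2 <- signal_track(rep("chr1", 3), c(0, 100, 200), 2^c(1, 2, 3))
  in2 <- signal_track(rep("chr1", 3), c(0, 100, 200), c(1, 1, 1))
  enr2 <- window_enrichment(ip2, in2, bandwidth = 250)
  expect_equal(enr2$value[enr2$pos == 100], 2)
  # singleton window: score equals the probe's own log2 ratio
  enr3 <- window_enrichment(ip2, in2, bandwidth = 50)
  expect_equal(enr3$value, c(1, 2, 3))

  in_far <- signal_track("chr1", 5000, 1)
  expect_error(window_enrichment(ip2, in_far, bandwidth = 250), "share no probe")
})

test_that("standardization matches the reference moments and is idempotent", {
  t1 <- signal_track(rep("chr1", 2), c(0, 50), c(4, 6))
  ref <- signal_track(rep("chr1", 2), c(0, 50), c(-1, 1))
  out <- standardize_track(t1, ref)
  expect_equal(out$value, c(-1, 1), tolerance = 1e-12)

  set.seed(5)
  t2 <- make_track(0, 5000, 50, function(p) rnorm(length(p), 3, 2))
  r2 <- make_track(0, 5000, 50, function(p) rnorm(length(p), -1, 0.5))
  s <- standardize_track(t2, r2)
  expect_lt(abs(mean(s$value) - mean(r2$value)), 1e-9)
  expect_lt(abs(sd(s$value) - sd(r2$value)), 1e-9)
  s2 <- standardize_track(s, r2)
  expect_lt(max(abs(s2$value - s$value)), 1e-12)
  ident <- standardize_track(t2, t2)
  expect_lt(max(abs(ident$value - t2$value)), 1e-12)

  const <- signal_track(rep("chr1", 3), c(0, 1, 2), c(5, 5, 5))
  expect_error(standardize_track(const, ref), "SD")
})

test_that("gene profiles preserve constants and are strand-symmetric", {
  scheme <- profile_scheme(flank_bp = 500, flank_bins = 10, body_bins = 40)
  tr <- make_track(0, 6000, 50, function(p) rep(1.5, length(p)))
  g <- make_ann(2000, 4000)
  pr <- gene_profile(tr, g[1, ], scheme)
  expect_true(pr$usable)
  expect_equal(pr$bins[pr$coverage > 0], rep(1.5, sum(pr$coverage > 0)))

  # mirror the genome: gene and probes reflected through M-1
  M <- 6050
  set.seed(6)
  vals <- rnorm(121)
  pos <- seq(0, 6000, 50)
  fwd <- signal_track(rep("chr1", 121), pos, vals)
  rpos <- M - 1 - pos
  o <- order(rpos)
  rev <- signal_track(rep("chr1", 121), rpos[o], vals[o])
  gf <- make_ann(2000, 4000, "+")
  gr <- make_ann(M - 4000, M - 2000, "-")
  pf <- gene_profile(fwd, gf[1, ], scheme)
  pr2 <- gene_profile(rev, gr[1, ], scheme)
  expect_equal(pr2$bins, pf$bins)
  expect_equal(pr2$coverage, pf$coverage)

  off <- gene_annotation("gx", "chrZ", "+", 0, 100)
  po <- gene_profile(tr, off[1, ], scheme)
  expect_false(po$usable)
  expect_equal(po$reason, "chromosome_absent")
})

test_that("promoter-peaked genes place their profile argmax at the TSS bins", {
  g <- simulate_genome(10, c(0, 0, 1), intergenic_gap = 3000, seed = 14)
  tr <- simulate_truth(g, seed = 14)
  tr$archetype_a <- "promoter_peaked"
  ch <- simulate_chip(g, tr, "a", probe_spacing = 50, noise_sd = 0, seed = 14)
  enr <- window_enrichment(ch$ip, ch$input, bandwidth = 50)
  scheme <- profile_scheme()
  profs <- gene_profiles(enr, g, scheme)
  argmax <- vapply(profs, function(p) which.max(p$bins), integer(1))
  expect_true(all(argmax %in% c(scheme$flank_bins, scheme$flank_bins + 1L)))
})

test_that("metagene averaging follows the bin-wise missing-data rule", {
  p1 <- structure(list(gene_id = "g1", bins = c(1, 2, 3), coverage = c(1L, 1L, 1L),
                       usable = TRUE, reason = NA), class = "positional_profile")
  p2 <- structure(list(gene_id = "g2", bins = c(3, NA, 5), coverage = c(1L, 0L, 2L),
                       usable = TRUE, reason = NA), class = "positional_profile")
  profs <- structure(list(g1 = p1, g2 = p2), class = "profile_set")
  mg <- metagene_average(profs, c("g1", "g2"), "pair")
  expect_equal(mg$mean, c(2, 2, 4))       # bin 2 uses g1 only
  expect_equal(mg$n_per_bin, c(2L, 1L, 2L))
  mg1 <- metagene_average(structure(list(g1 = p1, g1b = p1),
                                    class = "profile_set"))
  expect_equal(mg1$mean, p1$bins)
  expect_equal(mg1$sem, c(0, 0, 0))
  expect_error(metagene_average(profs, character(0)), "usable")
})

test_that("body-enriched genes show the planted body-over-flank contrast", {
  g <- simulate_genome(100, c(0, 0, 1), intergenic_gap = 2000, seed = 15)
  tr <- simulate_truth(g, seed = 15)
  tr$archetype_a <- "body_enriched"; tr$amplitude <- 2
  ch <- simulate_chip(g, tr, "a", noise_sd = 0.25, seed = 15)
  enr <- window_enrichment(ch$ip, ch$input, bandwidth = 250)
  scheme <- profile_scheme()
  mg <- metagene_average(gene_profiles(enr, g, scheme))
  bins <- scheme_bins(scheme)
  # interior body vs. outer flank bins (window smoothing blurs boundaries)
  contrast <- mean(mg$mean[bins$body[10:30]]) -
    mean(mg$mean[c(bins$flank_up[1:5], bins$flank_down[6:10])])
  expect_gt(contrast, 1.5)
})

test_that("gene grouping is deterministic with documented boundaries", {
  g9 <- make_ann(seq(0, 8000, 1000), seq(0, 8000, 1000) + 400)
  mi <- setNames(c(5, 3, 9, 1, 7, 2, 8, 4, 6), g9$gene_id)
  tert <- group_genes(g9, "expression_tertile", mean_intensity = mi)
  expect_equal(lengths(tert), c(low = 3L, mid = 3L, high = 3L))
  expect_setequal(tert$low, g9$gene_id[match(c(1, 2, 3), mi)])

  lens <- c(300, 800, 1500, 2000, 3000)
  ga <- make_ann(seq(0, 40000, 10000)[1:5], seq(0, 40000, 10000)[1:5] + lens)
  lb <- group_genes(ga, "length_bins")
  expect_equal(unname(lengths(lb)), c(1L, 1L, 2L, 1L))
  expect_true(ga$gene_id[4] %in% lb[["1000-2000"]])  # 2000 bp is not "long"
  expect_true(ga$gene_id[5] %in% lb[["gt2000"]])
  expect_error(group_genes(ga[1:2, ], "expression_tertile",
                           mean_intensity = mi), "fewer genes|missing")
})

test_that("bound-gene calls require strict threshold crossing in both conditions", {
  g <- make_ann(c(1000, 3000, 5000), c(2000, 4000, 6000))
  mk <- function(v1, v2, v3) {
    f <- function(p) ifelse(p >= 1000 & p < 2000, v1,
                     ifelse(p >= 3000 & p < 4000, v2,
                     ifelse(p >= 5000 & p < 6000, v3, 0)))
    make_track(0, 7000, 50, f)
  }
  ta <- mk(1.5, 1.4, 2.0)
  tb <- mk(1.5, 1.4, 0.5)
  bound <- call_bound_genes(ta, tb, g, threshold_log2 = 1.4, flank_bp = 0)
  expect_equal(as.character(bound), "g001")   # 1.4 exactly and 2.0/0.5 both fail
})

test_that("doubling body bins and re-averaging reproduces the coarse profile", {
  g <- simulate_genome(5, c(0, 0, 1), intergenic_gap = 3000, seed = 16)
  tr <- simulate_truth(g, seed = 16)
  tr$archetype_a <- "body_enriched"
  ch <- simulate_chip(g, tr, "a", probe_spacing = 10, noise_sd = 0, seed = 16)
  enr <- window_enrichment(ch$ip, ch$input, bandwidth = 10)
  coarse <- profile_scheme(body_bins = 20)
  fine <- profile_scheme(body_bins = 40)
  for (i in seq_len(nrow(g))) {
    pc <- gene_profile(enr, g[i, ], coarse)
    pf <- gene_profile(enr, g[i, ], fine)
    body_c <- pc$bins[scheme_bins(coarse)$body]
    body_f <- pf$bins[scheme_bins(fine)$body]
    paired <- (body_f[c(TRUE, FALSE)] + body_f[c(FALSE, TRUE)]) / 2
    # agreement within probe-discretization error at the bin edges
    expect_equal(paired, body_c, tolerance = 0.15)
  }
})
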