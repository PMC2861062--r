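# Independent oracles and small fixture builders shared across tests.

# Exact upper-tail hypergeometric by direct enumeration of the pmf in
# integer arithmetic (choose() is exact for the N <= 12 grid used here).
hyper_upper_enum <- function(x, n, K, N) {
  xs <- x:min(n, K)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Upper-tail hypergeometric by log-gamma term summation; independent of
# stats::phyper's algorithm.
hyper_upper_lgamma <- function(x, n, K, N) {
  xs <- x:min(n, K)
  lse <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
  lterms <- lgamma(K + 1) - lgamma(xs + 1) - lgamma(K - xs + 1) +
    lgamma(N - K + 1) - lgamma(n - xs + 1) - lgamma(N - K - n + xs + 1) -
    (lgamma(N + 1) - lgamma(n + 1) - lgamma(N - n + 1))
  if (length(lterms) == 0) return(0)
  exp(lse(lterms))
}

# Minimal annotation: genes laid on one chromosome with explicit coords.
make_ann <- function(starts, ends, strands = NULL, chrom = "chr1") {
  n <- length(starts)
  if (is.null(strands)) strands <- rep("+", n)
  gene_annotation(sprintf("g%03d", seq_len(n)), chrom, strands, starts, ends)
}

# Regular-grid signal track from a value function of position.
make_track <- function(from, to, by, f, chrom = "chr1", label = "t") {
  pos <- seq(from, to, by = by)
  signal_track(rep(chrom, length(pos)), pos, f(pos), label = label,
               sorted_input = TRUE)
}

# Frozen Monte-Carlo oracle for the null DE-call fractions: 1e5 genes,
# 4 replicates of SD 0.25, all true means 0, seed 20260928
# (scripts kept outside the package; values frozen here).
NULL_DE_ORACLE <- c(induced = 0.02220, repressed = 0.02237)

# five well-separated positional archetypes on a 60-bin grid
archetype_profiles <- function(n_per = 20, noise_sd = 0, seed = 1,
                               amplitude = 2) {
  bins <- 60
  shapes <- list(
    tss_peak = amplitude * exp(-((1:bins - 11)^2) / 18),
    body_plateau = amplitude * as.numeric(1:bins %in% 11:50),
    tes_peak = amplitude * exp(-((1:bins - 50)^2) / 18),
    mid_peak = amplitude * exp(-((1:bins - 30)^2) / 50),
    ramp_down = amplitude * seq(1, 0, length.out = bins)
  )
  set.seed(seed)
  m <- do.call(rbind, lapply(seq_along(shapes), function(i)
    matrix(rep(shapes[[i]], each = n_per), nrow = n_per) +
      rnorm(n_per * bins, 0, noise_sd)))
  rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  labels <- rep(seq_along(shapes), each = n_per)
  names(labels) <- rownames(m)
  list(profiles = m, labels = labels)
}

expect_rel_error <- function(value, reference, tol) {
  expect_true(all(abs(value - reference) <=
                    tol * pmax(abs(reference), .Machine$double.xmin)))
}
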