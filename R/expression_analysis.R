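#' Normalize replicate log2 ratios
#'
#' `median_center` subtracts each replicate's median; `lowess_ma` removes
#' the intensity-dependent trend of each replicate's log2 ratios (MA-style
#' lowess against log2 mean intensity, fitted trend subtracted).
#'
#' @param x an [expression_matrix()].
#' @param method `"median_center"` or `"lowess_ma"`.
#' @param span lowess span (fraction of points), default 0.3.
#' @param contrasts contrast names to normalize (default all).
#' @return A normalized [expression_matrix()].
#' @export
normalize_ratios <- function(x, method = c("median_center", "lowess_ma"),
                             span = 0.3, contrasts = names(x$contrasts)) {
  stopifnot(inherits(x, "expression_matrix"))
  method <- match.arg(method)
  if (method == "lowess_ma" && is.null(x$mean_intensity))
    stop2("lowess_ma normalization requires a mean_intensity channel")
  out <- x$contrasts
  for (nm in contrasts) {
    m <- out[[nm]]
    for (j in seq_len(ncol(m))) {
      y <- m[, j]
      ok <- !is.na(y)
      if (!any(ok)) next
      if (method == "median_center") {
        m[ok, j] <- y[ok] - stats::median(y[ok])
      } else {
        a <- log2(x$mean_intensity)[ok]
        fit <- stats::lowess(a, y[ok], f = span)
        trend <- stats::approx(fit$x, fit$y, xout = a, rule = 2, ties = mean)$y
        m[ok, j] <- y[ok] - trend
      }
    }
    out[[nm]] <- m
  }
  expression_matrix(out, mean_intensity = x$mean_intensity)
}

#' Call stress-regulated and unchanged gene sets
#'
#' Regulated genes are those whose mean log2 ratio exceeds the overall
#' population mean by `sd_multiplier` population SDs (induced above,
#' repressed below) AND whose two-sided one-sample t-test against 0 gives
#' p < `alpha` (uncorrected). Unchanged genes have |fold change| below
#' `unchanged_fold` (i.e. |mean log2 ratio| < log2(`unchanged_fold`)).
#' Genes between the two thresholds belong to no set.
#'
#' @param x an [expression_matrix()].
#' @param contrast contrast name.
#' @param sd_multiplier SD multiple defining the regulated threshold.
#' @param alpha t-test significance level.
#' @param unchanged_fold linear fold-change bound defining "unchanged".
#' @return A `response_sets` list: `induced`, `repressed`, `unchanged`
#'   (character vectors), `universe` (usable genes), `thresholds`, `stats`.
#' @export
call_response_sets <- function(x, contrast, sd_multiplier = 1, alpha = 0.05,
                               unchanged_fold = 1.2) {
  check_number(sd_multiplier, "sd_multiplier", lower = 0)
  check_number(alpha, "alpha", lower = 1e-12, upper = 1)
  check_number(unchanged_fold, "unchanged_fold", lower = 1)
  st <- contrast_stats(x, contrast)
  st <- st[st$usable, ]
  if (nrow(st) == 0L) stop2("no usable genes in contrast '", contrast, "'")
  m <- mean(st$mean_log2fc)
  s <- stats::sd(st$mean_log2fc)
  if (!is.finite(s) || s == 0)
    stop2("population SD of mean log2 ratios is zero; thresholds undefined")
  up <- m + sd_multiplier * s
  dn <- m - sd_multiplier * s
  sets <- list(
    induced = st$gene_id[st$mean_log2fc > up & st$p < alpha],
    repressed = st$gene_id[st$mean_log2fc < dn & st$p < alpha],
    unchanged = st$gene_id[abs(st$mean_log2fc) < log2(unchanged_fold)],
    universe = st$gene_id,
    thresholds = list(population_mean = m, population_sd = s,
                      sd_multiplier = sd_multiplier, alpha = alpha,
                      unchanged_fold = unchanged_fold,
                      upper = up, lower = dn),
    stats = st
  )
  structure(sets, class = "response_sets")
}

#' Select coregulator-dependent stress-response genes
#'
#' Dependent-induced genes are stress-induced in wild type but lower in the
#' deletion mutant under stress (mutant/wt contrast called repressed);
#' dependent-repressed genes are stress-repressed in wild type but higher
#' in the mutant (mutant/wt contrast called induced).
#'
#' @param wt_sets [call_response_sets()] result for the wild-type stress
#'   contrast.
#' @param dep_sets [call_response_sets()] result for the mutant/wild-type
#'   stress contrast, built on the same gene universe.
#' @return A `dependency_classes` list: `dependent_induced`,
#'   `dependent_repressed` (character vectors).
#' @export
select_gcn5_dependent <- function(wt_sets, dep_sets) {
  stopifnot(inherits(wt_sets, "response_sets"),
            inherits(dep_sets, "response_sets"))
  if (!setequal(wt_sets$universe, dep_sets$universe))
    stop2("response sets built on different gene universes")
  structure(list(
    dependent_induced = sort(intersect(wt_sets$induced, dep_sets$repressed)),
    dependent_repressed = sort(intersect(wt_sets$repressed, dep_sets$induced))
  ), class = "dependency_classes")
}

#' Compare the spread of dependency effects between conditions
#'
#' Quantifies how much broader the distribution of mutant/wild-type log2
#' ratios becomes under stress: returns the chosen spread statistic of the
#' per-gene mean log2 ratios for each contrast, their plus/minus ratio, and
#' the binned frequency distributions used for plotting.
#'
#' @param x an [expression_matrix()].
#' @param contrast_minus,contrast_plus contrast names (no-stress / stress).
#' @param statistic `"sd"` or `"iqr"`.
#' @param bin_width histogram bin width in log2 units.
#' @return list: `spread_minus`, `spread_plus`, `ratio`, `histogram`
#'   (data frame with bin mids and per-contrast frequencies).
#' @export
dependency_spread <- function(x, contrast_minus, contrast_plus,
                              statistic = c("sd", "iqr"), bin_width = 0.1) {
  statistic <- match.arg(statistic)
  sm <- contrast_stats(x, contrast_minus)
  sp <- contrast_stats(x, contrast_plus)
  vm <- sm$mean_log2fc[sm$usable]
  vp <- sp$mean_log2fc[sp$usable]
  if (length(vm) < 10 || length(vp) < 10)
    stop2("dependency_spread needs at least 10 genes per contrast")
  f <- if (statistic == "sd") stats::sd else function(z) stats::IQR(z)
  spread_minus <- f(vm); spread_plus <- f(vp)
  rng <- range(c(vm, vp))
  breaks <- seq(floor(rng[1] / bin_width) * bin_width,
                ceiling(rng[2] / bin_width) * bin_width + bin_width, bin_width)
  hm <- graphics::hist(vm, breaks = breaks, plot = FALSE)
  hp <- graphics::hist(vp, breaks = breaks, plot = FALSE)
  list(spread_minus = spread_minus, spread_plus = spread_plus,
       ratio = spread_plus / spread_minus, statistic = statistic,
       histogram = data.frame(mid = hm$mids, freq_minus = hm$counts,
                              freq_plus = hp$counts))
}

#' Overlap of a gene set with a reference set
#'
#' Intersection size, fraction of the query covered, and upper-tail
#' hypergeometric p-value of the overlap in the given universe (e.g. the
#' overlap of stress-regulated genes with a general environmental stress
#' response reference list).
#'
#' @param set_a query gene set (non-empty, subset of `universe`).
#' @param reference reference gene set (subset of `universe`).
#' @param universe gene universe.
#' @return list: `intersection`, `n_overlap`, `fraction_of_a`, `p`.
#' @export
overlap_with_reference <- function(set_a, reference, universe) {
  set_a <- unique(set_a); reference <- unique(reference)
  universe <- unique(universe)
  if (length(set_a) == 0L) stop2("set_a is empty")
  if (!all(set_a %in% universe) || !all(reference %in% universe))
    stop2("set_a and reference must be subsets of the universe")
  inter <- intersect(set_a, reference)
  list(intersection = sort(inter),
       n_overlap = length(inter),
       fraction_of_a = length(inter) / length(set_a),
       p = hypergeom_upper(length(inter), n = length(set_a),
                           K = length(reference), N = length(universe)))
}
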