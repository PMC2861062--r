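#' Metagene profile scheme
#'
#' Bin layout for mapping every gene onto a hypothetical gene of average
#' length: fixed-bp flank bins on each side plus length-normalized body
#' bins.
#'
#' @param flank_bp flank width in bp (default 500).
#' @param flank_bins bins per flank (default 10).
#' @param body_bins bins over the gene body (default 40).
#' @param min_probes_per_gene minimum probes within flank+body+flank for a
#'   usable profile (default 5).
#' @return A `profile_scheme` list.
#' @export
profile_scheme <- function(flank_bp = 500, flank_bins = 10, body_bins = 40,
                           min_probes_per_gene = 5) {
  check_number(flank_bp, "flank_bp", lower = 0)
  check_number(flank_bins, "flank_bins", lower = 1)
  check_number(body_bins, "body_bins", lower = 1)
  check_number(min_probes_per_gene, "min_probes_per_gene", lower = 1)
  structure(list(flank_bp = flank_bp, flank_bins = as.integer(flank_bins),
                 body_bins = as.integer(body_bins),
                 min_probes_per_gene = as.integer(min_probes_per_gene)),
            class = "profile_scheme")
}

#' @rdname profile_scheme
#' @param scheme a `profile_scheme`.
#' @return `scheme_bins()`: list of integer index vectors `flank_up`,
#'   `body`, `flank_down` into the profile vector.
#' @export
scheme_bins <- function(scheme) {
  fb <- scheme$flank_bins; bb <- scheme$body_bins
  list(flank_up = seq_len(fb),
       body = fb + seq_len(bb),
       flank_down = fb + bb + seq_len(fb))
}

#' Windowed log-ratio enrichment score
#'
#' Joins IP and input tracks on probe position, drops probes with
#' non-positive raw intensity, and scores each probe with the chosen
#' summary of log2(IP/input) over all probes within +/- `bandwidth`/2 on
#' the same chromosome. A simplified windowed substitute for model-based
#' tiling-array scoring; downstream analysis consumes only relative
#' enrichment.
#'
#' @param ip,input [signal_track()]s of raw intensities sharing a probe grid.
#' @param bandwidth window width in bp (default 250).
#' @param summary `"mean"` or `"trimmed_mean"` (10% trim).
#' @return A [signal_track()] of log2 enrichment scores; attribute
#'   `join_report` counts unmatched and non-positive probes dropped.
#' @export
window_enrichment <- function(ip, input, bandwidth = 250,
                              summary = c("mean", "trimmed_mean")) {
  stopifnot(inherits(ip, "signal_track"), inherits(input, "signal_track"))
  summary <- match.arg(summary)
  check_number(bandwidth, "bandwidth", lower = 0)
  key_ip <- paste(ip$chrom, ip$pos)
  key_in <- paste(input$chrom, input$pos)
  shared <- intersect(key_ip, key_in)
  if (length(shared) == 0L) stop2("IP and input tracks share no probe positions")
  n_unmatched <- (length(key_ip) - length(shared)) +
    (length(key_in) - length(shared))
  i_ip <- match(shared, key_ip); i_in <- match(shared, key_in)
  chrom <- ip$chrom[i_ip]; pos <- ip$pos[i_ip]
  v_ip <- ip$value[i_ip]; v_in <- input$value[i_in]
  pos_ok <- v_ip > 0 & v_in > 0
  n_nonpos <- sum(!pos_ok)
  chrom <- chrom[pos_ok]; pos <- pos[pos_ok]
  logr <- log2(v_ip[pos_ok] / v_in[pos_ok])
  if (length(logr) == 0L) stop2("no probes left after dropping non-positive intensities")
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]; logr <- logr[o]
  half <- bandwidth / 2
  score <- numeric(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    p <- pos[idx]; v <- logr[idx]
    lo <- findInterval(p - half, p, left.open = TRUE) + 1L
    hi <- findInterval(p + half, p)
    if (summary == "mean") {
      cs <- c(0, cumsum(v))
      score[idx] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    } else {
      score[idx] <- vapply(seq_along(p), function(i)
        mean(v[lo[i]:hi[i]], trim = 0.1), numeric(1))
    }
  }
  out <- signal_track(chrom, pos, score,
                      label = paste0(attr(ip, "label") %||% "ip", "_enrichment"),
                      sorted_input = TRUE)
  attr(out, "join_report") <- list(n_unmatched = n_unmatched,
                                   n_nonpositive_dropped = n_nonpos)
  out
}

#' Standardize a track to a reference's mean and SD
#'
#' Affine transform `x -> (x - m_t)/s_t * s_r + m_r` using genome-wide
#' means and SDs, so two conditions' enrichment tracks share the same
#' overall standard deviation and mean value. The reference is unchanged.
#'
#' @param track track to transform.
#' @param reference reference [signal_track()].
#' @return The transformed [signal_track()].
#' @export
standardize_track <- function(track, reference) {
  stopifnot(inherits(track, "signal_track"), inherits(reference, "signal_track"))
  m_t <- mean(track$value); s_t <- stats::sd(track$value)
  m_r <- mean(reference$value); s_r <- stats::sd(reference$value)
  if (!is.finite(s_t) || s_t == 0 || !is.finite(s_r) || s_r == 0)
    stop2("standardize_track requires non-degenerate tracks (SD > 0)")
  out <- track
  out$value <- (track$value - m_t) / s_t * s_r + m_r
  attr(out, "standardization") <- list(mean_track = m_t, sd_track = s_t,
                                       mean_reference = m_r, sd_reference = s_r)
  out
}

profile_bin_index <- function(u, len, scheme) {
  fb <- scheme$flank_bins; bb <- scheme$body_bins; fl <- scheme$flank_bp
  bin <- rep(NA_integer_, length(u))
  up <- u >= -fl & u < 0
  bin[up] <- 1L + pmin(fb - 1L, floor((u[up] + fl) / fl * fb))
  body <- u >= 0 & u < len
  bin[body] <- fb + 1L + pmin(bb - 1L, floor(u[body] / len * bb))
  down <- u >= len & u < len + fl
  bin[down] <- fb + bb + 1L + pmin(fb - 1L, floor((u[down] - len) / fl * fb))
  bin
}

#' Per-gene positional profile
#'
#' Maps probe signal around one gene onto the fixed metagene coordinate:
#' the upstream flank `[tss - flank_bp, tss)` split into `flank_bins` equal
#' bins, the body `[tss, tes)` into `body_bins` equal fractional-length
#' bins, and the downstream flank likewise; probe values are averaged per
#' bin. Bin 1 is always 5'-most (minus-strand genes are flipped). Bins
#' without probes are `NA`; genes with fewer than `min_probes_per_gene`
#' probes in the window (or on a chromosome absent from the track) are
#' marked unusable with a reason code.
#'
#' @param track a [signal_track()] of enrichment scores.
#' @param gene one row of a [gene_annotation()].
#' @param scheme a [profile_scheme()].
#' @return A `positional_profile`: list with `gene_id`, `bins`, `coverage`,
#'   `usable`, `reason`.
#' @export
gene_profile <- function(track, gene, scheme = profile_scheme()) {
  stopifnot(inherits(track, "signal_track"))
  n_bins <- 2L * scheme$flank_bins + scheme$body_bins
  empty <- function(reason) structure(
    list(gene_id = gene$gene_id, bins = rep(NA_real_, n_bins),
         coverage = integer(n_bins), usable = FALSE, reason = reason),
    class = "positional_profile")
  tc <- track_chrom(track, gene$chrom)
  if (length(tc$pos) == 0L) return(empty("chromosome_absent"))
  lo <- gene$start - scheme$flank_bp
  hi <- gene$end + scheme$flank_bp
  sel <- tc$pos >= lo & tc$pos < hi
  if (sum(sel) < scheme$min_probes_per_gene) return(empty("too_few_probes"))
  pos <- tc$pos[sel]; val <- tc$value[sel]
  u <- if (gene$strand == "+") pos - gene$tss else gene$tss - pos - 1
  bin <- profile_bin_index(u, gene$length, scheme)
  ok <- !is.na(bin)
  bins <- rep(NA_real_, n_bins); coverage <- integer(n_bins)
  if (any(ok)) {
    agg <- tapply(val[ok], bin[ok], mean)
    idx <- as.integer(names(agg))
    bins[idx] <- as.numeric(agg)
    cnt <- table(bin[ok])
    coverage[as.integer(names(cnt))] <- as.integer(cnt)
  }
  structure(list(gene_id = gene$gene_id, bins = bins, coverage = coverage,
                 usable = TRUE, reason = NA_character_),
            class = "positional_profile")
}

#' Positional profiles for every gene
#'
#' @param track a [signal_track()] of enrichment scores.
#' @param genes a [gene_annotation()].
#' @param scheme a [profile_scheme()].
#' @return A `profile_set`: named list of `positional_profile`s.
#' @export
gene_profiles <- function(track, genes, scheme = profile_scheme()) {
  stopifnot(inherits(genes, "gene_annotation"))
  out <- lapply(seq_len(nrow(genes)), function(i)
    gene_profile(track, genes[i, ], scheme))
  names(out) <- genes$gene_id
  structure(out, class = "profile_set", scheme = scheme)
}

#' Profile matrix from a profile set
#'
#' Stacks usable per-gene profiles into a genes x bins matrix. Bins without
#' probe coverage are `NA`; `fill` controls how they are handled before
#' analyses that need complete vectors: `"drop"` removes genes with any
#' missing bin, `"interpolate"` fills missing bins by linear interpolation
#' over the bin index (the standard resampling step when genes much shorter
#' than the bin grid are mapped onto a model gene; genes with fewer than 2
#' covered bins are dropped), `"none"` keeps the `NA`s.
#'
#' @param profiles a `profile_set`.
#' @param fill `"drop"` (default), `"interpolate"` or `"none"`.
#' @return numeric matrix, genes x bins (usable genes only).
#' @export
profile_matrix <- function(profiles, fill = c("drop", "interpolate", "none")) {
  fill <- match.arg(fill)
  usable <- Filter(function(p) p$usable, profiles)
  if (length(usable) == 0L) stop2("no usable profiles")
  m <- do.call(rbind, lapply(usable, function(p) p$bins))
  rownames(m) <- vapply(usable, function(p) p$gene_id, character(1))
  if (fill == "drop") {
    m <- m[stats::complete.cases(m), , drop = FALSE]
  } else if (fill == "interpolate" && anyNA(m)) {
    keep <- rowSums(!is.na(m)) >= 2L
    m <- m[keep, , drop = FALSE]
    for (i in which(!stats::complete.cases(m))) {
      row <- m[i, ]
      ok <- which(!is.na(row))
      m[i, ] <- stats::approx(ok, row[ok], xout = seq_along(row), rule = 2)$y
    }
  }
  m
}

#' Average (metagene) profile over a gene group
#'
#' Bin-wise mean over the usable member profiles; a bin's mean uses only
#' genes with probe coverage there. Per-bin SEM and per-bin n are reported.
#'
#' @param profiles a `profile_set` from [gene_profiles()].
#' @param group gene IDs to average (default all).
#' @param group_label label for the group.
#' @return A `metagene_profile`: list with `group_label`, `mean`, `sem`,
#'   `n_genes`, `n_per_bin`.
#' @export
metagene_average <- function(profiles, group = names(profiles),
                             group_label = "all") {
  members <- profiles[intersect(names(profiles), group)]
  members <- Filter(function(p) p$usable, members)
  if (length(members) == 0L) stop2("no usable profiles in group '", group_label, "'")
  m <- do.call(rbind, lapply(members, function(p) p$bins))
  n_per_bin <- colSums(!is.na(m))
  mu <- suppressWarnings(colMeans(m, na.rm = TRUE))
  mu[n_per_bin == 0] <- NA_real_
  sem <- apply(m, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 2) return(NA_real_)
    stats::sd(col) / sqrt(length(col))
  })
  structure(list(group_label = group_label, mean = mu, sem = sem,
                 n_genes = length(members), n_per_bin = n_per_bin),
            class = "metagene_profile")
}

#' Group genes for metagene averaging
#'
#' Three grouping modes: `regulation` uses induced/repressed/unchanged
#' calls from [call_response_sets()]; `expression_tertile` splits genes
#' into equal-count tertiles of mean signal intensity (ties broken by gene
#' ID for determinism); `length_bins` groups by ORF length with default
#' bins short (< 500 bp), 500-1000, 1000-2000 (upper bound inclusive) and
#' long (> 2000 bp).
#'
#' @param genes a [gene_annotation()].
#' @param by grouping mode.
#' @param response_sets a `response_sets` (for `by = "regulation"`).
#' @param mean_intensity named positive vector (for `expression_tertile`).
#' @return named list of gene ID character vectors.
#' @export
group_genes <- function(genes, by = c("regulation", "expression_tertile",
                                      "length_bins"),
                        response_sets = NULL, mean_intensity = NULL) {
  stopifnot(inherits(genes, "gene_annotation"))
  by <- match.arg(by)
  ids <- genes$gene_id
  if (by == "regulation") {
    if (!inherits(response_sets, "response_sets"))
      stop2("grouping by regulation requires a response_sets object")
    list(induced = intersect(ids, response_sets$induced),
         repressed = intersect(ids, response_sets$repressed),
         unchanged = intersect(ids, response_sets$unchanged))
  } else if (by == "expression_tertile") {
    if (is.null(mean_intensity)) stop2("expression_tertile requires mean_intensity")
    mi <- mean_intensity[ids]
    if (any(is.na(mi))) stop2("mean_intensity missing for some genes")
    if (length(ids) < 3L) stop2("fewer genes than groups")
    o <- ids[order(mi, ids)]
    k <- length(o)
    cut1 <- floor(k / 3); cut2 <- floor(2 * k / 3)
    list(low = o[seq_len(cut1)],
         mid = o[(cut1 + 1):cut2],
         high = o[(cut2 + 1):k])
  } else {
    len <- genes$length
    # short is strictly < 500, long strictly > 2000; inner boundary at 1000
    grp <- ifelse(len < 500, "lt500",
           ifelse(len < 1000, "500-1000",
           ifelse(len <= 2000, "1000-2000", "gt2000")))
    split(ids, factor(grp, levels = c("lt500", "500-1000", "1000-2000", "gt2000")))
  }
}

#' Call bound genes from two standardized enrichment tracks
#'
#' A gene is called bound if its maximum windowed enrichment within
#' flank+body+flank strictly exceeds `threshold_log2` in BOTH conditions.
#' Genes with no probe coverage in either track are excluded and counted.
#'
#' @param track_a,track_b standardized enrichment [signal_track()]s.
#' @param genes a [gene_annotation()].
#' @param threshold_log2 strict log2 threshold (default 1.4, i.e. 2.6-fold).
#' @param flank_bp flank width defining the per-gene window.
#' @param summary `"max"` (default) or `"mean"` of in-window scores.
#' @return character vector of bound gene IDs; attribute `n_excluded`
#'   counts genes without coverage.
#' @export
call_bound_genes <- function(track_a, track_b, genes, threshold_log2 = 1.4,
                             flank_bp = 500, summary = c("max", "mean")) {
  stopifnot(inherits(genes, "gene_annotation"))
  summary <- match.arg(summary)
  f <- if (summary == "max") max else mean
  gene_score <- function(track, gene) {
    tc <- track_chrom(track, gene$chrom)
    sel <- tc$pos >= gene$start - flank_bp & tc$pos < gene$end + flank_bp
    if (!any(sel)) return(NA_real_)
    f(tc$value[sel])
  }
  bound <- character(0); n_excluded <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    sa <- gene_score(track_a, g); sb <- gene_score(track_b, g)
    if (is.na(sa) || is.na(sb)) { n_excluded <- n_excluded + 1L; next }
    if (sa > threshold_log2 && sb > threshold_log2) bound <- c(bound, g$gene_id)
  }
  attr(bound, "n_excluded") <- n_excluded
  bound
}
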