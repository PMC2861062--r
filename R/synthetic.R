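#' Simulate a compact single-chromosome genome annotation
#'
#' Genes are laid end-to-end with a fixed intergenic gap on one synthetic
#' chromosome, alternating strands. Lengths are drawn uniformly within
#' three ORF-length categories: short (< 500 bp), medium (500-2000 bp) and
#' long (> 2000 bp, capped at `long_max`). Category counts follow a
#' deterministic largest-remainder allocation of `proportions`, and the
#' category order along the chromosome is shuffled by `seed`.
#'
#' @param n_genes number of genes (>= 1).
#' @param proportions length-3 numeric (short, medium, long), summing to 1.
#' @param intergenic_gap gap between consecutive genes, bp (> 0).
#' @param seed integer seed; identical seeds give identical output.
#' @param long_max maximum long-gene length, bp.
#' @param chrom chromosome name.
#' @return A [gene_annotation()] with an extra `length_category` attribute
#'   (character vector named by gene).
#' @export
simulate_genome <- function(n_genes, proportions = c(0.25, 0.5, 0.25),
                            intergenic_gap = 200, seed = 1,
                            long_max = 6000, chrom = "chrS1") {
  if (n_genes < 1) stop2("n_genes must be >= 1")
  if (intergenic_gap <= 0) stop2("intergenic_gap must be positive")
  if (length(proportions) != 3L || any(proportions < 0) ||
      abs(sum(proportions) - 1) > 1e-8)
    stop2("proportions must be 3 non-negative numbers summing to 1")
  # largest-remainder allocation: exact, deterministic
  raw <- proportions * n_genes
  counts <- floor(raw)
  rem <- n_genes - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  set.seed(seed)
  cats <- sample(rep(c("short", "medium", "long"), counts))
  len <- integer(n_genes)
  len[cats == "short"] <- sample(100:499, sum(cats == "short"), replace = TRUE)
  len[cats == "medium"] <- sample(500:2000, sum(cats == "medium"), replace = TRUE)
  len[cats == "long"] <- sample(2001:long_max, sum(cats == "long"), replace = TRUE)
  start <- cumsum(c(intergenic_gap, utils::head(len, -1) + intergenic_gap))
  ann <- gene_annotation(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    chrom = chrom,
    strand = rep_len(c("+", "-"), n_genes),
    start = start, end = start + len
  )
  attr(ann, "length_category") <- stats::setNames(cats, ann$gene_id)
  ann
}

ARCHETYPES <- c("promoter_peaked", "body_enriched", "uniform", "unbound")

#' Plant per-gene truth labels for the synthetic study
#'
#' Assigns each gene an occupancy archetype per condition, an expression
#' class and a coregulator-dependency class, with planted effect sizes.
#' The default occupancy plan emulates stress-driven redistribution: in the
#' untreated condition (A) enrichment sits on short genes (body-enriched on
#' their short ORFs) while long genes carry only a promoter peak; under
#' stress (B) the signal swaps so body enrichment concentrates on long-gene
#' transcribed regions and short genes retain only a promoter peak. Medium
#' genes are stable promoter-peaked anchors, so both conditions contain the
#' same well-shaped cluster archetypes.
#'
#' @param genes a [gene_annotation()] from [simulate_genome()] (its
#'   `length_category` attribute drives the occupancy plan).
#' @param frac_induced,frac_repressed fractions of genes planted as
#'   stress-induced / stress-repressed (rest unchanged).
#' @param frac_dependent fraction of induced (resp. repressed) genes whose
#'   response requires the coregulator.
#' @param effect_size planted |log2 fold change| for regulated genes.
#' @param amplitude planted log2 enrichment at the occupancy peak.
#' @param occupancy_a,occupancy_b named character vectors mapping length
#'   category (short/medium/long) to an archetype, per condition.
#' @param seed integer seed.
#' @return A `synthetic_truth` data frame: `gene_id`, `length_category`,
#'   `archetype_a`, `archetype_b`, `expression_class`, `dependency_class`,
#'   `effect_size`, `amplitude`.
#' @export
simulate_truth <- function(genes,
                           frac_induced = 0.1, frac_repressed = 0.1,
                           frac_dependent = 0.4,
                           effect_size = 2, amplitude = 2,
                           occupancy_a = c(short = "body_enriched",
                                           medium = "promoter_peaked",
                                           long = "promoter_peaked"),
                           occupancy_b = c(short = "promoter_peaked",
                                           medium = "promoter_peaked",
                                           long = "body_enriched"),
                           seed = 1) {
  stopifnot(inherits(genes, "gene_annotation"))
  if (effect_size <= 0) stop2("effect_size must be positive")
  if (!all(occupancy_a %in% ARCHETYPES) || !all(occupancy_b %in% ARCHETYPES))
    stop2("occupancy archetypes must be one of: ",
          paste(ARCHETYPES, collapse = ", "))
  cat_by_gene <- attr(genes, "length_category")
  if (is.null(cat_by_gene)) {
    cat_by_gene <- cut(genes$length, c(-Inf, 500, 2000, Inf),
                       labels = c("short", "medium", "long"), right = FALSE)
    cat_by_gene <- stats::setNames(as.character(cat_by_gene), genes$gene_id)
    cat_by_gene[genes$length == 2000] <- "medium"   # long is strictly > 2000
  }
  n <- nrow(genes)
  set.seed(seed)
  expr_class <- rep("unchanged", n)
  n_ind <- round(frac_induced * n); n_rep <- round(frac_repressed * n)
  picks <- sample.int(n, n_ind + n_rep)
  expr_class[picks[seq_len(n_ind)]] <- "induced"
  expr_class[picks[n_ind + seq_len(n_rep)]] <- "repressed"
  dep_class <- rep("independent", n)
  ind_idx <- which(expr_class == "induced")
  rep_idx <- which(expr_class == "repressed")
  if (length(ind_idx) > 0 && frac_dependent > 0)
    dep_class[sample(ind_idx, round(frac_dependent * length(ind_idx)))] <-
      "dependent_induced"
  if (length(rep_idx) > 0 && frac_dependent > 0)
    dep_class[sample(rep_idx, round(frac_dependent * length(rep_idx)))] <-
      "dependent_repressed"
  truth <- data.frame(
    gene_id = genes$gene_id,
    length_category = unname(cat_by_gene[genes$gene_id]),
    archetype_a = unname(occupancy_a[cat_by_gene[genes$gene_id]]),
    archetype_b = unname(occupancy_b[cat_by_gene[genes$gene_id]]),
    expression_class = expr_class,
    dependency_class = dep_class,
    effect_size = effect_size,
    amplitude = amplitude,
    stringsAsFactors = FALSE
  )
  class(truth) <- c("synthetic_truth", "data.frame")
  truth
}

#' @rdname simulate_truth
#' @param truth a `synthetic_truth`.
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname simulate_truth
#' @export
read_truth <- function(path) {
  truth <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  class(truth) <- c("synthetic_truth", "data.frame")
  truth
}

archetype_shape <- function(archetype, pos, gene, amplitude, flank,
                            peak_sd = 150) {
  switch(archetype,
    promoter_peaked = amplitude * exp(-((pos - gene$tss)^2) / (2 * peak_sd^2)),
    body_enriched = amplitude * as.numeric(pos >= gene$start & pos < gene$end),
    uniform = amplitude * as.numeric(pos >= gene$start - flank &
                                       pos < gene$end + flank),
    unbound = numeric(length(pos)),
    stop2("unknown archetype: ", archetype)
  )
}

#' Simulate tiling-array IP and input tracks
#'
#' A regular probe grid covers the chromosome plus `flank` on each side.
#' The input channel is flat (log2 intensity 0) plus Gaussian noise; the IP
#' channel adds, per gene, the occupancy archetype shape planted in `truth`
#' for the requested condition, scaled to the planted amplitude:
#' a Gaussian promoter peak (sd 150 bp) centred on the TSS, a plateau over
#' the gene body, a plateau over flank+body+flank, or nothing. Shapes of
#' adjacent genes are summed where probe windows overlap, as on a real
#' array. Tracks hold raw (linear-scale) intensities `2^log2value`.
#'
#' @param genes a [gene_annotation()].
#' @param truth a `synthetic_truth` from [simulate_truth()].
#' @param condition `"a"` (untreated) or `"b"` (stress).
#' @param probe_spacing probe grid spacing, bp (>= 1).
#' @param noise_sd per-channel log2 noise SD (>= 0).
#' @param flank flank width covered around each gene, bp.
#' @param peak_sd promoter peak SD, bp.
#' @param seed integer seed.
#' @return list of two [signal_track()]s: `ip` and `input`.
#' @export
simulate_chip <- function(genes, truth, condition = c("a", "b"),
                          probe_spacing = 50, noise_sd = 0.25,
                          flank = 500, peak_sd = 150, seed = 1) {
  stopifnot(inherits(genes, "gene_annotation"),
            inherits(truth, "synthetic_truth"))
  condition <- match.arg(condition)
  if (probe_spacing < 1) stop2("probe_spacing must be >= 1")
  if (noise_sd < 0) stop2("noise_sd must be >= 0")
  arch_col <- if (condition == "a") "archetype_a" else "archetype_b"
  arch <- stats::setNames(truth[[arch_col]], truth$gene_id)
  amp <- stats::setNames(truth$amplitude, truth$gene_id)
  chrom <- unique(genes$chrom)
  all_pos <- list(); all_chrom <- list(); all_shape <- list()
  for (ch in chrom) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    lo <- max(0, min(g$start) - flank)
    hi <- max(g$end) + flank
    pos <- seq(lo, hi, by = probe_spacing)
    shape <- numeric(length(pos))
    for (i in seq_len(nrow(g))) {
      gi <- g[i, ]
      near <- pos >= gi$start - flank - 4 * peak_sd &
              pos < gi$end + flank + 4 * peak_sd
      if (!any(near)) next
      shape[near] <- shape[near] +
        archetype_shape(arch[[gi$gene_id]], pos[near], gi,
                        amp[[gi$gene_id]], flank, peak_sd)
    }
    all_pos[[ch]] <- pos
    all_chrom[[ch]] <- rep(ch, length(pos))
    all_shape[[ch]] <- shape
  }
  pos <- unlist(all_pos, use.names = FALSE)
  chv <- unlist(all_chrom, use.names = FALSE)
  shape <- unlist(all_shape, use.names = FALSE)
  set.seed(seed)
  noise_ip <- stats::rnorm(length(pos), 0, noise_sd)
  noise_in <- stats::rnorm(length(pos), 0, noise_sd)
  list(
    ip = signal_track(chv, pos, 2^(shape + noise_ip),
                      label = paste0("ip_", condition), sorted_input = TRUE),
    input = signal_track(chv, pos, 2^noise_in,
                         label = paste0("input_", condition),
                         sorted_input = TRUE)
  )
}

#' Simulate a replicated expression matrix with planted classes
#'
#' Emits four channels: the stress-response contrast `wt_kcl`
#' (stress vs. untreated in wild type), the baseline dependency contrast
#' `mut_vs_wt_ctrl` (mutant vs. wild type, untreated; null), the stress
#' dependency contrast `mut_vs_wt_kcl` (mutant vs. wild type under stress),
#' and a lognormal mean-intensity channel for expression-level grouping.
#' Replicate log2 ratios are Normal(mu, `noise_sd`): mu is +/-`effect_size`
#' for planted induced/repressed genes in `wt_kcl`, -`effect_size` for
#' dependent-induced and +`effect_size` for dependent-repressed genes in
#' `mut_vs_wt_kcl`, and 0 otherwise (optionally Normal(0, `null_sd`) for a
#' wide null).
#'
#' @param genes a [gene_annotation()].
#' @param truth a `synthetic_truth`.
#' @param noise_sd replicate log2 noise SD.
#' @param n_replicates replicates per contrast (>= 2).
#' @param null_sd SD of gene-level true means for unplanted effects
#'   (default 0: pure null).
#' @param intensity_meanlog,intensity_sdlog lognormal parameters of the
#'   mean-intensity channel.
#' @param seed integer seed.
#' @return An [expression_matrix()].
#' @export
simulate_expression <- function(genes, truth, noise_sd = 0.25,
                                n_replicates = 4, null_sd = 0,
                                intensity_meanlog = 7, intensity_sdlog = 1,
                                seed = 1) {
  stopifnot(inherits(genes, "gene_annotation"),
            inherits(truth, "synthetic_truth"))
  if (n_replicates < 2) stop2("n_replicates must be >= 2 (t-test undefined)")
  n <- nrow(genes)
  truth <- truth[match(genes$gene_id, truth$gene_id), ]
  es <- truth$effect_size
  mu_wt <- ifelse(truth$expression_class == "induced", es,
                  ifelse(truth$expression_class == "repressed", -es, 0))
  mu_dep <- ifelse(truth$dependency_class == "dependent_induced", -es,
                   ifelse(truth$dependency_class == "dependent_repressed", es, 0))
  set.seed(seed)
  if (null_sd > 0) {
    wide <- stats::rnorm(n, 0, null_sd)
    mu_wt <- mu_wt + ifelse(truth$expression_class == "unchanged", wide, 0)
  }
  draw <- function(mu) {
    m <- matrix(stats::rnorm(n * n_replicates, rep(mu, n_replicates), noise_sd),
                nrow = n, dimnames = list(genes$gene_id, NULL))
    m
  }
  contrasts <- list(
    wt_kcl = draw(mu_wt),
    mut_vs_wt_ctrl = draw(rep(0, n)),
    mut_vs_wt_kcl = draw(mu_dep)
  )
  mi <- stats::rlnorm(n, intensity_meanlog, intensity_sdlog)
  names(mi) <- genes$gene_id
  expression_matrix(contrasts, mean_intensity = mi)
}
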