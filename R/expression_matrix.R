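#' Construct an expression matrix
#'
#' Gene x replicate log2 ratio tables for named contrasts (e.g. the
#' stress-response contrast `wt_kcl` and the mutant-dependency contrast
#' `mut_vs_wt_kcl`), plus an optional positive mean-intensity channel used
#' for intensity-dependent normalization and expression-level grouping.
#'
#' @param contrasts named list of numeric matrices; each has one row per
#'   gene (rownames = gene IDs) and >= 2 replicate columns.
#' @param mean_intensity optional named positive numeric vector over genes.
#' @return An `expression_matrix` (list with `genes`, `contrasts`,
#'   `mean_intensity`).
#' @export
expression_matrix <- function(contrasts, mean_intensity = NULL) {
  if (!is.list(contrasts) || is.null(names(contrasts)) || any(names(contrasts) == ""))
    stop2("'contrasts' must be a named list of matrices")
  genes <- rownames(contrasts[[1]])
  if (is.null(genes)) stop2("contrast matrices must have gene rownames")
  for (nm in names(contrasts)) {
    m <- contrasts[[nm]]
    if (!is.matrix(m)) stop2("contrast '", nm, "' is not a matrix")
    if (ncol(m) < 2L) stop2("contrast '", nm, "' has fewer than 2 replicates")
    if (!identical(rownames(m), genes))
      stop2("contrast '", nm, "' gene rownames differ from the first contrast")
  }
  if (!is.null(mean_intensity)) {
    mean_intensity <- mean_intensity[genes]
    if (any(is.na(mean_intensity)) || any(mean_intensity <= 0))
      stop2("mean_intensity must be positive and cover every gene")
    names(mean_intensity) <- genes
  }
  structure(list(genes = genes, contrasts = contrasts,
                 mean_intensity = mean_intensity),
            class = "expression_matrix")
}

#' Per-gene summary statistics for one contrast
#'
#' Mean log2 fold change, one-sample two-sided t statistic and p-value of
#' the replicate log2 ratios against 0 (no multiple-testing correction).
#' Genes with any missing replicate are flagged `usable = FALSE` and carry
#' NA statistics.
#'
#' @param x an [expression_matrix()].
#' @param contrast contrast name.
#' @return data frame: `gene_id`, `mean_log2fc`, `t`, `p`, `n_rep`, `usable`.
#' @export
contrast_stats <- function(x, contrast) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!contrast %in% names(x$contrasts))
    stop2("unknown contrast '", contrast, "'")
  m <- x$contrasts[[contrast]]
  usable <- rowSums(is.na(m)) == 0L
  n <- ncol(m)
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  se <- sdv / sqrt(n)
  t <- mu / se
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  # degenerate zero-variance rows: certain effect if mean != 0, certain null if 0
  zero <- usable & sdv == 0
  p[zero & mu != 0] <- .Machine$double.xmin
  t[zero & mu != 0] <- sign(mu[zero & mu != 0]) * Inf
  p[zero & mu == 0] <- 1
  t[zero & mu == 0] <- 0
  mu[!usable] <- NA_real_; t[!usable] <- NA_real_; p[!usable] <- NA_real_
  data.frame(gene_id = x$genes, mean_log2fc = mu, t = t, p = p,
             n_rep = n, usable = usable, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Read/write an expression matrix as long-format TSV
#'
#' Columns: `gene_id`, `contrast`, `replicate`, `log2_ratio`. The optional
#' intensity channel is stored under the reserved contrast name
#' `.mean_intensity` with a single replicate. Round-trips at 6 significant
#' digits.
#'
#' @param x an [expression_matrix()].
#' @param path TSV path.
#' @return `path` invisibly / an `expression_matrix`.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  rows <- lapply(names(x$contrasts), function(nm) {
    m <- x$contrasts[[nm]]
    data.frame(gene_id = rep(rownames(m), ncol(m)),
               contrast = nm,
               replicate = rep(seq_len(ncol(m)), each = nrow(m)),
               log2_ratio = signif(as.vector(m), 6),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (!is.null(x$mean_intensity)) {
    df <- rbind(df, data.frame(gene_id = x$genes, contrast = ".mean_intensity",
                               replicate = 1L,
                               log2_ratio = signif(x$mean_intensity, 6),
                               stringsAsFactors = FALSE))
  }
  ok <- tryCatch(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                    row.names = FALSE),
                 error = function(e) stop2("failed writing ", path, ": ",
                                           conditionMessage(e)))
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop2("expression TSV not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "contrast", "replicate", "log2_ratio")
  if (!all(need %in% colnames(df)))
    stop2("expression TSV ", path, " must have columns: ",
          paste(need, collapse = ", "))
  intens <- df[df$contrast == ".mean_intensity", ]
  df <- df[df$contrast != ".mean_intensity", ]
  if (nrow(df) == 0L) stop2("no contrast rows in ", path)
  genes <- unique(df$gene_id)
  contrasts <- lapply(split(df, df$contrast), function(d) {
    reps <- sort(unique(d$replicate))
    m <- matrix(NA_real_, nrow = length(genes), ncol = length(reps),
                dimnames = list(genes, NULL))
    m[cbind(match(d$gene_id, genes), match(d$replicate, reps))] <- d$log2_ratio
    m
  })
  mi <- NULL
  if (nrow(intens) > 0L) {
    mi <- stats::setNames(intens$log2_ratio, intens$gene_id)[genes]
  }
  expression_matrix(contrasts, mean_intensity = mi)
}

#' Write per-gene or metagene profile tables as TSV
#'
#' Per-gene profile matrices are written genes x bins; metagene profiles
#' one row per bin with mean, SEM and per-bin n. Round-trips at 6
#' significant digits via [read_profile_table()].
#'
#' @param x a profile matrix (genes x bins) or a `metagene_profile`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_metagene_table <- function(x, path) {
  if (inherits(x, "metagene_profile")) {
    df <- data.frame(bin = seq_along(x$mean) - 1L,
                     mean = signif(x$mean, 6), sem = signif(x$sem, 6),
                     n = x$n_per_bin)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    m <- as.matrix(x)
    df <- data.frame(gene_id = rownames(m), signif(m, 6),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("gene_id", paste0("bin", seq_len(ncol(m)) - 1L))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_metagene_table
#' @export
read_profile_table <- function(path) {
  if (!file.exists(path)) stop2("profile table not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
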