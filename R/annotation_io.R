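#' Construct a gene annotation set
#'
#' The coordinate backbone for all profiling: one row per gene with
#' chromosome, strand and 0-based half-open start/end, plus derived ORF
#' length and strand-aware TSS/TES.
#'
#' @param gene_id unique character IDs.
#' @param chrom chromosome names.
#' @param strand "+" or "-" per gene.
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @return A `gene_annotation` data frame with columns `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `length`, `tss`, `tes`.
#' @export
gene_annotation <- function(gene_id, chrom, strand, start, end) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    stop2("duplicate gene_id values: ",
          paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-")))
    stop2("strand must be '+' or '-' for every gene")
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)) || any(start >= end))
    stop2("every gene must satisfy start < end (0-based half-open)")
  ann <- data.frame(
    gene_id = gene_id, chrom = as.character(chrom), strand = strand,
    start = start, end = end,
    length = end - start,
    tss = ifelse(strand == "+", start, end),
    tes = ifelse(strand == "+", end, start),
    stringsAsFactors = FALSE
  )
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Read gene annotations from GFF3 or BED
#'
#' GFF3 (1-based inclusive) and BED (0-based half-open) are both converted
#' to the internal 0-based half-open convention on read.
#'
#' @param path file path.
#' @param format `"gff3"` or `"bed"`; default guessed from the extension.
#' @param feature_type GFF3 feature type to keep (default `"gene"`).
#' @param id_attribute GFF3 attribute holding the gene ID; the first of
#'   `ID`, `gene_id`, `Name` that is present is used when `NULL`.
#' @return A [gene_annotation()] object.
#' @export
read_gene_annotation <- function(path, format = c("gff3", "bed"),
                                 feature_type = "gene", id_attribute = NULL) {
  if (!file.exists(path)) stop2("annotation file not found: ", path)
  if (missing(format))
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  format <- match.arg(format)
  gr <- tryCatch(
    if (format == "gff3") rtracklayer::import(path, format = "gff3")
    else rtracklayer::import(path, format = "bed"),
    error = function(e) stop2("failed to parse ", path, " as ", format, ": ",
                              conditionMessage(e)))
  if (format == "gff3") {
    keep <- as.character(gr$type) == feature_type
    gr <- gr[keep]
    if (length(gr) == 0L)
      stop2("no records of feature type '", feature_type, "' in ", path)
    md <- S4Vectors::mcols(gr)
    if (is.null(id_attribute)) {
      id_attribute <- intersect(c("ID", "gene_id", "Name"), colnames(md))[1]
      if (is.na(id_attribute)) stop2("no ID/gene_id/Name attribute in ", path)
    }
    ids <- as.character(md[[id_attribute]])
  } else {
    ids <- as.character(gr$name)
  }
  if (any(is.na(ids)) || any(ids == ""))
    stop2("missing gene identifiers in ", path)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop2("missing strand in ", path)
  # GRanges are 1-based inclusive regardless of source dialect
  gene_annotation(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Construct a signal track
#'
#' Per-chromosome sorted (position, value) series holding probe-level
#' intensities or derived log2 enrichment scores. Positions at identical
#' coordinates are averaged; non-finite values are dropped and counted in
#' `attr(x, "load_report")`.
#'
#' @param chrom,pos,value parallel vectors.
#' @param label track label.
#' @param sorted_input if `FALSE` (default) positions are sorted per
#'   chromosome; out-of-order input triggers a warning.
#' @return A `signal_track` data frame (`chrom`, `pos`, `value`), positions
#'   strictly increasing within each chromosome.
#' @export
signal_track <- function(chrom, pos, value, label = "signal",
                         sorted_input = FALSE) {
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  value <- as.numeric(value)
  bad <- !is.finite(value) | !is.finite(pos)
  n_dropped <- sum(bad)
  if (n_dropped > 0L) {
    chrom <- chrom[!bad]; pos <- pos[!bad]; value <- value[!bad]
  }
  if (length(pos) == 0L) stop2("signal track '", label, "' is empty")
  o <- order(chrom, pos)
  if (!sorted_input) {
    disordered <- any(unlist(tapply(pos, chrom, is.unsorted, simplify = FALSE)))
    if (disordered)
      warning("positions not sorted in track '", label, "'; sorting",
              call. = FALSE)
  }
  chrom <- chrom[o]; pos <- pos[o]; value <- value[o]
  key <- paste(chrom, pos)
  n_ties <- 0L
  if (anyDuplicated(key)) {
    n_ties <- sum(duplicated(key))
    agg <- tapply(value, key, mean)
    first <- !duplicated(key)
    value <- as.numeric(agg[key[first]])
    chrom <- chrom[first]; pos <- pos[first]
  }
  tr <- data.frame(chrom = chrom, pos = pos, value = value,
                   stringsAsFactors = FALSE)
  class(tr) <- c("signal_track", "data.frame")
  attr(tr, "label") <- label
  attr(tr, "load_report") <- list(n_dropped_nonfinite = n_dropped,
                                  n_tied_positions = n_ties)
  tr
}

#' Read a probe signal track from bedGraph or WIG
#'
#' bedGraph intervals are collapsed to their midpoint position (the pipeline
#' is probe-centric); overlapping intervals whose midpoints coincide are
#' averaged with a warning. Fixed- and variable-step WIG are supported; WIG
#' 1-based positions are converted to the internal 0-based convention.
#' Non-finite values are dropped and counted in the load report.
#'
#' @inheritParams read_gene_annotation
#' @param format `"bedgraph"` or `"wig"`; default guessed from the extension.
#' @param label track label; default the file name.
#' @return A [signal_track()].
#' @export
read_signal_track <- function(path, format = c("bedgraph", "wig"),
                              label = basename(path)) {
  if (!file.exists(path)) stop2("signal file not found: ", path)
  if (missing(format))
    format <- if (grepl("\\.wig$", path, ignore.case = TRUE)) "wig" else "bedgraph"
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|track|browser|$)", lines)]
  if (format == "bedgraph") {
    if (length(lines) == 0L) stop2("empty bedGraph file: ", path)
    parts <- strsplit(lines, "\\s+")
    nf <- lengths(parts)
    if (any(nf < 4L))
      stop2("unparseable bedGraph line ", which(nf < 4L)[1], " in ", path)
    m <- matrix(unlist(lapply(parts, `[`, 1:4)), ncol = 4, byrow = TRUE)
    s <- suppressWarnings(as.numeric(m[, 2])); e <- suppressWarnings(as.numeric(m[, 3]))
    if (any(is.na(s) | is.na(e)))
      stop2("non-numeric coordinates in bedGraph line ",
            which(is.na(s) | is.na(e))[1], " in ", path)
    v <- suppressWarnings(as.numeric(m[, 4]))
    pos <- floor((s + e) / 2)
    key <- paste(m[, 1], pos)
    if (anyDuplicated(key)) {
      dupv <- tapply(v, key, function(z) length(unique(z[is.finite(z)])) > 1L)
      if (any(dupv, na.rm = TRUE))
        warning("overlapping bedGraph intervals with conflicting values in ",
                path, "; averaging at shared midpoints", call. = FALSE)
    }
    return(signal_track(m[, 1], pos, v, label = label))
  }
  # WIG
  if (length(lines) == 0L) stop2("empty WIG file: ", path)
  chroms <- character(0); positions <- numeric(0); values <- numeric(0)
  mode <- NULL; cur_chrom <- NA_character_; fs_pos <- NA_real_; fs_step <- NA_real_
  get_field <- function(line, field) {
    m <- regmatches(line, regexec(paste0(field, "=(\\S+)"), line))[[1]]
    if (length(m) < 2L) NA_character_ else m[2]
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^variableStep", ln)) {
      mode <- "variable"; cur_chrom <- get_field(ln, "chrom")
      if (is.na(cur_chrom)) stop2("WIG line ", i, ": variableStep without chrom")
    } else if (grepl("^fixedStep", ln)) {
      mode <- "fixed"; cur_chrom <- get_field(ln, "chrom")
      fs_pos <- as.numeric(get_field(ln, "start"))
      fs_step <- as.numeric(get_field(ln, "step"))
      if (is.na(cur_chrom) || is.na(fs_pos) || is.na(fs_step))
        stop2("WIG line ", i, ": fixedStep needs chrom, start and step")
    } else if (is.null(mode)) {
      stop2("WIG line ", i, ": data before any step declaration in ", path)
    } else if (mode == "variable") {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 2L) stop2("unparseable WIG line ", i, " in ", path)
      p <- suppressWarnings(as.numeric(f[1]))
      if (is.na(p)) stop2("unparseable WIG line ", i, " in ", path)
      chroms <- c(chroms, cur_chrom)
      positions <- c(positions, p - 1)        # WIG is 1-based
      values <- c(values, suppressWarnings(as.numeric(f[2])))
    } else {
      chroms <- c(chroms, cur_chrom)
      positions <- c(positions, fs_pos - 1)
      values <- c(values, suppressWarnings(as.numeric(trimws(ln))))
      fs_pos <- fs_pos + fs_step
    }
  }
  if (length(positions) == 0L) stop2("no data lines in WIG file: ", path)
  signal_track(chroms, positions, values, label = label)
}

#' Write a signal track as bedGraph
#'
#' Each probe becomes a 1-bp interval `[pos, pos + 1)` so that the midpoint
#' rule of [read_signal_track()] recovers the probe position exactly.
#'
#' @param track a [signal_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal_track <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  df <- data.frame(track$chrom, format(track$pos, scientific = FALSE, trim = TRUE),
                   format(track$pos + 1, scientific = FALSE, trim = TRUE),
                   signif(track$value, 10))
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) stop2("failed writing ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Subset a signal track to one chromosome
#' @param track a [signal_track()].
#' @param chrom chromosome name.
#' @return list with numeric vectors `pos` and `value` (possibly empty).
#' @export
track_chrom <- function(track, chrom) {
  i <- track$chrom == chrom
  list(pos = track$pos[i], value = track$value[i])
}

#' Read an ortholog pair map
#'
#' Two-column TSV of one-to-one ("unambiguous") ortholog pairs; an ID
#' repeated on either side is a load error.
#'
#' @param path TSV path (optional header `id_species1`, `id_species2`).
#' @return An `ortholog_map` data frame with columns `id_species1`,
#'   `id_species2`.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) stop2("ortholog map not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop2("ortholog map must have two columns: ", path)
  if (identical(tolower(df[1, 1]), "id_species1")) df <- df[-1, , drop = FALSE]
  ortholog_map(df[[1]], df[[2]])
}

#' @rdname read_ortholog_map
#' @param id_species1,id_species2 paired ID vectors.
#' @export
ortholog_map <- function(id_species1, id_species2) {
  id_species1 <- as.character(id_species1); id_species2 <- as.character(id_species2)
  if (length(id_species1) != length(id_species2))
    stop2("ortholog map columns have unequal length")
  if (anyDuplicated(id_species1) || anyDuplicated(id_species2))
    stop2("ortholog map is not one-to-one: duplicated IDs present")
  om <- data.frame(id_species1 = id_species1, id_species2 = id_species2,
                   stringsAsFactors = FALSE)
  class(om) <- c("ortholog_map", "data.frame")
  om
}

#' @rdname read_ortholog_map
#' @param map an `ortholog_map`.
#' @export
write_ortholog_map <- function(map, path) {
  stopifnot(inherits(map, "ortholog_map"))
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GMT term-to-gene map
#'
#' Each line is `term_id<TAB>term_name<TAB>gene1<TAB>gene2...`; every term
#' must have at least one gene.
#'
#' @param path GMT file path.
#' @return A `term_map`: named list of `list(name =, genes =)`.
#' @export
read_term_map <- function(path) {
  if (!file.exists(path)) stop2("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop2("empty GMT file: ", path)
  terms <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop2("GMT line ", i, " has no genes in ", path)
    terms[[f[1]]] <- list(name = f[2], genes = unique(f[-(1:2)]))
  }
  class(terms) <- "term_map"
  terms
}

#' @rdname read_term_map
#' @param terms a `term_map`.
#' @export
write_term_map <- function(terms, path) {
  stopifnot(inherits(terms, "term_map"))
  lines <- vapply(names(terms), function(id) {
    paste(c(id, terms[[id]]$name, terms[[id]]$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write gene annotations as GFF3
#' @param ann a [gene_annotation()].
#' @param path output path.
#' @param feature_type GFF3 feature type to emit.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(ann, path, feature_type = "gene") {
  stopifnot(inherits(ann, "gene_annotation"))
  lines <- c("##gff-version 3",
             sprintf("%s\tcoregshift\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     ann$chrom, feature_type, ann$start + 1L, ann$end,
                     ann$strand, ann$gene_id))
  writeLines(lines, path)
  invisible(path)
}
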