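#' Build and validate a pipeline configuration
#'
#' Collects every input path and analysis threshold in one validated
#' object. The config round-trips losslessly through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param genes path to the gene annotation (GFF3 or BED).
#' @param expression path to the long-format expression TSV.
#' @param chip named list, one entry per condition (`a`, `b`), each a list
#'   with `ip` and `input` bedGraph/WIG paths.
#' @param outdir output directory.
#' @param contrasts named list: `wt` (stress response contrast), `dep`
#'   (mutant/wt stress contrast), `dep_baseline` (mutant/wt untreated).
#' @param orthologs optional list: `map` (2-column TSV path), `set2` (TSV
#'   path with columns gene_id, direction for the second species' set).
#' @param terms optional GMT path for term enrichment.
#' @param reference_set optional path to a reference gene list (one ID per
#'   line), e.g. general stress-response genes.
#' @param normalization `"median_center"` or `"lowess_ma"`.
#' @param sd_multiplier,alpha,unchanged_fold regulated/unchanged-call
#'   thresholds (see [call_response_sets()]).
#' @param enrich_alpha term-enrichment significance threshold.
#' @param bound_threshold_log2 strict bound-gene threshold (log2).
#' @param bandwidth enrichment window width, bp.
#' @param k,iterations,restarts k-means parameters.
#' @param scheme a [profile_scheme()] or list of its fields.
#' @param seed integer master seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(genes, expression, chip, outdir,
                            contrasts = list(wt = "wt_kcl",
                                             dep = "mut_vs_wt_kcl",
                                             dep_baseline = "mut_vs_wt_ctrl"),
                            orthologs = NULL, terms = NULL,
                            reference_set = NULL,
                            normalization = "median_center",
                            sd_multiplier = 1, alpha = 0.05,
                            unchanged_fold = 1.2, enrich_alpha = 0.02,
                            bound_threshold_log2 = 1.4, bandwidth = 250,
                            k = 5, iterations = 100, restarts = 20,
                            scheme = profile_scheme(), seed = 17) {
  if (!normalization %in% c("median_center", "lowess_ma"))
    stop2("config field 'normalization' must be median_center or lowess_ma")
  check_number(sd_multiplier, "sd_multiplier", lower = 0)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stop2("config field 'alpha' must lie in (0, 1]")
  if (!is.numeric(enrich_alpha) || enrich_alpha <= 0 || enrich_alpha > 1)
    stop2("config field 'enrich_alpha' must lie in (0, 1]")
  check_number(unchanged_fold, "unchanged_fold", lower = 1)
  check_number(bound_threshold_log2, "bound_threshold_log2")
  check_number(bandwidth, "bandwidth", lower = 1)
  check_number(k, "k", lower = 2)
  check_number(iterations, "iterations", lower = 1)
  check_number(restarts, "restarts", lower = 1)
  check_number(seed, "seed")
  if (!is.list(chip) || !all(c("a", "b") %in% names(chip)))
    stop2("config field 'chip' needs conditions 'a' and 'b'")
  for (cond in c("a", "b"))
    if (!all(c("ip", "input") %in% names(chip[[cond]])))
      stop2("chip condition '", cond, "' needs 'ip' and 'input' paths")
  if (!all(c("wt", "dep", "dep_baseline") %in% names(contrasts)))
    stop2("contrasts must name 'wt', 'dep' and 'dep_baseline'")
  if (!inherits(scheme, "profile_scheme"))
    scheme <- do.call(profile_scheme, as.list(scheme))
  structure(list(
    genes = genes, expression = expression, chip = chip, outdir = outdir,
    contrasts = contrasts, orthologs = orthologs, terms = terms,
    reference_set = reference_set, normalization = normalization,
    sd_multiplier = sd_multiplier, alpha = alpha,
    unchanged_fold = unchanged_fold, enrich_alpha = enrich_alpha,
    bound_threshold_log2 = bound_threshold_log2, bandwidth = bandwidth,
    k = as.integer(k), iterations = as.integer(iterations),
    restarts = as.integer(restarts), scheme = scheme,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$scheme <- unclass(x$scheme)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop2("config file not found: ", path)
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full redistribution analysis pipeline
#'
#' Executes the nine stages in order: expression calls and dependency
#' classes; enrichment scoring and cross-condition standardization;
#' metagene profiling per condition; profile clustering per condition;
#' cluster matching; redistribution summary; and set enrichment (terms,
#' reference overlap and ortholog comparison where inputs are configured).
#' Every stage's outputs are md5-hashed into the returned manifest;
#' identical config and seed give identical hashes.
#'
#' @param config a [pipeline_config()] or YAML path.
#' @param dry_run if TRUE, validate the config and input files and return
#'   the stage plan without computing anything.
#' @return A `run_manifest` list: `stages` (name, outputs, md5 per stage),
#'   `config`, `seed`, `package_version`. Also written as
#'   `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- c(config$genes, config$expression,
              config$chip$a$ip, config$chip$a$input,
              config$chip$b$ip, config$chip$b$input,
              config$orthologs$map, config$orthologs$set2,
              config$terms, config$reference_set)
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in))
    stop2("missing input file(s): ", paste(missing_in, collapse = ", "))
  stage_names <- c("express", "standardize", "metagene_a", "metagene_b",
                   "cluster_a", "cluster_b", "match", "redistribution",
                   "enrich")
  if (dry_run) {
    # parse headers only
    read_gene_annotation(config$genes)
    read_expression_matrix(config$expression)
    return(structure(list(stages = lapply(stage_names, function(s)
      list(name = s, outputs = character(0), md5 = character(0))),
      config = config, seed = config$seed, dry_run = TRUE,
      package_version = as.character(utils::packageVersion("coregshift"))),
      class = "run_manifest"))
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "pipeline.log")
  logf <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  stages <- list()
  add_stage <- function(name, outputs) {
    md5 <- unname(tools::md5sum(outputs))
    stages[[name]] <<- list(name = name,
                            outputs = basename(outputs), md5 = md5)
    logf("stage ", name, ": ", length(outputs), " output(s)")
  }

  genes <- read_gene_annotation(config$genes)
  expr <- read_expression_matrix(config$expression)

  ## 1 express -----------------------------------------------------------
  expr <- normalize_ratios(expr, method = config$normalization)
  wt_sets <- call_response_sets(expr, config$contrasts$wt,
                                sd_multiplier = config$sd_multiplier,
                                alpha = config$alpha,
                                unchanged_fold = config$unchanged_fold)
  dep_sets <- call_response_sets(expr, config$contrasts$dep,
                                 sd_multiplier = config$sd_multiplier,
                                 alpha = config$alpha,
                                 unchanged_fold = config$unchanged_fold)
  dependency <- select_gcn5_dependent(wt_sets, dep_sets)
  spread <- dependency_spread(expr, config$contrasts$dep_baseline,
                              config$contrasts$dep)
  call_table <- function(sets, contrast) {
    st <- sets$stats
    st$call <- "intermediate"
    st$call[st$gene_id %in% sets$induced] <- "induced"
    st$call[st$gene_id %in% sets$repressed] <- "repressed"
    st$call[st$gene_id %in% sets$unchanged] <- "unchanged"
    st$contrast <- contrast
    st[, c("gene_id", "contrast", "mean_log2fc", "t", "p", "call")]
  }
  f_calls <- write_tsv(rbind(call_table(wt_sets, config$contrasts$wt),
                             call_table(dep_sets, config$contrasts$dep)),
                       file.path(outdir, "expression_calls.tsv"))
  dep_df <- data.frame(
    gene_id = c(dependency$dependent_induced, dependency$dependent_repressed),
    class = rep(c("dependent_induced", "dependent_repressed"),
                c(length(dependency$dependent_induced),
                  length(dependency$dependent_repressed))))
  f_dep <- write_tsv(dep_df, file.path(outdir, "dependency_classes.tsv"))
  f_spread <- file.path(outdir, "dependency_spread.json")
  jsonlite::write_json(spread[c("spread_minus", "spread_plus", "ratio",
                                "statistic")],
                       f_spread, auto_unbox = TRUE, digits = NA)
  out_express <- c(f_calls, f_dep, f_spread)
  if (!is.null(config$reference_set)) {
    ref <- readLines(config$reference_set, warn = FALSE)
    ref <- intersect(ref, wt_sets$universe)
    regulated <- union(wt_sets$induced, wt_sets$repressed)
    if (length(regulated) > 0 && length(ref) > 0) {
      ov <- overlap_with_reference(regulated, ref, wt_sets$universe)
      f_ref <- file.path(outdir, "reference_overlap.json")
      jsonlite::write_json(ov[c("n_overlap", "fraction_of_a", "p")], f_ref,
                           auto_unbox = TRUE, digits = NA)
      out_express <- c(out_express, f_ref)
    }
  }
  add_stage("express", out_express)

  ## 2 standardize --------------------------------------------------------
  read_tr <- function(p) read_signal_track(p)
  enr_a <- window_enrichment(read_tr(config$chip$a$ip),
                             read_tr(config$chip$a$input),
                             bandwidth = config$bandwidth)
  enr_b <- window_enrichment(read_tr(config$chip$b$ip),
                             read_tr(config$chip$b$input),
                             bandwidth = config$bandwidth)
  enr_b <- standardize_track(enr_b, enr_a)
  f_enr_a <- file.path(outdir, "enrichment_a.bedgraph")
  f_enr_b <- file.path(outdir, "enrichment_b.bedgraph")
  write_signal_track(enr_a, f_enr_a)
  write_signal_track(enr_b, f_enr_b)
  bound <- call_bound_genes(enr_a, enr_b, genes,
                            threshold_log2 = config$bound_threshold_log2,
                            flank_bp = config$scheme$flank_bp)
  f_bound <- write_tsv(data.frame(gene_id = bound),
                       file.path(outdir, "bound_genes.tsv"))
  f_std <- file.path(outdir, "standardization.json")
  jsonlite::write_json(attr(enr_b, "standardization"), f_std,
                       auto_unbox = TRUE, digits = NA)
  add_stage("standardize", c(f_enr_a, f_enr_b, f_bound, f_std))

  ## 3-4 metagene per condition ------------------------------------------
  scheme <- config$scheme
  groups <- c(
    group_genes(genes, "length_bins"),
    group_genes(genes, "regulation", response_sets = wt_sets),
    if (!is.null(expr$mean_intensity))
      group_genes(genes, "expression_tertile",
                  mean_intensity = expr$mean_intensity)
  )
  metagene_stage <- function(enr, cond) {
    profs <- gene_profiles(enr, genes, scheme)
    f_prof <- write_metagene_table(profile_matrix(profs, fill = "none"),
                                   file.path(outdir, paste0("profiles_", cond, ".tsv")))
    f_groups <- character(0)
    for (gname in names(groups)) {
      if (length(intersect(groups[[gname]], names(profs))) == 0) next
      mg <- tryCatch(metagene_average(profs, groups[[gname]], gname),
                     error = function(e) NULL)
      if (is.null(mg)) next
      f <- write_metagene_table(mg,
             file.path(outdir, paste0("metagene_", cond, "_", gname, ".tsv")))
      f_groups <- c(f_groups, f)
    }
    list(profiles = profs, outputs = c(f_prof, f_groups))
  }
  ma <- metagene_stage(enr_a, "a")
  add_stage("metagene_a", ma$outputs)
  mb <- metagene_stage(enr_b, "b")
  add_stage("metagene_b", mb$outputs)

  ## 5-6 cluster per condition -------------------------------------------
  pm_a <- profile_matrix(ma$profiles, fill = "interpolate")
  pm_b <- profile_matrix(mb$profiles, fill = "interpolate")
  cl_a <- kmeans_profiles(pm_a, k = config$k, iterations = config$iterations,
                          restarts = config$restarts, seed = config$seed,
                          condition_label = "a")
  cl_b <- kmeans_profiles(pm_b, k = config$k, iterations = config$iterations,
                          restarts = config$restarts, seed = config$seed + 1L,
                          condition_label = "b")
  cluster_stage <- function(cl, cond) {
    f_lab <- write_tsv(data.frame(gene_id = names(cl$labels),
                                  cluster = unname(cl$labels)),
                       file.path(outdir, paste0("clusters_", cond, ".tsv")))
    cent <- data.frame(cluster = seq_len(cl$k), signif(cl$centroids, 6))
    f_cen <- write_tsv(cent, file.path(outdir, paste0("centroids_", cond, ".tsv")))
    c(f_lab, f_cen)
  }
  add_stage("cluster_a", cluster_stage(cl_a, "a"))
  add_stage("cluster_b", cluster_stage(cl_b, "b"))

  ## 7 match --------------------------------------------------------------
  matching <- match_clusters(cl_a, cl_b)
  f_match <- write_tsv(as.data.frame(matching),
                       file.path(outdir, "cluster_matching.tsv"))
  add_stage("match", f_match)

  ## 8 redistribution ------------------------------------------------------
  rs <- redistribution_summary(cl_a, cl_b, matching, pm_a, pm_b,
                               scheme = scheme, genes = genes)
  f_flow <- write_tsv(as.data.frame.matrix(unclass(rs$flow)),
                      file.path(outdir, "label_flow.tsv"))
  f_assoc <- write_tsv(rs$association_change,
                       file.path(outdir, "association_change.tsv"))
  f_rsum <- file.path(outdir, "redistribution.json")
  jsonlite::write_json(list(body_shift_a = rs$body_shift_a,
                            body_shift_b = rs$body_shift_b,
                            n_common = rs$n_common),
                       f_rsum, auto_unbox = TRUE, digits = NA)
  out_redist <- c(f_flow, f_assoc, f_rsum)
  if (!is.null(rs$enrichment_a)) {
    f_en <- write_tsv(rbind(cbind(condition = "a", category = "long",
                                  rs$enrichment_a$long),
                            cbind(condition = "a", category = "short",
                                  rs$enrichment_a$short),
                            cbind(condition = "b", category = "long",
                                  rs$enrichment_b$long),
                            cbind(condition = "b", category = "short",
                                  rs$enrichment_b$short)),
                      file.path(outdir, "cluster_length_enrichment.tsv"))
    out_redist <- c(out_redist, f_en)
  }
  add_stage("redistribution", out_redist)

  ## 9 enrich ---------------------------------------------------------------
  out_enrich <- character(0)
  dep_all <- c(dependency$dependent_induced, dependency$dependent_repressed)
  if (!is.null(config$terms) && length(dep_all) > 0) {
    terms <- read_term_map(config$terms)
    te <- term_enrichment(dep_all, terms, universe = wt_sets$universe,
                          alpha = config$enrich_alpha)
    out_enrich <- c(out_enrich,
                    write_tsv(te, file.path(outdir, "term_enrichment.tsv")))
  }
  if (!is.null(config$orthologs) && length(dep_all) > 0) {
    omap <- read_ortholog_map(config$orthologs$map)
    s2 <- utils::read.table(config$orthologs$set2, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    dir1 <- stats::setNames(
      rep(c("induced", "repressed"),
          c(length(dependency$dependent_induced),
            length(dependency$dependent_repressed))), dep_all)
    dir2 <- stats::setNames(s2$direction, s2$gene_id)
    oo <- ortholog_overlap(dep_all, s2$gene_id, dir1, dir2, omap)
    f_oo <- file.path(outdir, "ortholog_overlap.json")
    jsonlite::write_json(oo[c("n1", "n2", "N", "observed",
                              "observed_undirected", "expected",
                              "expected_concordant", "p")],
                         f_oo, auto_unbox = TRUE, digits = NA)
    out_enrich <- c(out_enrich, f_oo)
  }
  if (length(out_enrich) == 0) {
    f_note <- file.path(outdir, "enrichment_skipped.json")
    jsonlite::write_json(list(note = "no terms/orthologs configured or no dependent genes"),
                         f_note, auto_unbox = TRUE)
    out_enrich <- f_note
  }
  add_stage("enrich", out_enrich)

  manifest <- structure(list(
    stages = stages[stage_names],
    config = unclass(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("coregshift"))
  ), class = "run_manifest")
  mj <- manifest
  mj$config$scheme <- unclass(mj$config$scheme)
  jsonlite::write_json(unclass(mj), file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  manifest
}

#' Generate the bundled demo inputs and run the whole pipeline
#'
#' Simulates a small truth-labelled genome (annotation, two-condition
#' tiling IP/input tracks, replicated expression matrix, ortholog map,
#' term map and a reference gene list), writes the inputs as standard
#' files, then runs [run_pipeline()] on them. Deterministic given `seed`.
#'
#' @param outdir output directory (inputs under `inputs/`, results under
#'   `results/`).
#' @param seed integer master seed.
#' @param n_genes demo genome size (default 300).
#' @param noise_sd expression/ChIP noise SD (log2 units).
#' @return the `run_manifest`, with the truth table path attached as
#'   attribute `truth`.
#' @export
run_demo <- function(outdir, seed = 17, n_genes = 300, noise_sd = 0.25) {
  indir <- file.path(outdir, "inputs")
  dir.create(indir, showWarnings = FALSE, recursive = TRUE)
  genes <- simulate_genome(n_genes, seed = seed)
  truth <- simulate_truth(genes, seed = seed + 1L)
  chip_a <- simulate_chip(genes, truth, "a", noise_sd = noise_sd,
                          seed = seed + 2L)
  chip_b <- simulate_chip(genes, truth, "b", noise_sd = noise_sd,
                          seed = seed + 3L)
  expr <- simulate_expression(genes, truth, noise_sd = noise_sd,
                              seed = seed + 4L)
  f_genes <- file.path(indir, "genes.gff3")
  write_gene_annotation(genes, f_genes)
  f_truth <- write_truth(truth, file.path(indir, "truth.tsv"))
  paths <- list(a = list(), b = list())
  for (cond in c("a", "b")) {
    ch <- if (cond == "a") chip_a else chip_b
    for (wch in c("ip", "input")) {
      f <- file.path(indir, paste0(wch, "_", cond, ".bedgraph"))
      write_signal_track(ch[[wch]], f)
      paths[[cond]][[wch]] <- f
    }
  }
  f_expr <- file.path(indir, "expression.tsv")
  write_expression_matrix(expr, f_expr)
  # ortholog map over half the genes, plus a second-species response set
  set.seed(seed + 5L)
  mapped <- sort(sample(genes$gene_id, floor(n_genes / 2)))
  omap <- ortholog_map(mapped, sub("^g", "p", mapped))
  f_omap <- write_ortholog_map(omap, file.path(indir, "orthologs.tsv"))
  dep_genes <- truth$gene_id[truth$dependency_class != "independent"]
  s2_ids <- sub("^g", "p", sample(dep_genes, min(10, length(dep_genes))))
  s2_extra <- setdiff(sample(omap$id_species2, 20), s2_ids)
  s2 <- data.frame(
    gene_id = c(s2_ids, s2_extra),
    direction = sample(c("induced", "repressed"),
                       length(s2_ids) + length(s2_extra), replace = TRUE))
  f_s2 <- write_tsv(s2, file.path(indir, "species2_set.tsv"))
  # term map: one term enriched in dependent genes, plus random terms
  terms <- list(
    T001 = list(name = "planted_dependent_module",
                genes = sample(dep_genes, min(15, length(dep_genes)))),
    T002 = list(name = "random_module_1", genes = sample(genes$gene_id, 25)),
    T003 = list(name = "random_module_2", genes = sample(genes$gene_id, 40))
  )
  class(terms) <- "term_map"
  f_terms <- write_term_map(terms, file.path(indir, "terms.gmt"))
  ref <- unique(c(truth$gene_id[truth$expression_class != "unchanged" &
                                  stats::runif(nrow(truth)) < 0.5],
                  sample(genes$gene_id, 30)))
  f_ref <- file.path(indir, "reference_genes.txt")
  writeLines(sort(ref), f_ref)
  config <- pipeline_config(
    genes = f_genes, expression = f_expr,
    chip = paths, outdir = file.path(outdir, "results"),
    orthologs = list(map = f_omap, set2 = f_s2),
    terms = f_terms, reference_set = f_ref, seed = seed)
  write_pipeline_config(config, file.path(indir, "config.yaml"))
  manifest <- run_pipeline(config)
  attr(manifest, "truth") <- f_truth
  manifest
}
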