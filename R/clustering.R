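row_standardize <- function(m) {
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  list(z = (m - mu) / sdv, sd = sdv)
}

# Pearson correlation of each z-scored row of `z` with one z-scored centroid
cor_to_centroid <- function(z, centroid) {
  p <- ncol(z)
  mu <- mean(centroid)
  sdv <- stats::sd(centroid)
  if (!is.finite(sdv) || sdv == 0) return(rep(0, nrow(z)))  # degenerate: uncorrelated
  cz <- (centroid - mu) / sdv
  as.numeric(z %*% cz) / (p - 1)
}

#' K-means clustering of positional profiles with correlation distance
#'
#' Lloyd iterations using distance `1 - Pearson(x, centroid)` ("standard
#' correlation" similarity). Internally each profile is z-scored (Pearson
#' correlation is invariant to per-profile affine maps), which makes the
#' arithmetic-mean centroid the exact minimiser of summed correlation
#' distance, so the objective is non-increasing and is asserted at every
#' iteration. The best of `restarts` k-means++-style seeded initializations
#' (by final objective) is returned; results are deterministic given `seed`
#' and invariant to input row order (rows are sorted by gene ID first).
#' Zero-variance profiles (correlation undefined) are dropped and reported;
#' profiles with missing bins are dropped or mean-imputed per `missing`.
#'
#' @param profiles numeric gene x bin matrix with gene ID rownames.
#' @param k number of clusters (default 5).
#' @param iterations maximum Lloyd iterations per restart (default 100).
#' @param restarts number of seeded restarts (default 20).
#' @param seed integer seed.
#' @param missing `"drop"` (default) or `"impute_mean"` for missing bins.
#' @param condition_label label stored on the result.
#' @return A `cluster_assignment`: list with `condition_label`, `labels`
#'   (named integer vector), `centroids` (k x bins, arithmetic means of raw
#'   member profiles), `objective`, `objective_trace`, `restart`,
#'   `dropped` (gene IDs removed), `k`, `seed`.
#' @export
kmeans_profiles <- function(profiles, k = 5, iterations = 100, restarts = 20,
                            seed = 1, missing = c("drop", "impute_mean"),
                            condition_label = "condition") {
  missing <- match.arg(missing)
  m <- as.matrix(profiles)
  if (is.null(rownames(m))) stop2("profiles must have gene ID rownames")
  m <- m[order(rownames(m)), , drop = FALSE]
  dropped <- character(0)
  if (anyNA(m)) {
    if (missing == "drop") {
      bad <- !stats::complete.cases(m)
      dropped <- c(dropped, rownames(m)[bad])
      m <- m[!bad, , drop = FALSE]
    } else {
      for (i in which(!stats::complete.cases(m))) {
        row <- m[i, ]
        row[is.na(row)] <- mean(row, na.rm = TRUE)
        m[i, ] <- row
      }
    }
  }
  sdv <- apply(m, 1, stats::sd)
  degenerate <- !is.finite(sdv) | sdv == 0
  if (any(degenerate)) {
    dropped <- c(dropped, rownames(m)[degenerate])
    m <- m[!degenerate, , drop = FALSE]
  }
  n <- nrow(m)
  if (k < 2) stop2("k must be >= 2")
  if (k > n) stop2("k (", k, ") exceeds usable genes (", n, ")")
  z <- row_standardize(m)$z
  p <- ncol(z)

  corr_dist_to_rows <- function(idx) {
    # 1 - Pearson between every row and the rows in idx (matrix n x |idx|)
    1 - (z %*% t(z[idx, , drop = FALSE])) / (p - 1)
  }

  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    # k-means++ style init on correlation distance
    centers_idx <- sample.int(n, 1L)
    while (length(centers_idx) < k) {
      d <- corr_dist_to_rows(centers_idx)
      dmin <- apply(d, 1, min)
      dmin[centers_idx] <- 0
      w <- pmax(dmin, 0)
      if (sum(w) <= 0) {   # all remaining points coincide with a center
        w <- as.numeric(!seq_len(n) %in% centers_idx)
      }
      centers_idx <- c(centers_idx, sample.int(n, 1L, prob = w))
    }
    centroids_z <- z[centers_idx, , drop = FALSE]
    labels <- rep(0L, n)
    trace <- numeric(0)
    prev_obj <- Inf
    for (it in seq_len(iterations)) {
      corr <- vapply(seq_len(k), function(j)
        cor_to_centroid(z, centroids_z[j, ]), numeric(n))
      d <- 1 - corr
      new_labels <- max.col(-d, ties.method = "first")
      # refill empty clusters with the gene farthest from its centroid
      for (j in seq_len(k)) {
        if (!any(new_labels == j)) {
          far <- which.max(d[cbind(seq_len(n), new_labels)])
          new_labels[far] <- j
          d[far, ] <- 0  # its own cluster now; distance irrelevant this pass
        }
      }
      obj <- sum(vapply(seq_len(k), function(j) {
        mem <- new_labels == j
        if (!any(mem)) return(0)
        cen <- colMeans(z[mem, , drop = FALSE])
        sum(1 - cor_to_centroid(z[mem, , drop = FALSE], cen))
      }, numeric(1)))
      if (obj > prev_obj + 1e-9)
        stop2("internal error: k-means objective increased (",
              prev_obj, " -> ", obj, ")")
      trace <- c(trace, obj)
      converged <- identical(new_labels, labels)
      labels <- new_labels
      centroids_z <- t(vapply(seq_len(k), function(j)
        colMeans(z[labels == j, , drop = FALSE]), numeric(p)))
      prev_obj <- obj
      if (converged) break
    }
    if (is.null(best) || prev_obj < best$objective - 1e-12) {
      best <- list(labels = labels, objective = prev_obj, restart = r,
                   trace = trace)
    }
  }
  labels <- stats::setNames(best$labels, rownames(m))
  centroids <- t(vapply(seq_len(k), function(j)
    colMeans(m[best$labels == j, , drop = FALSE]), numeric(p)))
  rownames(centroids) <- paste0("cluster", seq_len(k))
  structure(list(condition_label = condition_label, labels = labels,
                 centroids = centroids, objective = best$objective,
                 objective_trace = best$trace, restart = best$restart,
                 dropped = dropped, k = k, seed = seed),
            class = "cluster_assignment")
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    block <- matrix(rest[sub], nrow = nrow(sub))
    out[r:(r + nrow(sub) - 1L), ] <- cbind(rep(i, nrow(sub)), block)
    r <- r + nrow(sub)
  }
  out
}

#' Match clusters across conditions by centroid correlation
#'
#' Finds the bijection between the two assignments' clusters that
#' maximizes total centroid-to-centroid Pearson correlation, by exact
#' exhaustive search over assignments (k <= 8). Degenerate (zero-variance)
#' centroids are matched last with an undefined (NA) score.
#'
#' @param a,b `cluster_assignment`s with equal profile length and equal k.
#' @return A `cluster_matching`: data frame with columns `cluster_a`,
#'   `cluster_b`, `score`; attribute `total_score`.
#' @export
match_clusters <- function(a, b) {
  stopifnot(inherits(a, "cluster_assignment"), inherits(b, "cluster_assignment"))
  if (ncol(a$centroids) != ncol(b$centroids))
    stop2("centroid profile lengths differ")
  if (a$k != b$k) stop2("cluster counts differ (rectangular matching not supported)")
  k <- a$k
  if (k > 8) stop2("exhaustive matching supports k <= 8")
  S <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ca <- a$centroids[i, ]; cb <- b$centroids[j, ]
    if (stats::sd(ca) > 0 && stats::sd(cb) > 0)
      S[i, j] <- stats::cor(ca, cb)
  }
  S_use <- S
  S_use[is.na(S_use)] <- -1.5   # below any correlation: matched last
  perms <- all_permutations(k)
  scores <- perms
  tot <- vapply(seq_len(nrow(perms)), function(r)
    sum(S_use[cbind(seq_len(k), perms[r, ])]), numeric(1))
  bestp <- perms[which.max(tot), ]
  out <- data.frame(cluster_a = seq_len(k), cluster_b = bestp,
                    score = S[cbind(seq_len(k), bestp)])
  attr(out, "total_score") <- max(tot)
  class(out) <- c("cluster_matching", "data.frame")
  out
}

#' Length-category enrichment of each cluster
#'
#' Upper-tail hypergeometric enrichment of a gene-length category in each
#' cluster, over the universe of clustered genes.
#'
#' @param assign a `cluster_assignment`.
#' @param genes a [gene_annotation()].
#' @param category gene ID character vector, or a predicate function on
#'   gene length in bp (e.g. `function(l) l > 2000`).
#' @param universe gene universe (default: all clustered genes).
#' @return data frame: `cluster`, `n`, `x`, `K`, `N`, `expected`, `p`.
#' @export
cluster_length_enrichment <- function(assign, genes, category,
                                      universe = names(assign$labels)) {
  stopifnot(inherits(assign, "cluster_assignment"),
            inherits(genes, "gene_annotation"))
  if (is.function(category)) {
    category <- genes$gene_id[category(genes$length)]
  }
  category <- intersect(unique(category), universe)
  if (length(category) == 0L) stop2("category is empty within the universe")
  N <- length(universe); K <- length(category)
  rows <- lapply(seq_len(assign$k), function(j) {
    members <- intersect(names(assign$labels)[assign$labels == j], universe)
    n <- length(members)
    x <- length(intersect(members, category))
    data.frame(cluster = j, n = n, x = x, K = K, N = N,
               expected = n * K / N,
               p = if (n == 0) 1 else hypergeom_upper(x, n = n, K = K, N = N))
  })
  do.call(rbind, rows)
}

#' Summarize coregulator redistribution between conditions
#'
#' Combines two cluster assignments over a common gene set into: (i) the
#' k x k label-flow matrix (rows: condition-A cluster; columns: condition-B
#' cluster relabelled through the matching so the diagonal holds stable
#' genes), (ii) per matched cluster pair the change in mean association
#' (mean per-gene profile average, condition B - A), (iii) length-category
#' enrichment tables for both conditions when an annotation is supplied,
#' and (iv) a signed body-shift statistic per condition: the mean over
#' genes of (body-bin mean - flank-bin mean).
#'
#' @param a,b `cluster_assignment`s for the two conditions.
#' @param matching a `cluster_matching` from [match_clusters()].
#' @param profiles_a,profiles_b gene x bin profile matrices per condition.
#' @param scheme the [profile_scheme()] used to build the profiles.
#' @param genes optional [gene_annotation()] for composition enrichment.
#' @param long_predicate,short_predicate length predicates for the
#'   composition tables.
#' @return A `redistribution_summary` list: `flow` (matched), `flow_raw`,
#'   `association_change`, `body_shift_a`, `body_shift_b`,
#'   `enrichment_a`, `enrichment_b`, `n_common`.
#' @export
redistribution_summary <- function(a, b, matching, profiles_a, profiles_b,
                                   scheme = profile_scheme(), genes = NULL,
                                   long_predicate = function(l) l > 2000,
                                   short_predicate = function(l) l < 500) {
  stopifnot(inherits(a, "cluster_assignment"), inherits(b, "cluster_assignment"),
            inherits(matching, "cluster_matching"))
  common <- intersect(names(a$labels), names(b$labels))
  if (length(common) == 0L) stop2("assignments share no genes")
  k <- a$k
  la <- a$labels[common]
  lb <- b$labels[common]
  # map condition-B labels to matched condition-A slots
  b_to_slot <- stats::setNames(matching$cluster_a, matching$cluster_b)
  lb_matched <- unname(b_to_slot[as.character(lb)])
  flow_raw <- table(factor(la, levels = seq_len(k)),
                    factor(lb, levels = seq_len(k)))
  flow <- table(factor(la, levels = seq_len(k)),
                factor(lb_matched, levels = seq_len(k)))
  dimnames(flow) <- list(cluster_a = paste0("A", seq_len(k)),
                         matched_b = paste0("A", seq_len(k)))
  assoc <- vapply(seq_len(nrow(matching)), function(r) {
    i <- matching$cluster_a[r]; j <- matching$cluster_b[r]
    ga <- intersect(names(a$labels)[a$labels == i], rownames(profiles_a))
    gb <- intersect(names(b$labels)[b$labels == j], rownames(profiles_b))
    mean(rowMeans(profiles_b[gb, , drop = FALSE]), na.rm = TRUE) -
      mean(rowMeans(profiles_a[ga, , drop = FALSE]), na.rm = TRUE)
  }, numeric(1))
  bins <- scheme_bins(scheme)
  body_shift <- function(m) {
    body <- rowMeans(m[, bins$body, drop = FALSE], na.rm = TRUE)
    flank <- rowMeans(m[, c(bins$flank_up, bins$flank_down), drop = FALSE],
                      na.rm = TRUE)
    mean(body - flank, na.rm = TRUE)
  }
  enrich <- function(assign) {
    if (is.null(genes)) return(NULL)
    safe <- function(pred) tryCatch(
      cluster_length_enrichment(assign, genes, pred),
      error = function(e) NULL)   # category absent from the clustered universe
    list(long = safe(long_predicate), short = safe(short_predicate))
  }
  structure(list(
    flow = flow, flow_raw = flow_raw,
    association_change = data.frame(cluster_a = matching$cluster_a,
                                    cluster_b = matching$cluster_b,
                                    match_score = matching$score,
                                    mean_change = assoc),
    body_shift_a = body_shift(profiles_a),
    body_shift_b = body_shift(profiles_b),
    enrichment_a = enrich(a), enrichment_b = enrich(b),
    n_common = length(common)
  ), class = "redistribution_summary")
}
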