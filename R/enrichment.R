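#' Upper-tail hypergeometric probability
#'
#' `P(X >= x)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `x` category members when drawing `n` items without
#' replacement from a universe of `N` items of which `K` are in the
#' category. Exact (no normal approximation), computed in log space.
#'
#' @param x observed count, `0 <= x <= min(n, K)`.
#' @param n draw (query set) size.
#' @param K category size in the universe.
#' @param N universe size.
#' @return the upper-tail probability (vectorized over `x`, `n`, `K`, `N`).
#' @export
hypergeom_upper <- function(x, n, K, N) {
  args <- cbind(x = x, n = n, K = K, N = N)
  x <- args[, "x"]; n <- args[, "n"]; K <- args[, "K"]; N <- args[, "N"]
  if (any(args != floor(args)) || any(args < 0))
    stop2("all arguments must be non-negative integers")
  if (any(n > N) || any(K > N)) stop2("n and K must not exceed N")
  if (any(x > n)) stop2("x must not exceed n")
  if (any(x > K)) stop2("x must not exceed K (impossible outcome)")
  unname(stats::phyper(x - 1, m = K, n = N - K, k = n, lower.tail = FALSE))
}

#' Term (gene-set) enrichment by the hypergeometric test
#'
#' One upper-tail hypergeometric test per term against an explicit gene
#' universe. P-values are deliberately uncorrected (matching the original
#' analysis style); a Benjamini-Hochberg column is emitted for modern use
#' but never drives the `significant` flag.
#'
#' @param query gene set (subset of `universe`, non-empty).
#' @param terms a `term_map` from [read_term_map()].
#' @param universe gene universe (non-empty). The background choice
#'   dominates these p-values, so it is a required argument.
#' @param alpha significance flag threshold on the uncorrected p (default
#'   0.02).
#' @return data frame sorted by `p` then `term_id`: `term_id`, `term_name`,
#'   `K`, `x`, `n`, `N`, `expected`, `p`, `p_bh`, `significant`.
#' @export
term_enrichment <- function(query, terms, universe, alpha = 0.02) {
  stopifnot(inherits(terms, "term_map"))
  query <- unique(query); universe <- unique(universe)
  if (length(query) == 0L) stop2("query set is empty")
  if (length(universe) == 0L) stop2("universe is empty")
  if (!all(query %in% universe)) stop2("query must be a subset of the universe")
  n <- length(query); N <- length(universe)
  rows <- lapply(names(terms), function(id) {
    tg <- intersect(terms[[id]]$genes, universe)
    K <- length(tg)
    if (K == 0L) return(NULL)
    x <- length(intersect(query, tg))
    data.frame(term_id = id, term_name = terms[[id]]$name,
               K = K, x = x, n = n, N = N, expected = n * K / N,
               p = hypergeom_upper(x, n = n, K = K, N = N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) stop2("no term overlaps the universe")
  out <- out[order(out$p, out$term_id), ]
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p <= alpha
  rownames(out) <- NULL
  out
}

#' Cross-species ortholog-set overlap with chance expectation
#'
#' Restricts each species' gene set to genes with an ortholog partner,
#' counts ortholog pairs whose two members are both selected AND share the
#' same regulation direction, and compares the overlap with the chance
#' expectation `n1 * n2 / N` over the `N` ortholog pairs. The significance
#' test is computed on the undirected overlap (conservative, reported as
#' such); the direction-concordant expectation is also reported, scaled by
#' the concordance probability implied by the direction marginals.
#'
#' @param set1,set2 gene sets in species 1 / species 2.
#' @param direction1,direction2 named character vectors ("induced" /
#'   "repressed") covering `set1` / `set2`.
#' @param orthomap an [ortholog_map()].
#' @return An `ortholog_overlap` list: `n1`, `n2`, `N`, `observed`
#'   (direction-concordant pairs), `observed_undirected`, `expected`,
#'   `expected_concordant`, `p` (upper-tail hypergeometric on the
#'   undirected overlap), `pairs` (data frame of co-occurring pairs).
#' @export
ortholog_overlap <- function(set1, set2, direction1, direction2, orthomap) {
  stopifnot(inherits(orthomap, "ortholog_map"))
  N <- nrow(orthomap)
  if (N == 0L) stop2("ortholog map is empty")
  set1 <- unique(set1); set2 <- unique(set2)
  if (!all(set1 %in% names(direction1)))
    stop2("direction labels missing for some genes in set1")
  if (!all(set2 %in% names(direction2)))
    stop2("direction labels missing for some genes in set2")
  mapped1 <- intersect(set1, orthomap$id_species1)
  mapped2 <- intersect(set2, orthomap$id_species2)
  n1 <- length(mapped1); n2 <- length(mapped2)
  in1 <- orthomap$id_species1 %in% mapped1
  in2 <- orthomap$id_species2 %in% mapped2
  both <- in1 & in2
  pairs <- orthomap[both, , drop = FALSE]
  concord <- if (nrow(pairs) == 0L) logical(0) else
    direction1[pairs$id_species1] == direction2[pairs$id_species2]
  observed <- sum(concord)
  p <- if (n1 == 0 || n2 == 0) 1 else
    hypergeom_upper(sum(both), n = n1, K = n2, N = N)
  p_conc <- if (n1 == 0 || n2 == 0) 0 else {
    d1 <- table(factor(direction1[mapped1], levels = c("induced", "repressed"))) / n1
    d2 <- table(factor(direction2[mapped2], levels = c("induced", "repressed"))) / n2
    sum(d1 * d2)
  }
  structure(list(
    n1 = n1, n2 = n2, N = N,
    observed = observed, observed_undirected = sum(both),
    expected = n1 * n2 / N,
    expected_concordant = n1 * n2 / N * p_conc,
    p = p,
    pairs = data.frame(pairs,
                       concordant = as.logical(concord),
                       row.names = NULL)
  ), class = "ortholog_overlap")
}
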