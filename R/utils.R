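#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop2(sprintf("'%s' must be a single finite number in [%s, %s]", name, lower, upper))
  x
}

#' Adjusted Rand index between two labellings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to score recovered cluster labels against planted archetypes.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number; 1 for identical partitions, ~0 for random ones.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop2("label vectors must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_i * sum_j / n
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
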