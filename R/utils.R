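#' @importFrom stats cor dist kmeans median nls optim pchisq phyper plogis
#'   p.adjust prcomp qchisq quantile rnbinom rnorm runif sd setNames var
#'   coef resid qt pt mahalanobis rmultinom
#' @importFrom utils head read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Adjusted Rand index between two labelings
#'
#' Measures agreement between two partitions of the same cells, corrected
#' for chance. Used throughout to compare recovered cell-type labels with
#' the generator's ground truth.
#'
#' @param a,b vectors of equal length; treated as categorical labels.
#' @return a single number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("labelings differ in length (%d vs %d)", length(a), length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

## deterministic argmax with lexicographic tie-break; returns index and tie flag
argmax_lex <- function(x, names_) {
  m <- max(x)
  hits <- which(x >= m - 1e-12)
  tie <- length(hits) > 1
  if (tie) hits <- hits[order(names_[hits])]
  list(index = hits[1], tie = tie)
}

row_sds <- function(m) {
  mu <- rowMeans(m)
  sqrt(pmax(rowMeans(m^2) - mu^2, 0) * ncol(m) / max(1, ncol(m) - 1))
}
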