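#' @useDynLib arcticpico, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats ave cmdscale cor dist isoreg pt rbinom rlnorm
#'   rnorm rpois runif sd setNames t.test
#' @importFrom utils head modifyList read.csv write.csv read.delim
#'   write.table str
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stop2 <- function(...) stop(..., call. = FALSE)

#' Lower-triangle vector of a square matrix
#' @noRd
lower_tri <- function(m) m[lower.tri(m)]

#' Index pairs (i > j) matching lower.tri() order
#' @noRd
pair_index <- function(n) {
  j <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  i <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

check_square <- function(D, what = "distance matrix") {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop2(what, " must be a square matrix")
  if (max(abs(D - t(D))) > 1e-8)
    stop2(what, " must be symmetric")
  invisible(D)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples,
#' used to score cluster recovery against known synthetic group labels.
#' 1 means identical partitions, 0 is the expected value for independent
#' random partitions.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop2("label vectors must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) sum(choose(x, 2))
  sum_ij <- comb2(tab)
  sum_a <- comb2(rowSums(tab))
  sum_b <- comb2(colSums(tab))
  n2 <- choose(length(a), 2)
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' All permutations of 1..n (for exhaustive permutation tests)
#' @noRd
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

#' Distinct permutations of a label multiset (as a matrix, one per row)
#' @noRd
distinct_label_permutations <- function(labels) {
  labels <- as.character(labels)
  uniq <- unique(labels)
  n <- length(labels)
  recurse <- function(remaining) {
    if (sum(remaining) == 0L) return(matrix(character(0), 1L, 0L))
    out <- list()
    for (u in seq_along(uniq)) {
      if (remaining[u] == 0L) next
      rem2 <- remaining
      rem2[u] <- rem2[u] - 1L
      tails <- recurse(rem2)
      out[[length(out) + 1L]] <- cbind(rep(uniq[u], nrow(tails)), tails)
    }
    do.call(rbind, out)
  }
  recurse(as.integer(table(factor(labels, levels = uniq))))
}
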