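# Distance and permutation inference over community profiles, implemented
# from first principles: Jaccard distances, ANOSIM, Mantel, Pearson.

#' Jaccard distances between community profiles
#'
#' `d(a, b) = 1 - |a n b| / |a u b|` over the presence sets of each pair
#' of samples.
#'
#' @param m logical (or 0/1) matrix, samples in rows.
#' @return symmetric distance matrix with zero diagonal, entries in
#'   \[0, 1\], sample ids as dimnames.
#' @export
jaccard_distances <- function(m) {
  m <- m * 1
  rs <- rowSums(m)
  if (any(rs == 0))
    stop2("sample(s) with empty presence set: ",
          paste(rownames(m)[rs == 0], collapse = ", "))
  inter <- m %*% t(m)
  union <- outer(rs, rs, "+") - inter
  d <- 1 - inter / union
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities. With ranks over all off-diagonal
#' pairs (ties averaged), `R = (mean_between - mean_within) / (M / 2)`
#' where `M = n (n - 1) / 2`. The one-sided p-value counts permuted R
#' values at least as large as the observed one, with the observed
#' labeling included: `p = (1 + #{R* >= R}) / (n_perm + 1)`. With
#' `exact = TRUE` all distinct label arrangements are enumerated instead
#' (p = proportion of arrangements with `R* >= R`, identity included).
#'
#' @param D symmetric dissimilarity matrix.
#' @param labels group labels, one per sample; >= 2 groups of size >= 2.
#' @param n_perm number of random permutations.
#' @param seed integer seed for the permutation stream.
#' @param exact enumerate all distinct label arrangements (small n only).
#' @return an `anosim_result` list: `R`, `p`, `n_perm`, `group_sizes`.
#' @export
anosim <- function(D, labels, n_perm = 999, seed = 1L, exact = FALSE) {
  check_square(D)
  n <- nrow(D)
  if (length(labels) != n) stop2("one label per sample required")
  sizes <- table(labels)
  if (length(sizes) < 2) stop2("ANOSIM needs at least 2 groups")
  if (any(sizes < 2)) stop2("every group must have size >= 2")
  idx <- pair_index(n)
  r <- rank(D[idx])
  M <- nrow(idx)
  stat <- function(lab) {
    within <- lab[idx[, 1]] == lab[idx[, 2]]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  R_obs <- stat(labels)
  if (exact) {
    perms <- distinct_label_permutations(labels)
    R_all <- apply(perms, 1L, stat)
    p <- mean(R_all >= R_obs - 1e-12)
    n_perm <- nrow(perms)
  } else {
    set.seed(seed)
    R_perm <- replicate(n_perm, stat(sample(labels)))
    p <- (1 + sum(R_perm >= R_obs - 1e-12)) / (n_perm + 1)
  }
  structure(list(R = R_obs, p = p, n_perm = n_perm,
                 group_sizes = as.integer(sizes)),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations; groups: %s)\n",
              x$R, x$p, x$n_perm, paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower triangles, with significance from
#' joint row/column permutations of the second matrix. One-sided
#' (greater), observed permutation included:
#' `p = (1 + #{r* >= r}) / (n_perm + 1)`. `exact = TRUE` enumerates all
#' `n!` sample orders (identity included).
#'
#' @param D1,D2 symmetric matrices over the same samples in the same
#'   order.
#' @inheritParams anosim
#' @return a `mantel_result` list: `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(D1, D2, n_perm = 999, seed = 1L, exact = FALSE) {
  check_square(D1, "D1")
  check_square(D2, "D2")
  n <- nrow(D1)
  if (nrow(D2) != n) stop2("matrices must have the same dimension")
  if (n < 4) stop2("Mantel test needs n >= 4")
  if (!is.null(rownames(D1)) && !is.null(rownames(D2)) &&
      !identical(rownames(D1), rownames(D2)))
    stop2("matrices must cover the same samples in the same order")
  v1 <- lower_tri(D1)
  if (sd(v1) == 0 || sd(lower_tri(D2)) == 0)
    stop2("zero variance in a distance triangle; correlation undefined")
  r_obs <- pearson(v1, lower_tri(D2))
  if (exact) {
    perms <- all_permutations(n)
    r_all <- apply(perms, 1L, function(p) pearson(v1, lower_tri(D2[p, p])))
    p <- mean(r_all >= r_obs - 1e-12)
    n_perm <- nrow(perms)
  } else {
    set.seed(seed)
    r_perm <- replicate(n_perm, {
      p <- sample(n)
      pearson(v1, lower_tri(D2[p, p]))
    })
    p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (n_perm + 1)
  }
  structure(list(r = r_obs, p = p, n_perm = n_perm), class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f, p = %.4g (%d permutations)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return the correlation coefficient.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop2("x and y must have equal length")
  if (length(x) < 3) stop2("need at least 3 points")
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sqrt(sum(xc^2))
  sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0) stop2("zero variance; correlation undefined")
  sum(xc * yc) / (sx * sy)
}
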