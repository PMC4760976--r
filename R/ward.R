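# Agglomerative Ward clustering via the Lance-Williams recurrence.

#' Ward clustering of a dissimilarity matrix
#'
#' Agglomerative clustering with Ward's minimum-variance update applied
#' directly to the supplied dissimilarities via the Lance--Williams
#' recurrence (the classic pre-3.1 "ward", i.e. `ward.D`, with no
#' pre-squaring by the caller; `method = "ward.D2"` squares within the
#' update instead). At each step the pair of clusters with the smallest
#' linkage distance is merged, ties broken by the smallest pair of
#' original sample indices; the tree is cut at `k_groups` clusters.
#'
#' @param D symmetric dissimilarity matrix.
#' @param k_groups number of clusters to cut the tree into.
#' @param method `"ward.D"` (default) or `"ward.D2"`.
#' @return integer cluster labels (1..k_groups) named by sample, in
#'   order of first appearance.
#' @export
ward_clusters <- function(D, k_groups = 4, method = c("ward.D", "ward.D2")) {
  method <- match.arg(method)
  check_square(D)
  n <- nrow(D)
  if (k_groups > n) stop2("k_groups exceeds the number of samples")
  if (k_groups < 1) stop2("k_groups must be >= 1")
  d <- D
  if (method == "ward.D2") d <- d^2
  diag(d) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  members <- as.list(seq_len(n))
  min_member <- seq_len(n)  # tie-break key: smallest original index
  n_clust <- n
  while (n_clust > k_groups) {
    # smallest linkage distance; ties by smallest (min_member_i, min_member_j)
    act <- which(active)
    sub <- d[act, act, drop = FALSE]
    mval <- min(sub)
    cand <- which(sub <= mval + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keyi <- pmin(min_member[act[cand[, 1]]], min_member[act[cand[, 2]]])
    keyj <- pmax(min_member[act[cand[, 1]]], min_member[act[cand[, 2]]])
    pick <- order(keyi, keyj)[1]
    i <- act[cand[pick, 1]]
    j <- act[cand[pick, 2]]
    dij <- d[i, j]
    for (kk in which(active)) {
      if (kk == i || kk == j) next
      ni <- size[i]; nj <- size[j]; nk <- size[kk]
      dk <- ((ni + nk) * d[kk, i] + (nj + nk) * d[kk, j] - nk * dij) /
        (ni + nj + nk)
      d[kk, i] <- d[i, kk] <- dk
    }
    size[i] <- size[i] + size[j]
    members[[i]] <- c(members[[i]], members[[j]])
    min_member[i] <- min(min_member[i], min_member[j])
    active[j] <- FALSE
    d[j, ] <- Inf
    d[, j] <- Inf
    n_clust <- n_clust - 1L
  }
  labels <- integer(n)
  act <- which(active)
  act <- act[order(min_member[act])]
  for (g in seq_along(act)) labels[members[[act[g]]]] <- g
  names(labels) <- rownames(D)
  labels
}
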