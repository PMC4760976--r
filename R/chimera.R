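# Two-parent (bimera) chimera screen: a deliberately simple split model,
# pluggable where a full chimera detector would otherwise run.

#' Flag a query sequence as a two-parent chimera
#'
#' For every ordered pair of candidate parents and every breakpoint along
#' the query (stride `stride` bp), the query's left part is aligned
#' against parent A's prefix and the right part against parent B's
#' suffix; the split model's score is the length-weighted mean of the two
#' identities. The query is flagged as a bimera iff the best split score
#' exceeds the best single-parent identity by at least `min_split_gain`
#' and is itself at least `min_two_parent` (default 0.99).
#'
#' @param query sequence to test.
#' @param parents character vector of candidate parent sequences (callers
#'   should supply sequences at least twice as abundant as the query; see
#'   [flag_chimeras()]).
#' @param min_split_gain required improvement of the split model over the
#'   best single parent.
#' @param stride breakpoint stride in bp.
#' @param min_two_parent minimum split-model identity.
#' @inheritParams pairwise_identity
#' @return logical flag with attributes `best_single`, `best_split`,
#'   `gain`.
#' @export
detect_bimeras <- function(query, parents, min_split_gain = 0.02,
                           stride = 10L, min_two_parent = 0.99,
                           match = 1, mismatch = 0, gap = -1) {
  if (length(parents) < 2) {
    res <- FALSE
    attr(res, "best_single") <- NA_real_
    attr(res, "best_split") <- NA_real_
    attr(res, "gain") <- NA_real_
    return(res)
  }
  L <- nchar(query)
  breaks <- seq(stride, L - stride, by = stride)
  if (length(breaks) == 0) breaks <- floor(L / 2)
  np <- length(parents)
  # empty-tolerant identity: an empty-vs-nonempty fragment aligns to all
  # gaps (identity 0); empty-vs-empty is a perfect trivial alignment
  id0 <- function(a, b) {
    if (!nzchar(a) && !nzchar(b)) return(1)
    if (!nzchar(a) || !nzchar(b)) return(0)
    pairwise_identity(a, b, match, mismatch, gap)
  }
  single <- vapply(parents, function(p)
    id0(query, p), 0, USE.NAMES = FALSE)
  best_single <- max(single)
  if (best_single + min_split_gain > 1) {
    # no split model can beat this single parent by the required gain
    res <- FALSE
    attr(res, "best_single") <- best_single
    attr(res, "best_split") <- NA_real_
    attr(res, "gain") <- NA_real_
    return(res)
  }
  # per-parent prefix/suffix identities at each breakpoint, then the best
  # ordered pair is a cheap combination
  left_id <- matrix(0, np, length(breaks))
  right_id <- matrix(0, np, length(breaks))
  for (p in seq_len(np)) {
    lp <- nchar(parents[p])
    for (b in seq_along(breaks)) {
      bp <- breaks[b]
      bp_p <- min(lp, bp)
      left_id[p, b] <- id0(substr(query, 1, bp),
                           substr(parents[p], 1, bp_p))
      right_id[p, b] <- id0(substr(query, bp + 1, L),
                            substr(parents[p], bp_p + 1, lp))
    }
  }
  best_split <- -Inf
  for (b in seq_along(breaks)) {
    wa <- breaks[b] / L
    la <- max(left_id[, b])
    rb <- max(right_id[, b])
    split <- wa * la + (1 - wa) * rb
    if (split > best_split) best_split <- split
  }
  res <- best_split >= best_single + min_split_gain &&
    best_split >= min_two_parent
  attr(res, "best_single") <- best_single
  attr(res, "best_split") <- best_split
  attr(res, "gain") <- best_split - best_single
  res
}

#' Screen dereplicated reads for bimeras
#'
#' Applies [detect_bimeras()] to every unique sequence. Candidate
#' parents are the unique sequences whose abundance is at least
#' `parent_ratio` times the query's, ranked by shared k-mer fraction
#' with the query (a true bimera shares about half its k-mers with each
#' parent, so real parents rank at the top) and capped at `max_parents`.
#' Sequences with fewer than two eligible parents are never flagged.
#'
#' @param derep dereplicated reads (see [dereplicate()]).
#' @param parent_ratio minimum parent:query abundance ratio (default 2).
#' @param max_parents cap on the candidate parent set size.
#' @param kmer k-mer length for the parent ranking.
#' @inheritParams detect_bimeras
#' @return logical vector, one flag per row of `derep`.
#' @export
flag_chimeras <- function(derep, min_split_gain = 0.02, parent_ratio = 2,
                          max_parents = 8L, stride = 10L,
                          min_two_parent = 0.99, kmer = 8L,
                          match = 1, mismatch = 0, gap = -1) {
  n <- nrow(derep)
  flags <- logical(n)
  for (q in seq_len(n)) {
    eligible <- which(derep$count >= parent_ratio * derep$count[q])
    eligible <- setdiff(eligible, q)
    if (length(eligible) < 2) next
    share <- .kmer_share_cpp(derep$seq[q], derep$seq[eligible], kmer)
    # a split model reaching the 0.99 floor needs each side nearly
    # identical to some parent, which requires a substantial shared
    # k-mer fraction; queries nowhere near any parent are skipped
    if (max(share) < 0.2) next
    eligible <- eligible[order(-share)]
    parents <- derep$seq[utils::head(eligible, max_parents)]
    flags[q] <- as.logical(detect_bimeras(derep$seq[q], parents,
                                          min_split_gain, stride,
                                          min_two_parent,
                                          match, mismatch, gap))
  }
  flags
}
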