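# 454-style amplicon pipeline: read QC, pairwise identity, farthest-
# neighbour OTU clustering, consensus calling, singleton removal, OTU
# table construction.

#' Quality-filter amplicon reads
#'
#' A read is kept iff its length lies in `[min_len, max_len]`, it carries
#' at most `max_n` ambiguous bases (N) and it starts with the forward
#' primer (exact prefix by default; Ns in the primer region count as
#' mismatches). Rules are evaluated in the order length-low, length-high,
#' N-count, primer, and the rejection log attributes each discarded read
#' to the first rule that fired; the kept set does not depend on this
#' order.
#'
#' @param reads read data.frame (`id`, `sample`, `seq`).
#' @param min_len,max_len length window in bp (defaults 300 and 670).
#' @param max_n maximum number of Ns (default 1).
#' @param forward_primer expected 5' primer (default 528F,
#'   `GCGGTAATTCCAGCTCCAA`).
#' @param primer_max_mismatch tolerated mismatches in the primer region
#'   (default 0, a strict prefix).
#' @return list with `kept` (read data.frame), `rejected` (data.frame
#'   `id`, `rule`) and `counts` (named rejection tally incl. `kept`).
#' @export
filter_reads <- function(reads, min_len = 300, max_len = 670, max_n = 1,
                         forward_primer = "GCGGTAATTCCAGCTCCAA",
                         primer_max_mismatch = 0L) {
  len <- nchar(reads$seq)
  n_count <- nchar(gsub("[^N]", "", reads$seq))
  plen <- nchar(forward_primer)
  prefix <- substr(reads$seq, 1L, plen)
  mism <- vapply(prefix, function(p) {
    if (nchar(p) < plen) return(plen)
    sum(utf8ToInt(p) != utf8ToInt(forward_primer))
  }, 0L, USE.NAMES = FALSE)
  rule <- rep(NA_character_, nrow(reads))
  rule[is.na(rule) & len < min_len] <- "length_low"
  rule[is.na(rule) & len > max_len] <- "length_high"
  rule[is.na(rule) & n_count > max_n] <- "n_count"
  rule[is.na(rule) & mism > primer_max_mismatch] <- "primer"
  kept <- is.na(rule)
  counts <- c(kept = sum(kept),
              table(factor(rule[!kept], levels = c("length_low", "length_high",
                                                   "n_count", "primer"))))
  list(kept = reads[kept, , drop = FALSE],
       rejected = data.frame(id = reads$id[!kept], rule = rule[!kept],
                             stringsAsFactors = FALSE),
       counts = counts)
}

#' Pairwise global-alignment identity
#'
#' Needleman--Wunsch global alignment (default scoring: match +1,
#' mismatch 0, gap -1 per position) with identity defined as matches
#' divided by total alignment length, so gap columns penalize identity.
#' N matches nothing. Among co-optimal alignments the one maximizing
#' matches and then minimizing alignment length is scored, making the
#' value deterministic.
#'
#' @param a,b sequences over \{A,C,G,T,N\}.
#' @param match,mismatch,gap alignment scores.
#' @return identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  if (!nzchar(a) || !nzchar(b)) stop2("sequences must be non-empty")
  unname(.nw_identity_cpp(a, b, match, mismatch, gap)[["identity"]])
}

#' All pairwise identities of a sequence set
#'
#' With `prescreen > 0`, pairs sharing fewer than that fraction of their
#' `kmer`-mers are reported as identity 0 without alignment — an
#' optimization for clustering, where such pairs lie far below any OTU
#' threshold of interest; pairs near a 97% threshold share well over
#' half their k-mers and are always aligned exactly.
#'
#' @param seqs character vector of sequences.
#' @param prescreen minimum shared k-mer fraction below which a pair is
#'   scored 0 unaligned (0 disables the prescreen).
#' @param kmer k-mer length for the prescreen.
#' @inheritParams pairwise_identity
#' @return symmetric matrix of identities (unit diagonal).
#' @export
identity_matrix <- function(seqs, match = 1, mismatch = 0, gap = -1,
                            prescreen = 0, kmer = 8L) {
  m <- .identity_matrix_cpp(seqs, match, mismatch, gap, prescreen, kmer)
  dimnames(m) <- list(names(seqs), names(seqs))
  m
}

#' Collapse identical reads
#'
#' @param reads read data.frame.
#' @return data.frame of unique sequences (sorted, so the result is
#'   independent of input order) with `count` and a `members` list-column
#'   of read ids.
#' @export
dereplicate <- function(reads) {
  groups <- split(reads$id, reads$seq)
  seqs <- sort(names(groups))
  data.frame(seq = seqs,
             count = vapply(groups[seqs], length, 0L),
             members = I(lapply(groups[seqs], sort)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Farthest-neighbour OTU clustering
#'
#' Complete-linkage agglomeration on distance `1 - identity`: two
#' clusters merge only while the maximum pairwise distance within the
#' merged cluster stays at most `1 - identity_threshold`, so every
#' member pair of an emitted OTU has identity at least the threshold
#' (the farthest-neighbour guarantee). Merges proceed in order of
#' smallest linkage distance, ties broken by the smallest pair of
#' member read ids; identical reads are collapsed first, which leaves
#' the partition unchanged. The result does not depend on input order.
#'
#' @param reads read data.frame (`id`, `sample`, `seq`).
#' @param identity_threshold minimum intra-OTU pairwise identity.
#' @param prescreen shared k-mer fraction below which pairs skip
#'   alignment (see [identity_matrix()]); cannot change the partition at
#'   thresholds near 0.97.
#' @inheritParams pairwise_identity
#' @return an `otu_set`: list of OTUs, each with `id`, `members` (read
#'   ids), `seqs` (unique member sequences) and `consensus`; ordered by
#'   decreasing size. OTU consensus sequences are computed with
#'   [consensus_sequence()].
#' @export
cluster_otus_farthest_neighbor <- function(reads, identity_threshold = 0.97,
                                           match = 1, mismatch = 0, gap = -1,
                                           prescreen = 0.5) {
  if (nrow(reads) == 0) stop2("no reads to cluster")
  derep <- dereplicate(reads)
  k <- nrow(derep)
  height <- 1 - identity_threshold
  if (k == 1) {
    clusters <- list(1L)
  } else {
    d <- 1 - identity_matrix(derep$seq, match, mismatch, gap, prescreen)
    clusters <- complete_linkage_threshold(d, height,
                                           vapply(derep$members,
                                                  function(m) m[1], ""))
  }
  rep_counts <- vapply(derep$members, length, 0L)
  sizes <- vapply(clusters, function(cl) sum(rep_counts[cl]), 0L)
  first_id <- vapply(clusters, function(cl)
    min(unlist(derep$members[cl])), "")
  ord <- order(-sizes, first_id)
  otus <- lapply(seq_along(ord), function(r) {
    cl <- clusters[[ord[r]]]
    member_ids <- sort(unlist(derep$members[cl], use.names = FALSE))
    seqs <- rep(derep$seq[cl], rep_counts[cl])
    list(id = sprintf("OTU_%04d", r), members = member_ids, seqs = seqs,
         consensus = consensus_sequence(seqs, match, mismatch, gap))
  })
  structure(otus, class = "otu_set",
            identity_threshold = identity_threshold)
}

# Merge-while-below-threshold complete linkage on a distance matrix.
# tie_key gives each leaf a stable id used to break equal-distance merges.
complete_linkage_threshold <- function(d, height, tie_key) {
  k <- nrow(d)
  clusters <- as.list(seq_len(k))
  keys <- tie_key
  dd <- d
  diag(dd) <- Inf
  repeat {
    mval <- min(dd)
    if (!is.finite(mval) || mval > height + 1e-12) break
    cand <- which(dd <= mval + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key1 <- pmin(keys[cand[, 1]], keys[cand[, 2]])
    key2 <- pmax(keys[cand[, 1]], keys[cand[, 2]])
    pick <- order(key1, key2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    # complete linkage: new distance is the max of the two
    new_d <- pmax(dd[i, ], dd[j, ])
    dd[i, ] <- new_d
    dd[, i] <- new_d
    dd[i, i] <- Inf
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    keys[i] <- min(keys[i], keys[j])
    clusters[[j]] <- NA
    dd[j, ] <- Inf
    dd[, j] <- Inf
    keys[j] <- "\uFFFF"  # sorts after any read id; cluster j is retired
  }
  clusters[!vapply(clusters, function(x) all(is.na(x)), TRUE)]
}

#' @export
print.otu_set <- function(x, ...) {
  sizes <- vapply(x, function(o) length(o$members), 0L)
  cat("OTU set:", length(x), "OTUs,", sum(sizes), "reads",
      sprintf("(identity >= %.2f)\n", attr(x, "identity_threshold")))
  invisible(x)
}

#' Majority-rule consensus of OTU member sequences
#'
#' Members are aligned by center-star: the longest member (ties broken
#' alphabetically) is the star, all members are globally aligned to it,
#' and their aligned symbols are projected onto the star's columns
#' (insertions relative to the star are dropped). Per column the most
#' frequent non-N base wins, ties going to the alphabetically first
#' base; columns gapped in a majority of members are dropped.
#'
#' @param seqs character vector of member sequences (>= 1).
#' @inheritParams pairwise_identity
#' @return the consensus sequence.
#' @export
consensus_sequence <- function(seqs, match = 1, mismatch = 0, gap = -1) {
  if (length(seqs) == 0) stop2("consensus of zero sequences")
  if (length(seqs) == 1) return(seqs)
  star <- seqs[order(-nchar(seqs), seqs)][1]
  L <- nchar(star)
  n <- length(seqs)
  # identical members vote with multiplicity; align each unique once
  w <- table(seqs)
  uniq <- names(w)
  prof <- matrix("-", length(uniq), L)
  for (m in seq_along(uniq)) {
    if (uniq[m] == star) {
      prof[m, ] <- strsplit(star, "")[[1]]
      next
    }
    aln <- .nw_align_cpp(star, uniq[m], match, mismatch, gap)
    sa <- strsplit(aln$a, "")[[1]]
    sb <- strsplit(aln$b, "")[[1]]
    keep <- sa != "-"            # project onto star columns
    prof[m, ] <- sb[keep]
  }
  wt <- as.numeric(w)
  cons <- character(0)
  for (col in seq_len(L)) {
    symb <- prof[, col]
    if (sum(wt[symb == "-"]) > n / 2) next
    is_base <- symb %in% c("A", "C", "G", "T")
    if (!any(is_base)) next
    votes <- tapply(wt[is_base], symb[is_base], sum)
    cons <- c(cons, sort(names(votes)[votes == max(votes)])[1])
  }
  paste(cons, collapse = "")
}

#' Drop singleton OTUs
#'
#' OTUs comprising exactly one read are removed; they are dominated by
#' sequencing errors and one-off artifacts.
#'
#' @param otus an `otu_set`.
#' @return the filtered `otu_set`; warns when nothing survives.
#' @export
remove_singletons <- function(otus) {
  sizes <- vapply(otus, function(o) length(o$members), 0L)
  kept <- otus[sizes > 1]
  if (length(kept) == 0) warning("all OTUs are singletons; empty set returned")
  attrs <- attributes(otus)
  attributes(kept) <- c(attributes(kept),
                        attrs[setdiff(names(attrs), "names")])
  class(kept) <- "otu_set"
  kept
}

#' Per-sample OTU count table
#'
#' @param otus an `otu_set`.
#' @param reads the read data.frame the OTUs were built from (supplies
#'   each member read's sample id).
#' @return data.frame with columns `otu_id`, `consensus`, `taxonomy`
#'   (empty, to be filled by [assign_taxonomy()]) and one integer count
#'   column per sample; column sums equal the per-sample retained read
#'   counts.
#' @export
build_otu_table <- function(otus, reads) {
  sample_of <- setNames(reads$sample, reads$id)
  samples <- sort(unique(reads$sample))
  if (length(otus) == 0) {
    out <- data.frame(otu_id = character(), consensus = character(),
                      taxonomy = character(), stringsAsFactors = FALSE)
    for (s in samples) out[[s]] <- integer()
    return(out)
  }
  rows <- lapply(otus, function(o) {
    ms <- sample_of[o$members]
    if (any(is.na(ms)))
      stop2("member read(s) without a sample id in OTU ", o$id)
    counts <- table(factor(ms, levels = samples))
    cbind(data.frame(otu_id = o$id, consensus = o$consensus, taxonomy = "",
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(as.integer(counts)),
                        col.names = samples, check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count columns of an OTU table
#' @noRd
otu_count_matrix <- function(otu_table) {
  cols <- setdiff(names(otu_table), c("otu_id", "consensus", "taxonomy"))
  m <- as.matrix(otu_table[, cols, drop = FALSE])
  rownames(m) <- otu_table$otu_id
  m
}
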