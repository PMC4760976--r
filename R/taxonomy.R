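# Confidence-thresholded taxonomy: bootstrapped k-mer nearest-reference
# classification, lineage exclusion, abundant/rare partitioning and
# rank-level composition summaries.

#' Load a reference set for taxonomic assignment
#'
#' @param fasta_path reference sequences (FASTA).
#' @param lineage_path TSV mapping reference ids to semicolon-delimited
#'   ranked lineages (see [read_lineage_table()]).
#' @param tree_path optional Newick tree whose tips are reference ids;
#'   parsed (via ape) and retained for lineage lookup only.
#' @return a `reference_set` list: `seq` (named character), `lineage`
#'   (named character), `tree` (phylo or NULL).
#' @export
read_reference_set <- function(fasta_path, lineage_path, tree_path = NULL) {
  refs <- read_fasta(fasta_path)
  lin <- read_lineage_table(lineage_path)
  missing <- setdiff(refs$id, lin$id)
  if (length(missing))
    stop2("reference(s) without lineage: ", paste(missing, collapse = ", "))
  tree <- NULL
  if (!is.null(tree_path)) {
    if (!requireNamespace("ape", quietly = TRUE))
      stop2("package 'ape' is required to read a reference tree")
    tree <- ape::read.tree(tree_path)
    tips_missing <- setdiff(tree$tip.label, lin$id)
    if (length(tips_missing))
      stop2("tree tip(s) without lineage: ",
            paste(tips_missing, collapse = ", "))
  }
  structure(list(seq = setNames(refs$seq, refs$id),
                 lineage = setNames(lin$lineage, lin$id),
                 tree = tree),
            class = "reference_set")
}

kmer_set <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  unique(substring(seq, 1:(L - k + 1), k:L))
}

#' Assign taxonomy to a consensus sequence
#'
#' Bootstrapped k-mer nearest-reference classification. The query's
#' unique k-mers are compared against each reference's k-mer set; the
#' reference sharing the largest fraction is the point estimate. Each of
#' `n_bootstrap` rounds resamples 1/8 of the query k-mers and votes for
#' its own nearest reference (rounds with no shared k-mer abstain). The
#' per-rank confidence is the fraction of rounds agreeing with the point
#' estimate's lineage truncated at that rank, and the deepest rank with
#' confidence at or above `confidence_threshold` is reported; if even the
#' top rank falls below the threshold, the query is unassigned.
#'
#' @param consensus query sequence (OTU consensus).
#' @param refs a `reference_set` (see [read_reference_set()]).
#' @param k k-mer length.
#' @param n_bootstrap number of bootstrap rounds.
#' @param confidence_threshold minimum per-rank confidence (default
#'   0.85).
#' @param min_kmer_share minimum fraction of query k-mers the nearest
#'   reference must share for any assignment at all; queries with no
#'   plausible relative in the reference set stay unassigned (default
#'   0.1 — an 8% diverged relative still shares about half its 8-mers,
#'   while an unrelated sequence shares about 1% by chance).
#' @param seed integer seed for the bootstrap resampling.
#' @return a list: `lineage` (possibly truncated; "" when unassigned),
#'   `confidence` (at the reported rank; NA when unassigned), `assigned`,
#'   `best_ref`, `rank_confidence` (vector over all ranks).
#' @export
assign_taxonomy <- function(consensus, refs, k = 8L, n_bootstrap = 100L,
                            confidence_threshold = 0.85,
                            min_kmer_share = 0.1, seed = 1L) {
  stopifnot(inherits(refs, "reference_set"))
  if (nchar(consensus) < k) stop2("query shorter than k")
  qk <- kmer_set(consensus, k)
  ref_ids <- names(refs$seq)
  ref_sets <- lapply(refs$seq, kmer_set, k = k)
  # membership matrix: query k-mers x references
  member <- vapply(ref_sets, function(s) qk %in% s,
                   logical(length(qk)))
  if (!is.matrix(member)) member <- matrix(member, nrow = length(qk))
  shared <- colSums(member)
  unassigned <- list(lineage = "", confidence = NA_real_, assigned = FALSE,
                     best_ref = NA_character_,
                     rank_confidence = numeric(0))
  if (max(shared) < min_kmer_share * length(qk)) return(unassigned)
  best <- which.max(shared)  # ties: first reference in set order
  best_lineage <- strsplit(refs$lineage[[ref_ids[best]]], ";", fixed = TRUE)[[1]]
  n_ranks <- length(best_lineage)
  m <- max(1L, ceiling(length(qk) / 8))
  set.seed(seed)
  votes <- matrix(0, nrow = n_bootstrap, ncol = n_ranks)
  for (b in seq_len(n_bootstrap)) {
    idx <- sample.int(length(qk), m, replace = TRUE)
    counts <- colSums(member[idx, , drop = FALSE])
    if (max(counts) == 0) next  # abstain
    win <- which.max(counts)
    lin <- strsplit(refs$lineage[[ref_ids[win]]], ";", fixed = TRUE)[[1]]
    depth <- min(length(lin), n_ranks)
    agree <- seq_len(depth)[lin[seq_len(depth)] == best_lineage[seq_len(depth)]]
    # agreement at rank r requires agreement at all shallower ranks
    if (length(agree) && agree[1] == 1L) {
      run <- agree[cumsum(agree) == cumsum(seq_along(agree))]
      votes[b, seq_len(length(run))] <- 1
    }
  }
  conf <- colMeans(votes)
  names(conf) <- best_lineage
  deepest <- which(conf >= confidence_threshold)
  if (length(deepest) == 0) {
    out <- unassigned
    out$rank_confidence <- conf
    return(out)
  }
  depth <- max(deepest)
  list(lineage = paste(best_lineage[seq_len(depth)], collapse = ";"),
       confidence = conf[[depth]], assigned = TRUE,
       best_ref = ref_ids[best], rank_confidence = conf)
}

#' Assign taxonomy to every OTU of a table
#'
#' @param otu_table OTU table (see [build_otu_table()]).
#' @inheritParams assign_taxonomy
#' @return the OTU table with its `taxonomy` column filled in, plus an
#'   `assignments` attribute (list of per-OTU assignment results).
#' @export
assign_otu_taxonomy <- function(otu_table, refs, k = 8L, n_bootstrap = 100L,
                                confidence_threshold = 0.85,
                                min_kmer_share = 0.1, seed = 1L) {
  res <- lapply(seq_len(nrow(otu_table)), function(i)
    assign_taxonomy(otu_table$consensus[i], refs, k, n_bootstrap,
                    confidence_threshold, min_kmer_share,
                    seed = seed + i))
  otu_table$taxonomy <- vapply(res, `[[`, "", "lineage")
  attr(otu_table, "assignments") <- setNames(res, otu_table$otu_id)
  otu_table
}

#' Remove OTUs assigned to banned lineages
#'
#' Drops OTUs whose lineage contains any banned rank name (default Fungi
#' and Metazoa, which fall outside the pico-eukaryote scope). Unassigned
#' OTUs are retained.
#'
#' @param otu_table OTU table with a `taxonomy` column.
#' @param banned character vector of rank names.
#' @return the filtered OTU table.
#' @export
exclude_lineages <- function(otu_table, banned = c("Fungi", "Metazoa")) {
  if (length(banned) == 0) return(otu_table)
  ranks <- strsplit(otu_table$taxonomy, ";", fixed = TRUE)
  hit <- vapply(ranks, function(r) any(r %in% banned), TRUE)
  otu_table[!hit, , drop = FALSE]
}

#' Abundant vs rare biosphere partition
#'
#' An OTU is abundant in a sample iff it contributes strictly more than
#' `threshold` (default 1%) of that sample's reads; otherwise (including
#' exactly 1%) it belongs to the rare biosphere. The classification is
#' per sample: the same OTU can be abundant at one station and rare at
#' another.
#'
#' @param otu_table OTU table.
#' @param threshold abundance fraction (strict >).
#' @return logical matrix (OTUs x samples): TRUE = abundant. OTUs with
#'   zero count in a sample are reported rare there; abundant and rare
#'   sets partition each sample's OTU list.
#' @export
abundant_biosphere <- function(otu_table, threshold = 0.01) {
  counts <- otu_count_matrix(otu_table)
  totals <- colSums(counts)
  if (any(totals == 0))
    stop2("sample(s) with zero total reads: ",
          paste(colnames(counts)[totals == 0], collapse = ", "))
  sweep(counts, 2, totals, "/") > threshold
}

#' Rank-level community composition
#'
#' Aggregates read-count proportions to the requested lineage rank.
#' Unassigned OTUs (and lineages truncated above the requested rank) are
#' pooled as `"unclassified"`. Proportions sum to 1 per sample.
#'
#' @param otu_table OTU table with taxonomy.
#' @param rank 1-based rank depth (e.g. 2 = phylum in
#'   `Eukaryota;Haptophyta;...`).
#' @return matrix (taxon groups x samples) of proportions.
#' @export
composition_summary <- function(otu_table, rank = 2L) {
  counts <- otu_count_matrix(otu_table)
  ranks <- strsplit(otu_table$taxonomy, ";", fixed = TRUE)
  grp <- vapply(ranks, function(r)
    if (length(r) >= rank) r[rank] else "unclassified", "")
  agg <- rowsum(counts, grp)
  totals <- colSums(agg)
  if (any(totals == 0)) stop2("sample(s) with zero total reads")
  sweep(agg, 2, totals, "/")
}

#' Correlation of a taxon's sequence abundance with chlorophyll
#'
#' Pearson correlation between a taxon group's per-sample read
#' proportion and a chlorophyll value (total or pico fraction) over the
#' matched stations.
#'
#' @param composition matrix from [composition_summary()].
#' @param chl chlorophyll data.frame with a `station` column matching the
#'   composition's sample names.
#' @param taxon row name of `composition` to correlate.
#' @param what `"total"` or `"pico"`.
#' @param allow_partial passed to [total_chl()].
#' @return Pearson correlation coefficient.
#' @export
taxon_chl_correlation <- function(composition, chl, taxon,
                                  what = c("total", "pico"),
                                  allow_partial = FALSE) {
  what <- match.arg(what)
  if (!taxon %in% rownames(composition))
    stop2("taxon '", taxon, "' not in composition")
  common <- intersect(colnames(composition), chl$station)
  if (length(common) < 3) stop2("need at least 3 matched stations")
  vals <- if (what == "total") {
    setNames(total_chl(chl, allow_partial), chl$station)[common]
  } else {
    setNames(chl$chl_0p4_3, chl$station)[common]
  }
  pearson(composition[taxon, common], vals)
}
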