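# End-to-end conveniences composing the module functions; also the
# workhorses behind the command-line interface.

#' Run the ARISA community pipeline
#'
#' Peak QC (50 bp threshold), triplicate consolidation, shifted-frame
#' binning, Jaccard distances, Ward clustering, ANOSIM over the cluster
#' labels and a 2-d NMDS ordination.
#'
#' @param peaks raw peak table.
#' @param config a [pipeline_config()].
#' @param k_groups number of community clusters to cut.
#' @param labels optional a-priori group labels (named by sample); when
#'   absent the Ward clusters are tested, mirroring the a-priori
#'   grouping-by-clustering workflow.
#' @param n_perm ANOSIM permutations.
#' @param run_nmds compute the NMDS ordination (skippable for speed).
#' @return list: `pa` (presence/absence matrix), `D` (Jaccard),
#'   `clusters`, `anosim`, `nmds` (or NULL).
#' @export
run_arisa_pipeline <- function(peaks, config = pipeline_config(),
                               k_groups = 4, labels = NULL, n_perm = 999,
                               run_nmds = TRUE) {
  ar <- config$arisa
  qc <- qc_peaks(peaks, ar$min_fragment_bp)
  cons <- consolidate_replicates(qc, ar$replicate_tol_bp,
                                 ar$replicate_min_count)
  pa <- bin_fragments(cons, ar$bin_width_bp, ar$shift_step_bp)
  D <- jaccard_distances(pa)
  clusters <- ward_clusters(D, k_groups)
  test_labels <- if (is.null(labels)) clusters else labels[rownames(D)]
  an <- anosim(D, test_labels, n_perm = n_perm, seed = config$seed)
  ord <- if (run_nmds) nmds(D, k = 2, seed = config$seed) else NULL
  list(pa = pa, D = D, clusters = clusters, anosim = an, nmds = ord)
}

#' Run the amplicon OTU pipeline
#'
#' Read QC filters, chimera screening on the dereplicated reads,
#' farthest-neighbour OTU clustering at the configured identity,
#' singleton removal and OTU-table construction; when a reference set is
#' given, consensus sequences are classified, banned lineages (Fungi,
#' Metazoa) excluded, and per-sample abundant/rare partitions and a
#' family-rank composition summary are added.
#'
#' @param reads read data.frame.
#' @param config a [pipeline_config()].
#' @param refs optional `reference_set` for taxonomy.
#' @param composition_rank lineage rank for the composition summary.
#' @return list: `filter` (QC result), `chimera_flags`, `otus`,
#'   `otu_table`, and with refs also `abundant`, `composition`.
#' @export
run_amplicon_pipeline <- function(reads, config = pipeline_config(),
                                  refs = NULL, composition_rank = 4L) {
  am <- config$amplicon
  flt <- filter_reads(reads, am$min_len, am$max_len, am$max_n,
                      am$forward_primer, am$primer_max_mismatch)
  kept <- flt$kept
  derep <- dereplicate(kept)
  flags <- flag_chimeras(derep, min_split_gain = am$min_split_gain,
                         match = am$align$match,
                         mismatch = am$align$mismatch,
                         gap = am$align$gap)
  chimeric_ids <- unlist(derep$members[flags], use.names = FALSE)
  clean <- kept[!kept$id %in% chimeric_ids, , drop = FALSE]
  otus <- cluster_otus_farthest_neighbor(clean, am$identity_threshold,
                                         am$align$match, am$align$mismatch,
                                         am$align$gap)
  otus <- remove_singletons(otus)
  tab <- build_otu_table(otus, clean)
  out <- list(filter = flt, chimera_flags = setNames(flags, derep$seq),
              chimeric_ids = chimeric_ids, otus = otus, otu_table = tab)
  if (!is.null(refs) && nrow(tab) > 0) {
    tab <- assign_otu_taxonomy(tab, refs, am$kmer$k, am$kmer$n_bootstrap,
                               am$confidence_threshold, seed = config$seed)
    tab <- exclude_lineages(tab)
    out$otu_table <- tab
    out$abundant <- abundant_biosphere(tab, am$abundance_threshold)
    out$composition <- composition_summary(tab, composition_rank)
  }
  out
}

#' Summarize station oceanography
#'
#' Water-mass classification, freezing-line offset, Pacific-water
#' fraction (where nutrients permit) and per-region means for a station
#' table.
#'
#' @param stations station data.frame.
#' @param config a [pipeline_config()].
#' @return list: `stations` (with `water_mass`, `dT_freezing`,
#'   `pacific_fraction` columns), `summary` (per-region means).
#' @export
run_ocean_summary <- function(stations, config = pipeline_config()) {
  stations$water_mass <- classify_water_mass(stations$temp, stations$sal,
                                             config)
  stations$dT_freezing <- stations$temp - freezing_temperature(stations$sal)
  pf <- rep(NA_real_, nrow(stations))
  ok <- !is.na(stations$no3) & !is.na(stations$po4) & stations$po4 > 0
  pf[ok] <- pacific_fraction(stations$no3[ok], stations$po4[ok], config)
  stations$pacific_fraction <- pf
  list(stations = stations,
       summary = group_summary(stations))
}
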