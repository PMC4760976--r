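# Synthetic-data generators. Everything the pipeline consumes can be
# generated with the statistical structure the analysis assumes: four
# water-mass-structured community clusters, triplicate ARISA peak tables
# with size jitter and noise peaks, pyrosequencing-style reads with
# length artifacts, Ns, chimeras and singleton variants, and
# size-fractionated chlorophyll coupled to a designated bloom taxon.
# All generators are pure functions of (parameters, seed).

# Fixed seed sequences the taxon pool is derived from (60 bp lines).
SEED_SEQS <- c(
  paste0("AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGA",
         "ACCCCCTGCACGCCCTAAAGTACAATTAGGATATTCATCCCTACACTGTATATGCCGAAC",
         "GTTCTAATAAACGACTTAGCAACAAGTCGCCTAGAAAGGTACCGCTGGCATATCACGCCT",
         "CCCGCTTGCCGTCTTCAACTTCATGACCCTCGTGCATCACAAAGCCTCAAGCCGGAGTCT",
         "AGGCTTTGAAACAGCTGAATAAATCGTGTGAATACGTGAGTCGTCGGAAAGCAGTTGAAT",
         "ATCTAACGACCCCTGCGCAAGGACACACTAGTCGCCCTTGAGAGCACTCCAGTCCAGGCG",
         "AGGTATCCACGACGATACGACTCGGCTAGCAAACGCGCGGTTTATCTATGCAGCTAATAT"),
  paste0("CCTTAGTAGTCGACCCCTGAGATGACCGGTCATCAGGCGGCATCCGACGCACCAACGGCT",
         "CCTACAGACTCGTGCTACCGGACCATGCGACTCGAACATCAGATGGACAGACCTCGTAAT",
         "AGCCGGGCCATGTAACACTGATGTCTCCGGGCAGCTCATGACGAGCACCAGACCCGAGAG",
         "TTCCTGTTAGTTTTGGTTAGGCACGGAACGCTATCGAGCGCGTAAGCGCCAACCCGCATT",
         "TACGAAGTACCCATCGTATGTAATAAGACCTCGAGTACGTCGGGACGTTGGCTGTGATGT",
         "TTTGATGAGCGAAGTTCGACGTTGCCGATGTTTACCCTAAGGGAGACGACATCATCGCAC",
         "GACTCGTCATTTGCATCATCTCCACTGCCCCGATGTCTGCTATGGACGGCTTCACCTGAT"),
  paste0("GTGGAGCGAGGGTACTGATAGATATACGACAATGCACGTAGTCTCGATACGTCATTGGTA",
         "CGAACAGTTCGTATTCCCCATGTCTGGACCGACGTTAAGCTCATGTCTCAGGACGGAGAA",
         "TGCAGCCCAACAGCTTGGCCGGATCAAGCAGGATGAGAGGCACTTACTTTCCCCGCTACG",
         "ATGCTTTGCACAAATTCTACCGCATTGATCGTGGATTACTAGTTTTGATGGCATGGGTAA",
         "TGGTGGAGCCAAACATCCAGCTAGCAGCTGCAAGCTTTGCCTACGTGGAGTCTCTGTGAA",
         "ATTCAGAGATACGCAGCTAATGGCCCCGCTTAACGGGTGCATCGGCACAGCCTCGTGCAG",
         "CCCTCACAAATTTCCGCCATCAGTGATTCAGTATTGTTTCACCGCAGTTACCGTGAAGTG"),
  paste0("CCGCCATATACACAGGTTCATGCTAGAGAAACTGCCACCCGGGCTTGCCAACCGGCAACG",
         "TGGCGTTGATTGACAGAGCTTCTTAAGCCGCTGATGTCCAAAAACTGAGTTAGTTCGAGA",
         "TAGTTGGATGTCGCACTAGAGGGAACAGCCATAGGACCGATACAGACAGTTCAATGGCGG",
         "ATGCCCGCACCTGTATACACCTAGTATGTAAAAATTGAATACGAGAGGGGCACCCTTTTG",
         "CCCTCCCACTGTCTATTCCAGGTCGCCGAATATGTCCCGACTTCGACCCGTTTGGTAGGC",
         "CAGGGGCCTGGGCTAAACACGGCCTTCCCGATTGCCATGAACTCGTTTCGCCTTAAAGTC",
         "CAACCGTAAAGAAGCGACAGCGACCTAATCCGAGCTTTATCTTTTAAGCGGGCGCGGGGA"))

COMMUNITY_CLUSTERS <- c("fram_E", "fram_W", "nansen", "amundsen")

LINEAGE_FAMILIES <- c(
  "Eukaryota;Haptophyta;Prymnesiophyceae;Phaeocystaceae",
  "Eukaryota;Chlorophyta;Mamiellophyceae;Mamiellaceae",
  "Eukaryota;Alveolata;Dinophyceae;Prorocentrales",
  "Eukaryota;Alveolata;Dinophyceae;Gymnodiniales",
  "Eukaryota;Alveolata;Syndiniales;Amoebophryaceae",
  "Eukaryota;Stramenopiles;Bolidophyceae;Bolidomonadaceae",
  "Eukaryota;Haptophyta;Prymnesiophyceae;Chrysochromulinaceae",
  "Eukaryota;Chlorophyta;Pyramimonadophyceae;Pyramimonadaceae")

mutate_positions <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in positions) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic taxon pool
#'
#' Builds `n_taxa` taxa from a handful of fixed seed sequences, mutating
#' each seed at ~12% of its positions per taxon so that any two taxa are
#' at least ~10% diverged (verified, so the 97% OTU radius cleanly
#' separates taxa). Each taxon gets a unique ARISA (ITS) fragment length
#' on a grid whose spacing exceeds twice the bin width, a ranked lineage,
#' and an affinity weight per community cluster. Taxon 1 is a dominant
#' Phaeocystaceae-like bloom former in the Atlantic-influenced clusters
#' (it also drives the chlorophyll coupling); taxon 2 is a
#' Micromonas-like Mamiellaceae peaking in the Nansen cluster; a fungal
#' and a metazoan taxon exercise downstream lineage exclusion. The
#' Nansen and western-Fram pools overlap strongly.
#'
#' @param n_taxa number of taxa (>= 30).
#' @param seed integer seed.
#' @param bin_width_bp ARISA bin width the fragment-length grid must
#'   respect.
#' @return a data.frame (`taxon`, `lineage`, `seq`, `its_len`, one
#'   `aff_*` column per cluster) with attribute `chl_taxon` (the
#'   chlorophyll-coupled taxon id).
#' @export
make_taxon_pool <- function(n_taxa = 40L, seed = 1L, bin_width_bp = 2) {
  if (n_taxa < 30) stop2("need at least 30 taxa for the cluster pools")
  set.seed(seed)
  seqs <- character(n_taxa)
  lens <- sample(330:480, n_taxa, replace = TRUE)
  for (i in seq_len(n_taxa)) {
    base <- SEED_SEQS[(i - 1) %% length(SEED_SEQS) + 1]
    repeat {
      n_mut <- ceiling(0.12 * nchar(base))
      cand <- mutate_positions(base, sample(nchar(base), n_mut))
      cand <- substr(cand, 1, lens[i])
      ok <- TRUE
      for (j in seq_len(i - 1)) {
        L <- min(nchar(cand), nchar(seqs[j]))
        same <- sum(strsplit(substr(cand, 1, L), "")[[1]] ==
                      strsplit(substr(seqs[j], 1, L), "")[[1]])
        if (same / L > 0.90) { ok <- FALSE; break }
      }
      if (ok) break
    }
    seqs[i] <- cand
  }
  step <- max(5, 2 * bin_width_bp + 1)
  its <- sort(sample(seq(105, 1195, by = step), n_taxa))
  aff <- matrix(0, n_taxa, 4,
                dimnames = list(NULL, COMMUNITY_CLUSTERS))
  aff[3:15, "fram_E"] <- 1
  aff[8:25, "fram_W"] <- 1
  aff[12:28, "nansen"] <- 1
  aff[26:n_taxa, "amundsen"] <- 1
  aff[1, "fram_E"] <- 12    # Phaeocystaceae-like bloom former
  aff[1, "fram_W"] <- 7
  aff[1, c("nansen", "amundsen")] <- 0.05   # rare biosphere only
  aff[2, "nansen"] <- 8     # Micromonas-like
  aff[2, "amundsen"] <- 2.5
  aff[2, "fram_W"] <- 0.8
  aff[30, "amundsen"] <- 3  # Syndiniales-like, Amundsen abundant
  fam <- LINEAGE_FAMILIES[(seq_len(n_taxa) - 1) %% length(LINEAGE_FAMILIES) + 1]
  fam[1] <- LINEAGE_FAMILIES[1]
  fam[2] <- LINEAGE_FAMILIES[2]
  fam[30] <- LINEAGE_FAMILIES[5]
  fam[24] <- "Eukaryota;Opisthokonta;Fungi;Chytridiomycetes"
  fam[n_taxa - 1] <- "Eukaryota;Opisthokonta;Metazoa;Maxillopoda"
  pool <- data.frame(taxon = sprintf("T%02d", seq_len(n_taxa)),
                     lineage = paste0(fam, ";", sprintf("Species_%02d",
                                                        seq_len(n_taxa))),
                     seq = seqs, its_len = its,
                     stringsAsFactors = FALSE)
  colnames(aff) <- paste0("aff_", COMMUNITY_CLUSTERS)
  pool <- cbind(pool, aff)
  attr(pool, "chl_taxon") <- pool$taxon[1]
  pool
}

pool_affinity <- function(pool) {
  m <- as.matrix(pool[, paste0("aff_", COMMUNITY_CLUSTERS)])
  rownames(m) <- pool$taxon
  colnames(m) <- COMMUNITY_CLUSTERS
  m
}

#' Generate synthetic stations with known water-mass structure
#'
#' Four station groups mirror the observed regional hydrography:
#' Atlantic-inflow stations (`fram_E`) draw S ~ N(34.95, 0.1) and
#' T ~ N(5, 1); the three halocline groups (`fram_W`, `nansen`,
#' `amundsen`) draw S ~ U(30, 34.3) with T on the surface freezing line
#' plus |N(0, 0.15)|. Ice concentration and NO3/Si/PO4 are drawn from
#' each region's observed mean (ice: mean plus U(-15, 15), clipped to
#' \[0, 100\]; nutrients: normal with the region's mean and SD from
#' [ps80_stations()], truncated at 0). `n_runoff` stations in the shelf-
#' influenced groups are marked as continental-runoff sites (they get a
#' depressed pico chlorophyll share downstream).
#'
#' @param n_per_group stations per group (>= 2).
#' @param seed integer seed.
#' @param config a [pipeline_config()] (supplies the Pacific-fraction
#'   endmember lines used for the recorded truth).
#' @param n_runoff number of runoff-influenced stations.
#' @return list with `stations` (a station data.frame with a `runoff`
#'   column) and `truth` (list: `cluster`, `pacific_fraction`, `runoff`,
#'   all named by station).
#' @export
make_stations <- function(n_per_group = 8L, seed = 1L,
                          config = pipeline_config(), n_runoff = 2L) {
  if (n_per_group < 2) stop2("n_per_group must be >= 2")
  set.seed(seed)
  ref <- ps80_stations()
  stats_of <- function(region, var) {
    x <- ref[[var]][ref$region == region]
    c(mean = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE))
  }
  rows <- list()
  for (g in COMMUNITY_CLUSTERS) {
    if (g == "fram_E") {
      S <- rnorm(n_per_group, 34.95, 0.1)
      T <- rnorm(n_per_group, 5.0, 1.0)
    } else {
      S <- runif(n_per_group, 30, 34.3)
      T <- freezing_temperature(S) + abs(rnorm(n_per_group, 0, 0.15))
    }
    ice_mu <- stats_of(g, "ice")[["mean"]]
    ice <- pmin(100, pmax(0, ice_mu + runif(n_per_group, -15, 15)))
    nut <- sapply(c("no3", "si", "po4"), function(v) {
      st <- stats_of(g, v)
      pmax(0.01, rnorm(n_per_group, st[["mean"]], st[["sd"]]))
    })
    rows[[g]] <- data.frame(
      station = sprintf("SY_%s_%02d", g, seq_len(n_per_group)),
      date = NA_character_, region = g, ice = ice, temp = T, sal = S,
      no3 = nut[, "no3"], si = nut[, "si"], po4 = nut[, "po4"],
      stringsAsFactors = FALSE)
  }
  st <- do.call(rbind, rows)
  rownames(st) <- NULL
  shelf <- which(st$region %in% c("fram_W", "amundsen"))
  runoff <- rep(FALSE, nrow(st))
  runoff[sample(shelf, min(n_runoff, length(shelf)))] <- TRUE
  st$runoff <- runoff
  truth <- list(
    cluster = setNames(st$region, st$station),
    pacific_fraction = setNames(
      pacific_fraction(st$no3, st$po4, config), st$station),
    runoff = setNames(runoff, st$station))
  list(stations = st, truth = truth)
}

#' Draw per-sample taxon proportions for the community truth
#'
#' Each sample's community is its cluster's taxon pool: taxa with
#' affinity weight >= 2 (the cluster's dominants) are always present,
#' the remaining pool members are present with probability 0.75, and
#' proportions are the affinity weights perturbed by lognormal(0, 0.5)
#' noise and renormalized. The proportions matrix is stored in the truth
#' so that the ARISA, read and chlorophyll generators see one consistent
#' community.
#'
#' @param truth truth list from [make_stations()].
#' @param pool taxon pool from [make_taxon_pool()].
#' @param seed integer seed.
#' @param accessory_presence presence probability for non-dominant pool
#'   members.
#' @return the truth list with `proportions` (taxa x samples matrix,
#'   columns summing to 1) and `chl_driver` (the chlorophyll-coupled
#'   taxon's proportion per sample) added.
#' @export
simulate_community <- function(truth, pool, seed = 1L,
                               accessory_presence = 0.75) {
  set.seed(seed)
  aff <- pool_affinity(pool)
  samples <- names(truth$cluster)
  P <- matrix(0, nrow(pool), length(samples),
              dimnames = list(pool$taxon, samples))
  for (s in samples) {
    w <- aff[, truth$cluster[[s]]]
    in_pool <- w > 0
    present <- in_pool & (w >= 2 | runif(length(w)) < accessory_presence)
    if (!any(present)) present <- in_pool & w == max(w[in_pool])
    q <- w * present * rlnorm(length(w), 0, 0.5)
    P[, s] <- q / sum(q)
  }
  truth$proportions <- P
  truth$chl_driver <- P[attr(pool, "chl_taxon") %||% pool$taxon[1], ]
  truth
}

#' Simulate triplicate ARISA peak tables
#'
#' Every sample is fingerprinted in 3 replicates. A taxon with
#' proportion q produces a peak in a replicate with probability
#' `1 - dropout_p * (1 - q)`, at its true fragment length plus
#' N(0, `jitter_sd_bp`), with height proportional to q. Each replicate
#' additionally carries Poisson(`noise_rate`) spurious peaks at
#' U(40, 1200) bp — some below the 50 bp QC threshold by design.
#'
#' @param truth truth list with proportions (see [simulate_community()]).
#' @param pool taxon pool.
#' @param jitter_sd_bp fragment-size measurement noise (bp).
#' @param dropout_p per-replicate dropout scale for low-abundance taxa.
#' @param noise_rate expected spurious peaks per replicate.
#' @param seed integer seed.
#' @return a peak table data.frame (see [read_peak_table()]).
#' @export
simulate_arisa <- function(truth, pool, jitter_sd_bp = 0.3, dropout_p = 0.1,
                           noise_rate = 1.0, seed = 1L) {
  if (is.null(truth$proportions))
    stop2("truth lacks proportions; run simulate_community() first")
  stopifnot(dropout_p >= 0, dropout_p < 1, noise_rate >= 0)
  set.seed(seed)
  its <- setNames(pool$its_len, pool$taxon)
  rows <- list()
  for (s in colnames(truth$proportions)) {
    q <- truth$proportions[, s]
    present <- names(q)[q > 0]
    for (rep_i in 1:3) {
      emit <- runif(length(present)) < 1 - dropout_p * (1 - q[present])
      taxa <- present[emit]
      if (length(taxa)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, replicate = rep_i,
          size_bp = its[taxa] + rnorm(length(taxa), 0, jitter_sd_bp),
          height = 5000 * q[taxa], stringsAsFactors = FALSE)
      }
      n_noise <- rpois(1, noise_rate)
      if (n_noise > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, replicate = rep_i,
          size_bp = runif(n_noise, 40, 1200),
          height = runif(n_noise, 20, 120), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

random_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")

apply_errors <- function(seq, sub_rate, n_rate) {
  L <- nchar(seq)
  n_sub <- rbinom(1, L, sub_rate)
  if (n_sub > 0) seq <- mutate_positions(seq, sample(L, n_sub))
  n_n <- rbinom(1, L, n_rate)
  if (n_n > 0) {
    chars <- strsplit(seq, "")[[1]]
    chars[sample(L, n_n)] <- "N"
    seq <- paste(chars, collapse = "")
  }
  seq
}

#' Simulate pyrosequencing-style amplicon reads
#'
#' Reads are drawn from the taxon base sequences in proportion to the
#' per-sample community, prefixed with the forward primer 528F. Error
#' model: per-base substitutions at `sub_rate`, per-base N conversion at
#' `n_rate`; a `len_spread` fraction of reads is truncated below 300 bp
#' or padded above 670 bp (to exercise the length filters); `chimera_p`
#' of reads are two-parent splices with a breakpoint at U(0.25, 0.75) of
#' the read; `singleton_k` reads per sample come from unique one-off
#' variants about 8% diverged from every pool sequence. Injected
#' chimera and singleton read ids are recorded in the truth.
#'
#' @param truth truth list with proportions.
#' @param pool taxon pool.
#' @param n_reads_per_sample reads per sample (>= 50).
#' @param sub_rate,n_rate per-base substitution and N-conversion rates.
#' @param len_spread fraction of reads with a length artifact.
#' @param chimera_p fraction of reads replaced by chimeras.
#' @param singleton_k number of singleton-variant reads per sample.
#' @param forward_primer 5' primer prepended to every read.
#' @param seed integer seed.
#' @return list with `reads` (read data.frame) and `truth` (updated with
#'   `chimera_ids` and `singleton_ids`).
#' @export
simulate_reads <- function(truth, pool, n_reads_per_sample = 150L,
                           sub_rate = 0.002, n_rate = 5e-4,
                           len_spread = 0.04, chimera_p = 0.05,
                           singleton_k = 2L,
                           forward_primer = "GCGGTAATTCCAGCTCCAA",
                           seed = 1L) {
  if (is.null(truth$proportions))
    stop2("truth lacks proportions; run simulate_community() first")
  if (n_reads_per_sample < 50) stop2("n_reads_per_sample must be >= 50")
  stopifnot(sub_rate >= 0, sub_rate < 1, chimera_p >= 0, chimera_p < 1)
  set.seed(seed)
  base_read <- setNames(paste0(forward_primer, pool$seq), pool$taxon)
  chim_ids <- character(0)
  sing_ids <- character(0)
  out <- list()
  for (s in colnames(truth$proportions)) {
    q <- truth$proportions[, s]
    n <- n_reads_per_sample
    n_sing <- min(singleton_k, n)
    n_chim <- rbinom(1, n - n_sing, chimera_p)
    n_norm <- n - n_sing - n_chim
    ids <- sprintf("%s_r%04d", s, seq_len(n))
    type <- sample(c(rep("norm", n_norm), rep("chim", n_chim),
                     rep("sing", n_sing)))
    seqs <- character(n)
    for (i in seq_len(n)) {
      if (type[i] == "norm") {
        tx <- sample(pool$taxon, 1, prob = q)
        rd <- base_read[[tx]]
        if (runif(1) < len_spread) {
          if (runif(1) < 0.5) {
            rd <- substr(rd, 1, sample(150:295, 1))
          } else {
            rd <- paste0(rd, random_bases(sample(675:700, 1) - nchar(rd)))
          }
        }
        seqs[i] <- apply_errors(rd, sub_rate, n_rate)
      } else if (type[i] == "chim") {
        # bimeras splice closely related co-amplified templates at a
        # homologous coordinate; formation scales with the product of
        # the two template abundances, so dominant same-family pairs
        # dominate (an abundance floor, relaxed when no pair meets it,
        # keeps vanishingly rare pairings out)
        fam <- (seq_along(pool$taxon) - 1) %% length(SEED_SEQS)
        pairs <- NULL
        for (floor_q in c(0.03, 0.01, 0)) {
          idx <- which(q > floor_q)
          cand <- expand.grid(a = idx, b = idx)
          cand <- cand[cand$a != cand$b & fam[cand$a] == fam[cand$b], ]
          if (nrow(cand) >= 1) { pairs <- cand; break }
        }
        if (is.null(pairs)) {
          idx <- which(q > 0)
          pairs <- expand.grid(a = idx, b = idx)
          pairs <- pairs[pairs$a != pairs$b, ]
        }
        pick <- pairs[sample.int(nrow(pairs), 1,
                                 prob = q[pairs$a] * q[pairs$b]), ]
        ra <- base_read[[pool$taxon[pick$a]]]
        rb <- base_read[[pool$taxon[pick$b]]]
        bp <- round(runif(1, 0.25, 0.75) * min(nchar(ra), nchar(rb)))
        rd <- paste0(substr(ra, 1, bp), substr(rb, bp + 1, nchar(rb)))
        seqs[i] <- apply_errors(rd, sub_rate, n_rate)
        chim_ids <- c(chim_ids, ids[i])
      } else {
        tx <- sample(pool$taxon, 1, prob = q)
        rd <- base_read[[tx]]
        body <- substr(rd, nchar(forward_primer) + 1, nchar(rd))
        n_mut <- ceiling(0.08 * nchar(body))
        body <- mutate_positions(body, sample(nchar(body), n_mut))
        seqs[i] <- paste0(forward_primer, body)
        sing_ids <- c(sing_ids, ids[i])
      }
    }
    out[[s]] <- data.frame(id = ids, sample = s, seq = seqs,
                           stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, out)
  rownames(reads) <- NULL
  truth$chimera_ids <- chim_ids
  truth$singleton_ids <- sing_ids
  list(reads = reads, truth = truth)
}

#' Simulate size-fractionated chlorophyll a
#'
#' Total Chl a is lognormal with the Atlantic group's median about five
#' times the halocline groups' median; within each group the residual is
#' coupled (Pearson `coupling_r` on the log scale) to the
#' Phaeocystaceae-like taxon's within-group standardized proportion, so
#' the bloom taxon's sequence abundance and chlorophyll co-vary. The
#' pico (0.4--3 um) share is U(0.60, 0.90) except at runoff stations,
#' where larger cells dominate and the share is U(0.10, 0.35). The two
#' larger fractions split the remainder. Total equals the sum of the
#' fractions by construction.
#'
#' @param truth truth list with proportions (see [simulate_community()]).
#' @param seed integer seed.
#' @param coupling_r within-group log-scale correlation between total
#'   Chl a and the bloom taxon's proportion.
#' @param sdlog lognormal spread of total Chl a.
#' @return a chlorophyll data.frame (see [read_chl_table()]).
#' @export
simulate_chl <- function(truth, seed = 1L, coupling_r = 0.8, sdlog = 0.25) {
  if (is.null(truth$chl_driver))
    stop2("truth lacks chl_driver; run simulate_community() first")
  set.seed(seed)
  samples <- names(truth$cluster)
  meanlog <- ifelse(truth$cluster == "fram_E", log(1.5), log(0.3))
  z <- ave(truth$chl_driver, truth$cluster, FUN = function(x) {
    s <- sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  eps <- rnorm(length(samples))
  total <- exp(meanlog + sdlog * (coupling_r * z +
                                    sqrt(1 - coupling_r^2) * eps))
  share <- ifelse(truth$runoff[samples],
                  runif(length(samples), 0.10, 0.35),
                  runif(length(samples), 0.60, 0.90))
  pico <- share * total
  split_big <- runif(length(samples), 0.3, 0.7)
  gt10 <- (total - pico) * split_big
  mid <- total - pico - gt10
  data.frame(station = samples, chl_gt10 = gt10, chl_3_10 = mid,
             chl_0p4_3 = pico, stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a taxon pool as a reference set
#'
#' Emits the pool's base sequences as a lineage-annotated reference
#' FASTA + TSV pair usable with [read_reference_set()]. The files are
#' synthetic stand-ins for a curated reference database.
#'
#' @param pool taxon pool from [make_taxon_pool()].
#' @param fasta_path,lineage_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_reference_set <- function(pool, fasta_path, lineage_path) {
  write_fasta(data.frame(id = pool$taxon, seq = pool$seq,
                         stringsAsFactors = FALSE), fasta_path)
  write.table(data.frame(id = pool$taxon, lineage = pool$lineage),
              lineage_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(fasta = fasta_path, lineage = lineage_path))
}
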