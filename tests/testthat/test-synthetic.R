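test_that("generators are pure functions of parameters and seed", {
  a <- make_stations(4, seed = 9)
  b <- make_stations(4, seed = 9)
  expect_identical(a, b)
  pool1 <- make_taxon_pool(seed = 9)
  pool2 <- make_taxon_pool(seed = 9)
  expect_identical(pool1, pool2)
  tr1 <- simulate_community(a$truth, pool1, seed = 9)
  tr2 <- simulate_community(b$truth, pool2, seed = 9)
  expect_identical(tr1, tr2)
  expect_identical(simulate_arisa(tr1, pool1, seed = 9),
                   simulate_arisa(tr2, pool2, seed = 9))
  expect_identical(simulate_reads(tr1, pool1, seed = 9),
                   simulate_reads(tr2, pool2, seed = 9))
  expect_identical(simulate_chl(tr1, seed = 9), simulate_chl(tr2, seed = 9))
})

test_that("taxon pool separates taxa and spaces ARISA fragments", {
  pool <- make_taxon_pool(seed = 2)
  expect_false(any(duplicated(pool$its_len)))
  expect_true(all(diff(sort(pool$its_len)) >= 2 * 2))  # >= 2x bin width
  expect_true(all(nchar(pool$seq) >= 310 & nchar(pool$seq) <= 500))
  aff <- as.matrix(pool[, grep("^aff_", names(pool))])
  expect_true(all(rowSums(aff) > 0))
  # any two taxa are beyond the 97% OTU radius
  idm <- identity_matrix(pool$seq, prescreen = 0)
  expect_lt(max(idm[lower.tri(idm)]), 0.97)
})

test_that("halocline stations hug the freezing line; Atlantic stations do not", {
  st <- make_stations(20, seed = 3)$stations
  halo <- st[st$region != "fram_E", ]
  expect_true(all(abs(halo$temp - freezing_temperature(halo$sal)) <= 0.7))
  atl <- st[st$region == "fram_E", ]
  expect_gt(mean(atl$sal), 34.5)
  expect_true(all(st$ice >= 0 & st$ice <= 100))
})

test_that("generated nutrients reproduce the observed regional statistics", {
  st <- make_stations(200, seed = 8)$stations
  ref <- ps80_stations()
  for (v in c("no3", "si", "po4")) {
    x <- ref[[v]][ref$region == "nansen"]
    target <- mean(x, na.rm = TRUE)
    se <- sd(x, na.rm = TRUE) / sqrt(200)
    got <- mean(st[[v]][st$region == "nansen"])
    expect_lt(abs(got - target), 2 * se + 1e-9)
  }
})

test_that("per-sample proportions are a distribution over the cluster pool", {
  w <- tiny_world(seed = 5)
  P <- w$truth$proportions
  expect_equal(unname(colSums(P)), rep(1, ncol(P)), tolerance = 1e-12)
  aff <- as.matrix(w$pool[, grep("^aff_", names(w$pool))])
  colnames(aff) <- sub("^aff_", "", colnames(aff))
  for (s in colnames(P)) {
    outside <- aff[, w$truth$cluster[[s]]] == 0
    expect_true(all(P[outside, s] == 0))
  }
})

test_that("ARISA noise-free limit reproduces the truth support exactly", {
  w <- tiny_world(seed = 10, n_per_group = 3)
  pk <- simulate_arisa(w$truth, w$pool, jitter_sd_bp = 0, dropout_p = 0,
                       noise_rate = 0, seed = 10)
  pa <- bin_fragments(consolidate_replicates(qc_peaks(pk)))
  support <- t(w$truth$proportions > 0)[rownames(pa), ]
  support <- support[, colSums(support) > 0, drop = FALSE]
  expect_true(all(unname(pa) == unname(support)))
  expect_equal(dim(pa), dim(support))
})

test_that("read simulation conserves counts and records artifact ids", {
  w <- tiny_world(seed = 11, n_per_group = 2)
  rd <- simulate_reads(w$truth, w$pool, n_reads_per_sample = 60, seed = 11)
  expect_equal(unname(table(rd$reads$sample)),
               unname(table(rep(names(w$truth$cluster), each = 60))))
  expect_true(all(rd$truth$chimera_ids %in% rd$reads$id))
  expect_true(all(rd$truth$singleton_ids %in% rd$reads$id))
  expect_false(any(duplicated(rd$reads$id)))
  # singleton variants stay far from every pool sequence
  for (id in utils::head(rd$truth$singleton_ids, 3)) {
    sq <- rd$reads$seq[rd$reads$id == id]
    ids <- vapply(paste0("GCGGTAATTCCAGCTCCAA", w$pool$seq),
                  function(p) pairwise_identity(sq, p), 0)
    expect_lt(max(ids), 0.97)
  }
})

test_that("noiseless reads recover one OTU per taxon with >= 2 reads", {
  w <- tiny_world(seed = 12, n_per_group = 2)
  rd <- simulate_reads(w$truth, w$pool, n_reads_per_sample = 60,
                       sub_rate = 0, n_rate = 0, len_spread = 0,
                       chimera_p = 0, singleton_k = 0, seed = 12)
  flt <- filter_reads(rd$reads)
  otus <- remove_singletons(cluster_otus_farthest_neighbor(flt$kept))
  taxon_counts <- table(factor(
    vapply(flt$kept$seq, function(s)
      w$pool$taxon[match(s, paste0("GCGGTAATTCCAGCTCCAA", w$pool$seq))], ""),
    levels = w$pool$taxon))
  expect_equal(length(otus), sum(taxon_counts >= 2))
})

test_that("chlorophyll fractions are internally consistent", {
  w <- tiny_world(seed = 13, n_per_group = 6)
  chl <- simulate_chl(w$truth, seed = 13)
  tot <- total_chl(chl)
  expect_equal(chl$chl_gt10 + chl$chl_3_10 + chl$chl_0p4_3, tot,
               tolerance = 1e-12)
  share <- pico_share(chl)
  runoff <- w$truth$runoff[chl$station]
  expect_true(all(share[!runoff] >= 0.60 & share[!runoff] <= 0.90))
  expect_true(all(share[runoff] >= 0.10 & share[runoff] <= 0.35))
  # Atlantic stations carry roughly five-fold the halocline biomass
  med_atl <- median(tot[w$truth$cluster[chl$station] == "fram_E"])
  med_halo <- median(tot[w$truth$cluster[chl$station] != "fram_E"])
  expect_gt(med_atl / med_halo, 2.5)
})

test_that("the Atlantic bloom taxon dominates the abundant biosphere there", {
  w <- tiny_world(seed = 14, n_per_group = 4)
  P <- w$truth$proportions
  atl <- names(w$truth$cluster)[w$truth$cluster == "fram_E"]
  phaeo <- attr(w$pool, "chl_taxon")
  # among taxa above 1%, the bloom former carries > 40% of the mass
  share <- vapply(atl, function(s) {
    q <- P[, s]
    abundant <- q > 0.01
    q[phaeo] / sum(q[abundant])
  }, 0)
  expect_gt(mean(share), 0.40)
})
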