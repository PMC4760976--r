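make_refs <- function(pool) {
  td <- withr::local_tempdir(.local_envir = parent.frame())
  write_reference_set(pool, file.path(td, "refs.fasta"),
                      file.path(td, "lineage.tsv"))
  read_reference_set(file.path(td, "refs.fasta"), file.path(td, "lineage.tsv"))
}

test_that("a query identical to a reference gets its full lineage at confidence 1", {
  pool <- make_taxon_pool(seed = 1)
  refs <- make_refs(pool)
  res <- assign_taxonomy(pool$seq[1], refs, seed = 3)
  expect_true(res$assigned)
  expect_equal(res$lineage, pool$lineage[1])
  expect_equal(unname(res$confidence), 1)
  # confidence never increases with rank depth
  expect_true(all(diff(res$rank_confidence) <= 1e-12))
})

test_that("random queries are rejected by the confidence threshold", {
  pool <- make_taxon_pool(seed = 1)
  refs <- make_refs(pool)
  set.seed(99)
  unassigned <- vapply(1:10, function(i) {
    q <- random_dna(400)
    !assign_taxonomy(q, refs, seed = i)$assigned
  }, TRUE)
  expect_gte(mean(unassigned), 0.95)
})

test_that("banned lineages are excluded, unassigned OTUs are kept", {
  tab <- data.frame(
    otu_id = c("OTU_0001", "OTU_0002", "OTU_0003", "OTU_0004"),
    consensus = "ACGT",
    taxonomy = c("Eukaryota;Opisthokonta;Metazoa;Maxillopoda;X",
                 "Eukaryota;Haptophyta;Prymnesiophyceae;Phaeocystaceae;Y",
                 "",  # unassigned
                 "Eukaryota;Opisthokonta;Fungi;Chytridiomycetes;Z"),
    s1 = c(5L, 10L, 2L, 3L), stringsAsFactors = FALSE)
  out <- exclude_lineages(tab)
  expect_setequal(out$otu_id, c("OTU_0002", "OTU_0003"))
  expect_equal(exclude_lineages(tab, banned = character(0)), tab)
})

test_that("abundant biosphere uses a strict >1% per-sample rule", {
  tab <- data.frame(otu_id = c("O1", "O2", "O3"), consensus = "ACGT",
                    taxonomy = "",
                    s1 = c(15L, 10L, 975L), s2 = c(0L, 500L, 500L),
                    stringsAsFactors = FALSE)
  ab <- abundant_biosphere(tab)
  expect_true(ab["O1", "s1"])    # 1.5% > 1%
  expect_false(ab["O2", "s1"])   # exactly 1% is rare
  expect_true(ab["O2", "s2"])    # per-sample classification
  # abundant + rare partition every sample's OTUs
  expect_true(all(ab | !ab))
  expect_equal(dim(ab), c(3L, 2L))
  zero <- tab
  zero$s1 <- 0L
  expect_error(abundant_biosphere(zero), "zero total")
})

test_that("composition sums to one and pools unassigned reads", {
  tab <- data.frame(otu_id = c("O1", "O2", "O3"), consensus = "ACGT",
                    taxonomy = c("Eukaryota;Haptophyta;P;F;S",
                                 "Eukaryota;Chlorophyta;M;F2;S2", ""),
                    s1 = c(60L, 30L, 10L), s2 = c(0L, 0L, 5L),
                    stringsAsFactors = FALSE)
  comp <- composition_summary(tab, rank = 2)
  expect_equal(colSums(comp), c(s1 = 1, s2 = 1), tolerance = 1e-12)
  expect_equal(comp["Haptophyta", "s1"], 0.6)
  expect_equal(comp["unclassified", "s2"], 1)
})

test_that("exclusion and abundance classification commute on shared totals", {
  set.seed(8)
  # the banned OTU carries no reads here, so both orders see identical
  # per-sample denominators and must agree cell-for-cell
  tab <- data.frame(otu_id = sprintf("O%d", 1:6), consensus = "ACGT",
                    taxonomy = c("Eukaryota;Opisthokonta;Metazoa;X;Y",
                                 rep("Eukaryota;Haptophyta;P;F;S", 5)),
                    s1 = c(0L, sample(1:400, 5)),
                    s2 = c(0L, sample(1:400, 5)),
                    stringsAsFactors = FALSE)
  surv <- exclude_lineages(tab)
  path1 <- abundant_biosphere(surv)
  path2 <- abundant_biosphere(tab)[surv$otu_id, , drop = FALSE]
  expect_equal(path1, path2)
})

test_that("taxon-chlorophyll coupling is recovered near the design value", {
  pool <- make_taxon_pool(seed = 5)
  st <- make_stations(200, seed = 5)
  truth <- simulate_community(st$truth, pool, seed = 5)
  chl <- simulate_chl(truth, seed = 5, coupling_r = 0.8)
  fram <- names(truth$cluster)[truth$cluster == "fram_E"]
  comp <- matrix(truth$proportions[attr(pool, "chl_taxon"), fram],
                 nrow = 1, dimnames = list("Phaeocystaceae", fram))
  r <- taxon_chl_correlation(comp, chl[chl$station %in% fram, ],
                             "Phaeocystaceae")
  expect_gte(r, 0.7)
  expect_lte(r, 0.9)
  # an uncoupled taxon shows no correlation once the compositional
  # closure with the bloom former is removed (its share of the
  # non-bloom mass is independent of chlorophyll by construction)
  resid <- truth$proportions["T07", fram] /
    (1 - truth$proportions[attr(pool, "chl_taxon"), fram])
  comp0 <- matrix(resid, nrow = 1, dimnames = list("other", fram))
  r0 <- taxon_chl_correlation(comp0, chl[chl$station %in% fram, ], "other")
  expect_lt(abs(r0), 0.2)
  # perfect coupling is the identity case
  compx <- comp
  chlx <- chl[chl$station %in% fram, ]
  chlx$chl_gt10 <- 0
  chlx$chl_3_10 <- 0
  chlx$chl_0p4_3 <- comp[1, chlx$station]
  expect_equal(taxon_chl_correlation(compx, chlx, "Phaeocystaceae"), 1)
})

test_that("an optional reference tree is parsed and its tips validated", {
  skip_if_not_installed("ape")
  pool <- make_taxon_pool(seed = 1)
  td <- withr::local_tempdir()
  write_reference_set(pool, file.path(td, "refs.fasta"),
                      file.path(td, "lineage.tsv"))
  writeLines("(T01,(T02,T03));", file.path(td, "tree.nwk"))
  refs <- read_reference_set(file.path(td, "refs.fasta"),
                             file.path(td, "lineage.tsv"),
                             file.path(td, "tree.nwk"))
  expect_s3_class(refs$tree, "phylo")
  expect_setequal(refs$tree$tip.label, c("T01", "T02", "T03"))
  writeLines("(T01,UNKNOWN);", file.path(td, "tree.nwk"))
  expect_error(read_reference_set(file.path(td, "refs.fasta"),
                                  file.path(td, "lineage.tsv"),
                                  file.path(td, "tree.nwk")),
               "without lineage")
})
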