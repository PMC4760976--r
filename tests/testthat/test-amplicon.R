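PRIMER <- "GCGGTAATTCCAGCTCCAA"

make_read <- function(id, body, sample = "s1", primer = PRIMER) {
  data.frame(id = id, sample = sample, seq = paste0(primer, body),
             stringsAsFactors = FALSE)
}

test_that("read filters fire one rule each on a constructed toy set", {
  set.seed(1)
  body300 <- random_dna(300 - nchar(PRIMER))
  reads <- rbind(
    make_read("clean1", body300),
    make_read("clean2", random_dna(420)),
    make_read("short", random_dna(250 - nchar(PRIMER))),             # 250 bp
    make_read("long", random_dna(700 - nchar(PRIMER))),              # 700 bp
    make_read("many_n", sub("^(.{10})..", "\\1NN", random_dna(400))),
    data.frame(id = "no_primer", sample = "s1",
               seq = paste0("TTTT", random_dna(350)))
  )
  res <- filter_reads(reads)
  expect_setequal(res$kept$id, c("clean1", "clean2"))
  expect_equal(unname(res$counts[c("length_low", "length_high",
                                   "n_count", "primer")]),
               rep(1L, 4))
  expect_equal(sort(res$rejected$rule),
               sort(c("length_low", "length_high", "n_count", "primer")))
})

test_that("length and N boundaries are inclusive as specified", {
  r299 <- make_read("a", random_dna(299 - nchar(PRIMER)))
  r300 <- make_read("b", random_dna(300 - nchar(PRIMER)))
  res <- filter_reads(rbind(r299, r300))
  expect_equal(res$kept$id, "b")
  expect_equal(res$rejected$rule, "length_low")

  one_n <- make_read("one", paste0(random_dna(200), "N", random_dna(200)))
  two_n <- make_read("two", paste0(random_dna(200), "NN", random_dna(200)))
  res <- filter_reads(rbind(one_n, two_n))
  expect_equal(res$kept$id, "one")
  expect_equal(res$rejected$rule, "n_count")
})

test_that("an N inside the primer region counts as a primer mismatch", {
  bad <- data.frame(id = "n_primer", sample = "s1",
                    seq = paste0(sub("G", "N", PRIMER), random_dna(350)),
                    stringsAsFactors = FALSE)
  res <- filter_reads(bad)
  # the single N fails the strict primer prefix (N count itself is fine)
  expect_equal(res$rejected$rule, "primer")
})

test_that("pairwise identity matches its worked examples", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 1)
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGA"), 7 / 8)
  expect_equal(pairwise_identity("ANGT", "AAGT"), 3 / 4)  # N matches nothing
})

test_that("compiled identity equals an independent R dynamic program", {
  set.seed(42)
  for (i in 1:100) {
    a <- random_dna(sample(15:45, 1))
    b <- random_dna(sample(15:45, 1))
    if (runif(1) < 0.3) substr(b, 3, 4) <- "NN"
    expect_equal(pairwise_identity(a, b), r_nw_identity(a, b),
                 info = paste(a, b))
  }
})

test_that("identity matrix agrees with pairwise calls; prescreen zeroes far pairs", {
  set.seed(3)
  seqs <- replicate(6, random_dna(40))
  m <- identity_matrix(seqs)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(m[i, j], pairwise_identity(seqs[i], seqs[j]))
  ms <- identity_matrix(seqs, prescreen = 0.5)
  expect_true(all(ms[ms > 0] == m[ms > 0]))
})

test_that("farthest-neighbour clustering blocks merges past the radius", {
  # A-B and B-C within 97%, A-C at ~95%: C stays out
  set.seed(10)
  A <- random_dna(100)
  mutate_at <- function(s, pos) {
    cs <- strsplit(s, "")[[1]]
    for (p in pos) cs[p] <- setdiff(c("A", "C", "G", "T"), cs[p])[1]
    paste(cs, collapse = "")
  }
  B <- mutate_at(A, c(5, 50))
  C <- mutate_at(B, c(20, 70))
  expect_gte(pairwise_identity(A, B), 0.97)
  expect_gte(pairwise_identity(B, C), 0.97)
  expect_lt(pairwise_identity(A, C), 0.97)
  reads <- data.frame(id = c("a", "b", "c"), sample = "s1",
                      seq = c(A, B, C), stringsAsFactors = FALSE)
  otus <- cluster_otus_farthest_neighbor(reads, prescreen = 0)
  parts <- lapply(otus, `[[`, "members")
  expect_equal(sort(vapply(parts, paste, "", collapse = "+")),
               c("a+b", "c"))
})

test_that("identical reads collapse to one OTU and order never matters", {
  reads <- data.frame(id = sprintf("r%d", 1:5), sample = "s1",
                      seq = "ACGTACGTAA", stringsAsFactors = FALSE)
  otus <- cluster_otus_farthest_neighbor(reads)
  expect_length(otus, 1)
  expect_length(otus[[1]]$members, 5)

  set.seed(6)
  rnd <- random_read_set(15)
  p1 <- cluster_otus_farthest_neighbor(rnd, prescreen = 0)
  p2 <- cluster_otus_farthest_neighbor(rnd[sample(nrow(rnd)), ], prescreen = 0)
  key <- function(otus) sort(vapply(otus, function(o)
    paste(sort(o$members), collapse = "+"), ""))
  expect_equal(key(p1), key(p2))
})

test_that("every emitted OTU honors the farthest-neighbour guarantee", {
  set.seed(30)
  rnd <- random_read_set(20, max_sub = 2)
  otus <- cluster_otus_farthest_neighbor(rnd, prescreen = 0)
  for (o in otus) {
    u <- unique(o$seqs)
    if (length(u) > 1) {
      m <- identity_matrix(u)
      expect_gte(min(m[lower.tri(m)]), 0.97)
    }
  }
})

test_that("consensus follows majority vote with alphabetical ties", {
  expect_equal(consensus_sequence("ACGT"), "ACGT")
  expect_equal(consensus_sequence(c("ACGT", "ACGT", "ACTT")), "ACGT")
  expect_equal(consensus_sequence(c("CA", "CA", "CT", "CT")), "CA")
})

test_that("singleton removal drops only size-1 OTUs", {
  mk <- function(sizes) {
    structure(lapply(seq_along(sizes), function(i)
      list(id = sprintf("OTU_%04d", i),
           members = sprintf("m%d_%d", i, seq_len(sizes[i])),
           seqs = rep("ACGT", sizes[i]), consensus = "ACGT")),
      class = "otu_set", identity_threshold = 0.97)
  }
  out <- remove_singletons(mk(c(5, 1, 2, 1)))
  expect_equal(vapply(out, function(o) length(o$members), 0L), c(5L, 2L))
  keep <- mk(c(3, 2))
  expect_equal(length(remove_singletons(keep)), 2)
  expect_warning(none <- remove_singletons(mk(c(1, 1))), "singleton")
  expect_length(none, 0)
})

test_that("OTU tables conserve read counts per sample", {
  reads <- rbind(random_read_set(12), random_read_set(8))
  reads$id <- sprintf("r%02d", seq_len(nrow(reads)))
  otus <- cluster_otus_farthest_neighbor(reads, prescreen = 0)
  tab <- build_otu_table(otus, reads)
  counts <- as.matrix(tab[, c("s1", "s2")])
  expect_equal(colSums(counts), c(s1 = sum(reads$sample == "s1"),
                                  s2 = sum(reads$sample == "s2")))
  tab2 <- build_otu_table(otus, reads[sample(nrow(reads)), ])
  expect_equal(tab, tab2)
  empty <- build_otu_table(structure(list(), class = "otu_set"), reads)
  expect_equal(nrow(empty), 0)
})
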