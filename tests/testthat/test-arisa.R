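peak_df <- function(sample, replicate, size, height = 100) {
  data.frame(sample = sample, replicate = replicate, size_bp = size,
             height = height, stringsAsFactors = FALSE)
}

test_that("peak QC drops fragments below 50 bp, keeping the boundary", {
  pk <- peak_df("a", 1, c(43.1, 50.0, 102.4))
  expect_message(out <- qc_peaks(pk), "removed 1")
  expect_equal(out$size_bp, c(50.0, 102.4))
  empty <- pk[0, ]
  expect_equal(nrow(qc_peaks(empty)), 0)
  ok <- peak_df("a", 1, c(50, 60, 1200))
  expect_equal(qc_peaks(ok), ok)
})

test_that("replicate consolidation keeps peaks seen in >= 2 of 3 runs", {
  pk <- peak_df("a", c(1, 2, 3), c(100.1, 100.3, 99.9))
  out <- consolidate_replicates(pk)
  expect_equal(nrow(out), 1)
  expect_equal(out$size_bp, mean(c(100.1, 100.3, 99.9)), tolerance = 1e-12)

  lone <- rbind(pk, peak_df("a", 2, 250))
  out <- consolidate_replicates(lone)
  expect_equal(out$size_bp, 100.1, tolerance = 1e-9)  # singleton peak dropped

  apart <- peak_df("a", c(1, 2), c(100.0, 101.8))
  expect_equal(nrow(consolidate_replicates(apart, tol_bp = 1.0)), 0)
})

test_that("binning picks the frame that shares jittered peaks", {
  pk <- rbind(peak_df("a", 0, 100.9), peak_df("b", 0, 101.1))
  pa <- bin_fragments(pk, bin_width_bp = 2, shift_step = 0.1)
  expect_equal(ncol(pa), 1)          # both peaks in one shared bin
  expect_true(all(pa))
  expect_equal(attr(pa, "mean_similarity"), 1)
})

test_that("binning is invariant to sample order and to whole-width shifts", {
  set.seed(5)
  pk <- peak_df(rep(c("a", "b", "c"), each = 4), 0,
                runif(12, 100, 400))
  pa1 <- bin_fragments(pk)
  pk_rev <- pk[nrow(pk):1, ]
  pa2 <- bin_fragments(pk_rev)
  expect_equal(pa1, pa2)
  pk_shift <- pk
  pk_shift$size_bp <- pk_shift$size_bp + 3 * 2  # integer multiple of width
  pa3 <- bin_fragments(pk_shift)
  expect_equal(unname(pa1), unname(pa3))
})

test_that("the selected frame maximizes mean pairwise similarity", {
  set.seed(6)
  pk <- peak_df(rep(c("a", "b", "c", "d"), each = 5), 0,
                rep(runif(5, 100, 300), 4) + rnorm(20, 0, 0.4))
  pa <- bin_fragments(pk, bin_width_bp = 2, shift_step = 0.1)
  best <- attr(pa, "mean_similarity")
  for (o in seq(0, 1.95, by = 0.1)) {
    m <- arcticpico:::frame_matrix(pk, sort(unique(pk$sample)), 2, o)
    sim <- mean(1 - arcticpico:::lower_tri(jaccard_distances(m)))
    expect_lte(sim, best + 1e-12)
  }
})

test_that("jittered simulation is recovered almost exactly at width 2", {
  w <- tiny_world(seed = 2, n_per_group = 4)
  pk <- simulate_arisa(w$truth, w$pool, jitter_sd_bp = 0.3, dropout_p = 0,
                       noise_rate = 0, seed = 2)
  pa <- bin_fragments(consolidate_replicates(qc_peaks(pk)))
  # expected profile: the true fragment lengths of each sample's taxa,
  # binned in the frame the binner selected
  origin <- attr(pa, "origin")
  width <- attr(pa, "bin_width")
  truth_bins <- lapply(rownames(pa), function(s) {
    lens <- w$pool$its_len[w$truth$proportions[, s] > 0]
    unique(floor((lens - origin) / width))
  })
  all_bins <- sort(unique(c(unlist(truth_bins),
                            floor((as.numeric(colnames(pa)) - origin +
                                     width / 2) / width))))
  expected <- matrix(FALSE, nrow(pa), length(all_bins),
                     dimnames = list(rownames(pa), all_bins))
  for (i in seq_along(truth_bins))
    expected[i, as.character(truth_bins[[i]])] <- TRUE
  got <- matrix(FALSE, nrow(pa), length(all_bins),
                dimnames = dimnames(expected))
  got_bins <- floor((as.numeric(colnames(pa)) - origin + width / 2) / width)
  for (j in seq_along(got_bins))
    got[, as.character(got_bins[j])] <- got[, as.character(got_bins[j])] |
      pa[, j]
  expect_gte(mean(got == expected), 0.95)
})

test_that("empty input is rejected", {
  expect_error(bin_fragments(peak_df("a", 0, 100)[0, ]), "no peaks")
})
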