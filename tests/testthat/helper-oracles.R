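# Independent oracles used across test files.

# Plain-R Needleman-Wunsch oracle, written independently of the compiled
# implementation: forward DP over (score, matches, diagonal-steps) with
# lexicographic maximization (same disambiguation contract).
r_nw_identity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av)
  nb <- length(bv)
  S <- matrix(0, na + 1, nb + 1)
  M <- matrix(0L, na + 1, nb + 1)
  D <- matrix(0L, na + 1, nb + 1)
  S[1, ] <- gap * (0:nb)
  S[, 1] <- gap * (0:na)
  beats <- function(s1, m1, d1, s2, m2, d2) {
    s1 > s2 || (s1 == s2 && (m1 > m2 || (m1 == m2 && d1 > d2)))
  }
  for (i in 2:(na + 1)) {
    for (j in 2:(nb + 1)) {
      is_match <- av[i - 1] == bv[j - 1] && av[i - 1] != "N"
      sd <- S[i - 1, j - 1] + if (is_match) match else mismatch
      md <- M[i - 1, j - 1] + is_match
      dd <- D[i - 1, j - 1] + 1L
      bs <- sd; bm <- md; bd <- dd
      if (beats(S[i - 1, j] + gap, M[i - 1, j], D[i - 1, j], bs, bm, bd)) {
        bs <- S[i - 1, j] + gap; bm <- M[i - 1, j]; bd <- D[i - 1, j]
      }
      if (beats(S[i, j - 1] + gap, M[i, j - 1], D[i, j - 1], bs, bm, bd)) {
        bs <- S[i, j - 1] + gap; bm <- M[i, j - 1]; bd <- D[i, j - 1]
      }
      S[i, j] <- bs; M[i, j] <- bm; D[i, j] <- bd
    }
  }
  alen <- na + nb - D[na + 1, nb + 1]
  M[na + 1, nb + 1] / alen
}

# Welch formulas written out longhand (oracle for welch_t_test).
r_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Set-arithmetic Jaccard oracle over a presence/absence matrix.
r_jaccard <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- which(m[i, ] > 0)
    b <- which(m[j, ] > 0)
    d[i, j] <- 1 - length(intersect(a, b)) / length(union(a, b))
  }
  d
}

# ANOSIM statistic from scratch (for enumeration oracles).
r_anosim_R <- function(D, labels) {
  n <- nrow(D)
  pairs <- which(lower.tri(D), arr.ind = TRUE)
  r <- rank(D[pairs])
  within <- labels[pairs[, 1]] == labels[pairs[, 2]]
  M <- nrow(pairs)
  (mean(r[!within]) - mean(r[within])) / (M / 2)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Small clustered read set: k centers, each read a center with a few
# substitutions and occasional indels; the varying alignment lengths keep
# pairwise identities (matches / alignment length) mostly tie-free.
random_read_set <- function(n_reads = 20, n_centers = 5, len = 60,
                            max_sub = 3) {
  centers <- replicate(n_centers, random_dna(len))
  seqs <- vapply(seq_len(n_reads), function(i) {
    cs <- strsplit(sample(centers, 1), "")[[1]]
    k <- sample(0:max_sub, 1)
    if (k > 0) {
      pos <- sample(length(cs), k)
      for (p in pos) cs[p] <- sample(setdiff(c("A", "C", "G", "T"), cs[p]), 1)
    }
    n_indel <- sample(0:2, 1)
    for (j in seq_len(n_indel)) {
      if (runif(1) < 0.5 && length(cs) > 5) {
        cs <- cs[-sample(length(cs), 1)]
      } else {
        at <- sample(length(cs), 1)
        cs <- append(cs, sample(c("A", "C", "G", "T"), 1), after = at)
      }
    }
    paste(cs, collapse = "")
  }, "")
  data.frame(id = sprintf("r%02d", seq_len(n_reads)),
             sample = rep(c("s1", "s2"), length.out = n_reads),
             seq = seqs, stringsAsFactors = FALSE)
}

# A minimal synthetic world shared by several files.
tiny_world <- function(seed = 7, n_per_group = 3) {
  pool <- make_taxon_pool(seed = seed)
  st <- make_stations(n_per_group, seed = seed)
  truth <- simulate_community(st$truth, pool, seed = seed)
  list(pool = pool, stations = st$stations, truth = truth)
}
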