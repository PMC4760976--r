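test_that("Jaccard distances match set arithmetic and vegan", {
  m <- matrix(c(1, 1, 1, 0, 0, 1, 1, 1), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("100", "102", "104", "106")))
  D <- jaccard_distances(m)
  expect_equal(D["a", "b"], 0.5)   # 1 - 2/4
  expect_equal(diag(D), c(a = 0, b = 0))

  set.seed(9)
  big <- matrix(runif(200) > 0.5, 10, 20)
  big[rowSums(big) == 0, 1] <- TRUE
  rownames(big) <- sprintf("s%02d", 1:10)
  D <- jaccard_distances(big)
  expect_equal(unname(D), r_jaccard(big), tolerance = 1e-12)
  skip_if_not_installed("vegan")
  Dv <- as.matrix(vegan::vegdist(big * 1, method = "jaccard", binary = TRUE))
  expect_equal(unname(D), unname(Dv), tolerance = 1e-12)

  expect_equal(max(jaccard_distances(rbind(a = c(1, 0), b = c(0, 1)))), 1)
  expect_error(jaccard_distances(rbind(a = c(0, 0), b = c(1, 0))), "empty")
})

test_that("ANOSIM reaches R = 1 at maximal separation and is label-invariant", {
  n <- 8
  D <- matrix(0.9, n, n)
  D[1:4, 1:4] <- 0.1
  D[5:8, 5:8] <- 0.1
  diag(D) <- 0
  labels <- rep(c("x", "y"), each = 4)
  res <- anosim(D, labels, n_perm = 199, seed = 1)
  expect_equal(res$R, 1)
  relabeled <- anosim(D, rep(c("y", "x"), each = 4), n_perm = 199, seed = 1)
  expect_equal(relabeled$R, res$R)
  expect_true(res$p >= 1 / 200 && res$p <= 1)
})

test_that("ANOSIM agrees with vegan on a random configuration", {
  skip_if_not_installed("vegan")
  set.seed(21)
  X <- rbind(matrix(rnorm(20), 10, 2), matrix(rnorm(20, 1.5), 10, 2))
  D <- as.matrix(dist(X))
  labels <- rep(c("a", "b"), each = 10)
  mine <- anosim(D, labels, n_perm = 999, seed = 2)
  veg <- vegan::anosim(as.dist(D), labels, permutations = 999)
  expect_equal(mine$R, unname(veg$statistic), tolerance = 1e-12)
})

test_that("exact ANOSIM p equals a brute-force enumeration (n = 6)", {
  set.seed(13)
  D <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
  labels <- rep(c("g1", "g2"), each = 3)
  mine <- anosim(D, labels, exact = TRUE)
  # oracle: enumerate all choose(6,3) = 20 assignments directly
  combos <- combn(6, 3)
  R_all <- apply(combos, 2, function(ix) {
    lab <- rep("g2", 6)
    lab[ix] <- "g1"
    r_anosim_R(D, lab)
  })
  expect_equal(mine$n_perm, 20)
  expect_equal(mine$p, mean(R_all >= mine$R - 1e-12))
  expect_equal(mine$R, r_anosim_R(D, labels), tolerance = 1e-12)
})

test_that("Mantel r is 1 under identity and positive affine maps", {
  set.seed(4)
  D1 <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
  expect_equal(mantel_test(D1, D1, n_perm = 99)$r, 1)
  D2 <- 2.5 * D1 + 0.3
  diag(D2) <- 0
  expect_equal(mantel_test(D1, D2, n_perm = 99)$r, 1, tolerance = 1e-12)
})

test_that("exact Mantel p equals full enumeration over 120 orders (n = 5)", {
  set.seed(17)
  D1 <- as.matrix(dist(matrix(rnorm(10), 5, 2)))
  D2 <- as.matrix(dist(matrix(rnorm(10), 5, 2)))
  mine <- mantel_test(D1, D2, exact = TRUE)
  v1 <- D1[lower.tri(D1)]
  perms <- rbind(1:5)
  # oracle: recursive generation of all permutations, independent code path
  gen <- function(v) if (length(v) == 1) list(v) else {
    out <- list()
    for (i in seq_along(v))
      for (rest in gen(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  r_all <- vapply(gen(1:5), function(p) {
    Dp <- D2[p, p]
    stats::cor(v1, Dp[lower.tri(Dp)])
  }, 0)
  expect_equal(mine$n_perm, 120)
  expect_equal(mine$p, mean(r_all >= mine$r - 1e-12))
})

test_that("Mantel agrees with vegan and validates inputs", {
  skip_if_not_installed("vegan")
  set.seed(5)
  D1 <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  D2 <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  mine <- mantel_test(D1, D2, n_perm = 99, seed = 1)
  veg <- vegan::mantel(as.dist(D1), as.dist(D2), permutations = 99)
  expect_equal(mine$r, unname(veg$statistic), tolerance = 1e-12)
  expect_error(mantel_test(D1, matrix(0, 3, 3)), "dimension")
  expect_error(mantel_test(D1[1:3, 1:3], D2[1:3, 1:3]), "n >= 4")
})

test_that("pearson matches its definition and rejects degenerate input", {
  x <- c(1, 2, 4, 7)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -x), -1)
  set.seed(2)
  y <- rnorm(50)
  z <- rnorm(50)
  expect_equal(pearson(y, z), cor(y, z), tolerance = 1e-12)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson(1:2, 1:2), "3 points")
})

test_that("adjusted Rand index matches mclust and its anchors", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c(2, 2, 3, 3, 1, 1)), 1)
  skip_if_not_installed("mclust")
  set.seed(8)
  for (i in 1:10) {
    x <- sample(1:4, 25, TRUE)
    y <- sample(1:3, 25, TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
})
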