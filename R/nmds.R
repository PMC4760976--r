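# Non-metric multidimensional scaling by alternating isotonic regression
# and Guttman updates, minimizing Kruskal's stress-1.

#' Non-metric multidimensional scaling
#'
#' Embeds a dissimilarity matrix in `k` dimensions minimizing Kruskal's
#' stress-1, `sqrt(sum((d - dhat)^2) / sum(d^2))`, where `d` are
#' configuration distances and `dhat` the monotone (pool-adjacent-
#' violators) regression of `d` on the dissimilarity ranks (primary tie
#' treatment: tied dissimilarities are ordered by current configuration
#' distance before the isotonic fit). Each run alternates the isotonic
#' fit with a Guttman transform and stops when stress no longer
#' decreases by `tol`; the best of `n_restarts` random starts plus one
#' classical-scaling start is returned.
#'
#' @param D symmetric dissimilarity matrix.
#' @param k embedding dimension.
#' @param n_restarts number of random starts (in addition to the
#'   classical-scaling start).
#' @param max_iter iteration cap per run.
#' @param tol stress-decrease convergence tolerance.
#' @param seed integer seed for the random starts.
#' @return an `nmds_result` list: `points` (n x k matrix), `stress`,
#'   `converged`, `n_restarts`, `seed`, `stress_trace` (per-iteration
#'   stress of the winning run, non-increasing).
#' @export
nmds <- function(D, k = 2, n_restarts = 20, max_iter = 300, tol = 1e-7,
                 seed = 1L) {
  check_square(D)
  n <- nrow(D)
  if (n < k + 1) stop2("need at least k + 1 samples")
  idx <- pair_index(n)
  diss <- D[idx]
  ord0 <- order(diss)
  set.seed(seed)
  starts <- c(list(classical_start(D, k)),
              replicate(n_restarts,
                        matrix(runif(n * k, -1, 1), n, k), simplify = FALSE))
  best <- NULL
  for (X0 in starts) {
    run <- nmds_run(X0, diss, idx, k, max_iter, tol)
    if (is.null(best) || run$stress < best$stress) best <- run
  }
  rownames(best$points) <- rownames(D)
  best$n_restarts <- n_restarts
  best$seed <- seed
  class(best) <- "nmds_result"
  best
}

classical_start <- function(D, k) {
  X <- try(cmdscale(D, k = k), silent = TRUE)
  n <- nrow(D)
  if (inherits(X, "try-error") || NCOL(X) < k) {
    X2 <- matrix(0, n, k)
    if (!inherits(X, "try-error") && NCOL(X) > 0)
      X2[, seq_len(NCOL(X))] <- X
    return(X2 + matrix(rnorm(n * k, sd = 1e-4), n, k))
  }
  X
}

nmds_run <- function(X, diss, idx, k, max_iter, tol) {
  n <- nrow(X)
  stress_of <- function(d, dhat) {
    denom <- sum(d^2)
    if (denom == 0) return(0)
    sqrt(sum((d - dhat)^2) / denom)
  }
  config_dist <- function(X) {
    sqrt(rowSums((X[idx[, 1], , drop = FALSE] - X[idx[, 2], , drop = FALSE])^2))
  }
  d <- config_dist(X)
  dhat <- monotone_fit(diss, d)
  s <- stress_of(d, dhat)
  trace <- s
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # Guttman transform with target dhat
    ratio <- ifelse(d > 1e-12, dhat / d, 0)
    B <- matrix(0, n, n)
    B[idx] <- -ratio
    B[idx[, c(2, 1)]] <- -ratio
    diag(B) <- -rowSums(B)
    Xn <- B %*% X / n
    dn <- config_dist(Xn)
    dhn <- monotone_fit(diss, dn)
    sn <- stress_of(dn, dhn)
    if (sn <= s - tol) {
      X <- Xn; d <- dn; dhat <- dhn; s <- sn
      trace <- c(trace, s)
    } else {
      converged <- TRUE
      break
    }
  }
  list(points = X, stress = s, converged = converged, stress_trace = trace)
}

# Isotonic regression of configuration distances on dissimilarity order.
# Primary tie treatment: ties in the dissimilarities are pre-sorted by
# the current distances, so tied blocks are free to fit monotonically.
monotone_fit <- function(diss, d) {
  o <- order(diss, d)
  fit <- isoreg(d[o])$yf
  out <- numeric(length(d))
  out[o] <- fit
  out
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d points in %d dims, stress-1 = %.5f (%s, %d restarts)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "converged" else "iteration cap reached",
              x$n_restarts))
  invisible(x)
}
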