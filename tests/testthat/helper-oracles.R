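# Independent oracles used to freeze expected values. Each deliberately
# avoids the code path it checks.

# Hypergeometric upper tail P(X >= k) by direct summation of the pmf
# in log space (never calls phyper).
hyper_tail_oracle <- function(N, K, n, k) {
  j <- seq(max(k, max(0, n - (N - K))), min(K, n))
  if (length(j) == 0L) return(0)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# Truncated communicability by explicit enumeration of every walk of
# length 1..max_len. Walks are materialized as (start, current) pairs and
# extended one edge at a time; each completed walk of length k contributes
# 1/k! to its (start, end) cell. No matrix products involved.
walk_comm_oracle <- function(A, max_len = 6L) {
  n <- nrow(A)
  G <- matrix(0, n, n)
  if (n == 0L) return(G)
  nbr <- lapply(seq_len(n), function(i) which(A[i, ] == 1))
  deg <- lengths(nbr)
  start <- seq_len(n)
  cur <- seq_len(n)            # walks of length 0
  kfact <- 1
  for (k in seq_len(max_len)) {
    idx <- rep.int(seq_along(cur), deg[cur])
    if (length(idx) == 0L) break
    start <- start[idx]
    cur <- unlist(nbr[cur], use.names = FALSE)
    kfact <- kfact * k
    counts <- tabulate(start + n * (cur - 1L), nbins = n * n)
    G <- G + matrix(counts, n, n) / kfact
  }
  dimnames(G) <- dimnames(A)
  G
}

# Adjacency matrix of the graph encoded by bit mask `mask` over the
# pairs of n labelled nodes.
mask_adjacency <- function(n, mask) {
  A <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  pairs <- which(upper.tri(A), arr.ind = TRUE)
  for (b in seq_len(nrow(pairs))) {
    if (bitwAnd(mask, bitwShiftL(1L, b - 1L)) != 0L) {
      A[pairs[b, 1L], pairs[b, 2L]] <- 1
      A[pairs[b, 2L], pairs[b, 1L]] <- 1
    }
  }
  A
}

adjacency_to_network <- function(A) {
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  edges <- cbind(rownames(A)[idx[, 1L]], colnames(A)[idx[, 2L]])
  ppi_network(edges, nodes = rownames(A))
}

# Gamma-Poisson marginal by numerical quadrature over the rate. The
# integrand is concentrated where both the prior and the likelihood have
# mass; a finite upper bound from extreme gamma quantiles keeps the
# adaptive rule on target even for spiked priors.
marginal_quadrature_oracle <- function(k, n, a, b) {
  logf <- function(r) stats::dpois(k, n * r, log = TRUE) +
    stats::dgamma(r, shape = a, rate = b, log = TRUE)
  # the product of the two densities concentrates where a gamma with the
  # combined shape/rate has mass; rescale by the peak so the integrand
  # stays in floating-point range even when the marginal is ~1e-60
  peak_at <- if (a + k > 1) (a + k - 1) / (b + n) else
    stats::qgamma(0.5, shape = a + k, rate = b + n)
  L <- logf(peak_at)
  f <- function(r) exp(logf(r) - L)
  qs <- c(stats::qgamma(c(1e-12, 0.5, 1 - 1e-13), shape = a + k,
                        rate = b + n),
          stats::qgamma(1 - 1e-13, shape = a, rate = b))
  br <- sort(unique(c(0, qs)))
  total <- 0
  for (i in seq_len(length(br) - 1L)) {
    total <- total + stats::integrate(f, br[i], br[i + 1L],
                                      rel.tol = 1e-12, abs.tol = 1e-30,
                                      subdivisions = 2000L)$value
  }
  total * exp(L)
}

# One-sided rank-sum p-value by exhaustive enumeration of group
# assignments (feasible for tiny samples only).
ranksum_perm_oracle <- function(a, b) {
  v <- c(a, b)
  n <- length(v)
  idx <- utils::combn(n, length(a))
  w_obs <- sum(rank(v)[seq_along(a)])
  w_all <- apply(idx, 2L, function(i) sum(rank(v)[i]))
  mean(w_all >= w_obs)
}
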