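# Independent oracles and fixture builders used across the suite.

# build a site matrix object directly from a binary states matrix
make_sites <- function(states, positions = seq_len(ncol(states)),
                       gene_id = "test") {
  storage.mode(states) <- "integer"
  structure(list(gene_id = gene_id, positions = as.integer(positions),
                 states = states, S = ncol(states), n_seqs = nrow(states)),
            class = "phg_sites")
}

# build an alignment from explicit residue strings
make_alignment <- function(seqs, gene_id = "g", group_id = "grp") {
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- sprintf("s%d", seq_along(seqs))
  alignment(gene_id, group_id, mat)
}

# random biallelic site matrix: every column carries both alleles
rand_sites <- function(n, S, maxpos = 10L * S) {
  st <- matrix(stats::rbinom(n * S, 1L, 0.5), n, S)
  for (j in seq_len(S)) {
    if (length(unique(st[, j])) == 1L) st[sample(n, 1L), j] <- 1L - st[1L, j]
  }
  make_sites(st, positions = sort(sample.int(maxpos, S)))
}

# oracle 1: maximum number of pairwise disjoint intervals by dynamic
# programming (weighted interval scheduling with unit weights)
dp_max_disjoint <- function(iv) {
  k <- nrow(iv)
  if (k == 0L) return(0L)
  iv <- iv[order(iv$right_pos, iv$left_pos), , drop = FALSE]
  M <- integer(k)
  for (j in seq_len(k)) {
    p <- 0L
    for (i in rev(seq_len(j - 1L))) {
      if (iv$right_pos[i] <= iv$left_pos[j]) { p <- i; break }
    }
    M[j] <- max(if (j > 1L) M[j - 1L] else 0L,
                1L + if (p > 0L) M[p] else 0L)
  }
  M[k]
}

# oracle 2: exhaustive search over subsets (include/exclude recursion);
# only for small interval sets
exhaustive_max_disjoint <- function(iv) {
  k <- nrow(iv)
  if (k == 0L) return(0L)
  stopifnot(k <= 18L)
  iv <- iv[order(iv$left_pos, iv$right_pos), , drop = FALSE]
  recurse <- function(idx) {
    if (length(idx) == 0L) return(0L)
    first <- idx[1L]
    # exclude first
    best <- recurse(idx[-1L])
    # include first: keep only intervals disjoint from it
    rest <- idx[-1L]
    ok <- rest[iv$left_pos[rest] >= iv$right_pos[first] |
                 iv$right_pos[rest] <= iv$left_pos[first]]
    max(best, 1L + recurse(ok))
  }
  recurse(seq_len(k))
}

# gamete-set enumeration for a site pair (independent of the package's
# arithmetic encoding)
gametes_of <- function(a, b) unique(paste0(a, b))

# hypergeometric enumeration oracle for Fisher's exact test
fisher_enum <- function(a, b, c, d, sided = "two") {
  m <- a + b; K <- a + c; N <- a + b + c + d
  lo <- max(0L, m - (N - K)); hi <- min(m, K)
  support <- lo:hi
  probs <- stats::dhyper(support, K, N - K, m)
  p_obs <- stats::dhyper(a, K, N - K, m)
  if (sided == "two") {
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  } else if (sided == "greater") {
    sum(probs[support >= a])
  } else {
    sum(probs[support <= a])
  }
}

# exact attained size of the two-sided level-alpha Fisher test at given
# margins (m = row-1 total, K = column-1 total, N = grand total)
fisher_exact_size <- function(m, K, N, alpha = 0.05) {
  lo <- max(0L, m - (N - K)); hi <- min(m, K)
  as <- lo:hi
  pv <- vapply(as, function(a) {
    fisher_enum(a, m - a, K - a, N - K - m + a, "two")
  }, numeric(1))
  sum(stats::dhyper(as, K, N - K, m)[pv <= alpha])
}

# closed-form OLS via the normal equations
ols_normal_equations <- function(points) {
  X <- cbind(1, points$x1, points$x2)
  solve(crossprod(X), crossprod(X, points$y))[, 1L]
}

# one-sided Welch p-value via explicit statistic + density quadrature
welch_quadrature <- function(a, b) {
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- stats::integrate(function(x) stats::dt(x, df), lower = t,
                        upper = Inf, rel.tol = 1e-10)$value
  list(t = t, df = df, p = p)
}
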