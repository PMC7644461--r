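# Independent oracles used to verify the package's implementations.
# Each is written as directly as possible (enumeration / naive DP / closed
# form) and shares no code with the functions it checks.

# Spearman rho by explicit mid-rank + product-moment formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Exact permutation distribution of |rho| for small n: enumerate all n!
# permutations of y and count those at least as extreme as observed.
oracle_exact_perm_fraction <- function(x, y) {
  n <- length(y)
  perms <- all_permutations(n)
  obs <- abs(oracle_spearman(x, y))
  hits <- apply(perms, 1L, function(idx) {
    abs(oracle_spearman(x, y[idx])) >= obs - 1e-9
  })
  mean(hits)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Exhaustive optimal partitioning: unpruned O(n^2) dynamic program with the
# same Gaussian change-in-mean cost definition (naive per-segment RSS).
oracle_optimal_partition <- function(values, penalty, min_segment = 2L) {
  n <- length(values)
  sig2 <- var(diff(values)) / 2
  if (!is.finite(sig2) || sig2 <= 0) sig2 <- var(values)
  if (!is.finite(sig2) || sig2 <= 0) return(integer())
  segcost <- function(i, j) {
    x <- values[i:j]
    sum((x - mean(x))^2) / sig2
  }
  f <- c(-penalty, rep(Inf, n))
  prev <- integer(n)
  for (t in seq_len(n)) {
    if (t < min_segment) next
    for (tau in 0:(t - min_segment)) {
      v <- f[tau + 1L] + segcost(tau + 1L, t) + penalty
      if (v < f[t + 1L]) {
        f[t + 1L] <- v
        prev[t] <- tau
      }
    }
  }
  cps <- integer()
  t <- n
  while (t > 0L) {
    tau <- prev[t]
    if (tau > 0L) cps <- c(tau, cps)
    t <- tau
  }
  as.integer(cps)
}

# Exact two-sided paired-Wilcoxon p by full 2^n enumeration of sign flips
# applied to the observed mid-ranks.
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  total <- sum(r)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wp <- drop(signs %*% r)
  min(1, mean(wp <= w + 1e-9 | wp >= total - w - 1e-9))
}

# Small reusable community: 21 taxa across all six guilds.
small_group_counts <- function() {
  c(virus = 1L, bacteria = 2L, phytoplankton = 8L, HF = 2L,
    naked_ciliate = 4L, tintinnid = 4L)
}

small_community <- function(seed = 42L, n_weeks = 30L,
                            plan = interaction_plan()) {
  taxa <- generate_taxa(small_group_counts(), seed = seed)
  m <- generate_abundances(taxa, n_weeks, plan = plan, seed = seed + 1L)
  list(taxa = taxa, m = m)
}

# Abundance matrix of mutually independent lognormal columns.
independent_matrix <- function(n_cols, n_rows, seed) {
  taxa <- generate_taxa(c(phytoplankton = n_cols), seed = seed)
  generate_abundances(taxa, n_rows, plan = interaction_plan(), seed = seed)
}
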