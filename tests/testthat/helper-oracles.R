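# Independent oracle implementations used to cross-check the package's
# statistics, plus small fixture builders.  The oracles deliberately use
# different algorithms from the implementation they check.

# Brute-force two-sample K-S statistic: evaluate both ECDFs at every
# pooled point directly.
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}

# Permutation p value for the two-sample K-S statistic.
oracle_ks_perm_p <- function(x, y, B = 10000L) {
  d_obs <- oracle_ks_D(x, y)
  pooled <- c(x, y)
  n <- length(x)
  hits <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(length(pooled), n)
    if (oracle_ks_D(pooled[idx], pooled[-idx]) >= d_obs - 1e-12)
      hits <- hits + 1L
  }
  (hits + 1) / (B + 1)
}

# Fisher exact two-sided p by explicit enumeration of all tables with the
# observed margins, using choose() products directly.
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n2 <- c_ + d; k <- a + c_
  total <- choose(m + n2, k)
  xs <- max(0, k - n2):min(k, m)
  probs <- choose(m, xs) * choose(n2, k - xs) / total
  obs <- probs[xs == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Textbook Benjamini-Hochberg step-up, written independently of
# p.adjust: sort, apply p*(m/i), cummin from the largest rank.
oracle_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  pv <- p[idx]
  m <- length(pv)
  o <- order(pv)
  adj <- pv[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out[idx[o]] <- adj
  out
}

# Tiny deterministic count fixture with a known structure.
toy_counts <- function() {
  m <- matrix(c(10L, 20L, 5L,
                30L, 60L, 15L), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  m
}

# Minimal paired sample sheet: `pairs` littermate pairs x 2 genotypes x
# 2 fractions.
toy_samples <- function(pairs = 2L) {
  g <- expand.grid(fraction = c("IP", "Input"), genotype = c("WT", "KO"),
                   pair_id = seq_len(pairs), stringsAsFactors = FALSE)
  g$animal_id <- paste0("p", g$pair_id, "_", g$genotype)
  g$sample_id <- paste0(g$animal_id, "_", g$fraction)
  g[, c("sample_id", "fraction", "genotype", "pair_id", "animal_id")]
}

# Small simulated dataset for fast end-to-end tests.
small_sim <- function(seed = 101L, n_genes = 1500L, ...) {
  simulate_trap(sim_config(n_genes = n_genes, seed = seed,
                           n_up = 20L, n_down = 10L, n_target = 100L,
                           ...))
}
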