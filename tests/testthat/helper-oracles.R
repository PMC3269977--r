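# Independent oracles used to cross-check the implementation. These are
# deliberately written from first principles (plain loops, closed forms)
# and share no code with the package internals they validate.

# Pearson correlation of the two 0/1 allele indicator columns of a panel.
oracle_r_cor <- function(panel, i, j) {
  stats::cor(panel$haplotypes[, i], panel$haplotypes[, j])
}

# Mendelian legality of one (sire, dam, offspring) genotype triple by
# explicit enumeration of transmissible gametes; NA compatible with anything.
oracle_mendel_legal <- function(s, d, o) {
  if (is.na(o)) return(TRUE)
  gametes <- function(g) {
    if (is.na(g)) return(0:1)
    if (g == 0) return(0L)
    if (g == 1) return(0:1)
    1L
  }
  for (a in gametes(s)) for (b in gametes(d)) if (a + b == o) return(TRUE)
  FALSE
}

# Exact HWE p-value from the closed-form conditional probability of each
# heterozygote count (multinomial over genotypes / binomial over alleles),
# evaluated directly through lgamma.
oracle_hwe_exact <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  na_ <- 2 * n_aa + n_ab
  nb_ <- 2 * n - na_
  if (min(na_, nb_) == 0) return(1)
  h <- seq(min(na_, nb_) %% 2, min(na_, nb_), by = 2)
  logp <- lgamma(n + 1) - lgamma((na_ - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((nb_ - h) / 2 + 1) + h * log(2) +
    lgamma(na_ + 1) + lgamma(nb_ + 1) - lgamma(2 * n + 1)
  p <- exp(logp)
  p <- p / sum(p)
  p_obs <- p[h == n_ab]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

# OLS slope and intercept by the normal equations, written out longhand.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Random valid haplotype panel on one chromosome; columns polymorphic.
random_panel <- function(h, m, seed, spacing = 1000, population = "test") {
  set.seed(seed)
  repeat {
    p <- runif(m, 0.1, 0.9)
    X <- matrix(rbinom(h * m, 1, rep(p, each = h)), h, m)
    f <- colMeans(X)
    if (all(f > 0 & f < 1)) break
  }
  map <- marker_map(rep("1", m), sprintf("m%03d", seq_len(m)),
                    seq_len(m) * spacing)
  haplotype_panel(population, map, X)
}

# Trio set constructed directly from genotype matrices (bypasses sampling).
manual_trios <- function(sire, dam, off, population = "p") {
  m <- ncol(sire)
  map <- marker_map(rep("1", m), sprintf("m%03d", seq_len(m)),
                    seq_len(m) * 1000)
  trio_set(population, map, sire, dam, off,
           sprintf("t%03d", seq_len(nrow(sire))))
}
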