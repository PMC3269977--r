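# Synthetic-data generator: ancestral chain, Wright-Fisher evolution,
# population divergence, trio sampling.

#' Simulate an ancestral haplotype panel
#'
#' Builds the marker map and the ancestral phased panel from the first-order
#' copying chain described in [sim_config()]. Adjacent-marker allele
#' correlation decays on average as `exp(-d / ld_decay_length_bp)` (times
#' `1 - 2 * phase_flip_prob` in sign when inversions are enabled); target
#' allele frequencies are uniform in the configured MAF range.
#'
#' @param config a [sim_config()].
#' @return A [haplotype_panel()] named `"ancestral"`; its `map` element is
#'   the generated [marker_map()].
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 50,
#'                   ancestral_haplotypes = 20)
#' simulate_ancestral_panel(cfg)
#' @export
simulate_ancestral_panel <- function(config) {
  validate_sim_config(config)
  .with_seed(.op_seed(config$seed, "ancestral"), {
    M <- config$markers_per_chromosome
    H <- config$ancestral_haplotypes
    chroms <- character(0); ids <- character(0); pos <- numeric(0)
    hap <- NULL
    for (ch in seq_len(config$n_chromosomes)) {
      gaps <- pmax(1, round(stats::rexp(M, rate = 1 / config$marker_spacing_bp)))
      p_bp <- cumsum(gaps)
      maf <- stats::runif(M, config$maf_low, config$maf_high)
      p1 <- ifelse(stats::runif(M) < 0.5, maf, 1 - maf)
      mu <- exp(-gaps / config$ld_decay_length_bp)
      cp <- if (is.finite(config$ld_dispersion)) {
        stats::rbeta(M, mu * config$ld_dispersion, (1 - mu) * config$ld_dispersion)
      } else mu
      inv <- stats::runif(M) < config$phase_flip_prob
      X <- matrix(0L, H, M)
      X[, 1] <- stats::rbinom(H, 1, p1[1])
      for (m in seq_len(M)[-1]) {
        copy <- stats::runif(H) < cp[m]
        src <- if (inv[m]) 1L - X[, m - 1] else X[, m - 1]
        X[, m] <- ifelse(copy, src, stats::rbinom(H, 1, p1[m]))
      }
      chroms <- c(chroms, rep(as.character(ch), M))
      ids <- c(ids, sprintf("chr%d_m%04d", ch, seq_len(M)))
      pos <- c(pos, p_bp)
      hap <- cbind(hap, X)
    }
    map <- marker_map(chroms, ids, pos)
    haplotype_panel("ancestral", map, hap)
  })
}

# One gamete per entry of `parents` (diploid indices into `hap`, whose rows
# 2i-1 and 2i are individual i). Crossover count per chromosome is Poisson
# with mean = genetic map length in Morgans; positions uniform on the
# physical span. Chromosomes with no crossover copy one parental haplotype
# whole, which is the overwhelmingly common case at chip scale.
#' @keywords internal
.make_gametes <- function(hap, parents, map, morgans_per_bp) {
  n <- length(parents)
  G <- matrix(0L, n, ncol(hap))
  for (ch in unique(map$chrom)) {
    cols <- which(map$chrom == ch)
    pc <- map$pos_bp[cols]
    L <- (max(pc) - min(pc)) * morgans_per_bp
    k <- stats::rpois(n, L)
    start <- sample.int(2L, n, replace = TRUE) - 1L
    plain <- k == 0L
    if (any(plain)) {
      G[plain, cols] <- hap[2L * parents[plain] - 1L + start[plain], cols]
    }
    for (g in which(!plain)) {
      xo <- sort(stats::runif(k[g], min(pc), max(pc)))
      seg <- (start[g] + findInterval(pc, xo)) %% 2L
      h1 <- hap[2L * parents[g] - 1L, cols]
      h2 <- hap[2L * parents[g], cols]
      G[g, cols] <- ifelse(seg == 0L, h1, h2)
    }
  }
  G
}

# `gens` generations of monoecious Wright-Fisher reproduction at diploid
# size Ne: each offspring draws two parents uniformly at random (with
# replacement) and receives one recombinant gamete from each.
#' @keywords internal
.wf_evolve <- function(hap, gens, ne, map, morgans_per_bp) {
  if (gens == 0) return(hap)
  .assert(nrow(hap) == 2L * ne, "haplotype pool must hold exactly 2*Ne rows")
  for (g in seq_len(gens)) {
    sires <- sample.int(ne, ne, replace = TRUE)
    dams <- sample.int(ne, ne, replace = TRUE)
    gs <- .make_gametes(hap, sires, map, morgans_per_bp)
    gd <- .make_gametes(hap, dams, map, morgans_per_bp)
    nxt <- matrix(0L, 2L * ne, ncol(hap))
    nxt[seq(1L, 2L * ne, 2L), ] <- gs
    nxt[seq(2L, 2L * ne, 2L), ] <- gd
    hap <- nxt
  }
  hap
}

#' @keywords internal
.resample_pool <- function(hap, ne) {
  hap[sample.int(nrow(hap), 2L * ne, replace = TRUE), , drop = FALSE]
}

#' @keywords internal
.morgans_per_bp <- function(config) config$recomb_rate_cM_per_Mb * 1e-8

#' Bring a panel toward drift-recombination stationarity
#'
#' Runs Wright-Fisher reproduction (with recombination) on the panel's
#' haplotype pool for a number of generations at the configured effective
#' size. Used before a population split: the closed-form decay of phase
#' correlation assumes the common ancestor is near drift-recombination
#' equilibrium, which the raw copying chain is not. Heterozygosity decays at
#' rate 1/(2Ne) per generation, so long burn-ins fix markers; downstream MAF
#' filtering removes those.
#'
#' @param panel a [haplotype_panel()].
#' @param config a [sim_config()]; uses `effective_size`,
#'   `recomb_rate_cM_per_Mb` and `seed`.
#' @param generations number of generations; defaults to
#'   `config$burn_in_generations`.
#' @return A `haplotype_panel` of `2 * effective_size` haplotypes.
#' @export
equilibrate_panel <- function(panel, config, generations = config$burn_in_generations) {
  validate_sim_config(config)
  .assert(generations >= 0, "generations must be >= 0")
  .with_seed(.op_seed(config$seed, "equilibrate"), {
    pool <- .resample_pool(panel$haplotypes, config$effective_size)
    pool <- .wf_evolve(pool, generations, config$effective_size, panel$map,
                       .morgans_per_bp(config))
    haplotype_panel(panel$population, panel$map, pool)
  })
}

#' Split an ancestral panel into diverged daughter populations
#'
#' Each daughter population is founded by resampling `2 * effective_size`
#' haplotypes from the ancestral pool and then evolves independently for
#' `generations` generations of Wright-Fisher reproduction with
#' recombination. Daughters inherit the ancestral reference-allele coding,
#' so signed r is comparable across them. With `generations = 0` the
#' daughters are plain resamples of the ancestral pool.
#'
#' @param ancestral a [haplotype_panel()], typically from
#'   [simulate_ancestral_panel()] (optionally passed through
#'   [equilibrate_panel()]).
#' @param config a [sim_config()].
#' @param n_populations number of daughter populations (>= 2).
#' @param generations divergence time T in generations; defaults to
#'   `config$divergence_generations`.
#' @return Named list of `haplotype_panel`s (`pop1`, `pop2`, ...).
#' @export
diverge_populations <- function(ancestral, config, n_populations = 2,
                                generations = config$divergence_generations) {
  validate_sim_config(config)
  .assert(n_populations >= 2, "n_populations must be >= 2")
  .assert(generations >= 0, "divergence generations T must be >= 0")
  mbp <- .morgans_per_bp(config)
  out <- lapply(seq_len(n_populations), function(i) {
    .with_seed(.op_seed(config$seed, "diverge", i), {
      pool <- .resample_pool(ancestral$haplotypes, config$effective_size)
      pool <- .wf_evolve(pool, generations, config$effective_size,
                         ancestral$map, mbp)
      haplotype_panel(paste0("pop", i), ancestral$map, pool)
    })
  })
  names(out) <- vapply(out, `[[`, "", "population")
  out
}

#' Simulate a full set of diverged populations
#'
#' Convenience wrapper running the study design end to end: ancestral
#' copying chain, burn-in to quasi-stationarity at the daughter effective
#' size, then an independent Wright-Fisher split. This is the generator used
#' by the divergence-time experiments.
#'
#' @inheritParams diverge_populations
#' @return Named list of daughter `haplotype_panel`s; the equilibrated
#'   ancestor is attached as attribute `"ancestral"`.
#' @export
simulate_diverged_panels <- function(config, n_populations = 2,
                                     generations = config$divergence_generations) {
  anc <- simulate_ancestral_panel(config)
  anc <- equilibrate_panel(anc, config)
  out <- diverge_populations(anc, config, n_populations, generations)
  attr(out, "ancestral") <- anc
  out
}

#' Sire/dam/offspring trio genotypes
#'
#' Container for unphased trio genotypes: three n_trios x M integer matrices
#' (`sire`, `dam`, `offspring`) with values 0/1/2 counting reference alleles
#' and `NA` for missing, aligned to a shared [marker_map()].
#'
#' @param population population label.
#' @param map a [marker_map()].
#' @param sire,dam,offspring genotype matrices, one row per trio.
#' @param trio_id character vector of trio identifiers.
#' @return An object of class `trio_set`.
#' @export
trio_set <- function(population, map, sire, dam, offspring, trio_id) {
  for (g in list(sire, dam, offspring)) {
    .assert(is.matrix(g) && ncol(g) == nrow(map),
            "genotype matrices must have one column per mapped marker")
    .assert(all(g %in% c(0L, 1L, 2L) | is.na(g)),
            "genotypes must be 0/1/2 or NA")
  }
  .assert(nrow(sire) == nrow(dam) && nrow(dam) == nrow(offspring),
          "sire, dam and offspring must have the same number of rows")
  .assert(length(trio_id) == nrow(sire), "one trio_id per trio required")
  storage.mode(sire) <- "integer"; storage.mode(dam) <- "integer"
  storage.mode(offspring) <- "integer"
  structure(list(population = as.character(population), map = map,
                 sire = sire, dam = dam, offspring = offspring,
                 trio_id = as.character(trio_id)),
            class = "trio_set")
}

#' @export
print.trio_set <- function(x, ...) {
  cat(sprintf("<trio_set> population '%s': %d trios x %d markers (%.1f%% missing)\n",
              x$population, length(x$trio_id), nrow(x$map),
              100 * mean(is.na(rbind(x$sire, x$dam, x$offspring)))))
  invisible(x)
}

#' Sample sire/dam/offspring trios from a phased panel
#'
#' Sire and dam of each trio are disjoint diploids drawn without replacement
#' from the panel; the offspring receives one recombinant gamete from each
#' parent. Genotypes are then masked to missing independently at
#' `missing_rate`, and a fraction `mendel_error_rate` of the offspring's
#' non-missing calls is replaced by a genotype inconsistent with the true
#' parental genotypes wherever such a value exists (it does not when both
#' parents are heterozygous).
#'
#' @param panel a [haplotype_panel()] with at least `4 * n_trios` haplotypes.
#' @param n_trios number of trios to draw.
#' @param missing_rate per-call probability of missingness, in [0,1].
#' @param mendel_error_rate per-call probability that an offspring genotype
#'   is replaced by a Mendelian-inconsistent value, in [0,1].
#' @param config a [sim_config()] supplying the recombination rate; defaults
#'   to `sim_config()`.
#' @param seed integer seed; defaults to `config$seed`.
#' @return A [trio_set()].
#' @export
sample_trios <- function(panel, n_trios, missing_rate = 0.02,
                         mendel_error_rate = 0.002,
                         config = sim_config(), seed = config$seed) {
  .assert(n_trios >= 1, "n_trios must be >= 1")
  .assert(missing_rate >= 0 && missing_rate <= 1 &&
            mendel_error_rate >= 0 && mendel_error_rate <= 1,
          "rates must be in [0,1]")
  H <- nrow(panel$haplotypes)
  .assert(H >= 4 * n_trios,
          "panel has %d haplotypes; need >= %d for %d trios with disjoint parents",
          H, 4 * n_trios, n_trios)
  .with_seed(.op_seed(seed, "trios"), {
    M <- ncol(panel$haplotypes)
    mbp <- .morgans_per_bp(config)
    hap_idx <- sample.int(H, 4L * n_trios)
    # rebuild a pool whose diploid i is (2i-1, 2i); trio i has sire 2i-1, dam 2i
    pool <- panel$haplotypes[hap_idx, , drop = FALSE]
    sire_dip <- 2L * seq_len(n_trios) - 1L
    dam_dip <- 2L * seq_len(n_trios)
    geno_of <- function(dip) pool[2L * dip - 1L, , drop = FALSE] +
      pool[2L * dip, , drop = FALSE]
    sire <- geno_of(sire_dip)
    dam <- geno_of(dam_dip)
    off <- .make_gametes(pool, sire_dip, panel$map, mbp) +
      .make_gametes(pool, dam_dip, panel$map, mbp)
    sire_true <- sire; dam_true <- dam
    mask <- function(g) {
      g[matrix(stats::runif(length(g)) < missing_rate, nrow(g))] <- NA_integer_
      g
    }
    if (missing_rate > 0) { sire <- mask(sire); dam <- mask(dam); off <- mask(off) }
    if (mendel_error_rate > 0) {
      hit <- matrix(stats::runif(length(off)) < mendel_error_rate, nrow(off)) &
        !is.na(off)
      for (ix in which(hit)) {
        bad <- .inconsistent_offspring(sire_true[ix], dam_true[ix])
        if (length(bad)) off[ix] <- bad[sample.int(length(bad), 1L)]
      }
    }
    trio_set(panel$population, panel$map, sire, dam, off,
             sprintf("%s_trio%03d", panel$population, seq_len(n_trios)))
  })
}

# offspring genotypes impossible given true parental genotypes
#' @keywords internal
.inconsistent_offspring <- function(s, d) {
  gam <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  ok <- unique(outer(gam[[as.character(s)]], gam[[as.character(d)]], `+`))
  setdiff(0:2, ok)
}
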