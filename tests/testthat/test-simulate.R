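test_that("configuration validation rejects degenerate settings", {
  expect_error(sim_config(markers_per_chromosome = 1), "markers_per_chromosome")
  expect_error(sim_config(maf_low = 0), "maf_low")
  expect_error(sim_config(maf_low = 0.3, maf_high = 0.2), "maf_low")
  expect_error(sim_config(effective_size = 1), "effective_size")
  expect_error(sim_config(ld_decay_length_bp = 0), "ld_decay_length_bp")
  expect_error(sim_config(divergence_generations = -1), "divergence_generations")
})

test_that("generator is deterministic and satisfies panel invariants", {
  expect_error(sim_config(ancestral_haplotypes = 31), "even")
  cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 40,
                    marker_spacing_bp = 20000, ancestral_haplotypes = 32,
                    seed = 11)
  a <- simulate_ancestral_panel(cfg)
  b <- simulate_ancestral_panel(cfg)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$map, b$map)
  expect_true(all(a$haplotypes %in% c(0L, 1L)))
  expect_equal(nrow(a$haplotypes) %% 2, 0)
  for (ch in unique(a$map$chrom))
    expect_true(all(diff(a$map$pos_bp[a$map$chrom == ch]) > 0))

  d1 <- diverge_populations(a, cfg, n_populations = 3, generations = 5)
  d2 <- diverge_populations(a, cfg, n_populations = 3, generations = 5)
  expect_identical(lapply(d1, `[[`, "haplotypes"),
                   lapply(d2, `[[`, "haplotypes"))
  # allele coding shared with the ancestor: same marker ids, same map
  for (d in d1) expect_identical(d$map, a$map)

  t1 <- sample_trios(a, 5, missing_rate = 0.1, mendel_error_rate = 0.05,
                     config = cfg)
  t2 <- sample_trios(a, 5, missing_rate = 0.1, mendel_error_rate = 0.05,
                     config = cfg)
  expect_identical(t1$offspring, t2$offspring)
  expect_identical(is.na(t1$sire), is.na(t2$sire))
})

test_that("copying-chain limits: perfect copy and independence", {
  # lambda -> Inf: copy probability 1, every marker column identical
  cfg_inf <- sim_config(n_chromosomes = 1, markers_per_chromosome = 30,
                        marker_spacing_bp = 50000, ancestral_haplotypes = 60,
                        ld_decay_length_bp = 1e15, ld_dispersion = Inf,
                        phase_flip_prob = 0, seed = 5)
  p <- simulate_ancestral_panel(cfg_inf)
  expect_true(all(p$haplotypes == p$haplotypes[, 1]))
  ld <- pairwise_ld(p, max_distance_bp = Inf)
  expect_true(all(abs(ld$r_squared - 1) < 1e-12))

  # lambda -> 0: markers independent, mean r^2 near the 1/H sampling floor
  cfg0 <- sim_config(n_chromosomes = 1, markers_per_chromosome = 40,
                     marker_spacing_bp = 50000, ancestral_haplotypes = 200,
                     ld_decay_length_bp = 1e-6, ld_dispersion = Inf,
                     phase_flip_prob = 0, seed = 5)
  p0 <- simulate_ancestral_panel(cfg0)
  ld0 <- pairwise_ld(p0, max_distance_bp = Inf)
  nonadj <- ld0[match(ld0$marker_j, p0$map$marker_id) -
                  match(ld0$marker_i, p0$map$marker_id) > 1, ]
  floor_r2 <- 1 / nrow(p0$haplotypes)
  expect_lt(abs(mean(nonadj$r_squared) - floor_r2), 3 * floor_r2)
})

test_that("adjacent-marker correlation tracks the exp(-d/lambda) target", {
  # homogeneous chain at the example configuration: lambda 100 kb, H = 200,
  # 60 kb mean spacing; the per-pair target is exp(-d/lambda), averaged
  # over >= 20 seeds
  devs <- vapply(1:20, function(s) {
    cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 120,
                      marker_spacing_bp = 60000, ancestral_haplotypes = 200,
                      ld_decay_length_bp = 1e5, ld_dispersion = Inf,
                      phase_flip_prob = 0, seed = s)
    p <- simulate_ancestral_panel(cfg)
    X <- p$haplotypes
    m <- ncol(X)
    r_emp <- vapply(seq_len(m - 1), function(i) stats::cor(X[, i], X[, i + 1]), 0)
    d <- diff(p$map$pos_bp)
    mean(r_emp - exp(-d / cfg$ld_decay_length_bp))
  }, 0)
  expect_lt(abs(mean(devs)), 0.04)
})

test_that("offspring alleles always derive from parents when error-free", {
  cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 60,
                    marker_spacing_bp = 30000, ancestral_haplotypes = 80,
                    seed = 21)
  p <- simulate_ancestral_panel(cfg)
  expect_error(sample_trios(p, 100, config = cfg), "disjoint")

  tr <- sample_trios(p, 15, missing_rate = 0, mendel_error_rate = 0,
                     config = cfg)
  ok <- mapply(oracle_mendel_legal, tr$sire, tr$dam, tr$offspring)
  expect_true(all(ok))

  tr_na <- sample_trios(p, 5, missing_rate = 1, mendel_error_rate = 0,
                        config = cfg)
  expect_true(all(is.na(tr_na$sire)) && all(is.na(tr_na$offspring)))
})

test_that("injected Mendelian errors appear at the configured rate", {
  rate <- 0.05
  cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 1000,
                    marker_spacing_bp = 5000, ancestral_haplotypes = 40,
                    seed = 31)
  p <- simulate_ancestral_panel(cfg)
  tr <- sample_trios(p, 10, missing_rate = 0, mendel_error_rate = rate,
                     config = cfg)
  bad <- !mapply(oracle_mendel_legal, tr$sire, tr$dam, tr$offspring)
  # expected count: rate x markers where an inconsistent genotype exists
  # (none when both parents are heterozygous)
  vulnerable <- !(tr$sire == 1L & tr$dam == 1L)
  expected <- rate * sum(vulnerable)
  expect_lt(abs(sum(bad) - expected), 4 * sqrt(expected))
})

test_that("daughter populations at T = 0 are resamples of the ancestral pool", {
  cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 150,
                    marker_spacing_bp = 10000, ancestral_haplotypes = 200,
                    effective_size = 100, seed = 41)
  p <- simulate_ancestral_panel(cfg)
  d <- diverge_populations(p, cfg, n_populations = 2, generations = 0)
  # every daughter haplotype occurs in the ancestral pool
  anc_keys <- apply(p$haplotypes, 1, paste, collapse = "")
  for (dd in d)
    expect_true(all(apply(dd$haplotypes, 1, paste, collapse = "") %in% anc_keys))
  # short-range phase correlation between the daughters is ~1
  common <- common_marker_set(d, 0.05)
  sub <- lapply(d, subset_panel, marker_ids = common$marker_id)
  ld <- lapply(sub, pairwise_ld, max_distance_bp = 1e5)
  pb <- phase_correlation(ld[[1]], ld[[2]], bin_width_bp = 1e5,
                          max_distance_bp = 1e5)
  expect_gt(pb$correlation_R[1], 0.95)
})

test_that("without recombination signed r is preserved across daughters", {
  cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 100,
                    marker_spacing_bp = 20000, ancestral_haplotypes = 1000,
                    effective_size = 500, recomb_rate_cM_per_Mb = 0, seed = 51)
  p <- simulate_ancestral_panel(cfg)
  d <- diverge_populations(p, cfg, n_populations = 2, generations = 1)
  common <- common_marker_set(d, 0.05)
  sub <- lapply(d, subset_panel, marker_ids = common$marker_id)
  ld <- lapply(sub, pairwise_ld, max_distance_bp = Inf)
  m <- merge(as.data.frame(ld[[1]]), as.data.frame(ld[[2]]),
             by = c("marker_i", "marker_j"))
  expect_gt(stats::cor(m$r_signed.x, m$r_signed.y), 0.97)
})

test_that("simulated LD decays with distance on average", {
  r2_by_bin <- rowMeans(vapply(1:20, function(s) {
    cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 100,
                      marker_spacing_bp = 40000, ancestral_haplotypes = 100,
                      ld_decay_length_bp = 1e5, seed = s)
    p <- simulate_ancestral_panel(cfg)
    b <- ld_decay_bins(pairwise_ld(p, 1e6), bin_width_bp = 2e5,
                       max_distance_bp = 1e6)
    b$mean_r2
  }, numeric(5)))
  expect_true(all(diff(r2_by_bin) < 0.02))  # non-increasing within noise
  expect_gt(r2_by_bin[1], r2_by_bin[5])
})
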