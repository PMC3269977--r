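test_that("Mendelian masking flags exactly the impossible triples", {
  # homozygote parents cannot yield a heterozygote
  tr <- manual_trios(sire = matrix(c(0L, 0L), 1), dam = matrix(c(0L, 2L), 1),
                     off = matrix(c(1L, 1L), 1))
  out <- mask_mendelian_inconsistencies(tr)
  expect_true(is.na(out$trios$offspring[1, 1]))   # (0,0,1) masked
  expect_true(is.na(out$trios$sire[1, 1]))        # all three members masked
  expect_identical(out$trios$offspring[1, 2], 1L) # (0,2,1) forced het, kept
  expect_equal(out$report$n_removed, 1)

  # missing is compatible with anything that has a legal completion,
  # but sire = 0 with offspring = 2 is impossible whatever the dam
  tr2 <- manual_trios(sire = matrix(c(0L, 0L), 1), dam = matrix(c(NA, NA), 1),
                      off = matrix(c(1L, 2L), 1))
  out2 <- mask_mendelian_inconsistencies(tr2)
  expect_identical(out2$trios$offspring[1, 1], 1L)
  expect_true(is.na(out2$trios$offspring[1, 2]))

  # random trios with injected errors: masked count equals the brute-force
  # count over all 27 (plus missing) genotype triples
  cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 400,
                    marker_spacing_bp = 5000, ancestral_haplotypes = 60,
                    seed = 7)
  p <- simulate_ancestral_panel(cfg)
  tr3 <- sample_trios(p, 12, missing_rate = 0.05, mendel_error_rate = 0.02,
                      config = cfg)
  bad_oracle <- !mapply(oracle_mendel_legal, tr3$sire, tr3$dam, tr3$offspring)
  out3 <- mask_mendelian_inconsistencies(tr3)
  expect_equal(out3$report$n_removed, sum(bad_oracle))
  expect_true(all(is.na(out3$trios$offspring[matrix(bad_oracle, 12)])))
})

test_that("trio missingness removal uses a strict 'more than' boundary", {
  m <- 50
  g_clean <- matrix(1L, 3, m)
  sire <- g_clean; dam <- g_clean; off <- g_clean
  sire[1, 1:5] <- NA   # exactly 10% missing -> retained
  dam[2, 1:6] <- NA    # 12% missing -> trio removed
  tr <- manual_trios(sire, dam, off)
  out <- filter_trio_missingness(tr, qc_thresholds())
  expect_identical(out$trios$trio_id, c("t001", "t003"))
  expect_equal(out$report$n_removed, 1)

  # random missingness agrees with an independent per-member recount
  set.seed(2)
  mk <- function() matrix(ifelse(runif(20 * m) < 0.12, NA, 1L), 20, m)
  tr2 <- manual_trios(mk(), mk(), mk())
  out2 <- filter_trio_missingness(tr2, qc_thresholds())
  worst <- sapply(seq_len(20), function(i) {
    max(mean(is.na(tr2$sire[i, ])), mean(is.na(tr2$dam[i, ])),
        mean(is.na(tr2$offspring[i, ])))
  })
  expect_identical(out2$trios$trio_id, sprintf("t%03d", which(worst <= 0.10)))
})

test_that("SNP call rate keeps markers typed in at least 90% of samples", {
  # 30 samples total (10 trios x 3 members): 3 missing = exactly 90%, kept;
  # 4 missing = 86.7%, removed
  m <- 4
  g <- matrix(1L, 10, m)
  sire <- g; dam <- g; off <- g
  sire[1:3, 2] <- NA                       # marker 2: 27/30 called, kept
  sire[1:3, 3] <- NA; dam[1, 3] <- NA      # marker 3: 26/30, removed
  tr <- manual_trios(sire, dam, off)
  out <- filter_snp_callrate(tr, qc_thresholds())
  expect_identical(out$keep, c(TRUE, TRUE, FALSE, TRUE))

  # pooled across populations, equals an independent recount
  tr_b <- manual_trios(g, g, g, population = "q")
  out2 <- filter_snp_callrate(list(tr, tr_b), qc_thresholds())
  pooled <- rbind(tr$sire, tr$dam, tr$offspring,
                  tr_b$sire, tr_b$dam, tr_b$offspring)
  expect_identical(out2$keep, colMeans(!is.na(pooled)) >= 0.9)
})

test_that("MAF filtering is per population with removal strictly below 5%", {
  # 10 trios -> 20 founders -> 40 founder alleles
  n <- 10; m <- 4
  sire <- matrix(0L, n, m); dam <- matrix(0L, n, m); off <- matrix(0L, n, m)
  sire[1, 1] <- 2L                 # marker 1: 2/40 = 0.05, kept (boundary)
  sire[1, 2] <- 1L                 # marker 2: 1/40 = 0.025, removed
  sire[, 3] <- 2L; dam[, 3] <- 2L  # marker 3 fixed (freq 1): MAF 0, removed
  sire[1:4, 4] <- 1L               # marker 4: 4/40 = 0.10, kept
  tr <- manual_trios(sire, dam, off)
  out <- filter_maf(tr, qc_thresholds())
  expect_identical(out$keep, c(TRUE, FALSE, FALSE, TRUE))

  # all-missing marker is removed and counted separately
  sire2 <- sire; dam2 <- dam
  sire2[, 2] <- NA; dam2[, 2] <- NA
  out2 <- filter_maf(manual_trios(sire2, dam2, off), qc_thresholds())
  expect_false(out2$keep[2])
  expect_equal(out2$n_all_missing, 1)

  # panels: frequencies recounted from haplotypes
  p <- random_panel(50, 30, seed = 9)
  out3 <- filter_maf(p, qc_thresholds())
  f <- colMeans(p$haplotypes)
  expect_identical(unname(out3$keep), unname(pmin(f, 1 - f) >= 0.05))
})

test_that("offspring are excluded from founder frequencies and HWE", {
  n <- 10
  sire <- matrix(1L, n, 1); dam <- matrix(1L, n, 1)
  off <- matrix(2L, n, 1)   # offspring would push frequency up
  tr <- manual_trios(sire, dam, off)
  fa <- filter_maf(tr, qc_thresholds())
  expect_true(fa$keep[1])   # founder frequency is 0.5 regardless of offspring
  hw <- filter_hwe(tr, qc_thresholds())
  # all 20 founders heterozygous: extreme het excess, removed at alpha 0.001
  expect_false(hw$keep[1])
  expect_equal(hw$p_values[1], oracle_hwe_exact(0, 20, 0), tolerance = 1e-12)
})

test_that("HWE exact p-values match the enumeration oracle", {
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 1e-9)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)
  expect_equal(hwe_exact_test(21, 48, 31), oracle_hwe_exact(21, 48, 31),
               tolerance = 1e-10)
  # monomorphic: single configuration, p = 1, kept
  expect_equal(hwe_exact_test(30, 0, 0), 1)
  # spot grid across sample sizes and allele frequencies
  set.seed(4)
  for (i in 1:50) {
    n <- sample(3:120, 1)
    g <- as.vector(stats::rmultinom(1, n, prob = runif(3)))
    expect_equal(hwe_exact_test(g[1], g[2], g[3]),
                 oracle_hwe_exact(g[1], g[2], g[3]), tolerance = 1e-9)
  }
})

test_that("the full cascade is idempotent and conserves counts", {
  cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 150,
                    marker_spacing_bp = 10000, ancestral_haplotypes = 150,
                    seed = 13)
  p <- simulate_ancestral_panel(cfg)
  trios <- list(
    a = sample_trios(p, 12, missing_rate = 0.06, mendel_error_rate = 0.01,
                     config = cfg, seed = 1),
    b = sample_trios(p, 12, missing_rate = 0.12, mendel_error_rate = 0.02,
                     config = cfg, seed = 2))
  trios$a$population <- "a"; trios$b$population <- "b"
  res1 <- qc_cascade(trios, qc_thresholds())
  # conservation at every stage
  expect_true(all(res1$report$n_in - res1$report$n_removed == res1$report$n_out))
  # stage chaining: marker stages start from the previous stage's survivors
  rep_a <- res1$report[res1$report$population %in% c("all", "a"), ]
  cr <- rep_a[rep_a$stage == "snp_callrate", ]
  au <- rep_a[rep_a$stage == "autosomal", ]
  maf <- rep_a[rep_a$stage == "maf", ]
  hwe <- rep_a[rep_a$stage == "hwe", ]
  expect_equal(au$n_in, cr$n_out)
  expect_equal(maf$n_in, au$n_out)
  expect_equal(hwe$n_in, maf$n_out)
  expect_equal(sum(res1$marker_keep$a), hwe$n_out)

  # idempotence: re-running the cascade on its own output changes nothing
  res2 <- qc_cascade(res1$trios, qc_thresholds())
  expect_identical(res2$marker_keep, res1$marker_keep)
  expect_identical(lapply(res2$trios, `[[`, "offspring"),
                   lapply(res1$trios, `[[`, "offspring"))
  expect_equal(sum(res2$report$n_removed[res2$report$stage == "mendelian_mask"]), 0)
  expect_equal(sum(res2$report$n_removed[res2$report$stage == "trio_missingness"]), 0)
})
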