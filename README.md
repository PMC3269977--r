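# ldphase

Linkage disequilibrium (LD) decay, persistence of gametic phase across
populations, and divergence-time estimation from phased SNP haplotypes —
the analysis core of multi-breed genotyping studies in livestock genetics.
It is written for quantitative geneticists who need to judge, from chip
data, whether marker effects estimated in one population will transfer to
another, and how dense a marker panel must be for marker-assisted
selection or imputation.

## What it computes

For two biallelic markers *i*, *j* with reference-allele frequencies
`p_i`, `p_j` and double-reference haplotype frequency `p_ij`:

```
r_ij  = (p_ij − p_i·p_j) / sqrt(p_i(1−p_i)·p_j(1−p_j))      r²_ij = r_ij²
```

computed by counting over phased haplotypes (`pairwise_ld()`), summarised
as adjacent-pair means (`adjacent_mean_r2()`), distance-binned decay
curves (`ld_decay_bins()`), and marker-thinning series
(`thinning_series()`).

Persistence of gametic phase between populations *k*, *k'* is the Pearson
correlation `R_k,k'` of signed `r` over the same marker pairs within a
distance class (`phase_correlation()`), with the fraction of sign-discordant
pairs alongside, and Fisher-z comparisons between population pairs
(`compare_phase_correlations()`).

If two populations diverged *T* generations ago, their phase correlation
at recombination distance *c* decays as `R0·e^(−2cT)`;
`estimate_divergence_time()` regresses `ln R` on *c* over fine distance
classes and reports `T_hat = −slope/2`.

Around that core sit a trio-genotype QC cascade (Mendelian masking, trio
missingness, call rate, per-population MAF and exact Hardy–Weinberg
filtering: `qc_cascade()`), phased VCF / PED-MAP readers and writers, a
Wright–Fisher forward simulator with a tunable ancestral-LD model
(`sim_config()`, `simulate_diverged_panels()`, `sample_trios()`), and an
end-to-end pipeline (`run_pipeline()`, plus a thin CLI in
`inst/cli/ldphase.R`). See the methods vignette
(`vignettes/ldphase-methods.Rmd`) for the model assumptions and design
choices.

## Worked example

Simulate two populations that split 30 generations ago from a common
ancestor (effective size 100, 1 cM/Mb), then estimate LD decay and recover
the divergence time:

```r
library(ldphase)
cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 400,
                  marker_spacing_bp = 12000, ancestral_haplotypes = 200,
                  effective_size = 100, burn_in_generations = 100,
                  divergence_generations = 30, seed = 42)
panels <- simulate_diverged_panels(cfg, n_populations = 2)
panels$pop1
#> <haplotype_panel> population 'pop1': 200 haplotypes (100 diploids) x 800 markers on 2 chromosome(s)

ld1 <- pairwise_ld(panels$pop1, max_distance_bp = 1e6)
head(ld_decay_bins(ld1, bin_width_bp = 2e5, max_distance_bp = 1e6), 3)
#>   bin_lo_bp bin_hi_bp   mean_r2 n_pairs
#> 1     0e+00     2e+05 0.6859632    8074
#> 2     2e+05     4e+05 0.3812078    6936
#> 3     4e+05     6e+05 0.2734372    6040
```

Mean `r²` falls from 0.69 below 200 kb to 0.27 at 400–600 kb: the decay
curve a breeder would use to pick a panel density. Phase persistence and
divergence time between the two populations:

```r
common <- common_marker_set(panels, maf_min = 0.05)
sub <- lapply(panels, subset_panel, marker_ids = common$marker_id)
ld <- lapply(sub, pairwise_ld, max_distance_bp = 3e5)

fine <- phase_correlation(ld$pop1, ld$pop2, bin_width_bp = 2500,
                          max_distance_bp = 3e5)
estimate_divergence_time(fine)
#> <divergence_estimate> T_hat = 27.76 generations (slope -55.5/Morgan, R0_hat 1.030)
#>   fit window [10000, 300000) bp at 1 cM/Mb; 116 classes used, 0 dropped (R <= 0 or undefined)
```

The fitted slope of `ln R` on recombination distance is −55.5 per Morgan,
i.e. `T_hat ≈ 27.8` generations against a simulated truth of 30. The
short-range phase classes show how strongly phase persists at close
spacing in this scenario:

```r
coarse <- phase_correlation(ld$pop1, ld$pop2, bin_edges = c(0, 1e4, 5e4, 1e5))
coarse[, c("bin_lo_bp", "bin_hi_bp", "correlation_R", "n_pairs")]
#>   bin_lo_bp bin_hi_bp correlation_R n_pairs
#> 1         0     1e+04     0.9981373     394
#> 2     10000     5e+04     0.9924075    1585
#> 3     50000     1e+05     0.9843110    1708
```

Comparing two phase correlations of 0.921 and 0.875, each estimated from
1,520 SNP pairs, with Fisher's z:

```r
compare_phase_correlations(0.921, 1520, 0.875, 1520)
#> $z
#> [1] 6.652542
#> $p_value
#> [1] 2.880734e-11
```

— a difference of that size at that pair count is far beyond the 0.001
level.

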