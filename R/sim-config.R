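#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. The generator stands
#' in for a multi-breed SNP-chip study: an ancestral population with tunable
#' LD structure is split into daughter populations that drift apart for
#' `divergence_generations` generations of Wright-Fisher reproduction with
#' recombination, and sire/dam/offspring trios can be sampled from any panel.
#'
#' The ancestral LD model is a first-order copying chain along each
#' chromosome: on a given haplotype, the allele at marker m copies the allele
#' at marker m-1 with a copy probability whose mean is `exp(-d/lambda)` for
#' inter-marker distance d and `lambda = ld_decay_length_bp`, and otherwise
#' is drawn fresh from the marker's allele frequency. Two features make the
#' chain's LD heterogeneous the way real panels are: copy probabilities are
#' Beta-dispersed around their mean (precision `ld_dispersion`; `Inf` gives
#' the homogeneous chain), and each inter-marker interval inverts the copied
#' allele with probability `phase_flip_prob`, which mixes the sign of r
#' across pairs (reference-allele coding on a chip is arbitrary, so real
#' signed LD is sign-diverse at every distance). `burn_in_generations` of
#' Wright-Fisher reproduction at `effective_size` bring the chain output
#' near drift-recombination stationarity before a split; the closed-form
#' phase-decay model assumes such a quasi-stationary ancestor.
#'
#' @param n_chromosomes number of chromosomes.
#' @param markers_per_chromosome markers simulated per chromosome (>= 2).
#' @param marker_spacing_bp mean inter-marker gap; gaps are exponential with
#'   this mean (minimum 1 bp), giving the heavy-tailed spacing of a real chip
#'   so every distance class down to a few kb holds marker pairs.
#' @param ancestral_haplotypes haplotypes in the ancestral chain panel (even).
#' @param ld_decay_length_bp lambda of the copy-probability decay, in bp.
#' @param ld_dispersion Beta precision of per-interval copy probabilities;
#'   `Inf` = homogeneous chain.
#' @param phase_flip_prob per-interval probability that the copied allele is
#'   inverted; 0 gives all-positive chain LD.
#' @param maf_low,maf_high bounds of the target minor-allele-frequency range
#'   markers are drawn in (before drift), 0 < maf_low <= maf_high <= 0.5.
#' @param divergence_generations generations T since the daughter
#'   populations split from the common ancestor.
#' @param effective_size diploid effective size Ne of each daughter
#'   population (and of the burn-in epoch).
#' @param recomb_rate_cM_per_Mb recombination map scaling; crossovers per
#'   meiosis are Poisson with mean equal to the chromosome's genetic length.
#' @param burn_in_generations Wright-Fisher generations applied to the chain
#'   output before a split by [simulate_diverged_panels()].
#' @param seed integer seed; every generator operation derives its own
#'   stream from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 18,
                       markers_per_chromosome = 2000,
                       marker_spacing_bp = 60000,
                       ancestral_haplotypes = 200,
                       ld_decay_length_bp = 2e5,
                       ld_dispersion = 5,
                       phase_flip_prob = 0.3,
                       maf_low = 0.1,
                       maf_high = 0.5,
                       divergence_generations = 30,
                       effective_size = 100,
                       recomb_rate_cM_per_Mb = 1,
                       burn_in_generations = 100,
                       seed = 1) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              markers_per_chromosome = as.integer(markers_per_chromosome),
              marker_spacing_bp = as.numeric(marker_spacing_bp),
              ancestral_haplotypes = as.integer(ancestral_haplotypes),
              ld_decay_length_bp = as.numeric(ld_decay_length_bp),
              ld_dispersion = as.numeric(ld_dispersion),
              phase_flip_prob = as.numeric(phase_flip_prob),
              maf_low = as.numeric(maf_low),
              maf_high = as.numeric(maf_high),
              divergence_generations = as.integer(divergence_generations),
              effective_size = as.integer(effective_size),
              recomb_rate_cM_per_Mb = as.numeric(recomb_rate_cM_per_Mb),
              burn_in_generations = as.integer(burn_in_generations),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  .assert(cfg$n_chromosomes >= 1, "n_chromosomes must be >= 1")
  .assert(cfg$markers_per_chromosome >= 2,
          "markers_per_chromosome must be >= 2")
  .assert(cfg$marker_spacing_bp >= 1, "marker_spacing_bp must be >= 1")
  .assert(cfg$ancestral_haplotypes >= 2 && cfg$ancestral_haplotypes %% 2 == 0,
          "ancestral_haplotypes must be an even count >= 2")
  .assert(cfg$ld_decay_length_bp > 0, "ld_decay_length_bp must be > 0")
  .assert(cfg$ld_dispersion > 0, "ld_dispersion must be > 0 (Inf allowed)")
  .assert(cfg$phase_flip_prob >= 0 && cfg$phase_flip_prob <= 1,
          "phase_flip_prob must be in [0,1]")
  .assert(cfg$maf_low > 0 && cfg$maf_low <= cfg$maf_high && cfg$maf_high <= 0.5,
          "need 0 < maf_low <= maf_high <= 0.5")
  .assert(cfg$divergence_generations >= 0,
          "divergence_generations must be >= 0")
  .assert(cfg$effective_size >= 2, "effective_size must be >= 2")
  .assert(cfg$recomb_rate_cM_per_Mb >= 0, "recomb_rate_cM_per_Mb must be >= 0")
  .assert(cfg$burn_in_generations >= 0, "burn_in_generations must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
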