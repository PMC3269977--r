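# The divergence-recovery experiment protocol shared by the acceptance
# suite: simulate a quasi-stationary ancestor, split it for T generations,
# and re-estimate T from the decay of phase correlation over 10-300 kb at
# 2.5 kb resolution. Problem sizes are desk scale: 3 chromosomes x 700
# markers at 12 kb mean spacing give each 2.5 kb class on the order of a
# hundred aligned pairs, enough that per-class correlation noise does not
# distort the log-linear fit.

divergence_experiment_config <- function(seed) {
  sim_config(n_chromosomes = 3, markers_per_chromosome = 700,
             marker_spacing_bp = 12000, ancestral_haplotypes = 200,
             ld_decay_length_bp = 2e5, ld_dispersion = 5,
             phase_flip_prob = 0.3, maf_low = 0.1, maf_high = 0.5,
             effective_size = 100, recomb_rate_cM_per_Mb = 1,
             burn_in_generations = 100, seed = seed)
}

# Returns T_hat for each requested divergence time, re-using one
# equilibrated ancestor per seed.
estimate_T_hat <- function(seed, T_values) {
  cfg <- divergence_experiment_config(seed)
  anc <- equilibrate_panel(simulate_ancestral_panel(cfg), cfg)
  vapply(T_values, function(tt) {
    daughters <- diverge_populations(anc, cfg, n_populations = 2,
                                     generations = tt)
    common <- common_marker_set(daughters, maf_min = 0.05)
    sub <- lapply(daughters, subset_panel, marker_ids = common$marker_id)
    ld <- lapply(sub, pairwise_ld, max_distance_bp = 3e5)
    fine <- phase_correlation(ld[[1]], ld[[2]], bin_width_bp = 2500,
                              max_distance_bp = 3e5)
    estimate_divergence_time(fine, fit_lo_bp = 1e4, fit_hi_bp = 3e5,
                             cM_per_Mb = 1)$T_hat
  }, 0)
}
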