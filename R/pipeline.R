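# End-to-end pipeline: inputs (files or simulation) -> QC -> LD decay ->
# thinning -> phase persistence for every population pair -> divergence
# estimates -> TSV summaries.

#' Pipeline configuration
#'
#' Collects every setting of the end-to-end analysis. Panels come either
#' from files (`populations` = named vector of paths) or from the built-in
#' simulator (`populations = NULL`).
#'
#' @param populations named character vector of phased input files (one per
#'   population), or `NULL` to simulate.
#' @param format `"vcf"` or `"ped"`.
#' @param trio_paths optional named character vector of trio PED prefixes
#'   (one per population) for the QC stage.
#' @param sim a [sim_config()] used when simulating.
#' @param n_populations populations to simulate (ignored for file input).
#' @param n_trios trios to sample per simulated population (0 skips QC).
#' @param missing_rate,mendel_error_rate trio corruption rates for the
#'   simulated QC stage.
#' @param thresholds a [qc_thresholds()].
#' @param bin_width_bp,max_distance_bp LD decay binning.
#' @param thinning_ks thinning factors.
#' @param phase_maf_min MAF threshold defining the common marker set.
#' @param phase_bin_edges optional explicit phase class edges in bp.
#' @param divergence_bin_width_bp fine class width for the divergence fit
#'   (default 2.5 kb).
#' @param fit_lo_bp,fit_hi_bp divergence fit window.
#' @param cM_per_Mb physical-to-genetic scaling.
#' @param seed pipeline seed (simulation streams derive from it).
#' @param out_dir output directory for [write_summaries()], or `NULL` to
#'   skip writing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(populations = NULL, format = c("vcf", "ped"),
                            trio_paths = NULL, sim = sim_config(),
                            n_populations = 2, n_trios = 0,
                            missing_rate = 0.02, mendel_error_rate = 0.002,
                            thresholds = qc_thresholds(),
                            bin_width_bp = 1e5, max_distance_bp = 1e7,
                            thinning_ks = c(1, 2, 4, 10, 50, 100, 200),
                            phase_maf_min = 0.05, phase_bin_edges = NULL,
                            divergence_bin_width_bp = 2500,
                            fit_lo_bp = 1e4, fit_hi_bp = 3e5, cM_per_Mb = 1,
                            seed = sim$seed, out_dir = NULL) {
  format <- match.arg(format)
  if (!is.null(populations)) {
    .assert(!is.null(names(populations)) && all(nzchar(names(populations))),
            "populations must be a named vector of paths")
    missing_files <- populations[!file.exists(.input_probe(populations, format))]
    .assert(length(missing_files) == 0, "input file(s) not found: %s",
            paste(missing_files, collapse = ", "))
  }
  validate_sim_config(sim)
  structure(list(populations = populations, format = format,
                 trio_paths = trio_paths, sim = sim,
                 n_populations = n_populations, n_trios = n_trios,
                 missing_rate = missing_rate,
                 mendel_error_rate = mendel_error_rate,
                 thresholds = thresholds,
                 bin_width_bp = bin_width_bp,
                 max_distance_bp = max_distance_bp,
                 thinning_ks = thinning_ks,
                 phase_maf_min = phase_maf_min,
                 phase_bin_edges = phase_bin_edges,
                 divergence_bin_width_bp = divergence_bin_width_bp,
                 fit_lo_bp = fit_lo_bp, fit_hi_bp = fit_hi_bp,
                 cM_per_Mb = cM_per_Mb, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' @keywords internal
.input_probe <- function(paths, format) {
  if (format == "ped") paste0(sub("\\.ped$", "", paths), ".ped") else paths
}

#' @keywords internal
.config_to_list <- function(cfg) {
  if (is.null(cfg)) return(NULL)
  out <- unclass(cfg)
  out$sim <- if (!is.null(out$sim)) unclass(out$sim)
  out$thresholds <- if (!is.null(out$thresholds)) unclass(out$thresholds)
  lapply(out, function(x) if (is.null(x)) NULL else x)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `path` (write) or the re-built `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(.config_to_list(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- do.call(sim_config, raw$sim %||% list())
  thr <- do.call(qc_thresholds, raw$thresholds %||% list())
  args <- raw[setdiff(names(raw), c("sim", "thresholds"))]
  args$populations <- if (!is.null(args$populations)) unlist(args$populations)
  args$trio_paths <- if (!is.null(args$trio_paths)) unlist(args$trio_paths)
  do.call(pipeline_config, c(args, list(sim = sim, thresholds = thr)))
}

#' @keywords internal
.log_stage <- function(fmt, ...) message(sprintf(paste0("[ldphase] ", fmt), ...))

#' Run the end-to-end analysis
#'
#' Stages, in order: obtain panels (read or simulate); optional trio QC
#' cascade, whose surviving markers restrict each population's panel; LD
#' decay bins, adjacent-pair means and a thinning series per population;
#' phase persistence for every population pair on the common marker set;
#' divergence-time estimates from fine-binned phase correlations. Stage
#' logs (record counts in and out) go to the message stream; failures abort
#' with the stage named.
#'
#' @param config a [pipeline_config()].
#' @return A list with elements `panels`, `qc`, `ld_bins`, `adjacent`,
#'   `thinning`, `phase_bins`, `divergence`, `config`; summaries are
#'   written to `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (!is.null(config$out_dir)) {
    ok <- dir.exists(config$out_dir) || dir.create(config$out_dir, recursive = TRUE)
    .assert(ok && file.access(config$out_dir, 2) == 0,
            "output directory '%s' is not writable", config$out_dir)
  }

  inputs <- stage("input", {
    if (is.null(config$populations)) {
      .log_stage("simulating %d populations (T = %d, Ne = %d)",
                 config$n_populations, config$sim$divergence_generations,
                 config$sim$effective_size)
      ps <- simulate_diverged_panels(config$sim, config$n_populations)
      tr <- if (config$n_trios > 0) {
        lapply(ps, sample_trios, n_trios = config$n_trios,
               missing_rate = config$missing_rate,
               mendel_error_rate = config$mendel_error_rate,
               config = config$sim)
      }
      list(panels = ps, trios = tr)
    } else {
      ps <- lapply(seq_along(config$populations), function(i)
        read_phased_panel(config$populations[i], config$format,
                          population = names(config$populations)[i]))
      names(ps) <- names(config$populations)
      tr <- if (!is.null(config$trio_paths))
        lapply(config$trio_paths, read_trios_ped)
      list(panels = ps, trios = tr)
    }
  })
  panels <- inputs$panels
  trios <- inputs$trios
  .log_stage("input: %d populations, %d markers", length(panels),
             nrow(panels[[1]]$map))

  qc <- NULL
  if (!is.null(trios)) {
    qc <- stage("qc", qc_cascade(trios, config$thresholds))
    panels <- stage("qc", {
      out <- lapply(names(panels), function(nm) {
        keep <- qc$marker_keep[[nm]] %||% Reduce(`&`, qc$marker_keep)
        subset_panel(panels[[nm]], panels[[nm]]$map$marker_id[keep])
      })
      names(out) <- names(panels)
      out
    })
    .log_stage("qc: %s markers survive per population",
               paste(vapply(qc$marker_keep, sum, 0L), collapse = "/"))
  }

  ld_bins <- stage("ld_decay", {
    do.call(rbind, lapply(names(panels), function(nm) {
      ld <- pairwise_ld(panels[[nm]], config$max_distance_bp)
      cbind(population = nm,
            ld_decay_bins(ld, config$bin_width_bp, config$max_distance_bp))
    }))
  })
  adjacent <- stage("ld_decay", {
    do.call(rbind, lapply(names(panels), function(nm) {
      a <- adjacent_mean_r2(panels[[nm]])
      data.frame(population = nm, mean_adjacent_r2 = a$mean_r2,
                 mean_adjacent_distance_bp = a$mean_distance_bp,
                 n_pairs = a$n_pairs)
    }))
  })
  .log_stage("ld_decay: %d bins x %d populations",
             nrow(ld_bins) / length(panels), length(panels))

  thinning <- stage("thinning", {
    do.call(rbind, lapply(names(panels), function(nm)
      cbind(population = nm, thinning_series(panels[[nm]], config$thinning_ks))))
  })

  phase_bins <- NULL; divergence <- NULL
  if (length(panels) >= 2) {
    common <- stage("phase", common_marker_set(panels, config$phase_maf_min))
    .log_stage("phase: %d common markers", nrow(common))
    sub <- lapply(panels, subset_panel, marker_ids = common$marker_id)
    ld_common <- lapply(sub, pairwise_ld, max_distance_bp = config$max_distance_bp)
    pairs <- utils::combn(names(panels), 2, simplify = FALSE)
    phase_bins <- stage("phase", {
      do.call(rbind, lapply(pairs, function(pr) {
        pb <- phase_correlation(ld_common[[pr[1]]], ld_common[[pr[2]]],
                                bin_width_bp = config$bin_width_bp,
                                max_distance_bp = config$max_distance_bp,
                                bin_edges = config$phase_bin_edges)
        cbind(pop_k = pr[1], pop_kprime = pr[2], pb)
      }))
    })
    divergence <- stage("divergence", {
      do.call(rbind, lapply(pairs, function(pr) {
        fine <- phase_correlation(ld_common[[pr[1]]], ld_common[[pr[2]]],
                                  bin_width_bp = config$divergence_bin_width_bp,
                                  max_distance_bp = config$fit_hi_bp)
        est <- estimate_divergence_time(fine, config$fit_lo_bp,
                                        config$fit_hi_bp, config$cM_per_Mb)
        data.frame(pop_k = pr[1], pop_kprime = pr[2],
                   slope = est$slope, intercept = est$intercept,
                   T_hat = est$T_hat, R0_hat = est$R0_hat,
                   n_bins_used = est$n_bins_used,
                   bins_dropped_nonpositive = est$bins_dropped_nonpositive,
                   non_physical = est$non_physical)
      }))
    })
    .log_stage("divergence: %d population pairs", length(pairs))
  }

  results <- list(panels = panels, trios = trios, qc = qc, ld_bins = ld_bins,
                  adjacent = adjacent, thinning = thinning,
                  phase_bins = phase_bins, divergence = divergence,
                  config = config)
  if (!is.null(config$out_dir)) write_summaries(results, config$out_dir)
  invisible(results)
}
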