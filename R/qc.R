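# QC cascade for trio genotypes: Mendelian masking -> trio missingness ->
# SNP call rate (pooled) -> autosomal restriction -> per-population MAF ->
# per-population HWE. Boundary conventions follow the stage wording
# literally: "more than 10%" is a strict >, "at least 90%" is >=, "below 5%"
# is a strict <.

#' QC thresholds
#'
#' @param trio_missing_max a trio is removed iff any member's missing
#'   fraction is strictly greater than this (default 0.10).
#' @param snp_callrate_min a marker is kept iff its non-missing fraction
#'   across all samples of all populations is at least this (default 0.90).
#' @param maf_min a marker is kept in a population iff its minor allele
#'   frequency there is at least this (removal is "below" the threshold;
#'   default 0.05).
#' @param hwe_alpha a marker is removed in a population iff its
#'   Hardy-Weinberg p-value is strictly below this (default 0.001).
#' @param hwe_method `"exact"` (default) or `"chisq"`.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(trio_missing_max = 0.10, snp_callrate_min = 0.90,
                          maf_min = 0.05, hwe_alpha = 0.001,
                          hwe_method = c("exact", "chisq")) {
  vals <- c(trio_missing_max, snp_callrate_min, maf_min, hwe_alpha)
  .assert(all(vals >= 0 & vals <= 1), "thresholds must be in [0,1]")
  structure(list(trio_missing_max = trio_missing_max,
                 snp_callrate_min = snp_callrate_min,
                 maf_min = maf_min, hwe_alpha = hwe_alpha,
                 hwe_method = match.arg(hwe_method)),
            class = "qc_thresholds")
}

#' @keywords internal
.qc_report_row <- function(stage, population, n_in, n_removed, unit) {
  data.frame(stage = stage, population = population, unit = unit,
             n_in = n_in, n_removed = n_removed, n_out = n_in - n_removed,
             stringsAsFactors = FALSE)
}

# Legality of a (sire, dam, offspring) genotype triple under Mendelian
# transmission, missing treated as compatible with anything. Encoded as a
# 4x4x4 lookup (0,1,2,NA); built once at load from the transmissible-gamete
# sets, so the rule is derived rather than hand-typed.
.mendel_legal <- local({
  gam <- list(0L, 0:1, 1L, 0:1)     # gametes of genotype 0,1,2,missing
  arr <- array(FALSE, c(4, 4, 4))
  for (s in 1:4) for (d in 1:4) {
    possible <- unique(outer(gam[[s]], gam[[d]], `+`))
    for (o in 1:4) {
      arr[s, d, o] <- (o == 4) || ((o - 1) %in% possible)
    }
  }
  arr
})

#' @keywords internal
.g_index <- function(g) ifelse(is.na(g), 4L, g + 1L)

#' Mask Mendelian inconsistencies in trio genotypes
#'
#' For each trio and marker, if the (sire, dam, offspring) genotype triple is
#' impossible under Mendelian transmission -- with missing genotypes treated
#' as compatible with anything -- the genotypes of all three members at that
#' marker are set missing in that trio only. All other calls are untouched.
#'
#' @param trios a [trio_set()].
#' @return List with elements `trios` (the masked `trio_set`) and `report`
#'   (a one-row-per-stage data frame; `n_removed` counts masked
#'   trio-by-marker cells).
#' @export
mask_mendelian_inconsistencies <- function(trios) {
  bad <- !.mendel_legal[cbind(as.vector(.g_index(trios$sire)),
                              as.vector(.g_index(trios$dam)),
                              as.vector(.g_index(trios$offspring)))]
  bad <- matrix(bad, nrow(trios$sire))
  trios$sire[bad] <- NA_integer_
  trios$dam[bad] <- NA_integer_
  trios$offspring[bad] <- NA_integer_
  list(trios = trios,
       report = .qc_report_row("mendelian_mask", trios$population,
                               length(bad), sum(bad), "trio-marker cells"))
}

#' Remove trios with excessive missingness
#'
#' A trio is eliminated iff one or more of its members has missing genotypes
#' in strictly more than `trio_missing_max` of the markers; a member at
#' exactly the threshold is retained. Intended to run after
#' [mask_mendelian_inconsistencies()].
#'
#' @param trios a [trio_set()].
#' @param thresholds a [qc_thresholds()].
#' @return List with `trios` (filtered) and `report`.
#' @export
filter_trio_missingness <- function(trios, thresholds = qc_thresholds()) {
  frac <- pmax(rowMeans(is.na(trios$sire)),
               rowMeans(is.na(trios$dam)),
               rowMeans(is.na(trios$offspring)))
  drop <- frac > thresholds$trio_missing_max
  out <- trios
  for (m in c("sire", "dam", "offspring")) out[[m]] <- out[[m]][!drop, , drop = FALSE]
  out$trio_id <- out$trio_id[!drop]
  list(trios = out,
       report = .qc_report_row("trio_missingness", trios$population,
                               length(drop), sum(drop), "trios"))
}

#' @keywords internal
.stack_genotypes <- function(trios) {
  rbind(trios$sire, trios$dam, trios$offspring)
}

#' Filter markers by pooled call rate
#'
#' A marker is kept iff genotypes are available for at least
#' `snp_callrate_min` of the samples pooled across every population's trios
#' (a marker at exactly the threshold is kept).
#'
#' @param trio_sets a single [trio_set()] or a list of them (one per
#'   population) sharing a marker map.
#' @param thresholds a [qc_thresholds()].
#' @return List with `keep` (logical vector over markers) and `report`.
#' @export
filter_snp_callrate <- function(trio_sets, thresholds = qc_thresholds()) {
  if (inherits(trio_sets, "trio_set")) trio_sets <- list(trio_sets)
  pooled <- do.call(rbind, lapply(trio_sets, .stack_genotypes))
  keep <- colMeans(!is.na(pooled)) >= thresholds$snp_callrate_min
  list(keep = keep,
       report = .qc_report_row("snp_callrate", "all", length(keep),
                               sum(!keep), "markers"))
}

#' Restrict to autosomal markers
#'
#' Keeps markers whose `autosomal` flag in the marker map is `TRUE`.
#'
#' @param map a [marker_map()].
#' @return List with `keep` and `report`.
#' @export
filter_autosomal <- function(map) {
  keep <- map$autosomal
  list(keep = keep,
       report = .qc_report_row("autosomal", "all", length(keep),
                               sum(!keep), "markers"))
}

#' @keywords internal
.founder_allele_freq <- function(trios) {
  founders <- rbind(trios$sire, trios$dam)
  n_called <- colSums(!is.na(founders))
  freq <- colSums(founders, na.rm = TRUE) / (2 * n_called)
  list(freq = freq, n_called = n_called)
}

#' Filter markers by minor allele frequency within a population
#'
#' Allele frequencies are computed from the founder animals (sire and dam)
#' of a population's trios, or from all haplotypes when given a phased
#' panel. A marker is removed iff its MAF is strictly below `maf_min`;
#' markers with no called genotype in the population are removed and
#' counted separately.
#'
#' @param x a [trio_set()] or a [haplotype_panel()].
#' @param thresholds a [qc_thresholds()].
#' @return List with `keep`, `report` and `n_all_missing`.
#' @export
filter_maf <- function(x, thresholds = qc_thresholds()) {
  if (inherits(x, "haplotype_panel")) {
    freq <- allele_frequencies(x)
    all_missing <- rep(FALSE, length(freq))
    population <- x$population
  } else {
    fa <- .founder_allele_freq(x)
    freq <- fa$freq
    all_missing <- fa$n_called == 0
    population <- x$population
  }
  maf <- pmin(freq, 1 - freq)
  keep <- !all_missing & maf >= thresholds$maf_min
  list(keep = keep, n_all_missing = sum(all_missing),
       report = .qc_report_row("maf", population, length(keep),
                               sum(!keep), "markers"))
}

#' Filter markers by Hardy-Weinberg equilibrium within a population
#'
#' Tests each marker in the founder animals of a population (offspring
#' genotypes are not independent of their parents' and are excluded). A
#' marker is removed iff its p-value is strictly below `hwe_alpha`.
#' Monomorphic markers test at p = 1 and are kept.
#'
#' @param trios a [trio_set()].
#' @param thresholds a [qc_thresholds()]; `hwe_method` selects the exact
#'   conditional test (default) or the chi-square approximation.
#' @return List with `keep`, `p_values` and `report`.
#' @export
filter_hwe <- function(trios, thresholds = qc_thresholds()) {
  founders <- rbind(trios$sire, trios$dam)
  n_bb <- colSums(founders == 0L, na.rm = TRUE)   # homozygous non-reference
  n_ab <- colSums(founders == 1L, na.rm = TRUE)
  n_aa <- colSums(founders == 2L, na.rm = TRUE)
  p <- if (thresholds$hwe_method == "exact") hwe_exact_test(n_aa, n_ab, n_bb)
       else hwe_chisq_test(n_aa, n_ab, n_bb)
  keep <- p >= thresholds$hwe_alpha
  list(keep = keep, p_values = p,
       report = .qc_report_row("hwe", trios$population, length(keep),
                               sum(!keep), "markers"))
}

#' Run the full QC cascade over all populations
#'
#' Applies, in order: Mendelian masking and trio-missingness filtering per
#' population; pooled SNP call rate; autosomal restriction; then MAF and HWE
#' within each population. The marker stages accumulate per-population
#' keep-lists; the surviving marker set of a population satisfies the pooled
#' filters and its own MAF/HWE filters.
#'
#' @param trio_sets list of [trio_set()]s, one per population, sharing one
#'   marker map.
#' @param thresholds a [qc_thresholds()].
#' @return A list of class `qc_result` with elements `trios` (filtered trio
#'   sets), `marker_keep` (named list of per-population logical vectors),
#'   `report` (stacked stage reports) and `map`.
#' @export
qc_cascade <- function(trio_sets, thresholds = qc_thresholds()) {
  .assert(length(trio_sets) >= 1, "need at least one population")
  if (inherits(trio_sets, "trio_set")) trio_sets <- list(trio_sets)
  map <- trio_sets[[1]]$map
  reports <- list()

  masked <- lapply(trio_sets, function(ts) {
    st <- mask_mendelian_inconsistencies(ts)
    reports[[length(reports) + 1]] <<- st$report
    st$trios
  })
  filtered <- lapply(masked, function(ts) {
    st <- filter_trio_missingness(ts, thresholds)
    reports[[length(reports) + 1]] <<- st$report
    st$trios
  })

  cr <- filter_snp_callrate(filtered, thresholds)
  reports[[length(reports) + 1]] <- cr$report
  au <- filter_autosomal(map)
  # autosomal stage counts removals among markers still standing
  au$report$n_in <- sum(cr$keep)
  au$report$n_removed <- sum(cr$keep & !au$keep)
  au$report$n_out <- au$report$n_in - au$report$n_removed
  reports[[length(reports) + 1]] <- au$report
  global_keep <- cr$keep & au$keep

  marker_keep <- lapply(filtered, function(ts) {
    mf <- filter_maf(ts, thresholds)
    hw <- filter_hwe(ts, thresholds)
    mf$report$n_in <- sum(global_keep)
    mf$report$n_removed <- sum(global_keep & !mf$keep)
    mf$report$n_out <- mf$report$n_in - mf$report$n_removed
    keep_after_maf <- global_keep & mf$keep
    hw$report$n_in <- sum(keep_after_maf)
    hw$report$n_removed <- sum(keep_after_maf & !hw$keep)
    hw$report$n_out <- hw$report$n_in - hw$report$n_removed
    reports[[length(reports) + 1]] <<- mf$report
    reports[[length(reports) + 1]] <<- hw$report
    keep_after_maf & hw$keep
  })
  names(marker_keep) <- vapply(filtered, `[[`, "", "population")
  names(filtered) <- names(marker_keep)

  structure(list(trios = filtered, marker_keep = marker_keep,
                 report = do.call(rbind, reports), map = map),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result>\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
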