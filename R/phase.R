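# Persistence of gametic phase between populations: within-distance-class
# correlation of signed r, sign-discordance proportions, and the Fisher-z
# comparison of phase correlations.

#' Markers usable in every population
#'
#' Intersection of the markers whose minor allele frequency is at least
#' `maf_min` in each of the given panels, returned in map order. Phase
#' comparisons are computed on this common set so each pair of markers has a
#' defined signed r in every population.
#'
#' @param panels list of [haplotype_panel()]s sharing reference-allele
#'   coding and marker ids.
#' @param maf_min per-population MAF threshold (default 0.05).
#' @return The common [marker_map()] (subset of the first panel's map).
#' @export
common_marker_set <- function(panels, maf_min = 0.05) {
  .assert(length(panels) >= 2, "need at least two panels")
  ids <- Reduce(intersect, lapply(panels, function(p) {
    f <- allele_frequencies(p)
    p$map$marker_id[pmin(f, 1 - f) >= maf_min]
  }))
  .assert(length(ids) > 0, "no marker passes the MAF threshold in every population")
  map <- panels[[1]]$map[panels[[1]]$map$marker_id %in% ids, , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("marker_map", "data.frame")
  map
}

#' @keywords internal
.resolve_bin_edges <- function(bin_edges, bin_width_bp, max_distance_bp) {
  if (!is.null(bin_edges)) {
    .assert(length(bin_edges) >= 2 && all(diff(bin_edges) > 0),
            "bin_edges must be increasing with >= 2 values")
    return(as.numeric(bin_edges))
  }
  edges <- seq(0, max_distance_bp, by = bin_width_bp)
  if (edges[length(edges)] < max_distance_bp) edges <- c(edges, max_distance_bp)
  edges
}

#' Correlation of gametic phase between two populations
#'
#' Aligns two pairwise-LD tables by marker-pair identity and, within each
#' distance class, computes the Pearson correlation between the two
#' populations' signed r values, together with the fraction of pairs whose
#' r signs differ (a zero r in either population counts as concordant) and
#' the pair count. High positive correlation means the same gametic phase
#' tends to be preserved across the two populations at that distance.
#'
#' The correlation is reported only for classes holding at least 3 aligned
#' pairs with non-degenerate variance on both sides; other classes carry
#' `NA` and a reason column.
#'
#' @param ld_k,ld_kprime [pairwise_ld()] tables of the two populations,
#'   computed on a common marker set (see [common_marker_set()]); pairs are
#'   matched by `(marker_i, marker_j)` identity, never by position.
#' @param bin_width_bp distance class width (default 100 kb), ignored when
#'   `bin_edges` is given.
#' @param max_distance_bp upper end of the binned range (default 10 Mb).
#' @param bin_edges optional explicit vector of class edges in bp
#'   (half-open classes `[e_i, e_{i+1})`), e.g. `c(0, 1e4, 5e4, 1e5)` for
#'   the short-range classes.
#' @return A data.frame of class `phase_bins` with columns `bin_lo_bp`,
#'   `bin_hi_bp`, `mean_distance_bp`, `correlation_R`,
#'   `opposite_sign_fraction`, `n_pairs`, `undefined_reason`; populations
#'   recorded in attribute `populations`.
#' @export
phase_correlation <- function(ld_k, ld_kprime, bin_width_bp = 1e5,
                              max_distance_bp = 1e7, bin_edges = NULL) {
  m <- merge(as.data.frame(ld_k)[, c("marker_i", "marker_j", "distance_bp", "r_signed")],
             as.data.frame(ld_kprime)[, c("marker_i", "marker_j", "r_signed")],
             by = c("marker_i", "marker_j"), suffixes = c("_k", "_kprime"))
  n_k <- nrow(ld_k); n_kp <- nrow(ld_kprime)
  if (nrow(m) < n_k || nrow(m) < n_kp)
    warning(sprintf("LD tables share %d pairs (of %d and %d); unmatched pairs dropped",
                    nrow(m), n_k, n_kp))
  edges <- .resolve_bin_edges(bin_edges, bin_width_bp, max_distance_bp)
  keep <- m$distance_bp >= edges[1] & m$distance_bp < edges[length(edges)]
  m <- m[keep, , drop = FALSE]
  idx <- findInterval(m$distance_bp, edges, rightmost.closed = FALSE)
  nb <- length(edges) - 1
  rows <- lapply(seq_len(nb), function(b) {
    sel <- idx == b
    n <- sum(sel)
    r1 <- m$r_signed_k[sel]; r2 <- m$r_signed_kprime[sel]
    opp <- if (n > 0) mean(r1 * r2 < 0) else NA_real_
    if (n < 3) {
      R <- NA_real_; reason <- if (n == 0) "empty" else "fewer than 3 pairs"
    } else if (stats::sd(r1) == 0 || stats::sd(r2) == 0) {
      R <- NA_real_; reason <- "zero variance"
    } else {
      R <- stats::cor(r1, r2); reason <- NA_character_
    }
    data.frame(bin_lo_bp = edges[b], bin_hi_bp = edges[b + 1],
               mean_distance_bp = if (n > 0) mean(m$distance_bp[sel]) else NA_real_,
               correlation_R = R, opposite_sign_fraction = opp,
               n_pairs = n, undefined_reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "populations") <- c(attr(ld_k, "population") %||% "k",
                                attr(ld_kprime, "population") %||% "kprime")
  class(out) <- c("phase_bins", "data.frame")
  out
}

#' Compare two phase correlations by Fisher's z
#'
#' Two-sided z-test of the difference between two independent correlation
#' coefficients after Fisher's variance-stabilising transformation:
#' `z = (atanh(R1) - atanh(R2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with `n` the
#' number of SNP pairs entering each correlation.
#'
#' @param r1,r2 the two correlations, strictly inside (-1, 1).
#' @param n1,n2 pair counts behind each correlation (>= 4).
#' @return List with `z` and `p_value`.
#' @examples
#' compare_phase_correlations(0.921, 1520, 0.875, 1520)
#' @export
compare_phase_correlations <- function(r1, n1, r2, n2) {
  .assert(abs(r1) < 1 && abs(r2) < 1,
          "correlations must lie strictly inside (-1, 1); the transformation diverges at |R| = 1")
  .assert(n1 >= 4 && n2 >= 4, "need at least 4 pairs per correlation")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}
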