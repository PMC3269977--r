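# Core LD estimation from phased haplotypes: signed r and r^2 per marker
# pair, adjacent-pair means, distance-binned decay, and thinning series.

#' Two-locus haplotype frequencies
#'
#' Counts, over a panel's haplotypes, the reference-allele frequency at two
#' markers and the frequency of the haplotype carrying the reference allele
#' at both.
#'
#' @param panel a [haplotype_panel()].
#' @param i,j marker ids or column indices; must lie on the same chromosome.
#' @return Named numeric vector `c(p_i, p_j, p_ij)`.
#' @export
haplotype_frequencies <- function(panel, i, j) {
  ix <- if (is.character(i)) match(i, panel$map$marker_id) else as.integer(i)
  jx <- if (is.character(j)) match(j, panel$map$marker_id) else as.integer(j)
  .assert(!is.na(ix) && !is.na(jx), "unknown marker")
  .assert(panel$map$chrom[ix] == panel$map$chrom[jx],
          "markers %s and %s are on different chromosomes",
          panel$map$marker_id[ix], panel$map$marker_id[jx])
  a <- panel$haplotypes[, ix]
  b <- panel$haplotypes[, jx]
  c(p_i = mean(a), p_j = mean(b), p_ij = mean(a & b))
}

#' Signed r and r-squared from two-locus frequencies
#'
#' The LD correlation between two biallelic markers:
#' `r = (p_ij - p_i * p_j) / sqrt(p_i (1-p_i) p_j (1-p_j))`, carrying the
#' sign of the unsquared numerator, and its square. Both markers must be
#' polymorphic; a zero denominator is an error because callers are expected
#' to pre-filter monomorphic markers.
#'
#' @param p_i,p_j reference-allele frequencies at the two markers, in (0,1).
#' @param p_ij frequency of the doubly-reference haplotype.
#' @return Named numeric vector `c(r_signed, r_squared)`; `r_signed` is
#'   clipped to [-1, 1] only against floating-point overshoot.
#' @examples
#' r_pair(0.5, 0.5, 0.25)  # linkage equilibrium
#' r_pair(0.5, 0.5, 0.5)   # complete association
#' @export
r_pair <- function(p_i, p_j, p_ij) {
  .assert(all(p_i > 0 & p_i < 1) && all(p_j > 0 & p_j < 1),
          "marker frequencies must be strictly between 0 and 1 (monomorphic markers must be filtered first)")
  r <- (p_ij - p_i * p_j) / sqrt(p_i * (1 - p_i) * p_j * (1 - p_j))
  r <- pmin(1, pmax(-1, r))
  c(r_signed = r, r_squared = r * r)
}

#' All pairwise LD records within a distance cap
#'
#' Computes signed r and r^2 for every same-chromosome marker pair closer
#' than `max_distance_bp`, from haplotype counts over the panel.
#' Monomorphic markers are skipped (their pair denominator is zero) and
#' their count is attached as attribute `n_monomorphic_skipped`.
#'
#' The scan is vectorised per chromosome through cross-products of the
#' haplotype matrix, which is exactly the counting estimator applied to all
#' pairs at once.
#'
#' @param panel a [haplotype_panel()].
#' @param max_distance_bp cap on pair distance in bp (default 10 Mb,
#'   matching the usual cap that keeps the pair list tractable; LD beyond it
#'   is near its sampling floor).
#' @return A data.frame of class `pairwise_ld` with columns `chrom`,
#'   `marker_i`, `marker_j`, `distance_bp`, `r_signed`, `r_squared`.
#' @export
pairwise_ld <- function(panel, max_distance_bp = 1e7) {
  .assert(max_distance_bp > 0, "max_distance_bp must be > 0")
  H <- nrow(panel$haplotypes)
  out <- list()
  n_mono <- 0L
  for (ch in unique(panel$map$chrom)) {
    cols <- which(panel$map$chrom == ch)
    X <- panel$haplotypes[, cols, drop = FALSE]
    p <- colMeans(X)
    poly <- p > 0 & p < 1
    n_mono <- n_mono + sum(!poly)
    if (sum(poly) < 2) next
    X <- X[, poly, drop = FALSE]
    p <- p[poly]
    ids <- panel$map$marker_id[cols][poly]
    pos <- panel$map$pos_bp[cols][poly]
    pij <- crossprod(X) / H
    num <- pij - tcrossprod(p)
    den <- sqrt(tcrossprod(p * (1 - p)))
    r <- num / den
    r[] <- pmin(1, pmax(-1, r))   # clip float overshoot, keep dim
    ut <- which(upper.tri(r), arr.ind = TRUE)
    d <- pos[ut[, 2]] - pos[ut[, 1]]
    keep <- d < max_distance_bp
    ut <- ut[keep, , drop = FALSE]
    if (nrow(ut) == 0) next
    out[[length(out) + 1]] <- data.frame(
      chrom = rep(ch, nrow(ut)),
      marker_i = ids[ut[, 1]],
      marker_j = ids[ut[, 2]],
      distance_bp = d[keep],
      r_signed = r[ut],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), marker_i = character(),
               marker_j = character(), distance_bp = numeric(),
               r_signed = numeric(), stringsAsFactors = FALSE)
  res$r_squared <- res$r_signed^2
  rownames(res) <- NULL
  attr(res, "n_monomorphic_skipped") <- n_mono
  attr(res, "population") <- panel$population
  class(res) <- c("pairwise_ld", "data.frame")
  res
}

#' Mean r-squared between adjacent markers
#'
#' Arithmetic mean of r^2 over all physically adjacent marker pairs, pooled
#' across chromosomes: the denominator is the total number of adjacent
#' pairs, the sum over chromosomes of (markers - 1). Pairs spanning a
#' chromosome boundary do not exist; a chromosome with fewer than two
#' markers contributes no pairs. Pairs involving a monomorphic marker have
#' no defined r and are excluded from both numerator and denominator, with
#' their count reported.
#'
#' @param panel a [haplotype_panel()].
#' @return List with `mean_r2`, `mean_distance_bp`, `n_pairs`,
#'   `n_undefined` (monomorphic-pair exclusions) and `per_chromosome`
#'   breakdown.
#' @export
adjacent_mean_r2 <- function(panel) {
  H <- nrow(panel$haplotypes)
  rows <- list()
  for (ch in unique(panel$map$chrom)) {
    cols <- which(panel$map$chrom == ch)
    if (length(cols) < 2) {
      rows[[length(rows) + 1]] <- data.frame(chrom = ch, n_pairs = 0L,
                                             n_undefined = 0L, sum_r2 = 0,
                                             sum_dist = 0)
      next
    }
    X <- panel$haplotypes[, cols, drop = FALSE]
    p <- colMeans(X)
    a <- seq_len(length(cols) - 1)
    pa <- p[a]; pb <- p[a + 1]
    pij <- colMeans(X[, a, drop = FALSE] * X[, a + 1, drop = FALSE])
    den <- pa * (1 - pa) * pb * (1 - pb)
    ok <- den > 0
    r2 <- (pij[ok] - pa[ok] * pb[ok])^2 / den[ok]
    d <- diff(panel$map$pos_bp[cols])
    rows[[length(rows) + 1]] <- data.frame(chrom = ch, n_pairs = sum(ok),
                                           n_undefined = sum(!ok),
                                           sum_r2 = sum(r2),
                                           sum_dist = sum(d[ok]))
  }
  per <- do.call(rbind, rows)
  per$mean_r2 <- ifelse(per$n_pairs > 0, per$sum_r2 / per$n_pairs, NA_real_)
  n <- sum(per$n_pairs)
  list(mean_r2 = if (n > 0) sum(per$sum_r2) / n else NA_real_,
       mean_distance_bp = if (n > 0) sum(per$sum_dist) / n else NA_real_,
       n_pairs = n,
       n_undefined = sum(per$n_undefined),
       per_chromosome = per[, c("chrom", "n_pairs", "n_undefined", "mean_r2")])
}

#' Distance-binned LD decay
#'
#' Groups pairwise LD records by physical distance into half-open classes
#' `[k*w, (k+1)*w)` and reports the arithmetic mean r^2 and pair count per
#' class. Empty classes are kept with `n_pairs = 0` and `mean_r2 = NA`.
#'
#' @param ld a [pairwise_ld()] table (or any data.frame with `distance_bp`
#'   and `r_squared`).
#' @param bin_width_bp class width, default 100 kb.
#' @param max_distance_bp upper end of the binned range, default 10 Mb;
#'   pairs at or beyond it are excluded.
#' @return A data.frame of class `ld_bins` with columns `bin_lo_bp`,
#'   `bin_hi_bp`, `mean_r2`, `n_pairs`.
#' @export
ld_decay_bins <- function(ld, bin_width_bp = 1e5, max_distance_bp = 1e7) {
  .assert(bin_width_bp > 0 && max_distance_bp > bin_width_bp / 2,
          "invalid bin specification")
  edges <- seq(0, max_distance_bp, by = bin_width_bp)
  if (edges[length(edges)] < max_distance_bp)
    edges <- c(edges, max_distance_bp)
  keep <- ld$distance_bp < max_distance_bp
  idx <- findInterval(ld$distance_bp[keep], edges, rightmost.closed = FALSE)
  nb <- length(edges) - 1
  n_pairs <- tabulate(idx, nbins = nb)
  sums <- vapply(seq_len(nb), function(b) sum(ld$r_squared[keep][idx == b]), 0)
  out <- data.frame(bin_lo_bp = edges[-length(edges)],
                    bin_hi_bp = edges[-1],
                    mean_r2 = ifelse(n_pairs > 0, sums / n_pairs, NA_real_),
                    n_pairs = n_pairs)
  class(out) <- c("ld_bins", "data.frame")
  out
}

#' LD at reduced marker density
#'
#' For each thinning factor k, keeps every k-th marker in map order and
#' recomputes the adjacent-pair mean r^2 and the mean adjacent spacing.
#' Reproduces the usual "% of SNP kept / average r^2 / average distance"
#' panel-density summary.
#'
#' @param panel a [haplotype_panel()] (after QC).
#' @param ks integer thinning factors; default `c(1, 2, 4, 10, 50, 100, 200)`.
#' @return A data.frame of class `thinning_series` with columns
#'   `keep_every`, `fraction_kept`, `n_markers`, `mean_adjacent_r2`,
#'   `mean_adjacent_distance_bp`.
#' @export
thinning_series <- function(panel, ks = c(1, 2, 4, 10, 50, 100, 200)) {
  rows <- lapply(ks, function(k) {
    th <- thin_panel(panel, k)
    adj <- adjacent_mean_r2(th)
    data.frame(keep_every = k, fraction_kept = 1 / k,
               n_markers = nrow(th$map),
               mean_adjacent_r2 = adj$mean_r2,
               mean_adjacent_distance_bp = adj$mean_distance_bp)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("thinning_series", "data.frame")
  out
}
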