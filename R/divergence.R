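# Divergence-time inference from the decay of phase correlation with
# recombination distance.

#' Expected between-population correlation of phase
#'
#' Closed-form decay of the correlation of signed r between two populations
#' that split from a common ancestor T generations ago, as a function of
#' the recombination distance c between the markers of a pair:
#' the exponential form `R0 * exp(-2 c T)` or the discrete-generation form
#' `R0 * (1 - c)^(2T)`. `R0` is the ancestral short-range phase
#' correlation; the two forms agree to first order in c.
#'
#' @param c recombination distance in Morgans (vectorised, >= 0).
#' @param T generations since divergence (>= 0).
#' @param R0 ancestral short-range correlation, in (0, 1]; default 1.
#' @param form `"exponential"` (default) or `"discrete"`.
#' @return Numeric vector of expected correlations.
#' @examples
#' expected_phase_correlation(0.01, 40, 0.92)  # ~0.41
#' expected_phase_correlation(0.05, 40, 0.92)  # ~0.02
#' @export
expected_phase_correlation <- function(c, T, R0 = 1,
                                       form = c("exponential", "discrete")) {
  form <- match.arg(form)
  .assert(all(c >= 0), "recombination distance c must be >= 0")
  .assert(T >= 0, "T must be >= 0")
  .assert(R0 > 0 && R0 <= 1, "R0 must be in (0, 1]")
  if (form == "exponential") return(R0 * exp(-2 * c * T))
  .assert(all(c < 1), "discrete form requires recombination distance c < 1")
  R0 * (1 - c)^(2 * T)
}

#' Estimate generations since divergence from phase-correlation decay
#'
#' Ordinary least squares of `ln(R)` on the recombination distance c of each
#' distance class (the class's mean pairwise distance converted to Morgans
#' through `cM_per_Mb`), over classes inside `[fit_lo_bp, fit_hi_bp)`.
#' The slope estimates -2T, so `T_hat = -slope / 2`; the intercept is the
#' log of the extrapolated short-range correlation. Classes with undefined
#' or non-positive correlation carry no information for the log fit and are
#' dropped with a count.
#'
#' @param phase_bins a [phase_correlation()] table, typically at fine (e.g.
#'   2.5 kb) resolution over the fit window.
#' @param fit_lo_bp,fit_hi_bp fit window in bp; defaults 10 kb to 300 kb.
#' @param cM_per_Mb physical-to-genetic conversion (default 1).
#' @param weight_by_pairs if `TRUE`, weight each class by its pair count
#'   (weighted least squares); default `FALSE` (plain regression).
#' @return A list of class `divergence_estimate`: `slope` (per Morgan),
#'   `intercept`, `T_hat`, `R0_hat` (`exp(intercept)`), `fit_lo_bp`,
#'   `fit_hi_bp`, `n_bins_used`, `bins_dropped_nonpositive`,
#'   `non_physical` (`TRUE` when the slope is positive, in which case T_hat
#'   is negative and should not be interpreted as a time).
#' @export
estimate_divergence_time <- function(phase_bins, fit_lo_bp = 1e4,
                                     fit_hi_bp = 3e5, cM_per_Mb = 1,
                                     weight_by_pairs = FALSE) {
  .assert(cM_per_Mb > 0, "cM_per_Mb must be > 0")
  b <- as.data.frame(phase_bins)
  b <- b[b$bin_lo_bp >= fit_lo_bp & b$bin_hi_bp <= fit_hi_bp, , drop = FALSE]
  .assert(nrow(b) > 0, "no distance classes inside the fit window")
  usable <- !is.na(b$correlation_R) & b$correlation_R > 0
  dropped <- sum(!usable)
  b <- b[usable, , drop = FALSE]
  .assert(nrow(b) >= 3, "fewer than 3 usable distance classes in the fit window")
  c_morgans <- b$mean_distance_bp * cM_per_Mb * 1e-8
  w <- if (weight_by_pairs) b$n_pairs else NULL
  fit <- stats::lm(log(b$correlation_R) ~ c_morgans, weights = w)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  structure(list(slope = slope, intercept = intercept,
                 T_hat = -slope / 2, R0_hat = exp(intercept),
                 fit_lo_bp = fit_lo_bp, fit_hi_bp = fit_hi_bp,
                 cM_per_Mb = cM_per_Mb,
                 n_bins_used = nrow(b),
                 bins_dropped_nonpositive = dropped,
                 non_physical = slope > 0),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("<divergence_estimate> T_hat = %.2f generations (slope %.1f/Morgan, R0_hat %.3f)\n",
              x$T_hat, x$slope, x$R0_hat))
  cat(sprintf("  fit window [%g, %g) bp at %g cM/Mb; %d classes used, %d dropped (R <= 0 or undefined)\n",
              x$fit_lo_bp, x$fit_hi_bp, x$cM_per_Mb, x$n_bins_used,
              x$bins_dropped_nonpositive))
  if (x$non_physical)
    cat("  WARNING: positive slope; estimate is non-physical\n")
  invisible(x)
}

#' Short-range phase correlation as an ancestral-LD estimate
#'
#' At very short distances the recombination distance is nearly zero, so
#' the between-population correlation of phase approximates the LD
#' correlation structure of the common ancestral population. Returns the
#' phase correlation of the `[0, max_bp)` class; when several classes fall
#' inside the range, their pair-count-weighted average is returned with a
#' message.
#'
#' @param phase_bins a [phase_correlation()] table.
#' @param max_bp upper end of the short range (default 10 kb).
#' @return Single numeric value.
#' @export
short_range_ancestral_ld <- function(phase_bins, max_bp = 1e4) {
  b <- as.data.frame(phase_bins)
  b <- b[b$bin_hi_bp <= max_bp & !is.na(b$correlation_R) & b$n_pairs > 0, ,
         drop = FALSE]
  .assert(nrow(b) > 0,
          "no defined phase correlation below %g bp", max_bp)
  if (nrow(b) == 1) return(b$correlation_R)
  message(sprintf("%d classes below %g bp; returning pair-weighted average",
                  nrow(b), max_bp))
  sum(b$correlation_R * b$n_pairs) / sum(b$n_pairs)
}
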