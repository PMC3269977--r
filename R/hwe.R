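#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test for a biallelic marker: given the observed allele
#' counts, the probability of each possible heterozygote count is evaluated
#' under random union of gametes, and the p-value is the total probability
#' of heterozygote counts no more probable than the observed one (the usual
#' two-sided exact SNP test). Monomorphic markers have a single reachable
#' configuration and return p = 1.
#'
#' Vectorised over genotype counts. Probabilities are computed by an
#' upward/downward ratio recurrence from the observed count, which is
#' numerically stable for sample sizes far beyond chip-study scale.
#'
#' @param n_aa,n_ab,n_bb observed counts of the three genotypes (vectors).
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)   # perfect proportions: p = 1
#' hwe_exact_test(50, 0, 50)    # total heterozygote deficit
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  .assert(length(n_aa) == length(n_ab) && length(n_ab) == length(n_bb),
          "genotype count vectors must have equal length")
  mapply(.hwe_exact_one, n_aa, n_ab, n_bb)
}

#' @keywords internal
.hwe_exact_one <- function(n_aa, n_ab, n_bb) {
  .assert(all(c(n_aa, n_ab, n_bb) >= 0), "genotype counts must be >= 0")
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab
  n_minor <- min(n_a, 2 * n - n_a)
  if (n_minor == 0) return(1)
  # heterozygote counts share the parity of the minor allele count
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # relative probabilities by recurrence:
  # P(h+2)/P(h) = 4 * n_aa(h) * n_bb(h) / ((h+2) * (h+1))
  # with n_aa(h) = (n_minor - h)/2 rare homozygotes, n_bb(h) the common ones.
  np <- length(hets)
  prob <- numeric(np)
  prob[1] <- 1
  if (np > 1) {
    for (i in seq_len(np - 1)) {
      h <- hets[i]
      rare_hom <- (n_minor - h) / 2
      com_hom <- n - rare_hom - h
      prob[i + 1] <- prob[i] * 4 * rare_hom * com_hom / ((h + 2) * (h + 1))
    }
  }
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_ab, hets)]
  if (is.na(p_obs)) stop("impossible genotype configuration", call. = FALSE)
  # observed or less probable, with a tolerance guarding ties against
  # floating-point noise
  sum(prob[prob <= p_obs * (1 + 1e-12)])
}

#' Chi-square test of Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom goodness-of-fit test against expected
#' Hardy-Weinberg genotype proportions, without continuity correction.
#' Offered as a large-sample alternative to [hwe_exact_test()]; the exact
#' test is the QC default.
#'
#' @inheritParams hwe_exact_test
#' @return Numeric vector of p-values.
#' @export
hwe_chisq_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  p <- (2 * n_aa + n_ab) / (2 * n)
  exp_counts <- cbind(n * p^2, 2 * n * p * (1 - p), n * (1 - p)^2)
  obs <- cbind(n_aa, n_ab, n_bb)
  stat <- rowSums((obs - exp_counts)^2 / exp_counts)
  out <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  out[p %in% c(0, 1)] <- 1   # monomorphic: nothing to test
  out
}
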