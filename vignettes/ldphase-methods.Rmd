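---
title: "Methods: LD decay, persistence of phase, and divergence time"
author: "ldphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LD decay, persistence of phase, and divergence time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldphase)
```

## The quantities this package estimates

For two biallelic markers $i$ and $j$ with reference-allele frequencies
$p_i$, $p_j$ and double-reference haplotype frequency $p_{ij}$, linkage
disequilibrium is measured as the allelic correlation

$$ r_{ij} \;=\; \frac{p_{ij} - p_i p_j}
      {\sqrt{p_i(1-p_i)\,p_j(1-p_j)}}, \qquad r^2_{ij} = r_{ij}^2 , $$

with the sign taken from the unsquared numerator. `r_pair()` evaluates the
formula; `pairwise_ld()` applies it to every same-chromosome marker pair of
a phased panel by counting haplotypes, which is algebraically identical to
the Pearson correlation of the two 0/1 allele indicator columns (the test
suite checks this equivalence to 1e-12 on random panels).

Panel-level summaries follow the standard chip-study conventions:

* `adjacent_mean_r2()` -- the arithmetic mean of $r^2$ over physically
  adjacent pairs, pooled over chromosomes with denominator
  $\sum_l (M_l - 1)$;
* `ld_decay_bins()` -- mean $r^2$ by pairwise distance in half-open classes
  (default 100 kb wide, 0 to 10 Mb);
* `thinning_series()` -- the same adjacent-pair mean after keeping every
  $k$-th marker in map order, emulating lower-density panels.

**Persistence of gametic phase.** For two populations $k, k'$ genotyped at
a common marker set, `phase_correlation()` aligns pairs by marker identity
and computes, within each distance class, the Pearson correlation
$R_{k,k'}$ of the signed $r$ values, plus the fraction of pairs whose signs
disagree. High $R$ at a distance means a marker-QTL association estimated
in one population transfers to the other at that distance. Correlations of
correlations are compared across population pairs with Fisher's z
(`compare_phase_correlations()`), using the number of SNP pairs in the
class as the sample size.

**Divergence time.** If two populations split from a common ancestor $T$
generations ago, the expected correlation of phase at recombination
distance $c$ (Morgans) decays as

$$ R(c) \;\approx\; R_0 \, e^{-2cT} \;\approx\; R_0 (1-c)^{2T}, $$

where $R_0$ is the short-range (ancestral) phase correlation.
`estimate_divergence_time()` regresses $\ln R$ on $c$ over fine distance
classes (default 2.5 kb classes between 10 and 300 kb, physical distance
converted at 1 cM/Mb) and reports $\hat T = -\text{slope}/2$.
`expected_phase_correlation()` evaluates the closed forms; at
$c = 0.01, T = 40, R_0 = 0.92$ it gives 0.41, and 0.02 at $c = 0.05$.

A note on the two closed forms: they agree to first order in $c$, and the
exact relative gap is $1 - e^{-Tc^2 + O(c^3)}$. At $c = 0.05$ and $T = 80$
that gap is about 18%, so "first-order agreement" must not be read as a
uniform few-percent bound over the whole plausible $(c, T)$ range; both
forms round to the same two decimals at the worked points above.

## Trio quality control

`qc_cascade()` applies, in order:

1. **Mendelian masking** (`mask_mendelian_inconsistencies()`): a
   (sire, dam, offspring) genotype triple impossible under Mendelian
   transmission is set missing in all three members, in that trio only.
   Missing genotypes are compatible with anything that has a legal
   completion, so e.g. sire 0 / dam missing / offspring 2 is still masked.
2. **Trio missingness** (`filter_trio_missingness()`): a trio is removed
   iff any member is missing at *strictly more than* 10% of markers (a
   member at exactly 10% survives).
3. **Call rate** (`filter_snp_callrate()`): a marker is kept iff typed in
   *at least* 90% of samples pooled over all populations.
4. **Autosomal restriction**: a per-marker boolean on the map; the package
   implements no genome-build logic.
5. **MAF per population** (`filter_maf()`): removal *strictly below* 5%,
   frequencies counted on founder animals (sire and dam).
6. **HWE per population** (`filter_hwe()`): exact conditional test,
   removal at p < 0.001.

The boundary conventions (strict vs. inclusive) follow the wording of the
stage definitions literally and are asserted in the tests. Two choices
here were genuinely open and deserve a note:

* **Founders only.** Offspring genotypes are deterministic functions of
  their parents' gametes, so including them would double-count families in
  allele-frequency and HWE calculations. Frequencies and HWE therefore use
  sire and dam only.
* **HWE test.** The exact conditional test (probability of the observed or
  any less probable heterozygote count given the allele counts) is the
  standard choice for SNP QC and is fully enumerable, which gives the test
  suite an independent closed-form oracle. Probabilities are computed by a
  ratio recurrence; ties with the observed configuration count toward the
  p-value, guarded by a 1e-12 relative tolerance. A chi-square variant
  (`hwe_chisq_test()`) is available but off by default. Monomorphic
  markers have a single reachable configuration, test at p = 1, and are
  left for the MAF filter to judge.

The cascade is idempotent (running it twice changes nothing) and each
stage's report row satisfies `n_in - n_removed = n_out`, with marker
stages chained so that each starts from the previous stage's survivors.

## The synthetic-data generator

No genotypes ship with the package; every analysis stage is exercised on
simulated panels that mimic the structure of a multi-breed chip study.

**Marker map.** Inter-marker gaps are exponential with the configured mean
(default 60 kb, minimum 1 bp). A uniform-jitter spacing was rejected
deliberately: it leaves no pairs closer than about half the mean spacing,
which would empty the 0-10 kb class and the 2.5 kb divergence classes that
the phase analyses rely on. Real chips have strongly heavy-tailed spacing,
which the exponential model reproduces adequately.

**Ancestral LD.** Along each chromosome, a haplotype's allele at marker
$m$ copies marker $m-1$ with a copy probability whose mean is
$e^{-d_m/\lambda}$ ($d_m$ the gap, $\lambda$ = `ld_decay_length_bp`,
default 200 kb); otherwise it is drawn fresh from the marker's target
frequency (MAF uniform in [0.1, 0.5] by default). Two ingredients make the
chain's LD heterogeneous the way real LD is:

* copy probabilities are Beta-dispersed around their mean
  (`ld_dispersion`, default precision 5); and
* each interval *inverts* the copied allele with probability
  `phase_flip_prob` (default 0.3), so signed $r$ is sign-diverse at every
  distance, as it is on a chip where reference-allele coding is arbitrary.

Setting `ld_dispersion = Inf` and `phase_flip_prob = 0` recovers the
homogeneous chain, whose adjacent-pair correlation tracks the
$e^{-d/\lambda}$ target directly (tested against that target per pair,
averaged over 20 seeds).

**Why sign diversity and a burn-in matter.** The decay law
$R(c) = e^{-2cT}$ rests on the ancestor being near drift-recombination
stationarity: in a stationary population the between-pair variance of $r$
is conserved, and the correlation between the two daughters' $r$ values
reduces exactly to the autocorrelation of the ancestral process,
$\left[(1-c)(1-\tfrac{1}{2N_e})\right]^{2T}$, whose $c$-dependent part is
$e^{-2cT}$ (the drift part moves only the intercept of the log-linear
fit, not the slope). A homogeneous all-positive chain violates this badly:
at short range every pair carries nearly the same $r \approx 1$, the
shared between-pair variance degenerates, and the measured phase
correlation *rises* with distance instead of falling. The generator
therefore (a) makes ancestral LD heterogeneous and sign-diverse, and (b)
runs `burn_in_generations` (default 100) of Wright-Fisher reproduction at
the daughter effective size before a split (`equilibrate_panel()`,
applied automatically by `simulate_diverged_panels()`). The burn-in length
balances two pressures: relaxation toward stationarity at rate
$\approx 2c + 1/(2N_e)$ per generation argues for more generations, while
heterozygosity loss at rate $1/(2N_e)$ (there is no mutation model to
replenish it) argues for fewer.

**Divergence.** `diverge_populations()` founds each daughter by resampling
$2N_e$ haplotypes from the ancestral pool and evolves it independently for
$T$ generations of monoecious Wright-Fisher reproduction: each offspring
draws two parents uniformly with replacement and receives one recombinant
gamete from each, with the crossover count per chromosome Poisson with
mean equal to the chromosome's genetic length (physical length times
`recomb_rate_cM_per_Mb`) and crossover positions uniform on the physical
span. At $T = 0$ the daughters are plain resamples of the ancestral pool
and their short-range phase correlation is ~1.

**Trios.** `sample_trios()` draws disjoint sire/dam diploids without
replacement, builds each offspring from one recombinant gamete per parent,
then corrupts the genotypes: independent Bernoulli missingness (the rate
is a free knob; nothing in the emulated study design constrains it, so the
default 2% reflects a typical chip call-rate deficit), followed by
Mendelian errors that replace a fraction of offspring calls with a
genotype inconsistent with the true parents wherever an inconsistent value
exists (none does when both parents are heterozygous).

**Reproducibility.** Every operation derives its own RNG stream from
`seed` plus a fixed per-operation offset, so stages can be re-run
independently and a full pipeline is bit-reproducible from its
configuration; the RNG state of the calling session is never disturbed.

## What the simulations do and do not show

The generator reproduces the *structural* features the estimators need:
irregular marker spacing, exponential-like LD decay with heterogeneous,
sign-diverse pair-level LD, drift-diverged populations with a shared
reference-allele coding, and trios with controlled missingness and
Mendelian-error rates. It does not model mutation, selection, migration or
admixture, sex chromosomes, genotyping-batch artifacts, or a realistic
two-epoch effective-size history. One visible consequence: at the default
$N_e = 100$, equilibrium short-range $r^2$ (~0.7-0.8 below 100 kb) is
higher than the ~0.4 typical of real pig chip panels, whose short-range LD
reflects a much larger ancient population. Passing tests therefore show
the estimators are correct and the decay model is recoverable under its
own assumptions -- not that any particular livestock history matches the
defaults.

## Numerical and interface choices

* Distance classes are half-open $[\text{lo}, \text{hi})$ everywhere; a
  pair at exactly 100 kb falls in the second 100 kb class.
* Coordinates are 1-based; distances in bp; conversions use
  1 cM/Mb by default and are overridable (`cM_per_Mb`).
* Monomorphic markers make the $r$ denominator zero; `pairwise_ld()` skips
  them and reports a count instead of erroring mid-scan, while `r_pair()`
  called directly on a monomorphic frequency errors.
* Phase classes need at least 3 aligned pairs and non-degenerate variance
  on both sides; anything else is `NA` with a reason string. Pairs with
  $r = 0$ in either population count as sign-concordant.
* In the divergence fit, classes with $R \le 0$ carry no information for
  $\ln R$ and are dropped with a count (`bins_dropped_nonpositive`); a
  positive fitted slope is flagged `non_physical` rather than silently
  reported as a negative time. Weighted least squares (by pair count) is
  available but plain least squares is the default. The intercept is a
  free parameter, not constrained through the short-range class.
* The short-range phase correlation itself (not its square) is used as the
  ancestral-LD level $R_0$ in the decay model, consistent with the decay
  of *correlations* being modeled; `short_range_ancestral_ld()` returns
  the $[0, 10\,\text{kb})$ class.
* Thinning anchors at the first marker of each chromosome and depends only
  on map order, never on allele frequencies.
* TSV outputs have fixed column order and formatting and contain no
  timestamps, so identical configurations produce byte-identical files;
  the YAML manifest records the configuration and package version and can
  be fed back to replay a run.

## Problem sizes used by the test experiments

The divergence-recovery experiment in the test suite uses 3 chromosomes of
700 markers at 12 kb mean spacing, 200 observed haplotypes, $N_e = 100$,
100 burn-in generations, and 12 replicate seeds for
$T \in \{10, 30, 60\}$. The marker density is chosen so each 2.5 kb class
holds on the order of a hundred aligned pairs: the logarithm of a noisy
correlation estimate is biased downward, more strongly in sparse classes,
and with too few pairs per class that bias masquerades as extra slope
(i.e. inflated $\hat T$). Other statistical tests average 10-20 replicate
seeds at smaller sizes; oracle-equivalence tests run on panels up to 200
haplotypes and 60 markers where exhaustive recomputation is instant.

## Known limitations

* The divergence estimator assumes a single clean split; admixture after
  divergence inflates long-range phase agreement and biases $\hat T$
  downward. No admixture-aware model is provided.
* $\hat T$ recovery was validated for $T$ up to 60 at $N_e = 100$; much
  larger $T$ at small $N_e$ pushes many distance classes toward $R \le 0$
  and degrades the fit (the drop count in the estimate flags this).
* The exact HWE test enumerates heterozygote counts conditional on allele
  counts; for founder counts in the low hundreds this is exact and fast,
  and it has been cross-checked exhaustively up to n = 60 and on
  randomized tables up to n = 200.
* `read_phased_panel()` trusts the phasing in its input; it validates
  structure (biallelic, phased, sorted, unique ids) but cannot detect
  phasing errors.
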