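#' Selfing fixation probabilities
#'
#' Fate of a mutation that is heterozygous in the regenerated T0 plant after
#' `g` rounds of self-fertilization. Each round a heterozygous site fixes to
#' homozygous mutant with probability 1/4, stays heterozygous with 1/2, and
#' reverts to homozygous wild type with 1/4, so after g rounds
#' p_hom = (1 - 2^-g)/2, p_het = 2^-g, and p_lost = p_hom by symmetry.
#'
#' @param g Integer number of selfing generations since T0 (a T3 plant has
#'   g = 3).
#' @return A list with elements `g`, `p_hom`, `p_het`, `p_lost`.
#' @examples
#' fixation_probabilities(3) # p_hom 0.4375, p_het 0.125
#' @export
fixation_probabilities <- function(g) {
  if (length(g) != 1L || is.na(g) || g < 0 || g != floor(g))
    stop("'g' must be a single non-negative integer")
  p_het <- 2^(-g)
  p_hom <- (1 - p_het) / 2
  list(g = as.integer(g), p_hom = p_hom, p_het = p_het, p_lost = p_hom)
}

#' Round half away from zero
#'
#' Presentation rounding used for all reported integer counts. `base::round`
#' rounds half to even; printed tables round .5 away from zero. Exact .5 ties
#' essentially never arise from the ratios involved, but the rule is fixed for
#' determinism.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits to keep.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Back-estimate the T0 mutation count for one variant class
#'
#' A line at generation g retains, as homozygous-mutant calls, a fraction
#' f * p_hom(g) of the mutations present (heterozygous) in its T0 ancestor:
#' f is the fraction of the genome callable in all compared samples, p_hom(g)
#' the fixation probability. The estimator inverts this:
#' raw / f / p_hom(g). Arithmetic is kept unrounded; rounding is presentation
#' only.
#'
#' @param raw_hom Observed homozygous variant count in the shared-callable
#'   region (one class, e.g. SNPs).
#' @param coverage_fraction Shared-callable genome fraction f in (0, 1].
#' @param g Selfing generations since T0 (>= 1).
#' @return A list with `estimate` (unrounded) and `rounded`.
#' @examples
#' estimate_t0_count(45, 0.46, 3) # 223.6 -> 224
#' @export
estimate_t0_count <- function(raw_hom, coverage_fraction, g) {
  if (raw_hom < 0) stop("'raw_hom' must be non-negative")
  if (coverage_fraction <= 0 || coverage_fraction > 1)
    stop("'coverage_fraction' must be in (0, 1]")
  p <- fixation_probabilities(g)
  if (p$p_hom == 0)
    stop("g = 0: no selfing yet, homozygous counts carry no information ",
         "about the T0 load (p_hom = 0)")
  est <- raw_hom / coverage_fraction / p$p_hom
  list(estimate = est, rounded = round_half_up(est))
}

#' Back-estimate the total T0 mutation count (SNPs + InDels)
#'
#' Totals are computed from unrounded per-class estimates and rounded once:
#' rounding per class first and summing gives a different (wrong) total.
#'
#' @inheritParams estimate_t0_count
#' @param raw_hom_snps,raw_hom_indels Observed homozygous SNP / InDel counts.
#' @return A list with `estimate` (unrounded) and `rounded`.
#' @examples
#' estimate_t0_total(45, 15, 0.46, 3) # 298 (224 + 75 rounded separately is 299)
#' @export
estimate_t0_total <- function(raw_hom_snps, raw_hom_indels, coverage_fraction, g) {
  snps <- estimate_t0_count(raw_hom_snps, coverage_fraction, g)
  indels <- estimate_t0_count(raw_hom_indels, coverage_fraction, g)
  est <- snps$estimate + indels$estimate
  list(estimate = est, rounded = round_half_up(est),
       snps = snps, indels = indels)
}

#' Average T0 estimates over sibling lines
#'
#' Lines descended from the same T0 plant estimate the same quantity; their
#' unrounded estimates are averaged and rounded once.
#'
#' @param estimates Numeric vector of (preferably unrounded) per-line T0
#'   estimates.
#' @return A list with `estimate` (mean) and `rounded`.
#' @examples
#' sibling_average(c(465, 537)) # 501
#' @export
sibling_average <- function(estimates) {
  if (length(estimates) == 0) stop("need at least one estimate")
  est <- mean(estimates)
  list(estimate = est, rounded = round_half_up(est))
}

#' Per-base somaclonal mutation rate
#'
#' @param t0_total Estimated total mutations in the T0 plant.
#' @param genome_size Genome size in bp (rice: 3.9e8).
#' @return Mutations per base.
#' @examples
#' mutation_rate(390, 3.9e8) # 1e-6
#' @export
mutation_rate <- function(t0_total, genome_size) {
  if (genome_size <= 0) stop("'genome_size' must be positive")
  t0_total / genome_size
}

#' Fold coverage from read counts
#'
#' @param n_reads Number of retained reads.
#' @param read_length Read length in bp.
#' @param genome_size Genome size in bp.
#' @return Fold coverage, rounded to one decimal.
#' @examples
#' coverage_from_reads(55633580, 76, 3.9e8) # 10.8
#' @export
coverage_from_reads <- function(n_reads, read_length, genome_size) {
  if (n_reads < 0 || read_length <= 0 || genome_size <= 0)
    stop("read count must be >= 0 and lengths positive")
  round_half_up(n_reads * read_length / genome_size, 1)
}

#' Average sequencing depth across lines
#'
#' Mean of per-line depth summaries (e.g. the per-line depth-distribution
#' peaks), rounded to one decimal.
#'
#' @param depths Numeric vector of per-line depth values.
#' @return Mean depth, one decimal.
#' @examples
#' average_depth(c(8, 4, 6, 10)) # 7
#' @export
average_depth <- function(depths) {
  if (length(depths) == 0) stop("need at least one depth value")
  round_half_up(mean(depths), 1)
}

#' Mode of an integer depth distribution
#'
#' The depth value with the highest frequency (smallest value wins ties),
#' matching how a per-base depth histogram peak is read off.
#'
#' @param depth Integer vector of per-base depths.
#' @return The modal depth.
#' @export
depth_peak <- function(depth) {
  if (length(depth) == 0) stop("empty depth vector")
  tab <- table(depth)
  as.integer(names(tab)[which.max(tab)])
}

#' Bootstrap confidence interval for a T0 estimate
#'
#' Parametric bootstrap on the observed homozygous count: replicate counts
#' are drawn Poisson around the observed raw count, each re-estimated with
#' the same coverage fraction and generation, and the percentile interval of
#' the replicates is returned. (A nonparametric resample of the called
#' variants cannot vary a plain count, so the Poisson model of the count is
#' used instead.)
#'
#' @inheritParams estimate_t0_count
#' @param n_boot Number of bootstrap replicates (default 200).
#' @param level Interval coverage (default 0.95).
#' @return list: estimate, lower, upper, n_boot.
#' @export
bootstrap_t0_interval <- function(raw_hom, coverage_fraction, g,
                                  n_boot = 200L, level = 0.95) {
  est <- estimate_t0_count(raw_hom, coverage_fraction, g)$estimate
  reps <- stats::rpois(n_boot, raw_hom) / coverage_fraction /
    fixation_probabilities(g)$p_hom
  a <- (1 - level) / 2
  q <- stats::quantile(reps, c(a, 1 - a), names = FALSE)
  list(estimate = est, lower = q[1], upper = q[2], n_boot = n_boot)
}
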