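#' Estimate the true variant count from a quality-ranked partial validation
#'
#' Candidates are ranked by descending caller quality (rank 1 = highest). A
#' subset was re-sequenced, each with outcome confirmed or not detected.
#' Validation outcomes are expected to be rank-consistent: confirmations
#' above, failures below. The estimated number of truly existing variants is
#' the number of candidates ranked above the confirmed/failed boundary:
#'
#' * with failures present, everything from the lowest-ranked failure down is
#'   discounted, so the estimate is (lowest failed rank - 1);
#' * if a confirmation sits below a failure (inconsistent outcomes), the
#'   boundary is placed at the lowest-ranked confirmation instead;
#' * with no failures the whole candidate list stands.
#'
#' With 45 candidates whose 12 lowest-quality were validated as 6 confirmed
#' over 6 failed, this yields 39; with 121 candidates whose 48 highest-quality
#' were validated as 13 confirmed over 35 failed, it yields 13.
#'
#' @param n_candidates Total candidate count.
#' @param confirmed_ranks Ranks (1-based, 1 = best quality) of validated
#'   candidates that were confirmed.
#' @param failed_ranks Ranks of validated candidates not detected.
#' @return Integer estimate of truly existing variants.
#' @export
estimate_true_count <- function(n_candidates, confirmed_ranks = integer(0),
                                failed_ranks = integer(0)) {
  if (n_candidates == 0) return(0L)
  ranks <- c(confirmed_ranks, failed_ranks)
  if (any(ranks < 1 | ranks > n_candidates)) stop("rank outside 1..n")
  if (anyDuplicated(ranks)) stop("duplicated validation ranks")
  if (length(failed_ranks) == 0) return(as.integer(n_candidates))
  boundary <- min(failed_ranks)
  if (length(confirmed_ranks) && any(confirmed_ranks > boundary))
    return(as.integer(max(confirmed_ranks)))
  as.integer(boundary - 1L)
}

#' Ranked-validation estimate from an outcome table
#'
#' Convenience wrapper around [estimate_true_count()] for a table of
#' candidates with qualities and (partial) validation outcomes.
#'
#' @param candidates data.frame with `quality` and `outcome` columns; outcome
#'   is "confirmed", "not_detected", or NA for unvalidated candidates.
#' @return Integer estimate.
#' @export
estimate_true_count_table <- function(candidates) {
  if (nrow(candidates) == 0) return(0L)
  ord <- order(-candidates$quality)
  ranked <- candidates$outcome[ord]
  estimate_true_count(
    nrow(candidates),
    confirmed_ranks = which(!is.na(ranked) & ranked == "confirmed"),
    failed_ranks = which(!is.na(ranked) & ranked == "not_detected"))
}

#' Observed vs expected homozygous/heterozygous ratio
#'
#' Compares the ratio of validated homozygous to heterozygous variant
#' estimates with the Mendelian expectation p_hom(g)/p_het(g). The comparison
#' is descriptive; no test is performed.
#'
#' @param homo_estimate,het_estimate Estimated true counts.
#' @param g Selfing generations since T0.
#' @return list: observed, expected, defined (FALSE when het_estimate == 0).
#' @export
consistency_ratio <- function(homo_estimate, het_estimate, g) {
  p <- fixation_probabilities(g)
  if (het_estimate == 0 || p$p_het == 0)
    return(list(observed = NA_real_, expected = NA_real_, defined = FALSE))
  list(observed = homo_estimate / het_estimate,
       expected = p$p_hom / p$p_het, defined = TRUE)
}
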