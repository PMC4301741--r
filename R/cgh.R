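#' Design a tiling probe set
#'
#' 60-mer probes tiled over the single strand of the host region at
#' `host_step` bp (abutting tiles by default) and over both strands of the
#' vector at `vector_step` bp (5-bp slide by default), plus 13 control
#' probes with no genomic coordinates.
#'
#' @param host_region,vector Character scalars (sequences).
#' @param probe_length Probe length (60).
#' @param host_step,vector_step Tiling steps in bp.
#' @param n_controls Number of control probes (13).
#' @return data.frame: probe_id, source (host_region | vector_forward |
#'   vector_reverse | control), start (1-based on the source; NA for
#'   controls), length, sequence.
#' @export
design_probes <- function(host_region, vector, probe_length = 60L,
                          host_step = 60L, vector_step = 5L,
                          n_controls = 13L) {
  if (host_step <= 0 || vector_step <= 0) stop("tiling step must be positive")
  if (nchar(host_region) < probe_length || nchar(vector) < probe_length)
    stop("sources must be longer than the probe length")
  tile <- function(seqstr, step, source) {
    starts <- seq(1L, nchar(seqstr) - probe_length + 1L, by = step)
    data.frame(source = source, start = starts, length = probe_length,
               sequence = substring(seqstr, starts, starts + probe_length - 1L),
               stringsAsFactors = FALSE)
  }
  probes <- rbind(
    tile(host_region, host_step, "host_region"),
    tile(vector, vector_step, "vector_forward"),
    tile(revcomp(vector), vector_step, "vector_reverse"),
    data.frame(source = "control", start = NA_integer_, length = probe_length,
               sequence = NA_character_, stringsAsFactors = FALSE)[rep(1, n_controls), ]
  )
  probes <- cbind(probe_id = sprintf("p%05d", seq_len(nrow(probes))), probes)
  rownames(probes) <- NULL
  probes
}

#' Simulate two-channel tiling-array intensities
#'
#' Signal model: intensity = gain * (copies + background_fraction) *
#' exp(N(0, sigma)) independently per probe and channel. `copies` is the copy
#' number per diploid genome seen by the probe in that channel's sample;
#' control probes carry a fixed nominal copy number of 2 in both channels.
#' The additive background keeps zero-copy probes finite and makes a
#' homozygous insertion roughly double a heterozygous one on the ratio scale.
#'
#' @param probes Probe set from [design_probes()].
#' @param copies_test,copies_ref Numeric vectors of per-probe copy numbers
#'   (recycled; control probes are overridden to 2).
#' @param params [sim_params()] (uses cgh_noise, background_fraction,
#'   cgh_gain, seed).
#' @return `probes` with `cy5` (test) and `cy3` (reference) columns.
#' @export
simulate_cgh <- function(probes, copies_test, copies_ref,
                         params = sim_params()) {
  if (params$cgh_noise < 0) stop("noise sigma must be non-negative")
  if (any(copies_test < 0) || any(copies_ref < 0))
    stop("copy numbers must be non-negative")
  set.seed(params$seed + 2000L)
  n <- nrow(probes)
  ct <- rep_len(copies_test, n)
  cr <- rep_len(copies_ref, n)
  ctrl <- probes$source == "control"
  ct[ctrl] <- 2; cr[ctrl] <- 2
  b <- params$background_fraction
  a <- params$cgh_gain
  noise <- function() if (params$cgh_noise > 0)
    exp(stats::rnorm(n, 0, params$cgh_noise)) else rep(1, n)
  probes$cy5 <- a * (ct + b) * noise()
  probes$cy3 <- a * (cr + b) * noise()
  probes
}

#' Normalize two-channel intensities and compute log2 ratios
#'
#' Each channel is divided by the median intensity of its control probes and
#' the log2 ratio is log2(test / reference) with the reference floored to
#' keep ratios finite. With `centralize = TRUE` (default) the log2 ratios are
#' then re-centered on the median of the host-genome probes, which are
#' copy-neutral by design: the 13 control probes alone leave a residual
#' channel-gain offset of a few percent that does not average out, and
#' centering on the neutral bulk removes it.
#'
#' @param array data.frame with source, cy5, cy3 columns (see
#'   [simulate_cgh()]).
#' @param ref_floor Floor applied to the normalized reference channel.
#' @param centralize Re-center log2 ratios on the host-probe median.
#' @return `array` with norm_cy5, norm_cy3, log2_ratio columns; of class
#'   `ArrayResult`.
#' @export
normalize_and_ratio <- function(array, ref_floor = 1e-6, centralize = TRUE) {
  ctrl <- array$source == "control"
  if (!any(ctrl)) stop("no control probes present")
  m5 <- stats::median(array$cy5[ctrl])
  m3 <- stats::median(array$cy3[ctrl])
  if (m5 <= 0 || m3 <= 0) stop("zero control median")
  array$norm_cy5 <- array$cy5 / m5
  array$norm_cy3 <- array$cy3 / m3
  array$log2_ratio <- log2(array$norm_cy5 / pmax(array$norm_cy3, ref_floor))
  if (centralize) {
    neutral <- array$source == "host_region"
    if (!any(neutral)) neutral <- !ctrl
    array$log2_ratio <- array$log2_ratio -
      stats::median(array$log2_ratio[neutral])
  }
  class(array) <- c("ArrayResult", class(array))
  array
}

#' Centered moving average of an ordered track
#'
#' Mean over a centered window of `window` probes; near the track ends the
#' window is truncated to the available probes (no padding). Window 1 is the
#' identity. For even windows the extra probe is taken on the right.
#'
#' @param values Numeric track ordered by position.
#' @param window Window size in probes (e.g. 1, 5, 10, 20).
#' @return Smoothed numeric track, same length.
#' @export
moving_average <- function(values, window = 1L) {
  n <- length(values)
  if (window <= 1L || n == 0) return(values)
  left <- (window - 1L) %/% 2L
  right <- window - 1L - left
  cs <- cumsum(c(0, values))
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Call aberrant intervals on a smoothed track
#'
#' Finds maximal runs of consecutive probes whose smoothed log2 ratio
#' deviates from zero with a common sign and magnitude above
#' `fuzzy_zero_floor`, and keeps runs with at least `min_probes` probes and
#' interval score |mean| * sqrt(n) / robustSD(track) >= `score_threshold`.
#' The robust SD is the MAD of the whole track; when it degenerates to zero
#' the score test falls back to the |mean| test alone.
#'
#' @param values Smoothed log2 ratios, ordered by position.
#' @param min_probes Minimum probes per called region (5).
#' @param score_threshold Interval score threshold (4.0).
#' @param fuzzy_zero_floor Minimum |mean| for a region (0.3).
#' @return data.frame: start_index, end_index, n_probes, mean_log2, score.
#' @export
call_aberrations <- function(values, min_probes = 5L, score_threshold = 4,
                             fuzzy_zero_floor = 0.3) {
  n <- length(values)
  if (n < min_probes)
    stop("track shorter than min_probes")
  dev <- sign(values) * (abs(values) > fuzzy_zero_floor)
  r <- rle(dev)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sdr <- stats::mad(values)
  out <- list()
  for (j in seq_along(r$values)) {
    if (r$values[j] == 0) next
    if (r$lengths[j] < min_probes) next
    seg <- values[starts[j]:ends[j]]
    m <- mean(seg)
    if (abs(m) < fuzzy_zero_floor) next
    score <- if (sdr > 0) abs(m) * sqrt(length(seg)) / sdr else Inf
    if (is.finite(score) && score < score_threshold) next
    out[[length(out) + 1L]] <- data.frame(
      start_index = starts[j], end_index = ends[j],
      n_probes = r$lengths[j], mean_log2 = m,
      score = score)
  }
  if (length(out) == 0)
    return(data.frame(start_index = integer(0), end_index = integer(0),
                      n_probes = integer(0), mean_log2 = numeric(0),
                      score = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Copy-state label for a host-genome region
#'
#' Thresholds follow the standard CGH reading (one-copy gain around +0.6,
#' two-copy gain >= +1, one-copy loss around -1, two-copy loss <= -2) with a
#' +-0.2 tolerance band.
#'
#' @param mean_log2 Mean log2 ratio of the region.
#' @return One of "two_copy_gain", "one_copy_gain", "neutral",
#'   "one_copy_loss", "two_copy_loss".
#' @export
copy_state_host <- function(mean_log2) {
  if (!is.finite(mean_log2)) stop("mean_log2 must be finite")
  if (mean_log2 >= 0.8) "two_copy_gain"
  else if (mean_log2 >= 0.4) "one_copy_gain"
  else if (mean_log2 <= -1.8) "two_copy_loss"
  else if (mean_log2 <= -0.8) "one_copy_loss"
  else "neutral"
}

#' Zygosity of a vector insertion from paired array ratios
#'
#' A line carrying the insertion on both haplotypes shows roughly double the
#' Cy5/Cy3 ratio of a heterozygous carrier over the vector probes, i.e. a
#' log2 difference of about 1. Given a line's mean vector-probe log2 ratio
#' and that of a known heterozygous companion line, the line is called
#' homozygous when the difference is 1.0 +- 0.3 and heterozygous (same dose)
#' when it is within +-0.3 of zero.
#'
#' @param mean_log2 The line's mean log2 ratio over vector probes.
#' @param het_reference_mean_log2 Same quantity for a heterozygous reference
#'   line.
#' @param tol Tolerance on the log2 difference (0.3).
#' @return "homozygous", "heterozygous", or "indeterminate".
#' @export
copy_state_vector <- function(mean_log2, het_reference_mean_log2, tol = 0.3) {
  d <- mean_log2 - het_reference_mean_log2
  if (abs(d - 1) <= tol) "homozygous"
  else if (abs(d) <= tol) "heterozygous"
  else "indeterminate"
}
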