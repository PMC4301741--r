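#' Variant filter profiles
#'
#' `DP2Q10` keeps calls supported by >= 2 reads with quality >= 10; `DP4Q20`
#' requires >= 4 reads and quality >= 20.
#'
#' @param name One of "DP2Q10", "DP4Q20", or "custom".
#' @param min_depth,min_quality Thresholds for a custom profile.
#' @return A list (name, min_depth, min_quality).
#' @export
filter_profile <- function(name = c("DP2Q10", "DP4Q20", "custom"),
                           min_depth = NULL, min_quality = NULL) {
  name <- match.arg(name)
  p <- switch(name,
    DP2Q10 = list(name = name, min_depth = 2L, min_quality = 10),
    DP4Q20 = list(name = name, min_depth = 4L, min_quality = 20),
    custom = list(name = name, min_depth = min_depth, min_quality = min_quality))
  if (is.null(p$min_depth) || is.null(p$min_quality))
    stop("custom profile needs min_depth and min_quality")
  p
}

# Per-call quality: a simple monotone proxy in the supporting-read count.
call_quality <- function(supporting, per_read = 3, cap = 60) {
  pmin(cap, round(per_read * supporting))
}

# Depth at which a homozygous call clears a profile, given quality =
# per_read * supporting. Used to make callable masks stringency-consistent
# with the filters (the shared-callable fraction at DP4Q20 is smaller than
# at DP2Q10, as in the study).
callable_min_depth <- function(profile = NULL, per_read = 3) {
  if (is.null(profile)) return(1L)
  max(profile$min_depth, ceiling(profile$min_quality / per_read))
}

#' Simulate per-line variant calls and depth tracks
#'
#' Per line, per-base depth is Poisson with the line's mean. At each truth
#' site the carried alleles are sampled from the local depth: a
#' homozygous-alternate site yields only alternate reads; a heterozygous site
#' splits reads Binomial(depth, 1/2) and is emitted as heterozygous when both
#' alleles are seen (all-alternate sampling is emitted as a homozygous
#' miscall; all-reference sampling yields no call). The recorded depth is the
#' supporting (alternate) read count and quality is a monotone function of
#' it. Optional false positives are sprinkled uniformly at
#' `params$false_positive_rate` per base.
#'
#' @param truth Segregated truth set (output of [segregate()]).
#' @param plans Line plans.
#' @param params [sim_params()].
#' @return A list with one element per line: `calls` (data.frame: line,
#'   chrom, pos, ref, alt, vtype, zygosity, depth, quality) and `depth`
#'   (integer per-base track over the host).
#' @export
simulate_variant_calls <- function(truth, plans, params = sim_params()) {
  validate_line_plans(plans)
  set.seed(params$seed + 1000L)
  L <- params$l_host
  out <- list()
  for (i in seq_len(nrow(plans))) {
    line <- plans$name[i]
    dm <- if (length(params$depth_mean) > 1) params$depth_mean[[line]] else params$depth_mean
    if (dm <= 0) stop("depth_mean must be positive")
    depth_track <- stats::rpois(L, dm)
    zyg <- truth[[paste0("zyg_", line)]]
    keep <- which(zyg != "hom_ref")
    rows <- list()
    if (length(keep)) {
      d <- depth_track[truth$pos[keep]]
      alt_reads <- integer(length(keep))
      hom <- zyg[keep] == "hom_alt"
      alt_reads[hom] <- d[hom]
      alt_reads[!hom] <- stats::rbinom(sum(!hom), d[!hom], 0.5)
      emit <- alt_reads >= 1L
      emitted_zyg <- ifelse(alt_reads == d, "hom_alt", "het")
      idx <- keep[emit]
      rows$true <- data.frame(
        line = line, chrom = truth$chrom[idx], pos = truth$pos[idx],
        ref = truth$ref[idx], alt = truth$alt[idx], vtype = truth$vtype[idx],
        zygosity = emitted_zyg[emit], depth = alt_reads[emit],
        quality = call_quality(alt_reads[emit], params$quality_per_read,
                               params$quality_cap),
        stringsAsFactors = FALSE)
    }
    if (params$false_positive_rate > 0) {
      n_fp <- stats::rpois(1, params$false_positive_rate * L)
      if (n_fp > 0) {
        pos <- sample.int(L, n_fp)
        refb <- sample(BASES, n_fp, replace = TRUE)
        altb <- vapply(refb, function(b) sample(setdiff(BASES, b), 1), character(1))
        sup <- 1L + stats::rpois(n_fp, 1)
        rows$fp <- data.frame(
          line = line, chrom = truth$chrom[1], pos = pos, ref = refb,
          alt = altb, vtype = "SNP", zygosity = "het", depth = sup,
          quality = call_quality(sup, params$quality_per_read,
                                 params$quality_cap),
          stringsAsFactors = FALSE)
      }
    }
    calls <- if (length(rows)) do.call(rbind, rows) else
      data.frame(line = character(0), chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0), vtype = character(0),
                 zygosity = character(0), depth = integer(0),
                 quality = numeric(0), stringsAsFactors = FALSE)
    calls <- calls[order(calls$pos), , drop = FALSE]
    rownames(calls) <- NULL
    out[[line]] <- list(calls = calls, depth = depth_track)
  }
  out
}

#' Callable mask from a depth track
#'
#' A position is callable when its depth clears the profile-consistent
#' threshold (default: depth >= 1). Returned as an IRanges of callable runs.
#'
#' @param depth Integer per-base depth track.
#' @param profile Optional [filter_profile()]; when given, the threshold is
#'   `max(min_depth, ceiling(min_quality / per_read))` so that a homozygous
#'   variant inside the mask would survive the filter.
#' @param per_read Quality gained per supporting read (see [sim_params()]).
#' @return An `IRanges` of callable intervals (1-based, closed).
#' @export
callable_mask <- function(depth, profile = NULL, per_read = 3) {
  thr <- callable_min_depth(profile, per_read)
  methods::as(S4Vectors::Rle(depth >= thr), "IRanges")
}

#' Intersect callable masks and compute the shared coverage fraction
#'
#' @param masks List of `IRanges` masks over the same genome.
#' @param genome_size Genome length in bp.
#' @return A list: `mask` (IRanges intersection) and `fraction` f =
#'   |intersection| / genome_size.
#' @export
shared_callable <- function(masks, genome_size) {
  if (length(masks) == 0) stop("need at least one mask")
  ends <- vapply(masks, function(m)
    if (length(m)) max(IRanges::end(m)) else 0L, numeric(1))
  if (any(ends > genome_size))
    stop("mask extends beyond the stated genome size")
  acc <- masks[[1]]
  for (m in masks[-1]) acc <- IRanges::intersect(acc, m)
  list(mask = acc, fraction = sum(IRanges::width(acc)) / genome_size)
}
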