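#' Filter variant calls by depth and quality
#'
#' @param calls data.frame with `depth` (supporting reads) and `quality`.
#' @param profile A [filter_profile()].
#' @return The surviving calls.
#' @export
filter_calls <- function(calls, profile) {
  keep <- calls$depth >= profile$min_depth & calls$quality >= profile$min_quality
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

variant_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Partition calls into background polymorphisms and line-specific variants
#'
#' A variant (identified by chrom/pos/ref/alt) carried by `min_carriers` or
#' more lines whose carrier set is not confined to a single sibling group is
#' treated as a background polymorphism between the laboratory stock and the
#' reference genome. Variants seen in one line only, or only within one
#' sibling group (siblings inherit the same T0 mutations), remain candidate
#' induced mutations.
#'
#' @param callsets Named list (line -> calls data.frame).
#' @param sibling_groups Named character vector or list mapping line ->
#'   group label; lines absent from it form their own singleton group.
#' @param min_carriers Carrier-count threshold for "shared" (default 2).
#' @return List with `background` (data.frame of shared variant keys and
#'   carriers) and `line_specific` (named list of per-line call data.frames).
#' @export
partition_shared <- function(callsets, sibling_groups, min_carriers = 2L) {
  lines <- names(callsets)
  grp <- vapply(lines, function(l) {
    g <- if (l %in% names(sibling_groups)) sibling_groups[[l]] else NA_character_
    if (is.null(g) || is.na(g)) l else g
  }, character(1))
  keys <- lapply(callsets, variant_key)
  all_keys <- unique(unlist(keys, use.names = FALSE))
  carrier <- matrix(FALSE, nrow = length(all_keys), ncol = length(lines),
                    dimnames = list(all_keys, lines))
  for (l in lines) carrier[unique(keys[[l]]), l] <- TRUE
  n_carriers <- rowSums(carrier)
  n_groups <- apply(carrier, 1, function(v) length(unique(grp[v])))
  is_bg <- n_carriers >= min_carriers & n_groups > 1L
  bg_keys <- all_keys[is_bg]

  line_specific <- lapply(lines, function(l) {
    cs <- callsets[[l]]
    out <- cs[!(keys[[l]] %in% bg_keys), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(line_specific) <- lines
  background <- data.frame(
    key = bg_keys,
    carriers = vapply(bg_keys, function(k)
      paste(lines[carrier[k, ]], collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  rownames(background) <- NULL
  list(background = background, line_specific = line_specific)
}

#' Restrict calls to a callable mask
#'
#' @param calls Calls data.frame with `pos`.
#' @param mask `IRanges` mask (e.g. from [shared_callable()]).
#' @return Calls whose position falls inside the mask.
#' @export
restrict_to_mask <- function(calls, mask) {
  if (nrow(calls) == 0) return(calls)
  hits <- IRanges::overlapsAny(IRanges::IRanges(calls$pos, calls$pos), mask)
  out <- calls[hits, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a base substitution into the six strand-symmetric classes
#'
#' G>A and C>T both map to GC>AT, etc. Transitions are purine<->purine or
#' pyrimidine<->pyrimidine changes (classes AT>GC and GC>AT).
#'
#' @param ref_base,alt_base Single bases in {A,C,G,T}, ref != alt.
#' @return list(class, transition).
#' @export
classify_substitution <- function(ref_base, alt_base) {
  if (!(ref_base %in% BASES) || !(alt_base %in% BASES))
    stop("bases must be one of A, C, G, T")
  if (ref_base == alt_base) stop("ref and alt must differ")
  # canonical representative: express the change from the A/G strand base
  if (ref_base %in% c("T", "C")) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ref_base <- comp[[ref_base]]; alt_base <- comp[[alt_base]]
  }
  pair_from <- if (ref_base == "A") "AT" else "GC"
  pair_to <- switch(alt_base, A = "AT", T = "TA", G = "GC", C = "CG")
  cls <- paste0(pair_from, ">", pair_to)
  # A>G gives "AT>GC"; G>A gives "GC>AT"; A>C -> "AT>CG"; A>T -> "AT>TA";
  # G>C -> "GC>CG"; G>T -> "GC>TA"
  transition <- cls %in% c("AT>GC", "GC>AT")
  list(class = cls, transition = transition)
}

#' Mutation spectrum table
#'
#' Counts and one-decimal percentages per substitution class for a set of
#' SNP calls, plus transition/transversion totals and their two-decimal
#' ratio.
#'
#' @param variants data.frame with `ref`, `alt` (and optionally `vtype`,
#'   in which case non-SNPs are rejected).
#' @return list of class `SpectrumTable`: `table` (class, count, percent),
#'   `total`, `ti`, `tv`, `titv` (two decimals; NA when tv == 0).
#' @export
spectrum_table <- function(variants) {
  if (!is.null(variants$vtype) && any(variants$vtype != "SNP"))
    stop("spectrum_table expects SNPs only")
  cls <- if (nrow(variants)) vapply(seq_len(nrow(variants)), function(i)
    classify_substitution(variants$ref[i], variants$alt[i])$class,
    character(1)) else character(0)
  counts <- vapply(SNP_CLASSES, function(k) sum(cls == k), numeric(1))
  spectrum_from_counts(counts)
}

#' Spectrum table from pre-tabulated class counts
#'
#' @param counts Numeric vector of six counts, in class order
#'   AT>GC, GC>AT, AT>CG, AT>TA, GC>CG, GC>TA.
#' @return As [spectrum_table()].
#' @export
spectrum_from_counts <- function(counts) {
  stopifnot(length(counts) == 6)
  counts <- stats::setNames(as.numeric(counts), SNP_CLASSES)
  total <- sum(counts)
  pct <- if (total > 0) round_half_up(100 * counts / total, 1) else counts * 0
  ti <- counts[["AT>GC"]] + counts[["GC>AT"]]
  tv <- total - ti
  titv <- if (tv > 0) round_half_up(ti / tv, 2) else NA_real_
  structure(list(
    table = data.frame(class = SNP_CLASSES, count = unname(counts),
                       percent = unname(pct), stringsAsFactors = FALSE),
    total = total, ti = ti, tv = tv, titv = titv),
    class = "SpectrumTable")
}

#' Average Ti/Tv across lines
#'
#' Averages the per-line transition/transversion ratios after each is rounded
#' to two decimals (the convention used when per-line ratios are reported to
#' two decimals and then averaged); the mean is reported to three decimals.
#'
#' @param tables List of `SpectrumTable`s, or a numeric vector of per-line
#'   ratios.
#' @return Mean ratio, three decimals; NA if any ratio is undefined.
#' @export
titv_average <- function(tables) {
  ratios <- if (is.numeric(tables)) tables else
    vapply(tables, function(t) t$titv, numeric(1))
  if (length(ratios) == 0) stop("need at least one table")
  if (anyNA(ratios)) return(NA_real_)
  round_half_up(mean(round_half_up(ratios, 2)), 3)
}
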