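# Independent brute-force oracles used by the property tests. These are kept
# deliberately naive (per-position loops, whole-sequence translation) so they
# share no code path with the package implementations they check.

oracle_moving_average <- function(x, window) {
  n <- length(x)
  left <- (window - 1L) %/% 2L
  right <- window - 1L - left
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - left); hi <- min(n, i + right)
    mean(x[lo:hi])
  }, numeric(1))
}

oracle_filter <- function(calls, min_depth, min_quality) {
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls)))
    keep[i] <- calls$depth[i] >= min_depth && calls$quality[i] >= min_quality
  sum(keep)
}

oracle_shared_fraction <- function(masks, genome_size) {
  acc <- rep(TRUE, genome_size)
  for (m in masks) {
    v <- rep(FALSE, genome_size)
    for (j in seq_along(m)) {
      v[IRanges::start(m)[j]:IRanges::end(m)[j]] <- TRUE
    }
    acc <- acc & v
  }
  sum(acc) / genome_size
}

# Whole-sequence-translation effect classifier: mutates the genome, rebuilds
# the full CDS / 5'UTR, and compares proteins or ATG counts. One category per
# (position, alt, model); NA when the model does not apply.
oracle_classify_snp <- function(p, alt, model, genome) {
  strand <- model$strand
  tx1 <- model$tx[1]; tx2 <- model$tx[2]
  if (p < tx1 || p > tx2) {
    five <- if (strand == "+") p < tx1 else p > tx2
    return(if (five) "UPSTREAM_CAND" else "DOWNSTREAM_CAND")
  }
  ex <- model$exons
  if (nrow(ex) >= 2) {
    for (j in seq_len(nrow(ex) - 1)) {
      s <- ex[j, 2] + 1L; e <- ex[j + 1, 1] - 1L
      if (p %in% c(s, s + 1L, e - 1L, e)) {
        left <- p <= s + 1L
        donor <- (left && strand == "+") || (!left && strand == "-")
        return(if (donor) "SPLICE_SITE_DONOR" else "SPLICE_SITE_ACCEPTOR")
      }
    }
  }
  get_cds <- function(g) {
    parts <- character(0)
    for (j in seq_len(nrow(model$cds)))
      parts <- c(parts, substr(g, model$cds[j, 1], model$cds[j, 2]))
    s <- paste(parts, collapse = "")
    if (strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }
  in_cds <- any(p >= model$cds[, 1] & p <= model$cds[, 2])
  mut <- genome
  substr(mut, p, p) <- alt
  if (in_cds) {
    ref_cds <- get_cds(genome); alt_cds <- get_cds(mut)
    tr <- function(s) as.character(Biostrings::translate(
      Biostrings::DNAString(s)))
    if (substr(alt_cds, 1, 3) != "ATG") return("START_LOST")
    ra <- tr(ref_cds); aa <- tr(alt_cds)
    if (ra == aa) return("SYNONYMOUS_CODING")
    d <- which(strsplit(ra, "")[[1]] != strsplit(aa, "")[[1]])[1]
    if (substr(aa, d, d) == "*") return("STOP_GAINED")
    return("NON_SYNONYMOUS_CODING")
  }
  in_exon <- any(p >= ex[, 1] & p <= ex[, 2])
  if (!in_exon) return("INTRON")
  cds1 <- min(model$cds[, 1]); cds2 <- max(model$cds[, 2])
  utr5_side <- if (strand == "+") p < cds1 else p > cds2
  if (utr5_side) {
    get_utr5 <- function(g) {
      parts <- character(0)
      for (j in seq_len(nrow(ex))) {
        lo <- ex[j, 1]; hi <- ex[j, 2]
        if (strand == "+") { hi <- min(hi, cds1 - 1L) } else { lo <- max(lo, cds2 + 1L) }
        if (lo <= hi) parts <- c(parts, substr(g, lo, hi))
      }
      s <- paste(parts, collapse = "")
      if (strand == "-")
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      s
    }
    n_atg <- function(s) length(gregexpr("ATG", s, fixed = TRUE)[[1]][
      gregexpr("ATG", s, fixed = TRUE)[[1]] > 0])
    if (n_atg(get_utr5(mut)) > n_atg(get_utr5(genome))) return("START_GAINED")
    return("UTR_5_PRIME")
  }
  "UTR_3_PRIME"
}

# Oracle wrapper matching annotate_variant's per-model record (window logic
# resolved here so the two sides stay comparable).
oracle_annotate <- function(p, alt, models, genome, window) {
  recs <- character(0)
  for (model in models) {
    cat <- oracle_classify_snp(p, alt, model, genome)
    if (cat == "UPSTREAM_CAND") {
      d <- if (model$strand == "+") model$tx[1] - p else p - model$tx[2]
      if (d <= window) recs <- c(recs, "UPSTREAM")
    } else if (cat == "DOWNSTREAM_CAND") {
      d <- if (model$strand == "+") p - model$tx[2] else model$tx[1] - p
      if (d <= window) recs <- c(recs, "DOWNSTREAM")
    } else recs <- c(recs, cat)
  }
  if (length(recs) == 0) recs <- "INTERGENIC"
  sort(recs)
}

# small cached reference so several test files can share one build
toy_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_reference(sim_params(seed = 42, l_host = 20000L,
                                              n_genes = 4L))
    cache
  }
})
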