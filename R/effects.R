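EFFECT_CATEGORIES <- c(
  "FRAME_SHIFT", "NON_SYNONYMOUS_CODING", "CODON_CHANGE_PLUS_CODON_DELETION",
  "START_GAINED", "START_LOST", "STOP_GAINED", "SPLICE_SITE_ACCEPTOR",
  "SPLICE_SITE_DONOR", "SYNONYMOUS_CODING", "EXON", "INTRON", "UTR_3_PRIME",
  "UTR_5_PRIME", "UPSTREAM", "DOWNSTREAM", "INTERGENIC")

IMPACTFUL_CATEGORIES <- EFFECT_CATEGORIES[1:8]

COMP <- c(A = "T", C = "G", G = "C", T = "A")

translate_codon <- function(codon) {
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     no.init.codon = TRUE))
}

# transcript-oriented CDS sequence of a model
cds_sequence <- function(model, genome) {
  pieces <- apply(model$cds, 1, function(iv) substr(genome, iv[1], iv[2]))
  s <- paste(pieces, collapse = "")
  if (model$strand == "-") revcomp(s) else s
}

# transcript-oriented offset (1-based) of genomic position p within the CDS,
# or NA if p is outside the CDS
cds_offset <- function(model, p) {
  cds <- model$cds
  w <- cds[, 2] - cds[, 1] + 1L
  hit <- which(p >= cds[, 1] & p <= cds[, 2])
  if (length(hit) == 0) return(NA_integer_)
  if (model$strand == "+") {
    before <- if (hit > 1) sum(w[seq_len(hit - 1)]) else 0L
    before + (p - cds[hit, 1] + 1L)
  } else {
    after <- if (hit < nrow(cds)) sum(w[(hit + 1):nrow(cds)]) else 0L
    after + (cds[hit, 2] - p + 1L)
  }
}

in_intervals <- function(p, m) {
  nrow(m) > 0 && any(p >= m[, 1] & p <= m[, 2])
}

# intron intervals (genomic) between consecutive exons
introns_of <- function(model) {
  ex <- model$exons
  if (nrow(ex) < 2) return(matrix(integer(0), ncol = 2))
  cbind(ex[-nrow(ex), 2] + 1L, ex[-1, 1] - 1L)
}

# UTR intervals: exonic minus CDS, split by transcript side of the CDS
utrs_of <- function(model) {
  ex_ir <- IRanges::IRanges(model$exons[, 1], model$exons[, 2])
  cds_ir <- IRanges::IRanges(model$cds[, 1], model$cds[, 2])
  utr <- IRanges::setdiff(ex_ir, cds_ir)
  cds_start <- min(model$cds[, 1]); cds_end <- max(model$cds[, 2])
  left <- utr[IRanges::end(utr) < cds_start]
  right <- utr[IRanges::start(utr) > cds_end]
  if (model$strand == "+") list(utr5 = left, utr3 = right)
  else list(utr5 = right, utr3 = left)
}

# does substituting alt at genomic position p create a new ATG (transcript
# orientation) covering p? The scan window is clamped to [lo_bound, hi_bound]
# (the surrounding 5'UTR interval) so an ATG straddling the UTR boundary does
# not count.
creates_atg <- function(genome, p, alt, strand, lo_bound = 1L,
                        hi_bound = nchar(genome)) {
  lo <- max(lo_bound, p - 2L); hi <- min(hi_bound, p + 2L)
  ref_win <- substr(genome, lo, hi)
  alt_win <- ref_win
  substr(alt_win, p - lo + 1L, p - lo + 1L) <- alt
  if (strand == "-") { ref_win <- revcomp(ref_win); alt_win <- revcomp(alt_win) }
  has_atg <- function(s) grepl("ATG", s, fixed = TRUE)
  has_atg(alt_win) && !has_atg(ref_win)
}

classify_in_transcript <- function(variant, model, genome) {
  is_snp <- nchar(variant$ref) == 1 && nchar(variant$alt) == 1
  p <- if (is_snp) variant$pos else variant$pos + 1L  # first changed base
  ir <- introns_of(model)
  # splice sites: first/last 2 bases of an intron; donor is the transcript-5'
  # end of the intron
  if (nrow(ir) > 0) {
    for (j in seq_len(nrow(ir))) {
      s <- ir[j, 1]; e <- ir[j, 2]
      at_left <- p >= s & p <= s + 1L
      at_right <- p >= e - 1L & p <= e
      if (at_left || at_right) {
        donor_left <- model$strand == "+"
        if ((at_left && donor_left) || (at_right && !donor_left))
          return("SPLICE_SITE_DONOR")
        return("SPLICE_SITE_ACCEPTOR")
      }
    }
  }
  if (in_intervals(p, model$cds)) {
    if (!is_snp) {
      indel_len <- abs(nchar(variant$ref) - nchar(variant$alt))
      if (indel_len %% 3 != 0) return("FRAME_SHIFT")
      if (nchar(variant$ref) > nchar(variant$alt))
        return("CODON_CHANGE_PLUS_CODON_DELETION")
      warning("in-frame insertion in CDS tallied as EXON (category not emitted)")
      return("EXON")
    }
    off <- cds_offset(model, p)
    cds_seq <- cds_sequence(model, genome)
    ci <- (off - 1L) %/% 3L + 1L
    within <- (off - 1L) %% 3L + 1L
    ref_codon <- substr(cds_seq, 3L * (ci - 1L) + 1L, 3L * ci)
    alt_base <- if (model$strand == "+") variant$alt else COMP[[variant$alt]]
    alt_codon <- ref_codon
    substr(alt_codon, within, within) <- alt_base
    if (ci == 1L && !identical(alt_codon, "ATG")) return("START_LOST")
    ref_aa <- translate_codon(ref_codon)
    alt_aa <- translate_codon(alt_codon)
    if (alt_aa == "*" && ref_aa != "*") return("STOP_GAINED")
    if (alt_aa == ref_aa) return("SYNONYMOUS_CODING")
    return("NON_SYNONYMOUS_CODING")
  }
  utr <- utrs_of(model)
  hit5 <- IRanges::overlapsAny(utr$utr5, IRanges::IRanges(p, p))
  if (any(hit5)) {
    iv <- utr$utr5[hit5][1]
    if (is_snp && creates_atg(genome, p, variant$alt, model$strand,
                              IRanges::start(iv), IRanges::end(iv)))
      return("START_GAINED")
    return("UTR_5_PRIME")
  }
  if (IRanges::overlapsAny(IRanges::IRanges(p, p), utr$utr3))
    return("UTR_3_PRIME")
  if (nrow(ir) > 0 && in_intervals(p, ir)) return("INTRON")
  if (in_intervals(p, model$exons)) return("EXON")
  NA_character_
}

#' Annotate a variant against gene models
#'
#' One record per transcript the variant overlaps or lies near (within the
#' upstream/downstream windows, strand-aware); INTERGENIC when none. Within a
#' transcript the precedence is splice site (within 2 bp of an intron
#' boundary) > CDS > UTR > intron > exon. CDS SNPs are classified by codon
#' translation (standard code): initiator-ATG-destroying -> START_LOST, new
#' stop -> STOP_GAINED, else synonymous/non-synonymous. CDS indels:
#' frameshift unless length is a multiple of 3; in-frame deletions ->
#' CODON_CHANGE_PLUS_CODON_DELETION; in-frame insertions are tallied as EXON
#' with a warning. A 5'UTR SNP creating a new ATG -> START_GAINED.
#'
#' @param variant A one-row data.frame or list with chrom, pos, ref, alt.
#' @param models List of gene models (see [generate_reference()]).
#' @param genome Host genome sequence (character scalar).
#' @param upstream_window,downstream_window bp windows outside the transcript
#'   (defaults 5000, the conventional annotation-tool default).
#' @return data.frame of class records: transcript, category, impactful.
#' @export
annotate_variant <- function(variant, models, genome,
                             upstream_window = 5000L,
                             downstream_window = 5000L) {
  p <- variant$pos
  recs <- list()
  for (model in models) {
    if (!identical(model$chrom, variant$chrom)) next
    cat <- NA_character_
    if (p >= model$tx[1] && p <= model$tx[2]) {
      cat <- classify_in_transcript(variant, model, genome)
    } else {
      five_prime_side <- if (model$strand == "+") p < model$tx[1] else p > model$tx[2]
      dist <- if (p < model$tx[1]) model$tx[1] - p else p - model$tx[2]
      if (p < model$tx[1] || p > model$tx[2]) {
        if (five_prime_side && dist <= upstream_window) cat <- "UPSTREAM"
        if (!five_prime_side && dist <= downstream_window) cat <- "DOWNSTREAM"
      }
    }
    if (!is.na(cat))
      recs[[length(recs) + 1L]] <- data.frame(
        transcript = model$gene_id, category = cat,
        stringsAsFactors = FALSE)
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(transcript = NA_character_, category = "INTERGENIC",
               stringsAsFactors = FALSE)
  out$impactful <- out$category %in% IMPACTFUL_CATEGORIES
  out
}

#' Annotate a set of variants
#'
#' @param variants data.frame with chrom, pos, ref, alt (one row per variant).
#' @inheritParams annotate_variant
#' @return data.frame with variant index, transcript, category, impactful.
#' @export
annotate_variants <- function(variants, models, genome,
                              upstream_window = 5000L,
                              downstream_window = 5000L) {
  recs <- lapply(seq_len(nrow(variants)), function(i) {
    r <- annotate_variant(variants[i, ], models, genome,
                          upstream_window, downstream_window)
    r$variant <- i
    r
  })
  out <- do.call(rbind, recs)
  out[, c("variant", "transcript", "category", "impactful")]
}

#' Tally effect records by category
#'
#' A variant can contribute several records (one per nearby transcript), so
#' the total can exceed the variant count. Percentages are of total effect
#' records, reported to two decimals.
#'
#' @param effects data.frame with a `category` column.
#' @return data.frame: category, count, percent, impactful (all 16
#'   categories, zero-filled).
#' @export
tally_effects <- function(effects) {
  counts <- vapply(EFFECT_CATEGORIES,
                   function(k) sum(effects$category == k), numeric(1))
  total <- sum(counts)
  pct <- if (total > 0) round_half_up(100 * counts / total, 2) else counts * 0
  data.frame(category = EFFECT_CATEGORIES, count = unname(counts),
             percent = unname(pct),
             impactful = EFFECT_CATEGORIES %in% IMPACTFUL_CATEGORIES,
             stringsAsFactors = FALSE)
}

#' Count protein-affecting effects
#'
#' Sum over the eight categories predicted to affect protein quantity or
#' quality (frameshift, non-synonymous, in-frame codon deletion, start
#' gained/lost, stop gained, splice acceptor/donor).
#'
#' @param tally Output of [tally_effects()], or a numeric vector of counts
#'   for the eight impactful categories.
#' @return Integer sum.
#' @export
impactful_count <- function(tally) {
  if (is.numeric(tally)) return(sum(tally))
  sum(tally$count[tally$impactful])
}
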