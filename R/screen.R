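#' Quality-trim and length-filter reads
#'
#' Removes leading and trailing bases whose quality falls below
#' `quality_floor`, optionally strips a configured adapter-like prefix, and
#' discards reads shorter than `min_length` (default 20 bp) after trimming.
#'
#' @param reads data.frame with `seq` and `qual` (Phred+33) columns.
#' @param quality_floor Phred threshold below which end bases are trimmed.
#' @param min_length Minimum surviving read length.
#' @param adapter Optional adapter prefix to strip when a read starts with it.
#' @return The surviving reads, trimmed, same columns.
#' @export
qc_reads <- function(reads, quality_floor = 20L, min_length = 20L,
                     adapter = NULL) {
  if (nrow(reads) == 0) return(reads)
  seqs <- reads$seq
  quals <- reads$qual
  if (!is.null(adapter) && nzchar(adapter)) {
    hit <- startsWith(seqs, adapter)
    al <- nchar(adapter)
    seqs[hit] <- substring(seqs[hit], al + 1L)
    quals[hit] <- substring(quals[hit], al + 1L)
  }
  n <- length(seqs)
  keep_from <- integer(n); keep_to <- integer(n)
  for (i in seq_len(n)) {
    q <- as.integer(charToRaw(quals[i])) - 33L
    good <- which(q >= quality_floor)
    if (length(good) == 0) { keep_from[i] <- 1L; keep_to[i] <- 0L }
    else { keep_from[i] <- good[1]; keep_to[i] <- good[length(good)] }
  }
  len <- keep_to - keep_from + 1L
  sel <- len >= min_length
  out <- reads[sel, , drop = FALSE]
  out$seq <- substring(seqs[sel], keep_from[sel], keep_to[sel])
  out$qual <- substring(quals[sel], keep_from[sel], keep_to[sel])
  rownames(out) <- NULL
  out
}

# k-mer position table of a reference, restricted to k-mers absent from the
# host on both strands ("unique" k-mers: matching one is what mapping-quality
# filtering approximates).
unique_kmer_table <- function(reference, host_kmers, k = 31L) {
  km <- kmers(reference, k)
  pos <- seq_along(km)
  keep <- !(km %in% host_kmers)
  list(kmer = km[keep], pos = pos[keep], k = k, length = nchar(reference))
}

#' Screen reads for foreign (vector / Agrobacterium) sequences
#'
#' Replaces read mapping with exact matching of unique k-mers: a read hits a
#' reference when it shares, on either strand, at least one k-mer
#' (`min_exact_match` long) that occurs in the reference but nowhere in the
#' host genome. Coverage is accumulated over the reference spans of matched
#' k-mers.
#'
#' @param reads data.frame with a `seq` column (post-QC).
#' @param references Named list/character vector of reference sequences
#'   (e.g. vector backbone, T-DNA, Agrobacterium panel).
#' @param host Host genome sequence used to define k-mer uniqueness.
#' @param k Exact-match seed length (default 31).
#' @param min_hits,min_covered_fraction Decision thresholds for the verdict.
#' @return data.frame of class `ScreenReport`: reference, hits,
#'   covered_bases, covered_fraction, verdict.
#' @export
screen_reads <- function(reads, references, host, k = 31L,
                         min_hits = 3L, min_covered_fraction = 0.01) {
  if (length(references) == 0) stop("empty reference panel")
  references <- as.list(references)
  if (is.null(names(references)) || any(!nzchar(names(references))))
    stop("references must be named")
  host_kmers <- unique(c(kmers(host, k), kmers(revcomp(host), k)))
  read_kmers_fwd <- if (nrow(reads))
    unlist(lapply(reads$seq, kmers, k = k), use.names = FALSE) else character(0)
  read_ids <- if (nrow(reads))
    rep(seq_len(nrow(reads)),
        vapply(reads$seq, function(s) max(0L, nchar(s) - k + 1L), integer(1)))
    else integer(0)

  rows <- lapply(names(references), function(nm) {
    refseq <- references[[nm]]
    tabs <- list(unique_kmer_table(refseq, host_kmers, k),
                 unique_kmer_table(revcomp(refseq), host_kmers, k))
    covered <- logical(nchar(refseq))
    hit_read <- logical(nrow(reads))
    for (si in 1:2) {
      tab <- tabs[[si]]
      m <- match(read_kmers_fwd, tab$kmer)
      ok <- !is.na(m)
      if (any(ok)) {
        hit_read[unique(read_ids[ok])] <- TRUE
        starts <- tab$pos[m[ok]]
        if (si == 2) starts <- tab$length - (starts + k - 1L) + 1L
        for (s in unique(starts)) covered[s:(s + k - 1L)] <- TRUE
      }
    }
    data.frame(reference = nm, hits = sum(hit_read),
               covered_bases = sum(covered),
               covered_fraction = sum(covered) / nchar(refseq),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep$verdict <- screen_verdict(rep, min_hits, min_covered_fraction)
  attr(rep, "thresholds") <- list(k = k, min_hits = min_hits,
                                  min_covered_fraction = min_covered_fraction)
  class(rep) <- c("ScreenReport", class(rep))
  rep
}

#' Presence/absence verdict from a screen report
#'
#' @param report `ScreenReport` (or data.frame with hits / covered_fraction).
#' @param min_hits Minimum hit-read count.
#' @param min_covered_fraction Minimum fraction of the reference covered.
#' @return Character vector "present"/"absent" per reference.
#' @export
screen_verdict <- function(report, min_hits = 3L, min_covered_fraction = 0.01) {
  if (min_hits < 0 || min_covered_fraction < 0) stop("thresholds must be >= 0")
  ifelse(report$hits >= min_hits &
           report$covered_fraction >= min_covered_fraction,
         "present", "absent")
}
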