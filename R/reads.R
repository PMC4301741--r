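#' Simulate short reads from a genome
#'
#' Uniform start positions, substitution errors at a fixed per-base rate,
#' Sanger-scale (Phred+33) base qualities. Optionally each read receives
#' low-quality tails at both ends (lengths uniform on 0..`low_tail_max`,
#' quality `low_tail_q`), emulating the degraded read ends that QC trimming
#' removes.
#'
#' @param genome Character scalar template sequence.
#' @param n_reads Number of reads.
#' @param read_length Read length in bp (must not exceed the genome).
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @param base_q Phred quality assigned to ordinary bases.
#' @param low_tail_max,low_tail_q Maximum low-quality tail length per end and
#'   the quality assigned inside tails (0 disables tails).
#' @return data.frame: id, seq, qual (Phred+33 string), start (1-based).
#' @export
simulate_reads <- function(genome, n_reads, read_length = 76L,
                           error_rate = 0, seed = 1L, base_q = 35L,
                           low_tail_max = 0L, low_tail_q = 2L) {
  if (n_reads < 0) stop("n_reads must be non-negative")
  L <- nchar(genome)
  if (read_length > L) stop("read_length exceeds the genome length")
  set.seed(seed)
  if (n_reads == 0)
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), start = integer(0),
                      stringsAsFactors = FALSE))
  starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
  seqs <- substring(genome, starts, starts + read_length - 1L)
  if (error_rate > 0) {
    n_err <- stats::rbinom(n_reads, read_length, error_rate)
    for (i in which(n_err > 0)) {
      b <- chars(seqs[i])
      at <- sample.int(read_length, n_err[i])
      b[at] <- vapply(b[at], function(x) sample(setdiff(BASES, x), 1),
                      character(1))
      seqs[i] <- paste(b, collapse = "")
    }
  }
  qv <- matrix(base_q, nrow = n_reads, ncol = read_length)
  if (low_tail_max > 0) {
    lt <- sample.int(low_tail_max + 1L, n_reads, replace = TRUE) - 1L
    rt <- sample.int(low_tail_max + 1L, n_reads, replace = TRUE) - 1L
    for (i in seq_len(n_reads)) {
      if (lt[i] > 0) qv[i, seq_len(lt[i])] <- low_tail_q
      if (rt[i] > 0) qv[i, read_length - seq_len(rt[i]) + 1L] <- low_tail_q
    }
  }
  quals <- apply(qv, 1, function(q) rawToChar(as.raw(q + 33L)))
  data.frame(id = sprintf("read%06d", seq_len(n_reads)), seq = seqs,
             qual = quals, start = starts, stringsAsFactors = FALSE)
}

#' Simulate reads from a diploid line
#'
#' Splits reads evenly (binomially) between the two haplotypes of a line, so
#' a heterozygous vector insertion contributes roughly half the depth of a
#' homozygous one.
#'
#' @param haplotypes Character vector of two haplotype sequences (see
#'   [line_haplotypes()]).
#' @param n_reads Total read count.
#' @inheritParams simulate_reads
#' @return data.frame as [simulate_reads()] with a `haplotype` column.
#' @export
simulate_reads_diploid <- function(haplotypes, n_reads, read_length = 76L,
                                   error_rate = 0, seed = 1L, ...) {
  stopifnot(length(haplotypes) == 2)
  set.seed(seed)
  n1 <- stats::rbinom(1, n_reads, 0.5)
  r1 <- simulate_reads(haplotypes[1], n1, read_length, error_rate,
                       seed = seed + 1L, ...)
  r2 <- simulate_reads(haplotypes[2], n_reads - n1, read_length, error_rate,
                       seed = seed + 2L, ...)
  r1$haplotype <- if (nrow(r1)) 1L else integer(0)
  r2$haplotype <- if (nrow(r2)) 2L else integer(0)
  out <- rbind(r1, r2)
  out$id <- sprintf("read%06d", seq_len(nrow(out)))
  out
}
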