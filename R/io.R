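#' @importClassesFrom vcfR vcfR
NULL

#' Write/read FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write/read FASTQ
#'
#' @param reads data.frame with id, seq, qual (Phred+33).
#' @param path Output file.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' @rdname write_fastq
#' @return `read_fastq` returns a data.frame (id, seq, qual).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write per-line calls as VCF 4.2
#'
#' DP (supporting reads) goes to the genotype DP field and INFO; QUAL carries
#' the call quality; GT is 0/1 for heterozygous and 1/1 for homozygous-
#' alternate calls. Output is bgzip-free gzip as written by vcfR.
#'
#' @param calls Calls data.frame (line, chrom, pos, ref, alt, zygosity,
#'   depth, quality).
#' @param path Output path (conventionally .vcf.gz).
#' @param sample Sample name; defaults to the line name in the calls.
#' @export
write_vcf <- function(calls, path, sample = NULL) {
  if (is.null(sample))
    sample <- if (nrow(calls)) calls$line[1] else "sample"
  meta <- c("##fileformat=VCFv4.2",
            "##contig=<ID=chr1>",
            "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Supporting read depth\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Supporting read depth\">")
  n <- nrow(calls)
  fix <- cbind(CHROM = as.character(calls$chrom),
               POS = as.character(calls$pos),
               ID = rep(".", n),
               REF = as.character(calls$ref),
               ALT = as.character(calls$alt),
               QUAL = as.character(calls$quality),
               FILTER = rep("PASS", n),
               INFO = paste0("DP=", calls$depth))
  gt <- matrix(c(rep("GT:DP", n),
                 paste0(ifelse(calls$zygosity == "hom_alt", "1/1", "0/1"),
                        ":", calls$depth)),
               nrow = n, ncol = 2, dimnames = list(NULL, c("FORMAT", sample)))
  if (n == 0) {
    # vcfR cannot serialize a body-less object; emit the header directly
    con <- gzfile(path, "w")
    writeLines(c(meta, paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\t",
                              "INFO\tFORMAT\t", sample)), con)
    close(con)
    return(invisible(path))
  }
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read a VCF written by [write_vcf()]
#'
#' @param path VCF path (.vcf or .vcf.gz).
#' @return Calls data.frame (line, chrom, pos, ref, alt, vtype, zygosity,
#'   depth, quality).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gtm <- v@gt
  sample <- colnames(gtm)[2]
  if (nrow(fix) == 0)
    return(data.frame(line = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      vtype = character(0), zygosity = character(0),
                      depth = integer(0), quality = numeric(0)))
  gt_field <- sub(":.*$", "", gtm[, 2])
  dp_field <- as.integer(sub("^[^:]*:", "", gtm[, 2]))
  vtype <- ifelse(nchar(fix$REF) == 1 & nchar(fix$ALT) == 1, "SNP",
                  ifelse(nchar(fix$REF) > nchar(fix$ALT), "deletion",
                         "insertion"))
  data.frame(line = sample, chrom = fix$CHROM, pos = as.integer(fix$POS),
             ref = fix$REF, alt = fix$ALT, vtype = vtype,
             zygosity = ifelse(gt_field == "1/1", "hom_alt", "het"),
             depth = dp_field, quality = as.numeric(fix$QUAL),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write/read a callable mask as BED
#'
#' Intervals are stored 0-based half-open on disk (BED contract) and 1-based
#' closed in memory (IRanges contract); unsorted input is sorted to the
#' canonical form.
#'
#' @param mask `IRanges` of callable intervals.
#' @param path Output path.
#' @param chrom Chromosome name.
#' @export
write_bed <- function(mask, path, chrom = "chr1") {
  mask <- IRanges::reduce(BiocGenerics::sort(mask))
  gr <- GenomicRanges::GRanges(chrom, mask)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @return `read_bed` returns an `IRanges`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  BiocGenerics::sort(IRanges::ranges(gr))
}

#' Write/read gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features (1-based closed, GFF contract).
#'
#' @param models Gene-model list (see [generate_reference()]).
#' @param path Output path.
#' @export
write_gff3 <- function(models, path) {
  feats <- list()
  for (m in models) {
    mk <- function(type, iv, id, parent = NA, phase = NA_integer_) {
      GenomicRanges::GRanges(m$chrom,
        IRanges::IRanges(iv[, 1], iv[, 2]), strand = m$strand,
        type = type, ID = id, Parent = ifelse(is.na(parent), NA, parent),
        phase = phase)
    }
    tx_id <- paste0(m$gene_id, ".1")
    # CDS phase in transcript order: bases to skip before the next codon
    w <- m$cds[, 2] - m$cds[, 1] + 1L
    if (m$strand == "-") w <- rev(w)
    ph <- (3L - cumsum(c(0L, w[-length(w)])) %% 3L) %% 3L
    if (m$strand == "-") ph <- rev(ph)
    feats[[length(feats) + 1]] <- mk("gene", matrix(m$tx, ncol = 2), m$gene_id)
    feats[[length(feats) + 1]] <- mk("mRNA", matrix(m$tx, ncol = 2), tx_id,
                                     m$gene_id)
    feats[[length(feats) + 1]] <- mk("exon", m$exons,
                                     paste0(tx_id, ".exon",
                                            seq_len(nrow(m$exons))), tx_id)
    feats[[length(feats) + 1]] <- mk("CDS", m$cds,
                                     paste0(tx_id, ".cds",
                                            seq_len(nrow(m$cds))), tx_id, ph)
  }
  gr <- suppressWarnings(do.call(c, feats))
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' @rdname write_gff3
#' @return `read_gff3` returns a gene-model list.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  genes <- gr[gr$type == "gene"]
  lapply(seq_along(genes), function(i) {
    gid <- genes$ID[i]
    tx_id <- paste0(gid, ".1")
    sel <- function(type) {
      f <- gr[gr$type == type &
              vapply(gr$Parent, function(p) tx_id %in% p, logical(1))]
      f <- BiocGenerics::sort(f)
      cbind(GenomicRanges::start(f), GenomicRanges::end(f))
    }
    list(gene_id = gid,
         chrom = as.character(GenomicRanges::seqnames(genes))[i],
         strand = as.character(GenomicRanges::strand(genes))[i],
         tx = c(GenomicRanges::start(genes)[i], GenomicRanges::end(genes)[i]),
         exons = sel("exon"), cds = sel("CDS"))
  })
}

#' TSV write/read wrappers
#'
#' @param x data.frame.
#' @param path File path.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_file
#' @export
read_tsv_file <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
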