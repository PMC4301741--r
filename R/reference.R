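#' Default simulation parameters
#'
#' Study conditions the synthetic generator emulates: four sequenced lines
#' (two T2 siblings of one T0 regenerant plus two independent T3 plants),
#' roughly 500 tissue-culture mutations per T0 plant, 76-base reads, per-line
#' depth peaks of 8/4/6/10, a mutation spectrum matching the pooled observed
#' homozygous-SNP spectrum, and a two-channel tiling-array signal model with
#' a small additive background.
#'
#' @param seed Integer seed; every generator in the package is deterministic
#'   given the seed carried here.
#' @param ... Named overrides for any default element.
#' @return A list of class `gt_sim_params`.
#' @export
sim_params <- function(seed = 1L, ...) {
  p <- list(
    seed = as.integer(seed),
    l_host = 100000L,
    n_genes = 20L,
    gc = 0.44,
    n_t0_mutations = 500L,
    n_background_polymorphisms = 300L,
    spectrum_weights = default_spectrum(),
    indel_fraction = 0.34,
    depth_mean = c(`BSR-12-1` = 8, `BSR-12-2` = 4, `BSR-9-9-8` = 6,
                   `BSR-59-8-5` = 10),
    quality_per_read = 3,
    quality_cap = 60,
    read_length = 76L,
    base_error_rate = 0.001,
    false_positive_rate = 0,
    cgh_noise = 0.1,
    background_fraction = 0.02,
    cgh_gain = 1000
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  w <- p$spectrum_weights
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("spectrum weights must be non-negative and sum to 1")
  if (any(p$depth_mean <= 0)) stop("depth_mean must be positive")
  if (p$cgh_noise < 0) stop("cgh noise sigma must be non-negative")
  class(p) <- "gt_sim_params"
  p
}

#' Default SNP-class spectrum
#'
#' Pooled homozygous-SNP base-change spectrum across the four sequenced lines
#' (counts 56, 134, 19, 42, 29, 84 over the six strand-symmetric classes).
#'
#' @return Named numeric weights summing to 1.
#' @export
default_spectrum <- function() {
  counts <- c(`AT>GC` = 56, `GC>AT` = 134, `AT>CG` = 19,
              `AT>TA` = 42, `GC>CG` = 29, `GC>TA` = 84)
  counts / sum(counts)
}

#' The four line plans of the study design
#'
#' Two T2 siblings of one T0 plant carry the randomly integrated GT vector
#' (one fixed homozygous, one heterozygous); the two independent T3 plants
#' are clean.
#'
#' @param insertion_site 1-based host position where the vector is inserted
#'   for the carrier sibling group.
#' @return A data.frame of line plans (name, generation, vector_insertion,
#'   insertion_site, sibling_group).
#' @export
default_line_plans <- function(insertion_site = 50000L) {
  data.frame(
    name = c("BSR-12-1", "BSR-12-2", "BSR-9-9-8", "BSR-59-8-5"),
    generation = c(2L, 2L, 3L, 3L),
    vector_insertion = c("homo", "het", "none", "none"),
    insertion_site = c(insertion_site, insertion_site, NA_integer_, NA_integer_),
    sibling_group = c("BSR-12", "BSR-12", "BSR-9", "BSR-59"),
    stringsAsFactors = FALSE
  )
}

validate_line_plans <- function(plans) {
  stopifnot(is.data.frame(plans),
            all(c("name", "generation", "vector_insertion", "insertion_site",
                  "sibling_group") %in% names(plans)))
  if (any(plans$generation < 0)) stop("negative generation in line plans")
  ok <- xor(plans$vector_insertion == "none", !is.na(plans$insertion_site))
  if (!all(ok)) stop("insertion_site must be set iff vector_insertion != none")
  invisible(plans)
}

# Build one gene on its local axis: returns local 1-based coordinates and the
# local (plus-axis) sequence. Introns carry canonical GT..AG dinucleotides on
# the transcript strand; the CDS is ATG + sense codons + TAA.
build_gene_structure <- function(n_cds_exons, utr5_len, utr3_len,
                                 cds_codons_per_exon, intron_lens, gc) {
  sense <- setdiff(c(t(outer(BASES, c(t(outer(BASES, BASES, paste0))),
                             paste0))), c("TAA", "TAG", "TGA"))
  pick_codons <- function(n) paste(sample(sense, n, replace = TRUE), collapse = "")
  cds_pieces <- vapply(cds_codons_per_exon, pick_codons, character(1))
  # first codon ATG, last codon TAA
  cds_pieces[1] <- paste0("ATG", substr(cds_pieces[1], 4, nchar(cds_pieces[1])))
  last <- length(cds_pieces)
  nlast <- nchar(cds_pieces[last])
  cds_pieces[last] <- paste0(substr(cds_pieces[last], 1, nlast - 3), "TAA")
  introns <- vapply(intron_lens, function(l)
    paste0("GT", random_dna(l - 4, gc), "AG"), character(1))

  seq_parts <- character(0)
  exon_loc <- list(); cds_loc <- list()
  pos <- 1L
  utr5 <- random_dna(utr5_len, gc)
  for (i in seq_along(cds_pieces)) {
    ex_start <- pos
    if (i == 1L) { seq_parts <- c(seq_parts, utr5); pos <- pos + utr5_len }
    cds_start <- pos
    seq_parts <- c(seq_parts, cds_pieces[i])
    pos <- pos + nchar(cds_pieces[i])
    cds_loc[[i]] <- c(cds_start, pos - 1L)
    if (i == length(cds_pieces)) {
      utr3 <- random_dna(utr3_len, gc)
      seq_parts <- c(seq_parts, utr3); pos <- pos + utr3_len
    }
    exon_loc[[i]] <- c(ex_start, pos - 1L)
    if (i < length(cds_pieces)) {
      seq_parts <- c(seq_parts, introns[i])
      pos <- pos + nchar(introns[i])
    }
  }
  list(seq = paste(seq_parts, collapse = ""),
       exons = do.call(rbind, exon_loc),
       cds = do.call(rbind, cds_loc),
       length = pos - 1L)
}

# Map local (plus-axis) intervals of a gene of length L at genomic offset off
# to genomic coordinates, flipping for minus-strand genes.
map_intervals <- function(m, off, L, strand) {
  if (strand == "+") {
    cbind(m[, 1] + off, m[, 2] + off)
  } else {
    flipped <- cbind(off + L - m[, 2] + 1L, off + L - m[, 1] + 1L)
    flipped[order(flipped[, 1]), , drop = FALSE]
  }
}

#' Generate the reference bundle
#'
#' Builds a diploid host chromosome with non-overlapping gene models, a GT
#' vector partitioned into T-DNA and backbone, and a panel of foreign
#' (Agrobacterium stand-in) sequences. The vector is regenerated until it
#' shares no 31-mer with the host on either strand, so k-mer screening of
#' host-only reads is clean by construction (and it therefore contains
#' 20-mers absent from the host).
#'
#' @param params A [sim_params()] list.
#' @param l_host Host length in bp (defaults to `params$l_host`).
#' @param n_genes Number of gene models (defaults to `params$n_genes`).
#' @param vector_length,t_dna_length Vector and T-DNA lengths in bp.
#' @return A list of class `ReferenceBundle` with elements `chrom`, `host`,
#'   `gene_models`, `vector`, `t_dna`, `backbone`, `foreign_panel`, `ploidy`.
#' @export
generate_reference <- function(params = sim_params(), l_host = params$l_host,
                               n_genes = params$n_genes,
                               vector_length = 3000L, t_dna_length = 1200L) {
  set.seed(params$seed)
  gc <- params$gc
  host <- random_dna(l_host, gc)

  # gene structures first, so packing feasibility is known
  genes <- vector("list", n_genes)
  if (n_genes > 0) {
    for (i in seq_len(n_genes)) {
      n_ex <- sample(1:3, 1)
      genes[[i]] <- build_gene_structure(
        n_cds_exons = n_ex,
        utr5_len = sample(60:150, 1),
        utr3_len = sample(60:150, 1),
        cds_codons_per_exon = sample(20:60, n_ex, replace = TRUE),
        intron_lens = if (n_ex > 1) sample(60:200, n_ex - 1, replace = TRUE) else integer(0),
        gc = gc
      )
    }
    lens <- vapply(genes, `[[`, integer(1), "length")
    min_gap <- 100L
    need <- sum(lens) + (n_genes + 1L) * min_gap
    if (need > l_host)
      stop("cannot pack ", n_genes, " gene models into ", l_host,
           " bp (need >= ", need, " bp)")
    slack <- l_host - need
    extra <- if (slack > 0) as.vector(stats::rmultinom(1, slack, rep(1, n_genes + 1L))) else
      rep(0L, n_genes + 1L)
    gaps <- min_gap + extra
    off <- 0L
    models <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      off <- off + gaps[i]
      g <- genes[[i]]
      strand <- sample(c("+", "-"), 1)
      gseq <- if (strand == "+") g$seq else revcomp(g$seq)
      host <- str_assign(host, off + 1L, gseq)
      models[[i]] <- list(
        gene_id = sprintf("gene%02d", i),
        chrom = "chr1",
        strand = strand,
        tx = c(off + 1L, off + g$length),
        exons = map_intervals(g$exons, off, g$length, strand),
        cds = map_intervals(g$cds, off, g$length, strand)
      )
      off <- off + g$length
    }
  } else models <- list()

  host_k31 <- unique(c(kmers(host, 31L), kmers(revcomp(host), 31L)))
  gen_clean <- function(n) {
    for (try in 1:20) {
      s <- random_dna(n, 0.5)
      if (!any(kmers(s, 31L) %in% host_k31)) return(s)
    }
    stop("could not generate a sequence sharing no 31-mer with the host")
  }
  vec <- gen_clean(vector_length)
  foreign <- list(
    c58_circular = gen_clean(3000L),
    c58_linear   = gen_clean(3000L),
    plasmid_at   = gen_clean(2000L),
    plasmid_ti   = gen_clean(2000L)
  )

  structure(list(
    chrom = "chr1",
    host = host,
    gene_models = models,
    vector = vec,
    t_dna = c(1L, t_dna_length),
    backbone = c(t_dna_length + 1L, vector_length),
    foreign_panel = foreign,
    ploidy = 2L,
    gc = gc,
    seed = params$seed
  ), class = "ReferenceBundle")
}

#' Haplotype sequences of a line
#'
#' Returns the two host haplotypes of a line, with the GT vector inserted at
#' the planned site on both (homozygous), one (heterozygous) or neither
#' haplotype. Somaclonal point mutations are ignored here: at desk scale they
#' are irrelevant to read screening, which is what these sequences feed.
#'
#' @param ref A `ReferenceBundle`.
#' @param plan One row of a line-plan data.frame.
#' @return Character vector of two haplotype sequences.
#' @export
line_haplotypes <- function(ref, plan) {
  ins <- function() {
    at <- plan$insertion_site
    paste0(substr(ref$host, 1, at), ref$vector,
           substr(ref$host, at + 1, nchar(ref$host)))
  }
  switch(plan$vector_insertion,
    none = c(ref$host, ref$host),
    het  = c(ins(), ref$host),
    homo = { s <- ins(); c(s, s) },
    stop("unknown vector_insertion: ", plan$vector_insertion)
  )
}
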