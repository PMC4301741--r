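#' Extract a PCR amplicon by exact primer matching
#'
#' The forward primer must match the template exactly once on the plus
#' strand, the reverse primer exactly once as its reverse complement
#' downstream of the forward primer. The amplicon is the inclusive span from
#' the forward primer's first base to the reverse primer's outer end.
#'
#' @param template Character scalar template sequence.
#' @param fwd_primer,rev_primer Primer sequences (reverse primer given 5'->3'
#'   on the opposite strand, as ordered).
#' @return list of class `Amplicon`: sequence, start, end, fwd_primer,
#'   rev_primer.
#' @export
extract_amplicon <- function(template, fwd_primer, rev_primer) {
  t_dna <- Biostrings::DNAString(template)
  fhits <- Biostrings::matchPattern(Biostrings::DNAString(fwd_primer), t_dna)
  if (length(fhits) != 1)
    stop("forward primer matches ", length(fhits), " times (need exactly 1)")
  rpat <- Biostrings::reverseComplement(Biostrings::DNAString(rev_primer))
  rhits <- Biostrings::matchPattern(rpat, t_dna)
  if (length(rhits) != 1)
    stop("reverse primer matches ", length(rhits), " times (need exactly 1)")
  s <- Biostrings::start(fhits)[1]
  e <- Biostrings::end(rhits)[1]
  if (e < s) stop("reverse primer site lies upstream of the forward primer")
  structure(list(sequence = substr(template, s, e), start = s, end = e,
                 fwd_primer = fwd_primer, rev_primer = rev_primer),
            class = "Amplicon")
}

#' Restriction digest of a sequence
#'
#' Cuts after the configured offset inside every occurrence of the
#' recognition site (MfeI, C^AATTG, by default; the site is palindromic so
#' both strands cut at the same point).
#'
#' @param seq Character scalar (or an `Amplicon`).
#' @param site Recognition sequence.
#' @param cut_offset Bases after the site start at which the duplex is cut.
#' @return list of class `DigestResult`: site, cut_positions (1-based, cut is
#'   after this base), fragments (lengths, descending), n_sites.
#' @export
digest <- function(seq, site = "CAATTG", cut_offset = 1L) {
  if (inherits(seq, "Amplicon")) seq <- seq$sequence
  hits <- Biostrings::matchPattern(Biostrings::DNAString(site),
                                   Biostrings::DNAString(seq))
  cuts <- Biostrings::start(hits) + cut_offset - 1L
  bounds <- c(0L, sort(cuts), nchar(seq))
  fragments <- diff(bounds)
  structure(list(site = site, cut_positions = sort(cuts),
                 fragments = sort(fragments, decreasing = TRUE),
                 n_sites = length(cuts)),
            class = "DigestResult")
}

#' CAPS genotype from the two allelic digest patterns
#'
#' A diploid sample yields the union of the fragment patterns of its two
#' alleles: only cut fragments = homozygous GT, only the uncut amplicon =
#' wild type, both = heterozygous.
#'
#' @param allele1,allele2 `DigestResult`s of the two allelic amplicons.
#' @return "GT_homo", "WT", or "GT_het".
#' @export
caps_genotype <- function(allele1, allele2) {
  cut <- c(allele1$n_sites > 0, allele2$n_sites > 0)
  if (all(cut)) "GT_homo" else if (!any(cut)) "WT" else "GT_het"
}

#' Synthetic ALS CAPS locus fixture
#'
#' Builds a synthetic stand-in for the ALS CAPS assay: a template whose
#' F1/R1 amplicon is 2,287 bp, free of MfeI sites in the wild-type allele,
#' where the gene-targeting allele differs by the two codon edits
#' W548L (TGG -> TTG) and S627I (AGT -> ATT), each creating one new CAATTG
#' site, positioned so the digest yields fragments of 1,751, 299 and 237 bp
#' (cuts at 1,751 and 2,050 from the F1 end). The real locus sequence is not
#' public here; coordinates are a fixture convention.
#'
#' @param seed Integer seed.
#' @param flank Extra template sequence outside each primer.
#' @param primer_length Primer length.
#' @return list: template_wt, template_gt, fwd_primer, rev_primer,
#'   edits (data.frame of the two codon changes, template coordinates).
#' @export
caps_fixture <- function(seed = 101L, flank = 150L, primer_length = 22L) {
  set.seed(seed)
  amp_len <- 2287L
  # C^AATTG cuts after the leading C, so a cut at x needs the site to start
  # at x; fragment boundaries from the F1 end are 1,751 and 2,050
  site_start <- c(1751L, 2050L)
  repeat {
    amp <- random_dna(amp_len, 0.44)
    # WT hexamers whose single-base reversions of the codon edits are:
    # CAATGG (TGG codon at +3..+5) and CAAGTG (AGT codon at +2..+4)
    amp <- str_assign(amp, site_start[1], "CAATGG")
    amp <- str_assign(amp, site_start[2], "CAAGTG")
    if (!grepl("CAATTG", amp, fixed = TRUE) &&
        !grepl("CAATTG", revcomp(amp), fixed = TRUE)) break
  }
  gt <- amp
  substr(gt, site_start[1] + 4L, site_start[1] + 4L) <- "T"  # TGG -> TTG
  substr(gt, site_start[2] + 3L, site_start[2] + 3L) <- "T"  # AGT -> ATT
  fwd <- substr(amp, 1, primer_length)
  rev_site <- substr(amp, amp_len - primer_length + 1L, amp_len)
  count_sites <- function(tpl)
    length(Biostrings::matchPattern("CAATTG", Biostrings::DNAString(tpl)))
  one_hit <- function(tpl, pat)
    length(Biostrings::matchPattern(Biostrings::DNAString(pat),
                                    Biostrings::DNAString(tpl))) == 1
  repeat {
    left <- random_dna(flank, 0.44)
    right <- random_dna(flank, 0.44)
    template_wt <- paste0(left, amp, right)
    template_gt <- paste0(left, gt, right)
    if (one_hit(template_wt, fwd) && one_hit(template_gt, fwd) &&
        one_hit(template_wt, rev_site) && one_hit(template_gt, rev_site) &&
        count_sites(template_wt) == 0 && count_sites(template_gt) == 2) break
  }
  rc <- revcomp(rev_site)
  edits <- data.frame(
    name = c("W548L", "S627I"),
    codon_wt = c("TGG", "AGT"), codon_gt = c("TTG", "ATT"),
    template_pos = flank + c(site_start[1] + 4L, site_start[2] + 3L),
    stringsAsFactors = FALSE)
  list(template_wt = template_wt, template_gt = template_gt,
       fwd_primer = fwd, rev_primer = rc, edits = edits)
}
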