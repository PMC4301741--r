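#!/usr/bin/env Rscript
# Stage 2: in-silico CAPS genotyping of the ALS locus. The synthetic fixture
# mirrors the published assay: a 2,287 bp F1/R1 amplicon in which the two
# herbicide-tolerance edits (W548L: TGG->TTG, S627I: AGT->ATT) each create a
# novel MfeI site (CAATTG), so the GT allele digests to 1,751 + 299 + 237 bp
# while the WT amplicon stays uncut.

suppressPackageStartupMessages(library(gtaudit))

dir.create("results", showWarnings = FALSE)
fx <- caps_fixture(seed = 101L)

amp_wt <- extract_amplicon(fx$template_wt, fx$fwd_primer, fx$rev_primer)
amp_gt <- extract_amplicon(fx$template_gt, fx$fwd_primer, fx$rev_primer)
d_wt <- digest(amp_wt)
d_gt <- digest(amp_gt)

cat("Amplicon length:", nchar(amp_gt$sequence), "bp\n")
cat("WT digest:", paste(d_wt$fragments, collapse = " + "), "bp\n")
cat("GT digest:", paste(d_gt$fragments, collapse = " + "), "bp\n\n")

genotypes <- data.frame(
  template_pair = c("GT/GT", "WT/WT", "WT/GT"),
  genotype = c(caps_genotype(d_gt, d_gt),
               caps_genotype(d_wt, d_wt),
               caps_genotype(d_wt, d_gt)))
print(genotypes)

lines <- data.frame(
  line = c("BSR-12-1", "BSR-12-2", "BSR-9-9-8", "BSR-59-8-5"),
  genotype = caps_genotype(d_gt, d_gt),
  fragments = paste(d_gt$fragments, collapse = ","))
write_tsv_file(lines, "results/caps_genotypes.tsv")
cat("\nPer-line genotypes written to results/caps_genotypes.tsv\n")
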