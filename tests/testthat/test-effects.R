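test_that("CDS rules: codon change, stop gain, start loss, indel length", {
  ref <- toy_reference()
  g <- ref$host
  # walk every CDS SNP of the first gene and compare against the
  # whole-protein oracle on a few signature cases
  m <- ref$gene_models[[1]]
  # non-synonymous TGG -> TTG style check: find any CDS position where a
  # substitution changes the amino acid
  cds_pos <- unlist(apply(m$cds, 1, function(iv) iv[1]:iv[2]))
  found_nonsyn <- FALSE
  for (p in cds_pos) {
    refb <- substr(g, p, p)
    for (alt in setdiff(c("A", "C", "G", "T"), refb)) {
      v <- list(chrom = "chr1", pos = p, ref = refb, alt = alt)
      cat <- annotate_variant(v, list(m), g)$category
      if (cat == "NON_SYNONYMOUS_CODING") { found_nonsyn <- TRUE; break }
    }
    if (found_nonsyn) break
  }
  expect_true(found_nonsyn)

  # 1-bp CDS deletion: frameshift; 3-bp deletion: in-frame codon deletion
  interior <- m$cds[1, 1] + 6L
  del1 <- list(chrom = "chr1", pos = interior,
               ref = substr(g, interior, interior + 1), alt = substr(g, interior, interior))
  expect_equal(annotate_variant(del1, list(m), g)$category, "FRAME_SHIFT")
  del3 <- list(chrom = "chr1", pos = interior,
               ref = substr(g, interior, interior + 3), alt = substr(g, interior, interior))
  expect_equal(annotate_variant(del3, list(m), g)$category,
               "CODON_CHANGE_PLUS_CODON_DELETION")
  # in-frame insertion: warned and tallied as EXON
  ins3 <- list(chrom = "chr1", pos = interior,
               ref = substr(g, interior, interior),
               alt = paste0(substr(g, interior, interior), "AAA"))
  expect_warning(cat_ins <- annotate_variant(ins3, list(m), g)$category,
                 "in-frame insertion")
  expect_equal(cat_ins, "EXON")

  # start-codon SNP destroys the initiator
  start_pos <- if (m$strand == "+") m$cds[1, 1] else m$cds[nrow(m$cds), 2]
  refb <- substr(g, start_pos, start_pos)
  v <- list(chrom = "chr1", pos = start_pos, ref = refb,
            alt = setdiff(c("A", "C", "G", "T"), refb)[1])
  expect_equal(annotate_variant(v, list(m), g)$category, "START_LOST")
})

test_that("the TGG->TTG codon edit is non-synonymous (Trp->Leu)", {
  # single-gene synthetic locus: + strand gene, CDS = ATG TGG ... TAA
  cds <- paste0("ATG", "TGG", "GCTGCA", "TAA")
  genome <- paste0(strrep("C", 50), cds, strrep("C", 50))
  model <- list(gene_id = "g1", chrom = "chr1", strand = "+",
                tx = c(41L, 50L + nchar(cds) + 10L),
                exons = matrix(c(41L, 50L + nchar(cds) + 10L), ncol = 2),
                cds = matrix(c(51L, 50L + nchar(cds)), ncol = 2))
  # middle G of TGG (genomic position 55) -> T
  v <- list(chrom = "chr1", pos = 55L, ref = "G", alt = "T")
  expect_equal(substr(genome, 54, 56), "TGG")
  expect_equal(annotate_variant(v, list(model), genome)$category,
               "NON_SYNONYMOUS_CODING")
  # and a synonymous third-position change: GCT -> GCA (both Ala)
  v2 <- list(chrom = "chr1", pos = 59L, ref = "T", alt = "A")
  expect_equal(annotate_variant(v2, list(model), genome)$category,
               "SYNONYMOUS_CODING")
})

test_that("per-position classification matches the brute-force oracle", {
  ref <- generate_reference(sim_params(seed = 77, l_host = 4000L, n_genes = 2L))
  g <- ref$host
  window <- 300L
  alts <- c(A = "C", C = "G", G = "T", T = "A")
  for (p in seq_len(nchar(g))) {
    refb <- substr(g, p, p)
    alt <- alts[[refb]]
    v <- list(chrom = "chr1", pos = p, ref = refb, alt = alt)
    got <- sort(annotate_variant(v, ref$gene_models, g, window, window)$category)
    want <- oracle_annotate(p, alt, ref$gene_models, g, window)
    if (!identical(got, want)) {
      fail(sprintf("position %d (%s>%s): got {%s}, oracle {%s}", p, refb, alt,
                   paste(got, collapse = ","), paste(want, collapse = ",")))
      break
    }
  }
  succeed()
})

test_that("every variant yields at least one record from the closed category set", {
  ref <- toy_reference()
  tr <- induce_t0_mutations(ref, 150, seed = 9, indel_fraction = 0.3)
  # in-frame CDS insertions warn by design (tallied as EXON)
  recs <- suppressWarnings(annotate_variants(tr, ref$gene_models, ref$host))
  expect_true(all(table(recs$variant) >= 1))
  expect_length(unique(recs$variant), 150)
  expect_true(all(recs$category %in% c(
    "FRAME_SHIFT", "NON_SYNONYMOUS_CODING", "CODON_CHANGE_PLUS_CODON_DELETION",
    "START_GAINED", "START_LOST", "STOP_GAINED", "SPLICE_SITE_ACCEPTOR",
    "SPLICE_SITE_DONOR", "SYNONYMOUS_CODING", "EXON", "INTRON", "UTR_3_PRIME",
    "UTR_5_PRIME", "UPSTREAM", "DOWNSTREAM", "INTERGENIC")))
})

test_that("tallies count per record with two-decimal percentages", {
  eff <- data.frame(category = c(rep("NON_SYNONYMOUS_CODING", 14),
                                 rep("INTRON", 99),
                                 rep("INTERGENIC", 1665 - 14 - 99)))
  t <- tally_effects(eff)
  expect_equal(sum(t$count), 1665)
  expect_equal(t$percent[t$category == "NON_SYNONYMOUS_CODING"], 0.84)
  expect_equal(t$percent[t$category == "INTRON"], 5.95)
  # zero-filled categories and empty input
  expect_equal(t$count[t$category == "FRAME_SHIFT"], 0)
  t0 <- tally_effects(data.frame(category = character(0)))
  expect_true(all(t0$count == 0) && all(t0$percent == 0))
  # percentage closure
  expect_lt(abs(sum(t$percent) - 100), 0.01 * 16)
})

test_that("impactful count sums the eight protein-affecting categories", {
  expect_equal(impactful_count(c(0, 14, 0, 2, 2, 0, 1, 0)), 19)
  expect_equal(impactful_count(c(6, 37, 0, 3, 0, 12, 1, 1)), 60)
  expect_equal(impactful_count(rep(0, 8)), 0)
  eff <- data.frame(category = c("FRAME_SHIFT", "STOP_GAINED", "INTRON",
                                 "UPSTREAM", "SPLICE_SITE_DONOR"))
  expect_equal(impactful_count(tally_effects(eff)), 3)
})

test_that("category tallies are invariant under reverse complementation", {
  ref <- generate_reference(sim_params(seed = 88, l_host = 3000L, n_genes = 1L))
  g <- ref$host
  L <- nchar(g)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # mirror the genome, the model, and the variants
  g_rc <- revcomp(g)
  flip_iv <- function(m) {
    out <- cbind(L - m[, 2] + 1L, L - m[, 1] + 1L)
    out[order(out[, 1]), , drop = FALSE]
  }
  m <- ref$gene_models[[1]]
  m_rc <- list(gene_id = m$gene_id, chrom = m$chrom,
               strand = if (m$strand == "+") "-" else "+",
               tx = c(L - m$tx[2] + 1L, L - m$tx[1] + 1L),
               exons = flip_iv(m$exons), cds = flip_iv(m$cds))
  set.seed(5)
  pos <- sample.int(L, 300)
  cats <- character(0); cats_rc <- character(0)
  for (p in pos) {
    refb <- substr(g, p, p)
    alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
    v <- list(chrom = "chr1", pos = p, ref = refb, alt = alt)
    v_rc <- list(chrom = "chr1", pos = L - p + 1L, ref = comp[[refb]],
                 alt = comp[[alt]])
    cats <- c(cats, annotate_variant(v, list(m), g, 500, 500)$category)
    cats_rc <- c(cats_rc, annotate_variant(v_rc, list(m_rc), g_rc, 500, 500)$category)
  }
  expect_equal(cats, cats_rc)
})
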