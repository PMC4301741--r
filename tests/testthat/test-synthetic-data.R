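test_that("reference generation is deterministic and structurally valid", {
  p <- sim_params(seed = 42, l_host = 20000L, n_genes = 4L)
  ref <- toy_reference()
  ref2 <- generate_reference(p)
  expect_identical(ref, ref2)

  expect_equal(nchar(ref$host), 20000L)
  expect_length(ref$gene_models, 4L)
  expect_true(grepl("^[ACGT]+$", ref$host))
  expect_true(grepl("^[ACGT]+$", ref$vector))
  # t_dna and backbone partition the vector
  expect_equal(ref$t_dna[1], 1L)
  expect_equal(ref$backbone[1], ref$t_dna[2] + 1L)
  expect_equal(ref$backbone[2], nchar(ref$vector))
  # gene models: exons sorted/non-overlapping, CDS inside exons, CDS %% 3 == 0
  for (m in ref$gene_models) {
    ex <- m$exons
    expect_true(all(ex[, 1] <= ex[, 2]))
    if (nrow(ex) > 1) expect_true(all(ex[-1, 1] > ex[-nrow(ex), 2]))
    cds_len <- sum(m$cds[, 2] - m$cds[, 1] + 1)
    expect_equal(cds_len %% 3, 0)
    for (j in seq_len(nrow(m$cds)))
      expect_true(any(m$cds[j, 1] >= ex[, 1] & m$cds[j, 2] <= ex[, 2]))
    expect_true(m$tx[1] >= 1 && m$tx[2] <= nchar(ref$host))
  }
  # vector screenability: no 31-mer shared with host means unique 20-mers exist
  host_k <- unique(c(kmers(ref$host, 31), kmers(revcomp(ref$host), 31)))
  expect_false(any(kmers(ref$vector, 31) %in% host_k))
})

test_that("generated GC content sits inside the 99% binomial interval", {
  p <- sim_params(seed = 9, l_host = 100000L, n_genes = 0L)
  ref <- generate_reference(p)
  gc <- sum(chars(ref$host) %in% c("G", "C"))
  ci <- qbinom(c(0.005, 0.995), 100000L, 0.44)
  expect_gte(gc, ci[1])
  expect_lte(gc, ci[2])
})

test_that("gene packing failure is explicit", {
  expect_error(generate_reference(sim_params(seed = 1, l_host = 2000L,
                                             n_genes = 10L)),
               "cannot pack")
})

test_that("induced mutations honor count, zygosity, spectrum and position rules", {
  ref <- toy_reference()
  tr <- induce_t0_mutations(ref, 500, seed = 5, group = "G1")
  expect_equal(nrow(tr), 500)
  expect_true(all(tr$origin == "induced_T0"))
  expect_false(any(duplicated(tr$pos)))
  # ref alleles match the host sequence
  host <- ref$host
  expect_true(all(substring(host, tr$pos, tr$pos) == substr(tr$ref, 1, 1)))

  # degenerate spectrum: everything GC>AT at a G/C base
  w <- setNames(c(0, 1, 0, 0, 0, 0), names(default_spectrum()))
  tr2 <- induce_t0_mutations(ref, 100, spectrum = w, seed = 6)
  expect_true(all(tr2$ref %in% c("G", "C")))
  expect_true(all(paste0(tr2$ref, tr2$alt) %in% c("GA", "CT")))

  expect_error(induce_t0_mutations(ref, 10, spectrum = w * 2, seed = 1),
               "sum to 1")
})

test_that("large draws reproduce the configured spectrum (chi-square)", {
  ref <- generate_reference(sim_params(seed = 3, l_host = 60000L, n_genes = 0L))
  w <- setNames(c(0.154, 0.316, 0.043, 0.085, 0.060, 0.342),
                names(default_spectrum()))
  tr <- induce_t0_mutations(ref, 10000, spectrum = w, seed = 8)
  cls <- vapply(seq_len(nrow(tr)), function(i)
    classify_substitution(tr$ref[i], tr$alt[i])$class, character(1))
  obs <- table(factor(cls, levels = names(w)))
  p <- suppressWarnings(chisq.test(obs, p = w)$p.value)
  expect_gt(p, 0.01)
})

test_that("segregation matches Mendelian expectations across generations", {
  ref <- toy_reference()
  n <- 10000L
  truth <- data.frame(chrom = "chr1", pos = seq_len(n), ref = "A", alt = "G",
                      vtype = "SNP", class = "AT>GC", origin = "induced_T0",
                      group = "G", stringsAsFactors = FALSE)
  mk_plan <- function(g) data.frame(name = "L", generation = g,
                                    vector_insertion = "none",
                                    insertion_site = NA_integer_,
                                    sibling_group = "G",
                                    stringsAsFactors = FALSE)
  # g = 0: all heterozygous
  tr0 <- segregate(truth, mk_plan(0L), seed = 1)
  expect_true(all(tr0$zyg_L == "het"))
  # g = 3: hom fraction near 0.4375, conservation and hom/lost symmetry
  tr3 <- segregate(truth, mk_plan(3L), seed = 2)
  f <- table(tr3$zyg_L) / n
  se <- sqrt(0.4375 * (1 - 0.4375) / n)
  expect_lt(abs(f[["hom_alt"]] - 0.4375), 3 * se)
  expect_lt(abs(f[["hom_ref"]] - 0.4375), 3 * se)
  expect_lt(abs(f[["het"]] - 0.125), 3 * sqrt(0.125 * 0.875 / n))
  expect_equal(sum(f), 1)
  # g = 20: heterozygosity is essentially extinct (2^-20 per variant)
  tr20 <- segregate(truth, mk_plan(20L), seed = 3)
  expect_lt(mean(tr20$zyg_L == "het"), 1e-3)
  expect_error(segregate(truth, mk_plan(-1L), seed = 1), "negative")
})

test_that("simulated calls respect depth, quality and callable-mask structure", {
  ref <- toy_reference()
  plans <- default_line_plans(insertion_site = 10000L)
  truth <- induce_t0_mutations(ref, 300, seed = 4, group = "BSR-9")
  truth <- segregate(truth, plans, seed = 5)
  params <- sim_params(seed = 10, l_host = 20000L, n_genes = 4L,
                       depth_mean = c(`BSR-12-1` = 6, `BSR-12-2` = 6,
                                      `BSR-9-9-8` = 6, `BSR-59-8-5` = 6))
  ld <- simulate_variant_calls(truth, plans, params)
  calls <- ld[["BSR-9-9-8"]]$calls
  expect_true(all(calls$depth >= 1))
  expect_equal(calls$quality, pmin(60, round(3 * calls$depth)))

  # callable fraction at depth >= 1 approximates 1 - exp(-6)
  m <- callable_mask(ld[["BSR-9-9-8"]]$depth)
  frac <- sum(IRanges::width(m)) / 20000
  expect_lt(abs(frac - (1 - exp(-6))), 3 * sqrt(exp(-6) * (1 - exp(-6)) / 20000))

  # noise-free high-depth limit: emitted calls equal truth zygosities
  params_hi <- sim_params(seed = 11, l_host = 20000L, n_genes = 4L,
                          depth_mean = c(`BSR-12-1` = 60, `BSR-12-2` = 60,
                                         `BSR-9-9-8` = 60, `BSR-59-8-5` = 60))
  ld_hi <- simulate_variant_calls(truth, plans, params_hi)
  calls_hi <- ld_hi[["BSR-9-9-8"]]$calls
  tz <- truth$`zyg_BSR-9-9-8`
  expected <- truth[tz != "hom_ref", ]
  expect_equal(calls_hi$pos, expected$pos)
  expect_equal(calls_hi$zygosity, tz[tz != "hom_ref"])
  # homozygous call at the full site depth passes DP2 iff depth >= 2
  hom2 <- calls_hi[calls_hi$zygosity == "hom_alt", ][1, ]
  expect_true(hom2$depth >= 4) # depth 60 scale
})

test_that("read simulation has the stated coverage and error behavior", {
  g <- random_dna(5000, 0.5)
  rd <- simulate_reads(g, 1000, 76, error_rate = 0, seed = 2)
  expect_equal(sum(nchar(rd$seq)), 76000)
  # every error-free read is an exact substring
  expect_true(all(substring(g, rd$start, rd$start + 75) == rd$seq))

  # scaled coverage check: n * len / L
  g2 <- random_dna(390000, 0.5)
  rd2 <- simulate_reads(g2, 55634, 76, error_rate = 0, seed = 3)
  tab <- tabulate(unlist(lapply(seq_len(nrow(rd2)), function(i)
    rd2$start[i]:(rd2$start[i] + 75L))), nbins = 390000)
  expect_lt(abs(mean(tab) - 10.84), 3 * sqrt(stats::var(tab) / 390000))
  expect_error(simulate_reads(g, -1, 76), "non-negative")
  expect_error(simulate_reads(g, 10, 10000), "exceeds")
})

test_that("CGH signal model obeys its closed forms", {
  probes <- design_probes(random_dna(3000, 0.44), random_dna(1400, 0.5))
  vecp <- probes$source %in% c("vector_forward", "vector_reverse")
  p0 <- sim_params(seed = 5, cgh_noise = 0)
  raw <- simulate_cgh(probes, ifelse(vecp, 2, 2), ifelse(vecp, 0, 2), p0)
  arr <- normalize_and_ratio(raw)
  # noise-free host probes at (2,2): ratio exactly 1
  expect_equal(arr$log2_ratio[arr$source == "host_region"],
               rep(0, sum(arr$source == "host_region")))
  # noise-free vector probe 2 vs 0 with background 0.02: ratio 101
  expect_equal(2^arr$log2_ratio[vecp], rep(101, sum(vecp)), tolerance = 1e-12)

  # homo (2) vs het (1) lines: mean ratio ratio within [1.9, 2.1]
  pn <- sim_params(seed = 6, cgh_noise = 0.1)
  r_hom <- normalize_and_ratio(simulate_cgh(probes, ifelse(vecp, 2, 2),
                                            ifelse(vecp, 0, 2), pn))
  pn2 <- sim_params(seed = 7, cgh_noise = 0.1)
  r_het <- normalize_and_ratio(simulate_cgh(probes, ifelse(vecp, 1, 2),
                                            ifelse(vecp, 0, 2), pn2))
  expect_gte(sum(vecp), 500)
  rr <- mean(2^r_hom$log2_ratio[vecp]) / mean(2^r_het$log2_ratio[vecp])
  expect_gte(rr, 1.9); expect_lte(rr, 2.1)
  expect_error(simulate_cgh(probes, 2, 2, sim_params(seed = 1, cgh_noise = -1)))
})
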