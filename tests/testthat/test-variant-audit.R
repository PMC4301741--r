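make_calls <- function(n, seed = 1) {
  set.seed(seed)
  depth <- rpois(n, 6)
  depth[depth == 0] <- 1
  data.frame(line = "L", chrom = "chr1", pos = sample.int(1e5, n),
             ref = "A", alt = "G", vtype = "SNP",
             zygosity = sample(c("het", "hom_alt"), n, replace = TRUE),
             depth = depth, quality = 3 * depth, stringsAsFactors = FALSE)
}

test_that("depth/quality filtering matches brute force and is monotone", {
  calls <- make_calls(1000)
  p2 <- filter_profile("DP2Q10")
  p4 <- filter_profile("DP4Q20")
  expect_equal(nrow(filter_calls(calls, p2)), oracle_filter(calls, 2, 10))
  expect_equal(nrow(filter_calls(calls, p4)), oracle_filter(calls, 4, 20))
  # threshold arithmetic on a single call
  one <- data.frame(depth = 3, quality = 15)
  expect_equal(nrow(filter_calls(one, p2)), 1)
  expect_equal(nrow(filter_calls(one, p4)), 0)
  # empty in, empty out
  expect_equal(nrow(filter_calls(calls[0, ], p2)), 0)
  # monotonicity: DP4Q20 survivors are a subset of DP2Q10 survivors
  k2 <- paste(filter_calls(calls, p2)$pos)
  k4 <- paste(filter_calls(calls, p4)$pos)
  expect_true(all(k4 %in% k2))
})

test_that("shared-variant partition separates polymorphisms from induced candidates", {
  v <- function(pos) data.frame(line = "x", chrom = "chr1", pos = pos,
                                ref = "A", alt = "G", vtype = "SNP",
                                zygosity = "hom_alt", depth = 10, quality = 30,
                                stringsAsFactors = FALSE)
  groups <- c(`12-1` = "G12", `12-2` = "G12", `9` = "G9", `59` = "G59")
  callsets <- list(
    `12-1` = v(c(100, 200, 300)),      # 100 in all, 200 sibling pair, 300 own
    `12-2` = v(c(100, 200)),
    `9`    = v(c(100, 400)),           # 400 in two non-sibling lines
    `59`   = v(c(100, 400)))
  part <- partition_shared(callsets, groups)
  expect_setequal(part$background$key, c("chr1:100:A:G", "chr1:400:A:G"))
  expect_equal(part$line_specific$`12-1`$pos, c(200, 300))
  expect_equal(part$line_specific$`12-2`$pos, 200)
  expect_equal(nrow(part$line_specific$`9`), 0)
  # partition property: every input appears exactly once across outputs
  for (l in names(callsets)) {
    keys <- paste("chr1", callsets[[l]]$pos, "A", "G", sep = ":")
    in_bg <- keys %in% part$background$key
    in_spec <- keys %in% paste("chr1", part$line_specific[[l]]$pos, "A", "G",
                               sep = ":")
    expect_true(all(xor(in_bg, in_spec)))
  }
  # a line absent from the group map is its own singleton group
  part2 <- partition_shared(callsets, groups[1:2])
  expect_setequal(part2$background$key, c("chr1:100:A:G", "chr1:400:A:G"))
})

test_that("shared-callable intersection equals brute-force per-base AND", {
  set.seed(20)
  gsize <- 10000L
  masks <- lapply(1:4, function(i) {
    s <- sort(sample.int(gsize - 100L, 30))
    IRanges::reduce(IRanges::IRanges(s, s + sample.int(100, 30)))
  })
  sh <- shared_callable(masks, gsize)
  expect_equal(sh$fraction, oracle_shared_fraction(masks, gsize))
  # four identical masks covering 70.8%
  m708 <- IRanges::IRanges(1, 7080)
  expect_equal(shared_callable(list(m708, m708, m708, m708), gsize)$fraction,
               0.708)
  # disjoint masks
  expect_equal(shared_callable(list(IRanges::IRanges(1, 10),
                                    IRanges::IRanges(100, 110)), gsize)$fraction,
               0)
  expect_error(shared_callable(list(IRanges::IRanges(1, 20000)), gsize),
               "beyond")
})

test_that("substitution classes partition the 12 ordered base pairs", {
  pairs <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- vapply(seq_len(nrow(pairs)), function(i)
    classify_substitution(pairs$ref[i], pairs$alt[i])$class, character(1))
  expect_equal(sort(unique(cls)), sort(c("AT>GC", "GC>AT", "AT>CG", "AT>TA",
                                         "GC>CG", "GC>TA")))
  expect_true(all(table(cls) == 2))
  # spot checks and transition flags
  expect_equal(classify_substitution("G", "A"),
               list(class = "GC>AT", transition = TRUE))
  expect_equal(classify_substitution("A", "T"),
               list(class = "AT>TA", transition = FALSE))
  ti <- vapply(seq_len(nrow(pairs)), function(i)
    classify_substitution(pairs$ref[i], pairs$alt[i])$transition, logical(1))
  expect_equal(sum(ti), 4) # A>G, G>A, C>T, T>C
  expect_error(classify_substitution("N", "A"))
  expect_error(classify_substitution("A", "A"))
})

test_that("spectrum tables reproduce counts, percentages and Ti/Tv", {
  s1 <- spectrum_from_counts(c(6, 24, 2, 9, 6, 12))
  expect_equal(s1$total, 59)
  expect_equal(s1$table$percent[s1$table$class == "GC>AT"], 40.7)
  expect_equal(s1$ti, 30); expect_equal(s1$tv, 29)
  expect_equal(s1$titv, 1.03)
  s2 <- spectrum_from_counts(c(22, 37, 4, 11, 8, 18))
  expect_equal(s2$total, 100)
  expect_equal(s2$titv, 1.44)
  # single G>A variant: 100% GC>AT
  s3 <- spectrum_table(data.frame(ref = "G", alt = "A", vtype = "SNP"))
  expect_equal(s3$table$percent[s3$table$class == "GC>AT"], 100)
  expect_true(is.na(s3$titv)) # no transversions: undefined, not infinite
  # percentages sum to 100 up to rounding
  expect_lt(abs(sum(s1$table$percent) - 100), 0.1 * 6)
  expect_error(spectrum_table(data.frame(ref = "A", alt = "AT",
                                         vtype = "insertion")))
})

test_that("Ti/Tv averaging pre-rounds per-line ratios to two decimals", {
  expect_equal(titv_average(c(1.03, 1.10, 1.44, 0.89)), 1.115)
  # unrounded ratios average to 1.114: pre-rounding is what yields 1.115
  raw <- c(30 / 29, 46 / 42, 59 / 41, 55 / 62)
  expect_equal(round_half_up(mean(raw), 3), 1.114)
  expect_equal(titv_average(raw), 1.115)
  expect_equal(titv_average(1.5), 1.5)
  expect_true(is.na(titv_average(c(1.2, NA))))
})

test_that("noise-free audit recovers induced truth inside the shared mask", {
  ref <- toy_reference()
  plans <- default_line_plans(insertion_site = 10000L)
  truth <- empty_truth()
  for (g in unique(plans$sibling_group))
    truth <- rbind(truth, induce_t0_mutations(ref, 100, group = g,
                                              seed = 30 + match(g, unique(plans$sibling_group)),
                                              avoid = truth$pos))
  truth <- rbind(truth, background_polymorphisms(ref, 80, seed = 33,
                                                 avoid = truth$pos))
  truth <- segregate(truth, plans, seed = 34)
  params <- sim_params(seed = 35, l_host = 20000L, n_genes = 4L,
                       depth_mean = c(`BSR-12-1` = 40, `BSR-12-2` = 40,
                                      `BSR-9-9-8` = 40, `BSR-59-8-5` = 40))
  ld <- simulate_variant_calls(truth, plans, params)
  audit <- audit_callsets(lapply(ld, `[[`, "calls"), ld, plans,
                          filter_profile("DP2Q10"), 20000L)
  # at depth 40 everything is callable and every het/hom call survives:
  # line-specific filtered calls == induced truth with non-hom_ref zygosity
  for (l in plans$name) {
    zyg <- truth[[paste0("zyg_", l)]]
    own <- truth$origin == "induced_T0" & zyg != "hom_ref"
    got <- audit$line_specific[[l]]
    expect_setequal(paste(got$pos, got$zygosity),
                    paste(truth$pos[own], zyg[own]))
  }
})
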