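test_that("probe design counts follow the tiling arithmetic", {
  host <- random_dna(6000, 0.44)
  vec <- random_dna(1000, 0.5)
  probes <- design_probes(host, vec)
  expect_equal(sum(probes$source == "host_region"), 100)
  expect_equal(sum(probes$source == "vector_forward"), 189)
  expect_equal(sum(probes$source == "vector_reverse"), 189)
  expect_equal(sum(probes$source == "control"), 13)
  expect_true(all(probes$length == 60))
  real <- probes$source != "control"
  expect_true(all(nchar(probes$sequence[real]) == 60))
  expect_true(all(is.na(probes$start[!real])))
  # probe sequences come from the stated source coordinates
  i <- which(probes$source == "host_region")[5]
  expect_equal(probes$sequence[i],
               substr(host, probes$start[i], probes$start[i] + 59))
  j <- which(probes$source == "vector_reverse")[7]
  expect_equal(probes$sequence[j],
               substr(revcomp(vec), probes$start[j], probes$start[j] + 59))
  expect_error(design_probes(host, vec, host_step = 0), "positive")
  expect_error(design_probes("ACGT", vec), "longer")
})

test_that("normalization is scale invariant and anchored to control medians", {
  probes <- design_probes(random_dna(1200, 0.44), random_dna(400, 0.5))
  vecp <- probes$source %in% c("vector_forward", "vector_reverse")
  raw <- simulate_cgh(probes, ifelse(vecp, 1, 2), ifelse(vecp, 0, 2),
                      sim_params(seed = 21, cgh_noise = 0.1))
  arr1 <- normalize_and_ratio(raw)
  scaled <- raw
  scaled$cy5 <- scaled$cy5 * 2
  scaled$cy3 <- scaled$cy3 * 2
  arr2 <- normalize_and_ratio(scaled)
  expect_equal(arr1$log2_ratio, arr2$log2_ratio)
  # noise-free vector probe at test 3 vs ref 2 copies: log2((3+b)/(2+b))
  raw0 <- simulate_cgh(probes, ifelse(vecp, 3, 2), ifelse(vecp, 2, 2),
                       sim_params(seed = 22, cgh_noise = 0))
  arr0 <- normalize_and_ratio(raw0)
  expect_equal(arr0$log2_ratio[vecp],
               rep(log2(3.02 / 2.02), sum(vecp)), tolerance = 1e-12)
  bad <- raw; bad$cy5[bad$source == "control"] <- 0
  expect_error(normalize_and_ratio(bad), "control median")
})

test_that("moving average equals the brute-force centered mean", {
  set.seed(23)
  for (w in c(1L, 5L, 10L, 20L)) {
    x <- rnorm(137)
    expect_equal(moving_average(x, w), oracle_moving_average(x, w))
  }
  # identity and constant-track invariance
  x <- rnorm(50)
  expect_identical(moving_average(x, 1L), x)
  expect_equal(moving_average(rep(2.5, 40), 20L), rep(2.5, 40))
  # mean conservation on interior-supported tracks (zero at the edges)
  y <- c(rep(0, 10), rnorm(80), rep(0, 10))
  expect_equal(mean(moving_average(y, 5L)), mean(y), tolerance = 1e-12)
})

test_that("aberration calling finds the inserted block and nothing else", {
  set.seed(24)
  # flat zero track: no calls
  expect_equal(nrow(call_aberrations(rnorm(200, 0, 0.02))), 0)
  # synthetic vector block at +5.6 over 378 probes next to a host block at 0
  track <- c(rnorm(100, 0, 0.05), rnorm(378, 5.6, 0.05))
  sm <- moving_average(track, 20)
  ab <- call_aberrations(sm)
  expect_equal(nrow(ab), 1)
  expect_gt(ab$mean_log2, 5)
  expect_gte(ab$start_index, 85)  # transition blurred by the 20-probe window
  expect_lte(ab$start_index, 111)
  expect_equal(ab$end_index, 478)
  # a 4-probe deviation is below min_probes
  short <- c(rep(0, 50), rep(3, 4), rep(0, 50))
  expect_equal(nrow(call_aberrations(short)), 0)
  expect_error(call_aberrations(rnorm(3)), "min_probes")
})

test_that("copy-state labels follow the log2 thresholds", {
  expect_equal(copy_state_host(0.6), "one_copy_gain")
  expect_equal(copy_state_host(0), "neutral")
  expect_equal(copy_state_host(1.2), "two_copy_gain")
  expect_equal(copy_state_host(-1), "one_copy_loss")
  expect_equal(copy_state_host(-2.5), "two_copy_loss")
  expect_error(copy_state_host(NaN))
  expect_equal(copy_state_vector(6.6, 5.6), "homozygous")
  expect_equal(copy_state_vector(5.7, 5.6), "heterozygous")
  expect_equal(copy_state_vector(2, 5.6), "indeterminate")
})
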