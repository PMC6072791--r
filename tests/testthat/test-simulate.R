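test_that("identical configuration and seed reproduce the cohort exactly", {
  cfg <- simulation_config(n_patients = 2, n_positions = 300, seed = 21)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(names(a$pileups), names(b$pileups))
  for (s in names(a$pileups))
    expect_identical(as.data.frame(a$pileups[[s]]),
                     as.data.frame(b$pileups[[s]]))
  expect_identical(as.data.frame(a$sheet), as.data.frame(b$sheet))
})

test_that("spiked allele fractions are recovered at binomial accuracy", {
  # 200 replicate spikes at af = 0.05, depth 2000: mean alt count must land
  # within 3 standard errors of depth * af = 100 (binomial oracle)
  cfg <- simulation_config(n_positions = 200, seed = 5, strand_imbalance = 0)
  em <- simulate_error_model(cfg)
  key <- plasmatrack:::site_key(em$chrom, em$pos, em$alt)
  spikes <- stats::setNames(rep(0.05, 200), key[seq(1, by = 3, length.out = 200)])
  set.seed(99)
  p <- plasmatrack:::sim_sample(em, 2000, 1e6, true_af = spikes)
  long <- pileup_long(p)
  li <- match(names(spikes), plasmatrack:::site_key(long$chrom, long$pos,
                                                    long$alt))
  counts <- long$alt_reads[li] * 2000 / long$depth[li]  # normalize depth noise
  se <- sqrt(2000 * 0.05 * 0.95) / sqrt(200)
  expect_lt(abs(mean(counts) - 100), 3 * se)
})

test_that("a zero spike behaves as background error", {
  cfg <- simulation_config(n_positions = 300, seed = 6)
  em <- simulate_error_model(cfg)
  set.seed(7)
  p <- plasmatrack:::sim_sample(em, 2000, 50)
  long <- pileup_long(p)
  # pooled alt fraction across error-only sites approximates the mean error
  pooled <- sum(long$alt_reads) / sum(long$depth)
  expect_lt(abs(pooled - mean(em$rate)), 4 * sqrt(mean(em$rate) /
                                                    sum(long$depth) * 3))
})

test_that("truth variants outside the panel are refused", {
  cfg <- simulation_config(n_positions = 50, seed = 2)
  em <- simulate_error_model(cfg)
  expect_error(
    plasmatrack:::sim_sample(em, 1000, 50,
                             true_af = c("chrX:999999:T" = 0.1)),
    "outside the simulated panel")
})

test_that("reference standard spikes the requested number of sites at level", {
  rs <- simulate_reference_standard(levels = c(0.05), n_variants = 6,
                                    depth = 2000, seed = 31,
                                    n_positions = 600)
  expect_equal(nrow(rs$truth), 6L)
  long <- pileup_long(rs$pileups[["REF_0.05"]])
  li <- match(plasmatrack:::site_key(rs$truth$chrom, rs$truth$pos,
                                     rs$truth$alt),
              plasmatrack:::site_key(long$chrom, long$pos, long$alt))
  # mean alt count about depth * level (binomial oracle, 6 sites)
  expect_lt(abs(mean(long$alt_reads[li]) - 100),
            3 * sqrt(2000 * 0.05 * 0.95 / 6) + 3 * 100 / sqrt(100 * 6))
  # spiked sites are spaced beyond the proximity window
  expect_gt(min(diff(sort(rs$truth$pos))), 10)
  # determinism
  rs2 <- simulate_reference_standard(levels = c(0.05), n_variants = 6,
                                     depth = 2000, seed = 31,
                                     n_positions = 600)
  expect_identical(as.data.frame(rs$pileups[[1]]),
                   as.data.frame(rs2$pileups[[1]]))
})

test_that("a zero-level reference pileup carries only background error", {
  rs <- simulate_reference_standard(levels = 0, n_variants = 6, depth = 2000,
                                    seed = 33, n_positions = 600)
  long <- pileup_long(rs$pileups[["REF_0"]])
  li <- match(plasmatrack:::site_key(rs$truth$chrom, rs$truth$pos,
                                     rs$truth$alt),
              plasmatrack:::site_key(long$chrom, long$pos, long$alt))
  expect_lt(max(long$af[li]), 0.01)
})

test_that("replicate pairs share error structure but carry no truth", {
  cfg <- simulation_config(n_positions = 500, seed = 41)
  pairs <- simulate_replicate_pairs(21, cfg, seed = 41)
  expect_length(pairs, 21L)
  expect_equal(nrow(attr(pairs, "truth")), 0L)
  # paired difference in alt fraction has mean ~ 0 (no systematic excess)
  diffs <- unlist(lapply(pairs, function(pr) {
    a <- pileup_long(pr$a)
    b <- pileup_long(pr$b)
    a$af - b$af
  }))
  expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(length(diffs)))
  pairs2 <- simulate_replicate_pairs(21, cfg, seed = 41)
  expect_identical(as.data.frame(pairs[[3]]$a), as.data.frame(pairs2[[3]]$a))
})

test_that("true and observed allele fractions agree across the cohort", {
  # regression of observed on true spiked AF recovers slope 1
  cfg <- simulation_config(n_patients = 10, n_positions = 800,
                           variants_per_patient = 8,
                           mean_depth = c(FNA = 987, PBL = 1929,
                                          PLASMA = 2000),
                           seed = 17)
  co <- simulate_cohort(cfg)
  ta <- co$truth_af[grepl("_T000$", co$truth_af$sample_id), ]
  obs <- vapply(seq_len(nrow(ta)), function(i) {
    long <- pileup_long(co$pileups[[ta$sample_id[i]]])
    li <- match(plasmatrack:::site_key(ta$chrom[i], ta$pos[i], ta$alt[i]),
                plasmatrack:::site_key(long$chrom, long$pos, long$alt))
    long$af[li]
  }, numeric(1))
  fit <- stats::lm(obs ~ ta$true_af)
  expect_lt(abs(unname(stats::coef(fit)[2]) - 1), 0.08)
})
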