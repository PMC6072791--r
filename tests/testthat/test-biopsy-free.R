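cfg0 <- run_config()

test_that("prefilter enforces depth over 500, strand bias and support", {
  p <- fix_pileup(c(10L, 20L, 30L, 40L),
                  alt = c("T", "T", "T", "T"),
                  alt_reads = c(12L, 12L, 12L, 0L),
                  depth = c(500L, 2000L, 2000L, 2000L),
                  fwd_frac = c(0.5, 0.95, 0.55, 0.5))
  kept <- prefilter_sites(p, cfg0)
  # pos 10: depth exactly 500 -> excluded (strict "over 500")
  expect_false(10L %in% kept$pos)
  # pos 20: SB 0.95 -> excluded
  expect_false(20L %in% kept$pos)
  # pos 30: depth 2000, SB 0.55, 12 alt reads -> included
  expect_true(30L %in% kept$pos)
  # pos 40: no supporting reads -> not a candidate
  expect_false(40L %in% kept$pos)
})

test_that("binomial tail p-values match direct pmf summation", {
  # exact-oracle agreement to 1e-12 up to n = 5000
  cases <- expand.grid(alt = c(0L, 1L, 5L, 20L, 100L),
                       depth = c(50L, 500L, 2000L, 5000L),
                       g_alt = c(0L, 1L, 5L), g_depth = c(500L, 2000L))
  cases <- cases[cases$alt <= cases$depth, ]
  p_imp <- binomial_germline_test(cases$alt, cases$depth, cases$g_alt,
                                  cases$g_depth)
  p_oracle <- mapply(function(a, d, ga, gd) {
    p0 <- (ga + 0.5) / (gd + 1)
    sum(stats::dbinom(a:d, d, p0))
  }, cases$alt, cases$depth, cases$g_alt, cases$g_depth)
  expect_equal(p_imp, p_oracle, tolerance = 1e-12)
  expect_true(all(abs(p_imp - p_oracle) <= 1e-12))
  # degenerate ends
  expect_equal(binomial_germline_test(0L, 2000L, 3L, 2000L), 1)
  expect_lt(binomial_germline_test(2000L, 2000L, 0L, 2000L), 1e-300)
})

test_that("z-test matches the standard normal and survives underflow", {
  z0 <- ztest_background(1e-4, 1e-4, 5e-5)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 0.5)
  z2 <- ztest_background(2e-4, 1e-4, 5e-5)
  expect_equal(z2$z, 2)
  expect_equal(z2$p, stats::pnorm(2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(z2$p, 0.02275013, tolerance = 1e-6)
  # somatic-scale excess: z ~ 700, p far below double underflow
  zbig <- ztest_background(0.0354, 1e-4, 5e-5)
  expect_gt(zbig$z, 700)
  expect_equal(zbig$p, 0)
  expect_true(is.finite(zbig$log10_p))
  # normal tail bound oracle: log phi(z) - log z bounds log p above
  lt <- stats::dnorm(zbig$z, log = TRUE) / log(10) - log10(zbig$z)
  expect_lt(abs(zbig$log10_p - lt), 1)
  # the sd floor keeps zero-variance sites testable
  expect_true(is.finite(ztest_background(0.01, 0, 0, sd_floor = 1e-4)$z))
})

biopsy_free_fixture <- function(alt_reads, depth = 2000L, n_bg = 12,
                                positions = c(50L, 500L, 1000L)) {
  # candidate T alleles at given positions over an error-free background
  pos <- sort(unique(c(positions, c(50L, 500L, 1000L))))
  plasma <- fix_pileup(pos, alt = ifelse(pos %in% positions, "T", NA),
                       alt_reads = ifelse(pos %in% positions, alt_reads, 0L),
                       depth = depth, sample_id = "PL")
  germ <- fix_pileup(pos, depth = depth, sample_id = "GL")
  bg <- build_background(fix_panel(n_bg, pos, depth = depth))
  list(plasma = plasma, germ = germ, bg = bg)
}

test_that("a clean 1% variant at 2000x is called; 0.1% is not", {
  fx <- biopsy_free_fixture(alt_reads = 20L, positions = 500L)
  res <- call_biopsy_free(fx$plasma, fx$germ, fx$bg, cfg = cfg0)
  expect_equal(nrow(res$calls), 1L)
  expect_equal(res$calls$pos, 500L)
  expect_equal(res$calls$source, "M_P_TR_BF")
  expect_equal(res$calls$filters, "PASS")

  # at 0.1% (2 reads in 2000) the candidate dies before reaching the
  # supporting-read gate: against a clean germline 2 reads are not even
  # binomially significant
  fx2 <- biopsy_free_fixture(alt_reads = 2L, positions = 500L)
  res2 <- call_biopsy_free(fx2$plasma, fx2$germ, fx2$bg, cfg = cfg0)
  expect_equal(nrow(res2$calls), 0L)
  d <- res2$dropped[res2$dropped$pos == 500L & res2$dropped$alt == "T", ]
  expect_equal(d$reason, "binom_p")
})

test_that("statistically significant candidates below 8 reads are discarded", {
  # a deep background panel shrinks the z-test sd floor so that 7 reads in
  # 2000 pass both tests and fall to the supporting-read threshold alone
  pos <- c(50L, 500L)
  plasma <- fix_pileup(pos, alt = c(NA, "T"), alt_reads = c(0L, 7L),
                       depth = 2000L, sample_id = "PL")
  germ <- fix_pileup(pos, depth = 2000L, sample_id = "GL")
  bg <- build_background(fix_panel(12, pos, depth = 100000L))
  res <- call_biopsy_free(plasma, germ, bg, cfg = cfg0)
  expect_equal(nrow(res$calls), 0L)
  d <- res$dropped[res$dropped$pos == 500L & res$dropped$alt == "T", ]
  expect_equal(d$reason, "min_alt_reads")
  # one more read and the same site is called
  plasma8 <- fix_pileup(pos, alt = c(NA, "T"), alt_reads = c(0L, 8L),
                        depth = 2000L, sample_id = "PL")
  expect_equal(call_biopsy_free(plasma8, germ, bg, cfg = cfg0)$calls$pos,
               500L)
})

test_that("the proximity window drops only low-fraction clustered candidates", {
  pos <- c(100L, 105L, 400L)
  plasma <- fix_pileup(pos, alt = "T", alt_reads = c(100L, 600L, 100L),
                       depth = 2000L, sample_id = "PL")
  germ <- fix_pileup(pos, depth = 2000L, sample_id = "GL")
  bg <- build_background(fix_panel(12, pos, depth = 2000L))
  res <- call_biopsy_free(plasma, germ, bg, cfg = cfg0)
  # 5% at pos 100 clustered with 30% at pos 105 -> dropped; 30% kept;
  # isolated 5% at pos 400 kept
  expect_setequal(res$calls$pos, c(105L, 400L))
  expect_equal(res$dropped$reason[res$dropped$pos == 100L &
                                  res$dropped$alt == "T"], "window_af")
})

test_that("germline-positive, lane-SNP and annotation filters bind", {
  pos <- c(100L, 200L, 300L)
  plasma <- fix_pileup(pos, alt = "T", alt_reads = 40L, depth = 2000L,
                       sample_id = "PL")
  germ <- fix_pileup(pos, alt = c("T", NA, NA), alt_reads = c(30L, 0L, 0L),
                     depth = 2000L, sample_id = "GL")
  bg <- build_background(fix_panel(12, pos, depth = 2000L))
  ann <- data.frame(chrom = "chr1", pos = c(200L, 300L), ref = "A",
                    alt = "T", consequence = c("nonsynonymous", "synonymous"),
                    stringsAsFactors = FALSE)
  res <- call_biopsy_free(plasma, germ, bg, annotations = ann,
                          lane_snps = "chr1:300:T", cfg = cfg0)
  dr <- res$dropped
  # pos 100: germline AF 1.5% >= 0.5% -> germline
  expect_equal(dr$reason[dr$pos == 100L & dr$alt == "T"], "germline")
  # pos 300: lane SNP wins before consequence
  expect_equal(dr$reason[dr$pos == 300L & dr$alt == "T"], "lane_snp")
  expect_equal(res$calls$pos, 200L)

  # without the lane-SNP hit, pos 300 dies on its synonymous consequence
  res2 <- call_biopsy_free(plasma, germ, bg, annotations = ann, cfg = cfg0)
  expect_equal(res2$dropped$reason[res2$dropped$pos == 300L &
                                   res2$dropped$alt == "T"], "consequence")
  # and an unannotated surviving candidate is dropped explicitly
  res3 <- call_biopsy_free(plasma, germ, bg, annotations = ann[1, ],
                           cfg = cfg0)
  expect_equal(res3$dropped$reason[res3$dropped$pos == 300L &
                                   res3$dropped$alt == "T"], "no_annotation")
})

test_that("every candidate leaves the cascade exactly once", {
  sim <- simulation_config(n_positions = 500, seed = 71)
  em <- simulate_error_model(sim)
  panel <- simulate_plasma_panel(10, em, depth = 2000, seed = 72)
  bg <- build_background(panel, cfg = cfg0)
  pl <- plasmatrack:::with_substream(73, 1, plasmatrack:::sim_sample(
    em, 2000, 20, sample_id = "PL"))
  gl <- plasmatrack:::with_substream(73, 2, plasmatrack:::sim_sample(
    em, 2000, 20, sample_id = "GL"))
  res <- call_biopsy_free(pl, gl, bg, cfg = cfg0)
  long <- pileup_long(pl)
  n_cand <- sum(long$alt_reads >= 1)
  expect_equal(nrow(res$calls) + nrow(res$dropped), n_cand)
  expect_false(any(is.na(res$dropped$reason)))
  k <- c(plasmatrack:::site_key(res$calls$chrom, res$calls$pos,
                                res$calls$alt),
         plasmatrack:::site_key(res$dropped$chrom, res$dropped$pos,
                                res$dropped$alt))
  expect_equal(anyDuplicated(k), 0L)
})

test_that("relaxing a threshold never removes calls", {
  fx <- biopsy_free_fixture(alt_reads = c(9L, 20L, 60L),
                            positions = c(50L, 500L, 1000L))
  n_default <- nrow(call_biopsy_free(fx$plasma, fx$germ, fx$bg,
                                     cfg = cfg0)$calls)
  relaxed <- run_config(z_p_max = 1e-3, bf_min_alt_reads = 2L)
  n_relaxed <- nrow(call_biopsy_free(fx$plasma, fx$germ, fx$bg,
                                     cfg = relaxed)$calls)
  expect_gte(n_relaxed, n_default)
})

test_that("replicate pairs yield no calls but a spiked pair yields one", {
  sim <- simulation_config(n_positions = 600, seed = 81)
  em <- simulate_error_model(sim)
  pairs <- simulate_replicate_pairs(3, sim, seed = 81, error_model = em)
  panel <- simulate_plasma_panel(12, em, depth = 1929, seed = 82)
  bg <- build_background(panel, cfg = cfg0)
  expect_equal(as.integer(false_positive_assay(pairs, bg, cfg0)), 0L)
  expect_equal(as.integer(false_positive_assay(list(), bg, cfg0)), 0L)

  # positive control: spike a 10% somatic site into member A only
  site <- em[40, ]
  key <- plasmatrack:::site_key(site$chrom, site$pos, site$alt)
  spiked <- plasmatrack:::with_substream(83, 1, plasmatrack:::sim_sample(
    em, 1929, sim$depth_dispersion,
    true_af = stats::setNames(0.1, key), sample_id = "SPIKE_A"))
  pair <- list(list(a = spiked, b = pairs[[1]]$b))
  expect_equal(as.integer(false_positive_assay(pair, bg, cfg0)), 1L)
})
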