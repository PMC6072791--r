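mk_calls <- function(pos, maf = 0.02, source = "M_P_TR_BF") {
  n <- length(pos)
  maf <- rep_len(maf, n)
  data.frame(chrom = rep_len("chr1", n), pos = pos, ref = rep_len("A", n),
             alt = rep_len("T", n),
             alt_reads = as.integer(round(maf * 2000)),
             depth = rep_len(2000L, n), maf = maf,
             source = rep_len(source, n), filters = rep_len("PASS", n),
             stringsAsFactors = FALSE)
}

test_that("merged target-region set is a keyed union", {
  shared <- mk_calls(seq(10L, by = 10L, length.out = 15L))
  tracked <- rbind(shared, mk_calls(seq(200L, by = 10L, length.out = 13L)))
  tracked$detected <- TRUE
  bf <- rbind(shared, mk_calls(seq(400L, by = 10L, length.out = 12L)))
  m <- merge_mptr(tracked, bf)
  expect_equal(nrow(m), 15L + 13L + 12L)
  expect_true(all(m$source == "M_P_TR"))
  expect_gte(nrow(m), max(nrow(tracked), nrow(bf)))
  expect_lte(nrow(m), nrow(tracked) + nrow(bf))

  # empty biopsy-free set: tracked relabelled
  m2 <- merge_mptr(tracked, NULL)
  expect_equal(nrow(m2), nrow(tracked))
  expect_true(all(m2$source == "M_P_TR"))
  # idempotence on identical lists
  m3 <- merge_mptr(transform(bf, detected = TRUE), bf)
  expect_equal(nrow(m3), nrow(bf))
  # undetected tracked variants never enter the union
  tracked$detected <- FALSE
  expect_equal(nrow(merge_mptr(tracked, NULL)), 0L)
})

test_that("detection rates reproduce the worked proportions", {
  expect_equal(detection_rate(15, 17)$pct, 88.2)
  expect_equal(detection_rate(10, 17)$pct, 58.8)
  expect_equal(detection_rate(13, 17)$pct, 76.5)
  expect_error(detection_rate(1, 0), "positive")
  expect_error(detection_rate(5, 4), "\\[0, total\\]")
})

test_that("Clopper-Pearson intervals match beta-quantile inversion", {
  # oracle: exact binomial inversion via beta quantiles
  cp_oracle <- function(x, n, conf = 0.95) {
    a <- (1 - conf) / 2
    low <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
    high <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
    c(low, high) * 100
  }
  for (case in list(c(22, 23), c(0, 10), c(10, 10), c(7, 40), c(1, 1000))) {
    got <- detection_rate(case[1], case[2])
    want <- cp_oracle(case[1], case[2])
    expect_equal(c(got$ci_low, got$ci_high), want, tolerance = 1e-9)
  }
  got <- detection_rate(22, 23)
  expect_equal(got$ci_low, 78.05, tolerance = 0.01)
  expect_equal(got$ci_high, 99.89, tolerance = 0.01)
  # intervals contain the point estimate
  set.seed(4)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    x <- sample(0:n, 1)
    d <- detection_rate(x, n)
    expect_gte(100 * x / n + 1e-12, d$ci_low)
    expect_lte(100 * x / n - 1e-12, d$ci_high)
  }
})

test_that("Clopper-Pearson empirical coverage is at least nominal", {
  set.seed(27)
  n <- 60L
  p <- 0.3
  x <- stats::rbinom(2000, n, p)
  lo <- ifelse(x == 0, 0, stats::qbeta(0.025, x, n - x + 1))
  hi <- ifelse(x == n, 1, stats::qbeta(0.975, x + 1, n - x))
  covered <- lo <= p & p <= hi
  expect_gte(mean(covered), 0.95)
})

test_that("ANOVA F and p match textbook sum-of-squares arithmetic", {
  groups <- list(a = c(4.1, 5.2, 6.3, 5.5), b = c(7.7, 8.1, 9.0, 8.4),
                 c = c(2.0, 2.5, 1.8, 2.2))
  got <- anova_lsd(groups)
  # oracle: hand sum-of-squares
  y <- unlist(groups)
  gm <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(y) - length(groups)
  f_oracle <- (ssb / dfb) / (ssw / dfw)
  expect_equal(got$F, f_oracle, tolerance = 1e-10)
  expect_equal(got$p, stats::pf(f_oracle, dfb, dfw, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(got$ms_within, ssw / dfw, tolerance = 1e-10)
  # F is invariant under adding a constant
  shifted <- anova_lsd(lapply(groups, `+`, 100))
  expect_equal(shifted$F, got$F, tolerance = 1e-8)
})

test_that("two equal-mean groups give F = 0 and two groups reduce to a t-test", {
  eq <- anova_lsd(list(a = c(1, 2, 3), b = c(3, 2, 1)))
  expect_equal(eq$F, 0)
  expect_equal(eq$p, 1)

  g <- list(a = c(1.2, 3.4, 2.2, 4.4), b = c(5.5, 4.2, 6.6, 7.1))
  got <- anova_lsd(g)
  tt <- stats::t.test(g$a, g$b, var.equal = TRUE)
  expect_equal(got$p, tt$p.value, tolerance = 1e-12)
  expect_equal(got$pairwise$p, tt$p.value, tolerance = 1e-12)
  expect_equal(got$pairwise$p, got$p, tolerance = 1e-12)
})

test_that("undersized groups are excluded, and all-undersized errors", {
  expect_warning(
    res <- anova_lsd(list(a = 1:4 / 2, b = c(2, 3, 4, 5), c = 7)),
    "fewer than 2")
  expect_equal(res$df_between, 1)
  expect_error(anova_lsd(list(a = 1, b = 2)), "at least two groups")
})

test_that("records shortly before progression move into the PD group", {
  rec <- data.frame(sample_id = c("s1", "s2", "s3"),
                    patient_id = c("P1", "P1", "P2"),
                    timepoint_days = c(240L, 120L, 100L),
                    disease_status = c("SD", "SD", "SD"),
                    n_variants = 1L, mean_maf = 0.01, max_maf = 0.01,
                    stringsAsFactors = FALSE)
  out <- reassign_pd_window(rec, c(P1 = 300), window_days = 90)
  expect_equal(out$disease_status, c("PD", "SD", "SD"))  # 60 vs 180 days; P2 untouched
  # exactly at the window edge stays
  out2 <- reassign_pd_window(rec, c(P1 = 330), window_days = 90)
  expect_equal(out2$disease_status, c("SD", "SD", "SD"))
})

test_that("concordance reduces paired calls to sensitivity and specificity", {
  perfect <- concordance(rep(c(TRUE, FALSE), each = 10),
                         rep(c(TRUE, FALSE), each = 10))
  expect_equal(perfect$sensitivity$pct, 100.0)
  expect_equal(perfect$specificity$pct, 100.0)

  seqc <- c(rep(TRUE, 22), FALSE, rep(FALSE, 39))
  refc <- c(rep(TRUE, 23), rep(FALSE, 39))
  got <- concordance(seqc, refc)
  expect_equal(got$tp, 22L)
  expect_equal(got$fn, 1L)
  expect_equal(got$fp, 0L)
  expect_equal(got$sensitivity$pct, 95.7)
  expect_equal(got$specificity$pct, 100.0)

  none <- concordance(c(TRUE, FALSE), c(FALSE, FALSE))
  expect_null(none$sensitivity)
  expect_error(concordance(TRUE, c(TRUE, FALSE)), "equal length")
})

test_that("limit of detection follows supporting reads over depth", {
  expect_equal(theoretical_lod(800), 0.01)
  expect_equal(theoretical_lod(5532), 8 / 5532)
  expect_lt(abs(100 * theoretical_lod(5532) - 0.145), 0.002)
  expect_equal(theoretical_lod(1000, 0), 0)
  expect_error(theoretical_lod(0), "positive")
  # strictly decreasing in depth
  d <- seq(100, 6000, by = 100)
  expect_true(all(diff(theoretical_lod(d)) < 0))
})

test_that("genome equivalents convert mass at 3.3 pg per haploid copy", {
  expect_equal(genome_equivalents(0.0033), 1.0)
  expect_equal(genome_equivalents(50), 50 / 0.0033)
  expect_equal(round(genome_equivalents(50)), 15152)
  expect_equal(round(genome_equivalents(7.8)), 2364)
  expect_error(genome_equivalents(0), "positive")
  # the input-mass cap never improves the LOD
  capped <- lod_with_input_cap(5000, 7.8)
  expect_gte(capped$lod, theoretical_lod(5000))
  uncapped <- lod_with_input_cap(1000, 50)
  expect_equal(uncapped$lod, theoretical_lod(1000))
})

test_that("burden records summarize per-sample call sets", {
  sheet <- sample_sheet(data.frame(
    sample_id = c("P1_PBL", "P1_T000", "P1_T060"),
    patient_id = "P1", material = c("PBL", "PLASMA", "PLASMA"),
    timepoint_days = c(NA, 0L, 60L), lane_batch = "L01",
    input_dna_ng = c(200, 30, 30), stringsAsFactors = FALSE))
  sheet$disease_status <- c(NA, "Dx", "CR_PR")
  calls <- list(P1_T000 = mk_calls(c(10L, 20L), maf = c(0.02, 0.04)),
                P1_T060 = mk_calls(integer(0)))
  rec <- burden_records(calls, sheet)
  expect_equal(rec$n_variants, c(2L, 0L))
  expect_equal(rec$mean_maf, c(0.03, NA))
  expect_equal(rec$max_maf, c(0.04, NA))
  expect_equal(rec$disease_status, c("Dx", "CR_PR"))
  expect_error(burden_records(list(NOPE = mk_calls(1L)), sheet), "missing")
})

test_that("group summaries separate suppressed from progressing disease", {
  set.seed(31)
  n <- 12
  rec <- data.frame(
    sample_id = sprintf("s%02d", 1:(3 * n)),
    patient_id = rep(sprintf("P%02d", 1:n), 3),
    timepoint_days = rep(c(0L, 60L, 120L), each = n),
    disease_status = rep(c("Dx", "CR_PR", "PD"), each = n),
    n_variants = c(rpois(n, 3), rpois(n, 0.2), rpois(n, 4)),
    stringsAsFactors = FALSE)
  rec$mean_maf <- c(rnorm(n, 0.02, 0.004), abs(rnorm(n, 0.001, 0.0005)),
                    rnorm(n, 0.03, 0.006))
  rec$max_maf <- rec$mean_maf
  out <- burden_summaries(rec)
  gs <- out$group_stats
  expect_equal(gs$mean_maf[gs$disease_status == "CR_PR"],
               min(gs$mean_maf))
  expect_lt(out$anova_mean_maf$p, 0.05)
  expect_lt(out$anova_n_variants$p, 0.05)
  lsd <- out$anova_mean_maf$pairwise
  expect_lt(lsd$p[lsd$g1 == "CR_PR" | lsd$g2 == "CR_PR"][1], 0.05)
  expect_error(burden_summaries(rec[rec$disease_status == "Dx", ]),
               "two non-empty")
})
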