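test_that("background sampling is length-matched and avoids bound regions", {
  set.seed(1)
  genome <- c(chr1 = rand_seq(3000), chr2 = rand_seq(2000))
  peaks <- data.frame(chrom = c("chr1", "chr2"),
                      start = c(101L, 501L), end = c(300L, 900L),
                      summit = c(100L, 200L), peak_fdr = c(0.01, 0.01))
  bg <- sample_background(peaks, genome, seed = 5)
  expect_equal(bg$end - bg$start, peaks$end - peaks$start)

  # repeated draws never overlap the peaks
  for (sd in 1:200) {
    b <- sample_background(peaks[1, ], genome, seed = sd)
    expect_false(b$chrom == "chr1" & b$start <= 300 & b$end >= 101)
  }

  # excluded = the whole genome -> explicit failure
  excl <- data.frame(chrom = c("chr1", "chr2"), start = c(1L, 1L),
                     end = c(3000L, 2000L))
  expect_error(sample_background(peaks, genome, excluded = excl, seed = 1),
               "insufficient unbound space")
})

test_that("background start positions are uniform over the allowed space", {
  genome <- c(chr1 = rand_seq(120, seed = 2))
  peak <- data.frame(chrom = "chr1", start = 200L, end = 204L,
                     summit = 2L, peak_fdr = 0.01)
  # peak outside the 120-bp toy chromosome is impossible; use a real one
  peak <- data.frame(chrom = "chr1", start = 1L, end = 5L,
                     summit = 2L, peak_fdr = 0.01)
  starts <- vapply(1:2000, function(sd)
    sample_background(peak, genome, seed = sd)$start, 0L)
  # allowed starts are 6..116 (width 5, no overlap with the peak at 1..5)
  expect_true(all(starts >= 6 & starts <= 116))
  tab <- table(factor(starts, levels = 6:116))
  gof <- chisq.test(tab)
  expect_gt(gof$p.value, 0.001)
})

test_that("best site per region maximises score with deterministic ties", {
  cons <- consensus_pwm("ACGTACGT", pseudocount = 0.1)
  s <- paste0(strrep("T", 15), "ACGTACGT", strrep("T", 12))
  b <- best_site_per_region(cons, s)
  expect_equal(b$start, 16L)
  expect_equal(b$strand, "+")
  # equals the max over the full scan
  expect_equal(b$score, max(scan_pwm(cons, s)$score))

  # two equal-scoring windows -> leftmost wins
  s2 <- paste0("ACGTACGT", strrep("T", 10), "ACGTACGT")
  b2 <- best_site_per_region(cons, s2, bg_window = 2 * nchar(s2))
  expect_equal(b2$start, 1L)

  expect_error(best_site_per_region(cons, "ACG"), "shorter")
})

test_that("AUC equals the pairwise probability with ties at one half", {
  expect_equal(compute_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(compute_auc(c(5, 6), c(1, 2)), 1)
  expect_equal(compute_auc(c(2, 1), c(2, 0)), 0.625)
  expect_error(compute_auc(numeric(0), 1), "non-empty")

  # complementarity and monotone invariance
  set.seed(9)
  for (i in 1:10) {
    fg <- sample(0:5, 7, replace = TRUE)
    bg <- sample(0:5, 9, replace = TRUE)
    expect_equal(compute_auc(fg, bg) + compute_auc(bg, fg), 1)
    expect_equal(compute_auc(exp(fg), exp(bg)), compute_auc(fg, bg))
  }
})

test_that("PWM selection ranks the planting motif above a shuffled decoy", {
  set.seed(21)
  pwm <- generate_pwm(10, concentration = 30, seed = 21, name = "TRUE_TF")
  decoy <- build_pwm(pwm$counts[sample(10), ], pseudocount = 0.5,
                     name = "DECOY")
  peaks <- vapply(1:30, function(i) {
    s <- rand_seq(120)
    site <- pwm_consensus(pwm)
    paste0(substr(s, 1, 50), site, substr(s, 61, 120))
  }, "")
  bg <- vapply(1:30, function(i) rand_seq(120), "")
  ev <- select_pwm(list(pwm, decoy), peaks, bg)
  expect_equal(ev$pwm[1], "TRUE_TF")
  expect_gt(ev$auc[1], ev$auc[2])

  # a single candidate is returned regardless of AUC
  ev1 <- select_pwm(list(decoy), peaks[1:5], bg[1:5])
  expect_equal(nrow(ev1), 1L)

  # decoy on a background-vs-background split sits near 0.5
  ev0 <- select_pwm(list(decoy), bg[1:15], bg[16:30])
  n1 <- 15; n2 <- 15
  sigma <- sqrt((n1 + n2 + 1) / (12 * n1 * n2))
  expect_lt(abs(ev0$auc - 0.5), 3 * sigma)
})

test_that("prediction filters apply the likelihood-ratio and FDR rules", {
  peaks <- data.frame(chrom = "chr1",
                      start = c(1L, 101L, 201L), end = c(100L, 200L, 300L),
                      summit = c(50L, 50L, 50L),
                      peak_fdr = c(0.01, 0.05, 0.001))
  sites <- data.frame(chrom = "chr1",
                      start = c(40L, 140L, 240L), end = c(49L, 149L, 249L),
                      strand = "+", score = c(3.4, 9, 2), tf = "TOY")
  kept <- filter_predictions(sites, peaks)
  # site 1: LR 2^3.4 > 10, fdr .01 -> kept; site 2: fdr == 0.05 (strict <)
  # -> dropped; site 3: score below log2(10) -> dropped
  expect_equal(kept$start, 40L)

  # subset + idempotence
  expect_equal(filter_predictions(kept, peaks), kept)

  # hand-counted toy set of 10 sites
  set.seed(4)
  p10 <- data.frame(chrom = "chr1", start = seq(1, 901, 100),
                    end = seq(100, 1000, 100), summit = 50L,
                    peak_fdr = c(.01, .04, .06, .2, .049, .01, .5, .02,
                                 .03, .04))
  s10 <- data.frame(chrom = "chr1", start = seq(41, 941, 100),
                    end = seq(50, 950, 100), strand = "+",
                    score = c(4, 2, 8, 9, 3.33, 3.31, 12, 5, 3.5, 0),
                    tf = "TOY")
  # by hand: keep needs score >= log2(10) = 3.3219 and fdr < 0.05
  hand <- with(cbind(s10, fdr = p10$peak_fdr),
               sum(score >= log2(10) & fdr < 0.05))
  expect_equal(nrow(filter_predictions(s10, p10)), hand)
  expect_equal(hand, 4L) # sites 1, 5, 8, 9 survive both rules

  orphan <- data.frame(chrom = "chr2", start = 1L, end = 10L,
                       strand = "+", score = 5, tf = "TOY")
  expect_error(filter_predictions(orphan, peaks), "not contained")
})

test_that("summit offsets are signed, antisymmetric and centred", {
  peaks <- data.frame(chrom = "c", start = 1L, end = 200L, summit = 99L,
                      peak_fdr = 0.01)
  site <- data.frame(chrom = "c", start = 96L, end = 104L, strand = "+",
                     score = 5, tf = "T")
  off <- summit_offsets(site, peaks)
  expect_equal(off$offsets, 0) # midpoint 100 == 1 + 99

  # flipping the summit convention flips the sign
  pk2 <- peaks; pk2$summit <- 119L
  pk3 <- peaks; pk3$summit <- 79L
  expect_equal(summit_offsets(site, pk2)$offsets,
               -summit_offsets(site, pk3)$offsets)

  # synthetic peaks: summit = site centre + N(0, 20) jitter
  cfg <- sim_config(seed = 31, n_promoters = 150)
  st <- plant_sites(generate_promoters(cfg), generate_pwm(12, 8, 31), cfg)
  sites <- data.frame(chrom = st$truth$promoter_id,
                      start = st$truth$site_start,
                      end = st$truth$site_end, strand = st$truth$strand,
                      score = 0, tf = "SIM_TF")
  o <- summit_offsets(sites, st$peaks)
  expect_lt(abs(o$mean_offset), 5)
})

test_that("peak tables round-trip through the BED-like reader", {
  peaks <- data.frame(chrom = c("p1", "p2"), start = c(11L, 51L),
                      end = c(110L, 150L), name = c("a", "b"),
                      summit = c(40L, 60L), peak_fdr = c(0.01, 0.002))
  f <- tempfile(fileext = ".bed")
  write_peaks(peaks, f)
  back <- read_peaks(f)
  expect_equal(back$start, peaks$start)
  expect_equal(back$end, peaks$end)
  expect_equal(back$summit, peaks$summit)
  expect_equal(back$peak_fdr, peaks$peak_fdr)

  # narrowPeak layout: summit in col 10, q-value as -log10 in col 9
  f2 <- tempfile(fileext = ".narrowPeak")
  write.table(data.frame("p1", 10L, 110L, "a", 0L, ".", 1.5, 2, 2, 40L),
              f2, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  np <- read_peaks(f2, format = "narrowPeak")
  expect_equal(np$start, 11L)
  expect_equal(np$summit, 40L)
  expect_equal(np$peak_fdr, 0.01)
})
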