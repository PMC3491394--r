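test_that("site conservation averages the track and honours orientation", {
  track <- 1:10
  site <- list(start = 3L, end = 6L, strand = "+")
  sc <- site_conservation(site, track)
  expect_equal(sc$mean, mean(3:6))
  expect_equal(sc$profile, 3:6)

  # constant track
  expect_equal(site_conservation(site, rep(2.5, 10))$mean, 2.5)

  # minus-strand profile is the reverse of the plus-strand readout
  neg <- list(start = 3L, end = 6L, strand = "-")
  expect_equal(site_conservation(neg, track)$profile, rev(3:6))

  bad <- list(start = 8L, end = 12L, strand = "+")
  expect_error(site_conservation(bad, track), "outside")
})

test_that("distribution comparisons match exhaustive permutation nulls", {
  a <- c(0.1, 0.9, 2.3, 3.1, 4.7)
  b <- c(0.5, 1.7, 2.9, 5.2, 6.8)
  pool <- c(a, b)
  cmb <- combn(10, 5)
  D <- apply(cmb, 2, function(i) ks_stat(pool[i], pool[-i]))
  W <- apply(cmb, 2, function(i) sum(rank(pool)[i]) - 15)
  ks <- compare_distributions(a, b, "KS")
  expect_equal(ks$statistic, ks_stat(a, b))
  expect_equal(ks$p, mean(D >= ks_stat(a, b) - 1e-12))
  wx <- compare_distributions(a, b, "wilcoxon")
  wobs <- sum(rank(pool)[1:5]) - 15
  expect_equal(wx$statistic, wobs)
  expect_equal(wx$p, min(1, 2 * min(mean(W <= wobs), mean(W >= wobs))))

  # identities and degenerate cases
  same <- compare_distributions(1:8, 1:8, "KS")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  disj <- compare_distributions(1:10, 11:20, "KS")
  expect_equal(disj$statistic, 1)
  expect_error(compare_distributions(1:2, 1:5), "at least 3")

  # KS is invariant under a common monotone transform
  set.seed(12)
  x <- rnorm(15); y <- rnorm(15, 1)
  k1 <- compare_distributions(x, y, "KS")
  k2 <- compare_distributions(exp(x), exp(y), "KS")
  expect_equal(k1$statistic, k2$statistic)
  expect_equal(k1$p, k2$p)
})

test_that("TSS distances are transcript-oriented with a cumulative P_M", {
  ann <- data.frame(promoter_id = c("p", "m"), strand = c("+", "-"),
                    tss = c(500, 500))
  # site centred on the TSS
  s0 <- data.frame(promoter_id = "p", start = 498L, end = 502L)
  d0 <- tss_distance_distribution(s0, ann)
  expect_equal(d0$distances, 0)

  # minus-strand promoter, site 50 bp genomically left of the TSS is
  # downstream in transcript orientation: distance +50
  sm <- data.frame(promoter_id = "m", start = 448L, end = 452L)
  expect_equal(tss_distance_distribution(sm, ann)$distances, 50)

  # toy set {0, +-10, +-100}: P_10 = 3/5
  st <- data.frame(promoter_id = "p",
                   start = c(498, 508, 488, 598, 398),
                   end = c(502, 512, 492, 602, 402))
  dd <- tss_distance_distribution(st, ann)
  expect_equal(sort(dd$distances), c(-100, -10, 0, 10, 100))
  expect_equal(dd$cumulative(10), 0.6)
  expect_equal(dd$cumulative(1e9), 1)
  # cumulative is nondecreasing
  ms <- vapply(c(0, 5, 10, 50, 100, 200), dd$cumulative, 0)
  expect_true(all(diff(ms) >= 0))

  orphan <- data.frame(promoter_id = "zz", start = 1L, end = 5L)
  expect_error(tss_distance_distribution(orphan, ann), "no matching")

  # class comparisons on |distance| unchanged by shifting all coordinates
  ann2 <- ann; ann2$tss <- ann2$tss + 7
  st2 <- st; st2$start <- st2$start + 7; st2$end <- st2$end + 7
  expect_equal(tss_distance_distribution(st2, ann2)$abs_distances,
               dd$abs_distances)
})

test_that("IC permutation test recovers planted base preference", {
  # mirror of the activating/repressing logo comparison: group B fixes G
  # at the tested position, group A is scattered
  set.seed(9)
  mk <- function(n, pos4) vapply(seq_len(n), function(i) {
    ch <- sample(c("A", "C", "G", "T"), 8, replace = TRUE)
    ch[4] <- pos4[(i - 1) %% length(pos4) + 1]
    paste(ch, collapse = "")
  }, "")
  A <- mk(9, c("A", "C", "G", "T"))
  B <- mk(16, "G")
  r <- position_ic_permutation_test(A, B, 4, n_perm = 9999, seed = 2)
  expect_gt(r$delta_ic, 0)
  expect_lte(r$p, 0.01)

  # identical sets under shuffled labels: p well above the rejection level
  X <- mk(12, c("A", "C", "G", "T"))
  r0 <- position_ic_permutation_test(X, X, 4, n_perm = 999, seed = 3)
  expect_gt(r0$p, 0.05)

  # exact enumeration on tiny groups equals brute force
  A2 <- c("ACG", "ACG", "AAG", "ACG")
  B2 <- c("AGG", "AGG", "AGG", "ACG")
  expect_warning(re <- position_ic_permutation_test(A2, B2, 2, seed = 1),
                 "fewer than 5")
  expect_true(re$exact)
  ic_of <- function(b) {
    cnt <- table(factor(b, c("A", "C", "G", "T"))) + 0.5
    f <- cnt / sum(cnt)
    2 + sum(f * log2(f))
  }
  pool <- substr(c(A2, B2), 2, 2)
  obs <- ic_of(substr(B2, 2, 2)) - ic_of(substr(A2, 2, 2))
  perm <- apply(combn(8, 4), 2, function(i)
    ic_of(pool[-i]) - ic_of(pool[i]))
  expect_equal(re$p, mean(perm >= obs - 1e-12))
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(101)
  mk <- function(n) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = ""),
    "")
  rejections <- 0L
  for (rep in 1:200) {
    A <- mk(8); B <- mk(8)
    r <- position_ic_permutation_test(A, B, 3, n_perm = 199,
                                      seed = 1000 + rep)
    if (r$p <= 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections / 200, 0.07)
})

test_that("homotypic counting keeps the best of overlapping hits", {
  pwm <- consensus_pwm("ACGTACGTAC", pseudocount = 0.1)
  bgseq <- rand_seq(300, seed = 6)
  expect_equal(homotypic_count(bgseq, pwm, threshold = 12), 0L)

  # three planted non-overlapping copies
  s3 <- paste0(substr(bgseq, 1, 50), "ACGTACGTAC",
               substr(bgseq, 61, 150), "ACGTACGTAC",
               substr(bgseq, 161, 250), "ACGTACGTAC")
  expect_equal(homotypic_count(s3, pwm, threshold = 12), 3L)

  # two overlapping strong hits collapse to one
  s2 <- paste0(strrep("T", 30), "ACGTACGTACGTAC", strrep("T", 30))
  hits <- scan_pwm(pwm, s2, threshold = 12)
  expect_gte(nrow(hits), 2) # overlapping matches exist above threshold
  expect_equal(homotypic_count(s2, pwm, threshold = 12), 1L)
})

test_that("secondary-motif enrichment matches the hypergeometric tail", {
  motif <- consensus_pwm("ACGTACGTAC", pseudocount = 0.1)
  set.seed(15)
  with_m <- vapply(1:10, function(i)
    paste0(rand_seq(40), "ACGTACGTAC", rand_seq(40)), "")
  without <- vapply(1:10, function(i) rand_seq(90), "")
  r <- secondary_motif_enrichment(with_m, without, motif, threshold = 12)
  # all-vs-none split: p = 1 / choose(20, 10)
  expect_equal(r$p, 1 / choose(20, 10))
  expect_equal(r$odds_ratio, Inf)

  # identical presence rates give odds ratio 1
  r2 <- secondary_motif_enrichment(with_m, with_m, motif, threshold = 12)
  expect_equal(r2$odds_ratio, 1)

  # (8,2 / 3,7) table equals the independently summed hypergeometric tail
  tail_p <- sum(dhyper(8:10, 11, 9, 10))
  expect_equal(fisher.test(matrix(c(8, 2, 3, 7), 2),
                           alternative = "greater")$p.value, tail_p)
  expect_error(secondary_motif_enrichment(with_m[1:3], without, motif, 12),
               "at least 5")
})

test_that("normalized CpG follows its closed form and is strand-symmetric", {
  expect_equal(normalized_cpg("CGCGCG"), (3 / 5) / 0.25)
  expect_equal(normalized_cpg("CATGAC"), 0) # C and G present, no CpG
  s <- rand_seq(200, seed = 19)
  expect_equal(normalized_cpg(s), normalized_cpg(revcomp(s)))
  expect_error(normalized_cpg("AAAA"), "lacks C or G")
})

test_that("planted class differences in distance and conservation recover", {
  cfg <- sim_config(seed = 88, n_promoters = 400)
  pwm <- generate_pwm(cfg$pwm_width, cfg$pwm_concentration, seed = 88)
  st <- plant_sites(generate_promoters(cfg), pwm, cfg)
  tr <- st$truth
  ann <- generate_promoters(cfg)$annotations
  sites <- data.frame(promoter_id = tr$promoter_id, start = tr$site_start,
                      end = tr$site_end, strand = tr$strand)
  d <- tss_distance_distribution(sites, ann)
  func <- rowSums(as.matrix(tr[, grep("functional_", names(tr))])) > 0
  # functional (TSS-proximal / start-site) classes sit closer to the TSS
  cmp <- compare_distributions(abs(d$distances[func]),
                               abs(d$distances[!func]), "KS")
  expect_lt(cmp$p, 0.01)
  # conservation is elevated over functional sites
  consm <- vapply(seq_len(nrow(tr)), function(i)
    site_conservation(list(start = tr$site_start[i], end = tr$site_end[i],
                           strand = tr$strand[i]),
                      st$conservation[[tr$promoter_id[i]]])$mean, 0)
  cc <- compare_distributions(consm[func], consm[!func], "KS")
  expect_lt(cc$p, 0.01)
})

test_that("conservation tracks round-trip through bedGraph", {
  tracks <- list(p1 = c(0.5, 0.5, 1.25, -0.75, 0), p2 = rnorm(8))
  f <- tempfile(fileext = ".bedGraph")
  write_conservation_bedgraph(tracks, f)
  back <- read_conservation_bedgraph(f, lengths = c(p1 = 5L, p2 = 8L))
  expect_equal(back$p1, tracks$p1)
  expect_equal(back$p2, tracks$p2, tolerance = 1e-6)
})
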