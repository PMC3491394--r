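# Shared fixtures: tiny PWMs, random sequences and independent oracles
# used across the module tests.

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# deterministic PWM whose consensus is `seq` (frequency 1 on each base)
consensus_pwm <- function(seq, pseudocount = 0, name = "CONS") {
  ch <- strsplit(seq, "")[[1]]
  counts <- t(vapply(ch, function(b) 8 * (c("A", "C", "G", "T") == b),
                     numeric(4)))
  build_pwm(counts, pseudocount = pseudocount, name = name)
}

# brute-force pairwise AUC oracle: P(fg > bg) + 0.5 P(fg == bg)
auc_oracle <- function(fg, bg) {
  g <- outer(fg, bg, ">")
  e <- outer(fg, bg, "==")
  mean(g + 0.5 * e)
}

# brute-force best window: max log-odds over both strands at uniform bg
best_window_oracle <- function(pwm, seq) {
  W <- pwm_width(pwm)
  L <- nchar(seq)
  best <- -Inf
  for (s in seq_len(L - W + 1)) {
    win <- substr(seq, s, s + W - 1)
    for (w in c(win, revcomp(win)))
      best <- max(best, log_odds_score(pwm, w))
  }
  best
}

# hand-computed BH step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  pmin(1, cummin(n / (n:1) * p[o]))[order(o)]
}

# two-sample KS statistic
ks_stat <- function(x, y) {
  u <- sort(unique(c(x, y)))
  max(abs(ecdf(x)(u) - ecdf(y)(u)))
}

# simulated luminosity table for one plate
toy_plate <- function(raw, plate = "p1") {
  n <- length(raw)
  data.frame(construct_id = sprintf("c%d", seq_len(n)),
             allele = "WT", cell_line = "K562",
             prep_rep = 1L, txn_rep = 1L,
             plate_id = plate, raw = raw, stringsAsFactors = FALSE)
}
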