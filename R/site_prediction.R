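# Peak-centric TFBS prediction: matched background sampling, AUC-based PWM
# evaluation, best-site-per-peak calls and score / peak-FDR filters.

.validate_peaks <- function(peaks) {
  need <- c("chrom", "start", "end", "summit", "peak_fdr")
  miss <- setdiff(need, names(peaks))
  if (length(miss))
    stop("peaks missing columns: ", paste(miss, collapse = ", "))
  if (any(peaks$end < peaks$start)) stop("peak end < start")
  w <- peaks$end - peaks$start + 1L
  if (any(peaks$summit < 0 | peaks$summit >= w))
    stop("summit offset outside peak")
  if (any(peaks$peak_fdr < 0 | peaks$peak_fdr > 1))
    stop("peak_fdr outside [0, 1]")
  invisible(peaks)
}

.overlaps_any <- function(chrom, from, to, tab) {
  if (is.null(tab) || nrow(tab) == 0L) return(FALSE)
  any(tab$chrom == chrom & tab$start <= to & tab$end >= from)
}

#' Sample length-matched unbound background intervals
#'
#' For every peak, one interval of the same length is drawn uniformly from
#' the genomic positions not overlapping any peak, any excluded interval, or
#' any previously drawn background interval (sampling without replacement).
#' Each draw is attempted at most `max_attempts` times.
#'
#' @param peaks data.frame with chrom, start, end (1-based inclusive).
#' @param genome Named character vector of chromosome sequences (names are
#'   chromosome names), or a named vector of integer lengths.
#' @param excluded Optional data.frame (chrom, start, end) of intervals to
#'   avoid in addition to the peaks.
#' @param seed Integer seed; sampling is reproducible.
#' @param max_attempts Rejection-sampling budget per peak. Default 1000.
#' @return data.frame with chrom, start, end, one row per peak, same order.
#' @export
sample_background <- function(peaks, genome, excluded = NULL, seed = 1L,
                              max_attempts = 1000L) {
  if (is.character(genome)) glen <- nchar(genome) else glen <- genome
  if (is.null(names(glen))) stop("`genome` must be named by chromosome")
  set.seed(seed)
  avoid <- peaks[, c("chrom", "start", "end")]
  if (!is.null(excluded) && nrow(excluded))
    avoid <- rbind(avoid, excluded[, c("chrom", "start", "end")])
  out <- vector("list", nrow(peaks))
  failed <- integer(0)
  for (i in seq_len(nrow(peaks))) {
    w <- peaks$end[i] - peaks$start[i] + 1L
    slots <- pmax(glen - w + 1L, 0L)
    if (sum(slots) == 0L) { failed <- c(failed, w); next }
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      chrom <- sample(names(glen), 1L, prob = slots / sum(slots))
      st <- sample.int(slots[[chrom]], 1L)
      if (!.overlaps_any(chrom, st, st + w - 1L, avoid)) {
        out[[i]] <- data.frame(chrom = chrom, start = st, end = st + w - 1L,
                               stringsAsFactors = FALSE)
        # without replacement: later draws avoid this interval too
        avoid <- rbind(avoid, out[[i]])
        placed <- TRUE
        break
      }
    }
    if (!placed) failed <- c(failed, w)
  }
  if (length(failed))
    stop("insufficient unbound space for interval length(s): ",
         paste(sort(unique(failed)), collapse = ", "))
  do.call(rbind, out)
}

#' Highest-scoring binding site within one region
#'
#' Assumes a single (highest scoring) TFBS per region: scans both strands
#' and returns the maximal window; ties are resolved leftmost, plus strand
#' first.
#'
#' @param pwm A `pwm` object.
#' @param region_seq Character string of the region sequence.
#' @param bg_window Local background window size passed to [scan_pwm()].
#' @param chrom Sequence name recorded in the output.
#' @return One-row data.frame (chrom, start, end, strand, score, tf).
#' @export
best_site_per_region <- function(pwm, region_seq, bg_window = 100L,
                                 chrom = "seq") {
  if (nchar(region_seq) < pwm_width(pwm))
    stop("region shorter than PWM width")
  hits <- scan_pwm(pwm, region_seq, both_strands = TRUE, threshold = -Inf,
                   bg_window = bg_window, chrom = chrom)
  if (nrow(hits) == 0L) stop("no scoreable window (all windows ambiguous)")
  ord <- order(-hits$score, hits$start, hits$strand)
  out <- hits[ord[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Area under the ROC curve from two score sets
#'
#' Computed as the Mann-Whitney U statistic divided by n_fg * n_bg, with
#' ties counted one half: the probability that a random foreground score
#' exceeds a random background score.
#'
#' @param fg_scores Numeric scores for the positive (peak) set.
#' @param bg_scores Numeric scores for the background set.
#' @return AUC in [0, 1]; 0.5 is a random classifier.
#' @export
compute_auc <- function(fg_scores, bg_scores) {
  if (length(fg_scores) == 0L || length(bg_scores) == 0L)
    stop("both score lists must be non-empty")
  if (anyNA(fg_scores) || anyNA(bg_scores)) stop("NA score")
  n1 <- length(fg_scores)
  n2 <- length(bg_scores)
  r <- rank(c(fg_scores, bg_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Evaluate candidate PWMs by peak-versus-background AUC
#'
#' Each candidate is scored with [best_site_per_region()] on every peak and
#' background sequence; discrimination is summarised as AUC and candidates
#' are returned in (stable) descending-AUC order.
#'
#' @param candidates List of `pwm` objects.
#' @param peak_seqs Character vector of peak-region sequences.
#' @param bg_seqs Character vector of length-matched background sequences.
#' @param bg_window Local background window for scanning. Default 100.
#' @return data.frame with pwm, auc, n_peaks, n_background.
#' @export
select_pwm <- function(candidates, peak_seqs, bg_seqs, bg_window = 100L) {
  if (length(candidates) == 0L) stop("need at least one candidate PWM")
  best <- function(p, s) best_site_per_region(p, s, bg_window = bg_window)$score
  evals <- lapply(candidates, function(p) {
    fg <- vapply(peak_seqs, best, 0, p = p)
    bg <- vapply(bg_seqs, best, 0, p = p)
    data.frame(pwm = p$name, auc = compute_auc(fg, bg),
               n_peaks = length(fg), n_background = length(bg),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, evals)
  out <- out[order(-out$auc), , drop = FALSE] # stable: order() preserves ties
  rownames(out) <- NULL
  out
}

# pair each site with the peak containing it (same chrom, site inside peak)
.pair_site_peak <- function(sites, peaks) {
  idx <- vapply(seq_len(nrow(sites)), function(i) {
    j <- which(peaks$chrom == sites$chrom[i] &
                 peaks$start <= sites$start[i] &
                 peaks$end >= sites$end[i])
    if (length(j) == 0L)
      stop(sprintf("site %d (%s:%d-%d) not contained in any peak",
                   i, sites$chrom[i], sites$start[i], sites$end[i]))
    j[[1L]]
  }, 0L)
  idx
}

#' Filter predicted sites on score and peak quality
#'
#' Keeps sites whose likelihood ratio versus the local background is at
#' least `min_lr` (log-odds score >= log2(min_lr) bits) and whose ChIP-seq
#' peak FDR is strictly below `max_peak_fdr`.
#'
#' @param sites data.frame of scored sites (one per peak).
#' @param peaks data.frame of peaks with `peak_fdr` (and summit) columns.
#' @param min_lr Minimum fold likelihood ratio. Default 10.
#' @param max_peak_fdr Strict upper bound on the peak FDR. Default 0.05.
#' @return The surviving subset of `sites` (same columns).
#' @export
filter_predictions <- function(sites, peaks, min_lr = 10,
                               max_peak_fdr = 0.05) {
  .validate_peaks(peaks)
  if (nrow(sites) == 0L) return(sites)
  idx <- .pair_site_peak(sites, peaks)
  keep <- sites$score >= log2(min_lr) & peaks$peak_fdr[idx] < max_peak_fdr
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Offsets of predicted sites from their peak summits
#'
#' The offset is site midpoint minus summit position (peak start + summit
#' offset); a well-behaved prediction set is centred on the summits, i.e.
#' has mean offset near zero.
#'
#' @param sites data.frame of scored sites.
#' @param peaks data.frame of peaks (with `summit` offset from peak start).
#' @return list with `offsets` (signed numeric vector) and `mean_offset`.
#' @export
summit_offsets <- function(sites, peaks) {
  .validate_peaks(peaks)
  idx <- .pair_site_peak(sites, peaks)
  mid <- (sites$start + sites$end) / 2
  off <- mid - (peaks$start[idx] + peaks$summit[idx])
  list(offsets = off, mean_offset = mean(off))
}

#' Read peaks from a BED-like tab-separated file
#'
#' Two layouts are accepted: a 8-column BED-like table
#' (chrom, start, end, name, score, strand, summit, peak_fdr) and MACS
#' narrowPeak (10 columns; summit offset in column 10, q-value in column 9
#' as -log10, converted to a plain FDR). On-disk coordinates are 0-based
#' half-open and converted to 1-based inclusive.
#'
#' @param path Input file.
#' @param format "bed8" or "narrowPeak".
#' @return data.frame with chrom, start, end, name, summit, peak_fdr.
#' @export
read_peaks <- function(path, format = c("bed8", "narrowPeak")) {
  format <- match.arg(format)
  x <- read.table(path, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE, comment.char = "#")
  if (format == "bed8") {
    if (ncol(x) < 8L) stop("bed8 peak file needs 8 columns")
    out <- data.frame(chrom = x[[1]], start = x[[2]] + 1L, end = x[[3]],
                      name = x[[4]], summit = x[[7]], peak_fdr = x[[8]],
                      stringsAsFactors = FALSE)
  } else {
    if (ncol(x) < 10L) stop("narrowPeak file needs 10 columns")
    out <- data.frame(chrom = x[[1]], start = x[[2]] + 1L, end = x[[3]],
                      name = x[[4]], summit = x[[10]],
                      peak_fdr = 10^(-x[[9]]),
                      stringsAsFactors = FALSE)
  }
  .validate_peaks(out)
  out
}

#' Write peaks as a BED-like tab-separated file
#'
#' Inverse of [read_peaks()] (bed8 layout, 0-based half-open on disk).
#'
#' @param peaks data.frame with chrom, start, end, summit, peak_fdr and
#'   optionally name.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  .validate_peaks(peaks)
  nm <- if ("name" %in% names(peaks)) peaks$name
        else sprintf("peak_%d", seq_len(nrow(peaks)))
  out <- data.frame(peaks$chrom, peaks$start - 1L, peaks$end, nm,
                    0L, ".", peaks$summit, peaks$peak_fdr)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a PWM evaluation report as TSV
#'
#' @param evaluations data.frame from [select_pwm()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pwm_evaluation <- function(evaluations, path) {
  write.table(evaluations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
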