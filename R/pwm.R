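#' @importFrom stats median rnorm runif rbinom rgamma setNames complete.cases
#' @importFrom utils read.table write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

# complement lookup used throughout (plain character arithmetic keeps the
# scanner free of S4 overhead on million-window loops)
.comp_chartr_from <- "ACGTRYKMBVDHSWNacgtrykmbvdhswn"
.comp_chartr_to   <- "TGCAYRMKVBHDSWNtgcayrmkvbhdswn"

#' Reverse complement of a DNA string
#'
#' Accepts the full IUPAC alphabet; case is preserved.
#'
#' @param seq A single character string.
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  x <- chartr(.comp_chartr_from, .comp_chartr_to, seq)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

.seq_to_idx <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES)
}

#' Build a position weight matrix from base counts
#'
#' Rows are motif positions, columns the bases A, C, G, T. Frequencies are
#' computed with a Laplace-style pseudocount:
#' f = (count + pseudocount) / (rowsum + 4 * pseudocount).
#'
#' @param counts Numeric matrix, W x 4, non-negative counts (or frequencies).
#'   A 4 x W matrix with rownames A,C,G,T is transposed automatically.
#' @param pseudocount Non-negative real added to every cell. Default 0.5.
#' @param name Motif / transcription factor label.
#' @return An object of class `pwm`: list with `name`, `counts`,
#'   `pseudocount`, `freq` (row-stochastic W x 4 matrix).
#' @examples
#' m <- build_pwm(rbind(c(8, 0, 0, 0), c(0, 8, 0, 0)), pseudocount = 1)
#' m$freq[1, ] # 9/12, 1/12, 1/12, 1/12
#' @export
build_pwm <- function(counts, pseudocount = 0.5, name = "PWM") {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L && nrow(counts) == 4L &&
      !is.null(rownames(counts)) &&
      all(toupper(rownames(counts)) %in% DNA_BASES)) {
    counts <- t(counts)
  }
  if (ncol(counts) != 4L)
    stop("`counts` must have 4 columns (A, C, G, T)")
  if (nrow(counts) < 1L)
    stop("`counts` must have at least one row (motif position)")
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("invalid matrix: counts must be finite and non-negative")
  if (length(pseudocount) != 1L || !is.finite(pseudocount) || pseudocount < 0)
    stop("`pseudocount` must be a single non-negative number")
  rs <- rowSums(counts)
  if (pseudocount == 0 && any(rs == 0))
    stop("invalid matrix: all-zero row with pseudocount 0")
  colnames(counts) <- DNA_BASES
  freq <- (counts + pseudocount) / (rs + 4 * pseudocount)
  structure(list(name = name, counts = counts,
                 pseudocount = pseudocount, freq = freq),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': width %d, pseudocount %g, total IC %.2f bits\n",
              x$name, nrow(x$freq), x$pseudocount,
              sum(information_content(x))))
  print(round(x$freq, 3))
  invisible(x)
}

#' Motif width of a PWM
#' @param pwm A `pwm` object.
#' @return Integer number of positions.
#' @export
pwm_width <- function(pwm) nrow(pwm$freq)

#' Consensus sequence of a PWM
#'
#' Highest-frequency base per position; ties resolved alphabetically.
#'
#' @param pwm A `pwm` object.
#' @return Character string of length `pwm_width(pwm)`.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$freq, 1L, which.max)], collapse = "")
}

#' Per-position information content (bits)
#'
#' IC_j = 2 + sum_b f_jb log2 f_jb against a uniform background, with
#' 0 * log(0) taken as 0. Values lie in [0, 2].
#'
#' @param pwm A `pwm` object.
#' @return Numeric vector of length W.
#' @export
information_content <- function(pwm) {
  f <- pwm$freq
  lt <- ifelse(f > 0, f * log2(f), 0)
  ic <- 2 + rowSums(lt)
  pmin(pmax(ic, 0), 2)
}

#' Local background nucleotide abundances
#'
#' Abundances are floored at `eps` and renormalised to sum to one, so no
#' base ever has zero background probability.
#'
#' @param abundances Numeric vector of 4 non-negative values (A, C, G, T).
#' @param window_bp Width of the window the abundances came from (metadata).
#' @param eps Floor applied before renormalisation. Default 1e-3.
#' @return Object of class `local_background` (list with `window_bp`,
#'   `abundances`).
#' @export
local_background <- function(abundances, window_bp = 100L, eps = 1e-3) {
  stopifnot(length(abundances) == 4L, all(is.finite(abundances)),
            all(abundances >= 0))
  a <- abundances / sum(abundances)
  lo <- a < eps
  if (any(lo)) {
    # keep floored entries exactly at eps; rescale the rest to sum 1
    a[!lo] <- a[!lo] * (1 - sum(lo) * eps) / sum(a[!lo])
    a[lo] <- eps
  }
  structure(list(window_bp = as.integer(window_bp),
                 abundances = setNames(a, DNA_BASES)),
            class = "local_background")
}

.bg_abundances <- function(bg) {
  if (inherits(bg, "local_background")) bg$abundances
  else if (is.numeric(bg) && length(bg) == 4L) local_background(bg)$abundances
  else stop("`bg` must be a local_background or a numeric vector of 4")
}

#' Log-odds score of one window against a PWM
#'
#' score = sum_j log2( f_j(b_j) / q(b_j) ), in bits. Windows containing any
#' non-ACGT character score `-Inf` (they are never eligible as sites).
#'
#' @param pwm A `pwm` object.
#' @param window Character string of length `pwm_width(pwm)`.
#' @param bg A [local_background] or numeric vector of 4 abundances.
#'   Default uniform.
#' @return A single numeric score in bits.
#' @export
log_odds_score <- function(pwm, window, bg = rep(0.25, 4)) {
  W <- pwm_width(pwm)
  if (nchar(window) != W)
    stop(sprintf("window length %d != PWM width %d", nchar(window), W))
  idx <- .seq_to_idx(window)
  if (anyNA(idx)) return(-Inf)
  q <- .bg_abundances(bg)
  sum(log2(pwm$freq[cbind(seq_len(W), idx)]) - log2(q[idx]))
}

# region [from, to] of bg_window bp centred on the window [s, s+W-1],
# before clipping to [1, L]
.bg_region <- function(s, W, bg_window, L) {
  extra <- bg_window - W
  from <- s - floor(extra / 2)
  to <- s + W - 1L + ceiling(extra / 2)
  list(from = pmax(from, 1L), to = pmin(to, L))
}

#' Scan a sequence with a PWM using locally-conditioned log-odds scores
#'
#' For every window the background base abundances are estimated from a
#' `bg_window` bp region centred on that window (clipped at the sequence
#' ends, floored at 1e-3 and renormalised), emulating a POSSUM-style
#' locally-conditioned scan. Minus-strand scores are computed on the reverse
#' complement of the window against the same local background (whose
#' strand-complement is used, which leaves the denominator unchanged).
#' Windows containing non-ACGT characters score `-Inf` and are never
#' reported.
#'
#' @param pwm A `pwm` object.
#' @param seq Character string (case-insensitive DNA).
#' @param both_strands Scan the minus strand too? Default TRUE.
#' @param threshold Minimum score in bits to report. Default `-Inf`.
#' @param bg_window Local background window size in bp. Default 100.
#' @param chrom Sequence name recorded in the output. Default "seq".
#' @return data.frame with columns chrom, start, end (1-based inclusive),
#'   strand, score (bits), tf; sorted by start, plus strand first on ties.
#' @export
scan_pwm <- function(pwm, seq, both_strands = TRUE, threshold = -Inf,
                     bg_window = 100L, chrom = "seq") {
  W <- pwm_width(pwm)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), tf = character(),
                      stringsAsFactors = FALSE)
  L <- nchar(seq)
  if (L < W) {
    warning("sequence shorter than PWM width; no windows scanned")
    return(empty)
  }
  idx <- .seq_to_idx(seq)
  nw <- L - W + 1L
  ok <- !is.na(idx)
  idx0 <- ifelse(ok, idx, 1L)

  # windows containing any ambiguous base
  cumna <- c(0L, cumsum(!ok))
  win_na <- (cumna[seq_len(nw) + W] - cumna[seq_len(nw)]) > 0L

  # strand-specific numerators: sum over positions of log2 f
  lf <- log2(pwm$freq)
  lfr <- lf[W:1, 4:1, drop = FALSE] # reverse-complement orientation
  num_p <- numeric(nw)
  num_m <- numeric(nw)
  for (j in seq_len(W)) {
    sel <- idx0[j:(j + nw - 1L)]
    num_p <- num_p + lf[j, sel]
    num_m <- num_m + lfr[j, sel]
  }

  # cumulative base counts (ambiguous bases contribute to no base)
  cum <- matrix(0, nrow = 4L, ncol = L + 1L)
  for (b in 1:4) cum[b, ] <- c(0, cumsum(ok & idx0 == b))

  s <- seq_len(nw)
  reg <- .bg_region(s, W, bg_window, L)
  bc <- cum[, reg$to + 1L, drop = FALSE] - cum[, reg$from, drop = FALSE]
  tot <- colSums(bc)
  q <- sweep(bc, 2L, pmax(tot, 1), "/")
  q[, tot == 0] <- 0.25          # all-ambiguous region: fall back to uniform
  eps <- 1e-3
  lo <- q < eps
  scale <- (1 - colSums(lo) * eps) / colSums(q * !lo)
  q <- q * rep(scale, each = 4L)
  q[lo] <- eps

  # denominator: sum over window bases of log2 q; identical on both strands
  wc <- cum[, s + W, drop = FALSE] - cum[, s, drop = FALSE]
  den <- colSums(wc * log2(q))

  score_p <- num_p - den
  score_m <- num_m - den
  score_p[win_na] <- -Inf
  score_m[win_na] <- -Inf

  res <- data.frame(chrom = chrom, start = s, end = s + W - 1L,
                    strand = "+", score = score_p, tf = pwm$name,
                    stringsAsFactors = FALSE)
  if (both_strands) {
    res <- rbind(res,
                 data.frame(chrom = chrom, start = s, end = s + W - 1L,
                            strand = "-", score = score_m, tf = pwm$name,
                            stringsAsFactors = FALSE))
  }
  res <- res[is.finite(res$score) & res$score >= threshold, , drop = FALSE]
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read a PWM from text
#'
#' Two dialects are accepted: JASPAR-style (a `>` header then four rows
#' labelled A/C/G/T, optionally with brackets) and TRANSFAC-like plain
#' matrices (W rows by 4 columns, optional header line of base labels and
#' optional leading position column). The internal orientation is always
#' positions-as-rows.
#'
#' @param path File to read.
#' @param pseudocount Passed to [build_pwm()].
#' @param name Motif name; defaults to the JASPAR header or the file name.
#' @return A `pwm` object.
#' @export
read_pwm <- function(path, pseudocount = 0.5, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty PWM file")
  if (startsWith(lines[[1]], ">")) {
    hdr <- sub("^>\\s*", "", lines[[1]])
    if (is.null(name)) name <- strsplit(hdr, "\\s+")[[1]][1]
    lines <- lines[-1]
  }
  base_labelled <- grepl("^[ACGTacgt]\\s*[\\[:|]?\\s*[-0-9.]", lines,
                         perl = TRUE)
  if (all(base_labelled) && length(lines) == 4L) {
    rows <- lapply(lines, function(ln) {
      base <- toupper(substr(ln, 1, 1))
      nums <- regmatches(ln, gregexpr("[-0-9.eE+]+", ln))[[1]]
      list(base = base, x = as.numeric(nums))
    })
    bases <- vapply(rows, `[[`, "", "base")
    if (!setequal(bases, DNA_BASES)) stop("JASPAR dialect needs rows A,C,G,T")
    wds <- vapply(rows, function(r) length(r$x), 0L)
    if (length(unique(wds)) != 1L) stop("ragged JASPAR matrix")
    counts <- t(do.call(rbind, lapply(rows, `[[`, "x")))
    colnames(counts) <- bases
    counts <- counts[, DNA_BASES, drop = FALSE]
  } else {
    # TRANSFAC-like: drop XX/PO furniture, keep numeric rows
    keep <- grepl("[0-9]", lines) & !grepl("^(XX|//|PO|P0|ID|BF|NA)\\b", lines)
    hdr_line <- grepl("^(PO|P0)\\b", lines) | grepl("^A\\s+C\\s+G\\s+T\\s*$", lines)
    lines <- lines[keep & !hdr_line]
    if (length(lines) == 0L) stop("no matrix rows found")
    rows <- lapply(lines, function(ln)
      as.numeric(regmatches(ln, gregexpr("[-0-9.eE+]+", ln))[[1]]))
    ncols <- unique(vapply(rows, length, 0L))
    if (length(ncols) != 1L) stop("ragged TRANSFAC matrix")
    counts <- do.call(rbind, rows)
    if (ncols == 5L) counts <- counts[, -1L, drop = FALSE] # position column
    else if (ncols != 4L) stop("TRANSFAC dialect needs 4 count columns")
    colnames(counts) <- DNA_BASES
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  build_pwm(counts, pseudocount = pseudocount, name = name)
}

#' Write a PWM as JASPAR-style text
#'
#' @param pwm A `pwm` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", pwm$name), con)
  for (b in seq_along(DNA_BASES)) {
    writeLines(sprintf("%s [ %s ]", DNA_BASES[b],
                       paste(format(pwm$counts[, b], trim = TRUE),
                             collapse = " ")), con)
  }
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (upper or lower case tolerated).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Export scored sites as BED6
#'
#' Coordinates are converted to BED's 0-based half-open convention; the BED
#' score column is the log-odds score in bits times 100, rounded; the name
#' column is the TF label.
#'
#' @param sites data.frame as returned by [scan_pwm()].
#' @param path Output BED file.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$start, end = sites$end),
    strand = sites$strand)
  gr$name <- sites$tf
  gr$score <- round(100 * sites$score)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED6 site file written by [write_sites_bed()]
#'
#' @param path BED file.
#' @return data.frame with chrom, start, end (1-based inclusive), strand,
#'   score (bits), tf.
#' @export
read_sites_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             score = gr$score / 100,
             tf = gr$name,
             stringsAsFactors = FALSE)
}
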