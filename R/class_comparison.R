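# Comparisons between functional classes of binding sites: conservation,
# TSS / translational-start distances, per-position information content
# (permutation test), homotypic clusters, secondary-motif enrichment and
# normalized CpG content.

.check_annotation <- function(ann) {
  need <- c("promoter_id", "strand", "tss")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation missing columns: ", paste(miss, collapse = ", "))
  invisible(ann)
}

#' Conservation of one site within its promoter
#'
#' Mean per-base conservation over the site plus a per-position profile
#' (site +/- `flank`, clipped at the sequence ends). For minus-strand sites
#' the profile is reported in motif orientation, i.e. reversed.
#'
#' @param site One-row data.frame (or list) with start, end (1-based
#'   inclusive, promoter coordinates) and strand.
#' @param conservation Numeric per-base conservation track of the promoter.
#' @param flank Bases of flank on each side of the profile. Default 0.
#' @return list with `mean` (over the site bases only) and `profile`.
#' @export
site_conservation <- function(site, conservation, flank = 0L) {
  L <- length(conservation)
  if (site$start < 1L || site$end > L || site$end < site$start)
    stop("site outside the annotated sequence")
  core <- conservation[site$start:site$end]
  from <- max(1L, site$start - flank)
  to <- min(L, site$end + flank)
  prof <- conservation[from:to]
  if (!is.null(site$strand) && site$strand == "-") prof <- rev(prof)
  list(mean = mean(core), profile = prof)
}

#' Mean conservation profile across aligned sites
#'
#' Averages per-position profiles (motif-oriented) across sites of equal
#' width, with standard errors.
#'
#' @param sites data.frame with promoter_id, start, end, strand.
#' @param conservation Named list of per-base tracks, one per promoter.
#' @param flank Flank in bp on each side. Default 0. Sites whose flanked
#'   window would be clipped are dropped so positions stay aligned.
#' @return list with `mean`, `se` (vectors of width + 2*flank) and `n`.
#' @export
conservation_profile <- function(sites, conservation, flank = 0L) {
  profs <- lapply(seq_len(nrow(sites)), function(i) {
    tr <- conservation[[sites$promoter_id[i]]]
    if (is.null(tr)) stop("no conservation track for ",
                          sites$promoter_id[i])
    if (sites$start[i] - flank < 1L || sites$end[i] + flank > length(tr))
      return(NULL)
    site_conservation(sites[i, ], tr, flank)$profile
  })
  profs <- profs[!vapply(profs, is.null, TRUE)]
  if (length(profs) == 0L) stop("no usable sites")
  m <- do.call(rbind, profs)
  list(mean = colMeans(m),
       se = apply(m, 2L, stats::sd) / sqrt(nrow(m)),
       n = nrow(m))
}

#' Compare two empirical distributions
#'
#' Two-sided Kolmogorov-Smirnov (default) or Wilcoxon rank-sum test; exact
#' small-sample null distributions are used where the underlying tests
#' support them (no ties, small n).
#'
#' @param a,b Numeric samples, each of size >= 3.
#' @param method "KS" or "wilcoxon".
#' @return list with `statistic` and `p`.
#' @export
compare_distributions <- function(a, b, method = c("KS", "wilcoxon")) {
  method <- match.arg(method)
  if (length(a) < 3L || length(b) < 3L)
    stop("each sample must contain at least 3 values")
  if (method == "KS") {
    ht <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b,
                                              alternative = "two.sided"))
  }
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Signed TSS distances and their cumulative distribution
#'
#' Distance = site midpoint - TSS, measured in transcript orientation
#' (positive downstream of the TSS); on minus-strand promoters the sign is
#' flipped accordingly. The cumulative distribution P_M is the fraction of
#' sites within M bp of the TSS in either direction (|distance| <= M).
#'
#' @param sites data.frame with promoter_id, start, end.
#' @param annotations data.frame with promoter_id, strand, tss (promoter
#'   coordinates).
#' @return list of class `distance_distribution`: `distances` (signed),
#'   `cumulative` (function of M), `abs_distances`.
#' @export
tss_distance_distribution <- function(sites, annotations) {
  .check_annotation(annotations)
  j <- match(sites$promoter_id, annotations$promoter_id)
  if (anyNA(j))
    stop("site(s) with no matching promoter annotation: ",
         paste(unique(sites$promoter_id[is.na(j)]), collapse = ", "))
  mid <- (sites$start + sites$end) / 2
  d <- mid - annotations$tss[j]
  d <- ifelse(annotations$strand[j] == "-", -d, d)
  absd <- abs(d)
  structure(list(distances = d,
                 abs_distances = absd,
                 cumulative = function(M) mean(absd <= M)),
            class = "distance_distribution")
}

#' Permutation test for a per-position information-content difference
#'
#' Builds per-group PWMs (pseudocount 0.5) from two sets of aligned site
#' sequences and tests whether group B has higher information content than
#' group A at one motif position. The null distribution is obtained by
#' shuffling the group labels; the one-sided p-value is
#' (1 + #permutations with delta >= observed) / (n_perm + 1). When either
#' group has fewer than 5 sequences and complete enumeration of the label
#' assignments is feasible, the exact permutation distribution is used
#' instead (with a warning about the small group).
#'
#' @param sitesA,sitesB Character vectors of equal-width site sequences.
#' @param position Motif position to test (1-based).
#' @param n_perm Number of label shuffles. Default 9999.
#' @param seed Integer seed for reproducibility.
#' @return list with `delta_ic` (IC_B - IC_A at the position), `p`,
#'   `n_perm` (permutations actually used) and `exact` flag.
#' @export
position_ic_permutation_test <- function(sitesA, sitesB, position,
                                         n_perm = 9999L, seed = 1L) {
  w <- unique(nchar(c(sitesA, sitesB)))
  if (length(w) != 1L) stop("all site sequences must have the same width")
  if (position < 1L || position > w) stop("position outside motif width")
  base_at <- function(seqs) {
    match(toupper(substr(seqs, position, position)), DNA_BASES)
  }
  ic_of <- function(codes) {
    cnt <- tabulate(codes, nbins = 4L) + 0.5
    f <- cnt / sum(cnt)
    2 + sum(f * log2(f))
  }
  bA <- base_at(sitesA)
  bB <- base_at(sitesB)
  if (anyNA(bA) || anyNA(bB)) stop("ambiguous base at tested position")
  nA <- length(bA)
  nB <- length(bB)
  pool <- c(bA, bB)
  obs <- ic_of(bB) - ic_of(bA)
  delta_for <- function(idxA) {
    ic_of(pool[-idxA]) - ic_of(pool[idxA])
  }
  exact <- FALSE
  if (min(nA, nB) < 5L) {
    warning("group with fewer than 5 sequences")
    if (choose(nA + nB, nA) <= 2e5) exact <- TRUE
  }
  if (exact) {
    combs <- utils::combn(nA + nB, nA)
    perm <- apply(combs, 2L, delta_for)
    # exact enumeration: p is the plain null tail probability
    p <- mean(perm >= obs - 1e-12)
    n_used <- ncol(combs)
  } else {
    set.seed(seed)
    perm <- vapply(seq_len(n_perm), function(i)
      delta_for(sample.int(nA + nB, nA)), 0)
    p <- (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
    n_used <- n_perm
  }
  list(delta_ic = obs, p = p, n_perm = n_used, exact = exact)
}

#' Count homotypic binding sites on a promoter
#'
#' Re-scans the promoter with the same motif and score threshold used for
#' prediction and counts non-overlapping sites at or above the threshold,
#' resolving overlaps greedily best-first (highest score kept).
#'
#' @param seq Promoter sequence.
#' @param pwm The motif used for prediction.
#' @param threshold Score threshold in bits (same as prediction).
#' @param bg_window Local background window. Default 100.
#' @return Integer count of non-overlapping above-threshold sites.
#' @export
homotypic_count <- function(seq, pwm, threshold, bg_window = 100L) {
  hits <- scan_pwm(pwm, seq, both_strands = TRUE, threshold = threshold,
                   bg_window = bg_window)
  if (nrow(hits) == 0L) return(0L)
  hits <- hits[order(-hits$score, hits$start, hits$strand), , drop = FALSE]
  kept <- hits[0, ]
  for (i in seq_len(nrow(hits))) {
    if (!nrow(kept) ||
        !any(kept$start <= hits$end[i] & kept$end >= hits$start[i]))
      kept <- rbind(kept, hits[i, ])
  }
  nrow(kept)
}

#' Secondary-motif enrichment between promoter classes
#'
#' Scores presence (>= 1 site at or above `threshold`) of a secondary
#' motif on each promoter and tests overrepresentation among promoters
#' with functional sites versus promoters whose sites were not verified,
#' with a one-sided Fisher exact test. A p-value near 1 indicates
#' underrepresentation on the functional class.
#'
#' @param seqs_func Character vector of promoters with functional sites.
#' @param seqs_nonfunc Character vector of promoters without verified
#'   function (each class needs >= 5 promoters).
#' @param motif Secondary-motif `pwm`.
#' @param threshold Score threshold in bits for motif presence.
#' @param bg_window Local background window. Default 100.
#' @return list with `odds_ratio`, `p`, and the 2x2 `table`.
#' @export
secondary_motif_enrichment <- function(seqs_func, seqs_nonfunc, motif,
                                       threshold, bg_window = 100L) {
  if (length(seqs_func) < 5L || length(seqs_nonfunc) < 5L)
    stop("each promoter class needs at least 5 promoters")
  present <- function(s)
    nrow(scan_pwm(motif, s, both_strands = TRUE, threshold = threshold,
                  bg_window = bg_window)) > 0L
  a <- sum(vapply(seqs_func, present, TRUE))       # functional, motif+
  b <- length(seqs_func) - a
  c_ <- sum(vapply(seqs_nonfunc, present, TRUE))   # nonfunctional, motif+
  d <- length(seqs_nonfunc) - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2L,
                dimnames = list(c("motif+", "motif-"),
                                c("functional", "nonfunctional")))
  ht <- stats::fisher.test(tab, alternative = "greater")
  # sample odds ratio; equal cross-products (incl. the 0/0 cases where
  # presence rates are identical) give exactly 1
  orr <- if (a * d == b * c_) 1 else (a * d) / (b * c_)
  list(odds_ratio = orr, p = ht$p.value, table = tab)
}

#' Normalized CpG content of a sequence
#'
#' Observed CpG dinucleotide frequency divided by the product of the C and
#' G mononucleotide frequencies:
#' (#CG / (L-1)) / ((#C / L) * (#G / L)).
#'
#' @param seq DNA string with at least one C and one G.
#' @return Normalized CpG content (>= 0; ~1 means no depletion).
#' @export
normalized_cpg <- function(seq) {
  s <- toupper(seq)
  L <- nchar(s)
  if (L < 2L) stop("sequence too short")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  nC <- sum(ch == "C")
  nG <- sum(ch == "G")
  if (nC == 0L || nG == 0L)
    stop("normalized CpG undefined: sequence lacks C or G")
  ncg <- sum(ch[-L] == "C" & ch[-1L] == "G")
  (ncg / (L - 1)) / ((nC / L) * (nG / L))
}

#' Write a per-position frequency matrix for logo rendering
#'
#' Exports the PWM's position frequencies as TSV (positions as rows,
#' columns A, C, G, T) consumable by standard sequence-logo tools.
#'
#' @param pwm A `pwm` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_logo_matrix <- function(pwm, path) {
  tab <- data.frame(position = seq_len(pwm_width(pwm)), pwm$freq)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bedGraph conservation track into per-promoter vectors
#'
#' @param path bedGraph file (one score per base, sequence names are
#'   promoter ids).
#' @param lengths Named integer vector of promoter lengths (bases not
#'   covered default to 0).
#' @return Named list of numeric per-base tracks.
#' @export
read_conservation_bedgraph <- function(path, lengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- lapply(names(lengths), function(id) numeric(lengths[[id]]))
  names(out) <- names(lengths)
  sn <- as.character(GenomicRanges::seqnames(gr))
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  sc <- gr$score
  for (i in seq_along(sn)) {
    if (!sn[i] %in% names(out)) next
    out[[sn[i]]][st[i]:en[i]] <- sc[i]
  }
  out
}

#' Write per-promoter conservation tracks as bedGraph
#'
#' Adjacent equal values are run-length collapsed.
#'
#' @param tracks Named list of numeric per-base vectors.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_conservation_bedgraph <- function(tracks, path) {
  grl <- lapply(names(tracks), function(id) {
    r <- rle(tracks[[id]])
    en <- cumsum(r$lengths)
    st <- en - r$lengths + 1L
    GenomicRanges::GRanges(id, IRanges::IRanges(st, en), score = r$values)
  })
  # promoters are distinct sequences, so differing seqlevels are expected
  gr <- suppressWarnings(do.call(c, grl))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
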