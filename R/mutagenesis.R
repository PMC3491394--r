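# Design of binding-site-abolishing mutations: greedy substitution search
# minimising the PWM match while avoiding creation of other TFs' consensus
# binding sequences (IUPAC patterns, checked on both strands in context).

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad))
    stop("invalid IUPAC code(s): ", paste(unique(bad), collapse = ", "))
  paste(vapply(chars, function(ch) {
    b <- IUPAC_CODES[[ch]]
    if (length(b) == 1L) b else paste0("[", paste(b, collapse = ""), "]")
  }, ""), collapse = "")
}

#' Match an IUPAC consensus pattern against a sequence
#'
#' TRUE iff the pattern matches at any offset of the sequence or of its
#' reverse complement.
#'
#' @param seq DNA string to search.
#' @param pattern IUPAC consensus (e.g. "WGATAR" for GATA factors).
#' @return Logical scalar.
#' @export
iupac_match <- function(seq, pattern) {
  rx <- .iupac_regex(pattern)
  seq <- toupper(seq)
  grepl(rx, seq) || grepl(rx, revcomp(seq))
}

#' Build a consensus-pattern library
#'
#' @param tf Character vector of TF names.
#' @param pattern Character vector of IUPAC patterns (length >= 4 each).
#' @return data.frame of class `consensus_library`.
#' @export
consensus_library <- function(tf, pattern) {
  stopifnot(length(tf) == length(pattern))
  pattern <- toupper(pattern)
  if (any(nchar(pattern) < 4L)) stop("IUPAC patterns must have length >= 4")
  for (p in pattern) .iupac_regex(p) # validates codes
  structure(data.frame(tf = tf, pattern = pattern, stringsAsFactors = FALSE),
            class = c("consensus_library", "data.frame"))
}

#' Read a consensus library from a 2-column TSV (tf, IUPAC pattern)
#' @param path Input file.
#' @return A `consensus_library`.
#' @export
read_consensus_library <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  consensus_library(x[[1]], x[[2]])
}

# uniform-background log-odds score of a full-width site
.site_score_uniform <- function(pwm, idx) {
  sum(log2(pwm$freq[cbind(seq_along(idx), idx)]) - log2(0.25))
}

# does seq-in-context match any library pattern (either strand)?
.hits_library <- function(site_chars, flank5, flank3, lib) {
  if (is.null(lib) || nrow(lib) == 0L) return(FALSE)
  full <- paste0(flank5, paste(site_chars, collapse = ""), flank3)
  for (p in lib$pattern) if (iupac_match(full, p)) return(TRUE)
  FALSE
}

#' Design a binding-site-abolishing mutation
#'
#' Greedy search over single-base substitutions: in each of up to `max_mut`
#' rounds, among all (position, base) substitutions at positions not yet
#' mutated, the one giving the lowest uniform-background PWM score is
#' applied, skipping any substitution whose resulting sequence-in-context
#' matches a library consensus pattern on either strand. Ties are broken in
#' favour of the higher-information-content position, then the leftmost
#' position, then the alphabetically first base. The loop stops early once
#' the minimum achievable score is reached, or when a round offers no
#' admissible score-lowering substitution (in which case `flag` is set if
#' the library blocked every candidate).
#'
#' Library entries whose `tf` equals the PWM's own name are ignored
#' (otherwise the unmutated site itself would trivially "match").
#'
#' @param site Site sequence, length equal to the PWM width.
#' @param pwm The `pwm` being abolished.
#' @param library Optional [consensus_library()] of other TFs' patterns.
#' @param flank5,flank3 Flanking context so junction-spanning library
#'   matches are caught; supply at least (longest pattern - 1) bases.
#' @param max_mut Maximum number of substitutions. Default 5.
#' @return Object of class `mutation_plan`: list with `original`, `mutated`,
#'   `positions` (1-based, in mutation order), `score_before`, `score_after`
#'   (bits, uniform background) and `flag` (TRUE if the library blocked all
#'   remaining substitutions).
#' @export
design_mutation <- function(site, pwm, library = NULL, flank5 = "",
                            flank3 = "", max_mut = 5L) {
  W <- pwm_width(pwm)
  site <- toupper(site)
  if (nchar(site) != W)
    stop(sprintf("site length %d != PWM width %d", nchar(site), W))
  idx <- .seq_to_idx(site)
  if (anyNA(idx)) stop("site must be unambiguous ACGT")
  if (!is.null(library))
    library <- library[library$tf != pwm$name, , drop = FALSE]
  ic <- information_content(pwm)
  score0 <- .site_score_uniform(pwm, idx)
  min_score <- sum(log2(apply(pwm$freq, 1L, min)) - log2(0.25))

  cur <- idx
  used <- integer(0)
  flag <- FALSE
  eps <- 1e-12
  for (round in seq_len(max_mut)) {
    if (.site_score_uniform(pwm, cur) <= min_score + eps) break
    cand <- expand.grid(pos = setdiff(seq_len(W), used), base = 1:4)
    cand <- cand[cand$base != cur[cand$pos], , drop = FALSE]
    if (nrow(cand) == 0L) break
    cand$score <- vapply(seq_len(nrow(cand)), function(k) {
      tmp <- cur
      tmp[cand$pos[k]] <- cand$base[k]
      .site_score_uniform(pwm, tmp)
    }, 0)
    # tie-breaks: lowest score, then highest-IC position, then leftmost,
    # then alphabetical base
    cand <- cand[order(cand$score, -ic[cand$pos], cand$pos, cand$base), ,
                 drop = FALSE]
    cur_score <- .site_score_uniform(pwm, cur)
    applied <- FALSE
    blocked <- FALSE
    for (k in seq_len(nrow(cand))) {
      if (cand$score[k] >= cur_score - eps) break # no lowering move left
      tmp <- cur
      tmp[cand$pos[k]] <- cand$base[k]
      if (.hits_library(DNA_BASES[tmp], flank5, flank3, library)) {
        blocked <- TRUE
        next
      }
      cur <- tmp
      used <- c(used, cand$pos[k])
      applied <- TRUE
      break
    }
    if (!applied) {
      if (blocked) flag <- TRUE
      break
    }
  }
  structure(list(original = site,
                 mutated = paste(DNA_BASES[cur], collapse = ""),
                 positions = used,
                 score_before = score0,
                 score_after = .site_score_uniform(pwm, cur),
                 flag = flag),
            class = "mutation_plan")
}

#' @export
print.mutation_plan <- function(x, ...) {
  cat(sprintf("mutation plan: %s -> %s (%d change%s, %.2f -> %.2f bits%s)\n",
              x$original, x$mutated, length(x$positions),
              if (length(x$positions) == 1L) "" else "s",
              x$score_before, x$score_after,
              if (x$flag) ", library-blocked" else ""))
  invisible(x)
}

#' Write mutation plans as TSV
#'
#' @param plans List of `mutation_plan` objects, optionally named by site id.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mutation_plans <- function(plans, path) {
  ids <- names(plans)
  if (is.null(ids)) ids <- sprintf("site_%d", seq_along(plans))
  tab <- do.call(rbind, lapply(seq_along(plans), function(i) {
    p <- plans[[i]]
    data.frame(site_id = ids[i], original = p$original, mutated = p$mutated,
               positions = paste(p$positions, collapse = ","),
               score_before = p$score_before, score_after = p$score_after,
               flag = p$flag, stringsAsFactors = FALSE)
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
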