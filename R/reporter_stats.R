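# From replicate luminosities to functional calls: plate normalisation,
# Welch t tests of mutant vs wild type, one global Benjamini-Hochberg
# family, FDR < alpha calls with direction, and study-level summaries.

.validate_lum <- function(table) {
  need <- c("construct_id", "allele", "cell_line", "plate_id", "raw")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("luminosity table missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(table$raw)) || any(table$raw <= 0))
    stop("raw luminosities must be positive")
  invisible(table)
}

#' Normalise luminosities within each plate
#'
#' Every well (including the positive and negative control wells) is
#' divided by the median of all raw signals on its plate, giving
#' scale-free, plate-comparable values.
#'
#' @param table Luminosity data.frame with at least construct_id, allele,
#'   cell_line, plate_id, raw.
#' @return The table with a `normalized` column added.
#' @export
normalize_plate <- function(table) {
  .validate_lum(table)
  n_per <- table(table$plate_id)
  if (any(n_per < 2L))
    stop("plate(s) with fewer than 2 wells: ",
         paste(names(n_per)[n_per < 2L], collapse = ", "))
  med <- ave(table$raw, table$plate_id, FUN = median)
  table$normalized <- table$raw / med
  table
}

#' Welch t test of mutant versus wild-type luminosities
#'
#' Two-sided unequal-variance t test on the normalized values; the effect
#' is reported as log2(mean(mt) / mean(wt)), so negative values mean the
#' mutation lowered the signal (an activating site).
#'
#' @param wt Numeric wild-type values (typically 9: 3 preps x 3
#'   transfections).
#' @param mt Numeric mutant values.
#' @return list with `p` and `log2fc`.
#' @export
test_construct <- function(wt, mt) {
  if (length(wt) < 2L || length(mt) < 2L)
    stop("need at least 2 values per group")
  if (any(c(wt, mt) <= 0)) stop("luminosities must be positive")
  l2fc <- log2(mean(mt) / mean(wt))
  if (stats::sd(wt) == 0 && stats::sd(mt) == 0) {
    p <- if (isTRUE(all.equal(mean(wt), mean(mt)))) 1 else 0
  } else {
    p <- stats::t.test(mt, wt, var.equal = FALSE)$p.value
  }
  list(p = p, log2fc = l2fc)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric p-values in [0, 1].
#' @return Adjusted values (monotone in rank, clipped at 1), same order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call functional sites from pooled hypothesis tests
#'
#' All supplied tests (every construct x cell line, including the control
#' experiment classes) form one Benjamini-Hochberg family. A test is
#' functional iff its adjusted value is strictly below `alpha`; direction
#' follows the sign of log2fc: mutant below wild type (log2fc < 0) means
#' the intact site was activating.
#'
#' @param tests data.frame with construct_id, cell_line, p, log2fc and
#'   optionally class / tf columns (carried through).
#' @param alpha FDR threshold. Default 0.025.
#' @return The table with q, functional and direction columns added.
#' @export
call_functions <- function(tests, alpha = 0.025) {
  need <- c("construct_id", "cell_line", "p", "log2fc")
  miss <- setdiff(need, names(tests))
  if (length(miss))
    stop("tests missing columns: ", paste(miss, collapse = ", "))
  key <- paste(tests$construct_id, tests$cell_line)
  if (anyDuplicated(key))
    stop("duplicate (construct, cell line) test: ",
         key[anyDuplicated(key)])
  tests$q <- bh_adjust(tests$p)
  tests$functional <- tests$q < alpha
  tests$direction <- ifelse(!tests$functional, "none",
                            ifelse(tests$log2fc < 0, "activating",
                                   "repressing"))
  tests
}

#' Run the full reporter analysis on a luminosity table
#'
#' Plate-normalises, performs one Welch t test per (construct, cell line)
#' with both WT and MT wells, and calls function with a single global BH
#' family at `alpha`.
#'
#' @param table Luminosity data.frame (alleles WT/MT are tested; pos_ctrl /
#'   neg_ctrl wells take part in normalisation only).
#' @param meta Optional data.frame mapping construct_id to class / tf,
#'   merged into the result.
#' @param alpha FDR threshold. Default 0.025.
#' @return Calls data.frame as from [call_functions()].
#' @export
analyze_reporter <- function(table, meta = NULL, alpha = 0.025) {
  table <- normalize_plate(table)
  assay <- table[table$allele %in% c("WT", "MT"), , drop = FALSE]
  key <- paste(assay$construct_id, assay$cell_line, sep = "\r")
  groups <- split(seq_len(nrow(assay)), key)
  # vectorised Welch t test per (construct, cell line); same statistic as
  # test_construct() / stats::t.test (asserted in the test suite)
  res <- lapply(groups, function(ix) {
    wt <- assay$normalized[ix][assay$allele[ix] == "WT"]
    mt <- assay$normalized[ix][assay$allele[ix] == "MT"]
    if (length(wt) < 2L || length(mt) < 2L) return(NULL)
    m1 <- mean(mt); m2 <- mean(wt)
    v1 <- stats::var(mt); v2 <- stats::var(wt)
    n1 <- length(mt); n2 <- length(wt)
    se2 <- v1 / n1 + v2 / n2
    if (se2 == 0) {
      p <- if (isTRUE(all.equal(m1, m2))) 1 else 0
    } else {
      tstat <- (m1 - m2) / sqrt(se2)
      df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
      p <- 2 * stats::pt(-abs(tstat), df)
    }
    data.frame(construct_id = assay$construct_id[ix[1L]],
               cell_line = assay$cell_line[ix[1L]],
               p = p, log2fc = log2(m1 / m2), stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, res)
  rownames(tests) <- NULL
  if (!is.null(meta)) tests <- merge(tests, meta, by = "construct_id",
                                     sort = FALSE)
  call_functions(tests, alpha = alpha)
}

#' Summarise functional calls per TF and overall
#'
#' Counts, per TF and overall: constructs tested, functional in at least
#' one cell line, per-cell-line functional counts, ubiquitously functional
#' (all cell lines), and among those the consistently activating /
#' repressing ones. Overall rates are percentages rounded to the nearest
#' integer; control-class rates are reported to one decimal. Constructs
#' from control classes (class != "tfbs" when a class column is present)
#' are summarised separately and excluded from the main table.
#'
#' @param calls Calls data.frame with construct_id, cell_line, functional,
#'   direction and optionally tf and class columns.
#' @return list of class `call_summary`: `per_tf`, `overall` (named list),
#'   `by_n_cell_lines` (constructs functional in exactly k cell lines),
#'   `controls` (per control class: n, n functional, rate to 1 decimal).
#' @export
summarize_calls <- function(calls) {
  need <- c("construct_id", "cell_line", "functional", "direction")
  miss <- setdiff(need, names(calls))
  if (length(miss))
    stop("calls missing columns: ", paste(miss, collapse = ", "))
  if (!"class" %in% names(calls)) calls$class <- "tfbs"
  if (!"tf" %in% names(calls)) calls$tf <- "TF"

  main <- calls[calls$class == "tfbs", , drop = FALSE]
  cells <- sort(unique(main$cell_line))
  k <- length(cells)

  per_construct <- function(d) {
    # one row per construct: n cell lines assayed, n functional, direction set
    ids <- unique(d$construct_id)
    data.frame(
      construct_id = ids,
      tf = d$tf[match(ids, d$construct_id)],
      n_assayed = as.integer(table(factor(d$construct_id, ids))),
      n_func = vapply(ids, function(id)
        sum(d$functional[d$construct_id == id]), 0L),
      all_act = vapply(ids, function(id)
        all(d$direction[d$construct_id == id] == "activating"), TRUE),
      all_rep = vapply(ids, function(id)
        all(d$direction[d$construct_id == id] == "repressing"), TRUE),
      stringsAsFactors = FALSE)
  }
  pc <- per_construct(main)
  complete <- pc$n_assayed == k
  if (any(!complete))
    warning(sum(!complete),
            " construct(s) missing a cell line; excluded from ubiquity counts")

  per_cell_counts <- function(d)
    vapply(cells, function(cl)
      sum(d$functional[d$cell_line == cl]), 0L)

  per_tf <- do.call(rbind, lapply(sort(unique(pc$tf)), function(tfn) {
    sub <- pc[pc$tf == tfn, , drop = FALSE]
    d <- main[main$tf == tfn, , drop = FALSE]
    ubiq <- sub$n_func == k & sub$n_assayed == k
    row <- data.frame(tf = tfn,
                      n_tested = nrow(sub),
                      n_functional_any = sum(sub$n_func >= 1L),
                      n_ubiquitous = sum(ubiq),
                      n_ubiq_activating = sum(ubiq & sub$all_act),
                      n_ubiq_repressing = sum(ubiq & sub$all_rep),
                      stringsAsFactors = FALSE)
    cc <- per_cell_counts(d)
    for (i in seq_along(cells)) row[[paste0("n_func_", cells[i])]] <- cc[i]
    row
  }))
  rownames(per_tf) <- NULL

  ubiq_all <- pc$n_func == k & complete
  cc_all <- per_cell_counts(main)
  n_tested <- nrow(pc)
  overall <- list(
    n_tested = n_tested,
    n_functional_any = sum(pc$n_func >= 1L),
    pct_functional_any = round(100 * sum(pc$n_func >= 1L) / n_tested),
    n_never_functional = sum(pc$n_func == 0L),
    n_ubiquitous = sum(ubiq_all),
    n_ubiq_activating = sum(ubiq_all & pc$all_act),
    n_ubiq_repressing = sum(ubiq_all & pc$all_rep),
    n_func_per_cell_line = setNames(cc_all, cells),
    pct_func_per_cell_line = setNames(round(100 * cc_all / n_tested), cells))

  by_n <- setNames(vapply(k:0, function(m) sum(pc$n_func == m), 0L),
                   as.character(k:0))

  ctrl <- calls[calls$class != "tfbs", , drop = FALSE]
  controls <- if (nrow(ctrl)) {
    do.call(rbind, lapply(sort(unique(ctrl$class)), function(cl) {
      d <- ctrl[ctrl$class == cl, , drop = FALSE]
      data.frame(class = cl, n = nrow(d), n_functional = sum(d$functional),
                 pct_functional = round(100 * sum(d$functional) / nrow(d), 1),
                 stringsAsFactors = FALSE)
    }))
  } else NULL

  structure(list(per_tf = per_tf, overall = overall,
                 by_n_cell_lines = by_n, controls = controls),
            class = "call_summary")
}

#' @export
print.call_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf("functional in >=1 cell line: %d / %d (%d%%)\n",
              o$n_functional_any, o$n_tested, o$pct_functional_any))
  cat(sprintf("ubiquitously functional: %d (%d activating, %d repressing)\n",
              o$n_ubiquitous, o$n_ubiq_activating, o$n_ubiq_repressing))
  cat("per cell line (%): ",
      paste(sprintf("%s %d", names(o$pct_func_per_cell_line),
                    o$pct_func_per_cell_line), collapse = ", "), "\n")
  cat("functional in k cell lines:",
      paste(sprintf("%s:%d", names(x$by_n_cell_lines), x$by_n_cell_lines),
            collapse = " "), "\n")
  if (!is.null(x$controls)) {
    cat("control classes:\n")
    print(x$controls, row.names = FALSE)
  }
  invisible(x)
}

#' Cross-cell-line concordance of effect magnitudes
#'
#' Spearman rank correlation of |log2fc| between two cell lines, over the
#' constructs validated (functional) in at least one cell line anywhere in
#' the calls table.
#'
#' @param calls Calls data.frame (all cell lines).
#' @param cell_a,cell_b The two cell lines to compare.
#' @return Spearman correlation coefficient.
#' @export
concordance <- function(calls, cell_a, cell_b) {
  validated <- unique(calls$construct_id[calls$functional])
  a <- calls[calls$cell_line == cell_a &
               calls$construct_id %in% validated, , drop = FALSE]
  b <- calls[calls$cell_line == cell_b &
               calls$construct_id %in% validated, , drop = FALSE]
  ids <- intersect(a$construct_id, b$construct_id)
  if (length(ids) < 3L) stop("need at least 3 paired constructs")
  x <- abs(a$log2fc[match(ids, a$construct_id)])
  y <- abs(b$log2fc[match(ids, b$construct_id)])
  stats::cor(x, y, method = "spearman")
}

#' Write functional calls as TSV
#' @param calls Calls data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a luminosity or calls TSV written by this package
#' @param path Input file.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
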