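# Ground-truthed synthetic inputs for the whole pipeline: promoters with
# planted motif instances, ChIP-seq-like peaks, conservation tracks, and
# nested-replicate luminosity tables with known functional structure.

#' Simulation configuration
#'
#' Defaults mirror the study design this package analyses: four cell
#' lines with per-cell-line functional fractions 0.49 / 0.38 / 0.36 /
#' 0.39, repression in one third of functional sites, ~1 kb promoters,
#' 3 prep x 3 transfection replicates, plates carrying 4 positive and 4
#' negative control wells, and multiplicative lognormal measurement noise
#' with CV 0.2.
#'
#' @param seed Integer seed (mandatory; all generation is reproducible).
#' @param n_promoters Number of assayed promoter constructs. Default 455.
#' @param promoter_length Fragment length in bp. Default 1000.
#' @param gc_content Background GC fraction. Default 0.5.
#' @param pwm_width Planted motif width. Default 12.
#' @param pwm_concentration Dirichlet concentration of the consensus base
#'   per position; larger means sharper (higher-IC) motifs. Default 8.
#' @param cell_lines Assayed cell lines.
#' @param functional_fractions Per-cell-line probability that a site is
#'   functional. Default c(0.49, 0.38, 0.36, 0.39).
#' @param repressing_fraction Fraction of functional constructs whose site
#'   represses transcription. Default 1/3.
#' @param effect_range Range of |log2 fold effect| for functional sites,
#'   drawn uniformly. Default c(0.5, 2).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal well noise. Default 0.2.
#' @param constructs_per_plate Constructs per assay plate (each plate also
#'   carries `n_pos_ctrl_wells` + `n_neg_ctrl_wells` control wells).
#' @param n_pos_ctrl_wells,n_neg_ctrl_wells Control wells per plate.
#' @param summit_sigma SD (bp) of the Gaussian jitter between the planted
#'   site centre and the reported peak summit. Default 20.
#' @param peak_halfwidth Half-width of the ChIP-seq-like peak. Default 150.
#' @param conservation_baseline_sd SD of the phyloP-like baseline noise.
#' @param conservation_elevation Added conservation over functional site
#'   bases. Default 1.5.
#' @param n_negative_controls Constructs mutated in signal-free regions
#'   (assayed in the first cell line only). Default 12.
#' @param n_unbound Constructs with a motif match but no ChIP-seq peak
#'   (first cell line only). Default 23.
#' @param unbound_functional_fraction Functional probability for unbound
#'   motif-match constructs. Default 0.30.
#' @param homotypic_probs Probabilities that a promoter carries 2 or 3
#'   homotypic copies of the planted motif. Default c(0.08, 0.03).
#' @param tss_offset_from_end TSS position, bp upstream of the fragment
#'   3' end. Default 150.
#' @param tls_offset TSS-to-translational-start distance, bp. Default 50.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_promoters = 455L,
                       promoter_length = 1000L,
                       gc_content = 0.5,
                       pwm_width = 12L,
                       pwm_concentration = 8,
                       cell_lines = c("K562", "HCT116", "HT1080", "HepG2"),
                       functional_fractions = c(0.49, 0.38, 0.36, 0.39),
                       repressing_fraction = 1 / 3,
                       effect_range = c(0.5, 2),
                       noise_cv = 0.2,
                       constructs_per_plate = 8L,
                       n_pos_ctrl_wells = 4L,
                       n_neg_ctrl_wells = 4L,
                       summit_sigma = 20,
                       peak_halfwidth = 150L,
                       conservation_baseline_sd = 0.5,
                       conservation_elevation = 1.5,
                       n_negative_controls = 12L,
                       n_unbound = 23L,
                       unbound_functional_fraction = 0.30,
                       homotypic_probs = c(0.08, 0.03),
                       tss_offset_from_end = 150L,
                       tls_offset = 50L) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(gc_content > 0, gc_content < 1,
            all(functional_fractions >= 0 & functional_fractions <= 1),
            repressing_fraction >= 0, repressing_fraction <= 1,
            unbound_functional_fraction >= 0,
            unbound_functional_fraction <= 1,
            promoter_length > 0, pwm_width < promoter_length,
            length(functional_fractions) == length(cell_lines),
            noise_cv >= 0)
  cfg <- as.list(environment())
  cfg$functional_fractions <- setNames(functional_fractions, cell_lines)
  structure(cfg, class = "sim_config")
}

# lognormal multiplier with unit mean and given CV
.ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a random high-information motif
#'
#' Per position, one consensus base receives Dirichlet weight
#' `concentration` and the others weight 1; frequencies are drawn from
#' that Dirichlet and scaled to pseudo-counts.
#'
#' @param width Motif width.
#' @param concentration Consensus sharpness (see [sim_config()]).
#' @param seed Integer seed.
#' @param name Motif name.
#' @param n_obs Pseudo-count total per position. Default 100.
#' @return A `pwm` object.
#' @export
generate_pwm <- function(width, concentration = 8, seed = 1L,
                         name = "SIM_TF", n_obs = 100) {
  set.seed(seed)
  counts <- t(vapply(seq_len(width), function(j) {
    alpha <- rep(1, 4)
    alpha[sample.int(4L, 1L)] <- concentration
    g <- stats::rgamma(4L, shape = alpha)
    round(n_obs * g / sum(g), 2)
  }, numeric(4)))
  build_pwm(counts, pseudocount = 0.5, name = name)
}

#' Generate background promoter fragments
#'
#' I.i.d. background sequences at the configured GC content. The TSS sits
#' near the fragment 3' end (promoters are cloned upstream of the
#' reporter) and the translational start lies downstream of the TSS.
#'
#' @param config A [sim_config()].
#' @return list with `sequences` (named character vector) and
#'   `annotations` (data.frame: promoter_id, strand, tss, translational
#'   start, length; coordinates are 1-based positions within the
#'   fragment).
#' @export
generate_promoters <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$promoter_length
  n <- config$n_promoters
  p <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
         G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(DNA_BASES, L, replace = TRUE, prob = p), collapse = ""),
    "")
  ids <- sprintf("prom%03d", seq_len(n))
  names(seqs) <- ids
  tss <- L - config$tss_offset_from_end
  ann <- data.frame(promoter_id = ids,
                    strand = "+",
                    tss = tss,
                    translational_start = tss + config$tls_offset,
                    length = L,
                    stringsAsFactors = FALSE)
  list(sequences = seqs, annotations = ann)
}

# draw a site sequence from the PWM frequencies
.sample_site <- function(pwm) {
  paste(vapply(seq_len(pwm_width(pwm)), function(j)
    sample(DNA_BASES, 1L, prob = pwm$freq[j, ]), ""), collapse = "")
}

.splice <- function(seq, at, insert) {
  paste0(substr(seq, 1L, at - 1L), insert,
         substr(seq, at + nchar(insert), nchar(seq)))
}

#' Plant motif instances, peaks and conservation into promoters
#'
#' One primary site per promoter, sampled from the PWM. Placement encodes
#' the biology being emulated: activating sites go near the TSS,
#' repressing sites at or near the translational start, and
#' never-functional sites anywhere on the fragment. Each site gets a
#' ChIP-seq-like peak whose summit is the site centre plus Gaussian
#' jitter, and a phyloP-like conservation track elevated over functional
#' site bases. A configurable fraction of promoters receives 2-3
#' homotypic copies.
#'
#' @param promoters Output of [generate_promoters()].
#' @param pwm Planted motif (`pwm` object).
#' @param config A [sim_config()].
#' @return list with `sequences` (sites spliced in), `truth` (per-site
#'   data.frame: construct_id, promoter_id, site_start, site_end, strand,
#'   direction, homotypic_n, functional_<cell line> flags and
#'   effect_<cell line> sizes), `truth_cells` (long per cell line),
#'   `peaks` (promoter-coordinate peak table) and `conservation` (named
#'   list of per-base tracks).
#' @export
plant_sites <- function(promoters, pwm, config) {
  stopifnot(inherits(config, "sim_config"))
  # force arguments before seeding: lazily evaluated generator calls must
  # not consume (or reset) this function's RNG stream
  seqs <- promoters$sequences
  ann <- promoters$annotations
  force(pwm)
  set.seed(config$seed + 1L)
  W <- pwm_width(pwm)
  n <- length(seqs)
  cells <- config$cell_lines
  ff <- config$functional_fractions

  func <- matrix(stats::rbinom(n * length(cells), 1L,
                               rep(ff, each = n)) == 1L,
                 nrow = n, dimnames = list(NULL, cells))
  dir_construct <- ifelse(stats::runif(n) < config$repressing_fraction,
                          "repressing", "activating")
  any_func <- rowSums(func) > 0L
  dir_construct[!any_func] <- "none"

  truth <- data.frame(construct_id = ann$promoter_id,
                      promoter_id = ann$promoter_id,
                      class = "tfbs", tf = pwm$name,
                      direction = dir_construct,
                      stringsAsFactors = FALSE)
  cons <- vector("list", n)
  names(cons) <- ann$promoter_id
  peaks <- vector("list", n)
  site_start <- integer(n)
  site_strand <- character(n)
  homotypic_n <- integer(n)

  for (i in seq_len(n)) {
    L <- ann$length[i]
    tss <- ann$tss[i]
    tls <- ann$translational_start[i]
    center <- switch(dir_construct[i],
      activating = tss - round(stats::runif(1, 10, 250)),
      repressing = tls + round(stats::rnorm(1, 0, 10)),
      none = round(stats::runif(1, W, L - W)))
    start <- round(center - W / 2)
    start <- max(1L, min(L - W + 1L, start))
    strand <- sample(c("+", "-"), 1L)
    site <- .sample_site(pwm)
    planted <- if (strand == "-") revcomp(site) else site
    seqs[i] <- .splice(seqs[i], start, planted)
    site_start[i] <- start
    site_strand[i] <- strand

    # homotypic extras, non-overlapping with the primary site
    extra <- sample(0:2, 1L, prob = c(1 - sum(config$homotypic_probs),
                                      config$homotypic_probs))
    placed <- data.frame(start = start, end = start + W - 1L)
    tries <- 0L
    while (extra > 0L && tries < 1000L) {
      tries <- tries + 1L
      st2 <- sample.int(L - W + 1L, 1L)
      if (any(placed$start <= st2 + W - 1L & placed$end >= st2)) next
      s2 <- .sample_site(pwm)
      if (stats::runif(1) < 0.5) s2 <- revcomp(s2)
      seqs[i] <- .splice(seqs[i], st2, s2)
      placed <- rbind(placed, data.frame(start = st2, end = st2 + W - 1L))
      extra <- extra - 1L
    }
    homotypic_n[i] <- nrow(placed)

    # conservation: baseline noise, elevated over the primary site when
    # functional in at least one cell line
    tr <- stats::rnorm(L, 0, config$conservation_baseline_sd)
    if (any_func[i])
      tr[start:(start + W - 1L)] <-
        tr[start:(start + W - 1L)] + config$conservation_elevation
    cons[[i]] <- tr

    # peak centred near the site with jittered summit
    mid <- start + (W - 1) / 2
    pst <- max(1L, round(mid - config$peak_halfwidth))
    pen <- min(L, round(mid + config$peak_halfwidth))
    summit <- round(mid + stats::rnorm(1, 0, config$summit_sigma)) - pst
    summit <- max(0L, min(pen - pst, summit))
    peaks[[i]] <- data.frame(chrom = ann$promoter_id[i], start = pst,
                             end = pen, name = ann$promoter_id[i],
                             summit = summit,
                             peak_fdr = 10^stats::runif(1, -4, -1.35),
                             stringsAsFactors = FALSE)
  }

  truth$site_start <- site_start
  truth$site_end <- site_start + W - 1L
  truth$strand <- site_strand
  truth$homotypic_n <- homotypic_n
  effects <- matrix(0, nrow = n, ncol = length(cells),
                    dimnames = list(NULL, cells))
  effects[func] <- stats::runif(sum(func), config$effect_range[1],
                                config$effect_range[2])
  for (cl in cells) {
    truth[[paste0("functional_", cl)]] <- func[, cl]
    truth[[paste0("effect_", cl)]] <- effects[, cl]
  }

  truth_cells <- do.call(rbind, lapply(cells, function(cl)
    data.frame(construct_id = truth$construct_id, class = "tfbs",
               tf = pwm$name, cell_line = cl,
               functional = func[, cl],
               direction = ifelse(func[, cl], dir_construct, "none"),
               effect = effects[, cl], stringsAsFactors = FALSE)))

  list(sequences = seqs, truth = truth, truth_cells = truth_cells,
       peaks = do.call(rbind, peaks), conservation = cons)
}

#' Ground truth for the control experiment classes
#'
#' Negative controls (mutations in signal-free regions; never functional
#' by construction) and unbound motif-match constructs (functional with a
#' configurable low probability), both assayed in the first configured
#' cell line only.
#'
#' @param config A [sim_config()].
#' @return Long-format truth data.frame (construct_id, class, tf,
#'   cell_line, functional, direction, effect).
#' @export
control_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  cl <- config$cell_lines[1]
  neg <- data.frame(
    construct_id = sprintf("negctrl%02d", seq_len(config$n_negative_controls)),
    class = "neg_ctrl", tf = "none", cell_line = cl,
    functional = FALSE, direction = "none", effect = 0,
    stringsAsFactors = FALSE)
  ub_func <- stats::runif(config$n_unbound) < config$unbound_functional_fraction
  ub_dir <- ifelse(ub_func,
                   ifelse(stats::runif(config$n_unbound) <
                            config$repressing_fraction,
                          "repressing", "activating"),
                   "none")
  ub <- data.frame(
    construct_id = sprintf("unbound%02d", seq_len(config$n_unbound)),
    class = "unbound", tf = "unbound_motif", cell_line = cl,
    functional = ub_func, direction = ub_dir,
    effect = ifelse(ub_func,
                    stats::runif(config$n_unbound, config$effect_range[1],
                                 config$effect_range[2]), 0),
    stringsAsFactors = FALSE)
  rbind(neg, ub)
}

#' Simulate nested-replicate reporter luminosities
#'
#' Each (construct, cell line) yields 9 WT and 9 MT wells (3 prep
#' replicates x 3 transfections). A well value is
#' construct baseline x plate factor x lognormal noise; mutant wells are
#' additionally multiplied by 2^(-effect) when the intact site activates
#' transcription (mutating it lowers the signal) and 2^(+effect) when it
#' represses. Every plate carries 4 positive and 4 negative control
#' transfections that take part in plate normalisation.
#'
#' @param truth_cells Long-format truth (construct_id, cell_line,
#'   functional, direction, effect), e.g. from [plant_sites()] plus
#'   [control_truth()].
#' @param config A [sim_config()].
#' @return Luminosity data.frame: construct_id, allele, cell_line,
#'   prep_rep, txn_rep, plate_id, raw.
#' @export
simulate_luminosity <- function(truth_cells, config) {
  stopifnot(inherits(config, "sim_config"))
  force(truth_cells) # see plant_sites: forced before seeding
  set.seed(config$seed + 3L)
  cv <- config$noise_cv
  cpp <- config$constructs_per_plate
  ids <- unique(truth_cells$construct_id)
  baselines <- setNames(stats::rlnorm(length(ids), 0, 0.5), ids)
  npos <- config$n_pos_ctrl_wells
  nneg <- config$n_neg_ctrl_wells

  blocks <- lapply(unique(truth_cells$cell_line), function(cl) {
    tc <- truth_cells[truth_cells$cell_line == cl, , drop = FALSE]
    n_c <- nrow(tc)
    grp <- ceiling(seq_len(n_c) / cpp)
    n_g <- max(grp)
    pf <- matrix(stats::rlnorm(n_g * 3L, 0, 0.3), nrow = n_g) # plate factors

    # 18 assay wells per construct: 2 alleles x 3 preps x 3 transfections
    allele <- rep(rep(c("WT", "MT"), each = 9L), n_c)
    prep <- rep(rep(rep(1:3, each = 3L), 2L), n_c)
    txn <- rep(rep(1:3, 6L), n_c)
    ci <- rep(seq_len(n_c), each = 18L)
    cid <- tc$construct_id[ci]
    eff <- tc$effect[ci]
    dir <- tc$direction[ci]
    mult <- ifelse(allele == "MT" & dir == "activating", 2^(-eff),
                   ifelse(allele == "MT" & dir == "repressing", 2^(eff), 1))
    gi <- grp[ci]
    raw <- baselines[cid] * pf[cbind(gi, txn)] * mult *
      .ln_noise(length(cid), cv)
    assay <- data.frame(construct_id = cid, allele = allele, cell_line = cl,
                        prep_rep = prep, txn_rep = txn,
                        plate_id = sprintf("%s_g%02d_t%d", cl, gi, txn),
                        raw = raw, stringsAsFactors = FALSE)

    # 4 positive + 4 negative control transfections on every plate
    nw <- npos + nneg
    pg <- rep(seq_len(n_g), each = 3L * nw)
    pt <- rep(rep(1:3, each = nw), n_g)
    well <- rep(seq_len(nw), n_g * 3L)
    is_pos <- well <= npos
    ctrl <- data.frame(
      construct_id = ifelse(is_pos, sprintf("pos%d", well),
                            sprintf("neg%d", well - npos)),
      allele = ifelse(is_pos, "pos_ctrl", "neg_ctrl"),
      cell_line = cl, prep_rep = 1L, txn_rep = pt,
      plate_id = sprintf("%s_g%02d_t%d", cl, pg, pt),
      raw = ifelse(is_pos, 5, 0.05) * pf[cbind(pg, pt)] *
        .ln_noise(length(pg), cv),
      stringsAsFactors = FALSE)
    rbind(assay, ctrl)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Run the complete synthetic study
#'
#' Promoters, motif, planted sites/peaks/conservation, control constructs
#' and the full luminosity table, all from one seed.
#'
#' @param config A [sim_config()].
#' @return list with `config`, `pwm`, `promoters`, `planted` (see
#'   [plant_sites()]), `truth_cells` (assayed constructs plus controls)
#'   and `luminosity`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pwm <- generate_pwm(config$pwm_width, config$pwm_concentration,
                      seed = config$seed, name = "SIM_TF")
  promoters <- generate_promoters(config)
  planted <- plant_sites(promoters, pwm, config)
  truth_cells <- rbind(planted$truth_cells, control_truth(config))
  lum <- simulate_luminosity(truth_cells, config)
  list(config = config, pwm = pwm, promoters = promoters,
       planted = planted, truth_cells = truth_cells, luminosity = lum)
}

#' Reconstruct a calls table from published-style summary counts
#'
#' Builds a concrete per-(construct, cell line) functional-call table
#' whose marginals match a per-TF summary of the kind printed in study
#' reports: constructs tested, functional in at least one cell line,
#' ubiquitously functional (with consistently activating / repressing
#' subcounts), and per-cell-line functional totals. The non-ubiquitous
#' functional constructs are each assigned 1-3 functional cell lines by a
#' deterministic largest-remaining-demand allocation; an error is raised
#' if the stated counts are infeasible.
#'
#' Useful for re-deriving overall rates (percent functional in >= 1 cell
#' line, per-cell-line percentages, never-functional counts) from printed
#' per-TF tables via [summarize_calls()].
#'
#' @param per_tf data.frame with columns tf, tested, func_any, ubiq,
#'   ubiq_act, ubiq_rep and one `func_<cell line>` column per cell line.
#' @param cell_lines Character vector of cell line names.
#' @return Calls data.frame (construct_id, tf, cell_line, functional,
#'   direction, log2fc, class) suitable for [summarize_calls()].
#' @export
calls_from_counts <- function(per_tf, cell_lines) {
  k <- length(cell_lines)
  out <- vector("list", 0L)
  for (r in seq_len(nrow(per_tf))) {
    tf <- per_tf$tf[r]
    tested <- per_tf$tested[r]
    func_any <- per_tf$func_any[r]
    ubiq <- per_tf$ubiq[r]
    cell_tot <- vapply(cell_lines, function(cl)
      per_tf[[paste0("func_", cl)]][r], 0)
    n_partial <- func_any - ubiq
    demand <- cell_tot - ubiq
    if (any(demand < 0) || sum(demand) < n_partial ||
        sum(demand) > n_partial * (k - 1))
      stop("infeasible counts for TF ", tf)
    # functional-cell-line matrix: rows constructs, cols cell lines
    m <- matrix(FALSE, nrow = tested, ncol = k,
                dimnames = list(NULL, cell_lines))
    if (ubiq > 0) m[seq_len(ubiq), ] <- TRUE
    if (n_partial > 0) {
      if (any(demand > n_partial)) stop("infeasible counts for TF ", tf)
      # balanced fill: cell lines in decreasing demand, each assigned to
      # the constructs with fewest cell lines so far (capacity k - 1)
      alloc <- matrix(FALSE, nrow = n_partial, ncol = k)
      for (cl in order(-demand)) {
        need <- demand[cl]
        if (need == 0) next
        rs <- rowSums(alloc)
        cand <- order(rs)
        cand <- cand[rs[cand] < k - 1]
        if (length(cand) < need) stop("allocation failed for TF ", tf)
        alloc[cand[seq_len(need)], cl] <- TRUE
      }
      if (any(rowSums(alloc) == 0)) stop("infeasible counts for TF ", tf)
      m[ubiq + seq_len(n_partial), ] <- alloc
    }
    # directions: ubiq constructs get consistent directions per the
    # stated act/rep counts; any remainder alternates (mixed direction);
    # non-ubiquitous functional calls are labelled activating
    dirs <- matrix("none", nrow = tested, ncol = k)
    dirs[m] <- "activating"
    if (ubiq > 0) {
      n_act <- per_tf$ubiq_act[r]
      n_rep <- per_tf$ubiq_rep[r]
      if (n_act + n_rep > ubiq) stop("ubiq_act + ubiq_rep > ubiq for ", tf)
      lab <- rep("mixed", ubiq)
      if (n_act > 0) lab[seq_len(n_act)] <- "activating"
      if (n_rep > 0) lab[n_act + seq_len(n_rep)] <- "repressing"
      for (i in seq_len(ubiq)) {
        dirs[i, ] <- switch(lab[i],
          activating = "activating",
          repressing = "repressing",
          mixed = c("activating", rep("repressing", k - 1)))
      }
    }
    ids <- sprintf("%s_%03d", tf, seq_len(tested))
    for (j in seq_len(k)) {
      out[[length(out) + 1L]] <- data.frame(
        construct_id = ids, tf = tf, cell_line = cell_lines[j],
        functional = m[, j],
        direction = ifelse(m[, j], dirs[, j], "none"),
        log2fc = ifelse(!m[, j], 0,
                        ifelse(dirs[, j] == "activating", -1, 1)),
        class = "tfbs", stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
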