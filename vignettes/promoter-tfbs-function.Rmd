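---
title: "Predicting and functionally testing TF binding sites on promoters"
author: "sitefun"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and functionally testing TF binding sites on promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitefun)
```

## Overview

`sitefun` implements an analysis pipeline for characterising the
*function* of transcription factor binding sites (TFBSs) on human
promoters. The pipeline has five stages, each a module of the package:

1. **Motif scanning** (`build_pwm`, `scan_pwm`): position weight matrix
   (PWM) scoring of promoter/peak sequences with locally-conditioned
   log-odds scores.
2. **Site prediction** (`sample_background`, `select_pwm`,
   `best_site_per_region`, `filter_predictions`): ChIP-seq peak regions
   are reduced to one candidate site each; PWMs are ranked by their
   ability to separate peaks from length-matched unbound background
   (ROC AUC); predictions are filtered on match strength and peak
   quality.
3. **Mutagenesis design** (`design_mutation`): for each predicted site,
   up to five substitutions that abolish the PWM match without creating
   a consensus site for another factor.
4. **Reporter statistics** (`normalize_plate`, `analyze_reporter`,
   `call_functions`, `summarize_calls`): replicated luciferase
   luminosities of wild-type versus mutant promoter constructs are
   turned into per-(construct, cell line) functional calls with a
   global false-discovery-rate control, and summarised per TF.
5. **Class comparison** (`site_conservation`,
   `tss_distance_distribution`, `position_ic_permutation_test`,
   `homotypic_count`, `secondary_motif_enrichment`, `normalized_cpg`):
   functional classes of sites are compared on conservation, distance
   to the transcription start site (TSS), motif information content,
   homotypic clustering and secondary-motif content.

A sixth module (`sim_config`, `simulate_study`) generates fully
synthetic studies with known ground truth, so that every stage can be
exercised and validated end to end.

## Models and statistics

### PWM scoring with local backgrounds

A PWM over width $W$ stores per-position base frequencies
$f_{j}(b)$, built from counts with a Laplace pseudocount
($f = (c + s)/(\sum_b c_b + 4s)$, default $s = 0.5$). A window
$b_1 \dots b_W$ scores

$$\mathrm{score} = \sum_{j=1}^{W} \log_2 \frac{f_j(b_j)}{q(b_j)}\,,$$

in bits, where $q$ is the background base distribution. Following the
POSSUM style of scanning, $q$ is estimated *locally*, from a 100-bp
window centred on each candidate window (clipped at the sequence ends).
This conditions match strength on local composition — important on
promoters, where GC-rich islands would otherwise dominate. The window
size matters little in practice; 100 bp is the package default and a
`bg_window` argument exposes it.

Numerical choices:

* All logarithms are base 2; scores are bits throughout.
* Local abundances are floored at $\varepsilon = 10^{-3}$; floored
  entries are held at exactly $\varepsilon$ and the remaining entries
  rescaled so the distribution sums to one. This keeps scores finite on
  skewed compositions while preserving the floor invariant exactly.
* Windows containing `N` or other ambiguity codes score $-\infty$ and
  are never reported as sites.
* Minus-strand windows are scored as the reverse complement of the
  window against the PWM, with the complemented local background; the
  resulting scores are exactly strand-symmetric.
* Ties for the best site in a region resolve leftmost-first, plus
  strand before minus.

### PWM evaluation by AUC

Candidate PWMs are compared by scanning both the peak set and a
length-matched background set sampled uniformly from unbound genomic
space (without replacement, peaks and an arbitrary exclusion set
avoided), taking the single best window per region, and computing the
area under the ROC curve. The AUC is computed exactly as the
Mann-Whitney statistic scaled to $[0,1]$, with ties counted one half —
the probability that a random peak outscores a random background
region. 0.5 is chance; 1 is perfect separation.

### Prediction filters

Two filters mirror common practice for reporter-assay candidate
selection: the PWM match must represent at least a 10-fold likelihood
ratio over background (score $\ge \log_2 10 \approx 3.32$ bits — the
published filter is phrased as a 10-fold score excess, which we read as
a likelihood ratio), and the ChIP-seq peak's reported FDR must be
strictly below 0.05.

### Mutagenesis design

The designer runs a greedy loop: in each of up to five rounds it
considers every single-base substitution at positions not already
mutated, scores the mutated site against the PWM under a *uniform*
background (the designer has no ChIP context; uniform scoring makes
plans reproducible), and applies the admissible substitution with the
lowest resulting score. A substitution is inadmissible if the mutated
sequence, read in its flanking context on either strand, matches any
IUPAC consensus pattern in a library of other TFs' binding sequences
(the PWM's own entry is excluded, since the unmutated site trivially
matches itself). Ties resolve toward the higher-information-content
position, then leftmost, then alphabetically. The loop stops early when
the minimum achievable score is reached or no score-lowering
substitution remains; if the library blocked every candidate the plan
is returned with a flag rather than an error.

Greedy search is not guaranteed to find the global optimum over all
$\le 5$-subsets; we chose it for transparency and speed, and the test
suite holds each greedy round to an exhaustive per-round argmin oracle
on small widths.

### Reporter statistics

Each construct is assayed as 3 plasmid preparations $\times$ 3
transfections per cell line, for 9 wild-type and 9 mutant wells. Wells
are normalised by the median of all signals on their plate (including
the 4 positive and 4 negative control transfections every plate
carries); the median is robust and scale-free, and any common plate
factor cancels exactly.

Mutant and wild-type normalized luminosities are compared with a
two-sided Welch (unequal-variance) $t$ test on all 9 values per group.
The replicate hierarchy (preps within transfections) is deliberately
not modelled: with three-by-three nesting there is little information
to estimate variance components, and the Welch test on the pooled
replicates is the conventional analysis for this design. Averaging
technical replicates first would discard within-prep information
without changing the effect estimate, so it is not offered.

All hypothesis tests — every construct in every cell line, plus the
negative-control and unbound-site experiment classes — form **one**
Benjamini-Hochberg family (for the full design,
$455 \times 4 + 12 + 23 = 1855$ tests). A site is called functional
when its adjusted value satisfies $q < 0.025$ (strict). Direction
follows the fold change $\log_2(I_\mathrm{MT}/I_\mathrm{WT})$: a mutant
below its wild type means the intact site *activated* transcription;
above means it *repressed*.

`summarize_calls` reports, per TF and overall: constructs tested,
functional in at least one cell line, per-cell-line counts,
ubiquitously functional constructs (functional in every assayed cell
line), and among those the consistently activating / repressing ones.
Overall rates are integer percentages; control-class rates are given to
one decimal. Constructs missing a cell line are excluded from ubiquity
counts with a warning. Cross-cell-line concordance uses the Spearman
correlation of $|\log_2$ fold change$|$ over constructs validated in at
least one cell line.

### Class comparisons

* **Conservation**: per-site mean of a per-base phyloP-like track, and
  motif-oriented per-position profiles with standard errors. The
  "normalized" score on published conservation axes is not formally
  defined; we use the plain per-site mean.
* **TSS distance**: signed distance from site midpoint to the TSS in
  transcript orientation (downstream positive); class comparisons use
  $|$distance$|$, and the cumulative $\mathbb{P}_M$ gives the
  probability of finding a site within $M$ bp of the TSS.
* **Distribution comparisons**: two-sided Kolmogorov-Smirnov by
  default (sensitive to shape, not only location), Wilcoxon rank-sum as
  an alternative; exact small-sample nulls where the underlying tests
  provide them.
* **Information-content permutation test**: per-group PWMs (pseudocount
  0.5) are built from aligned site sequences; the statistic is the IC
  difference at one position and the null is formed by shuffling group
  labels, $p = (1 + \#\{\Delta_{perm} \ge \Delta_{obs}\})/(n_{perm}+1)$
  (one-sided, default 9,999 shuffles, seeded). Groups smaller than 5
  trigger exact enumeration of label assignments when feasible.
* **Homotypic clusters**: the promoter is re-scanned with the same
  motif and threshold used for prediction; overlapping hits are
  collapsed greedily best-first (the published analyses do not state an
  overlap rule; best-first is deterministic and conservative).
* **Secondary motifs**: presence/absence of at least one hit per
  promoter, one-sided Fisher exact test for overrepresentation on
  promoters with functional sites. A score-based randomisation test is
  an alternative in the literature; Fisher on presence was chosen for
  exactness and zero tuning. A $p$ near 1 indicates
  underrepresentation.
* **CpG content**: observed CpG dinucleotide frequency over the product
  of C and G frequencies, strand-symmetric by construction.

## The synthetic study generator

`sim_config` fixes every study condition; all generation is driven by
one mandatory seed, and generator functions force their arguments
before seeding so results do not depend on lazy-evaluation order.

Defaults emulate the assayed study design:

| Parameter | Default | Meaning |
|---|---|---|
| `n_promoters` | 455 | assayed promoter constructs |
| `promoter_length` | 1000 | ~1 kb cloned fragments |
| `functional_fractions` | .49/.38/.36/.39 | per cell line (K562, HCT116, HT1080, HepG2) |
| `repressing_fraction` | 1/3 | of functional constructs |
| `effect_range` | 0.5–2 | $|\log_2$ fold effect$|$, uniform |
| `noise_cv` | 0.2 | lognormal well noise |
| `summit_sigma` | 20 bp | peak summit jitter around the site |
| `n_negative_controls` | 12 | signal-free mutation controls (K562) |
| `n_unbound` | 23 | motif matches without peaks (K562) |
| `unbound_functional_fraction` | 0.30 | functional probability of the latter |

The TSS sits near the fragment 3' end (promoters are cloned upstream of
the reporter) with the translational start 50 bp downstream. Activating
sites are planted 10–250 bp upstream of the TSS, repressing sites at
the translational start (within ±10 bp), never-functional sites
anywhere — encoding the positional biology the class comparisons are
meant to detect. Conservation tracks are Gaussian baseline noise with a
flat elevation over functional site bases. Reporter noise is
multiplicative lognormal (reporter assays are ratio-scaled); the CV of
0.2 combined with the default effect sizes yields realistic partial
power rather than a trivially easy detection problem. Functional status
is drawn independently per cell line at the configured fractions;
direction and placement are construct-level.

What the generator does **not** emulate — and hence what passing tests
do not certify about real data: correlated functional status across
cell lines (real ubiquity rates are far above the independence
expectation), CpG-island structure and non-i.i.d. background
composition, chromatin and looping context absent from transient
transfection, read-level ChIP-seq noise, and plate-position effects.

## Problem sizes and runtimes

The test suite validates every operation against independent oracles:
exhaustive pairwise AUC on all short score lists, hand-computed BH
step-up on sets up to 8, per-round exhaustive mutagenesis argmin up to
width 8, full enumeration of KS/Wilcoxon nulls at $n=m=5$, exact
permutation enumeration on tiny groups, and a 200-replicate
super-uniformity check of permutation $p$-values. End-to-end checks run
one full-size study (455 constructs, 4 cell lines, 1,855 tests) for
parameter recovery and 100 null replicates for false-positive control;
these sizes keep the default suite within a few minutes on one CPU
while matching the assayed design exactly.

## Worked example

```{r example}
cfg <- sim_config(seed = 42, n_promoters = 60)
study <- simulate_study(cfg)
meta <- unique(study$truth_cells[, c("construct_id", "class", "tf")])
calls <- analyze_reporter(study$luminosity, meta = meta)
summarize_calls(calls)
```

## Known limitations

* The likelihood-ratio reading of the published 10-fold score filter is
  a declared interpretation; the original control-set construction is
  not fully specified.
* Published secondary-motif $p$-values were produced by a score-based
  method, so Fisher-exact results are comparable in direction but not
  numerically identical.
* The Welch test ignores the prep/transfection nesting (see above);
  strongly correlated preps would make the nominal FDR optimistic.
* Internal coordinates are 1-based inclusive (R convention); all BED
  output is 0-based half-open via `rtracklayer`.
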