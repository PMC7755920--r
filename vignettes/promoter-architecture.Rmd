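---
title: "Promoter architecture from CAGE CTSS data: methods and design"
author: "promarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter architecture from CAGE CTSS data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

CAGE (Cap Analysis of Gene Expression) maps transcription start sites
(TSSs) at single-base resolution: each observation is a CTSS — a genomic
position on one strand with a tag count. Comparing two conditions (for
example a wild-type sample against a knockout for a general
transcription factor) at CTSS resolution answers questions that
gene-level expression cannot: does the machinery prefer *sharp*
promoters, where initiation concentrates on one or a few bases, or
*broad* ones spreading over ~100 bp? Are sharp promoters driven by an
upstream A/T-rich element (a TATA box or TATA-like "W-box" near −30)?
And within a single promoter region, does the *position* of initiation
shift between conditions, revealing two co-existing sequence codes?

`promarch` implements this analysis as a reusable pipeline: condition
subtraction, power-law normalization, distance-based tag clustering
with interquantile-width sharpness, consensus promoters, SOM expression
profiling, Kolmogorov–Smirnov shift detection, and core-promoter
sequence analysis — plus a synthetic-data generator with recorded
ground truth, so that every stage can be tested for parameter recovery.

## Coordinate conventions

CTSS positions are 1-based. Relative coordinates around a TSS use the
no-zero convention: the TSS base is +1 and the first upstream base is
−1, so a −35/−20 window contains 16 bases and a −250/+250 window 500.
Minus-strand windows are reverse-complemented. Interquantile widths are
computed in genomic coordinate order on both strands (widths are
strand-symmetric); dominant TSSs and sequence windows are strand-aware.
BED output is 0-based half-open.

## Normalization to a referent power law

CAGE tag counts per position are approximately power-law distributed:
the reverse cumulative $N(x)$ (number of positions with count $\ge x$)
is close to linear in log–log space. `normalize_power_law()` fits a
least-squares line to $(\log_{10} x, \log_{10} N(x))$ over counts in
$[5, 1000]$ (evaluated at the distinct observed values with
$N(x) > 0$) and maps each raw count $x$ onto the referent law with
slope $\alpha_{\mathrm{ref}} = 1.53$ and total
$T = 10^6$ tags:

$$ y = \left( \frac{B_s\, x^{-\alpha_s}}{B_r} \right)^{-1/\alpha_{\mathrm{ref}}},
\qquad B_r = \frac{T}{\zeta(\alpha_{\mathrm{ref}})}, $$

where $B_s = 10^{\mathrm{intercept}}$ and $\alpha_s$ come from the
sample fit and $\zeta$ is the Riemann zeta function (the choice of
$B_r$ makes the referent's total tag count exactly $T$, since
$\sum_{x \ge 1} N_r(x) = T$). This is the unique monotone map equating
the two reverse-cumulative laws, and it is testable by refitting: the
normalized values must show slope 1.53. Equal raw counts map to equal
TPM and ranking is preserved. If fewer than two distinct counts fall in
the fit range the function falls back to plain tags-per-million
($x \cdot 10^6/\text{total}$) with a warning.

Two practical notes. First, the refit and total-TPM contracts are
statements about a library whose size is comparable to the referent
scale: $B_r \approx 4\times10^5$ positions, about $10^6$ tags. The
package's own verification therefore uses a Zipf sample of 575,000
positions (~$10^6$ tags). Second, an unbounded Pareto tail makes the
total-TPM sum dominated by the single largest count; the generator
truncates per-position counts at 5,000 by default — half a percent of
the referent library, about the most a single CTSS reaches in practice
— reflecting that a finite genome and library cannot support an
unbounded per-position tail.

## Subtraction, clustering and sharpness

To isolate the promoters that depend on the factor of interest, every
wild-type CTSS at a (chrom, pos, strand) where the mutant has any tag
is removed (`subtract_ctss()`, raw counts, before normalization); the
result is the *dependent* set and the mutant passes through as the
*independent* set. Whether "present in the mutant" should tolerate a
higher count floor is exposed as the caller's choice of input
filtering; the default is any tag ($\ge 1$).

`cluster_ctss()` implements distance-based clustering ("distclu"):
CTSSs below 1 TPM are discarded, surviving neighbours on the same
(chrom, strand) with gaps $\le 20$ bases join one cluster, and
single-CTSS clusters are dropped unless they reach 5 TPM. The dominant
TSS is the argmax-TPM position; ties break towards the most 5′ position
relative to the strand — the method text of clustering tools is
typically silent here, and a deterministic rule is required for
reproducible sequence windows. The interquantile width spans the
positions where cumulative cluster signal crosses 10% and 90% of the
total (scanning in ascending genomic order): small widths are "sharp"
promoters, large ones "broad".

## Consensus promoters, expression and the SOM

Per-sample clusters with $\ge 3$ TPM are trimmed to their interquantile
span and merged across samples when the gap between trimmed intervals
is at most 100 bases (`aggregate_clusters()`; merging is idempotent).
Consensus expression (`expression_matrix()`) counts *all* CTSS signal
within the consensus bounds, not only member-cluster signal — this is
robust to per-sample cluster fragmentation and is also what shift
scoring needs.

`som_profiles()` classifies promoter activity profiles: clusters
reaching 3 TPM in at least one sample (mirroring the single-sample
clustering threshold) are scaled to sum 1 and mapped onto a 3×2
self-organising map — online training with a Gaussian neighbourhood,
learning rate and radius decaying linearly, $100 n$ iterations, fixed
seed. The map is implemented directly in the package (it is ~40 lines
and the training schedule is part of the package's contract). Which of
the six nodes are the "downregulated" and "upregulated" groups is a
post-hoc label: `label_som_groups()` picks the nodes whose prototypes
put maximal weight on the first and second sample respectively, and
reports them as labels rather than hard-coding node indices.

## Shifting promoters

For each consensus cluster expressed at $\ge 3$ TPM in both samples,
the cumulative TSS distributions $F_{\mathrm{dep}}$ and
$F_{\mathrm{indep}}$ are accumulated 5′→3′ across the cluster and
compared with the two-sample Kolmogorov–Smirnov statistic
$D = \max |F_{\mathrm{dep}} - F_{\mathrm{indep}}|$. The p value is the
asymptotic KS tail with the Stephens small-sample correction,
$\lambda = (\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e})\,D$ with
$n_e = n_1 n_2/(n_1+n_2)$; effective sample sizes use *raw* tag counts
in the cluster, not TPM, because p values need counts. Selection is by
Benjamini–Hochberg FDR $\le 0.01$ with the score threshold at
$-\infty$, i.e. FDR-only. The signed shift score (cumulative
difference at the argmax position, positive when the dependent sample
initiates further 3′) and the strand-oriented offset between the two
samples' dominant TSSs are reported but never gate selection. On
discretized (tied) data the asymptotic p value is conservative, which
is the safe direction for FDR control.

## Core-promoter sequence analysis

* `ww_density()` marks A/T dinucleotides (AA/AT/TA/TT) along
  strand-oriented −250/+250 windows centred on dominant TSSs, rows
  ordered by ascending interquantile width; quantitative tests run on
  the unsmoothed 0/1 matrix (`smooth_density_map()` exists for
  rendering only).
* `pwm_relative_scores()` scores log-odds PWM matches with a 0.01
  pseudocount per cell against a uniform background, rescaled so the
  consensus scores 100% and the per-column-worst sequence 0%; `N`
  bases contribute their background-expected column score.
  `best_tata_match()` takes the maximum over all full-motif starts in
  the −35/−20 window (16 bases) upstream of each dominant TSS; the
  per-set median is the summary statistic. The packaged TBP matrix
  (JASPAR MA0108.2) ships as a JASPAR-text fixture so no download is
  ever needed; any JASPAR-format matrix is accepted.
* `wilcoxon_rank_sum()` compares match or width distributions
  (two-sided; exact for small untied samples, tie-corrected normal
  approximation with continuity correction otherwise).
* `information_content_logo()` computes per-position base frequencies
  and information content $2 - H$ bits over −35/+5 windows, with no
  small-sample correction; all-`N` positions are flagged and reported
  as 0.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with recorded ground truth (`plant_promoters()` returns a truth table
with every planted coordinate, class, shift offset and expression
rank):

* **Zipf expression.** Per-promoter expected totals follow a Zipf law
  with reverse-cumulative exponent $\alpha$ (default 1.9), sampled by
  jittered inverse CDF on rank strata $1..n$; exactly the requested
  number of tags is then distributed multinomially, so tag totals are
  conserved to the tag.
* **Position spread.** Tag positions are discretized Gaussians around
  the dominant TSS — the field characterises architectures only as
  sharp vs broad, so the spreads are free configuration, defaulting to
  sd 1 (sharp) and sd 25 (broad).
* **W-box.** Sharp promoters receive a random 8-mer over {A, T}
  written into −31..−24 relative to the wild-type dominant TSS
  (strand-aware); optionally the motif is sampled column-wise from a
  supplied PWM (using its most informative window of matching length).
  A "7 bp" description of this element co-exists in the literature
  with the 8-position interval −31..−24; the interval is taken as
  authoritative.
* **Shifting promoters.** Two Gaussian components separated by the
  shift offset (default 50 bases, transcription direction); each
  condition draws from a mixture with weight 0.9 on its own component,
  so per-condition dominant TSSs differ by exactly the offset.
* **Conditions.** `condition_weights` multiply expression per condition
  for sharp/broad classes (sharp defaults to wild-type-only, broad to
  both — so subtraction removes broad promoters and retains sharp
  ones, as in a factor-dependent library); for the shifting class they
  are the mixture weights, with equal expression.
* Strand is uniform per promoter, to exercise strand-orientation code
  everywhere.

What the generator does *not* emulate: read-level artifacts (mapping
errors, the reverse-transcriptase G addition), carrier chemistry,
sequence-dependent biases, correlated biological replicates, or
genome-scale promoter counts. Passing recovery tests therefore shows
the pipeline is correct and well-calibrated on data with the assumed
statistical structure, not that it reproduces any particular
genome-scale result on real libraries.

## Numerical choices and degenerate inputs

* Reverse-cumulative fits use distinct observed values with
  $N(x) > 0$; $\zeta(1.53)$ is computed numerically once and cached.
* A per-position count law can only be observed over the range its
  generative scales support: with 1,000 promoters and $10^6$ tags the
  [5, 1000] window lies inside that range for spreads around sd 10,
  which the generator's slope-recovery test uses.
* Windows reaching past contig ends are N-padded rather than erroring,
  so genome-edge promoters do not abort batch runs.
* Empty datasets, all-equal counts (degenerate fit), zero-signal
  clusters and single-profile SOM inputs raise typed conditions
  (`promarch_*` classes) or fall back with a warning where a fallback
  is well-defined.
* Problem sizes in the package's own verification: 575,000-position
  normalization libraries, 1,000 random clustering instances, 500+500
  planted promoters, 200 shifted + 800 null consensus clusters (10
  null replicates), 20 seeded SOM runs.

## Reproducibility

All stochastic stages take explicit seeds and restore the caller's RNG
state. `run_pipeline()` writes every stage table, logs record counts,
and emits a JSON manifest with the config snapshot (overrides flagged),
seeds, and MD5 checksums of inputs and outputs; deterministic stages
are bit-reproducible and stochastic ones reproduce given the recorded
seeds. A thin command-line wrapper
(`system.file("scripts", "promarch.R", package = "promarch")`) exposes
`simulate` and `run-all`; everything else is the R API.

## Known limitations

* The shift score's exact formula in existing CAGE toolchains is not
  published; the signed-cumulative-difference definition here is this
  package's own, and selection deliberately does not depend on it.
* Equivalence with any specific external implementation of power-law
  normalization is not claimed; the refit contract is the definition.
* Shift detection handles exactly two samples.
* The SOM grid is small (3×2) by design; it classifies profile shapes,
  it does not test differential expression.
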