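# promarch

Promoter-architecture analysis from CAGE transcription start site data.

## What it is for

CAGE (Cap Analysis of Gene Expression) maps transcription start sites
(TSSs) at single-base resolution: every observation ("CTSS") is a
genomic position on one strand with a tag count. `promarch` is for
regulatory genomicists comparing TSS usage between two conditions —
typically a wild-type library against one lacking a transcription
initiation factor — to ask which promoters depend on that factor, how
sharp their initiation is, whether they carry a TATA/W-box core
element, and whether initiation *shifts position* within shared
promoters.

The pipeline, per stage:

1. **Subtraction** — WT CTSSs at positions with any mutant tag are
   removed; the remainder is the *dependent* set, the mutant is the
   *independent* set.
2. **Power-law normalization** — each sample's reverse-cumulative tag
   count distribution `N(x) = B_s x^(−α_s)` is fitted by least squares
   over counts in [5, 1000] and mapped onto a referent law with
   α = 1.53 and total T = 10⁶ tags:
   `y = (B_s x^(−α_s) / B_r)^(−1/1.53)`, `B_r = T/ζ(1.53)`, giving
   tags-per-million comparable across libraries.
3. **Tag clustering (distclu)** — CTSSs ≥ 1 TPM, joined along the
   chromosome at gaps ≤ 20 bp, singletons rescued at ≥ 5 TPM; each
   cluster gets a dominant TSS and an interquantile width (10th–90th
   percentile of cumulative signal; small = sharp, large = broad).
4. **Consensus promoters** — per-sample clusters ≥ 3 TPM, trimmed to
   their interquantile span, merged across samples at gaps ≤ 100 bp.
5. **Expression profiling** — per-consensus, per-sample TPM matrix;
   profiles scaled to sum 1 and classified on a 3×2 self-organising
   map.
6. **Shifting promoters** — two-sample Kolmogorov–Smirnov statistic
   `D = max |F_dep − F_indep|` on the cumulative TSS distributions
   within each consensus cluster, asymptotic p with the Stephens
   correction on raw-count effective sample sizes, selection at
   Benjamini–Hochberg FDR ≤ 0.01.
7. **Core-promoter motifs** — WW (A/T) dinucleotide density over
   −250/+250, best TATA-box PWM match (relative score, consensus =
   100%) in −35/−20, information-content logo matrices for −35/+5.

A synthetic-data module generates genomes and two-condition CTSS
libraries with planted promoter classes (sharp + W-box at −31..−24,
broad TATA-less, dual-code shifting) and Zipf-distributed expression,
together with a ground-truth table, so every stage is testable by
parameter recovery.

## Worked example

```r
library(promarch)

genome  <- generate_genome(n_chroms = 1, chrom_length = 200000,
                           gc_content = 0.45, seed = 1)
specs   <- list(promoter_spec("sharp_wbox", 60),
                promoter_spec("broad", 60),
                promoter_spec("shifting", 20))
planted <- plant_promoters(genome, specs, min_spacing = 1000, seed = 2)
wt      <- simulate_ctss(planted$truth, "wt",     200000, seed = 3)
mutant  <- simulate_ctss(planted$truth, "mutant", 200000, seed = 4)

res <- run_pipeline(promarch_config(), wt, mutant, planted$genome,
                    out_dir = "demo_run")
```

```
[promarch] subtract: 8697 WT CTSS in = 948 retained + 7749 removed
[promarch] normalize: alpha_ref 1.53, T 1e+06
[promarch] cluster (dependent): 206 tag clusters
[promarch] cluster (independent): 100 tag clusters
[promarch] consensus: 140 consensus clusters
[promarch] som: 140 profiles on a 3x2 grid
[promarch] shift: 79 scored, 64 shifting at FDR <= 0.01
```

The mutant expresses only the broad promoters, so subtraction leaves
the sharp W-box promoters as the dependent set — 948 of 8,697 WT CTSS
positions survive. The dependent clusters are sharp and TATA-rich, the
independent ones broad and TATA-less:

```r
median(res$clusters$dependent$iq_width)    # 8
median(res$clusters$independent$iq_width)  # 64
median(res$motifs$dependent$tata)          # 56.2  (% of best possible TBP-PWM match)
median(res$motifs$independent$tata)        # 51.6
nrow(res$shifting)                         # 64 shifting promoters at FDR <= 0.01
```

Interquantile width is in bases (10th–90th percentile of cluster
signal): the factor-dependent promoters initiate within ~8 bp while the
independent ones spread over ~64 bp. The TATA match is the best
relative PWM score upstream (−35/−20) of each dominant TSS; the planted
W-boxes raise the dependent median. The shifting promoters are
dominated by the 20 planted dual-code promoters plus broad regions
whose WT-private residual positions differ from the mutant's
distribution after subtraction.

Every stage writes a TSV (plus BED for clusters) into `out_dir`,
together with `manifest.json` recording the config, seeds and MD5
checksums of all inputs and outputs. A thin CLI wrapper for shell use
lives at `inst/scripts/promarch.R` (subcommands `simulate`, `run-all`).

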