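Package: promarch
Title: Promoter Architecture Analysis from CAGE Transcription Start Site Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of promoter architecture from CAGE (Cap Analysis of
    Gene Expression) transcription start site data: per-sample CTSS tables
    are subtracted between conditions, normalized to a reference power-law
    tag distribution, clustered into tag clusters with interquantile-width
    sharpness estimates, aggregated into cross-sample consensus promoters,
    profiled with a self-organising map, scored for shifting TSS usage with
    a two-sample Kolmogorov-Smirnov test under Benjamini-Hochberg FDR
    control, and characterised at the sequence level (WW dinucleotide
    density, TATA-box position weight matrix matches, information-content
    logos). A synthetic-data generator produces genomes and two-condition
    CTSS datasets with planted promoter classes (sharp promoters with a
    W-box near -30, broad TATA-less promoters, and dual-code shifting
    promoters) together with ground truth for parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pracma,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
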