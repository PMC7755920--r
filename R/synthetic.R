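## Synthetic genomes and two-condition CTSS datasets with ground truth.
##
## The generator emulates the statistical structure the downstream
## analysis assumes: Zipf (power-law) distributed tag counts, sharp
## promoters carrying an A/T-rich W-box in their -31..-24 region, broad
## TATA-less promoters, and dual-code shifting promoters whose dominant
## TSS moves between the two conditions.  Conditions are labelled "wt"
## (the wild-type-like sample that is later subtracted) and "mutant".

SYN_CONDITIONS <- c("wt", "mutant")

#' Specify a class of synthetic promoters
#'
#' @param promoter_class one of `"sharp_wbox"`, `"broad"`, `"shifting"`.
#' @param n number of promoters of this class.
#' @param tss_spread_sd standard deviation (bases) of the discretized
#'   Gaussian spread of tag positions around the dominant TSS.  Defaults:
#'   1 (sharp_wbox), 25 (broad), 2 (shifting components).
#' @param wbox_offset_range no-zero relative interval that receives the
#'   planted W-box in `sharp_wbox` promoters; default `c(-31, -24)`.
#' @param shift_offset distance in bases (transcription direction) between
#'   the two conditions' dominant TSSs; `shifting` class only, default 50.
#' @param condition_weights length-2 fractions `(wt, mutant)`.  For
#'   `sharp_wbox` and `broad` these multiply the promoter's expression in
#'   each condition (defaults `c(1, 0)` and `c(1, 1)`); for `shifting`
#'   they are the mixture weight of the *unshifted* component in each
#'   condition (default `c(0.9, 0.1)`), expression being equal.
#' @param expression_zipf_alpha exponent (> 1) of the reverse-cumulative
#'   power law of promoter expression; default 1.9.
#' @return a `promoter_spec` list.
#' @export
promoter_spec <- function(promoter_class = c("sharp_wbox", "broad", "shifting"),
                          n,
                          tss_spread_sd = NULL,
                          wbox_offset_range = c(-31L, -24L),
                          shift_offset = 50L,
                          condition_weights = NULL,
                          expression_zipf_alpha = 1.9) {
  promoter_class <- match.arg(promoter_class)
  if (n < 0) stop_promarch("promarch_invalid_parameter", "n must be >= 0")
  tss_spread_sd <- tss_spread_sd %||%
    switch(promoter_class, sharp_wbox = 1, broad = 25, shifting = 2)
  if (tss_spread_sd < 0)
    stop_promarch("promarch_invalid_parameter", "tss_spread_sd must be >= 0")
  if (promoter_class == "broad" && tss_spread_sd < 20)
    warning("broad promoters are intended to have tss_spread_sd >= 20")
  condition_weights <- condition_weights %||%
    switch(promoter_class, sharp_wbox = c(1, 0), broad = c(1, 1),
           shifting = c(0.9, 0.1))
  if (length(condition_weights) != 2L ||
      any(condition_weights < 0) || any(condition_weights > 1))
    stop_promarch("promarch_invalid_parameter",
                  "condition_weights must be two fractions in [0,1]")
  if (expression_zipf_alpha <= 1)
    stop_promarch("promarch_invalid_parameter",
                  "expression_zipf_alpha must be > 1")
  structure(list(promoter_class = promoter_class, n = as.integer(n),
                 tss_spread_sd = tss_spread_sd,
                 wbox_offset_range = as.integer(wbox_offset_range),
                 shift_offset = as.integer(shift_offset),
                 condition_weights = condition_weights,
                 expression_zipf_alpha = expression_zipf_alpha),
            class = "promoter_spec")
}

#' Generate a random genome
#'
#' Bases are drawn i.i.d. with the requested GC content (C and G
#' equiprobable, likewise A and T).  Deterministic for a fixed seed.
#'
#' @param n_chroms number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chrom_length length of each chromosome in bases (>= 1000).
#' @param gc_content target GC fraction, strictly between 0 and 1.
#' @param seed integer RNG seed.
#' @param path optional FASTA output path.
#' @return a `DNAStringSet`.
#' @export
generate_genome <- function(n_chroms = 1L, chrom_length = 1e5L,
                            gc_content = 0.5, seed = 1L, path = NULL) {
  if (n_chroms < 1L || chrom_length < 1000L)
    stop_promarch("promarch_invalid_parameter",
                  "need n_chroms >= 1 and chrom_length >= 1000")
  if (gc_content <= 0 || gc_content >= 1)
    stop_promarch("promarch_invalid_parameter",
                  "gc_content must be strictly between 0 and 1")
  probs <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
             G = gc_content / 2, T = (1 - gc_content) / 2)
  seqs <- with_seed(seed, {
    vapply(seq_len(n_chroms), function(i) {
      paste(sample(names(probs), chrom_length, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1L))
  })
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(n_chroms))
  if (!is.null(path)) Biostrings::writeXStringSet(genome, path, width = 70L)
  genome
}

#' Plant promoters into a genome
#'
#' Lays promoters out along the chromosomes with at least `min_spacing`
#' bases between neighbouring dominant TSSs, assigns each a random
#' strand, plants an A/T 8-mer W-box (or a sample from `wbox_pwm`) into
#' the genome at `wbox_offset_range` relative to the condition-"wt"
#' dominant TSS of every `sharp_wbox` promoter, and records everything in
#' a ground-truth table.  The genome is modified only inside planted
#' motif intervals.
#'
#' @param genome a `DNAStringSet` (see [generate_genome()]).
#' @param specs a `promoter_spec` or list of them.
#' @param min_spacing minimal distance between neighbouring dominant TSSs.
#' @param seed integer RNG seed.
#' @param wbox_pwm optional base-frequency PWM (rows A,C,G,T) sampled
#'   column-wise for the planted motif instead of the uniform A/T 8-mer.
#' @param margin unused flank kept free at each chromosome end.
#' @return list with elements `genome` (modified copy) and `truth`, a
#'   `data.table` with one row per promoter: `id`, `chrom`, `strand`,
#'   `promoter_class`, `dominant_tss_wt`, `dominant_tss_mutant`,
#'   `motif_start`/`motif_end` (genomic, `NA` when no motif),
#'   `true_shift_offset`, `expected_expression_rank`, `tss_spread_sd`,
#'   `weight_wt`, `weight_mutant`, `zipf_alpha`.
#' @export
plant_promoters <- function(genome, specs, min_spacing = 1000L, seed = 1L,
                            wbox_pwm = NULL, margin = 400L) {
  if (inherits(specs, "promoter_spec")) specs <- list(specs)
  n_total <- sum(vapply(specs, function(s) s$n, integer(1L)))
  lens <- Biostrings::width(genome)
  slots_per_chrom <- pmax(0L, (lens - 2L * margin) %/% min_spacing + 1L)
  if (n_total == 0L) {
    return(list(genome = genome, truth = empty_truth(genome)))
  }
  if (sum(slots_per_chrom) < n_total)
    stop_promarch("promarch_capacity_error",
                  "genome has %d promoter slots but %d promoters requested",
                  sum(slots_per_chrom), n_total)
  ## slot coordinates: chrom index + dominant TSS position
  slot_chrom <- rep(seq_along(genome), slots_per_chrom)
  slot_pos <- unlist(lapply(seq_along(genome), function(i) {
    if (slots_per_chrom[i] == 0L) return(integer())
    margin + min_spacing * (seq_len(slots_per_chrom[i]) - 1L)
  }))
  with_seed(seed, {
    take <- seq_len(n_total)
    cls <- unlist(lapply(specs, function(s) rep(s$promoter_class, s$n)))
    sdv <- unlist(lapply(specs, function(s) rep(s$tss_spread_sd, s$n)))
    shf <- unlist(lapply(specs, function(s)
      rep(if (s$promoter_class == "shifting") s$shift_offset else 0L, s$n)))
    w1 <- unlist(lapply(specs, function(s) rep(s$condition_weights[1L], s$n)))
    w2 <- unlist(lapply(specs, function(s) rep(s$condition_weights[2L], s$n)))
    alp <- unlist(lapply(specs, function(s) rep(s$expression_zipf_alpha, s$n)))
    strand <- sample(c("+", "-"), n_total, replace = TRUE)
    truth <- data.table(
      id = paste0("prom_", seq_len(n_total)),
      chrom = names(genome)[slot_chrom[take]],
      strand = strand,
      promoter_class = cls,
      dominant_tss_wt = slot_pos[take],
      tss_spread_sd = sdv,
      true_shift_offset = shf,
      weight_wt = w1, weight_mutant = w2, zipf_alpha = alp,
      expected_expression_rank = sample(n_total)
    )
    truth[, dominant_tss_mutant :=
              dominant_tss_wt + strand_sign(strand) * true_shift_offset]
    ## plant W-boxes for sharp_wbox promoters
    truth[, c("motif_start", "motif_end") := list(NA_integer_, NA_integer_)]
    spec_idx <- rep(seq_along(specs), vapply(specs, function(s) s$n, integer(1L)))
    sharp <- which(truth$promoter_class == "sharp_wbox")
    if (length(sharp)) {
      for (i in sharp) {
        offs <- nozero_to_offset(specs[[spec_idx[i]]]$wbox_offset_range)
        motif_len <- abs(diff(offs)) + 1L
        motif <- sample_wbox(motif_len, wbox_pwm)
        tss <- truth$dominant_tss_wt[i]
        if (truth$strand[i] == "+") {
          gstart <- tss + min(offs); gend <- tss + max(offs)
          planted <- motif
        } else {
          gstart <- tss - max(offs); gend <- tss - min(offs)
          planted <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(motif)))
        }
        ci <- match(truth$chrom[i], names(genome))
        genome[[ci]] <- Biostrings::replaceAt(
          genome[[ci]], IRanges::IRanges(gstart, gend), planted)
        truth[i, c("motif_start", "motif_end") := list(gstart, gend)]
      }
    }
    setcolorder(truth, c("id", "chrom", "strand", "promoter_class",
                         "dominant_tss_wt", "dominant_tss_mutant",
                         "motif_start", "motif_end", "true_shift_offset",
                         "expected_expression_rank", "tss_spread_sd",
                         "weight_wt", "weight_mutant", "zipf_alpha"))
    setattr(truth, "conditions", SYN_CONDITIONS)
    setattr(truth, "chrom_lengths",
            stats::setNames(Biostrings::width(genome), names(genome)))
    list(genome = genome, truth = truth[])
  })
}

empty_truth <- function(genome) {
  truth <- data.table(
    id = character(), chrom = character(), strand = character(),
    promoter_class = character(), dominant_tss_wt = integer(),
    dominant_tss_mutant = integer(), motif_start = integer(),
    motif_end = integer(), true_shift_offset = integer(),
    expected_expression_rank = integer(), tss_spread_sd = numeric(),
    weight_wt = numeric(), weight_mutant = numeric(), zipf_alpha = numeric())
  setattr(truth, "conditions", SYN_CONDITIONS)
  setattr(truth, "chrom_lengths",
          stats::setNames(Biostrings::width(genome), names(genome)))
  truth[]
}

## An A/T 8-mer (W-box) or a column-wise sample from a frequency PWM.
## When the PWM is longer than the planted interval, the most informative
## run of `len` consecutive columns (highest total information content)
## is used, so the motif always fits the interval exactly.
sample_wbox <- function(len, pwm = NULL) {
  if (is.null(pwm))
    return(paste(sample(c("A", "T"), len, replace = TRUE), collapse = ""))
  freq <- sweep(pwm, 2L, colSums(pwm), "/")
  if (ncol(freq) > len) {
    ic <- apply(freq, 2L, function(f) {
      f <- f[f > 0]; 2 + sum(f * log2(f))
    })
    win_ic <- vapply(seq_len(ncol(freq) - len + 1L), function(s)
      sum(ic[s:(s + len - 1L)]), numeric(1L))
    s <- which.max(win_ic)
    freq <- freq[, s:(s + len - 1L), drop = FALSE]
  } else if (ncol(freq) < len) {
    stop_promarch("promarch_invalid_parameter",
                  "wbox PWM shorter than the planted interval")
  }
  paste(vapply(seq_len(ncol(freq)), function(j)
    sample(rownames(freq), 1L, prob = freq[, j]), character(1L)),
    collapse = "")
}

#' Sample per-position tag counts from a Zipf (power-law) distribution
#'
#' Counts have survival P(C >= x) = x^(-alpha) (x = 1, 2, ...), the law
#' whose reverse-cumulative log-log slope is -alpha, sampled by inverse
#' transform on a truncated support.  By default the inverse CDF is
#' evaluated on jittered rank strata 1..n (one uniform draw per rank),
#' which follows the law with minimal sampling noise in the tail;
#' `stratified = FALSE` gives plain i.i.d. draws.  The default truncation
#' bound, 5000 tags at one position, is half a percent of the referent
#' library of 1e6 tags — about the most a single CTSS reaches in
#' practice — and reflects that a finite genome cannot support an
#' unbounded per-position tail.
#'
#' @param n number of counts.
#' @param alpha tail exponent (> 0).
#' @param truncate upper bound on any single count, default 5000.
#' @param seed optional integer seed.
#' @param stratified jittered rank-stratified inverse CDF (default) or
#'   i.i.d. sampling.
#' @return integer vector of length `n`, all >= 1, in random order.
#' @export
rzipf_counts <- function(n, alpha, truncate = 5000L, seed = NULL,
                         stratified = TRUE) {
  if (alpha <= 0)
    stop_promarch("promarch_invalid_parameter", "alpha must be > 0")
  with_seed(seed, {
    u <- if (stratified) (seq_len(n) - runif(n)) / n else runif(n)
    counts <- pmax(1L, pmin(as.integer(floor(u^(-1 / alpha))),
                            as.integer(truncate)))
    if (stratified) counts <- sample(counts)
    counts
  })
}

#' Simulate a CTSS dataset for one condition
#'
#' Per-promoter expected totals follow the rank-based Zipf law recorded in
#' the truth table (weighted by the promoter's activity in the requested
#' condition); exactly `total_tags` tags are then distributed
#' multinomially and each tag's position is drawn from the promoter's
#' class distribution (discretized Gaussian around the dominant TSS; a
#' condition-weighted two-component mixture for shifting promoters).
#'
#' @param truth ground-truth table from [plant_promoters()].
#' @param condition `"wt"` or `"mutant"`.
#' @param total_tags total raw tag count to emit (conserved exactly).
#' @param seed integer RNG seed.
#' @return a `ctss` dataset with `sample_id = condition`.
#' @export
simulate_ctss <- function(truth, condition, total_tags, seed = 1L) {
  conds <- attr(truth, "conditions") %||% SYN_CONDITIONS
  if (!condition %in% conds)
    stop_promarch("promarch_lookup_error",
                  "unknown condition label: %s", condition)
  lens <- attr(truth, "chrom_lengths")
  if (nrow(truth) == 0L || total_tags == 0L)
    return(ctss_dataset(data.frame(), sample_id = condition))
  activity <- if (condition == conds[1L]) truth$weight_wt else truth$weight_mutant
  activity[truth$promoter_class == "shifting"] <- 1
  if (sum(activity) <= 0)
    stop_promarch("promarch_invalid_parameter",
                  "no promoter is active in condition %s", condition)
  with_seed(seed, {
    ## expected totals by jittered inverse CDF of the Zipf law on rank
    ## strata 1..n: survival exponent alpha, unbounded top stratum
    n <- nrow(truth)
    u <- (truth$expected_expression_rank - runif(n)) / n
    w <- u^(-1 / truth$zipf_alpha) * activity
    tot <- as.vector(rmultinom(1L, size = total_tags, prob = w))
    pieces <- vector("list", nrow(truth))
    mixw <- if (condition == conds[1L]) truth$weight_wt else truth$weight_mutant
    for (i in which(tot > 0L)) {
      k <- tot[i]
      sdv <- truth$tss_spread_sd[i]
      if (truth$promoter_class[i] == "shifting") {
        on_c1 <- rbinom(k, 1L, mixw[i]) == 1L
        centers <- ifelse(on_c1, truth$dominant_tss_wt[i],
                          truth$dominant_tss_mutant[i])
      } else {
        centers <- rep(truth$dominant_tss_wt[i], k)
      }
      pos <- centers + as.integer(round(rnorm(k, 0, sdv)))
      pos <- pmin(pmax(pos, 1L), lens[[truth$chrom[i]]])
      pieces[[i]] <- data.table(chrom = truth$chrom[i], pos = pos,
                                strand = truth$strand[i], count = 1L)
    }
    ctss_dataset(rbindlist(pieces), sample_id = condition)
  })
}

#' Write a synthetic ground-truth table
#' @param truth truth table from [plant_promoters()].
#' @param path output TSV path (header included).
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  fwrite(as.data.table(truth), path, sep = "\t", quote = FALSE)
  invisible(path)
}
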