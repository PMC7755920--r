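## Fixture builders and independent brute-force oracles.  The oracles
## deliberately avoid the code paths (and, where possible, the
## libraries) used by the implementation they check.

make_ctss <- function(chrom, pos, strand, count, tpm = NULL, id = "s") {
  df <- data.frame(chrom = chrom, pos = pos, strand = strand, count = count)
  if (!is.null(tpm)) df$tpm <- tpm
  ctss_dataset(df, sample_id = id)
}

## Brute-force O(n^2) single linkage at distance <= max_dist on one
## (chrom, strand): adjacency matrix + connected components by label
## propagation.  Returns a list of member-position sets (retained
## clusters only, applying the TPM threshold and singleton rescue).
oracle_single_linkage <- function(pos, tpm, max_dist = 20, threshold = 1,
                                  keep_singletons_above = 5) {
  keep <- tpm >= threshold
  pos <- pos[keep]; tpm <- tpm[keep]
  n <- length(pos)
  if (n == 0L) return(list())
  adj <- abs(outer(pos, pos, "-")) <= max_dist
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      m <- min(comp[nb])
      if (m < comp[i]) { comp[nb] <- m; comp[i] <- m; changed <- TRUE }
      else if (any(comp[nb] > comp[i])) { comp[nb] <- comp[i]; changed <- TRUE }
    }
    if (!changed) break
  }
  out <- lapply(split(seq_len(n), comp), function(ix) sort(pos[ix]))
  sizes <- lengths(out)
  tot <- vapply(split(tpm, comp), sum, numeric(1L))
  out[sizes > 1L | tot >= keep_singletons_above]
}

## Textbook two-sample Kolmogorov-Smirnov on expanded observation
## vectors (Numerical Recipes kstwo): D by merged scan of the two
## sorted samples, p from the asymptotic series with the Stephens
## small-sample correction.
oracle_ks2 <- function(x, y) {
  x <- sort(x); y <- sort(y)
  n1 <- length(x); n2 <- length(y)
  all_v <- sort(unique(c(x, y)))
  Fx <- vapply(all_v, function(v) sum(x <= v), numeric(1L)) / n1
  Fy <- vapply(all_v, function(v) sum(y <= v), numeric(1L)) / n2
  D <- max(abs(Fx - Fy))
  ne <- n1 * n2 / (n1 + n2)
  lam <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lam^2))
  list(D = D, p = min(1, max(0, p)))
}

## Brute-force relative PWM score of a single alignment: per-column
## frequency + pseudocount, log2 odds, explicit column loop.
oracle_pwm_score <- function(seq16, pwm, pseudocount = 0.01, bg = 0.25) {
  bases <- strsplit(toupper(seq16), "")[[1L]]
  L <- ncol(pwm)
  stopifnot(length(bases) == L)
  s <- 0; smin <- 0; smax <- 0
  for (j in seq_len(L)) {
    col <- pwm[, j] / sum(pwm[, j]) + pseudocount
    col <- col / sum(col)
    lo <- log2(col / bg)
    s <- s + lo[[bases[j]]]
    smin <- smin + min(lo)
    smax <- smax + max(lo)
  }
  100 * (s - smin) / (smax - smin)
}

## Brute-force interval merge: repeatedly join any two intervals on the
## same (chrom, strand) with start2 - end1 <= max_dist.
oracle_merge <- function(iv, max_dist = 100) {
  iv <- iv[order(iv$chrom, iv$strand, iv$start, iv$end), ]
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(iv)) {
      a <- iv[i, ]; b <- iv[i + 1L, ]
      if (a$chrom == b$chrom && a$strand == b$strand &&
          b$start - a$end <= max_dist) {
        iv$end[i] <- max(a$end, b$end)
        iv <- iv[-(i + 1L), ]
        merged <- TRUE
      } else i <- i + 1L
    }
    if (!merged) break
  }
  iv
}

## Assign each tag cluster to the nearest planted promoter (by dominant
## TSS distance on the same chrom/strand); NA when > tol away.
match_clusters_to_truth <- function(clusters, truth, tol = 100L) {
  cls <- rep(NA_character_, nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    cand <- truth[truth$chrom == clusters$chrom[i] &
                    truth$strand == clusters$strand[i], ]
    if (nrow(cand) == 0L) next
    d <- abs(cand$dominant_tss_wt - clusters$dominant_pos[i])
    j <- which.min(d)
    if (d[j] <= tol) cls[i] <- cand$promoter_class[j]
  }
  cls
}

## Small two-class planted genome reused by several tests.
sharp_broad_fixture <- function(n_sharp = 60L, n_broad = 60L, seed = 101L,
                                tags = 60000L, chrom_length = 100000L,
                                n_chroms = 2L) {
  g <- generate_genome(n_chroms, chrom_length, gc_content = 0.5,
                       seed = seed)
  pl <- plant_promoters(g, list(promoter_spec("sharp_wbox", n_sharp),
                                promoter_spec("broad", n_broad)),
                        min_spacing = 1000L, seed = seed + 1L)
  wt <- simulate_ctss(pl$truth, "wt", tags, seed = seed + 2L)
  list(genome = pl$genome, truth = pl$truth, wt = wt)
}
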