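## Cross-sample consensus promoters and the expression matrix.

#' Aggregate per-sample tag clusters into consensus promoters
#'
#' Clusters with `total_tpm` below `tpm_threshold` are discarded, the
#' survivors are trimmed to their interquantile span
#' `[q_low_pos, q_up_pos]`, and the trimmed intervals from all samples
#' are merged on the same (chrom, strand) whenever the gap between them
#' (next start minus previous end) is at most `max_dist` bases.
#' Consensus bounds are the union of the merged members, so aggregation
#' is idempotent.
#'
#' @param cluster_list named list of per-sample cluster tables from
#'   [cluster_ctss()].
#' @param tpm_threshold minimal cluster TPM, default 3.
#' @param max_dist maximal merging gap in bases, default 100.
#' @return `data.table` of consensus clusters: `id`, `chrom`, `strand`,
#'   `start`, `end`.
#' @export
aggregate_clusters <- function(cluster_list, tpm_threshold = 3,
                               max_dist = 100L) {
  if (inherits(cluster_list, "data.frame")) cluster_list <- list(cluster_list)
  pooled <- rbindlist(lapply(cluster_list, function(cl) {
    cl <- as.data.table(cl)[total_tpm >= tpm_threshold]
    cl[, .(chrom, strand, start = q_low_pos, end = q_up_pos)]
  }))
  if (nrow(pooled) == 0L)
    return(data.table(id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer()))
  gr <- GenomicRanges::GRanges(pooled$chrom,
                               IRanges::IRanges(pooled$start, pooled$end),
                               strand = pooled$strand)
  ## reduce() merges ranges whose gap is < min.gapwidth; gap here is
  ## (next start - previous end - 1), so min.gapwidth = max_dist merges
  ## exactly when next_start - prev_end <= max_dist.
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_dist)
  out <- data.table(chrom = as.character(GenomicRanges::seqnames(red)),
                    strand = as.character(GenomicRanges::strand(red)),
                    start = GenomicRanges::start(red),
                    end = GenomicRanges::end(red))
  setorder(out, chrom, strand, start)
  out[, id := paste0("CC_", .I)]
  setcolorder(out, c("id", "chrom", "strand", "start", "end"))
  out[]
}

#' Per-consensus, per-sample expression and dominant TSSs
#'
#' Each entry is the sum of the sample's normalized signal at every CTSS
#' inside the consensus bounds (strand-matched) — all signal in the
#' region counts, not only member-cluster signal.  The per-sample
#' dominant TSS is the argmax position within bounds, `NA` when the
#' sample has no signal there.
#'
#' @param consensus consensus table from [aggregate_clusters()].
#' @param datasets named list of normalized `ctss` datasets.
#' @return list with `expression` (matrix clusters x samples, TPM),
#'   `dominant_pos` (same shape, integer positions with `NA` for no
#'   signal), and `raw_count` (same shape, raw tag totals).
#' @export
expression_matrix <- function(consensus, datasets) {
  cc <- as.data.table(consensus)
  samples <- names(datasets)
  n <- nrow(cc)
  expr <- matrix(0, n, length(samples),
                 dimnames = list(cc$id, samples))
  dom <- matrix(NA_integer_, n, length(samples),
                dimnames = list(cc$id, samples))
  rawc <- matrix(0, n, length(samples), dimnames = list(cc$id, samples))
  cc2 <- cc[, .(chrom, strand, start, end)]
  cc2[, idx := .I]
  setkey(cc2, chrom, strand, start, end)
  for (s in samples) {
    d <- as.data.table(datasets[[s]])
    if (nrow(d) == 0L) next
    d2 <- d[, .(chrom, strand, p1 = pos, p2 = pos, pos, tpm, count)]
    ov <- foverlaps(d2, cc2, by.x = c("chrom", "strand", "p1", "p2"),
                    type = "within", nomatch = NULL)
    if (nrow(ov) == 0L) next
    agg <- ov[, .(tpm = sum(tpm), count = sum(count),
                  dom = pos[which.max(tpm)]), by = idx]
    expr[agg$idx, s] <- agg$tpm
    rawc[agg$idx, s] <- agg$count
    dom[agg$idx, s] <- agg$dom
  }
  list(expression = expr, dominant_pos = dom, raw_count = rawc)
}

#' Subset clusters by annotation intervals
#'
#' Keeps clusters whose dominant TSS lies inside any of the regions
#' (strand-agnostic by default).
#'
#' @param clusters table with `chrom`, `dominant_pos` (and `strand`).
#' @param regions intervals with `chrom`, `start`, `end` (1-based
#'   inclusive; see [read_bed()]), optionally `strand`.
#' @param match_strand also require matching strand? Default `FALSE`.
#' @return the retained rows of `clusters`.
#' @export
subset_by_regions <- function(clusters, regions, match_strand = FALSE) {
  cl <- as.data.table(clusters)
  rg <- as.data.table(regions)
  if (nrow(rg) == 0L || nrow(cl) == 0L) return(cl[0L])
  q <- GenomicRanges::GRanges(cl$chrom,
                              IRanges::IRanges(cl$dominant_pos, cl$dominant_pos),
                              strand = if (match_strand) cl$strand else "*")
  s <- GenomicRanges::GRanges(rg$chrom, IRanges::IRanges(rg$start, rg$end),
                              strand = if (match_strand && "strand" %in% names(rg))
                                rg$strand else "*")
  hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(q, s)))
  cl[sort(hit)]
}
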