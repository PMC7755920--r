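## Condition subtraction, distance-based CTSS clustering ("distclu"),
## dominant-TSS calling and interquantile (sharpness) widths.

#' Subtract one CTSS dataset from another
#'
#' Removes every wild-type CTSS at a (chrom, pos, strand) where the
#' mutant dataset has any tag; counts of the surviving positions are
#' unchanged.  Operates on raw counts, before normalization.
#'
#' @param wt the dataset to filter (e.g. wild type).
#' @param mutant positions present here are removed from `wt`.
#' @param sample_id label of the result; default
#'   `"<wt>_minus_<mutant>"`.
#' @return a `ctss` dataset.
#' @export
subtract_ctss <- function(wt, mutant, sample_id = NULL) {
  sample_id <- sample_id %||%
    paste0(attr(wt, "sample_id") %||% "wt", "_minus_",
           attr(mutant, "sample_id") %||% "mutant")
  w <- as.data.table(wt)
  m <- as.data.table(mutant)
  if (nrow(m) == 0L || nrow(w) == 0L) {
    out <- w
  } else {
    out <- w[!m, on = c("chrom", "pos", "strand")]
  }
  ctss_dataset(out, sample_id = sample_id)
}

#' Interquantile bounds of a per-position signal
#'
#' Scanning 5'->3' in genomic (ascending-coordinate) order, the lower
#' bound is the first position where the cumulative signal reaches
#' `q_low` of the total, the upper bound the first position where it
#' reaches `q_up`; the interquantile width is their distance + 1.
#' Widths are strand-symmetric, so genomic order is used regardless of
#' strand.
#'
#' @param pos integer positions, ascending.
#' @param signal per-position signal (e.g. TPM), same length as `pos`.
#' @param q_low,q_up quantiles, defaults 0.1 and 0.9.
#' @return list `q_low_pos`, `q_up_pos`, `iq_width`.
#' @export
interquantile_bounds <- function(pos, signal, q_low = 0.1, q_up = 0.9) {
  if (length(pos) == 0L || length(signal) != length(pos))
    stop_promarch("promarch_invalid_input",
                  "need equal-length, non-empty pos and signal")
  o <- order(pos)
  pos <- pos[o]; signal <- signal[o]
  cum <- cumsum(signal)
  total <- cum[length(cum)]
  lo <- pos[which(cum >= q_low * total - 1e-12)[1L]]
  up <- pos[which(cum >= q_up * total - 1e-12)[1L]]
  list(q_low_pos = lo, q_up_pos = up, iq_width = up - lo + 1L)
}

#' Cluster CTSSs along the chromosome (distclu)
#'
#' CTSSs below `threshold` TPM are discarded; surviving consecutive
#' positions on the same (chrom, strand) whose gap is at most `max_dist`
#' bases join one cluster (single linkage along the chromosome).
#' Single-CTSS clusters are dropped unless their signal reaches
#' `keep_singletons_above` TPM.  Each cluster records its dominant TSS
#' (argmax TPM; ties broken towards the most 5' position relative to the
#' strand) and its interquantile bounds.
#'
#' @param dataset a normalized `ctss` dataset (`tpm` present).
#' @param threshold minimal per-CTSS TPM, default 1.
#' @param max_dist maximal joining gap in bases, default 20.
#' @param keep_singletons_above TPM rescue threshold for singletons,
#'   default 5.
#' @param q_low,q_up interquantile quantiles, defaults 0.1 / 0.9.
#' @return `data.table` of tag clusters: `id`, `chrom`, `strand`,
#'   `start`, `end`, `n_ctss`, `total_tpm`, `dominant_pos`,
#'   `dominant_tpm`, `q_low_pos`, `q_up_pos`, `iq_width`.
#' @export
cluster_ctss <- function(dataset, threshold = 1, max_dist = 20L,
                         keep_singletons_above = 5, q_low = 0.1, q_up = 0.9) {
  if (!"tpm" %in% names(dataset))
    stop_promarch("promarch_state_error",
                  "dataset must be normalized before clustering (no tpm column)")
  d <- as.data.table(dataset)[tpm >= threshold]
  if (nrow(d) == 0L) return(empty_cluster_table())
  setorder(d, chrom, strand, pos)
  d[, gap := c(Inf, diff(pos)), by = .(chrom, strand)]
  d[, cluster_id := cumsum(gap > max_dist)]
  clus <- d[, {
    ib <- interquantile_bounds(pos, tpm, q_low, q_up)
    ## dominant: max tpm, tie -> most 5' w.r.t. strand
    cand <- which(tpm == max(tpm))
    dom <- if (strand[1L] == "+") cand[1L] else cand[length(cand)]
    .(chrom = chrom[1L], strand = strand[1L],
      start = pos[1L], end = pos[.N], n_ctss = .N,
      total_tpm = sum(tpm), dominant_pos = pos[dom],
      dominant_tpm = tpm[dom],
      q_low_pos = ib$q_low_pos, q_up_pos = ib$q_up_pos,
      iq_width = ib$iq_width)
  }, by = cluster_id]
  clus <- clus[n_ctss > 1L | total_tpm >= keep_singletons_above]
  if (nrow(clus) == 0L) return(empty_cluster_table())
  clus[, cluster_id := NULL]
  clus[, id := paste0("TC_", .I)]
  setcolorder(clus, c("id", "chrom", "strand", "start", "end", "n_ctss",
                      "total_tpm", "dominant_pos", "dominant_tpm",
                      "q_low_pos", "q_up_pos", "iq_width"))
  clus[]
}

empty_cluster_table <- function() {
  data.table(id = character(), chrom = character(), strand = character(),
             start = integer(), end = integer(), n_ctss = integer(),
             total_tpm = numeric(), dominant_pos = integer(),
             dominant_tpm = numeric(), q_low_pos = integer(),
             q_up_pos = integer(), iq_width = integer())
}
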