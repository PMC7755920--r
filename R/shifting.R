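## Shifting-promoter detection: Kolmogorov-Smirnov comparison of the
## cumulative TSS distributions of two samples within each consensus
## cluster, with Benjamini-Hochberg FDR selection.

#' Cumulative TSS distribution within a consensus cluster
#'
#' The per-position normalized signal over `[start, end]` is accumulated
#' 5'->3' (strand-oriented: descending genomic coordinates on the minus
#' strand) and scaled so the final value is 1.
#'
#' @param consensus a single consensus row (list or 1-row data.frame with
#'   `chrom`, `strand`, `start`, `end`).
#' @param dataset a normalized `ctss` dataset.
#' @return `data.table` with `pos` (5'->3' order) and `F` (non-decreasing,
#'   ending at 1).
#' @export
cumulative_distribution <- function(consensus, dataset) {
  sig <- cluster_signal(consensus, dataset)
  if (sum(sig$tpm) <= 0)
    stop_promarch("promarch_insufficient_signal",
                  "no signal inside the consensus cluster")
  data.table(pos = sig$pos, F = cumsum(sig$tpm) / sum(sig$tpm))
}

## Dense per-position signal over the consensus span, 5'->3'.
cluster_signal <- function(consensus, dataset) {
  cc <- as.list(consensus)
  d <- as.data.table(dataset)[chrom == cc$chrom & strand == cc$strand &
                                pos >= cc$start & pos <= cc$end]
  span <- cc$start:cc$end
  tpm <- numeric(length(span))
  cnt <- numeric(length(span))
  if (nrow(d)) {
    i <- d$pos - cc$start + 1L
    tpm[i] <- d$tpm
    cnt[i] <- d$count
  }
  if (cc$strand == "-") {
    span <- rev(span); tpm <- rev(tpm); cnt <- rev(cnt)
  }
  list(pos = span, tpm = tpm, count = cnt)
}

## Asymptotic two-sample KS tail probability with the Stephens
## small-sample correction: lambda = (sqrt(n_e) + 0.12 + 0.11/sqrt(n_e)) * D,
## Q(lambda) = 2 * sum_{j>=1} (-1)^(j-1) exp(-2 j^2 lambda^2).
ks_p_value <- function(D, n1, n2) {
  if (D <= 0) return(1)
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  j <- seq_len(100L)
  p <- 2 * sum((-1)^(j - 1L) * exp(-2 * j^2 * lambda^2))
  min(1, max(0, p))
}

#' Score TSS-usage shift of one consensus cluster between two samples
#'
#' Computes the two-sample Kolmogorov-Smirnov statistic between the
#' cumulative TSS distributions of the dependent and independent samples
#' within the cluster, its asymptotic p value (effective sample size
#' from the raw tag totals in the cluster), a signed shift score (the
#' value of `F_indep - F_dep` at the position of maximal absolute
#' difference; positive when the dependent sample initiates further 3'),
#' and the strand-oriented offset between the two samples' dominant
#' TSSs.
#'
#' @param consensus a single consensus row.
#' @param dep_dataset,indep_dataset normalized `ctss` datasets (raw
#'   `count` column retained).
#' @param tpm_threshold minimal per-sample expression inside the cluster,
#'   default 3.
#' @return one-row `data.table`: `consensus_id`, `ks_D`, `p_value`,
#'   `shift_score`, `dominant_offset`, `direction` (`"5'"`, `"3'"`,
#'   `"none"`).
#' @export
score_shift <- function(consensus, dep_dataset, indep_dataset,
                        tpm_threshold = 3) {
  cc <- as.list(consensus)
  sd_ <- cluster_signal(cc, dep_dataset)
  si <- cluster_signal(cc, indep_dataset)
  if (sum(sd_$tpm) < tpm_threshold || sum(si$tpm) < tpm_threshold)
    stop_promarch("promarch_insufficient_signal",
                  "cluster %s below the TPM threshold in one sample",
                  cc$id %||% "?")
  Fd <- cumsum(sd_$tpm) / sum(sd_$tpm)
  Fi <- cumsum(si$tpm) / sum(si$tpm)
  diff_ <- Fi - Fd
  k <- which.max(abs(diff_))
  D <- abs(diff_[k])
  n1 <- sum(sd_$count); n2 <- sum(si$count)
  p <- ks_p_value(D, n1, n2)
  dom_dep <- sd_$pos[which.max(sd_$tpm)]
  dom_indep <- si$pos[which.max(si$tpm)]
  off <- strand_sign(cc$strand) * (dom_dep - dom_indep)
  data.table(consensus_id = cc$id %||% NA_character_,
             ks_D = D, p_value = p,
             shift_score = diff_[k],
             dominant_offset = off,
             direction = if (off < 0L) "5'" else if (off > 0L) "3'" else "none")
}

#' Score shifts for every consensus cluster
#'
#' Applies [score_shift()] to each consensus cluster; clusters failing
#' the expression threshold in either sample are skipped with a message.
#' BH-adjusted FDR values are appended.
#'
#' @inheritParams score_shift
#' @param consensus consensus table from [aggregate_clusters()].
#' @param verbose log skipped clusters? Default `FALSE`.
#' @return `data.table` of [score_shift()] rows plus `fdr`.
#' @export
score_shifts <- function(consensus, dep_dataset, indep_dataset,
                         tpm_threshold = 3, verbose = FALSE) {
  cc <- as.data.table(consensus)
  rows <- vector("list", nrow(cc))
  for (i in seq_len(nrow(cc))) {
    rows[[i]] <- tryCatch(
      score_shift(cc[i], dep_dataset, indep_dataset, tpm_threshold),
      promarch_insufficient_signal = function(e) {
        if (verbose) message("skipped: ", conditionMessage(e))
        NULL
      })
  }
  out <- rbindlist(rows)
  if (nrow(out)) {
    out[, fdr := bh_fdr(p_value)]
  } else {
    out <- data.table(consensus_id = character(), ks_D = numeric(),
                      p_value = numeric(), shift_score = numeric(),
                      dominant_offset = integer(), direction = character(),
                      fdr = numeric())
  }
  out[]
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment with monotonicity enforcement; adjusted values
#' are never below the raw ones.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1))
    stop_promarch("promarch_invalid_input", "p values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Select shifting promoters
#'
#' @param results table from [score_shifts()].
#' @param fdr_threshold maximal BH-FDR, default 0.01.
#' @param score_threshold minimal (exclusive) shift score, default `-Inf`
#'   so selection is FDR-only.
#' @return the selected rows.
#' @export
get_shifting_promoters <- function(results, fdr_threshold = 0.01,
                                   score_threshold = -Inf) {
  r <- as.data.table(results)
  if (nrow(r) == 0L) return(r)
  r[fdr <= fdr_threshold & shift_score > score_threshold]
}
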