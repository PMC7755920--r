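## Core-promoter sequence analysis: WW dinucleotide density maps,
## rank-sum comparisons and information-content logos.

#' WW dinucleotide occurrence map
#'
#' Marks every position `i` of each (equal-length, strand-oriented)
#' sequence where `s[i..i+1]` is an A/T dinucleotide (AA, AT, TA or TT).
#' Rows are ordered by ascending interquantile width, mirroring the
#' standard pattern-density-map layout; column means form a positional
#' enrichment track.
#'
#' @param sequences character vector of equal-length sequences.
#' @param widths interquantile widths used for the row order; default
#'   keeps the input order.
#' @return a `motif_profile` list: `occurrence` (0/1 matrix, one column
#'   per scored position, i.e. length - 1), `order` (permutation applied
#'   to the rows), `column_means`.
#' @export
ww_density <- function(sequences, widths = NULL) {
  if (length(sequences) == 0L)
    stop_promarch("promarch_invalid_input", "no sequences")
  lens <- unique(nchar(sequences))
  if (length(lens) != 1L)
    stop_promarch("promarch_invalid_input", "sequences must have equal length")
  if (lens < 2L)
    stop_promarch("promarch_invalid_input", "sequences must have length >= 2")
  ord <- if (is.null(widths)) seq_along(sequences) else order(widths)
  seqs <- toupper(sequences[ord])
  chars <- vapply(seqs, function(s) strsplit(s, "")[[1L]] %in% c("A", "T"),
                  logical(lens))
  occ <- t(chars[-lens, , drop = FALSE] & chars[-1L, , drop = FALSE]) * 1L
  structure(list(occurrence = occ, order = ord,
                 column_means = colMeans(occ)),
            class = "motif_profile")
}

#' Smooth an occurrence matrix with a separable Gaussian kernel
#'
#' Rendering aid for pattern-density heatmaps; quantitative analyses use
#' the unsmoothed occurrence matrix.
#'
#' @param profile a `motif_profile` (or plain matrix).
#' @param bw_row,bw_col kernel standard deviations (rows, columns).
#' @return a numeric matrix of the same shape.
#' @export
smooth_density_map <- function(profile, bw_row = 5, bw_col = 3) {
  m <- if (inherits(profile, "motif_profile")) profile$occurrence else profile
  blur_vec <- function(v, bw) {
    if (bw <= 0 || length(v) < 2L) return(v)
    half <- max(1L, ceiling(3 * bw))
    k <- exp(-(-half:half)^2 / (2 * bw^2))
    k <- k / sum(k)
    padded <- c(rep(v[1L], half), v, rep(v[length(v)], half))
    vapply(seq_along(v), function(i)
      sum(padded[i:(i + 2L * half)] * k), numeric(1L))
  }
  out <- t(apply(m, 1L, blur_vec, bw = bw_col))
  apply(out, 2L, blur_vec, bw = bw_row)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Midranks for ties; exact enumeration for small untied samples
#' (`n1 + n2 <= 12`), otherwise the normal approximation with
#' tie-corrected variance and continuity correction.
#'
#' @param a,b numeric samples (non-empty).
#' @return list `statistic` (rank-sum W of `a`) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop_promarch("promarch_invalid_input", "both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && (length(a) + length(b)) <= 12L
  res <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Per-position information content and base frequencies
#'
#' For equal-length oriented sequences, computes base frequencies per
#' position (ignoring `N`) and the information content
#' `IC = 2 - H` bits, `H` the Shannon entropy of the four frequencies
#' (no small-sample correction).  Positions consisting only of `N` get
#' `IC = 0` and are flagged.
#'
#' @param sequences character vector of equal-length sequences.
#' @return list `ic` (numeric, in `[0, 2]`), `freq` (4 x L matrix, rows
#'   A, C, G, T; columns sum to 1), `all_n` (logical flag per position).
#' @export
information_content_logo <- function(sequences) {
  if (length(sequences) == 0L)
    stop_promarch("promarch_invalid_input", "no sequences")
  lens <- unique(nchar(sequences))
  if (length(lens) != 1L)
    stop_promarch("promarch_invalid_input", "sequences must have equal length")
  mat <- matrix(unlist(strsplit(toupper(sequences), "")), nrow = lens)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(lens), function(j)
    table(factor(mat[j, ], levels = bases)), numeric(4L))
  rownames(counts) <- bases
  totals <- colSums(counts)
  all_n <- totals == 0
  freq <- counts
  freq[, !all_n] <- sweep(counts[, !all_n, drop = FALSE], 2L,
                          totals[!all_n], "/")
  freq[, all_n] <- 0.25
  H <- apply(freq, 2L, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  ic <- 2 - H
  ic[all_n] <- 0
  list(ic = ic, freq = freq, all_n = all_n)
}
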