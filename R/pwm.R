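## Position weight matrices: JASPAR text parsing and relative-score
## scanning.

#' Read a JASPAR-format matrix
#'
#' Accepts the JASPAR text dialects
#' `>ID name` followed by four lines `A [ 1 2 3 ]` ... `T [ ... ]`, or
#' four bare rows of numbers in A, C, G, T order.
#'
#' @param path file path.
#' @return numeric matrix 4 x L with rownames A, C, G, T and attribute
#'   `source` (the header line, if any).
#' @export
read_jaspar <- function(path) {
  if (!file.exists(path))
    stop_promarch("promarch_io_error", "PWM file not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  src <- NULL
  if (length(lines) && startsWith(lines[1L], ">")) {
    src <- sub("^>\\s*", "", lines[1L])
    lines <- lines[-1L]
  }
  if (length(lines) < 4L)
    stop_promarch("promarch_parse_error", "JASPAR matrix needs 4 base rows")
  rows <- lapply(lines[1:4], function(l) {
    l <- sub("^[ACGTacgt]", "", l)
    l <- gsub("[][]", " ", l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
  })
  len <- unique(lengths(rows))
  if (length(len) != 1L || len < 1L)
    stop_promarch("promarch_parse_error", "JASPAR rows have unequal lengths")
  m <- do.call(rbind, rows)
  rownames(m) <- c("A", "C", "G", "T")
  if (any(m < 0) || anyNA(m))
    stop_promarch("promarch_parse_error", "PWM entries must be >= 0")
  attr(m, "source") <- src
  m
}

#' The packaged TBP (TATA-box) matrix
#'
#' The JASPAR TBP count matrix (MA0108.2) shipped with the package as a
#' JASPAR-text fixture.
#'
#' @return 4 x 15 count matrix.
#' @export
tbp_pwm <- function() {
  read_jaspar(system.file("extdata", "MA0108.2.jaspar",
                          package = "promarch", mustWork = TRUE))
}

## Log-odds matrix from counts or frequencies: pseudocount per cell,
## column-normalized, log2 against the background.
pwm_log_odds <- function(pwm, pseudocount = 0.01,
                         background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  f <- sweep(pwm, 2L, colSums(pwm), "/")
  f <- f + pseudocount
  f <- sweep(f, 2L, colSums(f), "/")
  log2(f / background)
}

#' Relative PWM match scores along a sequence
#'
#' Log-odds scoring with pseudocount-regularized frequencies against a
#' background, rescaled per start to
#' `100 * (S - S_min) / (S_max - S_min)` where `S_min`/`S_max` are the
#' minimal/maximal scores attainable over the motif length; the PWM
#' consensus therefore scores 100 and the per-column worst sequence 0.
#' `N` bases contribute their background-expected column score.
#'
#' @param sequence a character string (may contain `N`).
#' @param pwm 4 x L count or frequency matrix, rows A, C, G, T.
#' @param pseudocount per-cell pseudocount, default 0.01.
#' @param background base background frequencies, default uniform.
#' @return numeric vector of length `nchar(sequence) - L + 1`, values in
#'   `[0, 100]`.
#' @export
pwm_relative_scores <- function(sequence, pwm, pseudocount = 0.01,
                                background = c(A = 0.25, C = 0.25,
                                               G = 0.25, T = 0.25)) {
  L <- ncol(pwm)
  n <- nchar(sequence)
  if (n < L)
    stop_promarch("promarch_invalid_input",
                  "sequence (%d nt) shorter than motif (%d nt)", n, L)
  lo <- pwm_log_odds(pwm, pseudocount, background)
  s_max <- sum(apply(lo, 2L, max))
  s_min <- sum(apply(lo, 2L, min))
  expected <- colSums(lo * background)   # score of an N base per column
  base <- strsplit(toupper(sequence), "")[[1L]]
  idx <- match(base, c("A", "C", "G", "T"))
  n_starts <- n - L + 1L
  scores <- numeric(n_starts)
  for (start in seq_len(n_starts)) {
    cols <- seq_len(L)
    b <- idx[start + cols - 1L]
    contrib <- ifelse(is.na(b), expected[cols], lo[cbind(b, cols)])
    scores[start] <- sum(contrib)
  }
  100 * (scores - s_min) / (s_max - s_min)
}

#' Best TATA-box PWM match upstream of each dominant TSS
#'
#' Extracts the strand-oriented window (default -35..-20, 16 bases under
#' the no-zero convention) upstream of every cluster's dominant TSS and
#' reports the best relative PWM score over all starts where the motif
#' fits fully inside the window.  Off-contig windows are N-padded.
#'
#' @param clusters cluster table with `chrom`, `strand`, `dominant_pos`.
#' @param genome a `DNAStringSet` or FASTA path.
#' @param pwm PWM matrix; default the packaged TBP matrix.
#' @param window no-zero relative interval, default `c(-35, -20)`.
#' @param pseudocount,background passed to [pwm_relative_scores()].
#' @return numeric vector, one best score (percent) per cluster.
#' @export
best_tata_match <- function(clusters, genome, pwm = tbp_pwm(),
                            window = c(-35L, -20L), pseudocount = 0.01,
                            background = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25)) {
  cl <- as.data.table(clusters)
  genome <- as_genome(genome)
  upstream <- -min(window)
  win_len <- abs(diff(nozero_to_offset(window))) + 1L
  vapply(seq_len(nrow(cl)), function(i) {
    s <- fetch_window(genome, cl$chrom[i], cl$dominant_pos[i], cl$strand[i],
                      upstream = upstream, downstream = 0L)
    s <- substr(s, 1L, win_len)
    max(pwm_relative_scores(s, pwm, pseudocount, background))
  }, numeric(1L))
}
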