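## CTSS table, FASTA window and BED input/output.
##
## Coordinate conventions used throughout the package:
##   * CTSS positions are 1-based (the common CAGE 4-column dialect).
##   * BED output is 0-based half-open.
##   * Relative coordinates around a TSS use the no-zero convention:
##     the TSS base is +1, the first upstream base is -1; a -U/+D window
##     therefore contains exactly U + D bases.

#' Construct a CTSS dataset
#'
#' Canonicalizes a table of CAGE transcription start sites: one row per
#' (chrom, pos, strand) with a positive raw tag count, duplicates summed,
#' rows sorted by (chrom, strand, pos).  An optional `tpm` column carries
#' normalized tags-per-million values.
#'
#' @param x data.frame with columns `chrom`, `pos`, `strand`, `count` and
#'   optionally `tpm`.
#' @param sample_id label attached to the dataset.
#' @return a `data.table` of class `ctss` with attribute `sample_id`.
#' @export
ctss_dataset <- function(x, sample_id = "sample") {
  dt <- as.data.table(x)
  if (nrow(dt) == 0L) {
    dt <- data.table(chrom = character(), pos = integer(),
                     strand = character(), count = integer())
  }
  required <- c("chrom", "pos", "strand", "count")
  if (!all(required %in% names(dt)))
    stop_promarch("promarch_parse_error",
                  "CTSS table must have columns chrom, pos, strand, count")
  dt[, chrom := as.character(chrom)]
  dt[, pos := as.integer(pos)]
  dt[, strand := as.character(strand)]
  dt[, count := as.integer(count)]
  if (nrow(dt) > 0L) {
    if (!all(dt$strand %in% c("+", "-")))
      stop_promarch("promarch_parse_error", "strand must be '+' or '-'")
    if (anyNA(dt$pos) || anyNA(dt$count) || any(dt$count < 1L))
      stop_promarch("promarch_parse_error", "counts must be integers >= 1")
    has_tpm <- "tpm" %in% names(dt)
    if (has_tpm) {
      dt <- dt[, .(count = sum(count), tpm = sum(tpm)),
               by = .(chrom, pos, strand)]
    } else {
      dt <- dt[, .(count = sum(count)), by = .(chrom, pos, strand)]
    }
    setorder(dt, chrom, strand, pos)
  }
  setattr(dt, "sample_id", sample_id)
  setattr(dt, "class", c("ctss", class(dt)))
  dt[]
}

#' Total raw tag count of a CTSS dataset
#' @param dataset a `ctss` dataset.
#' @return integer sum of raw counts.
#' @export
total_raw <- function(dataset) sum(as.numeric(dataset$count))

#' Read a CTSS table
#'
#' Reads the 4-column tab-separated CTSS dialect
#' `chrom<TAB>pos<TAB>strand<TAB>count` (optionally a 5th `tpm` column),
#' positions 1-based, no header.  Duplicate (chrom, pos, strand) rows are
#' summed; output is sorted.
#'
#' @param path file path.
#' @param sample_id label for the dataset (defaults to the file name).
#' @return a `ctss` dataset.
#' @export
read_ctss <- function(path, sample_id = NULL) {
  if (!file.exists(path))
    stop_promarch("promarch_io_error", "CTSS file not found: %s", path)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(ctss_dataset(data.frame(), sample_id = sample_id))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop_promarch("promarch_parse_error",
                  "line %d: expected at least 4 tab-separated fields",
                  which(nf < 4L)[1L])
  mat <- vapply(fields, function(f) f[1:4], character(4L))
  strand <- mat[3L, ]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop_promarch("promarch_parse_error",
                  "line %d: malformed strand '%s'", bad[1L], strand[bad[1L]])
  pos <- suppressWarnings(as.integer(mat[2L, ]))
  bad <- which(is.na(pos))
  if (length(bad))
    stop_promarch("promarch_parse_error",
                  "line %d: non-integer position '%s'", bad[1L], mat[2L, bad[1L]])
  cnt <- suppressWarnings(as.integer(mat[4L, ]))
  bad <- which(is.na(cnt) | cnt < 1L)
  if (length(bad))
    stop_promarch("promarch_parse_error",
                  "line %d: non-integer or non-positive count '%s'",
                  bad[1L], mat[4L, bad[1L]])
  d <- data.table(chrom = mat[1L, ], pos = pos, strand = strand, count = cnt)
  if (all(nf >= 5L)) {
    tpm <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1L), 5L)))
    if (!anyNA(tpm)) d[, tpm := tpm]
  }
  ctss_dataset(d, sample_id = sample_id)
}

#' Write a CTSS table
#'
#' Emits the tab-separated 4-column CTSS format; with `tpm = TRUE` (or by
#' default when the dataset carries normalized values) a 5th column with
#' tags-per-million is included.  `read_ctss(write_ctss(d))` round-trips.
#'
#' @param dataset a `ctss` dataset.
#' @param path output path.
#' @param tpm emit the normalized column? Default: emit it iff present.
#' @return `path`, invisibly.
#' @export
write_ctss <- function(dataset, path, tpm = "tpm" %in% names(dataset)) {
  out <- as.data.table(dataset)
  cols <- c("chrom", "pos", "strand", "count", if (tpm) "tpm")
  ok <- tryCatch({
    fwrite(out[, cols, with = FALSE], path, sep = "\t",
           col.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    stop_promarch("promarch_io_error", "cannot write CTSS file: %s", path)
  invisible(path)
}

#' Extract an oriented sequence window around a position
#'
#' Relative coordinates use the no-zero convention (TSS = +1, first
#' upstream base = -1), so a `-upstream/+downstream` window contains
#' `upstream + downstream` bases.  Minus-strand windows are
#' reverse-complemented; positions outside the chromosome are padded
#' with `N`.
#'
#' @param genome a named `DNAStringSet` (or named character vector of
#'   sequences, or path to a FASTA file).
#' @param chrom chromosome name.
#' @param center_pos 1-based position taken as relative +1.
#' @param strand `"+"` or `"-"`.
#' @param upstream,downstream window extent in bases (both >= 0).
#' @return a character string of length `upstream + downstream`.
#' @export
fetch_window <- function(genome, chrom, center_pos, strand, upstream, downstream) {
  genome <- as_genome(genome)
  if (!chrom %in% names(genome))
    stop_promarch("promarch_lookup_error", "unknown chromosome: %s", chrom)
  seq <- genome[[chrom]]
  len <- length(seq)
  if (strand == "+") {
    gstart <- center_pos - upstream
    gend <- center_pos + downstream - 1L
  } else {
    gstart <- center_pos - downstream + 1L
    gend <- center_pos + upstream
  }
  left_pad <- max(0L, 1L - gstart)
  right_pad <- max(0L, gend - len)
  s <- max(1L, gstart); e <- min(len, gend)
  core <- if (s > e) "" else as.character(Biostrings::subseq(seq, s, e))
  out <- paste0(strrep("N", left_pad), core, strrep("N", right_pad))
  if (strand == "-")
    out <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(out)))
  out
}

## Accept a DNAStringSet, a named character vector, or a FASTA path.
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    return(Biostrings::readDNAStringSet(genome))
  if (is.character(genome) && !is.null(names(genome)))
    return(Biostrings::DNAStringSet(genome))
  stop_promarch("promarch_lookup_error",
                "genome must be a DNAStringSet, named sequences, or FASTA path")
}

#' Convert tag clusters to BED
#'
#' Produces BED6+2 records: 0-based half-open coordinates, score =
#' `round(total_tpm)`, and thickStart/thickEnd marking the dominant TSS
#' base.
#'
#' @param clusters a cluster table as returned by [cluster_ctss()] (or any
#'   table with `chrom`, `start`, `end`, `strand`, `total_tpm`,
#'   `dominant_pos` and optionally `id`).
#' @param path optional output path; when given the BED lines are written
#'   (tab-separated, no header).
#' @return a `data.table` of BED columns, invisibly when `path` is given.
#' @export
clusters_to_bed <- function(clusters, path = NULL) {
  cl <- as.data.table(clusters)
  bed <- data.table(
    chrom = cl$chrom,
    chromStart = cl$start - 1L,
    chromEnd = cl$end,
    name = if ("id" %in% names(cl)) as.character(cl$id) else
      paste0("cluster_", seq_len(nrow(cl))),
    score = as.integer(round(cl$total_tpm)),
    strand = cl$strand,
    thickStart = cl$dominant_pos - 1L,
    thickEnd = cl$dominant_pos
  )
  if (!is.null(path)) {
    fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
    return(invisible(bed))
  }
  bed[]
}

#' Read a BED file as 1-based inclusive intervals
#'
#' @param path BED file path (3+ columns, 0-based half-open).
#' @return `data.table` with `chrom`, `start`, `end` (1-based inclusive)
#'   and, when present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path))
    stop_promarch("promarch_io_error", "BED file not found: %s", path)
  raw <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (nrow(raw) == 0L)
    return(data.table(chrom = character(), start = integer(), end = integer()))
  out <- data.table(chrom = as.character(raw[[1L]]),
                    start = as.integer(raw[[2L]]) + 1L,
                    end = as.integer(raw[[3L]]))
  if (ncol(raw) >= 4L) out[, name := as.character(raw[[4L]])]
  if (ncol(raw) >= 5L) out[, score := as.numeric(raw[[5L]])]
  if (ncol(raw) >= 6L) out[, strand := as.character(raw[[6L]])]
  out[]
}
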