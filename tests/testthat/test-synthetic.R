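test_that("generated genomes have forced length, GC content and seed determinism", {
  g <- generate_genome(1L, 10000L, gc_content = 0.5, seed = 1L)
  expect_length(g, 1L)
  expect_equal(Biostrings::width(g), 10000L)

  g2 <- generate_genome(1L, 100000L, gc_content = 0.4, seed = 7L)
  comp <- Biostrings::letterFrequency(g2[[1L]], c("G", "C"))
  gc <- sum(comp) / 100000
  expect_gte(gc, 0.39)
  expect_lte(gc, 0.41)

  fa1 <- tempfile(fileext = ".fa"); fa2 <- tempfile(fileext = ".fa")
  generate_genome(2L, 5000L, 0.5, seed = 3L, path = fa1)
  generate_genome(2L, 5000L, 0.5, seed = 3L, path = fa2)
  expect_identical(readLines(fa1), readLines(fa2))

  expect_error(generate_genome(1L, 0L, 0.5, 1L), class = "promarch_invalid_parameter")
  expect_error(generate_genome(1L, 1e4, 1.2, 1L), class = "promarch_invalid_parameter")
})

test_that("planted W-boxes are all-A/T, recorded, and only motif bases change", {
  g <- generate_genome(1L, 120000L, 0.5, seed = 5L)
  pl <- plant_promoters(g, promoter_spec("sharp_wbox", 100L),
                        min_spacing = 1000L, seed = 6L)
  expect_equal(nrow(pl$truth), 100L)
  for (i in seq_len(100L)) {
    motif <- as.character(Biostrings::subseq(
      pl$genome[[pl$truth$chrom[i]]],
      pl$truth$motif_start[i], pl$truth$motif_end[i]))
    expect_match(motif, "^[AT]+$")
    expect_equal(nchar(motif), 8L)
  }
  ## outside-motif bases unchanged
  orig <- as.character(g[[1L]])
  new <- as.character(pl$genome[[1L]])
  mask <- rep(TRUE, nchar(orig))
  for (i in seq_len(100L))
    mask[pl$truth$motif_start[i]:pl$truth$motif_end[i]] <- FALSE
  ov <- strsplit(orig, "")[[1L]]; nv <- strsplit(new, "")[[1L]]
  expect_identical(ov[mask], nv[mask])
})

test_that("motif interval sits at -31..-24 of the wt dominant TSS, strand-aware", {
  g <- generate_genome(1L, 50000L, 0.5, seed = 9L)
  pl <- plant_promoters(g, promoter_spec("sharp_wbox", 30L),
                        min_spacing = 1000L, seed = 10L)
  tr <- pl$truth
  plus <- tr[tr$strand == "+", ]
  minus <- tr[tr$strand == "-", ]
  if (nrow(plus)) {
    expect_true(all(plus$motif_start == plus$dominant_tss_wt - 31L))
    expect_true(all(plus$motif_end == plus$dominant_tss_wt - 24L))
  }
  if (nrow(minus)) {
    expect_true(all(minus$motif_start == minus$dominant_tss_wt + 24L))
    expect_true(all(minus$motif_end == minus$dominant_tss_wt + 31L))
  }
})

test_that("shifting promoters place per-condition dominants exactly shift_offset apart", {
  g <- generate_genome(1L, 60000L, 0.5, seed = 11L)
  pl <- plant_promoters(g, promoter_spec("shifting", 40L, shift_offset = 50L),
                        min_spacing = 1000L, seed = 12L)
  tr <- pl$truth
  expect_true(all(abs(tr$dominant_tss_mutant - tr$dominant_tss_wt) == 50L))
  sgn <- ifelse(tr$strand == "+", 1L, -1L)
  expect_true(all(sgn * (tr$dominant_tss_mutant - tr$dominant_tss_wt) == 50L))
  expect_true(all(tr$true_shift_offset == 50L))
})

test_that("zero promoters give an empty truth table and capacity errors are raised", {
  g <- generate_genome(1L, 5000L, 0.5, seed = 1L)
  pl <- plant_promoters(g, promoter_spec("broad", 0L), seed = 1L)
  expect_equal(nrow(pl$truth), 0L)
  expect_error(plant_promoters(g, promoter_spec("broad", 1000L),
                               min_spacing = 1000L, seed = 1L),
               class = "promarch_capacity_error")
})

test_that("simulated tags are conserved exactly and deterministic per seed", {
  fx <- sharp_broad_fixture(20L, 20L, seed = 21L, tags = 10000L,
                            chrom_length = 50000L, n_chroms = 1L)
  expect_identical(total_raw(fx$wt), 10000)
  again <- simulate_ctss(fx$truth, "wt", 10000L, seed = 23L)
  expect_identical(as.data.frame(fx$wt), as.data.frame(again))
  expect_error(simulate_ctss(fx$truth, "p14", 100L, seed = 1L),
               class = "promarch_lookup_error")
})

test_that("per-position counts follow the requested Zipf slope", {
  ## a spread of 10 keeps the per-position law's support covering the
  ## whole [5, 1000] fit window at 1e6 tags over 1000 promoters
  spec <- suppressWarnings(promoter_spec("broad", 1000L, tss_spread_sd = 10,
                                         expression_zipf_alpha = 1.9))
  pl <- plant_promoters(generate_genome(2L, 550000L, 0.5, seed = 31L),
                        spec, min_spacing = 1000L, seed = 32L)
  d <- simulate_ctss(pl$truth, "wt", 1e6L, seed = 3L)
  ## independent least-squares refit of the reverse cumulative
  cnt <- d$count
  xs <- sort(unique(cnt[cnt >= 5 & cnt <= 1000]))
  N <- vapply(xs, function(x) sum(cnt >= x), numeric(1L))
  slope <- -unname(coef(lm(log10(N) ~ log10(xs)))[2L])
  expect_gte(slope, 1.9 - 0.15)
  expect_lte(slope, 1.9 + 0.15)
})

test_that("sharp promoters concentrate tags near the dominant TSS", {
  g <- generate_genome(1L, 20000L, 0.5, seed = 41L)
  pl <- plant_promoters(g, promoter_spec("sharp_wbox", 1L, tss_spread_sd = 1),
                        min_spacing = 1000L, seed = 42L)
  d <- simulate_ctss(pl$truth, "wt", 500L, seed = 43L)
  near <- d$count[abs(d$pos - pl$truth$dominant_tss_wt) <= 2L]
  expect_gte(sum(near) / 500, 0.90)
})

test_that("true sharp promoters have narrower empirical spread than broad ones", {
  for (seed in c(51L, 61L, 71L)) {
    fx <- sharp_broad_fixture(30L, 30L, seed = seed, tags = 60000L)
    d <- as.data.frame(fx$wt)
    spread <- vapply(seq_len(nrow(fx$truth)), function(i) {
      tr <- fx$truth[i, ]
      sel <- d$chrom == tr$chrom & d$strand == tr$strand &
        abs(d$pos - tr$dominant_tss_wt) <= 200L
      if (!any(sel)) return(NA_real_)
      p <- rep(d$pos[sel], d$count[sel])
      stats::sd(p)
    }, numeric(1L))
    s <- spread[fx$truth$promoter_class == "sharp_wbox"]
    b <- spread[fx$truth$promoter_class == "broad"]
    expect_lt(stats::median(s, na.rm = TRUE), stats::median(b, na.rm = TRUE))
  }
})

test_that("the stratified Zipf sampler honours its truncation bound and support", {
  z <- rzipf_counts(20000L, 1.9, truncate = 100L, seed = 8L)
  expect_true(all(z >= 1L))
  expect_true(all(z <= 100L))
  z2 <- rzipf_counts(20000L, 1.9, truncate = 100L, seed = 8L)
  expect_identical(z, z2)
  expect_error(rzipf_counts(10L, -1), class = "promarch_invalid_parameter")
})
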