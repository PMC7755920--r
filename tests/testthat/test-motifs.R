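test_that("WW occurrence marks exactly the A/T dinucleotide starts", {
  p <- ww_density(c("ATATAT", "GCGCGC"))
  expect_equal(dim(p$occurrence), c(2L, 5L))
  expect_equal(p$occurrence[1L, ], rep(1L, 5L))
  expect_equal(p$occurrence[2L, ], rep(0L, 5L))
  mixed <- ww_density("GATTGC")  # pairs: GA AT TT TG GC
  expect_equal(as.vector(mixed$occurrence), c(0L, 1L, 1L, 0L, 0L))
  expect_error(ww_density(c("AT", "ATT")), class = "promarch_invalid_input")
})

test_that("rows are ordered by ascending interquantile width", {
  p <- ww_density(c("AAAA", "GGGG", "TTTT"), widths = c(30L, 10L, 20L))
  expect_equal(p$order, c(2L, 3L, 1L))
  expect_equal(p$occurrence[1L, ], rep(0L, 3L))  # narrowest first (GGGG)
})

test_that("WW density of reverse complements is the mirror image", {
  set.seed(41)
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""),
    character(1L))
  rc <- vapply(seqs, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1L))
  a <- ww_density(seqs)$occurrence
  b <- ww_density(rc)$occurrence
  expect_equal(b, a[, ncol(a):1, drop = FALSE], ignore_attr = TRUE)
})

test_that("planted W-boxes enrich WW density at -31..-24 over upstream background", {
  g <- generate_genome(2L, 300000L, 0.5, seed = 61L)
  pl <- plant_promoters(g, promoter_spec("sharp_wbox", 500L),
                        min_spacing = 1000L, seed = 62L)
  tr <- pl$truth
  seqs <- vapply(seq_len(nrow(tr)), function(i)
    fetch_window(pl$genome, tr$chrom[i], tr$dominant_tss_wt[i], tr$strand[i],
                 upstream = 250L, downstream = 250L), character(1L))
  p <- ww_density(seqs)
  ## window base index for relative r (r < 0) is 250 + r + 1
  motif_cols <- (250 - 31 + 1):(250 - 24 + 1 - 1)   # pairs fully inside
  bg_cols <- 1:150                                  # -250..-100
  expect_gte(mean(p$column_means[motif_cols]),
             3 * mean(p$column_means[bg_cols]))
})

test_that("relative PWM scores hit 100 on the consensus and 0 on the anti-consensus", {
  pwm <- tbp_pwm()
  bases <- rownames(pwm)
  consensus <- paste(bases[apply(pwm, 2L, which.max)], collapse = "")
  anti <- paste(bases[apply(pwm, 2L, which.min)], collapse = "")
  expect_equal(pwm_relative_scores(consensus, pwm), 100, tolerance = 1e-9)
  expect_equal(pwm_relative_scores(anti, pwm), 0, tolerance = 1e-9)
  expect_error(pwm_relative_scores("ACGT", pwm),
               class = "promarch_invalid_input")
})

test_that("PWM scanning equals the brute-force column-sum oracle", {
  pwm <- tbp_pwm()
  set.seed(51)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 16, TRUE), collapse = "")
    got <- pwm_relative_scores(s, pwm)
    want <- vapply(1:2, function(st)
      oracle_pwm_score(substr(s, st, st + 14L), pwm), numeric(1L))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("scores are invariant to a constant added to all log-odds columns", {
  ## equivalent formulation: scaling all PWM columns by a constant factor
  pwm <- tbp_pwm()
  s <- "TACGTATAAAAGGCGG"
  expect_equal(pwm_relative_scores(s, pwm), pwm_relative_scores(s, pwm * 4),
               tolerance = 1e-9)
})

test_that("best_tata_match scores the -35/-20 window and responds to planted consensus", {
  pwm <- tbp_pwm()
  bases <- rownames(pwm)
  consensus <- paste(bases[apply(pwm, 2L, which.max)], collapse = "")
  poly_g <- paste(rep("G", 400L), collapse = "")
  g <- Biostrings::DNAStringSet(c(chrA = poly_g))
  cl <- data.frame(id = "c1", chrom = "chrA", strand = "+",
                   dominant_pos = 200L)
  base_score <- best_tata_match(cl, g, pwm)
  expect_lt(base_score, 50)
  ## plant the consensus at -35..-21 (starts at 200 - 35)
  planted <- g
  planted[["chrA"]] <- Biostrings::replaceAt(
    planted[["chrA"]], IRanges::IRanges(165L, 179L), consensus)
  expect_equal(best_tata_match(cl, planted, pwm), 100, tolerance = 1e-9)
  ## monotonicity: planting can only raise the best score
  expect_gte(best_tata_match(cl, planted, pwm), base_score)
})

test_that("sharp W-box promoters out-score broad ones on best TATA match", {
  fx <- sharp_broad_fixture(60L, 60L, seed = 71L, tags = 60000L)
  nd <- normalize_power_law(fx$wt)
  cl <- cluster_ctss(nd)
  cls <- match_clusters_to_truth(as.data.frame(cl), as.data.frame(fx$truth))
  tata <- best_tata_match(as.data.frame(cl), fx$genome)
  s <- tata[!is.na(cls) & cls == "sharp_wbox"]
  b <- tata[!is.na(cls) & cls == "broad"]
  expect_gt(length(s), 20L)
  expect_gt(length(b), 20L)
  expect_gt(median(s), median(b))
})

test_that("Wilcoxon wrapper reproduces exact and approximate behaviour", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  same <- wilcoxon_rank_sum(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(same$p_value, 0.9)
  set.seed(81)
  a <- rnorm(200); b <- rnorm(200, 0.5)
  r2 <- wilcoxon_rank_sum(a, b)
  ## independent normal-approximation oracle with continuity correction
  n1 <- 200; n2 <- 200
  rk <- rank(c(a, b))
  W <- sum(rk[1:n1]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sig <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  p_o <- 2 * pnorm(-(abs(W - mu) - 0.5) / sig)
  expect_equal(r2$p_value, p_o, tolerance = 0.1 * p_o + 1e-12)
  expect_error(wilcoxon_rank_sum(numeric(), 1),
               class = "promarch_invalid_input")
})

test_that("information content follows the Shannon entropy of base frequencies", {
  same <- rep("ACGT", 5L)
  l <- information_content_logo(same)
  expect_equal(l$ic, rep(2, 4))
  uniform <- c("AAAA", "CCCC", "GGGG", "TTTT")
  expect_equal(information_content_logo(uniform)$ic, rep(0, 4))
  ## frequencies (0.7, 0.1, 0.1, 0.1) -> 0.6432 bits
  seqs <- c(rep("A", 7L), "C", "G", "T")
  l3 <- information_content_logo(seqs)
  expect_equal(l3$ic, 0.6432, tolerance = 1e-4)
  expect_true(all(abs(colSums(l3$freq) - 1) < 1e-9))
  ## all-N positions are flagged with zero IC
  l4 <- information_content_logo(c("NA", "NC"))
  expect_true(l4$all_n[1L])
  expect_equal(l4$ic[1L], 0)
})
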