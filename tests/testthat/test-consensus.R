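mkcl <- function(chrom, strand, qlo, qup, tpm = 10) {
  data.frame(id = paste0("t", seq_along(qlo)), chrom = chrom, strand = strand,
             start = qlo, end = qup, n_ctss = 2L, total_tpm = tpm,
             dominant_pos = qlo, dominant_tpm = tpm / 2,
             q_low_pos = qlo, q_up_pos = qup,
             iq_width = qup - qlo + 1L)
}

test_that("trimmed intervals merge across samples by the gap rule", {
  a <- mkcl("chr1", "+", 100L, 120L)
  b <- mkcl("chr1", "+", 130L, 140L)
  cc <- aggregate_clusters(list(A = a, B = b))
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$start, 100L)
  expect_equal(cc$end, 140L)

  far <- mkcl("chr1", "+", 280L, 290L)   # 160 beyond end 120
  cc2 <- aggregate_clusters(list(A = a, B = far))
  expect_equal(nrow(cc2), 2L)

  ## gap boundary: start2 - end1 == max_dist merges, max_dist + 1 does not
  edge <- mkcl("chr1", "+", 220L, 230L)
  expect_equal(nrow(aggregate_clusters(list(A = a, B = edge))), 1L)
  over <- mkcl("chr1", "+", 221L, 230L)
  expect_equal(nrow(aggregate_clusters(list(A = a, B = over))), 2L)

  ## different strands never merge
  minus <- mkcl("chr1", "-", 130L, 140L)
  expect_equal(nrow(aggregate_clusters(list(A = a, B = minus))), 2L)
})

test_that("weak clusters are discarded before aggregation and empty input is fine", {
  weak <- mkcl("chr1", "+", 100L, 120L, tpm = 2)
  expect_equal(nrow(aggregate_clusters(list(A = weak))), 0L)
  expect_equal(nrow(aggregate_clusters(list())), 0L)
})

test_that("aggregation matches a brute-force interval-union oracle", {
  set.seed(13)
  for (rep in 1:40) {
    n <- sample(2:30, 1L)
    qlo <- sample(2000L, n)
    qup <- qlo + sample(0:80, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    cl <- mkcl("chr1", strand, qlo, qup)
    cc <- aggregate_clusters(list(s = cl))
    oracle <- oracle_merge(data.frame(chrom = "chr1", strand = strand,
                                      start = qlo, end = qup))
    got <- as.data.frame(cc[order(cc$strand, cc$start),
                            c("chrom", "strand", "start", "end")])
    want <- oracle[order(oracle$strand, oracle$start),
                   c("chrom", "strand", "start", "end")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("aggregating the consensus output again changes nothing", {
  set.seed(14)
  qlo <- sample(5000L, 40L)
  cl <- mkcl("chr1", sample(c("+", "-"), 40L, TRUE), qlo,
             qlo + sample(0:120, 40L, TRUE))
  cc1 <- aggregate_clusters(list(s = cl))
  again <- cc1
  again$q_low_pos <- again$start; again$q_up_pos <- again$end
  again$total_tpm <- 10
  cc2 <- aggregate_clusters(list(s = as.data.frame(again)))
  expect_equal(as.data.frame(cc2[, c("chrom", "strand", "start", "end")]),
               as.data.frame(cc1[, c("chrom", "strand", "start", "end")]))
})

test_that("expression entries count exactly the strand-matched signal in bounds", {
  cc <- data.frame(id = "CC_1", chrom = "chr1", strand = "+",
                   start = 100L, end = 140L)
  s1 <- make_ctss("chr1", c(110L, 200L), "+", c(3L, 4L), tpm = c(3, 4))
  em <- expression_matrix(cc, list(a = s1))
  expect_equal(unname(em$expression[1L, "a"]), 3)
  expect_equal(unname(em$dominant_pos[1L, "a"]), 110L)

  ## opposite strand does not count; empty bounds give 0 / NA
  s2 <- make_ctss("chr1", 110L, "-", 5L, tpm = 5)
  em2 <- expression_matrix(cc, list(b = s2))
  expect_equal(unname(em2$expression[1L, "b"]), 0)
  expect_true(is.na(em2$dominant_pos[1L, "b"]))
})

test_that("column sums equal each sample's total TPM within consensus bounds", {
  fx <- sharp_broad_fixture(20L, 20L, seed = 44L, tags = 30000L)
  wt <- normalize_power_law(fx$wt)
  mu <- normalize_power_law(simulate_ctss(fx$truth, "mutant", 30000L, seed = 45L))
  cl <- list(wt = cluster_ctss(wt), mutant = cluster_ctss(mu))
  cc <- aggregate_clusters(cl)
  em <- expression_matrix(cc, list(wt = wt, mutant = mu))
  for (nm in c("wt", "mutant")) {
    d <- as.data.frame(if (nm == "wt") wt else mu)
    total <- 0
    for (i in seq_len(nrow(cc))) {
      sel <- d$chrom == cc$chrom[i] & d$strand == cc$strand[i] &
        d$pos >= cc$start[i] & d$pos <= cc$end[i]
      total <- total + sum(d$tpm[sel])
    }
    expect_equal(sum(em$expression[, nm]), total, tolerance = 1e-9)
  }
})

test_that("SOM uses a fixed grid, scales profiles, and is seed-deterministic", {
  set.seed(7)
  mat <- matrix(runif(200, 0, 10), 100, 2,
                dimnames = list(paste0("c", 1:100), c("a", "b")))
  som <- som_profiles(mat, tpm_threshold = 3, seed = 5L)
  expect_equal(prod(som$grid), 6L)
  expect_equal(nrow(som$prototypes), 6L)
  expect_true(all(abs(rowSums(som$profiles) - 1) < 1e-9))
  expect_true(all(som$node >= 1L & som$node <= 6L))
  som2 <- som_profiles(mat, tpm_threshold = 3, seed = 5L)
  expect_identical(som$node, som2$node)
  ## low-expression clusters are excluded
  expect_true(all(apply(mat[names(som$node), , drop = FALSE], 1L, max) >= 3))
})

test_that("identical profiles collapse onto a single node", {
  mat <- matrix(rep(c(4, 8), each = 50), 50, 2)
  rownames(mat) <- paste0("c", 1:50)
  som <- som_profiles(mat, seed = 3L)
  expect_equal(length(unique(som$node)), 1L)
  expect_error(som_profiles(mat[1, , drop = FALSE]),
               class = "promarch_degenerate_input")
})

test_that("orthogonal condition-specific profiles occupy disjoint SOM nodes", {
  mat <- rbind(matrix(rep(c(10, 0), each = 50), 50, 2),
               matrix(rep(c(0, 10), each = 50), 50, 2))
  rownames(mat) <- paste0("c", 1:100)
  colnames(mat) <- c("wt", "mutant")
  som <- som_profiles(mat, seed = 11L)
  nodes_wt <- unique(som$node[1:50])
  nodes_mu <- unique(som$node[51:100])
  expect_length(intersect(nodes_wt, nodes_mu), 0L)
  groups <- label_som_groups(som)
  expect_true(all(groups$labels[1:50] == "downregulated"))
  expect_true(all(groups$labels[51:100] == "upregulated"))
})

test_that("subset_by_regions keeps clusters whose dominant TSS falls inside", {
  cl <- data.frame(id = c("a", "b"), chrom = "chr1", strand = "+",
                   dominant_pos = c(105L, 111L))
  rg <- data.frame(chrom = "chr1", start = 100L, end = 110L)
  out <- subset_by_regions(cl, rg)
  expect_equal(out$id, "a")
  expect_equal(nrow(subset_by_regions(cl, rg[0, ])), 0L)
})
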