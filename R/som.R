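## Self-organising-map classification of promoter expression profiles.

#' SOM expression profiling of consensus clusters
#'
#' Clusters whose maximal expression across samples is below
#' `tpm_threshold` are excluded; each retained profile is scaled to sum 1
#' across samples and mapped onto a rectangular `xdim` x `ydim`
#' self-organising map (online training, Gaussian neighbourhood,
#' linearly decaying learning rate and radius, `100 * n_profiles`
#' iterations).  Training is deterministic for a fixed seed.
#'
#' @param mat expression matrix (clusters x samples), e.g.
#'   `expression_matrix(...)$expression`.
#' @param tpm_threshold minimal max-across-samples expression, default 3.
#' @param xdim,ydim grid dimensions, defaults 3 and 2.
#' @param seed integer RNG seed.
#' @param lr learning-rate range (start, end).
#' @param radius neighbourhood-radius range (start, end); default decays
#'   from half the larger grid dimension to 0.5.
#' @return a `som_result` list: `grid = c(xdim, ydim)`, `node` (named
#'   integer vector, node index 1..xdim*ydim per profiled cluster),
#'   `node_coords` (node index -> grid x/y), `prototypes` (nodes x
#'   samples), `profiles` (the scaled profiles used), `seed`.
#' @export
som_profiles <- function(mat, tpm_threshold = 3, xdim = 3L, ydim = 2L,
                         seed = 1L, lr = c(0.05, 0.01), radius = NULL) {
  keep <- apply(mat, 1L, max) >= tpm_threshold
  prof <- mat[keep, , drop = FALSE]
  if (nrow(prof) < 2L)
    stop_promarch("promarch_degenerate_input",
                  "need at least 2 profiles above the TPM threshold")
  prof <- prof / rowSums(prof)
  n_nodes <- xdim * ydim
  coords <- cbind(x = rep(seq_len(xdim), times = ydim),
                  y = rep(seq_len(ydim), each = xdim))
  grid_d2 <- as.matrix(stats::dist(coords))^2
  radius <- radius %||% c(max(xdim, ydim) / 2, 0.5)
  n_iter <- 100L * nrow(prof)
  with_seed(seed, {
    w <- prof[sample(nrow(prof), n_nodes, replace = nrow(prof) < n_nodes), ,
              drop = FALSE]
    w <- w + matrix(runif(length(w), -1e-4, 1e-4), nrow = n_nodes)
    picks <- sample(nrow(prof), n_iter, replace = TRUE)
    for (t in seq_len(n_iter)) {
      xv <- prof[picks[t], ]
      d2 <- rowSums(sweep(w, 2L, xv)^2)
      bmu <- which.min(d2)
      frac <- (t - 1) / max(1L, n_iter - 1L)
      a <- lr[1L] + frac * (lr[2L] - lr[1L])
      sg <- radius[1L] + frac * (radius[2L] - radius[1L])
      h <- exp(-grid_d2[bmu, ] / (2 * sg^2))
      w <- w + a * h * sweep(-w, 2L, xv, FUN = "+")
    }
    node <- apply(prof, 1L, function(xv)
      which.min(colSums((t(w) - xv)^2)))
    names(node) <- rownames(prof)
    structure(list(grid = c(xdim = xdim, ydim = ydim), node = node,
                   node_coords = coords, prototypes = w,
                   profiles = prof, seed = seed),
              class = "som_result")
  })
}

#' Label the condition-specific SOM nodes
#'
#' Post-hoc labelling of the two nodes of interest: the node whose
#' prototype puts maximal weight on the first sample ("downregulated" in
#' a wild-type-vs-mutant comparison, i.e. wild-type-specific activity)
#' and the node with maximal weight on the second sample
#' ("upregulated").
#'
#' @param som a `som_result`.
#' @param sample_down,sample_up column names (or indices) of the two
#'   samples; defaults 1 and 2.
#' @return list `down_node`, `up_node` (node indices) and `labels`, a
#'   character vector over profiled clusters with values
#'   `"downregulated"`, `"upregulated"` or `"other"`.
#' @export
label_som_groups <- function(som, sample_down = 1L, sample_up = 2L) {
  down_node <- which.max(som$prototypes[, sample_down])
  up_node <- which.max(som$prototypes[, sample_up])
  labels <- rep("other", length(som$node))
  labels[som$node == down_node] <- "downregulated"
  labels[som$node == up_node] <- "upregulated"
  names(labels) <- names(som$node)
  list(down_node = down_node, up_node = up_node, labels = labels)
}
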