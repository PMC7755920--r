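## Power-law normalization of raw CTSS tag counts.
##
## CAGE tag counts per position follow an approximate power law: the
## reverse cumulative N(x) (number of positions with count >= x) is
## linear in log10-log10 space with slope -alpha.  Normalization maps
## every sample onto a common referent law with slope alpha_ref = 1.53
## and total tag count T = 1e6, so normalized values are comparable
## tags-per-million across libraries of different depths and tail
## behaviours.

#' Reverse cumulative count distribution
#'
#' `N(x)` = number of CTSS positions whose value is >= `x`.  By default
#' evaluated at every integer from 1 to the maximal raw count, so
#' `N(1)` equals the number of positions.
#'
#' @param dataset a `ctss` dataset (non-empty).
#' @param use `"count"` (raw) or `"tpm"` (normalized values).
#' @param x values at which to evaluate `N`; default `1:max`.
#' @return `data.table` with columns `x` and `N`, non-increasing in `x`.
#' @export
reverse_cumulative <- function(dataset, use = c("count", "tpm"), x = NULL) {
  use <- match.arg(use)
  if (nrow(dataset) == 0L)
    stop_promarch("promarch_empty_input", "empty dataset")
  v <- dataset[[use]]
  if (is.null(v))
    stop_promarch("promarch_state_error", "dataset has no '%s' column", use)
  if (is.null(x)) x <- seq_len(max(1L, floor(max(v))))
  sv <- sort(v)
  N <- length(sv) - findInterval(x, sv, left.open = TRUE)
  data.table(x = x, N = N)
}

#' Fit a power law to a tabulated reverse-cumulative distribution
#'
#' Least-squares line through `(log10 x, log10 N)` for `x` inside
#' `fit_range` with `N > 0`; the sample exponent is minus the slope.
#'
#' @param rc `data.frame` with columns `x`, `N`.
#' @param fit_range inclusive count interval used for the fit.
#' @return a `power_law_fit` list: `alpha_sample`, `intercept_sample`
#'   (log10 units), `fit_range`, `n_points_fit`.
#' @export
fit_reverse_cumulative <- function(rc, fit_range = c(5, 1000)) {
  rc <- as.data.table(rc)
  keep <- rc$x >= fit_range[1L] & rc$x <= fit_range[2L] & rc$N > 0
  pts <- unique(rc[keep, .(x, N)])
  if (length(unique(pts$x)) < 2L)
    stop_promarch("promarch_degenerate_fit",
                  "fewer than 2 distinct usable points in fit range [%g, %g]",
                  fit_range[1L], fit_range[2L])
  fit <- lm(log10(N) ~ log10(x), data = pts)
  structure(list(alpha_sample = -unname(coef(fit)[2L]),
                 intercept_sample = unname(coef(fit)[1L]),
                 fit_range = fit_range,
                 n_points_fit = nrow(pts)),
            class = "power_law_fit")
}

#' Fit the power law of a CTSS dataset
#'
#' The reverse cumulative is evaluated at the distinct values observed in
#' the dataset; see [fit_reverse_cumulative()].
#'
#' @param dataset a `ctss` dataset.
#' @param fit_range inclusive count interval, default `c(5, 1000)`.
#' @param use `"count"` or `"tpm"`.
#' @return a `power_law_fit`.
#' @export
fit_power_law <- function(dataset, fit_range = c(5, 1000),
                          use = c("count", "tpm")) {
  use <- match.arg(use)
  v <- dataset[[use]]
  if (is.null(v) || length(v) == 0L)
    stop_promarch("promarch_empty_input", "empty dataset")
  xs <- sort(unique(v))
  sv <- sort(v)
  N <- length(sv) - findInterval(xs, sv, left.open = TRUE)
  fit_reverse_cumulative(data.table(x = xs, N = N), fit_range = fit_range)
}

## zeta(alpha_ref) cache: B_ref = T / zeta(alpha_ref) makes the referent
## discrete law sum to exactly T tags over counts 1, 2, ...
.zeta_cache <- new.env(parent = emptyenv())
zeta_cached <- function(s) {
  key <- format(s, digits = 15)
  if (is.null(.zeta_cache[[key]])) .zeta_cache[[key]] <- pracma::zeta(s)
  .zeta_cache[[key]]
}

#' Normalize raw counts to a referent power law
#'
#' Quantile-matching map between the sample law
#' `N_s(x) = B_s * x^(-alpha_s)` (from the fit) and the referent law
#' `N_r(y) = B_r * y^(-alpha_ref)` with `B_r = T / zeta(alpha_ref)` (so
#' the referent's total tag count is `T`): each raw count `x` maps to
#' `y = (B_s * x^(-alpha_s) / B_r)^(-1/alpha_ref)`.  The map is strictly
#' increasing, so ranking by `tpm` equals ranking by raw count.  When the
#' fit is degenerate the function falls back to plain tags-per-million
#' (`count * 1e6 / total_raw`) with a warning.
#'
#' @param dataset a `ctss` dataset.
#' @param fit optional precomputed `power_law_fit`; fitted here otherwise.
#' @param fit_range passed to [fit_power_law()] when `fit` is `NULL`.
#' @param alpha_ref referent slope, default 1.53.
#' @param total_ref referent total tag count, default 1e6.
#' @return the dataset with a `tpm` column filled in.
#' @export
normalize_power_law <- function(dataset, fit = NULL, fit_range = c(5, 1000),
                                alpha_ref = 1.53, total_ref = 1e6) {
  d <- copy(as.data.table(dataset))
  if (nrow(d) == 0L) {
    d[, tpm := numeric()]
  } else {
    if (is.null(fit)) {
      fit <- tryCatch(fit_power_law(dataset, fit_range = fit_range),
                      promarch_degenerate_fit = function(e) NULL)
    }
    if (is.null(fit)) {
      warning("degenerate power-law fit; falling back to simple tags-per-million")
      d[, tpm := count * total_ref / sum(as.numeric(count))]
    } else {
      B_s <- 10^fit$intercept_sample
      B_r <- total_ref / zeta_cached(alpha_ref)
      d[, tpm := (B_s * count^(-fit$alpha_sample) / B_r)^(-1 / alpha_ref)]
    }
  }
  setattr(d, "sample_id", attr(dataset, "sample_id"))
  if (!inherits(d, "ctss")) setattr(d, "class", c("ctss", class(d)))
  d[]
}

#' Write a power-law fit report
#' @param fit a `power_law_fit`.
#' @param path output TSV path.
#' @param alpha_ref,total_ref referent parameters to record.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, alpha_ref = 1.53, total_ref = 1e6) {
  fwrite(data.table(alpha_sample = fit$alpha_sample,
                    intercept_sample = fit$intercept_sample,
                    n_points_fit = fit$n_points_fit,
                    fit_lower = fit$fit_range[1L],
                    fit_upper = fit$fit_range[2L],
                    alpha_ref = alpha_ref, total_ref = total_ref),
         path, sep = "\t", quote = FALSE)
  invisible(path)
}
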