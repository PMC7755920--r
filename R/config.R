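## Run configuration: every numeric parameter of the pipeline with its
## default, overridable from a YAML file or an override list.

#' Default pipeline configuration
#'
#' Nested list of every tunable parameter with its default:
#' normalization (`fit_range` 5..1000, `alpha` 1.53, `total` 1e6),
#' clustering (`threshold` 1 TPM, `max_dist` 20, `keep_singletons_above`
#' 5, `q_low` 0.1, `q_up` 0.9), consensus (`tpm_threshold` 3, `max_dist`
#' 100), SOM (`tpm_threshold` 3, `xdim` 3, `ydim` 2, `seed`), shifting
#' (`fdr_threshold` 0.01, `score_threshold` -Inf, `min_tpm` 3), motif
#' windows (density -250/+250, TATA scan -35/-20, logo -35/+5, W-box
#' -31..-24).
#'
#' @param overrides nested list (or path to a YAML file) whose leaves
#'   replace the corresponding defaults.
#' @return a `promarch_config` nested list with attribute `overridden`
#'   listing the keys changed from default.
#' @export
promarch_config <- function(overrides = NULL) {
  cfg <- list(
    normalization = list(fit_range = c(5, 1000), alpha = 1.53, total = 1e6),
    clustering = list(threshold = 1, max_dist = 20L,
                      keep_singletons_above = 5, q_low = 0.1, q_up = 0.9),
    consensus = list(tpm_threshold = 3, max_dist = 100L),
    som = list(tpm_threshold = 3, xdim = 3L, ydim = 2L, seed = 1L),
    shifting = list(fdr_threshold = 0.01, score_threshold = -Inf,
                    min_tpm = 3),
    motifs = list(density_window = c(-250L, 250L),
                  tata_window = c(-35L, -20L),
                  logo_window = c(-35L, 5L),
                  wbox_interval = c(-31L, -24L),
                  pseudocount = 0.01)
  )
  if (is.character(overrides) && length(overrides) == 1L)
    overrides <- yaml::read_yaml(overrides)
  overridden <- character()
  if (!is.null(overrides)) {
    flat_keys <- function(x, prefix = "") {
      unlist(lapply(names(x), function(k) {
        key <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
        if (is.list(x[[k]])) flat_keys(x[[k]], key) else key
      }))
    }
    overridden <- flat_keys(overrides)
    cfg <- utils::modifyList(cfg, overrides)
  }
  structure(cfg, class = "promarch_config", overridden = overridden)
}
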