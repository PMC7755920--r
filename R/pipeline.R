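## End-to-end orchestration: subtract -> normalize -> cluster -> widths
## -> consensus -> expression -> SOM -> shifts -> motifs, with stage
## logging, TSV/BED outputs and a machine-readable run manifest.

#' Run the full promoter-architecture pipeline
#'
#' Stage order (fixed): the mutant positions are subtracted from the
#' wild-type CTSSs to form the *dependent* set while the mutant set
#' passes through as the *independent* set; both sets are power-law
#' normalized and clustered with interquantile widths; clusters are
#' aggregated into consensus promoters; the per-sample expression matrix
#' is built and profiled with the SOM; shifting promoters are scored and
#' selected; core-promoter motifs (best TATA match per cluster, WW
#' positional enrichment, logo matrices) are computed around the
#' dominant TSSs of each set.  Every stage writes TSV (plus BED for
#' clusters) into `out_dir` and logs record counts; a JSON manifest
#' records the config snapshot, seeds, input checksums, per-stage output
#' paths and the package version.
#'
#' @param config a [promarch_config()] (or overrides list / YAML path).
#' @param wt_ctss,mutant_ctss `ctss` datasets or CTSS file paths.
#' @param genome `DNAStringSet` or FASTA path.
#' @param out_dir output directory (created if needed).
#' @param pwm TATA PWM matrix; default the packaged TBP matrix.
#' @param verbose log stage progress to standard error? Default `TRUE`.
#' @return invisibly, a list with the in-memory stage results
#'   (`dependent`, `independent`, `clusters`, `consensus`, `expression`,
#'   `som`, `shifts`, `shifting`, `motifs`) and the `manifest`.
#' @export
run_pipeline <- function(config = promarch_config(), wt_ctss, mutant_ctss,
                         genome, out_dir, pwm = tbp_pwm(), verbose = TRUE) {
  if (!inherits(config, "promarch_config")) config <- promarch_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_ <- function(...) if (verbose) message("[promarch] ", sprintf(...))
  inputs <- list()
  if (is.character(wt_ctss)) {
    inputs$wt_ctss <- wt_ctss
    wt_ctss <- read_ctss(wt_ctss, sample_id = "wt")
  }
  if (is.character(mutant_ctss)) {
    inputs$mutant_ctss <- mutant_ctss
    mutant_ctss <- read_ctss(mutant_ctss, sample_id = "mutant")
  }
  if (is.character(genome)) inputs$genome <- genome
  genome <- as_genome(genome)
  outputs <- character()
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    fwrite(as.data.table(obj), path, sep = "\t", quote = FALSE)
    outputs[[name]] <<- path
    path
  }
  stage <- "subtract"
  result <- tryCatch({
    ## -- subtraction ---------------------------------------------------
    dep <- subtract_ctss(wt_ctss, mutant_ctss, sample_id = "dependent")
    indep <- ctss_dataset(as.data.table(mutant_ctss), sample_id = "independent")
    log_("subtract: %d WT CTSS in = %d retained + %d removed",
         nrow(wt_ctss), nrow(dep), nrow(wt_ctss) - nrow(dep))
    ## -- normalization -------------------------------------------------
    stage <- "normalize"
    ncfg <- config$normalization
    sets <- list(dependent = dep, independent = indep)
    sets <- lapply(sets, function(d) {
      normalize_power_law(d, fit_range = ncfg$fit_range,
                          alpha_ref = ncfg$alpha, total_ref = ncfg$total)
    })
    for (nm in names(sets)) emit(sets[[nm]], paste0("ctss_", nm, ".tsv"))
    log_("normalize: alpha_ref %.2f, T %g", ncfg$alpha, ncfg$total)
    ## -- clustering + widths -------------------------------------------
    stage <- "cluster"
    ccfg <- config$clustering
    clusters <- lapply(sets, function(d)
      cluster_ctss(d, threshold = ccfg$threshold, max_dist = ccfg$max_dist,
                   keep_singletons_above = ccfg$keep_singletons_above,
                   q_low = ccfg$q_low, q_up = ccfg$q_up))
    for (nm in names(clusters)) {
      emit(clusters[[nm]], paste0("clusters_", nm, ".tsv"))
      bed <- file.path(out_dir, paste0("clusters_", nm, ".bed"))
      clusters_to_bed(clusters[[nm]], bed)
      outputs[[basename(bed)]] <- bed
      log_("cluster (%s): %d tag clusters", nm, nrow(clusters[[nm]]))
    }
    ## -- consensus + expression ----------------------------------------
    stage <- "consensus"
    acfg <- config$consensus
    consensus <- aggregate_clusters(clusters, tpm_threshold = acfg$tpm_threshold,
                                    max_dist = acfg$max_dist)
    emit(consensus, "consensus.tsv")
    log_("consensus: %d consensus clusters", nrow(consensus))
    stage <- "expression"
    em <- expression_matrix(consensus, sets)
    emit(data.table(id = rownames(em$expression), em$expression),
         "expression_matrix.tsv")
    ## -- SOM -----------------------------------------------------------
    stage <- "som"
    scfg <- config$som
    som <- tryCatch(
      som_profiles(em$expression, tpm_threshold = scfg$tpm_threshold,
                   xdim = scfg$xdim, ydim = scfg$ydim, seed = scfg$seed),
      promarch_degenerate_input = function(e) {
        log_("som: skipped (%s)", conditionMessage(e)); NULL
      })
    groups <- NULL
    if (!is.null(som)) {
      groups <- label_som_groups(som)
      emit(data.table(id = names(som$node), node = som$node,
                      group = groups$labels), "som_assignments.tsv")
      log_("som: %d profiles on a %dx%d grid", length(som$node),
           scfg$xdim, scfg$ydim)
    }
    ## -- shifting promoters --------------------------------------------
    stage <- "shift"
    hcfg <- config$shifting
    shifts <- score_shifts(consensus, sets$dependent, sets$independent,
                           tpm_threshold = hcfg$min_tpm)
    shifting <- get_shifting_promoters(shifts,
                                       fdr_threshold = hcfg$fdr_threshold,
                                       score_threshold = hcfg$score_threshold)
    emit(shifts, "shift_scores.tsv")
    emit(shifting, "shifting_promoters.tsv")
    log_("shift: %d scored, %d shifting at FDR <= %g",
         nrow(shifts), nrow(shifting), hcfg$fdr_threshold)
    ## -- motifs ---------------------------------------------------------
    stage <- "motifs"
    mcfg <- config$motifs
    motifs <- lapply(names(clusters), function(nm) {
      cl <- clusters[[nm]]
      if (nrow(cl) == 0L) return(NULL)
      tata <- best_tata_match(cl, genome, pwm, window = mcfg$tata_window,
                              pseudocount = mcfg$pseudocount)
      dw <- mcfg$density_window
      seqs <- vapply(seq_len(nrow(cl)), function(i)
        fetch_window(genome, cl$chrom[i], cl$dominant_pos[i], cl$strand[i],
                     upstream = -dw[1L], downstream = dw[2L]), character(1L))
      ww <- ww_density(seqs, widths = cl$iq_width)
      lw <- mcfg$logo_window
      logo_seqs <- vapply(seq_len(nrow(cl)), function(i)
        fetch_window(genome, cl$chrom[i], cl$dominant_pos[i], cl$strand[i],
                     upstream = -lw[1L], downstream = lw[2L]), character(1L))
      logo <- information_content_logo(logo_seqs)
      emit(data.table(id = cl$id, iq_width = cl$iq_width,
                      best_tata_match = tata),
           paste0("tata_matches_", nm, ".tsv"))
      emit(data.table(position = seq_along(ww$column_means),
                      ww_frequency = ww$column_means),
           paste0("ww_track_", nm, ".tsv"))
      emit(data.table(position = seq_along(logo$ic), ic = logo$ic,
                      t(logo$freq)), paste0("logo_", nm, ".tsv"))
      list(tata = tata, ww = ww, logo = logo)
    })
    names(motifs) <- names(clusters)
    list(dependent = sets$dependent, independent = sets$independent,
         clusters = clusters, consensus = consensus, expression = em,
         som = som, som_groups = groups, shifts = shifts,
         shifting = shifting, motifs = motifs)
  }, promarch_error = function(e) {
    stop_promarch("promarch_stage_error", "stage '%s' failed: %s",
                  stage, conditionMessage(e))
  })
  ## -- manifest ---------------------------------------------------------
  manifest <- list(
    tool = "promarch",
    version = as.character(packageVersion("promarch")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    overridden = attr(config, "overridden"),
    seeds = list(som = config$som$seed),
    inputs = lapply(inputs, function(p) list(path = p,
                                             md5 = unname(tools::md5sum(p)))),
    outputs = lapply(outputs, function(p) list(path = p,
                                               md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  result$manifest <- manifest
  invisible(result)
}
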