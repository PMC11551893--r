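#' Configuration of the end-to-end analysis pipeline
#'
#' @param simulation a [sim_config()] describing the simulated group.
#' @param decoders data.frame of decoder jobs with columns `feature`
#'   ("order"/"timing"/"integrated") and `phase`; default: all six
#'   feature-by-phase combinations.
#' @param shrinkage LDA / noise-covariance shrinkage ("auto" or [0,1]).
#' @param n_baseline_sims simulated groups for the no-switch baseline and the
#'   switch reference of the cross-phase analysis.
#' @param searchlight list with `grid_dims`, `signal_dims` (box of signal
#'   voxels), `target_size`, `max_radius_mm`, `t_threshold`, `n_subjects`.
#' @param bonferroni_decoding,bonferroni_geometry correction factors for the
#'   group decoding tests (default 6: 3 classifiers x 2 phases) and the
#'   cross-phase test (default 7: one per region in a typical ROI set).
#' @param output_dir where CSV / JSON / NIfTI outputs are written.
#' @param seed master seed propagated to every stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            decoders = expand.grid(
                              feature = c("order", "timing", "integrated"),
                              phase = c("preparation", "production"),
                              stringsAsFactors = FALSE),
                            shrinkage = "auto",
                            n_baseline_sims = 10,
                            searchlight = list(grid_dims = c(10, 10, 10),
                                               signal_dims = c(4, 5, 8),
                                               target_size = 160,
                                               max_radius_mm = 4,
                                               t_threshold = 3.48,
                                               n_subjects = 6),
                            bonferroni_decoding = 6,
                            bonferroni_geometry = 7,
                            output_dir = tempfile("seqmvpa_"),
                            seed = 1L) {
  stopifnot(inherits(simulation, "sim_config"))
  structure(list(simulation = simulation, decoders = decoders,
                 shrinkage = shrinkage, n_baseline_sims = n_baseline_sims,
                 searchlight = searchlight,
                 bonferroni_decoding = bonferroni_decoding,
                 bonferroni_geometry = bonferroni_geometry,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full simulated analysis pipeline
#'
#' Stages: (1) simulate a group of subjects; (2) run the three sequence
#' decoders per phase on every subject and test the group z-scores against
#' chance; (3) run the representational-geometry analysis (prewhitening, MDS,
#' normalized cross-phase distance) with a simulation-matched no-switch
#' baseline and switch reference; (4) run a volumetric searchlight demo with
#' an injected signal region and compute the group t-map and clusters. All
#' tables are written as CSV, the t-map as NIfTI, and a consolidated summary
#' as JSON. Re-running with the same seed reproduces every output.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the report list (also written to
#'   `file.path(cfg$output_dir, "summary.json")`).
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$output_dir, ...)

  stage <- function(name, expr) {
    message("[seqmvpa] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # -- stage 1: simulation ---------------------------------------------------
  group <- stage("simulate", simulate_group(cfg$simulation, seed = cfg$seed))
  n_subj <- length(group)

  # -- stage 2: decoding -----------------------------------------------------
  decoding_tab <- stage("decode", {
    rows <- list()
    for (s in seq_len(n_subj)) {
      for (j in seq_len(nrow(cfg$decoders))) {
        res <- decode_sequences(group[[s]],
                                feature = cfg$decoders$feature[j],
                                phase = cfg$decoders$phase[j],
                                shrinkage = cfg$shrinkage)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, decoder = cfg$decoders$feature[j],
          phase = cfg$decoders$phase[j],
          accuracy = res$accuracy, z = res$z, chance = res$chance)
      }
    }
    do.call(rbind, rows)
  })
  utils::write.csv(decoding_tab, out("decoding_subjects.csv"),
                   row.names = FALSE)

  group_tab <- do.call(rbind, lapply(seq_len(nrow(cfg$decoders)), function(j) {
    sub <- decoding_tab[decoding_tab$decoder == cfg$decoders$feature[j] &
                          decoding_tab$phase == cfg$decoders$phase[j], ]
    st <- one_sample_t(sub$z, mu = 0, tails = "one",
                       bonferroni_m = cfg$bonferroni_decoding)
    data.frame(decoder = cfg$decoders$feature[j],
               phase = cfg$decoders$phase[j],
               mean_accuracy = mean(sub$accuracy), mean_z = mean(sub$z),
               t = st$t, df = st$df, p_corrected = st$p_corrected,
               cohens_d = st$cohens_d, m = st$bonferroni_m)
  }))
  utils::write.csv(group_tab, out("decoding_group.csv"), row.names = FALSE)

  # -- stage 3: representational geometry ------------------------------------
  geometry <- stage("geometry", {
    values <- vapply(group, cross_phase_statistic, numeric(1),
                     shrinkage = cfg$shrinkage)
    # matched SNRs, floored so a signal-free dataset still yields a valid
    # (very low SNR) baseline simulation
    snr_prep <- max(mean(vapply(group, estimate_snr, numeric(1),
                                phase = "preparation")), 0.01)
    snr_prod <- max(mean(vapply(group, estimate_snr, numeric(1),
                                phase = "production")), 0.01)
    base <- simulate_cross_phase_baseline(
      n_voxels = cfg$simulation$n_voxels, n_runs = cfg$simulation$n_runs,
      snr_prep = snr_prep, snr_prod = snr_prod, n_subjects = n_subj,
      switch = FALSE, n_sims = cfg$n_baseline_sims,
      shrinkage = cfg$shrinkage, seed = cfg$seed + 1L)
    ref <- simulate_cross_phase_baseline(
      n_voxels = cfg$simulation$n_voxels, n_runs = cfg$simulation$n_runs,
      snr_prep = snr_prep, snr_prod = snr_prod, n_subjects = n_subj,
      switch = TRUE, n_sims = cfg$n_baseline_sims,
      shrinkage = cfg$shrinkage, seed = cfg$seed + 2L)
    st <- test_against_baseline(values, base,
                                bonferroni_m = cfg$bonferroni_geometry)
    rdm <- if (cfg$simulation$n_runs >= 4)
      crossnobis_rdm(group[[1]], shrinkage = cfg$shrinkage)
    else
      crossnobis_rdm(group[[1]],
                     estimate_noise_covariance(group[[1]], cfg$shrinkage))
    write_rdm_csv(rdm, out("rdm_subject1.csv"))
    utils::write.csv(data.frame(subject = seq_len(n_subj),
                                normalized_distance = values),
                     out("cross_phase_subjects.csv"), row.names = FALSE)
    list(normalized_distance = mean(values), baseline_mean = base$mean,
         switch_reference = ref$mean, t = st$t, p = st$p_corrected,
         d = st$cohens_d, snr_prep = snr_prep, snr_prod = snr_prod)
  })

  # -- stage 4: searchlight demo ---------------------------------------------
  sl_cfg <- cfg$searchlight
  searchlight_report <- stage("searchlight", {
    mask <- box_mask(sl_cfg$grid_dims)
    signal <- box_mask(sl_cfg$grid_dims,
                       box = cbind(c(1, 1, 1), sl_cfg$signal_dims))
    sls <- define_searchlights(mask, target_size = sl_cfg$target_size,
                               max_radius_mm = sl_cfg$max_radius_mm)
    sl_sim <- sim_config(n_voxels = prod(sl_cfg$signal_dims),
                         n_runs = cfg$simulation$n_runs,
                         snr_prep = 0.5, snr_prod = 0.5,
                         n_subjects = sl_cfg$n_subjects,
                         phase_offset = cfg$simulation$phase_offset)
    sl_group <- simulate_group(sl_sim, seed = cfg$seed + 3L)
    maps <- lapply(seq_along(sl_group), function(s) {
      vds <- embed_in_volume(sl_group[[s]], mask, signal,
                             seed = cfg$seed + 100L + s)
      run_searchlight(vds, sls, function(d)
        decode_sequences(d, "order", phase = "preparation",
                         shrinkage = cfg$shrinkage)$z,
        dims = dim(mask$grid))
    })
    gt <- group_t_map(maps, mu = 0, t_threshold = sl_cfg$t_threshold)
    write_map_nifti(gt$t_map, mask, out("searchlight_tmap.nii.gz"))
    utils::write.csv(gt$clusters, out("searchlight_clusters.csv"),
                     row.names = FALSE)
    list(n_searchlights = length(sls),
         max_members = max(vapply(sls, function(s) nrow(s$members), numeric(1))),
         n_clusters = nrow(gt$clusters),
         largest_extent = if (nrow(gt$clusters)) gt$clusters$extent[1] else 0,
         peak_t = if (nrow(gt$clusters)) gt$clusters$peak_t[1] else NA)
  })

  report <- list(seed = cfg$seed, n_subjects = n_subj,
                 decoding = group_tab, geometry = geometry,
                 searchlight = searchlight_report)
  jsonlite::write_json(report, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_config_yaml(cfg$simulation, out("simulation_config.yaml"))
  invisible(report)
}
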