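# End-to-end orchestration: simulate a cohort, cluster, backfit, extract
# parameters, run the group statistics and the meta-analysis, writing
# every intermediate artifact with a content-hash manifest.

#' Pipeline configuration
#'
#' Validated stage parameters with the study defaults: 64 electrodes at
#' 128 Hz, 1-40 Hz band, k = 4 classes, smoothing window half-size 5 and
#' Besag strength 10 with single-frame rejection, Holm family of 12.
#' Unknown keys are rejected.
#'
#' @param ... Overrides for any default field (see Details in the
#'   vignette); unknown names are an error.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    n_subjects = 10L, n_electrodes = 64L, sampling_rate = 128,
    duration = 300, k = 4L,
    mean_durations = c(70, 80, 90, 100), snr = 4,
    min_separation = 0.5,
    n_restarts = 20L, kmeans_tol = 1e-6, kmeans_max_iter = 100L,
    window_half_size = 5L, strength = 10, reject_single_frames = TRUE,
    holm_m = 12L, seed = 1L, out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, over)
  stop_if_not(cfg$n_subjects >= 1, "need at least one subject")
  structure(cfg, class = "pipeline_config")
}

file_hash <- function(path) unname(tools::md5sum(path))

#' Run the microstate analysis pipeline on a synthetic cohort
#'
#' Simulates `n_subjects` recordings from a common planted template set,
#' extracts GFP-peak maps, performs two-level clustering, backfits the
#' group templates on every recording, computes the per-class temporal
#' parameters, and (when `out_dir` is set) writes each intermediate in
#' its documented text format, returning a manifest with content hashes.
#'
#' @param config A [pipeline_config()].
#' @return List with `templates` (planted), `group_fit`, `alignment`
#'   (group vs planted), `params` (tidy long table), `segmentations`,
#'   `ground_truth`, and `manifest` (data.frame path/hash, empty when
#'   nothing is written).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  planted <- make_templates(cfg$n_electrodes, cfg$k,
                            min_separation = cfg$min_separation,
                            seed = derive_seed(cfg$seed, 1L))
  sims <- lapply(seq_len(cfg$n_subjects), function(s) {
    spec <- simulation_spec(planted, sampling_rate = cfg$sampling_rate,
                            duration = cfg$duration,
                            mean_durations = cfg$mean_durations,
                            snr = cfg$snr,
                            seed = derive_seed(cfg$seed, 100L + s))
    simulate_microstate_eeg(spec)
  })
  peak_maps <- lapply(sims, function(sim) {
    idx <- gfp_peaks(global_field_power(sim$recording))
    sim$recording$data[, idx, drop = FALSE]
  })
  tlc <- two_level_clustering(peak_maps, k = cfg$k,
                              n_restarts = cfg$n_restarts,
                              max_iter = cfg$kmeans_max_iter,
                              tol = cfg$kmeans_tol,
                              seed = derive_seed(cfg$seed, 2L))
  al <- align_templates(tlc$group$templates, planted)
  segs <- lapply(sims, function(sim)
    backfit(al$aligned, sim$recording,
            window_half_size = cfg$window_half_size,
            strength = cfg$strength,
            reject_single_frames = cfg$reject_single_frames))
  par_list <- lapply(segs, microstate_parameters)
  names(par_list) <- sprintf("S%02d", seq_len(cfg$n_subjects))
  params <- params_long(par_list)

  manifest <- data.frame(path = character(0), hash = character(0))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    p <- file.path(cfg$out_dir, "templates_group.tsv")
    write_templates(al$aligned, p, gev = tlc$group_gev, seed = cfg$seed)
    paths <- c(paths, p, paste0(p, ".json"))
    for (s in seq_along(sims)) {
      pr <- file.path(cfg$out_dir, sprintf("recording_%02d.tsv", s))
      write_recording(sims[[s]]$recording, pr, extra = list(seed = cfg$seed))
      pg <- file.path(cfg$out_dir, sprintf("ground_truth_%02d.tsv", s))
      write_ground_truth(sims[[s]]$ground_truth, pg)
      ps <- file.path(cfg$out_dir, sprintf("segmentation_%02d.tsv", s))
      write_segmentation(segs[[s]], ps)
      paths <- c(paths, pr, paste0(pr, ".json"), pg, ps)
    }
    pp <- file.path(cfg$out_dir, "params_long.tsv")
    utils::write.table(params, pp, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, pp)
    manifest <- data.frame(path = paths,
                           hash = vapply(paths, file_hash, character(1)))
    rownames(manifest) <- NULL
  }
  list(templates = planted, group_fit = tlc$group, alignment = al,
       params = params, segmentations = segs,
       ground_truth = lapply(sims, `[[`, "ground_truth"),
       manifest = manifest)
}
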