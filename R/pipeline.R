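#' Configuration for an end-to-end synthetic analysis run
#'
#' Collects every knob of the pipeline in one serializable object.
#' Unknown arguments are rejected. The defaults give a compact but
#' complete synthetic experiment; pass a `vwm_design`, `vwm_dynamics`
#' or replacement values to emulate other regimes.
#'
#' @param design a `vwm_design`.
#' @param dynamics a `vwm_dynamics`.
#' @param n_subjects number of simulated subjects.
#' @param n_voxels voxels per subject.
#' @param condition condition analysed by the decoding stages.
#' @param decode_timepoints timepoint indices for the cross-decoding
#'   matrix (`NULL` = all).
#' @param hyper decoder hyperparameters.
#' @param n_perm permutations for the cluster tests (values below 100
#'   trigger a warning that is recorded in the manifest).
#' @param alpha cluster significance level.
#' @param percentile voxel-selection null percentile.
#' @param n_select_perm permutations for the voxel-selection null.
#' @param select_window time window (seconds) averaged for the memory
#'   side of voxel selection; `NULL` uses the dataset's full time range.
#' @param apa_windows two time windows (seconds) compared by the subspace
#'   stage.
#' @param n_apa_iter split-half iterations for the aPA.
#' @param run_snrsim logical: also run the SNR cross-decoding simulation.
#' @param seed master seed; all stage seeds derive from it.
#' @return a list of class `vwm_config`.
#' @export
pipeline_config <- function(design = design_spec(),
                            dynamics = dynamics_spec(),
                            n_subjects = 3,
                            n_voxels = 60,
                            condition = "no_distractor",
                            decode_timepoints = NULL,
                            hyper = psvr_hyperparams(),
                            n_perm = 1000,
                            alpha = 0.05,
                            percentile = 75,
                            n_select_perm = 200,
                            select_window = NULL,
                            apa_windows = list(c(4, 8), c(9.6, 13.6)),
                            n_apa_iter = 100,
                            run_snrsim = FALSE,
                            seed = 1L) {
  structure(list(
    design = design, dynamics = dynamics,
    n_subjects = as.integer(n_subjects),
    n_voxels = as.integer(n_voxels),
    condition = condition,
    decode_timepoints = decode_timepoints,
    hyper = hyper, n_perm = as.integer(n_perm), alpha = alpha,
    percentile = percentile, n_select_perm = as.integer(n_select_perm),
    select_window = select_window,
    apa_windows = apa_windows, n_apa_iter = as.integer(n_apa_iter),
    run_snrsim = isTRUE(run_snrsim),
    seed = as.integer(seed)
  ), class = "vwm_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Generates one synthetic dataset per subject, selects reliable voxels
#' against a synthetic perception localizer drawn from the same tuning,
#' computes the temporal cross-decoding matrix per subject, identifies
#' dynamic-coding elements and the dynamicism index at the group level,
#' measures the above-baseline principal angle between two delay windows,
#' and (optionally) runs the SNR cross-decoding simulation. All artifacts
#' are written as tab-separated text or JSON under `out_dir` together
#' with a manifest (package version, seeds, stage warnings and file
#' hashes). Given the same configuration the run is deterministic.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "vwm_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  note <- function(...) {
    warnings_log <<- c(warnings_log, paste0(...))
  }
  if (config$n_perm < 100)
    note("n_perm = ", config$n_perm,
         ": fewer than 100 permutations, p-values are coarse")

  subj_seed <- function(s, stage) config$seed + 1000L * s + stage

  datasets <- lapply(seq_len(config$n_subjects), function(s) {
    tuning <- generate_tuned_voxels(config$n_voxels,
                                    seed = subj_seed(s, 1L))
    generate_experiment(config$design, config$dynamics, tuning,
                        seed = subj_seed(s, 2L))
  })

  # voxel selection against a synthetic perception localizer: an
  # independent single-timepoint run from the same tuned population
  loc_design <- design_spec(
    n_sessions = 2,
    n_trials_per_condition_per_session =
      config$design$n_trials_per_condition_per_session,
    conditions = "perception",
    orientation_bins = config$design$orientation_bins,
    tr_seconds = config$design$tr_seconds,
    timepoints = 1)
  selections <- lapply(seq_len(config$n_subjects), function(s) {
    tuning <- generate_tuned_voxels(config$n_voxels,
                                    seed = subj_seed(s, 1L))
    loc <- generate_experiment(loc_design, dynamics_spec(
      snr_schedule = mean(config$dynamics$snr_schedule)), tuning,
      seed = subj_seed(s, 3L))
    win <- config$select_window
    if (is.null(win)) win <- range(datasets[[s]]$time_s)
    mem <- window_average(datasets[[s]], win, config$condition)
    reliability_select(
      memory = list(patterns = mem$patterns,
                    labels = mem$trials$target_deg,
                    sessions = mem$trials$session),
      perception = list(patterns = loc$bold[, , 1],
                        labels = loc$trials$target_deg,
                        sessions = loc$trials$session),
      n_bins = config$design$orientation_bins,
      n_perm = config$n_select_perm,
      percentile = config$percentile,
      seed = subj_seed(s, 4L))
  })

  restrict <- function(dataset, mask) {
    dataset$bold <- dataset$bold[, mask, , drop = FALSE]
    dataset
  }
  analysed <- lapply(seq_len(config$n_subjects), function(s) {
    mask <- selections[[s]]$table$selected
    if (sum(mask) < 4) {
      note("subject ", s, ": fewer than 4 reliable voxels, ",
           "keeping all voxels")
      datasets[[s]]
    } else restrict(datasets[[s]], mask)
  })

  matrices <- lapply(seq_len(config$n_subjects), function(s)
    cross_decode_matrix(analysed[[s]], config$condition,
                        timepoints = config$decode_timepoints,
                        hyper = config$hyper))
  stack <- stack_subjects(matrices)
  dyn <- dynamic_elements(stack, n_perm = config$n_perm,
                          alpha = config$alpha,
                          seed = config$seed + 7L)
  dix <- dynamicism_index(dyn)

  apa <- vapply(seq_len(config$n_subjects), function(s)
    above_baseline_pa(analysed[[s]], config$apa_windows[[1]],
                      config$apa_windows[[2]],
                      condition = config$condition,
                      n_iter = config$n_apa_iter,
                      seed = subj_seed(s, 5L))$apa_deg, numeric(1))
  apa_p <- apa_sign_test(apa)

  # artifacts
  long <- do.call(rbind, lapply(seq_along(matrices), function(s)
    xdecode_long(matrices[[s]], subject = s)))
  utils::write.table(long, file.path(out_dir, "cross_decoding.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(time_s = attr(matrices[[1]], "time_s"),
               dynamicism = dix),
    file.path(out_dir, "dynamicism_index.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    which(dyn$is_dynamic, arr.ind = TRUE),
    file.path(out_dir, "dynamic_elements.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  for (s in seq_len(config$n_subjects))
    utils::write.table(
      selections[[s]]$table,
      file.path(out_dir, sprintf("voxel_selection_s%02d.tsv", s)),
      sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(apa_deg = apa, p = apa_p,
         windows = config$apa_windows,
         n_iter = config$n_apa_iter),
    file.path(out_dir, "apa.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  snr <- NULL
  if (config$run_snrsim) {
    tuning <- generate_tuned_voxels(200, seed = config$seed + 11L)
    snr <- snr_cross_decode(tuning, seed = config$seed + 12L)
    utils::write.table(
      as.matrix(snr), file.path(out_dir, "snr_cross_decoding.tsv"),
      sep = "\t", row.names = FALSE, col.names = FALSE)
  }

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("vwmdyn")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    n_subjects = config$n_subjects,
    condition = config$condition,
    counts = list(
      trials_per_subject = nrow(datasets[[1]]$trials),
      voxels_total = config$n_voxels,
      voxels_selected = vapply(selections, function(x)
        sum(x$table$selected), integer(1)),
      timepoints = dim(stack)[2]),
    dynamicism_index = dix,
    apa_deg = apa,
    apa_p = apa_p,
    warnings = warnings_log,
    hashes = as.list(stats::setNames(
      unname(tools::md5sum(files)), basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
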