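#' Write a dataset as plain-text files
#'
#' Serializes a `vwm_dataset` into a directory: `trials.tsv` (columns
#' trial, session, condition, target_deg, distractor_deg, bin),
#' `bold.tsv` (one row per trial; voxels vary fastest, then timepoints;
#' full double precision) and `meta.json` (dimensions, TR, seed and the
#' ground-truth dynamics when present). The written pair round-trips
#' through [read_dataset()] bit-identically.
#'
#' @param dataset a `vwm_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(dataset$trials, file.path(dir, "trials.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  d <- dim(dataset$bold)
  flat <- matrix(dataset$bold, d[1], d[2] * d[3])
  lines <- apply(flat, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, file.path(dir, "bold.tsv"))
  meta <- list(
    n_trials = d[1], n_voxels = d[2], n_timepoints = d[3],
    tr_seconds = dataset$tr_seconds,
    time_s = dataset$time_s,
    seed = dataset$seed)
  if (!is.null(dataset$truth)) {
    dyn <- dataset$truth$dynamics
    meta$truth <- list(
      rotation_schedule = dyn$rotation_schedule,
      distractor_subspace_overlap = dyn$distractor_subspace_overlap,
      snr_schedule = dyn$snr_schedule,
      tuning_basis = dataset$truth$tuning$basis,
      tuning_shifts = dataset$truth$tuning$shifts)
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' Validates the schema: required trial-table columns must be present,
#' conditions carrying an orientation distractor must have distractor
#' labels, and orientation values of exactly 180 degrees are normalized
#' to 0 with a warning (the label space is half-open).
#'
#' @param dir directory containing `trials.tsv`, `bold.tsv`, `meta.json`.
#' @return a `vwm_dataset`.
#' @export
read_dataset <- function(dir) {
  trials <- utils::read.table(file.path(dir, "trials.tsv"),
                              header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  required <- c("trial", "session", "condition", "target_deg",
                "distractor_deg", "bin")
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0)
    stop("trials.tsv lacks column(s): ", paste(missing, collapse = ", "))
  if (any(trials$target_deg >= 180 | trials$target_deg < 0)) {
    if (any(trials$target_deg == 180)) {
      warning("target orientations of 180 degrees normalized to 0")
      trials$target_deg[trials$target_deg == 180] <- 0
    }
    if (any(trials$target_deg >= 180 | trials$target_deg < 0))
      stop("target_deg must lie in [0, 180)")
  }
  dist_cond <- grepl("orientation_distractor", trials$condition)
  if (any(dist_cond & is.na(trials$distractor_deg)))
    stop("column 'distractor_deg' is missing for ",
         "orientation-distractor trials")
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(file.path(dir, "bold.tsv"),
                                      sep = "\t", header = FALSE))
  dimnames(flat) <- NULL
  if (nrow(flat) != meta$n_trials ||
      ncol(flat) != meta$n_voxels * meta$n_timepoints)
    stop("bold.tsv dimensions disagree with meta.json")
  if (nrow(flat) != nrow(trials))
    stop("bold.tsv and trials.tsv disagree on the number of trials")
  structure(list(
    trials = trials,
    bold = array(flat, c(meta$n_trials, meta$n_voxels,
                         meta$n_timepoints)),
    tr_seconds = meta$tr_seconds,
    time_s = meta$time_s,
    truth = meta$truth,
    seed = meta$seed
  ), class = "vwm_dataset")
}
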