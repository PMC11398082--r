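# Pipeline stages and the command-line surface. Stages communicate through
# files, not in-memory state, because the human-verification step is an
# offline gap in the real workflow: `sample` emits a manifest that a reviewer
# fills in, and later stages consume the labeled file. Each stage writes a
# log recording package version, seed and a config hash, so a logged run is
# fully reproducible.

stage_log <- function(dir, stage, seed, config) {
  lines <- c(
    sprintf("stage = %s", stage),
    sprintf("pamthresh_version = %s", as.character(utils::packageVersion("pamthresh"))),
    sprintf("timestamp = %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S", tz = "UTC")),
    sprintf("seed = %s", format(seed)),
    sprintf("config_hash = %s", rlang::hash(config))
  )
  readr::write_lines(lines, file.path(dir, paste0(stage, ".log")))
}

require_upstream <- function(path, stage) {
  if (!file.exists(path)) {
    abort(sprintf("stage '%s' needs missing upstream artifact: %s", stage, path))
  }
  path
}

#' Pipeline stages
#'
#' File-to-file stage functions mirroring the survey workflow: simulate a
#' detection table (stand-in for running the recognizer over a year of
#' audio), draw the stratified verification sample, estimate precision by
#' class, calibrate and derive the threshold, filter, and describe activity
#' patterns. `run_pipeline()` chains them end-to-end over the three-species
#' study preset, auto-labeling the manifests from simulated ground truth.
#'
#' @param outdir output directory (created if needed).
#' @param seed integer seed for every random stage.
#' @param scale preset rate multiplier (see [study_preset()]).
#' @param per_bin verification sample size per fine bin.
#' @param p_target target probability of correct identification.
#' @return `run_pipeline()` returns (invisibly) a list per species with the
#'   precision table, fit, threshold and — when the threshold is valid —
#'   the activity profiles.
#' @export
run_pipeline <- function(outdir, seed = 1L, scale = 1, per_bin = 50, p_target = 0.9) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- study_preset(scale)

  # simulate
  sim <- generate_detections(cfg, seed = seed)
  det_path <- file.path(outdir, "detections.tsv")
  write_detection_table(sim$detections, det_path)
  truth_path <- file.path(outdir, "ground_truth.csv")
  readr::write_csv(sim$truth, truth_path, progress = FALSE)
  stage_log(outdir, "simulate", seed, list(cfg = cfg, scale = scale))

  detections <- suppressMessages(read_detection_table(det_path))
  scheme <- bin_scheme()
  results <- list()
  summary_lines <- character()

  species <- unique(detections$scientific_name)
  for (i in seq_along(species)) {
    sp <- species[i]
    tag <- gsub("[^A-Za-z0-9]+", "_", sp)
    det_sp <- detections[detections$scientific_name == sp, ]

    # sample -> manifest -> (simulated reviewer) -> labels
    sampled <- stratified_sample(det_sp, scheme, per_bin = per_bin, seed = seed + i)
    man_path <- file.path(outdir, paste0("manifest_", tag, ".csv"))
    write_manifest(sampled, man_path)
    lab_path <- file.path(outdir, paste0("labels_", tag, ".csv"))
    autolabel_manifest(man_path, truth_path, lab_path)
    labels <- read_labels(lab_path, detections = det_sp)

    # precision
    ptab <- precision_table(labels, scheme, species = sp)
    write_precision_table(ptab, file.path(outdir, paste0("precision_", tag, ".tsv")))

    # calibrate
    fit <- fit_logistic(labels)
    thr <- threshold_for_probability(fit, p_target = p_target)
    write_calibration_report(fit, thr, file.path(outdir, paste0("calibration_", tag, ".txt")))

    res <- list(species = sp, precision = ptab, fit = fit, threshold = thr)
    summary_lines <- c(summary_lines, sprintf(
      "%s: overall precision %.1f%%, threshold %s (status %s)",
      sp, ptab$precision[nrow(ptab)],
      if (thr$status == "valid") sprintf("%.3f", thr$confidence_threshold) else "-",
      thr$status))

    # filter + patterns only where a valid threshold exists
    if (thr$status == "valid") {
      filt <- filter_by_threshold(det_sp, thr, quiet = TRUE)
      res$n_filtered <- nrow(filt)
      res$diel <- diel_profile(filt)
      res$annual <- annual_profile(filt)
      write_activity_table(res$diel, file.path(outdir, paste0("hourly_", tag, ".tsv")))
      write_activity_table(res$annual, file.path(outdir, paste0("monthly_", tag, ".tsv")))
      summary_lines <- c(summary_lines, sprintf(
        "  retained %d detections; dawn-window (06-08 h) share %.1f%%",
        nrow(filt), window_share(res$diel, c("06", "07", "08"))))
    }
    results[[sp]] <- res
  }
  stage_log(outdir, "pipeline", seed, list(cfg = cfg, per_bin = per_bin, p_target = p_target))
  readr::write_lines(summary_lines, file.path(outdir, "report.txt"))
  invisible(results)
}

#' Fill a verification manifest from a ground-truth file
#'
#' Stands in for the human reviewer when working with synthetic data: the
#' blank `correct` column of a manifest is filled from the generator's
#' ground-truth labels.
#'
#' @param manifest_path manifest written by [write_manifest()].
#' @param truth_path CSV with `detection_id`, `correct`.
#' @param out_path labeled manifest to write.
#' @export
autolabel_manifest <- function(manifest_path, truth_path, out_path) {
  man <- readr::read_csv(manifest_path,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  truth <- readr::read_csv(truth_path,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  idx <- match(man$detection_id, truth$detection_id)
  if (anyNA(idx)) abort("manifest contains detections absent from the ground truth.")
  man$correct <- tolower(truth$correct[idx])
  man$reviewer <- "simulated"
  readr::write_csv(man, out_path, progress = FALSE)
  invisible(out_path)
}

#' Command-line entry point
#'
#' Thin argument-parsing layer over the stage functions, used by the
#' `inst/cli/pamthresh` Rscript. Subcommands: `pipeline` (simulate through
#' report in one pass), `simulate`, `sample`, `precision`, `calibrate`,
#' `filter`, `patterns`. Exit codes: 0 success, 2 invalid threshold status,
#' 3 format error.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return integer exit code.
#' @export
pam_cli <- function(args) {
  usage <- paste(
    "usage: pamthresh <subcommand> [--key value ...]",
    "  pipeline  --out DIR [--seed N] [--scale X] [--per-bin N] [--target-probability P]",
    "  simulate  --out DIR [--seed N] [--scale X]",
    "  sample    --detections FILE --out MANIFEST [--per-bin N] [--seed N] [--species NAME]",
    "  precision --labels FILE --out FILE",
    "  calibrate --labels FILE --out FILE [--target-probability P]",
    "  filter    --detections FILE --calibration FILE --out FILE",
    "  patterns  --detections FILE --out-prefix PREFIX",
    sep = "\n")
  if (!length(args)) { cat(usage, "\n"); return(1L) }
  cmd <- args[1]
  opt <- parse_cli_args(args[-1])
  get <- function(key, default = NULL) {
    if (!is.null(opt[[key]])) opt[[key]] else if (!is.null(default)) default
    else abort(paste0("missing required flag --", key))
  }
  num <- function(key, default = NULL) as.numeric(get(key, default))
  tryCatch({
    switch(cmd,
      pipeline = {
        run_pipeline(get("out"), seed = as.integer(num("seed", 1)),
                     scale = num("scale", 1), per_bin = as.integer(num("per-bin", 50)),
                     p_target = num("target-probability", 0.9))
      },
      simulate = {
        outdir <- get("out")
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        sim <- emulate_study(seed = as.integer(num("seed", 1)), scale = num("scale", 1))
        write_detection_table(sim$detections, file.path(outdir, "detections.tsv"))
        readr::write_csv(sim$truth, file.path(outdir, "ground_truth.csv"), progress = FALSE)
        stage_log(outdir, "simulate", as.integer(num("seed", 1)), opt)
      },
      sample = {
        det <- read_detection_table(require_upstream(get("detections"), "sample"))
        if (!is.null(opt$species)) det <- det[det$scientific_name == opt$species, ]
        sampled <- stratified_sample(det, per_bin = as.integer(num("per-bin", 50)),
                                     seed = as.integer(num("seed", 1)))
        write_manifest(sampled, get("out"))
      },
      precision = {
        labels <- read_labels(require_upstream(get("labels"), "precision"))
        write_precision_table(precision_table(labels), get("out"))
      },
      calibrate = {
        labels <- read_labels(require_upstream(get("labels"), "calibrate"))
        fit <- fit_logistic(labels)
        thr <- threshold_for_probability(fit, p_target = num("target-probability", 0.9))
        write_calibration_report(fit, thr, get("out"))
        if (thr$status != "valid") {
          message("no valid threshold: status ", thr$status)
          return(2L)
        }
      },
      filter = {
        det <- read_detection_table(require_upstream(get("detections"), "filter"))
        rep <- read_config(require_upstream(get("calibration"), "filter"))
        if (!identical(rep$status, "valid")) {
          message("cannot filter: threshold status is ", rep$status)
          return(2L)
        }
        filt <- filter_by_threshold(det, rep$confidence_threshold, quiet = TRUE)
        write_detection_table(filt, get("out"))
      },
      patterns = {
        det <- read_detection_table(require_upstream(get("detections"), "patterns"))
        write_activity_table(diel_profile(det), paste0(get("out-prefix"), "_hourly.tsv"))
        write_activity_table(annual_profile(det), paste0(get("out-prefix"), "_monthly.tsv"))
      },
      { cat(usage, "\n"); return(1L) }
    )
    0L
  },
  pamthresh_invalid_threshold = function(e) { message(conditionMessage(e)); 2L },
  pamthresh_format_error = function(e) { message(conditionMessage(e)); 3L })
}

parse_cli_args <- function(args) {
  opt <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) abort(paste("unexpected argument:", args[i]))
    key <- sub("^--", "", args[i])
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      opt[[key]] <- TRUE; i <- i + 1
    } else {
      opt[[key]] <- args[i + 1]; i <- i + 2
    }
  }
  opt
}
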