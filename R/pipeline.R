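## Start-to-end orchestration: load -> segment (pluggable backend) ->
## optional papillary refinement -> biomarkers -> post-analysis QC.
## Studies are processed in isolation: a failing study is logged and
## skipped, never aborting the cohort. All outputs are deterministic
## (byte-identical across re-runs with the same inputs and config).

# apply the segmentation backend to one study, returning a study whose
# stacks are the backend's outputs
.apply_backend <- function(study, config) {
  if (config@backend == "passthrough") return(study)
  if (!nzchar(config@backendCommand))
    stop("backend 'command' requires a backendCommand executable")
  if (!length(study@intensities))
    stop("backend 'command' requires intensity volumes")
  out_stacks <- list()
  for (ph in names(study@intensities)) {
    tmp_in <- tempfile(fileext = ".nii"); tmp_out <- tempfile(fileext = ".nii")
    ref <- study@stacks[[ph]]
    .write_intensity(study@intensities[[ph]], ref, tmp_in)
    status <- system2(config@backendCommand, c(tmp_in, tmp_out))
    if (status != 0 || !file.exists(tmp_out))
      stop(sprintf("segmentation backend failed on phase '%s' (exit %d)", ph, status))
    arr <- .read_intensity(tmp_out)
    if (any(arr != as.integer(arr)))
      stop("backend produced non-integer labels")
    storage.mode(arr) <- "integer"
    out_stacks[[ph]] <- LabelStack(arr, ref@inPlaneSpacing, ref@sliceSpacing, ph)
    unlink(c(tmp_in, tmp_out))
  }
  CineStudy(study@studyId, out_stacks, study@intensities, study@meta)
}

# resolved config as a deterministic JSON string (for the run log)
.config_json <- function(config) {
  sc <- config@screening
  jsonlite::toJSON(list(
    backend = config@backend, papillary_mode = config@papillaryMode,
    myo_density_g_per_ml = config@myoDensity,
    apply_corrections = config@applyCorrections, seed = config@seed,
    screening = list(sv_discordance_fraction = sc@svDiscordanceFraction,
                     volume_ranges_ml = sc@volumeRangesMl,
                     min_lv_extent_mm = sc@minLvExtentMm,
                     apical_area_fraction_max = sc@apicalAreaFractionMax,
                     min_component_voxels = sc@minComponentVoxels)),
    auto_unbox = TRUE, digits = NA)
}

#' Run the full analysis pipeline over a cohort
#'
#' For each study: load (if given a manifest), segment via the configured
#' backend, compute biomarkers (with optional papillary exclusion), run
#' post-analysis QC with optional auto-correction, and write per-study
#' outputs (`biomarkers.csv`, `qc_report.csv`, corrected label stacks)
#' plus a cohort summary and a machine-readable JSON-lines run log
#' recording the resolved configuration and per-study flag counts.
#'
#' @param cohort list of [CineStudy-class] objects, or a cohort manifest
#'   CSV path (columns study_id, phase_tag, kind, path; several studies;
#'   paths relative to the manifest's directory). A `series_type` column,
#'   when present, filters rows to `series_type == "SAX"`.
#' @param config a [PipelineConfig-class].
#' @param outDir output directory (created); omit (NULL) to skip writing.
#' @return list with `summary` (one row per study: biomarkers, flag count,
#'   status), `results` (per-study list: study, report, biomarkers),
#'   `errors` (named character), and `status` (0 clean, 2 partial
#'   failures).
#' @export
runPipeline <- function(cohort, config = pipelineConfig(), outDir = NULL) {
  if (is.character(cohort)) {
    manifest <- utils::read.csv(cohort, stringsAsFactors = FALSE)
    if ("series_type" %in% names(manifest))
      manifest <- manifest[manifest$series_type == "SAX", , drop = FALSE]
    base <- dirname(cohort)
    cohort <- lapply(unique(manifest$study_id), function(id)
      loadStudy(base, manifest[manifest$study_id == id, , drop = FALSE]))
  }
  ids <- vapply(cohort, studyId, character(1))
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  results <- list(); errors <- character(); summary_rows <- list()
  log_lines <- c(.config_json(config))

  for (i in seq_along(cohort)) {
    id <- ids[i]
    res <- tryCatch({
      seg <- .apply_backend(cohort[[i]], config)
      qc <- runQcPost(seg, config@screening,
                      applyCorrections = config@applyCorrections,
                      papillaryMode = config@papillaryMode,
                      myoDensity = config@myoDensity)
      qc
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[id] <- conditionMessage(res)
      log_lines <- c(log_lines, jsonlite::toJSON(
        list(study_id = id, status = "error", message = conditionMessage(res)),
        auto_unbox = TRUE, digits = NA))
      next
    }
    results[[id]] <- res
    n_flags <- length(res$report)
    bm <- if (!is.null(res$biomarkers)) as.data.frame(res$biomarkers) else
      as.data.frame(as.list(stats::setNames(rep(NA_real_, length(.biomarker_names)),
                                            .biomarker_names)))
    summary_rows[[id]] <- cbind(data.frame(study_id = id, stringsAsFactors = FALSE),
                                bm, data.frame(n_flags = n_flags))
    log_lines <- c(log_lines, jsonlite::toJSON(
      list(study_id = id, status = "ok", n_flags = n_flags),
      auto_unbox = TRUE, digits = NA))

    if (!is.null(outDir)) {
      sdir <- file.path(outDir, id)
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(bm, file.path(sdir, "biomarkers.csv"), row.names = FALSE)
      writeFlagReport(res$report, id, file.path(sdir, "qc_report.csv"))
      for (ph in names(res$study@stacks))
        writeLabelStack(res$study@stacks[[ph]],
                        file.path(sdir, sprintf("%s_label.nii", ph)))
    }
  }

  summary <- if (length(summary_rows)) do.call(rbind, summary_rows) else NULL
  if (!is.null(summary)) rownames(summary) <- NULL
  if (!is.null(outDir)) {
    if (!is.null(summary))
      utils::write.csv(summary, file.path(outDir, "cohort_summary.csv"),
                       row.names = FALSE)
    writeLines(log_lines, file.path(outDir, "run_log.jsonl"))
  }
  list(summary = summary, results = results, errors = errors,
       status = if (length(errors)) 2L else 0L)
}
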