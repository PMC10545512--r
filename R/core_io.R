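## Canonical on-disk form: NIfTI-1 volumes (labels: int16; intensities:
## float64) stored (row, col, slice), plus a JSON sidecar per label volume
## {label_map, phase_tag, spacing_mm: [row, col, slice], slice0, dim}.
## Sidecar spacings override NIfTI header values when both are present.
## Slice index 1 is the most basal slice; a sidecar `slice0` of "apex"
## triggers a flip on load. Sidecars may declare a permuted label encoding,
## which is remapped to the canonical vocabulary on load; unknown voxel
## values are an error, never a coercion.

.default_sidecar_path <- function(volume_path)
  paste0(sub("\\.nii(\\.gz)?$", "", volume_path), ".json")

#' Write a LabelStack as NIfTI + JSON sidecar
#'
#' Writes an int16 NIfTI volume and a JSON sidecar such that
#' [readLabelStack()] inverts exactly (voxels, spacings, label map, phase
#' tag). Two writes of the same stack produce byte-identical sidecars.
#'
#' @param stack a [LabelStack-class].
#' @param volumePath output NIfTI path (.nii or .nii.gz).
#' @param sidecarPath output JSON path (default: volume path with .json).
#' @return invisibly, the two paths.
#' @export
writeLabelStack <- function(stack, volumePath,
                            sidecarPath = .default_sidecar_path(volumePath)) {
  stopifnot(is(stack, "LabelStack"))
  v <- stack@voxels
  if (!is.integer(v)) stop("labels are integer-only; refusing non-integer storage")
  arr <- aperm(v, c(2, 3, 1))  # (row, col, slice) on disk
  sp <- c(stack@inPlaneSpacing, stack@sliceSpacing)
  attr(arr, "pixdim") <- sp
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int16"), volumePath)
  sidecar <- list(
    label_map = as.list(stack@labelMap),
    phase_tag = stack@phaseTag,
    spacing_mm = sp,
    slice0 = "base",
    dim = dim(v))
  jsonlite::write_json(sidecar, sidecarPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(volume = volumePath, sidecar = sidecarPath))
}

#' Read a LabelStack from NIfTI + JSON sidecar
#'
#' @param volumePath NIfTI label volume.
#' @param sidecarPath JSON sidecar (default: volume path with .json); must
#'   declare `label_map`, `phase_tag` and `spacing_mm` (spacings in the
#'   sidecar override NIfTI header values).
#' @return a validated [LabelStack-class] in the canonical label
#'   vocabulary, slice 1 most basal.
#' @export
readLabelStack <- function(volumePath,
                           sidecarPath = .default_sidecar_path(volumePath)) {
  if (!file.exists(volumePath)) stop(sprintf("volume not found: %s", volumePath))
  if (!file.exists(sidecarPath)) stop(sprintf("sidecar not found: %s", sidecarPath))
  sidecar <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  for (f in c("label_map", "phase_tag", "spacing_mm"))
    if (is.null(sidecar[[f]])) stop(sprintf("sidecar lacks required field '%s'", f))

  img <- RNifti::readNifti(volumePath)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L) stop("label volume must be 2D or 3D")
  v <- aperm(arr, c(3, 1, 2))  # back to (slice, row, col)
  if (any(v != as.integer(v))) stop("labelling error: non-integer voxel values")
  storage.mode(v) <- "integer"

  if (!is.null(sidecar$dim) && !identical(as.integer(sidecar$dim), dim(v)))
    stop(sprintf("consistency error: sidecar dim [%s] does not match volume dim [%s]",
                 paste(sidecar$dim, collapse = ","), paste(dim(v), collapse = ",")))

  file_map <- unlist(sidecar$label_map)
  canonical <- canonicalLabelMap(with_pap = TRUE)
  bad_names <- setdiff(names(file_map), names(canonical))
  if (length(bad_names))
    stop(sprintf("labelling error: unknown class name(s) in sidecar: %s",
                 paste(bad_names, collapse = ", ")))
  unknown <- setdiff(unique(as.vector(v)), file_map)
  if (length(unknown)) {
    cnt <- sum(v %in% unknown)
    stop(sprintf("labelling error: voxel value(s) %s not in the declared label map (%d voxels)",
                 paste(sort(unknown), collapse = ", "), cnt))
  }
  # remap a (possibly permuted) file encoding to the canonical vocabulary
  if (!identical(file_map[names(file_map)], canonical[names(file_map)])) {
    remapped <- v
    for (nm in names(file_map)) remapped[v == file_map[[nm]]] <- canonical[[nm]]
    v <- remapped
  }
  if (identical(sidecar$slice0, "apex")) v <- v[rev(seq_len(dim(v)[1])), , , drop = FALSE]

  sp <- as.numeric(sidecar$spacing_mm)
  if (length(sp) != 3L) stop("sidecar spacing_mm must have 3 elements (row, col, slice)")
  if (any(sp <= 0) || any(!is.finite(sp)))
    stop("geometry error: non-positive voxel spacing in sidecar")
  lm <- if (any(v == 4L)) canonical else canonicalLabelMap()
  LabelStack(v, sp[1:2], sp[3], as.character(sidecar$phase_tag), labelMap = lm)
}

# read an intensity volume written by writeStudy (or any NIfTI scalar
# volume) into the (slice, row, col) convention
.read_intensity <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  aperm(arr, c(3, 1, 2))
}

.write_intensity <- function(vol, stack, path) {
  arr <- aperm(vol, c(2, 3, 1))
  attr(arr, "pixdim") <- c(stack@inPlaneSpacing, stack@sliceSpacing)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
}

#' Write a CineStudy to a directory
#'
#' Writes one label volume + sidecar per phase (`<phase>_label.nii`),
#' optional intensity volumes (`<phase>_intensity.nii`, float64), a
#' `manifest.csv` (study_id, phase_tag, kind, path) and a `meta.json`.
#'
#' @param study a [CineStudy-class].
#' @param directory output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
writeStudy <- function(study, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (ph in names(study@stacks)) {
    vol <- sprintf("%s_label.nii", ph)
    writeLabelStack(study@stacks[[ph]], file.path(directory, vol))
    rows[[length(rows) + 1L]] <- data.frame(
      study_id = study@studyId, phase_tag = ph, kind = "label", path = vol,
      stringsAsFactors = FALSE)
    if (ph %in% names(study@intensities)) {
      ivol <- sprintf("%s_intensity.nii", ph)
      .write_intensity(study@intensities[[ph]], study@stacks[[ph]],
                       file.path(directory, ivol))
      rows[[length(rows) + 1L]] <- data.frame(
        study_id = study@studyId, phase_tag = ph, kind = "intensity",
        path = ivol, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(directory, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  if (length(study@meta))
    jsonlite::write_json(study@meta, file.path(directory, "meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

#' Load a CineStudy from a directory and manifest
#'
#' @param directory directory holding the volumes; manifest paths are
#'   resolved relative to it.
#' @param manifest manifest CSV path or data.frame with columns study_id,
#'   phase_tag, kind (label|intensity), path; default
#'   `<directory>/manifest.csv`. Must describe a single study.
#' @param meta metadata list; default: `<directory>/meta.json` if present.
#' @return a validated [CineStudy-class].
#' @export
loadStudy <- function(directory, manifest = file.path(directory, "manifest.csv"),
                      meta = NULL) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop(sprintf("manifest not found: %s", manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  need <- c("study_id", "phase_tag", "kind", "path")
  if (!all(need %in% names(manifest)))
    stop(sprintf("manifest error: columns %s required", paste(need, collapse = ", ")))
  ids <- unique(manifest$study_id)
  if (length(ids) != 1L)
    stop("manifest error: loadStudy expects exactly one study_id")
  stacks <- list(); intens <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    path <- file.path(directory, row$path)
    if (!file.exists(path))
      stop(sprintf("manifest error: declared %s volume missing for phase '%s': %s",
                   row$kind, row$phase_tag, path))
    if (row$kind == "label") {
      stacks[[row$phase_tag]] <- readLabelStack(path)
    } else if (row$kind == "intensity") {
      intens[[row$phase_tag]] <- .read_intensity(path)
    } else {
      stop(sprintf("manifest error: unknown kind '%s'", row$kind))
    }
  }
  for (ph in names(intens)) {
    if (!ph %in% names(stacks))
      stop(sprintf("consistency error: intensity without label stack for phase '%s'", ph))
    if (!identical(dim(intens[[ph]]), dim(stacks[[ph]]@voxels)))
      stop(sprintf("consistency error: intensity/label shape mismatch for phase '%s'", ph))
  }
  if (is.null(meta)) {
    mp <- file.path(directory, "meta.json")
    meta <- if (file.exists(mp)) {
      m <- jsonlite::read_json(mp, simplifyVector = TRUE)
      lapply(m, function(x) if (is.list(x)) unlist(x) else x)
    } else list()
  }
  CineStudy(ids, stacks, intens, meta)
}

#' Read a cohort metadata table
#'
#' Expected columns: study_id, disease_group, vendor, model, field_T,
#' lv_ed_frame, lv_es_frame, rv_ed_frame, rv_es_frame (frame columns
#' optional).
#'
#' @param path CSV path.
#' @return named list (by study_id) of metadata lists suitable for
#'   [CineStudy()].
#' @export
readCohortMeta <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"study_id" %in% names(tab)) stop("cohort metadata must have a study_id column")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    m <- list(disease_group = row$disease_group %||% NA_character_,
              scanner_vendor = row$vendor %||% NA_character_,
              scanner_model = row$model %||% NA_character_,
              field_strength_T = row$field_T %||% NA_real_)
    if (!is.null(row$lv_ed_frame) && !is.na(row$lv_ed_frame))
      m$lv_phases <- c(row$lv_ed_frame, row$lv_es_frame)
    if (!is.null(row$rv_ed_frame) && !is.na(row$rv_ed_frame))
      m$rv_phases <- c(row$rv_ed_frame, row$rv_es_frame)
    m
  })
  stats::setNames(out, tab$study_id)
}

#' Serialize a FlagReport to CSV
#'
#' @param report a [FlagReport-class].
#' @param studyId study identifier written into the first column.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeFlagReport <- function(report, studyId, path) {
  e <- report@entries
  out <- cbind(data.frame(study_id = rep(studyId, nrow(e)),
                          stringsAsFactors = FALSE), e)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
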