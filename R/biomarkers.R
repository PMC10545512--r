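## Ventricular volumetry: voxel-count Simpson-style summation. Volumes are
## (voxel count) x (row spacing x col spacing x slice spacing) / 1000 mL;
## no partial-volume weighting or contour smoothing, matching mask-based
## ground truth and keeping the analytic oracle exact.

.incomplete <- function(msg) {
  stop(structure(class = c("cineqc_incomplete", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Volume of one label compartment
#'
#' @param stack a [LabelStack-class].
#' @param label label name or code.
#' @return volume in mL (0 for an empty label).
#' @examples
#' v <- array(0L, c(2, 10, 10)); v[1, 1:5, 1:4] <- 1L
#' compartmentVolume(LabelStack(v, c(1, 1), 10, "ED"), "LVBP")  # 0.2 mL
#' @export
compartmentVolume <- function(stack, label) {
  code <- .label_code(stack, label)
  sum(stack@voxels == code) * .voxel_ml(stack)
}

#' Select the ED and ES phases for one ventricle
#'
#' Metadata-declared phases (`lv_phases` / `rv_phases`) win when present;
#' otherwise ED is the phase of maximal and ES the phase of minimal
#' non-zero blood-pool volume. Clinical datasets may declare different
#' frames for the two ventricles.
#'
#' @param study a [CineStudy-class].
#' @param ventricle "LV" or "RV".
#' @return character vector `c(ED tag, ES tag)`.
#' @export
selectPhases <- function(study, ventricle = c("LV", "RV")) {
  ventricle <- match.arg(ventricle)
  declared <- study@meta[[if (ventricle == "LV") "lv_phases" else "rv_phases"]]
  if (!is.null(declared)) {
    if (length(declared) != 2L)
      stop("declared phases must name exactly an ED and an ES frame")
    if (!all(declared %in% names(study@stacks)))
      .incomplete(sprintf("declared %s phases (%s) not all present in the study",
                          ventricle, paste(declared, collapse = ", ")))
    return(as.character(declared))
  }
  code <- if (ventricle == "LV") 1L else 3L
  vols <- vapply(study@stacks, function(s) compartmentVolume(s, code), numeric(1))
  vols <- vols[vols > 0]
  if (length(vols) < 2L)
    .incomplete(sprintf("%s blood pool segmented in fewer than 2 phases", ventricle))
  c(names(vols)[which.max(vols)], names(vols)[which.min(vols)])
}

#' Compute biventricular biomarkers for a study
#'
#' EDV/ESV per ventricle from [compartmentVolume()] at the selected phases,
#' SV = EDV - ESV, EF = 100 (EDV - ESV)/EDV, and LV mass as the myocardial
#' volume at the LV ED phase times the tissue density (clinical convention:
#' mass at ED only, since the myocardium is often unannotated at ES). With
#' `papillaryMode = "exclude"`, the blood pools of the phases in use are
#' first refined by [refineBloodPool()] (reassigning papillary voxels to a
#' dedicated PAP class, so LV mass is unaffected); this requires intensity
#' volumes.
#'
#' @param study a [CineStudy-class].
#' @param papillaryMode "include" (default) or "exclude".
#' @param myoDensity myocardial density in g/mL (default 1.05).
#' @param bins,minIslandVoxels forwarded to [refineBloodPool()].
#' @return a [BiomarkerSet-class].
#' @examples
#' ph <- generatePhantom(randomPhantomSpec(3))
#' computeBiomarkers(ph$study)
#' @export
computeBiomarkers <- function(study, papillaryMode = c("include", "exclude"),
                              myoDensity = 1.05, bins = 256L,
                              minIslandVoxels = 2L) {
  papillaryMode <- match.arg(papillaryMode)
  lv_ph <- selectPhases(study, "LV")
  rv_ph <- selectPhases(study, "RV")
  used <- unique(c(lv_ph, rv_ph))
  stacks <- study@stacks[used]

  if (papillaryMode == "exclude") {
    missing_int <- setdiff(used, names(study@intensities))
    if (length(missing_int))
      stop(sprintf("papillary exclusion requires intensity volumes; missing for phase(s) %s",
                   paste(missing_int, collapse = ", ")))
    for (ph in used) {
      ref <- refineBloodPool(stacks[[ph]], study@intensities[[ph]],
                             target = "both", reassignTo = "PAP",
                             bins = bins, minIslandVoxels = minIslandVoxels)
      stacks[[ph]] <- ref$stack
    }
  }

  vol <- function(ph, code) compartmentVolume(stacks[[ph]], code)
  myo_ml <- vol(lv_ph[1], 2L)
  BiomarkerSet(
    LVEDV = vol(lv_ph[1], 1L), LVESV = vol(lv_ph[2], 1L),
    RVEDV = vol(rv_ph[1], 3L), RVESV = vol(rv_ph[2], 3L),
    LVM = if (myo_ml > 0) myo_ml * myoDensity else NA_real_,
    papillary_excluded = (papillaryMode == "exclude"),
    phases_used = list(LV = lv_ph, RV = rv_ph))
}
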