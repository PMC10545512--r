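#' @include AllClasses.R
NULL

#' Accessors for cineQC objects
#'
#' @param object a cineQC S4 object.
#' @name accessors
NULL

#' @describeIn accessors the 3D integer label array (slice, row, col).
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' @describeIn accessors in-plane spacing (row, col) in mm.
#' @export
setGeneric("inPlaneSpacing", function(object) standardGeneric("inPlaneSpacing"))

#' @describeIn accessors centre-to-centre slice spacing in mm.
#' @export
setGeneric("sliceSpacing", function(object) standardGeneric("sliceSpacing"))

#' @describeIn accessors phase tag of a stack.
#' @export
setGeneric("phaseTag", function(object) standardGeneric("phaseTag"))

#' @describeIn accessors named label vocabulary of a stack.
#' @export
setGeneric("labelMap", function(object) standardGeneric("labelMap"))

#' @describeIn accessors study identifier.
#' @export
setGeneric("studyId", function(object) standardGeneric("studyId"))

#' @describeIn accessors named list of label stacks.
#' @export
setGeneric("stacks", function(object) standardGeneric("stacks"))

#' @describeIn accessors named list of intensity volumes.
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @describeIn accessors study metadata list.
#' @export
setGeneric("studyMeta", function(object) standardGeneric("studyMeta"))

#' @describeIn accessors flag entries as a data.frame.
#' @export
setGeneric("flagEntries", function(object) standardGeneric("flagEntries"))

#' @describeIn accessors named numeric vector of biomarkers.
#' @export
setGeneric("biomarkerValues", function(object) standardGeneric("biomarkerValues"))

setMethod("voxels", "LabelStack", function(object) object@voxels)
setMethod("inPlaneSpacing", "LabelStack", function(object) object@inPlaneSpacing)
setMethod("sliceSpacing", "LabelStack", function(object) object@sliceSpacing)
setMethod("phaseTag", "LabelStack", function(object) object@phaseTag)
setMethod("labelMap", "LabelStack", function(object) object@labelMap)

setMethod("studyId", "CineStudy", function(object) object@studyId)
setMethod("stacks", "CineStudy", function(object) object@stacks)
setMethod("intensities", "CineStudy", function(object) object@intensities)
setMethod("studyMeta", "CineStudy", function(object) object@meta)

setMethod("flagEntries", "FlagReport", function(object) object@entries)
setMethod("biomarkerValues", "BiomarkerSet", function(object) object@values)

#' @describeIn accessors number of flag entries.
#' @param x a FlagReport.
#' @export
setMethod("length", "FlagReport", function(x) nrow(x@entries))

setMethod("show", "LabelStack", function(object) {
  d <- dim(object@voxels)
  fg <- sum(object@voxels != 0L)
  cat(sprintf("LabelStack [%s]: %d slices x %d x %d, %.2fx%.2fx%.1f mm, %d foreground voxels\n",
              object@phaseTag, d[1], d[2], d[3],
              object@inPlaneSpacing[1], object@inPlaneSpacing[2],
              object@sliceSpacing, fg))
  cat("  labels:", paste(sprintf("%s=%d", names(object@labelMap), object@labelMap),
                         collapse = ", "), "\n")
})

setMethod("show", "CineStudy", function(object) {
  cat(sprintf("CineStudy '%s': phases {%s}%s\n", object@studyId,
              paste(names(object@stacks), collapse = ", "),
              if (length(object@intensities))
                sprintf(", intensities {%s}",
                        paste(names(object@intensities), collapse = ", "))
              else ""))
})

setMethod("show", "FlagReport", function(object) {
  n <- nrow(object@entries)
  if (!n) {
    cat("FlagReport: clean (no entries)\n")
  } else {
    cat(sprintf("FlagReport: %d entr%s\n", n, if (n == 1) "y" else "ies"))
    print(object@entries)
  }
})

setMethod("show", "BiomarkerSet", function(object) {
  v <- object@values
  cat(sprintf("BiomarkerSet (papillary %s)\n",
              if (isTRUE(object@provenance$papillary_excluded)) "excluded" else "included"))
  cat(sprintf("  LV: EDV %.1f mL, ESV %.1f mL, SV %.1f mL, EF %.1f%%, mass %.1f g\n",
              v["LVEDV"], v["LVESV"], v["LVSV"], v["LVEF"], v["LVM"]))
  cat(sprintf("  RV: EDV %.1f mL, ESV %.1f mL, SV %.1f mL, EF %.1f%%\n",
              v["RVEDV"], v["RVESV"], v["RVSV"], v["RVEF"]))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d slices, %dx%d grid, %.2gx%.2gx%.2g mm, seed %d\n",
              object@nSlices, object@grid[1], object@grid[2],
              object@spacingMm[1], object@spacingMm[2], object@spacingMm[3],
              object@seed))
})

setMethod("show", "DefectSpec", function(object) {
  cat(sprintf("DefectSpec '%s' (targets rule '%s')\n",
              object@kind, object@designedRule))
})

#' Convert a BiomarkerSet to a one-row data.frame
#'
#' @param x a [BiomarkerSet-class].
#' @param row.names,optional,... passed for S3 compatibility (unused).
#' @return data.frame with one column per biomarker.
#' @export
as.data.frame.BiomarkerSet <- function(x, row.names = NULL, optional = FALSE, ...) {
  as.data.frame(as.list(x@values))
}

#' Convert a FlagReport to a data.frame
#'
#' @param x a [FlagReport-class].
#' @param row.names,optional,... passed for S3 compatibility (unused).
#' @return the entries data.frame.
#' @export
as.data.frame.FlagReport <- function(x, row.names = NULL, optional = FALSE, ...) {
  x@entries
}
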