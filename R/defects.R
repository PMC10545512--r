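## Defect injection: controlled corruption of phantom studies, one defect
## class per screening rule. Injection returns a modified copy; the input
## study is never touched. Geometric defects (myocardial hole, SV
## discordance) assume the heart is centred in the grid, as phantom studies
## are.

#' Inject an annotation defect into a study
#'
#' Applies the defect described by a [DefectSpec-class] to a deep copy of
#' the study; only the voxels/frames the defect names are modified. See
#' [defectSpec()] for the defect taxonomy and parameters.
#'
#' @param study a [CineStudy-class].
#' @param defect a [DefectSpec-class].
#' @param donor donor [CineStudy-class], required for `duplicate_of`.
#' @return The modified [CineStudy-class].
#' @export
injectDefect <- function(study, defect, donor = NULL) {
  stopifnot(is(study, "CineStudy"), is(defect, "DefectSpec"))
  p <- defect@params
  switch(defect@kind,
    missing_phase = .df_missing_phase(study, p$phase),
    dropped_basal_slices = .df_drop_slices(study, basal = TRUE, n = p$n),
    dropped_apical_slices = .df_drop_slices(study, basal = FALSE, n = p$n),
    mid_stack_gap = .df_mid_gap(study, p$slices),
    stray_component = .df_stray(study, p$label, p$size, p$offset),
    myocardial_hole = .df_myo_hole(study, p$arc_deg, p$phase),
    oversize_scale = .df_rescale(study, p$factor),
    undersize_scale = .df_rescale(study, p$factor),
    sv_discordance = .df_sv_discordance(study, p$factor),
    duplicate_of = .df_duplicate(study, donor),
    absent_class = .df_absent_class(study)
  )
}

.df_missing_phase <- function(study, phase) {
  if (!phase %in% names(study@stacks))
    stop(sprintf("defect inapplicable: phase '%s' not present", phase))
  study@stacks[[phase]] <- NULL
  study@intensities[[phase]] <- NULL
  study
}

# zero all labels on k basal slices, or on the k most-apical LV-bearing
# slices, in every phase
.df_drop_slices <- function(study, basal, n) {
  for (ph in names(study@stacks)) {
    v <- study@stacks[[ph]]@voxels
    if (n >= dim(v)[1]) stop("defect inapplicable: n must be below the slice count")
    if (basal) {
      v[seq_len(n), , ] <- 0L
    } else {
      lv_slices <- which(.slice_counts(study@stacks[[ph]], 1L) > 0)
      drop <- utils::tail(lv_slices, n)
      v[drop, , ] <- 0L
    }
    study@stacks[[ph]]@voxels <- v
  }
  study
}

# empty interior slices; default: the two middle LV-bearing slices
.df_mid_gap <- function(study, slices) {
  first <- study@stacks[[1]]
  if (is.null(slices)) {
    lv_slices <- which(.slice_counts(first, 1L) > 0)
    interior <- lv_slices[-c(1, length(lv_slices))]
    if (length(interior) < 2L) stop("defect inapplicable: too few interior slices")
    mid <- floor(length(interior) / 2)
    slices <- interior[c(mid, mid + 1L)]
  }
  for (ph in names(study@stacks)) {
    v <- study@stacks[[ph]]@voxels
    v[slices, , ] <- 0L
    study@stacks[[ph]]@voxels <- v
  }
  study
}

# compact blob of `size` voxels of `label`, disconnected from the heart,
# on the middle slice of the first phase
.df_stray <- function(study, label, size, offset) {
  ph <- names(study@stacks)[1]
  stack <- study@stacks[[ph]]
  v <- stack@voxels
  d <- dim(v)
  if (is.null(offset)) offset <- c(max(1L, d[1] %/% 2L), 3L, 3L)
  side <- ceiling(sqrt(size))
  rows <- offset[2] + seq_len(side) - 1L
  cols <- offset[3] + seq_len(side) - 1L
  if (max(rows) > d[2] || max(cols) > d[3])
    stop("defect inapplicable: stray blob does not fit at the given offset")
  cells <- as.matrix(expand.grid(row = rows, col = cols))[seq_len(size), , drop = FALSE]
  # require 8/face-disjointness from existing foreground
  guard_r <- max(1L, min(rows) - 1L):min(d[2], max(rows) + 1L)
  guard_c <- max(1L, min(cols) - 1L):min(d[3], max(cols) + 1L)
  if (any(v[offset[1], guard_r, guard_c] != 0L))
    stop("defect inapplicable: stray blob would touch existing foreground")
  code <- .label_code(stack, label)
  v[cbind(offset[1], cells[, "row"], cells[, "col"])] <- code
  study@stacks[[ph]]@voxels <- v
  study
}

# remove a wedge of the myocardial ring on the lateral wall (angle 0,
# opposite the RV crescent) on every slice of one phase
.df_myo_hole <- function(study, arc_deg, phase) {
  stack <- study@stacks[[phase]]
  if (is.null(stack)) stop(sprintf("defect inapplicable: phase '%s' absent", phase))
  v <- stack@voxels
  d <- dim(v)
  pol <- .plane_polar(d[2], d[3], stack@inPlaneSpacing[1], stack@inPlaneSpacing[2])
  wedge <- .ang_dist(pol$phi, 0) <= (arc_deg * pi / 180) / 2
  for (k in seq_len(d[1])) {
    sl <- v[k, , ]
    sl[sl == 2L & wedge] <- 0L
    v[k, , ] <- sl
  }
  study@stacks[[phase]]@voxels <- v
  study
}

# scale all voxel spacings (volumes scale with factor^3)
.df_rescale <- function(study, factor) {
  if (factor <= 0) stop("defect inapplicable: factor must be positive")
  for (ph in names(study@stacks)) {
    study@stacks[[ph]]@inPlaneSpacing <- study@stacks[[ph]]@inPlaneSpacing * factor
    study@stacks[[ph]]@sliceSpacing <- study@stacks[[ph]]@sliceSpacing * factor
  }
  study
}

# scale the ES RV volume: factor 2 mirror-duplicates the crescent about the
# column axis (an exact voxel bijection); factors < 1 trim the crescent's
# angular extent proportionally
.df_sv_discordance <- function(study, factor) {
  if (!"ES" %in% names(study@stacks)) stop("defect inapplicable: no ES stack")
  stack <- study@stacks[["ES"]]
  v <- stack@voxels
  d <- dim(v)
  idx <- which(v == 3L)
  if (!length(idx)) stop("defect inapplicable: no ES RV voxels")
  ai <- arrayInd(idx, d)
  if (factor > 1) {
    if (abs(factor - 2) > 1e-9)
      stop("defect inapplicable: enlargement is only supported with factor 2 (mirror duplication)")
    tgt <- cbind(ai[, 1], ai[, 2], d[3] + 1L - ai[, 3])
    if (any(v[tgt] != 0L))
      stop("defect inapplicable: mirrored crescent would overlap existing foreground")
    v[tgt] <- 3L
    if ("ES" %in% names(study@intensities)) {
      iv <- study@intensities[["ES"]]
      iv[tgt] <- iv[cbind(ai[, 1], ai[, 2], ai[, 3])]
      study@intensities[["ES"]] <- iv
    }
  } else {
    pol <- .plane_polar(d[2], d[3], stack@inPlaneSpacing[1], stack@inPlaneSpacing[2])
    ang <- .ang_dist(pol$phi, pi)[cbind(ai[, 2], ai[, 3])]
    cutoff <- factor * max(ang)
    v[idx[ang > cutoff]] <- 0L
  }
  study@stacks[["ES"]]@voxels <- v
  study
}

# copy the donor's ED stack (and intensity) into this study
.df_duplicate <- function(study, donor) {
  if (is.null(donor) || !is(donor, "CineStudy"))
    stop("defect inapplicable: duplicate_of requires a donor study")
  src <- donor@stacks[["ED"]]
  if (is.null(src)) stop("defect inapplicable: donor has no ED stack")
  if (!identical(dim(src@voxels), dim(study@stacks[["ED"]]@voxels)))
    stop("defect inapplicable: donor grid differs")
  study@stacks[["ED"]]@voxels <- src@voxels
  if ("ED" %in% names(donor@intensities) && "ED" %in% names(study@intensities))
    study@intensities[["ED"]] <- donor@intensities[["ED"]]
  study
}

# protocol variation: myocardium unannotated at ES
.df_absent_class <- function(study) {
  if (!"ES" %in% names(study@stacks)) stop("defect inapplicable: no ES stack")
  v <- study@stacks[["ES"]]@voxels
  v[v == 2L] <- 0L
  study@stacks[["ES"]]@voxels <- v
  study
}
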