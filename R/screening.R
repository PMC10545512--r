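## Rule engine shared by ground-truth QA (flag/exclude only) and
## post-analysis QC (which may auto-correct). Connectivity convention for
## anisotropic SAX stacks: 8-neighbour within a slice; face adjacency across
## slices only for the 3D heart-component check.

#' Connected components of one label
#'
#' Partitions the voxels of a label into maximal connected sets, either per
#' slice in 2D (8-connectivity) or across the whole stack in 3D (in-plane
#' 8-connectivity plus face adjacency across slices).
#'
#' @param stack a [LabelStack-class].
#' @param label label name or code.
#' @param mode `"per_slice_2d"` (default) or `"stack_3d"`.
#' @return list of components, each `list(indices, size)` with linear voxel
#'   indices into the stack array; ordered by decreasing size, ties broken
#'   by the lexicographically smallest (slice, row, col) member.
#' @export
connectedComponents <- function(stack, label,
                                mode = c("per_slice_2d", "stack_3d")) {
  mode <- match.arg(mode)
  code <- .label_code(stack, label)
  mask <- stack@voxels == code
  .components_of_mask(mask, dim(stack@voxels), mode == "stack_3d")
}

.components_of_mask <- function(mask, d, across_slice) {
  labels <- cc_label_cpp(as.vector(mask), as.integer(d), across_slice)
  n <- attr(labels, "n_components")
  if (n == 0L) return(list())
  idx <- which(mask)
  comp <- split(idx, labels[idx])
  # lexicographic (slice, row, col) rank of each component's smallest member
  lexmin <- vapply(comp, function(i) {
    a <- arrayInd(i, d)
    key <- (a[, 1] * d[2] + a[, 2]) * d[3] + a[, 3]
    min(key)
  }, numeric(1))
  sizes <- lengths(comp)
  ord <- order(-sizes, lexmin)
  lapply(ord, function(j) list(indices = comp[[j]], size = unname(sizes[j])))
}

#' Check that both cardiac phases are segmented
#'
#' Studies in which only one of the required phases is segmented cannot
#' yield stroke volume or ejection fraction and are excluded. An
#' all-background stack counts as unsegmented.
#'
#' @param study a [CineStudy-class].
#' @param required phase tags that must carry foreground (default: the
#'   union of the metadata-declared LV/RV phases, falling back to ED+ES).
#' @return data.frame of flag entries (severity `exclude`).
#' @export
checkFrameCompleteness <- function(study, required = NULL) {
  meta <- study@meta
  if (is.null(required))
    required <- unique(c(meta$lv_phases %||% c("ED", "ES"),
                         meta$rv_phases %||% c("ED", "ES")))
  out <- list()
  for (ph in required) {
    stack <- study@stacks[[ph]]
    if (is.null(stack)) {
      out[[length(out) + 1L]] <- .flag_entry(
        "frame_completeness", "exclude", ph, "stack",
        sprintf("required phase '%s' is not segmented", ph))
    } else if (!any(stack@voxels != 0L)) {
      out[[length(out) + 1L]] <- .flag_entry(
        "frame_completeness", "exclude", ph, "stack",
        sprintf("phase '%s' contains no foreground voxels (empty counts as unsegmented)", ph))
    }
  }
  do.call(.bind_entries, out)
}

#' Check base-to-apex coverage of the LV
#'
#' Flags a stack whose segmented LV extent (number of LVBP-bearing slices
#' times slice spacing) is below the configured minimum, or whose LVBP area
#' at the most-apical segmented slice exceeds the configured fraction of
#' the maximal LVBP slice area (a truncated apex).
#'
#' @param stack a [LabelStack-class].
#' @param config a [ScreeningConfig-class].
#' @return data.frame of flag entries.
#' @export
checkCoverage <- function(stack, config = screeningConfig()) {
  counts <- .slice_counts(stack, 1L)
  present <- which(counts > 0)
  out <- list()
  extent <- length(present) * stack@sliceSpacing
  if (extent < config@minLvExtentMm) {
    out[[length(out) + 1L]] <- .flag_entry(
      "coverage_extent", "flag", stack@phaseTag, "stack",
      sprintf("segmented LV extent %.1f mm below minimum %.1f mm",
              extent, config@minLvExtentMm))
  }
  if (length(present)) {
    apical <- max(present)
    ratio <- counts[apical] / max(counts)
    if (ratio > config@apicalAreaFractionMax) {
      out[[length(out) + 1L]] <- .flag_entry(
        "coverage_apex", "flag", stack@phaseTag, as.character(apical),
        sprintf("LVBP area at most-apical slice %d is %.0f%% of the maximal slice area (> %.0f%%): apex likely truncated",
                apical, 100 * ratio, 100 * config@apicalAreaFractionMax))
    }
  }
  do.call(.bind_entries, out)
}

#' Check for non-segmented slices between segmented slices
#'
#' For each label, flags every slice with zero voxels of that label lying
#' strictly between two slices that contain it.
#'
#' @param stack a [LabelStack-class].
#' @return data.frame of flag entries.
#' @export
checkGaps <- function(stack) {
  out <- list()
  lm <- stack@labelMap
  for (nm in setdiff(names(lm), "background")) {
    counts <- .slice_counts(stack, lm[[nm]])
    present <- which(counts > 0)
    if (length(present) < 2L) next
    missing <- setdiff(seq(min(present), max(present)), present)
    for (k in missing) {
      out[[length(out) + 1L]] <- .flag_entry(
        "gap", "flag", stack@phaseTag, sprintf("slice %02d", k),
        sprintf("no %s voxels on slice %d between segmented slices", nm, k))
    }
  }
  do.call(.bind_entries, out)
}

#' Check anatomical relations between ventricles and myocardium
#'
#' Per slice containing LVBP: flags (a) a myocardial-ring breach, i.e. an
#' in-plane 8-connected path of non-MYO voxels from the LV blood pool to
#' the image border (a hole in the wall, or an entirely absent ring), and
#' (b) direct LVBP/RVBP contact (blood pools must be separated by
#' myocardium).
#'
#' @param stack a [LabelStack-class].
#' @return data.frame of flag entries.
#' @export
checkAnatomyRelations <- function(stack) {
  v <- stack@voxels
  d <- dim(v)
  out <- list()
  for (k in seq_len(d[1])) {
    sl <- v[k, , ]
    lv <- sl == 1L
    if (!any(lv)) next
    # breach: flood-fill the non-MYO region; breach iff some component
    # holds both a border pixel and an LVBP pixel
    nonmyo <- sl != 2L
    labs <- cc_label_cpp(as.vector(nonmyo), c(1L, d[2], d[3]), FALSE)
    border <- unique(c(labs[1, , 1], labs[1, , d[3]], labs[1, 1, ], labs[1, d[2], ]))
    if (any(labs[1, , ][lv] %in% setdiff(border, 0L))) {
      out[[length(out) + 1L]] <- .flag_entry(
        "myo_breach", "flag", stack@phaseTag, sprintf("slice %02d", k),
        sprintf("LV blood pool reaches the image border through non-myocardium on slice %d (myocardial ring breached or absent)", k))
    }
    if (any(sl == 3L) && .touches(lv, sl == 3L)) {
      out[[length(out) + 1L]] <- .flag_entry(
        "lv_rv_contact", "flag", stack@phaseTag, sprintf("slice %02d", k),
        sprintf("LV and RV blood pools are 8-adjacent on slice %d", k))
    }
  }
  do.call(.bind_entries, out)
}

# any 8-adjacency between two in-plane masks?
.touches <- function(a, b) {
  nr <- nrow(a); nc <- ncol(a)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ra <- max(1, 1 + dr):min(nr, nr + dr)
    rb <- max(1, 1 - dr):min(nr, nr - dr)
    ca <- max(1, 1 + dc):min(nc, nc + dc)
    cb <- max(1, 1 - dc):min(nc, nc - dc)
    if (any(a[ra, ca] & b[rb, cb])) return(TRUE)
  }
  FALSE
}

#' Detect segmentation components disconnected from the heart
#'
#' Builds the 3D foreground (all labels except background) component set of
#' each phase; the largest component is the heart (ties broken by the
#' lexicographically smallest (slice, row, col) member). Every other
#' component larger than `minComponentVoxels` yields a flag plus a deletion
#' entry in the correction plan; smaller components enter the plan silently
#' as noise.
#'
#' @param study a [CineStudy-class].
#' @param config a [ScreeningConfig-class].
#' @return list with `entries` (data.frame of flags) and `plan` (list of
#'   `list(phase, indices, size, small)` deletions).
#' @export
checkExternalComponents <- function(study, config = screeningConfig()) {
  entries <- list(); plan <- list()
  for (ph in names(study@stacks)) {
    stack <- study@stacks[[ph]]
    d <- dim(stack@voxels)
    comps <- .components_of_mask(stack@voxels != 0L, d, across_slice = TRUE)
    if (!length(comps)) {
      entries[[length(entries) + 1L]] <- .flag_entry(
        "external_component", "flag", ph, "stack",
        "degenerate stack: no foreground voxels")
      next
    }
    if (length(comps) == 1L) next
    for (i in seq_along(comps)[-1]) {
      comp <- comps[[i]]
      small <- comp$size <= config@minComponentVoxels
      plan[[length(plan) + 1L]] <- list(phase = ph, indices = comp$indices,
                                        size = comp$size, small = small)
      if (!small) {
        sl <- sort(unique(arrayInd(comp$indices, d)[, 1]))
        entries[[length(entries) + 1L]] <- .flag_entry(
          "external_component", "flag", ph,
          sprintf("component %d", i),
          sprintf("foreground component of %d voxels on slice(s) %s disconnected from the heart",
                  comp$size, paste(sl, collapse = ",")))
      }
    }
  }
  list(entries = do.call(.bind_entries, entries), plan = plan)
}

#' Check biomarker plausibility ranges
#'
#' Flags each biomarker outside its configured interval. Missing (NA)
#' biomarkers are skipped.
#'
#' @param biomarkers a [BiomarkerSet-class].
#' @param config a [ScreeningConfig-class].
#' @return data.frame of flag entries.
#' @export
checkVolumePlausibility <- function(biomarkers, config = screeningConfig()) {
  v <- biomarkers@values
  out <- list()
  for (nm in names(config@volumeRangesMl)) {
    val <- v[[nm]]
    if (is.na(val)) next
    rng <- config@volumeRangesMl[[nm]]
    if (val < rng[1] || val > rng[2]) {
      unit <- if (nm == "LVM") "g" else "mL"
      out[[length(out) + 1L]] <- .flag_entry(
        "volume_range", "flag", "-", nm,
        sprintf("%s = %.1f %s outside plausibility range [%.0f, %.0f] %s",
                nm, val, unit, rng[1], rng[2], unit))
    }
  }
  do.call(.bind_entries, out)
}

#' Check LV/RV stroke-volume concordance
#'
#' Flags when the relative stroke-volume difference
#' |LVSV - RVSV| / mean(LVSV, RVSV) exceeds the configured fraction
#' (default 0.25, the clinical ">25% SV difference" rule). Non-positive
#' stroke volumes are flagged as implausible instead of tested. Flag-only:
#' SV discordance is never auto-corrected.
#'
#' @param biomarkers a [BiomarkerSet-class].
#' @param config a [ScreeningConfig-class].
#' @return data.frame of flag entries.
#' @export
checkSvDiscordance <- function(biomarkers, config = screeningConfig()) {
  v <- biomarkers@values
  lvsv <- v[["LVSV"]]; rvsv <- v[["RVSV"]]
  if (anyNA(c(lvsv, rvsv))) return(.bind_entries())
  if (lvsv <= 0 || rvsv <= 0) {
    return(.flag_entry("sv_discordance", "flag", "-", "SV",
                       sprintf("non-positive stroke volume (LVSV %.1f, RVSV %.1f mL): implausible",
                               lvsv, rvsv)))
  }
  frac <- abs(lvsv - rvsv) / mean(c(lvsv, rvsv))
  if (frac > config@svDiscordanceFraction) {
    return(.flag_entry("sv_discordance", "flag", "-", "SV",
                       sprintf("LV/RV stroke-volume difference %.0f%% exceeds %.0f%% (LVSV %.1f, RVSV %.1f mL)",
                               100 * frac, 100 * config@svDiscordanceFraction,
                               lvsv, rvsv)))
  }
  .bind_entries()
}

#' Flag duplicate segmentations across a cohort
#'
#' Flags every pair of non-empty stacks (across studies and phases) whose
#' voxel arrays are identical: comparison first groups by a cheap content
#' digest (dimensions plus per-label counts), then confirms by exact voxel
#' comparison. Empty stacks are handled by the completeness rule, not here.
#'
#' @param cohort list of [CineStudy-class] objects.
#' @return data.frame of flag entries; each pair yields one entry per
#'   involved study (column `study_id` identifies the owner).
#' @export
findDuplicates <- function(cohort) {
  recs <- list()
  for (study in cohort) {
    for (ph in names(study@stacks)) {
      v <- study@stacks[[ph]]@voxels
      if (!any(v != 0L)) next
      key <- paste(c(dim(v), tabulate(v + 1L, nbins = 6L)), collapse = "/")
      recs[[length(recs) + 1L]] <- list(study = study@studyId, phase = ph,
                                        key = key, voxels = v)
    }
  }
  out <- list()
  if (length(recs) >= 2L) {
    keys <- vapply(recs, `[[`, character(1), "key")
    for (key in unique(keys[duplicated(keys)])) {
      grp <- which(keys == key)
      for (i in grp) for (j in grp) {
        if (i >= j) next
        if (!identical(recs[[i]]$voxels, recs[[j]]$voxels)) next
        loci <- sprintf("%s/%s == %s/%s", recs[[i]]$study, recs[[i]]$phase,
                        recs[[j]]$study, recs[[j]]$phase)
        for (k in c(i, j)) {
          e <- .flag_entry("duplicate", "flag", recs[[k]]$phase, loci,
                           sprintf("identical voxel content: %s", loci))
          e$study_id <- recs[[k]]$study
          out[[length(out) + 1L]] <- e
        }
      }
    }
  }
  if (!length(out)) {
    e <- .bind_entries()
    e$study_id <- character()
    return(e)
  }
  do.call(rbind, out)
}

# biomarker-level checks, skipping studies whose phases are incomplete
.biomarker_checks <- function(study, config, papillaryMode, myoDensity) {
  bm <- tryCatch(
    computeBiomarkers(study, papillaryMode = papillaryMode,
                      myoDensity = myoDensity),
    cineqc_incomplete = function(e) NULL,
    error = function(e) NULL)
  if (is.null(bm)) return(list(entries = .bind_entries(), biomarkers = NULL))
  list(entries = .bind_entries(checkVolumePlausibility(bm, config),
                               checkSvDiscordance(bm, config)),
       biomarkers = bm)
}

#' Ground-truth quality assurance over a cohort
#'
#' Runs the full QA battery on every study: frame completeness, coverage,
#' gaps, anatomy relations, external components (flag-only: ground truth is
#' never modified), biomarker plausibility, SV concordance, and cohort-wide
#' duplicate detection. A study enters the exclusion list iff it has any
#' severity `exclude` entry; every other flagged study is listed for
#' review.
#'
#' @param cohort list of [CineStudy-class] objects.
#' @param config a [ScreeningConfig-class].
#' @param papillaryMode forwarded to [computeBiomarkers()] (default
#'   "include").
#' @param myoDensity myocardial density g/mL (default 1.05).
#' @return list with `reports` (named list of [FlagReport-class]),
#'   `excluded` (character study ids) and `flagged` (non-excluded studies
#'   with at least one entry).
#' @export
runQaGt <- function(cohort, config = screeningConfig(),
                    papillaryMode = "include", myoDensity = 1.05) {
  if (is(cohort, "CineStudy")) cohort <- list(cohort)
  ids <- vapply(cohort, studyId, character(1))
  names(cohort) <- ids
  dup <- findDuplicates(cohort)
  reports <- lapply(cohort, function(study) {
    entries <- .bind_entries(checkFrameCompleteness(study))
    for (ph in names(study@stacks)) {
      stack <- study@stacks[[ph]]
      entries <- .bind_entries(entries, checkCoverage(stack, config),
                               checkGaps(stack), checkAnatomyRelations(stack))
    }
    ext <- checkExternalComponents(study, config)
    entries <- .bind_entries(entries, ext$entries)
    bm <- .biomarker_checks(study, config, papillaryMode, myoDensity)
    entries <- .bind_entries(entries, bm$entries)
    if (nrow(dup)) {
      mine <- dup[dup$study_id == study@studyId, .flag_cols, drop = FALSE]
      entries <- .bind_entries(entries, mine)
    }
    FlagReport(entries)
  })
  n_entries <- vapply(reports, length, integer(1))
  excluded <- unname(ids[vapply(reports,
                                function(r) any(r@entries$severity == "exclude"),
                                logical(1))])
  list(reports = reports, excluded = excluded,
       flagged = setdiff(unname(ids[n_entries > 0]), excluded))
}

#' Post-analysis quality control with optional auto-correction
#'
#' Runs gap, anatomy, external-component, biomarker-plausibility and
#' SV-concordance checks on a (model-output) study. When
#' `applyCorrections`, the external-component deletion plan is executed
#' (deleted components are reported with severity `corrected`) and
#' biomarkers are recomputed from the corrected study. More complex issues
#' (gaps, anatomy breaches, implausible volumes, SV discordance) are
#' flagged for review but never modified.
#'
#' @param study a [CineStudy-class].
#' @param config a [ScreeningConfig-class].
#' @param applyCorrections execute the deletion plan (default TRUE).
#' @param papillaryMode,myoDensity forwarded to [computeBiomarkers()].
#' @return list with `study` (possibly corrected), `report`
#'   ([FlagReport-class]) and `biomarkers` ([BiomarkerSet-class] or NULL if
#'   phases are incomplete).
#' @export
runQcPost <- function(study, config = screeningConfig(),
                      applyCorrections = TRUE,
                      papillaryMode = "include", myoDensity = 1.05) {
  entries <- .bind_entries()
  ext <- checkExternalComponents(study, config)
  if (applyCorrections && length(ext$plan)) {
    for (del in ext$plan) {
      v <- study@stacks[[del$phase]]@voxels
      v[del$indices] <- 0L
      study@stacks[[del$phase]]@voxels <- v
      entries <- .bind_entries(entries, .flag_entry(
        "external_component", "corrected", del$phase,
        sprintf("%d voxels", del$size),
        sprintf("deleted %s component of %d voxels outside the heart (external-component deletion)",
                if (del$small) "noise" else "disconnected", del$size)))
    }
  } else {
    entries <- .bind_entries(entries, ext$entries)
  }
  # remaining checks run on the (possibly corrected) segmentation
  for (ph in names(study@stacks)) {
    stack <- study@stacks[[ph]]
    entries <- .bind_entries(entries, checkGaps(stack),
                             checkAnatomyRelations(stack))
  }
  bm <- .biomarker_checks(study, config, papillaryMode, myoDensity)
  entries <- .bind_entries(entries, bm$entries)
  list(study = study, report = FlagReport(entries), biomarkers = bm$biomarkers)
}
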