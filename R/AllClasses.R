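#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib cineQC, .registration = TRUE
NULL

#' Canonical segmentation label vocabulary
#'
#' The internal label encoding used throughout the package:
#' background = 0, LV blood pool (LVBP) = 1, LV myocardium (MYO) = 2,
#' RV blood pool (RVBP) = 3. Papillary-refined stacks may additionally carry
#' PAP = 4 for voxels reassigned out of the blood pools.
#'
#' @param with_pap logical; include the PAP label used by
#'   [refineBloodPool()] when voxels are reassigned to a dedicated class.
#' @return Named integer vector mapping class names to voxel values.
#' @export
canonicalLabelMap <- function(with_pap = FALSE) {
  m <- c(background = 0L, LVBP = 1L, MYO = 2L, RVBP = 3L)
  if (with_pap) m <- c(m, PAP = 4L)
  m
}

## ---------------------------------------------------------------------------
## LabelStack
## ---------------------------------------------------------------------------

#' LabelStack: one cardiac phase's 3D label volume with voxel geometry
#'
#' The atomic object every screening rule and biomarker consumes: an integer
#' label volume indexed (slice, row, col) with slice 0 at the most basal
#' slice, plus in-plane voxel spacing (mm) and centre-to-centre slice
#' spacing (mm). The voxel volume is
#' `in-plane row spacing x col spacing x slice spacing`, i.e. slice spacing
#' absorbs slice thickness plus any gap (Simpson-style summation).
#'
#' @slot voxels 3D integer array (slice, row, col); values must be in the
#'   range of `labelMap`.
#' @slot inPlaneSpacing numeric length 2, mm per voxel edge (row, col).
#' @slot sliceSpacing numeric, mm centre-to-centre between adjacent slices.
#' @slot labelMap named integer vector, see [canonicalLabelMap()].
#' @slot phaseTag character phase tag, conventionally "ED", "ES", or a frame
#'   label such as "f07".
#' @export
setClass("LabelStack", representation(
  voxels = "array",
  inPlaneSpacing = "numeric",
  sliceSpacing = "numeric",
  labelMap = "integer",
  phaseTag = "character"
))

setValidity("LabelStack", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L) return("voxels must be a 3D array (slice, row, col)")
  if (!is.integer(v)) return("voxels must be integer storage")
  if (dim(v)[1] < 1L) return("at least one slice required")
  lm <- object@labelMap
  if (is.null(names(lm)) || anyDuplicated(lm) || anyDuplicated(names(lm)))
    return("labelMap must be a uniquely named integer vector")
  bad <- setdiff(unique(as.vector(v)), lm)
  if (length(bad)) {
    cnt <- sum(v %in% bad)
    return(sprintf("unknown voxel value(s) %s (%d voxels) not in label map",
                   paste(sort(bad), collapse = ", "), cnt))
  }
  if (length(object@inPlaneSpacing) != 2L || any(object@inPlaneSpacing <= 0) ||
      any(!is.finite(object@inPlaneSpacing)))
    return("inPlaneSpacing must be two strictly positive values (row, col) in mm")
  if (length(object@sliceSpacing) != 1L || object@sliceSpacing <= 0 ||
      !is.finite(object@sliceSpacing))
    return("sliceSpacing must be a single strictly positive value in mm")
  if (length(object@phaseTag) != 1L || !nzchar(object@phaseTag))
    return("phaseTag must be a non-empty string")
  TRUE
})

#' Construct a LabelStack
#'
#' @param voxels 3D integer-valued array indexed (slice, row, col).
#' @param inPlaneSpacing numeric length 2, mm (row, col).
#' @param sliceSpacing numeric, mm centre-to-centre.
#' @param phaseTag phase tag string ("ED", "ES", ...).
#' @param labelMap named integer label vocabulary; defaults to the canonical
#'   map.
#' @return A validated [LabelStack-class] object.
#' @examples
#' s <- LabelStack(array(0L, c(4, 16, 16)), c(1.8, 1.8), 8, "ED")
#' s
#' @export
LabelStack <- function(voxels, inPlaneSpacing, sliceSpacing, phaseTag,
                       labelMap = canonicalLabelMap()) {
  if (!all(voxels == as.integer(voxels), na.rm = TRUE))
    stop("label voxels must be integer-valued")
  storage.mode(voxels) <- "integer"
  new("LabelStack", voxels = voxels,
      inPlaneSpacing = as.numeric(inPlaneSpacing),
      sliceSpacing = as.numeric(sliceSpacing),
      labelMap = structure(as.integer(labelMap), names = names(labelMap)),
      phaseTag = as.character(phaseTag))
}

## ---------------------------------------------------------------------------
## CineStudy
## ---------------------------------------------------------------------------

#' CineStudy: a subject's label stacks across phases
#'
#' The pipeline's unit of work: label stacks keyed by phase tag, optional
#' co-registered intensity volumes, and study metadata (disease group,
#' scanner vendor/model/field strength, and the ED/ES frame assignment per
#' ventricle, which may differ between LV and RV in clinical datasets).
#'
#' @slot studyId character study identifier.
#' @slot stacks named list of [LabelStack-class], keyed by phase tag.
#' @slot intensities named list of numeric 3D arrays congruent with the
#'   matching stack; may be empty.
#' @slot meta list; recognised fields are `disease_group`, `scanner_vendor`,
#'   `scanner_model`, `field_strength_T`, `lv_phases` (ED, ES tags) and
#'   `rv_phases`.
#' @export
setClass("CineStudy", representation(
  studyId = "character",
  stacks = "list",
  intensities = "list",
  meta = "list"
))

setValidity("CineStudy", function(object) {
  if (length(object@studyId) != 1L || !nzchar(object@studyId))
    return("studyId must be a non-empty string")
  st <- object@stacks
  if (length(st) && (is.null(names(st)) || any(!nzchar(names(st)))))
    return("stacks must be named by phase tag")
  for (tag in names(st)) {
    if (!is(st[[tag]], "LabelStack")) return("stacks must contain LabelStack objects")
    if (!identical(st[[tag]]@phaseTag, tag))
      return(sprintf("stack name '%s' disagrees with its phaseTag '%s'",
                     tag, st[[tag]]@phaseTag))
  }
  for (tag in names(object@intensities)) {
    if (!tag %in% names(st))
      return(sprintf("intensity volume '%s' has no matching label stack", tag))
    iv <- object@intensities[[tag]]
    if (!identical(dim(iv), dim(st[[tag]]@voxels)))
      return(sprintf("intensity volume '%s' shape differs from its label stack", tag))
  }
  TRUE
})

#' Construct a CineStudy
#'
#' @param studyId study identifier.
#' @param stacks named list of [LabelStack-class] keyed by phase tag, or an
#'   unnamed list (names taken from each stack's phase tag).
#' @param intensities optional named list of numeric 3D arrays congruent
#'   with the matching label stack.
#' @param meta metadata list; see [CineStudy-class].
#' @return A validated [CineStudy-class] object.
#' @export
CineStudy <- function(studyId, stacks, intensities = list(), meta = list()) {
  if (is.null(names(stacks)) && length(stacks))
    names(stacks) <- vapply(stacks, function(s) s@phaseTag, character(1))
  new("CineStudy", studyId = as.character(studyId), stacks = stacks,
      intensities = intensities, meta = meta)
}

## ---------------------------------------------------------------------------
## FlagReport
## ---------------------------------------------------------------------------

.flag_cols <- c("rule_id", "severity", "phase", "location", "detail")

#' FlagReport: structured QA/QC findings
#'
#' Each entry carries the rule id, a severity (`exclude`, `flag`, or
#' `corrected`), the phase tag it concerns, a free-text locus (slice index,
#' component id, biomarker name) and a human-readable detail string.
#' Entries with severity `corrected` always name the correcting operation in
#' their detail. An empty report means a clean study.
#'
#' @slot entries data.frame with columns rule_id, severity, phase, location,
#'   detail (all character).
#' @export
setClass("FlagReport", representation(entries = "data.frame"))

setValidity("FlagReport", function(object) {
  e <- object@entries
  if (!identical(names(e), .flag_cols))
    return(sprintf("entries must have columns %s", paste(.flag_cols, collapse = ", ")))
  if (nrow(e)) {
    if (!all(vapply(e, is.character, logical(1)))) return("entry columns must be character")
    if (!all(e$severity %in% c("exclude", "flag", "corrected")))
      return("severity must be exclude, flag, or corrected")
    corr <- e$severity == "corrected"
    if (any(corr & !nzchar(e$detail)))
      return("corrected entries must name the correcting operation in detail")
  }
  TRUE
})

#' Construct a FlagReport
#'
#' @param entries data.frame of entries (may be missing/empty for a clean
#'   report); see [FlagReport-class].
#' @return A [FlagReport-class] object with entries in canonical order
#'   (sorted by rule_id, phase, location).
#' @export
FlagReport <- function(entries = NULL) {
  if (is.null(entries) || !nrow(entries)) {
    entries <- data.frame(rule_id = character(), severity = character(),
                          phase = character(), location = character(),
                          detail = character(), stringsAsFactors = FALSE)
  }
  entries <- entries[order(entries$rule_id, entries$phase, entries$location), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  new("FlagReport", entries = entries)
}

.flag_entry <- function(rule_id, severity, phase, location, detail) {
  data.frame(rule_id = rule_id, severity = severity, phase = phase,
             location = as.character(location), detail = detail,
             stringsAsFactors = FALSE)
}

.bind_entries <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x), list(...))
  if (!length(parts)) return(FlagReport()@entries)
  do.call(rbind, parts)
}

## ---------------------------------------------------------------------------
## BiomarkerSet
## ---------------------------------------------------------------------------

.biomarker_names <- c("LVEDV", "LVESV", "LVSV", "LVEF", "LVM",
                      "RVEDV", "RVESV", "RVSV", "RVEF")

#' BiomarkerSet: biventricular functional biomarkers for one study
#'
#' Volumes in mL (EDV, ESV, SV per ventricle), ejection fractions in percent
#' and LV mass in grams, with provenance recording whether papillary muscle
#' was excluded from the blood pools and which phases were used per
#' ventricle. By construction SV = EDV - ESV; EF is `NA` when EDV is zero.
#'
#' @slot values named numeric vector with elements LVEDV, LVESV, LVSV, LVEF,
#'   LVM, RVEDV, RVESV, RVSV, RVEF.
#' @slot provenance list with at least `papillary_excluded` and
#'   `phases_used`.
#' @export
setClass("BiomarkerSet", representation(values = "numeric", provenance = "list"))

setValidity("BiomarkerSet", function(object) {
  v <- object@values
  if (!identical(names(v), .biomarker_names))
    return(sprintf("values must be named %s", paste(.biomarker_names, collapse = ", ")))
  # EDV/ESV/mass are non-negative; SV may be negative for implausible
  # segmentations (caught by the SV-discordance screen, not here)
  vol <- v[c("LVEDV", "LVESV", "LVM", "RVEDV", "RVESV")]
  if (any(!is.na(vol) & vol < -1e-9)) return("volumes and mass must be non-negative")
  for (side in c("LV", "RV")) {
    ed <- v[paste0(side, "EDV")]; es <- v[paste0(side, "ESV")]
    sv <- v[paste0(side, "SV")]
    if (!anyNA(c(ed, es, sv)) && abs(sv - (ed - es)) > 1e-6)
      return(sprintf("%sSV must equal %sEDV - %sESV", side, side, side))
  }
  TRUE
})

#' Construct a BiomarkerSet
#'
#' SV and EF are derived from the supplied EDV/ESV; EF is `NA` when EDV is
#' zero.
#'
#' @param LVEDV,LVESV,RVEDV,RVESV volumes in mL.
#' @param LVM LV mass in grams (`NA` if myocardium unavailable).
#' @param papillary_excluded logical provenance flag.
#' @param phases_used list with `LV` and `RV` elements naming the (ED, ES)
#'   phase tags used.
#' @return A validated [BiomarkerSet-class].
#' @examples
#' b <- BiomarkerSet(LVEDV = 100, LVESV = 40, RVEDV = 110, RVESV = 50, LVM = 105)
#' biomarkerValues(b)[["LVEF"]]
#' @export
BiomarkerSet <- function(LVEDV, LVESV, RVEDV, RVESV, LVM = NA_real_,
                         papillary_excluded = FALSE,
                         phases_used = list(LV = c("ED", "ES"), RV = c("ED", "ES"))) {
  ef <- function(edv, esv) if (is.na(edv) || edv <= 0) NA_real_ else 100 * (edv - esv) / edv
  vals <- c(LVEDV = LVEDV, LVESV = LVESV, LVSV = LVEDV - LVESV,
            LVEF = ef(LVEDV, LVESV), LVM = LVM,
            RVEDV = RVEDV, RVESV = RVESV, RVSV = RVEDV - RVESV,
            RVEF = ef(RVEDV, RVESV))
  new("BiomarkerSet", values = vals,
      provenance = list(papillary_excluded = papillary_excluded,
                        phases_used = phases_used))
}

## ---------------------------------------------------------------------------
## ScreeningConfig
## ---------------------------------------------------------------------------

#' ScreeningConfig: thresholds for the QA/QC rule engine
#'
#' @slot svDiscordanceFraction relative stroke-volume difference threshold
#'   (|LVSV - RVSV| / mean of the two); default 0.25, matching the clinical
#'   flagging rule for an SV difference above 25%.
#' @slot volumeRangesMl named list of `c(lo, hi)` plausibility intervals for
#'   LVEDV, LVESV, RVEDV, RVESV (mL) and LVM (g).
#' @slot minLvExtentMm minimal base-to-apex segmented LV length in mm
#'   (default 40).
#' @slot apicalAreaFractionMax maximal allowed ratio of LVBP area at the
#'   most-apical segmented slice to the maximal LVBP slice area (default
#'   0.5); larger ratios suggest a truncated apex.
#' @slot minComponentVoxels components of at most this size are treated as
#'   noise (default 2).
#' @export
setClass("ScreeningConfig", representation(
  svDiscordanceFraction = "numeric",
  volumeRangesMl = "list",
  minLvExtentMm = "numeric",
  apicalAreaFractionMax = "numeric",
  minComponentVoxels = "integer"
))

setValidity("ScreeningConfig", function(object) {
  if (object@svDiscordanceFraction <= 0 || object@svDiscordanceFraction > 1)
    return("svDiscordanceFraction must be in (0, 1]")
  if (object@apicalAreaFractionMax <= 0 || object@apicalAreaFractionMax > 1)
    return("apicalAreaFractionMax must be in (0, 1]")
  if (object@minLvExtentMm <= 0) return("minLvExtentMm must be positive")
  if (object@minComponentVoxels < 0L) return("minComponentVoxels must be >= 0")
  rng <- object@volumeRangesMl
  need <- c("LVEDV", "LVESV", "RVEDV", "RVESV", "LVM")
  if (!all(need %in% names(rng)))
    return(sprintf("volumeRangesMl must include %s", paste(need, collapse = ", ")))
  for (nm in names(rng)) {
    r <- rng[[nm]]
    if (length(r) != 2L || any(r <= 0) || r[1] >= r[2])
      return(sprintf("volume range for %s must be positive c(lo, hi) with lo < hi", nm))
  }
  TRUE
})

#' Construct a ScreeningConfig
#'
#' Defaults: SV discordance threshold 0.25; plausibility ranges
#' LVEDV/RVEDV 20-800 mL, LVESV/RVESV 10-700 mL, LVM 20-500 g; minimal LV
#' extent 40 mm; apical area fraction at most 0.5; components of up to 2
#' voxels ignored as noise. Connectivity is fixed: 8-neighbour in plane,
#' with face adjacency across slices only for the 3D heart-component check.
#'
#' @param svDiscordanceFraction,volumeRangesMl,minLvExtentMm,apicalAreaFractionMax,minComponentVoxels
#'   see [ScreeningConfig-class].
#' @return A validated [ScreeningConfig-class].
#' @export
screeningConfig <- function(svDiscordanceFraction = 0.25,
                            volumeRangesMl = list(
                              LVEDV = c(20, 800), LVESV = c(10, 700),
                              RVEDV = c(20, 800), RVESV = c(10, 700),
                              LVM = c(20, 500)),
                            minLvExtentMm = 40,
                            apicalAreaFractionMax = 0.5,
                            minComponentVoxels = 2L) {
  new("ScreeningConfig",
      svDiscordanceFraction = svDiscordanceFraction,
      volumeRangesMl = volumeRangesMl,
      minLvExtentMm = minLvExtentMm,
      apicalAreaFractionMax = apicalAreaFractionMax,
      minComponentVoxels = as.integer(minComponentVoxels))
}

## ---------------------------------------------------------------------------
## PhantomSpec / DefectSpec
## ---------------------------------------------------------------------------

#' PhantomSpec: parametric geometry of a synthetic SAX cine study
#'
#' Defines a two-phase (ED/ES) bright-blood SAX phantom with analytically
#' known biomarkers. The LV endocardium is a half-ellipsoid of revolution
#' (full radius at the base, tapering to zero at the apex), the myocardium a
#' closed annulus of constant thickness around it, and the RV a crescent
#' sharing the septal/epicardial border with the myocardium over a given
#' angular window. Papillary inclusions are spheres inside a blood pool that
#' keep the blood-pool *label* (protocol A) but take myocardial *intensity*.
#' The seed fully determines the voxel output.
#'
#' @slot nSlices number of slices (slice 0 most basal).
#' @slot grid integer (rows, cols).
#' @slot spacingMm numeric (row, col, slice) in mm.
#' @slot lv per-phase list: each element `list(radius_mm, extent_mm,
#'   wall_mm)` giving basal endocardial radius, base-to-apex long-axis
#'   extent and myocardial wall thickness.
#' @slot rv per-phase list: each element `list(outer_radius_mm,
#'   angular_extent_rad, thickness_mm)`.
#' @slot papillary list of `list(phase_tag, ventricle, center_mm, radius_mm)`
#'   spheres; `center_mm` is (z, y, x) in mm with the in-plane origin at the
#'   LV axis.
#' @slot intensity list(blood_mean, myo_mean, background_mean, noise_sd).
#' @slot withIntensities logical; generate intensity volumes.
#' @slot seed integer random seed for the intensity noise.
#' @export
setClass("PhantomSpec", representation(
  nSlices = "integer", grid = "integer", spacingMm = "numeric",
  lv = "list", rv = "list", papillary = "list", intensity = "list",
  withIntensities = "logical", seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  if (object@nSlices < 1L) return("need at least one slice")
  if (length(object@grid) != 2L || any(object@grid < 8L))
    return("grid must be (rows, cols), each at least 8")
  if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
    return("spacingMm must be three positive values (row, col, slice)")
  for (ph in names(object@lv)) {
    g <- object@lv[[ph]]
    if (g$radius_mm <= 0 || g$extent_mm <= 0 || g$wall_mm <= 0)
      return("LV radii, extents and wall thicknesses must be positive")
    if (g$extent_mm > object@nSlices * object@spacingMm[3])
      return("LV long-axis extent exceeds the stack coverage")
    if (g$wall_mm >= g$radius_mm)
      return("self-intersecting geometry: wall thickness must be below the endocardial radius")
  }
  for (ph in names(object@rv)) {
    g <- object@rv[[ph]]
    if (g$thickness_mm <= 0 || g$angular_extent_rad <= 0 ||
        g$angular_extent_rad >= pi)
      return("RV thickness must be positive and angular extent in (0, pi)")
  }
  for (p in object@papillary) {
    if (p$radius_mm <= 0) return("papillary radii must be positive")
    if (!.pap_inside(object, p))
      return("papillary inclusions must lie inside the blood pool of their phase")
  }
  TRUE
})

#' DefectSpec: an injectable annotation defect
#'
#' Each defect kind is designed to trigger a specific screening rule
#' (available via [defectRuleMap()]): `missing_phase`,
#' `dropped_basal_slices`, `dropped_apical_slices`, `mid_stack_gap`,
#' `stray_component`, `myocardial_hole`, `oversize_scale`,
#' `undersize_scale`, `sv_discordance`, `duplicate_of`, `absent_class`.
#'
#' @slot kind defect kind (see above).
#' @slot params named list of kind-specific parameters.
#' @slot designedRule the screening rule id this defect is designed to
#'   trigger.
#' @slot seed integer seed for any randomised placement.
#' @export
setClass("DefectSpec", representation(
  kind = "character", params = "list", designedRule = "character",
  seed = "integer"
))

#' Map defect kinds to the screening rule they are designed to trigger
#'
#' @return Named character vector: defect kind -> rule id.
#' @export
defectRuleMap <- function() {
  c(missing_phase = "frame_completeness",
    dropped_basal_slices = "coverage_extent",
    dropped_apical_slices = "coverage_apex",
    mid_stack_gap = "gap",
    stray_component = "external_component",
    myocardial_hole = "myo_breach",
    oversize_scale = "volume_range",
    undersize_scale = "volume_range",
    sv_discordance = "sv_discordance",
    duplicate_of = "duplicate",
    absent_class = "myo_breach")
}

#' Construct a DefectSpec
#'
#' Kind-specific parameters (defaults chosen so that each defect reliably
#' triggers its designed rule on phantoms from [randomPhantomSpec()]):
#' \describe{
#'   \item{missing_phase}{`phase` (default "ES").}
#'   \item{dropped_basal_slices}{`n` basal slices emptied (default 7).}
#'   \item{dropped_apical_slices}{`n` apical LV slices emptied (default 4).}
#'   \item{mid_stack_gap}{`slices` interior slice indices to empty (default:
#'     the two middle LV-bearing slices, chosen at injection).}
#'   \item{stray_component}{`label` (default "LVBP"), `size` voxels (default
#'     50), `offset` voxel (slice, row, col) of the blob seed (default: a
#'     grid corner on the middle slice).}
#'   \item{myocardial_hole}{`arc_deg` angular width (default 30), `phase`
#'     (default "ED").}
#'   \item{oversize_scale}{`factor` on all spacings (default 2.2).}
#'   \item{undersize_scale}{`factor` on all spacings (default 0.4).}
#'   \item{sv_discordance}{`factor` scaling the ES RV volume (default 2:
#'     exact mirror duplication of the crescent; factors < 1 trim the
#'     crescent's angular extent).}
#'   \item{duplicate_of}{`study_id` of the donor (its ED stack is copied in
#'     at injection via the `donor` argument of [injectDefect()]).}
#'   \item{absent_class}{no parameters: all MYO at ES relabelled
#'     background.}
#' }
#'
#' @param kind defect kind.
#' @param ... kind-specific parameters overriding the defaults above.
#' @param seed integer seed.
#' @return A [DefectSpec-class].
#' @export
defectSpec <- function(kind, ..., seed = 1L) {
  rules <- defectRuleMap()
  kind <- match.arg(kind, names(rules))
  defaults <- switch(kind,
    missing_phase = list(phase = "ES"),
    dropped_basal_slices = list(n = 7L),
    dropped_apical_slices = list(n = 4L),
    mid_stack_gap = list(slices = NULL),
    stray_component = list(label = "LVBP", size = 50L, offset = NULL),
    myocardial_hole = list(arc_deg = 30, phase = "ED"),
    oversize_scale = list(factor = 2.2),
    undersize_scale = list(factor = 0.4),
    sv_discordance = list(factor = 2),
    duplicate_of = list(study_id = NA_character_),
    absent_class = list()
  )
  override <- list(...)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad))
    stop(sprintf("unknown parameter(s) %s for defect kind '%s'",
                 paste(bad, collapse = ", "), kind))
  defaults[names(override)] <- override
  new("DefectSpec", kind = kind, params = defaults,
      designedRule = unname(rules[kind]), seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## PipelineConfig
## ---------------------------------------------------------------------------

#' PipelineConfig: resolved configuration for a pipeline run
#'
#' @slot screening a [ScreeningConfig-class].
#' @slot papillaryMode "include" (protocol A, default) or "exclude"
#'   (Otsu-based papillary exclusion; requires intensity volumes).
#' @slot myoDensity myocardial tissue density in g/mL (default 1.05).
#' @slot backend "passthrough" (stored labels; for testing) or
#'   "command" (external executable via `backendCommand`).
#' @slot backendCommand executable invoked as `cmd in.nii out.nii` per
#'   phase when `backend == "command"`.
#' @slot applyCorrections logical; execute external-component deletions.
#' @slot seed integer seed forwarded to any stochastic component.
#' @export
setClass("PipelineConfig", representation(
  screening = "ScreeningConfig", papillaryMode = "character",
  myoDensity = "numeric", backend = "character", backendCommand = "character",
  applyCorrections = "logical", seed = "integer"
))

#' Construct a PipelineConfig
#'
#' @param screening a [ScreeningConfig-class]; default [screeningConfig()].
#' @param papillaryMode,myoDensity,backend,backendCommand,applyCorrections,seed
#'   see [PipelineConfig-class].
#' @return A [PipelineConfig-class].
#' @export
pipelineConfig <- function(screening = screeningConfig(),
                           papillaryMode = c("include", "exclude"),
                           myoDensity = 1.05,
                           backend = c("passthrough", "command"),
                           backendCommand = "",
                           applyCorrections = TRUE,
                           seed = 1L) {
  new("PipelineConfig", screening = screening,
      papillaryMode = match.arg(papillaryMode), myoDensity = myoDensity,
      backend = match.arg(backend), backendCommand = backendCommand,
      applyCorrections = applyCorrections, seed = as.integer(seed))
}
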