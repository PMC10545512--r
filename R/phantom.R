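## Synthetic SAX cine phantom: half-ellipsoid LV cavity, annular myocardium,
## crescent RV, spherical papillary inclusions, bSSFP-like intensities.
##
## Geometry conventions: the long axis runs base (z = 0) to apex (z = L);
## slice k is centred at z_k = (k - 1/2) * slice_spacing. The endocardial
## radius profile is r(z) = R * sqrt(1 - (z/L)^2): full radius at the base,
## zero at the apex. A voxel belongs to a compartment iff its centre lies
## inside the continuous solid, which makes the voxel-count volume an
## unbiased midpoint-rule estimate of the analytic volume.

# endocardial radius at long-axis position z
.lv_radius <- function(z, radius, extent) {
  r <- radius * sqrt(pmax(0, 1 - (z / extent)^2))
  r[z >= extent | z < 0] <- 0
  r
}

# analytic compartment cross-section areas (mm^2) at long-axis position z
.area_lv <- function(z, lv) pi * .lv_radius(z, lv$radius_mm, lv$extent_mm)^2
.area_myo <- function(z, lv) {
  r <- .lv_radius(z, lv$radius_mm, lv$extent_mm)
  ifelse(z < lv$extent_mm & z >= 0, pi * ((r + lv$wall_mm)^2 - r^2), 0)
}
.area_rv <- function(z, lv, rv) {
  r <- .lv_radius(z, lv$radius_mm, lv$extent_mm)
  inner <- r + lv$wall_mm
  outer <- pmin(inner + rv$thickness_mm, rv$outer_radius_mm)
  ifelse(z < lv$extent_mm & z >= 0 & outer > inner,
         (rv$angular_extent_rad / 2) * (outer^2 - inner^2), 0)
}

# analytic compartment volume (mL) by adaptive quadrature over [0, L]
.analytic_volume_ml <- function(area_fun, extent) {
  stats::integrate(area_fun, 0, extent, rel.tol = 1e-10,
                   subdivisions = 400L)$value / 1000
}

# does a papillary sphere lie entirely inside its blood pool?
.pap_inside <- function(spec, p, tol = 1e-6) {
  ph <- p$phase_tag
  if (!ph %in% names(spec@lv)) return(FALSE)
  lv <- spec@lv[[ph]]
  z0 <- p$center_mm[1]; y0 <- p$center_mm[2]; x0 <- p$center_mm[3]
  rp <- p$radius_mm
  if (z0 - rp < 0 || z0 + rp > lv$extent_mm) return(FALSE)
  rho0 <- sqrt(x0^2 + y0^2)
  zs <- seq(z0 - rp, z0 + rp, length.out = 41L)
  rc <- sqrt(pmax(0, rp^2 - (zs - z0)^2))   # sphere slice radius
  r <- .lv_radius(zs, lv$radius_mm, lv$extent_mm)
  if (identical(p$ventricle, "LV")) return(all(rho0 + rc <= r + tol))
  rv <- spec@rv[[ph]]
  inner <- r + lv$wall_mm
  outer <- pmin(inner + rv$thickness_mm, rv$outer_radius_mm)
  if (!all(rho0 - rc >= inner - tol & rho0 + rc <= outer + tol)) return(FALSE)
  phi0 <- atan2(y0, x0)
  half_arc <- asin(pmin(1, rc / max(rho0, 1e-9)))
  all(.ang_dist(phi0, pi) + half_arc <= rv$angular_extent_rad / 2 + tol)
}

#' Construct a PhantomSpec
#'
#' See [PhantomSpec-class] for the geometry model. Most users will prefer
#' [randomPhantomSpec()], which draws physiologically plausible parameters.
#'
#' @param nSlices,grid,spacingMm,lv,rv,papillary,intensity,withIntensities,seed
#'   see [PhantomSpec-class].
#' @return A validated [PhantomSpec-class].
#' @export
phantomSpec <- function(nSlices, grid, spacingMm, lv, rv, papillary = list(),
                        intensity = list(blood_mean = 300, myo_mean = 100,
                                         background_mean = 50, noise_sd = 10),
                        withIntensities = TRUE, seed = 1L) {
  new("PhantomSpec", nSlices = as.integer(nSlices), grid = as.integer(grid),
      spacingMm = as.numeric(spacingMm), lv = lv, rv = rv,
      papillary = papillary, intensity = intensity,
      withIntensities = isTRUE(withIntensities), seed = as.integer(seed))
}

# RV crescent thickness achieving a target volume (mL), given the LV
# geometry and angular extent: solve (theta/2) * (2 A t + L t^2) = V with
# A = integral of the epicardial radius over z = pi R L / 4 + w L.
.rv_thickness_for_volume <- function(volume_ml, lv, angular_extent_rad) {
  A <- pi * lv$radius_mm * lv$extent_mm / 4 + lv$wall_mm * lv$extent_mm
  L <- lv$extent_mm
  th <- angular_extent_rad
  V <- volume_ml * 1000
  (-th * A + sqrt(th^2 * A^2 + 2 * th * L * V)) / (th * L)
}

# shrink a papillary sphere until it fits inside its blood pool
.fit_pap <- function(spec, p) {
  for (i in 1:40) {
    if (.pap_inside(spec, p)) return(p)
    p$radius_mm <- p$radius_mm * 0.92
  }
  stop("could not place papillary inclusion inside the blood pool")
}

#' Draw a random physiologically plausible PhantomSpec
#'
#' Parameter ranges emulate a typical adult CMR cohort: LVEDV uniform on
#' 100-220 mL, LVEF on 45-58%, myocardial wall 7-10 mm at ED with 2-4 mm
#' systolic thickening, LV long-axis extent 72-88 mm shortening by 4-10 mm
#' at ES, RVEDV within 0.85-1.05 of LVEDV and RVSV within 0.92-1.08 of
#' LVSV (so clean phantoms always satisfy the 25% SV-concordance rule), RV
#' angular extent 2.4-3.0 rad. Two LV and one RV papillary inclusion per
#' phase carry myocardial intensity inside the blood pools. Intensities are
#' bSSFP-like: blood 300, myocardium 100, background 50, Gaussian noise
#' SD 10.
#'
#' @param seed integer; fully determines the spec and the generated voxels.
#' @param nSlices,grid,spacingMm stack geometry (defaults 12 slices,
#'   100 x 100 grid, 1.8 x 1.8 x 8 mm).
#' @param withIntensities generate intensity volumes (default TRUE).
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- randomPhantomSpec(7)
#' ph <- generatePhantom(spec)
#' ph$truth
#' @export
randomPhantomSpec <- function(seed, nSlices = 12L, grid = c(100L, 100L),
                              spacingMm = c(1.8, 1.8, 8), withIntensities = TRUE) {
  with_seed(seed, {
    lvedv <- runif(1, 100, 220)
    ef <- runif(1, 0.45, 0.58)
    lvesv <- lvedv * (1 - ef)
    L_ed <- runif(1, 72, 88)
    L_es <- L_ed - runif(1, 4, 10)
    w_ed <- runif(1, 7, 10)
    w_es <- w_ed + runif(1, 2, 4)
    r_ed <- sqrt(lvedv * 1000 / ((2 / 3) * pi * L_ed))
    r_es <- sqrt(lvesv * 1000 / ((2 / 3) * pi * L_es))
    theta <- runif(1, 2.4, 3.0)
    rvedv <- lvedv * runif(1, 0.85, 1.05)
    rvsv <- (lvedv - lvesv) * runif(1, 0.92, 1.08)
    rvesv <- rvedv - rvsv

    lv <- list(ED = list(radius_mm = r_ed, extent_mm = L_ed, wall_mm = w_ed),
               ES = list(radius_mm = r_es, extent_mm = L_es, wall_mm = w_es))
    t_ed <- .rv_thickness_for_volume(rvedv, lv$ED, theta)
    t_es <- .rv_thickness_for_volume(rvesv, lv$ES, theta)
    rv <- list(ED = list(outer_radius_mm = r_ed + w_ed + t_ed + 10,
                         angular_extent_rad = theta, thickness_mm = t_ed),
               ES = list(outer_radius_mm = r_es + w_es + t_es + 10,
                         angular_extent_rad = theta, thickness_mm = t_es))

    spec <- phantomSpec(nSlices, grid, spacingMm, lv, rv, papillary = list(),
                        withIntensities = withIntensities, seed = seed)

    pap <- list()
    for (ph in c("ED", "ES")) {
      g <- lv[[ph]]
      z0 <- 0.35 * g$extent_mm
      rr <- .lv_radius(z0, g$radius_mm, g$extent_mm)
      for (ang in c(0.7, -0.7) + runif(2, -0.15, 0.15)) {
        rho0 <- 0.45 * rr
        rp <- if (ph == "ED") runif(1, 5.5, 6.5) else runif(1, 4.5, 5.5)
        p <- list(phase_tag = ph, ventricle = "LV",
                  center_mm = c(z0, rho0 * sin(ang), rho0 * cos(ang)),
                  radius_mm = rp)
        pap[[length(pap) + 1L]] <- .fit_pap(spec, p)
      }
      gr <- rv[[ph]]
      z0r <- 0.3 * g$extent_mm
      rho0 <- .lv_radius(z0r, g$radius_mm, g$extent_mm) + g$wall_mm +
        gr$thickness_mm / 2
      rp <- min(0.45 * gr$thickness_mm, if (ph == "ED") 5 else 4)
      p <- list(phase_tag = ph, ventricle = "RV",
                center_mm = c(z0r, rho0 * sin(pi), rho0 * cos(pi)),
                radius_mm = rp)
      pap[[length(pap) + 1L]] <- .fit_pap(spec, p)
    }
    spec@papillary <- pap
    validObject(spec)
    spec
  })
}

#' Generate a synthetic SAX cine study from a PhantomSpec
#'
#' Voxelizes the continuous phantom geometry (a voxel is foreground iff its
#' centre lies inside the continuous solid), builds bSSFP-like intensity
#' volumes with papillary inclusions drawn at myocardial intensity but
#' labelled as blood ("protocol A" ground truth), and returns ground-truth
#' biomarkers computed analytically from the continuous geometry by
#' adaptive quadrature (independent of the voxel grid).
#'
#' @param spec a [PhantomSpec-class].
#' @param studyId study identifier (default "phantom").
#' @return list with elements `study` (a [CineStudy-class]), `truth` (a
#'   [BiomarkerSet-class] from the continuous geometry) and `inclusions`
#'   (data.frame of papillary voxel counts per phase and ventricle).
#' @examples
#' ph <- generatePhantom(randomPhantomSpec(1), "demo")
#' ph$study
#' @export
generatePhantom <- function(spec, studyId = "phantom") {
  validObject(spec)
  rows <- spec@grid[1]; cols <- spec@grid[2]
  sp <- spec@spacingMm
  pol <- .plane_polar(rows, cols, sp[1], sp[2])
  zc <- .slice_z(spec@nSlices, sp[3])
  phases <- names(spec@lv)
  stacks <- list(); intens <- list()
  incl <- list()

  with_seed(spec@seed, {
    for (ph in phases) {
      lv <- spec@lv[[ph]]; rv <- spec@rv[[ph]]
      lab <- array(0L, c(spec@nSlices, rows, cols))
      for (k in seq_len(spec@nSlices)) {
        r <- .lv_radius(zc[k], lv$radius_mm, lv$extent_mm)
        if (r <= 0) next
        sl <- matrix(0L, rows, cols)
        inner <- r + lv$wall_mm
        outer <- min(inner + rv$thickness_mm, rv$outer_radius_mm)
        sl[pol$rho >= r & pol$rho < inner] <- 2L
        if (outer > inner)
          sl[pol$rho >= inner & pol$rho < outer &
               .ang_dist(pol$phi, pi) <= rv$angular_extent_rad / 2] <- 3L
        sl[pol$rho < r] <- 1L
        lab[k, , ] <- sl
      }
      stack <- LabelStack(lab, sp[1:2], sp[3], ph)
      stacks[[ph]] <- stack

      if (spec@withIntensities) {
        lev <- spec@intensity
        iv <- array(lev$background_mean, dim(lab))
        iv[lab == 1L | lab == 3L] <- lev$blood_mean
        iv[lab == 2L] <- lev$myo_mean
        for (p in spec@papillary) {
          if (!identical(p$phase_tag, ph)) next
          sel <- .sphere_voxels(p, zc, pol, dim(lab))
          sel <- sel[lab[sel] == 1L | lab[sel] == 3L]
          iv[sel] <- lev$myo_mean
          incl[[length(incl) + 1L]] <-
            data.frame(phase = ph, ventricle = p$ventricle,
                       voxels = length(sel), stringsAsFactors = FALSE)
        }
        if (lev$noise_sd > 0)
          iv <- iv + array(stats::rnorm(length(iv), 0, lev$noise_sd), dim(iv))
        intens[[ph]] <- iv
      }
    }
  })

  meta <- list(disease_group = "NOR", scanner_vendor = "Synthetic",
               scanner_model = "Phantom", field_strength_T = 1.5,
               lv_phases = c("ED", "ES"), rv_phases = c("ED", "ES"))
  study <- CineStudy(studyId, stacks, intens, meta)

  truth <- .analytic_truth(spec)
  inclusions <- if (length(incl)) do.call(rbind, incl) else
    data.frame(phase = character(), ventricle = character(), voxels = integer())
  agg <- if (nrow(inclusions))
    stats::aggregate(voxels ~ phase + ventricle, inclusions, sum) else inclusions
  list(study = study, truth = truth, inclusions = agg)
}

# linear indices of voxels whose centre lies inside a papillary sphere
.sphere_voxels <- function(p, zc, pol, dims) {
  ks <- which(abs(zc - p$center_mm[1]) <= p$radius_mm)
  if (!length(ks)) return(integer())
  out <- integer()
  nplane <- dims[2] * dims[3]
  for (k in ks) {
    rc2 <- p$radius_mm^2 - (zc[k] - p$center_mm[1])^2
    d2 <- (pol$y - p$center_mm[2])^2 + (pol$x - p$center_mm[3])^2
    idx <- which(d2 <= rc2)
    if (length(idx)) {
      ri <- ((idx - 1L) %% dims[2]) + 1L
      ci <- ((idx - 1L) %/% dims[2]) + 1L
      out <- c(out, k + (ri - 1L) * dims[1] + (ci - 1L) * dims[1] * dims[2])
    }
  }
  out
}

# ground-truth biomarkers from the continuous geometry
.analytic_truth <- function(spec) {
  vol <- function(ph, what) {
    lv <- spec@lv[[ph]]; rv <- spec@rv[[ph]]
    f <- switch(what,
                lv = function(z) .area_lv(z, lv),
                myo = function(z) .area_myo(z, lv),
                rv = function(z) .area_rv(z, lv, rv))
    .analytic_volume_ml(f, lv$extent_mm)
  }
  BiomarkerSet(LVEDV = vol("ED", "lv"), LVESV = vol("ES", "lv"),
               RVEDV = vol("ED", "rv"), RVESV = vol("ES", "rv"),
               LVM = vol("ED", "myo") * 1.05,
               papillary_excluded = FALSE)
}

#' Generate a cohort of random phantoms
#'
#' @param n number of studies.
#' @param seed integer; study i uses seed `seed + 131 * i`.
#' @param ... passed to [randomPhantomSpec()].
#' @return list with `studies`, `truths`, `specs` (all named by study id).
#' @export
randomPhantomCohort <- function(n, seed, ...) {
  ids <- sprintf("phantom%03d", seq_len(n))
  specs <- lapply(seq_len(n), function(i) randomPhantomSpec(seed + 131L * i, ...))
  gen <- mapply(function(s, id) generatePhantom(s, id), specs, ids,
                SIMPLIFY = FALSE)
  list(studies = stats::setNames(lapply(gen, `[[`, "study"), ids),
       truths = stats::setNames(lapply(gen, `[[`, "truth"), ids),
       specs = stats::setNames(specs, ids))
}
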