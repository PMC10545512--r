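test_that("compartment volume is voxel count times voxel volume", {
  v <- array(0L, c(10, 100, 100))
  v[1:10, 1:100, 1:10] <- 1L  # 10 000 voxels
  s <- LabelStack(v, c(1, 1), 10, "ED")
  expect_equal(compartmentVolume(s, "LVBP"), 100)  # mL
  expect_equal(compartmentVolume(s, "MYO"), 0)
  empty <- LabelStack(array(0L, c(2, 8, 8)), c(1, 1), 8, "ED")
  expect_equal(compartmentVolume(empty, 1L), 0)
})

test_that("phase selection: declared metadata wins, else argmax/argmin, else incomplete", {
  ph <- generatePhantom(small_spec(91))
  study <- ph$study
  # declared
  expect_identical(selectPhases(study, "LV"), c("ED", "ES"))
  # swap the declaration: declared wins regardless of volumes
  study@meta$lv_phases <- c("ES", "ED")
  expect_identical(selectPhases(study, "LV"), c("ES", "ED"))
  # undeclared: by blood-pool volume
  study@meta$lv_phases <- NULL
  expect_identical(selectPhases(study, "LV"), c("ED", "ES"))
  # single phase: incomplete error
  only_ed <- injectDefect(ph$study, defectSpec("missing_phase", phase = "ES"))
  only_ed@meta$lv_phases <- NULL
  expect_error(selectPhases(only_ed, "LV"), class = "cineqc_incomplete")
})

test_that("EF, SV and LV mass follow their closed forms", {
  bm <- BiomarkerSet(LVEDV = 100, LVESV = 40, RVEDV = 120, RVESV = 60, LVM = 105)
  v <- biomarkerValues(bm)
  expect_equal(v[["LVEF"]], 60)
  expect_equal(v[["LVSV"]], 60)
  expect_equal(v[["RVEF"]], 50)
  # mass: 100 mL of myocardium at 1.05 g/mL
  vx <- array(0L, c(10, 100, 100))
  vx[1:10, 1:100, 1:10] <- 2L
  vx[1:10, 1:100, 11:15] <- 1L
  ed <- LabelStack(vx, c(1, 1), 10, "ED")
  vx2 <- vx; vx2[vx2 == 2L] <- 0L
  vx2[1:10, 1:100, 11:13] <- 1L; vx2[1:10, 1:100, 14:15] <- 0L
  es <- LabelStack(vx2, c(1, 1), 10, "ES")
  # add a small RV so phases are selectable
  vx3 <- vx; vx3[1:10, 1:5, 20:29] <- 3L; ed2 <- LabelStack(vx3, c(1, 1), 10, "ED")
  vx4 <- vx2; vx4[1:10, 1:5, 20:24] <- 3L; es2 <- LabelStack(vx4, c(1, 1), 10, "ES")
  study <- CineStudy("m", list(ED = ed2, ES = es2),
                     meta = list(lv_phases = c("ED", "ES"), rv_phases = c("ED", "ES")))
  got <- biomarkerValues(computeBiomarkers(study))
  expect_equal(got[["LVM"]], 100 * 1.05)
  expect_equal(got[["LVEDV"]], 50)
  expect_equal(got[["LVEF"]], 100 * (50 - 30) / 50)
})

test_that("EF is missing when EDV is zero", {
  bm <- BiomarkerSet(LVEDV = 0, LVESV = 0, RVEDV = 100, RVESV = 50)
  expect_true(is.na(biomarkerValues(bm)[["LVEF"]]))
})

test_that("scaling all spacings by k scales volumes by k^3 and leaves EF unchanged", {
  ph <- generatePhantom(small_spec(92))
  b0 <- biomarkerValues(computeBiomarkers(ph$study))
  for (k in c(0.5, 2)) {
    scaled <- injectDefect(ph$study, defectSpec("oversize_scale", factor = k))
    b1 <- biomarkerValues(computeBiomarkers(scaled))
    vols <- c("LVEDV", "LVESV", "LVSV", "LVM", "RVEDV", "RVESV", "RVSV")
    expect_equal(b1[vols], b0[vols] * k^3, tolerance = 1e-12)
    expect_equal(b1[c("LVEF", "RVEF")], b0[c("LVEF", "RVEF")], tolerance = 1e-12)
  }
})

test_that("papillary exclusion changes EF by exactly the amount implied by moved voxel counts", {
  ph <- generatePhantom(fine_spec(93, withIntensities = TRUE))
  study <- ph$study
  inc <- computeBiomarkers(study, papillaryMode = "include")
  exc <- computeBiomarkers(study, papillaryMode = "exclude")
  # recompute the exact moved volumes from refineBloodPool's own accounting
  vox_ml <- prod(c(1, 1, 2)) / 1000
  moved <- lapply(c("ED", "ES"), function(tag)
    refineBloodPool(stacks(study)[[tag]], intensities(study)[[tag]],
                    target = "both")$summary)
  names(moved) <- c("ED", "ES")
  lv_ed <- moved$ED$moved[moved$ED$ventricle == "LV"] * vox_ml
  lv_es <- moved$ES$moved[moved$ES$ventricle == "LV"] * vox_ml
  vi <- biomarkerValues(inc); ve <- biomarkerValues(exc)
  expect_equal(ve[["LVEDV"]], vi[["LVEDV"]] - lv_ed, tolerance = 1e-12)
  expect_equal(ve[["LVESV"]], vi[["LVESV"]] - lv_es, tolerance = 1e-12)
  ef_expected <- 100 * (ve[["LVEDV"]] - ve[["LVESV"]]) / ve[["LVEDV"]]
  expect_equal(ve[["LVEF"]], ef_expected, tolerance = 1e-12)
  # equal inclusion volumes across phases would leave EF unchanged; here
  # they differ, so the EF change must be the exact signed amount
  expect_false(isTRUE(all.equal(ve[["LVEF"]], vi[["LVEF"]])))
  expect_true(biomarkerValues(exc)[["LVEDV"]] < biomarkerValues(inc)[["LVEDV"]])
})

test_that("papillary exclusion without intensities is a configuration error", {
  ph <- generatePhantom(small_spec(94, withIntensities = FALSE))
  expect_error(computeBiomarkers(ph$study, papillaryMode = "exclude"),
               "intensity")
})

test_that("phantom EF is recovered within 2 percentage points across random specs", {
  errs <- vapply(1:20, function(i) {
    ph <- generatePhantom(small_spec(900 + i))
    got <- biomarkerValues(computeBiomarkers(ph$study))
    want <- biomarkerValues(ph$truth)
    abs(got[["LVEF"]] - want[["LVEF"]])
  }, numeric(1))
  expect_lte(stats::median(errs), 2)
})
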