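test_that("connectedComponents agrees with a brute-force flood-fill oracle", {
  set.seed(71)
  for (i in 1:100) {
    mask <- matrix(runif(64) < 0.45, 8, 8)
    v <- array(0L, c(1, 8, 8)); v[1, , ][mask] <- 1L
    stack <- LabelStack(v, c(1, 1), 8, "ED")
    got <- canon_components(connectedComponents(stack, 1L, "per_slice_2d"))
    oracle <- flood_oracle_2d(mask)
    want <- lapply(sort(unique(oracle[oracle > 0])), function(l) sort(which(oracle == l)))
    want <- want[order(vapply(want, min, numeric(1)))]
    expect_identical(got, want)
  }
})

test_that("a disc plus an injected stray blob yields two components with the right sizes", {
  ph <- generatePhantom(small_spec(72))
  comps1 <- connectedComponents(stacks(ph$study)$ED, 1L, "stack_3d")
  expect_length(comps1, 1L)
  bad <- injectDefect(ph$study, defectSpec("stray_component", size = 50L))
  comps2 <- connectedComponents(stacks(bad)$ED, 1L, "stack_3d")
  expect_length(comps2, 2L)
  expect_equal(comps2[[2]]$size, 50L)
  expect_equal(comps2[[1]]$size, comps1[[1]]$size)
})

test_that("frame completeness excludes missing or empty phases", {
  ph <- generatePhantom(small_spec(73))
  expect_equal(nrow(checkFrameCompleteness(ph$study)), 0L)
  bad <- injectDefect(ph$study, defectSpec("missing_phase", phase = "ES"))
  e <- checkFrameCompleteness(bad)
  expect_equal(nrow(e), 1L)
  expect_identical(e$severity, "exclude")
  expect_identical(e$phase, "ES")
  # present but all-background counts as unsegmented
  empty <- ph$study
  v <- voxels(stacks(empty)$ES); v[] <- 0L
  empty@stacks$ES@voxels <- v
  e2 <- checkFrameCompleteness(empty)
  expect_equal(nrow(e2), 1L)
  expect_match(e2$detail, "empty")
})

test_that("coverage flags short LV extent and truncated apex by simple arithmetic", {
  # LV on 8 of 10 slices at 10 mm spacing (tapering apex): 80 mm >= 40 mm
  s8 <- ring_stack(n_slices = 10L)
  v <- voxels(s8); v[9:10, , ] <- 0L
  sl <- v[8, , ]; sl[] <- 0L; sl[19:22, 19:22] <- 1L  # small apical cap
  v[8, , ] <- sl
  s8@voxels <- v
  expect_equal(nrow(checkCoverage(s8)), 0L)
  # LV on 3 slices at 10 mm: 30 mm < 40 mm
  v[4:10, , ] <- 0L
  s3 <- s8; s3@voxels <- v
  e <- checkCoverage(s3)
  expect_true("coverage_extent" %in% e$rule_id)
  # apex truncation on phantoms: most-apical area ratio exceeds 0.5
  ph <- generatePhantom(small_spec(74))
  bad <- injectDefect(ph$study, defectSpec("dropped_apical_slices", n = 4L))
  stack <- stacks(bad)$ED
  counts <- vapply(seq_len(12), function(k) sum(voxels(stack)[k, , ] == 1L), integer(1))
  ratio <- counts[max(which(counts > 0))] / max(counts)
  expect_gt(ratio, 0.5)   # the constructed condition of the rule
  expect_true("coverage_apex" %in% checkCoverage(stack)$rule_id)
})

test_that("gap detection flags exactly the empty interior slices per label", {
  v <- array(0L, c(6, 10, 10))
  v[c(2, 3, 5), 4:6, 4:6] <- 1L
  s <- LabelStack(v, c(1, 1), 8, "ED")
  e <- checkGaps(s)
  expect_equal(nrow(e), 1L)
  expect_match(e$location, "04")
  v[4, 4:6, 4:6] <- 1L
  expect_equal(nrow(checkGaps(LabelStack(v, c(1, 1), 8, "ED"))), 0L)
  # injected mid-stack gap: one entry per label per missing slice
  ph <- generatePhantom(small_spec(75))
  bad <- injectDefect(ph$study, defectSpec("mid_stack_gap"))
  e2 <- checkGaps(stacks(bad)$ED)
  expect_equal(sum(grepl("LVBP", e2$detail)), 2L)
})

test_that("anatomy relations: closed annulus clean, wall hole breached, LV/RV contact flagged", {
  clean <- ring_stack(rv = TRUE)
  expect_equal(nrow(checkAnatomyRelations(clean)), 0L)
  holed <- ring_stack(rv = FALSE, gap_cols = 29:40)
  e <- checkAnatomyRelations(holed)
  expect_true("myo_breach" %in% e$rule_id)
  # zero-thickness septum: RV arc directly against the blood pool
  contact <- ring_stack(rv = FALSE)
  v <- voxels(contact)
  sl <- v[1, , ]
  sl[sl == 2L] <- 0L               # remove the wall entirely
  ctr <- (40 + 1) / 2
  sl[round(ctr), 1:(round(ctr) - 8)] <- 3L  # RV right up to the pool
  v[1, , ] <- sl
  contact@voxels <- v
  e2 <- checkAnatomyRelations(contact)
  expect_true("lv_rv_contact" %in% e2$rule_id)
  expect_true("myo_breach" %in% e2$rule_id)
})

test_that("external components: clean empty plan, stray planned for deletion, deterministic tie-break", {
  ph <- generatePhantom(small_spec(76))
  ext <- checkExternalComponents(ph$study)
  expect_equal(nrow(ext$entries), 0L)
  expect_length(ext$plan, 0L)
  bad <- injectDefect(ph$study, defectSpec("stray_component", size = 50L))
  ext2 <- checkExternalComponents(bad)
  expect_equal(nrow(ext2$entries), 1L)
  expect_length(ext2$plan, 1L)
  expect_equal(ext2$plan[[1]]$size, 50L)
  # two equal components: the one with the lexicographically smallest
  # (slice,row,col) voxel is kept, deterministically
  v <- array(0L, c(4, 12, 12))
  v[2, 2:3, 2:3] <- 1L
  v[3, 8:9, 8:9] <- 1L
  s <- CineStudy("tie", list(ED = LabelStack(v, c(1, 1), 8, "ED")),
                 meta = list(lv_phases = c("ED", "ED"), rv_phases = c("ED", "ED")))
  r1 <- checkExternalComponents(s)
  r2 <- checkExternalComponents(s)
  expect_identical(r1$plan[[1]]$indices, r2$plan[[1]]$indices)
  kept_not_planned <- setdiff(which(v == 1L), r1$plan[[1]]$indices)
  expect_equal(min(arrayInd(kept_not_planned, dim(v))[, 1]), 2L)
})

test_that("volume plausibility flags each biomarker outside its range", {
  ok <- BiomarkerSet(LVEDV = 150, LVESV = 60, RVEDV = 150, RVESV = 60, LVM = 105)
  expect_equal(nrow(checkVolumePlausibility(ok)), 0L)
  big <- BiomarkerSet(LVEDV = 900, LVESV = 60, RVEDV = 150, RVESV = 60, LVM = 10)
  e <- checkVolumePlausibility(big)
  expect_setequal(e$location, c("LVEDV", "LVM"))
})

test_that("SV discordance uses the mean denominator and the 25% threshold", {
  f <- function(lvsv, rvsv) {
    bm <- BiomarkerSet(LVEDV = 100 + lvsv, LVESV = 100, RVEDV = 100 + rvsv, RVESV = 100)
    nrow(checkSvDiscordance(bm))
  }
  expect_equal(f(60, 40), 1L)  # |20|/50 = 40% > 25%
  expect_equal(f(60, 55), 0L)  # 8.7%
  expect_equal(f(60, 60), 0L)  # identical
  neg <- BiomarkerSet(LVEDV = 100, LVESV = 110, RVEDV = 160, RVESV = 100)
  e <- checkSvDiscordance(neg)
  expect_match(e$detail, "non-positive")
})

test_that("duplicates are flagged across studies, not for empty stacks", {
  coh <- randomPhantomCohort(3, 77, nSlices = 12L, grid = c(84L, 84L),
                             spacingMm = c(2, 2, 8), withIntensities = FALSE)
  expect_equal(nrow(findDuplicates(coh$studies)), 0L)
  dup <- injectDefect(coh$studies[[2]],
                      defectSpec("duplicate_of", study_id = "phantom001"),
                      donor = coh$studies[[1]])
  e <- findDuplicates(list(coh$studies[[1]], dup, coh$studies[[3]]))
  expect_equal(nrow(e), 2L)  # one entry per involved study
  expect_match(e$location[1], "phantom001/ED == phantom002/ED")
  empties <- lapply(c("a", "b"), function(id)
    CineStudy(id, list(ED = LabelStack(array(0L, c(2, 8, 8)), c(1, 1), 8, "ED"))))
  expect_equal(nrow(findDuplicates(empties)), 0L)
})

test_that("QA never modifies ground truth and excludes exactly the incomplete studies", {
  coh <- randomPhantomCohort(4, 78, nSlices = 12L, grid = c(84L, 84L),
                             spacingMm = c(2, 2, 8), withIntensities = FALSE)
  studies <- coh$studies
  studies[[2]] <- injectDefect(studies[[2]], defectSpec("missing_phase"))
  before <- lapply(studies, function(s) lapply(stacks(s), voxels))
  qa <- runQaGt(studies)
  expect_identical(qa$excluded, "phantom002")
  after <- lapply(studies, function(s) lapply(stacks(s), voxels))
  expect_identical(before, after)
  expect_equal(length(qa$reports[["phantom001"]]), 0L)
})

test_that("QC auto-correction restores a stray-injected phantom voxel-exactly and is idempotent", {
  ph <- generatePhantom(small_spec(79))
  bad <- injectDefect(ph$study, defectSpec("stray_component", size = 50L))
  qc <- runQcPost(bad)
  expect_identical(voxels(stacks(qc$study)$ED), voxels(stacks(ph$study)$ED))
  corr <- flagEntries(qc$report)
  expect_equal(sum(corr$severity == "corrected"), 1L)
  expect_match(corr$detail[corr$severity == "corrected"], "deletion")
  qc2 <- runQcPost(qc$study)
  expect_identical(voxels(stacks(qc2$study)$ED), voxels(stacks(qc$study)$ED))
  expect_equal(sum(flagEntries(qc2$report)$severity == "corrected"), 0L)
})

test_that("QC corrections are minimal: no voxel outside the deletion plan changes", {
  ph <- generatePhantom(small_spec(80))
  bad <- injectDefect(ph$study, defectSpec("stray_component", size = 30L))
  plan <- checkExternalComponents(bad)$plan
  planned <- plan[[1]]$indices
  qc <- runQcPost(bad)
  for (tag in names(stacks(bad))) {
    va <- voxels(stacks(bad)[[tag]]); vb <- voxels(stacks(qc$study)[[tag]])
    changed <- which(va != vb)
    if (tag == plan[[1]]$phase) expect_setequal(changed, planned)
    else expect_length(changed, 0L)
  }
})

test_that("complex issues are flagged but never modified by QC", {
  ph <- generatePhantom(small_spec(81))
  bad <- injectDefect(ph$study, defectSpec("myocardial_hole"))
  qc <- runQcPost(bad)
  expect_true("myo_breach" %in% flagEntries(qc$report)$rule_id)
  expect_identical(voxels(stacks(qc$study)$ED), voxels(stacks(bad)$ED))
})

test_that("reports are deterministic and canonically ordered", {
  ph <- generatePhantom(small_spec(82))
  bad <- injectDefect(injectDefect(ph$study, defectSpec("myocardial_hole")),
                      defectSpec("mid_stack_gap"))
  r1 <- runQcPost(bad, applyCorrections = FALSE)$report
  r2 <- runQcPost(bad, applyCorrections = FALSE)$report
  expect_identical(flagEntries(r1), flagEntries(r2))
  e <- flagEntries(r1)
  expect_identical(order(e$rule_id, e$phase, e$location), seq_len(nrow(e)))
})
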