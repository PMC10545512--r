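test_that("an all-background volume with a valid sidecar loads as an empty stack", {
  s <- LabelStack(array(0L, c(8, 32, 32)), c(1.5, 1.5), 8, "ED")
  d <- withr::local_tempdir()
  writeLabelStack(s, file.path(d, "empty.nii"))
  r <- readLabelStack(file.path(d, "empty.nii"))
  expect_s4_class(r, "LabelStack")
  expect_equal(sum(voxels(r) != 0L), 0L)
  expect_identical(phaseTag(r), "ED")
})

test_that("write then read is a voxel- and metadata-exact round trip", {
  ph <- generatePhantom(small_spec(21), "rt")
  d <- withr::local_tempdir()
  for (tag in names(stacks(ph$study))) {
    s <- stacks(ph$study)[[tag]]
    writeLabelStack(s, file.path(d, paste0(tag, ".nii")))
    r <- readLabelStack(file.path(d, paste0(tag, ".nii")))
    expect_identical(voxels(r), voxels(s))
    expect_equal(inPlaneSpacing(r), inPlaneSpacing(s))
    expect_equal(sliceSpacing(r), sliceSpacing(s))
    expect_identical(labelMap(r), labelMap(s))
    expect_identical(phaseTag(r), phaseTag(s))
  }
})

test_that("two writes of the same stack produce byte-identical sidecars", {
  s <- stacks(generatePhantom(small_spec(22))$study)$ED
  d <- withr::local_tempdir()
  writeLabelStack(s, file.path(d, "a.nii"))
  writeLabelStack(s, file.path(d, "b.nii"))
  expect_identical(readLines(file.path(d, "a.json")),
                   readLines(file.path(d, "b.json")))
})

test_that("unknown voxel values are a labelling error naming value and count, never a coercion", {
  v <- array(0L, c(2, 8, 8)); v[1, 1:3, 1] <- 7L
  expect_error(LabelStack(v, c(1, 1), 8, "ED"), "7.*3 voxels")
  # on-disk: value outside the declared map
  s <- LabelStack(array(0L, c(2, 8, 8)), c(1, 1), 8, "ED")
  d <- withr::local_tempdir()
  writeLabelStack(s, file.path(d, "x.nii"))
  img <- RNifti::readNifti(file.path(d, "x.nii"))
  arr <- as.array(img); arr[1, 1, 1] <- 7
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int16"), file.path(d, "x.nii"))
  expect_error(readLabelStack(file.path(d, "x.nii")), "labelling error.*7")
})

test_that("non-integer label storage is refused", {
  expect_error(LabelStack(array(0.5, c(1, 4, 4)), c(1, 1), 8, "ED"),
               "integer")
})

test_that("a permuted sidecar label map is remapped to the canonical vocabulary", {
  v <- array(0L, c(1, 8, 8)); v[1, 1:2, 1] <- 9L; v[1, 3, 1] <- 5L
  d <- withr::local_tempdir()
  arr <- aperm(v, c(2, 3, 1)); attr(arr, "pixdim") <- c(1, 1, 8)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int16"), file.path(d, "p.nii"))
  jsonlite::write_json(list(label_map = list(background = 0, LVBP = 9, MYO = 5, RVBP = 3),
                            phase_tag = "ED", spacing_mm = c(1, 1, 8), slice0 = "base"),
                       file.path(d, "p.json"), auto_unbox = TRUE)
  r <- readLabelStack(file.path(d, "p.nii"))
  expect_equal(sum(voxels(r) == 1L), 2L)  # 9 -> LVBP
  expect_equal(sum(voxels(r) == 2L), 1L)  # 5 -> MYO
  expect_identical(labelMap(r), canonicalLabelMap())
})

test_that("sidecar slice0 = apex flips to the base-first convention on load", {
  v <- array(0L, c(3, 6, 6)); v[1, 2, 2] <- 1L  # apex-first file: LV at index 1
  d <- withr::local_tempdir()
  arr <- aperm(v, c(2, 3, 1)); attr(arr, "pixdim") <- c(1, 1, 8)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int16"), file.path(d, "f.nii"))
  jsonlite::write_json(list(label_map = as.list(canonicalLabelMap()), phase_tag = "ED",
                            spacing_mm = c(1, 1, 8), slice0 = "apex"),
                       file.path(d, "f.json"), auto_unbox = TRUE)
  r <- readLabelStack(file.path(d, "f.nii"))
  expect_equal(sum(voxels(r)[3, , ] == 1L), 1L)
  expect_equal(sum(voxels(r)[1, , ]), 0L)
})

test_that("sidecar spacing overrides the NIfTI header and must be positive", {
  s <- LabelStack(array(0L, c(2, 8, 8)), c(1, 1), 8, "ED")
  d <- withr::local_tempdir()
  writeLabelStack(s, file.path(d, "s.nii"))
  sc <- jsonlite::read_json(file.path(d, "s.json"), simplifyVector = TRUE)
  sc$spacing_mm <- c(2, 2, 10)
  jsonlite::write_json(sc, file.path(d, "s.json"), auto_unbox = TRUE)
  expect_equal(sliceSpacing(readLabelStack(file.path(d, "s.nii"))), 10)
  sc$spacing_mm <- c(-1, 2, 10)
  jsonlite::write_json(sc, file.path(d, "s.json"), auto_unbox = TRUE)
  expect_error(readLabelStack(file.path(d, "s.nii")), "geometry error")
})

test_that("loadStudy validates congruence and required phases", {
  ph <- generatePhantom(small_spec(23, withIntensities = TRUE), "io1")
  d <- withr::local_tempdir()
  writeStudy(ph$study, d)
  # label-only manifest -> intensities absent
  man <- utils::read.csv(file.path(d, "manifest.csv"), stringsAsFactors = FALSE)
  lab_only <- man[man$kind == "label", ]
  s <- loadStudy(d, lab_only)
  expect_length(intensities(s), 0)
  # declared phase whose file is missing -> manifest error
  man2 <- man; man2$path[1] <- "nonexistent.nii"
  expect_error(loadStudy(d, man2), "manifest error")
  # intensity/label shape mismatch -> consistency error
  bad <- intensities(ph$study)$ED[1:6, , ]
  st <- stacks(ph$study)$ED
  arr <- aperm(bad, c(2, 3, 1)); attr(arr, "pixdim") <- c(2, 2, 8)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"),
                     file.path(d, "ED_intensity.nii"))
  expect_error(loadStudy(d, man), "consistency error")
})

test_that("a phantom study round-trips through writeStudy and loadStudy", {
  ph <- generatePhantom(small_spec(24, withIntensities = TRUE), "io2")
  d <- withr::local_tempdir()
  writeStudy(ph$study, d)
  s2 <- loadStudy(d)
  expect_identical(studyId(s2), "io2")
  for (tag in names(stacks(ph$study)))
    expect_identical(voxels(stacks(s2)[[tag]]), voxels(stacks(ph$study)[[tag]]))
  expect_identical(intensities(s2)$ES, intensities(ph$study)$ES)
  expect_identical(studyMeta(s2)$lv_phases, c("ED", "ES"))
})
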