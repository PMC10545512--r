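make_mask_stack <- function(idx, n = 200, phase = "ED") {
  v <- array(0L, c(2, 10, 10))
  v[idx] <- 1L
  LabelStack(v, c(1, 1), 8, phase)
}

test_that("Dice endpoints: identical masks 100%, disjoint masks 0%, half overlap 50%", {
  a <- make_mask_stack(1:100)
  expect_equal(diceScore(a, a, "LVBP"), 100)
  b <- make_mask_stack(101:200)
  expect_equal(diceScore(a, b, "LVBP"), 0)
  c50 <- make_mask_stack(c(1:50, 101:150))
  expect_equal(diceScore(a, c50, "LVBP"), 50)
})

test_that("Dice is symmetric, NA for a label empty on both sides, and matches a set oracle", {
  set.seed(111)
  for (i in 1:25) {
    ia <- sample(200, 60); ib <- sample(200, 80)
    a <- make_mask_stack(ia); b <- make_mask_stack(ib)
    want <- 100 * 2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
    expect_equal(diceScore(a, b, "LVBP"), want)
    expect_equal(diceScore(b, a, "LVBP"), diceScore(a, b, "LVBP"))
  }
  a <- make_mask_stack(1:10)
  expect_true(is.na(diceScore(a, a, "MYO")))
  expect_error(diceScore(a, LabelStack(array(0L, c(1, 10, 10)), c(1, 1), 8, "ED"), 1L),
               "congruent")
})

test_that("Bland-Altman bias, limits and correlation follow their definitions", {
  expect_error(blandAltman(1:2, 1:2), "insufficient")
  m <- c(10, 20, 30, 40)
  ba <- blandAltman(m, m)
  expect_equal(ba$bias, 0); expect_equal(ba$loaLower, 0); expect_equal(ba$loaUpper, 0)
  ba2 <- blandAltman(m + 5, m)
  expect_equal(ba2$bias, 5)
  expect_equal(c(ba2$loaLower, ba2$loaUpper), c(5, 5))
  expect_equal(ba2$r, 1)
  set.seed(112)
  auto <- rnorm(200, 100, 20); manual <- auto + rnorm(200, 2, 5)
  ba3 <- blandAltman(auto, manual)
  d <- auto - manual
  expect_equal(ba3$bias, mean(d))
  expect_equal(ba3$loaUpper, mean(d) + 1.96 * sd(d))
  expect_equal(ba3$r, cor(auto, manual))
  # constant input: r undefined
  expect_true(is.na(blandAltman(rep(5, 10), rnorm(10))$r))
})

test_that("error summaries use median and interpolated IQR", {
  es <- errorSummary(c(1, 2, 3))
  expect_equal(es$medianAbsError, 2)
  expect_equal(es$iqr, 1)
  expect_equal(errorSummary(rep(0, 5))$medianAbsError, 0)
  set.seed(113)
  e <- abs(rnorm(1000))
  got <- errorSummary(e)
  q <- quantile(e, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  expect_equal(got$medianAbsError, q[2])
  expect_equal(got$iqr, q[3] - q[1])
})

test_that("group comparisons: null case non-significant, strong shift maximally significant", {
  x <- c(1, 2, 3, 4, 5)
  same <- groupCompare(x, x, "between", nTests = 20)
  expect_equal(same$stars, 0L)
  set.seed(114)
  a <- rnorm(50); b <- rnorm(50) + 100
  shift <- groupCompare(a, b, "between", nTests = 20)
  expect_equal(shift$stars, 3L)
  # threshold arithmetic
  gc <- groupCompare(a, b, nTests = 20, alphas = 0.01)
  expect_equal(gc$thresholds, 5e-4)
  # within-vs-zero design
  w <- groupCompare(rnorm(40, 3, 0.5), design = "within_vs_zero", nTests = 5)
  expect_equal(w$stars, 3L)
  expect_error(groupCompare(numeric(), x), "insufficient")
})

test_that("agreement summaries recompute per-biomarker statistics from the pairs", {
  set.seed(115)
  ref <- data.frame(study_id = sprintf("s%02d", 1:30),
                    LVEDV = rnorm(30, 150, 30), LVEF = rnorm(30, 55, 8))
  auto <- ref
  auto$LVEDV <- ref$LVEDV + rnorm(30, 3, 6)
  auto$LVEF <- ref$LVEF + rnorm(30, -1, 2)
  s <- agreementSummary(auto, ref)
  row <- s[s$metric == "LVEDV", ]
  expect_equal(row$bias, mean(auto$LVEDV - ref$LVEDV))
  expect_equal(row$medianAbsError, median(abs(auto$LVEDV - ref$LVEDV)))
  expect_equal(row$r, cor(auto$LVEDV, ref$LVEDV))
})

test_that("stratified reports reproduce injected shifts and mark insufficient strata", {
  set.seed(116)
  values <- data.frame(study_id = sprintf("s%02d", 1:40),
                       err = c(rnorm(20, 1, 0.1), rnorm(20, 5, 0.1)))
  meta <- data.frame(study_id = values$study_id,
                     disease_group = rep(c("NOR", "DCM"), each = 20))
  rep1 <- stratifiedReport(values, meta, "disease_group", reference = "NOR")
  s <- rep1$summary
  expect_equal(s$median[s$stratum == "DCM"], 5, tolerance = 0.2)
  expect_equal(s$median[s$stratum == "NOR"], 1, tolerance = 0.2)
  expect_equal(rep1$comparisons$stars[rep1$comparisons$stratum == "DCM"], 3L)
  # single stratum: identical to the unstratified summary, no comparisons
  rep2 <- stratifiedReport(values, transform(meta, disease_group = "ALL"),
                           "disease_group")
  expect_equal(rep2$summary$median, median(values$err))
  expect_null(rep2$comparisons)
  # missing metadata: explicit "(missing)" stratum, no crash
  meta3 <- meta; meta3$disease_group[1:2] <- NA
  rep3 <- stratifiedReport(values, meta3, "disease_group", reference = "NOR")
  expect_true("(missing)" %in% rep3$summary$stratum)
  expect_true(all(rep3$summary$insufficient[rep3$summary$stratum == "(missing)"]))
})
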