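## Agreement and validation statistics between two segmentation/biomarker
## sources (automated vs manual, observer vs observer), with stratified
## group comparisons.

#' Dice overlap between two label stacks
#'
#' 100 x 2|A n B| / (|A| + |B|) over the voxels of one label: 0% is no
#' agreement, 100% perfect agreement. When the label is empty in both
#' stacks the score is undefined and reported as `NA` (excluded from
#' medians), to avoid inflating scores for absent classes such as MYO at
#' ES.
#'
#' @param a,b congruent [LabelStack-class] objects.
#' @param label label name or code.
#' @return Dice score in percent, or `NA` if the label is empty in both.
#' @export
diceScore <- function(a, b, label) {
  if (!identical(dim(a@voxels), dim(b@voxels)))
    stop("stacks are not congruent: voxel dimensions differ")
  code <- .label_code(a, label)
  ma <- a@voxels == code
  mb <- b@voxels == code
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0L) return(NA_real_)
  100 * 2 * sum(ma & mb) / (na + nb)
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean of automated minus manual), limits of agreement (bias plus or
#' minus 1.96 standard deviations of the differences), and the Pearson
#' correlation of the two measurement series. With constant input on
#' either side the correlation is undefined and reported as `NA`.
#'
#' @param auto,manual paired numeric measurements (at least 3 pairs).
#' @return list with `bias`, `loaLower`, `loaUpper`, `sdDiff`, `r`, `rP`,
#'   `n`.
#' @examples
#' blandAltman(c(10, 20, 30), c(5, 15, 25))  # bias 5, limits (5, 5), r 1
#' @export
blandAltman <- function(auto, manual) {
  if (length(auto) != length(manual)) stop("auto and manual must be paired")
  ok <- is.finite(auto) & is.finite(manual)
  auto <- auto[ok]; manual <- manual[ok]
  if (length(auto) < 3L) stop("insufficient data: at least 3 pairs required")
  d <- auto - manual
  bias <- mean(d)
  s <- stats::sd(d)
  r <- rP <- NA_real_
  if (stats::sd(auto) > 0 && stats::sd(manual) > 0) {
    ct <- stats::cor.test(auto, manual, method = "pearson")
    r <- unname(ct$estimate); rP <- ct$p.value
  }
  list(bias = bias, loaLower = bias - 1.96 * s, loaUpper = bias + 1.96 * s,
       sdDiff = s, r = r, rP = rP, n = length(auto))
}

#' Median absolute error with interquartile range
#'
#' Absolute errors |auto - manual| summarized as median and IQR (75th minus
#' 25th percentile, linear interpolation).
#'
#' @param auto,manual paired numeric measurements; alternatively pass
#'   pre-computed absolute errors as `auto` and omit `manual`.
#' @return list with `medianAbsError`, `iqr`, `n`.
#' @export
errorSummary <- function(auto, manual = NULL) {
  err <- if (is.null(manual)) abs(auto) else abs(auto - manual)
  err <- err[is.finite(err)]
  if (!length(err)) stop("no finite errors to summarize")
  q <- stats::quantile(err, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(medianAbsError = q[2], iqr = q[3] - q[1], n = length(err))
}

#' Nonparametric group comparison with Bonferroni-adjusted tiers
#'
#' Between-group design: Mann-Whitney U test (two-sample Wilcoxon rank
#' sum). Within-vs-zero design: Wilcoxon signed-rank test of the values
#' against zero. Significance is reported at the Bonferroni-adjusted tiers
#' alpha / nTests for alpha in `alphas` (default 0.01, 0.001, 0.0001,
#' mirroring the star convention *P < 0.01/n, **P < 0.001/n,
#' ***P < 0.0001/n).
#'
#' @param x numeric values (first group, or the within-design values).
#' @param y second group for the between design.
#' @param design "between" or "within_vs_zero".
#' @param nTests number of tests in the comparison family (default 1).
#' @param alphas unadjusted significance tiers.
#' @return list with `statistic`, `p`, `thresholds` (alphas / nTests),
#'   `stars` (number of tiers passed) and `significant` (logical per tier).
#' @export
groupCompare <- function(x, y = NULL, design = c("between", "within_vs_zero"),
                         nTests = 1L, alphas = c(0.01, 0.001, 0.0001)) {
  design <- match.arg(design)
  x <- x[is.finite(x)]
  if (design == "between") {
    y <- y[is.finite(y)]
    if (length(x) < 2L || length(y) < 2L)
      stop("insufficient data: each group needs at least 2 values")
    ht <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  } else {
    if (!any(x != 0)) stop("insufficient data: need at least 1 nonzero difference")
    ht <- stats::wilcox.test(x, mu = 0, exact = FALSE, correct = TRUE)
  }
  thresholds <- alphas / nTests
  significant <- ht$p.value < thresholds
  list(statistic = unname(ht$statistic), p = ht$p.value,
       thresholds = thresholds, stars = sum(significant),
       significant = significant)
}

#' Per-biomarker agreement summary between two sources
#'
#' For each shared numeric column (biomarker) of two per-study tables:
#' Bland-Altman bias and limits of agreement, Pearson r with p-value, and
#' median absolute error with IQR.
#'
#' @param auto,ref data.frames with a `study_id` column plus numeric
#'   biomarker columns; rows are matched on `study_id`.
#' @return data.frame with one row per biomarker.
#' @export
agreementSummary <- function(auto, ref) {
  common <- intersect(auto$study_id, ref$study_id)
  if (length(common) < 3L) stop("insufficient data: fewer than 3 matched studies")
  a <- auto[match(common, auto$study_id), , drop = FALSE]
  r <- ref[match(common, ref$study_id), , drop = FALSE]
  metrics <- setdiff(intersect(names(a), names(r)), "study_id")
  metrics <- metrics[vapply(metrics, function(m) is.numeric(a[[m]]), logical(1))]
  rows <- lapply(metrics, function(m) {
    ba <- blandAltman(a[[m]], r[[m]])
    es <- errorSummary(a[[m]], r[[m]])
    data.frame(metric = m, n = ba$n, bias = ba$bias,
               loaLower = ba$loaLower, loaUpper = ba$loaUpper,
               r = ba$r, rP = ba$rP,
               medianAbsError = es$medianAbsError, iqr = es$iqr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratified agreement report
#'
#' Groups per-study metric values by a metadata stratum (disease group,
#' vendor, field strength), computes median/IQR summaries per stratum and
#' compares each stratum against a reference stratum with Mann-Whitney U
#' tests under Bonferroni correction. Strata below the minimum size are
#' reported as insufficient rather than silently dropped; studies with
#' missing metadata are collected in an explicit "(missing)" stratum.
#'
#' @param values data.frame with `study_id` plus numeric metric columns
#'   (e.g. absolute biomarker errors or Dice scores).
#' @param meta data.frame with `study_id` and the stratum column.
#' @param stratum metadata column to stratify on (e.g. "disease_group").
#' @param reference reference stratum for the comparisons (default: the
#'   largest stratum).
#' @param nTests Bonferroni family size (default: number of comparisons,
#'   i.e. (strata - 1) x metrics).
#' @param minN minimal stratum size for summaries/comparisons (default 3).
#' @return list with `summary` (stratum x metric medians/IQRs) and
#'   `comparisons` (stratum vs reference test results).
#' @export
stratifiedReport <- function(values, meta, stratum = "disease_group",
                             reference = NULL, nTests = NULL, minN = 3L) {
  if (!stratum %in% names(meta)) stop(sprintf("metadata lacks column '%s'", stratum))
  grp <- meta[[stratum]][match(values$study_id, meta$study_id)]
  grp[is.na(grp) | !nzchar(as.character(grp))] <- "(missing)"
  grp <- as.character(grp)
  metrics <- setdiff(names(values), "study_id")
  metrics <- metrics[vapply(metrics, function(m) is.numeric(values[[m]]), logical(1))]
  strata <- names(sort(table(grp), decreasing = TRUE))
  if (is.null(reference)) reference <- strata[1]

  summary_rows <- list(); cmp_rows <- list()
  for (s in strata) {
    idx <- grp == s
    n <- sum(idx)
    for (m in metrics) {
      vals <- values[[m]][idx]
      vals <- vals[is.finite(vals)]
      insufficient <- length(vals) < minN
      q <- if (length(vals)) stats::quantile(vals, c(0.25, 0.5, 0.75),
                                             names = FALSE, type = 7) else rep(NA_real_, 3)
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        stratum = s, metric = m, n = n,
        median = if (insufficient) NA_real_ else q[2],
        iqr = if (insufficient) NA_real_ else q[3] - q[1],
        insufficient = insufficient, stringsAsFactors = FALSE)
      if (s != reference) {
        refvals <- values[[m]][grp == reference]
        refvals <- refvals[is.finite(refvals)]
        if (insufficient || length(refvals) < minN) {
          cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
            stratum = s, metric = m, statistic = NA_real_, p = NA_real_,
            stars = NA_integer_, insufficient = TRUE, stringsAsFactors = FALSE)
        } else {
          nt <- nTests %||% ((length(strata) - 1L) * length(metrics))
          gc <- groupCompare(vals, refvals, "between", nTests = nt)
          cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
            stratum = s, metric = m, statistic = gc$statistic, p = gc$p,
            stars = gc$stars, insufficient = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(summary = do.call(rbind, summary_rows),
       comparisons = if (length(cmp_rows)) do.call(rbind, cmp_rows) else NULL,
       reference = reference)
}
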