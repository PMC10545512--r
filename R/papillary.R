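## Papillary-muscle exclusion: on bright-blood (bSSFP) cine, papillary
## muscle inside the blood pool is dark relative to blood, so an Otsu
## threshold on the within-mask intensity histogram separates the two
## classes. Applied per ventricle and per phase (histograms are not pooled:
## coil shading differs by region).

#' Build an intensity histogram
#'
#' @param values numeric intensity values.
#' @param bins number of equal-width bins over the value range (default
#'   256).
#' @return list with `bin_edges` (length bins + 1, monotone) and `counts`.
#'   When all values are identical the histogram degenerates to a single
#'   occupied bin.
#' @export
intensityHistogram <- function(values, bins = 256L) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite intensity values to histogram")
  rng <- range(values)
  if (rng[1] == rng[2]) {
    return(list(bin_edges = c(rng[1], rng[1] + 1), counts = length(values)))
  }
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  idx <- findInterval(values, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  list(bin_edges = edges, counts = tabulate(idx, nbins = bins))
}

#' Otsu threshold of an intensity histogram
#'
#' Returns the bin edge maximizing the between-class variance
#' w0 w1 (mu0 - mu1)^2 over all candidate splits, with ties broken by the
#' lowest threshold. Bin contents are represented by their midpoints.
#'
#' @param hist list with `bin_edges` and `counts`, as from
#'   [intensityHistogram()].
#' @return the threshold intensity (a bin edge); values strictly below it
#'   form the lower (dark) class.
#' @examples
#' h <- intensityHistogram(c(rep(50, 100), rep(200, 100)), bins = 16)
#' otsuThreshold(h)
#' @export
otsuThreshold <- function(hist) {
  counts <- as.numeric(hist$counts)
  edges <- hist$bin_edges
  if (length(counts) != length(edges) - 1L)
    stop("counts must have one element per bin")
  if (any(counts < 0)) stop("histogram counts must be non-negative")
  if (sum(counts > 0) < 2L)
    stop("degenerate histogram: intensity mass in fewer than 2 distinct bins")
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  n <- sum(counts)
  w0 <- cumsum(counts) / n
  m0 <- cumsum(counts * mids) / n       # unnormalized class-0 mean * w0
  mt <- m0[length(m0)]
  k <- seq_len(length(counts) - 1L)     # split after bin k
  w1 <- 1 - w0[k]
  valid <- w0[k] > 0 & w1 > 0
  bcv <- rep(-Inf, length(k))
  mu0 <- m0[k][valid] / w0[k][valid]
  mu1 <- (mt - m0[k][valid]) / w1[valid]
  bcv[valid] <- w0[k][valid] * w1[valid] * (mu0 - mu1)^2
  top <- max(bcv)
  best <- which(bcv >= top - 1e-12 * max(abs(top), 1))[1]  # lowest tie wins

  edges[best + 1L]
}

#' Remove papillary muscle from blood-pool segmentations
#'
#' Per target ventricle: builds the intensity histogram within the
#' blood-pool mask, applies [otsuThreshold()], and reassigns voxels on the
#' dark side of the threshold (muscle, on bright-blood cine) to
#' `reassignTo` -- except dark islands of at most `minIslandVoxels` voxels
#' (per-slice 8-connectivity), which are kept as blood and treated as
#' noise. A degenerate within-mask histogram makes the refinement a no-op
#' for that ventricle, with a warning entry in the summary.
#'
#' @param stack a [LabelStack-class].
#' @param intensity numeric 3D array congruent with the stack.
#' @param target "both" (default), "LV" or "RV".
#' @param reassignTo "PAP" (default; a dedicated 4th label so downstream
#'   consumers decide how to use the removed volume), "MYO" or
#'   "background".
#' @param bins histogram bins (default 256).
#' @param minIslandVoxels island size kept as blood (default 2).
#' @param darkBelow TRUE (default) removes the class below the threshold
#'   (bright-blood convention); FALSE removes the class above it.
#' @return list with `stack` (refined [LabelStack-class]) and `summary`
#'   (data.frame: ventricle, phase, threshold, moved, note).
#' @export
refineBloodPool <- function(stack, intensity,
                            target = c("both", "LV", "RV"),
                            reassignTo = c("PAP", "MYO", "background"),
                            bins = 256L, minIslandVoxels = 2L,
                            darkBelow = TRUE) {
  target <- match.arg(target)
  reassignTo <- match.arg(reassignTo)
  if (is.null(intensity)) stop("papillary refinement requires an intensity volume")
  if (!identical(dim(intensity), dim(stack@voxels)))
    stop("intensity volume shape differs from the label stack")

  codes <- switch(target, both = c(LV = 1L, RV = 3L), LV = c(LV = 1L),
                  RV = c(RV = 3L))
  new_code <- switch(reassignTo, PAP = 4L, MYO = 2L, background = 0L)
  if (reassignTo == "PAP" && !4L %in% stack@labelMap)
    stack@labelMap <- canonicalLabelMap(with_pap = TRUE)

  v <- stack@voxels
  d <- dim(v)
  summ <- list()
  for (vent in names(codes)) {
    idx <- which(v == codes[[vent]])
    row <- data.frame(ventricle = vent, phase = stack@phaseTag,
                      threshold = NA_real_, moved = 0L, note = "",
                      stringsAsFactors = FALSE)
    if (!length(idx)) {
      row$note <- "empty blood pool: skipped"
      summ[[length(summ) + 1L]] <- row; next
    }
    h <- intensityHistogram(intensity[idx], bins = bins)
    thr <- tryCatch(otsuThreshold(h), error = function(e) NA_real_)
    if (is.na(thr)) {
      row$note <- "degenerate histogram: no threshold applied"
      summ[[length(summ) + 1L]] <- row; next
    }
    dark <- if (darkBelow) intensity[idx] < thr else intensity[idx] >= thr
    sel <- idx[dark]
    if (length(sel) && minIslandVoxels > 0L) {
      mask <- array(FALSE, d); mask[sel] <- TRUE
      comps <- .components_of_mask(mask, d, across_slice = FALSE)
      keep_blood <- unlist(lapply(comps, function(cp)
        if (cp$size <= minIslandVoxels) cp$indices else integer()))
      sel <- setdiff(sel, keep_blood)
    }
    if (length(sel)) v[sel] <- new_code
    row$threshold <- thr
    row$moved <- length(sel)
    summ[[length(summ) + 1L]] <- row
  }
  stack@voxels <- v
  validObject(stack)
  list(stack = stack, summary = do.call(rbind, summ))
}
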