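## Partial-label (marginalized) segmentation loss. Clinical annotation
## protocols are inconsistent: e.g. the myocardium is often segmented at ED
## but not at ES. Instead of masking voxels, the loss folds each absent
## class's predicted probability into background (the marginal probability
## of "anything unannotated"), which preserves per-voxel normalization and
## makes the loss exactly invariant to how predicted mass is split between
## background and absent classes.

.loss_classes <- c("background", "LVBP", "MYO", "RVBP")

# validate a frame and normalise ref to character class names
.check_frame <- function(prob, ref, presentClasses, tol = 1e-6) {
  if (is.null(dim(prob)) || ncol(prob) != length(.loss_classes))
    stop(sprintf("prob must be a matrix with %d columns (%s)",
                 length(.loss_classes), paste(.loss_classes, collapse = ", ")))
  if (is.null(colnames(prob))) colnames(prob) <- .loss_classes
  if (!identical(colnames(prob), .loss_classes))
    stop("prob columns must be background, LVBP, MYO, RVBP in order")
  if (any(prob < -tol)) stop("predicted probabilities must be non-negative")
  rs <- rowSums(prob)
  if (any(abs(rs - 1) > tol))
    stop("predicted probability rows must sum to 1 (within 1e-6)")
  if (!"background" %in% presentClasses)
    stop("background must always be among the present classes")
  bad <- setdiff(presentClasses, .loss_classes)
  if (length(bad)) stop(sprintf("unknown class(es): %s", paste(bad, collapse = ", ")))
  if (is.numeric(ref)) ref <- .loss_classes[ref + 1L]
  if (anyNA(ref) || !all(ref %in% .loss_classes))
    stop("reference labels must be class codes 0-3 or class names")
  if (length(ref) != nrow(prob))
    stop("one reference label per prediction row required")
  absent <- setdiff(.loss_classes, presentClasses)
  if (any(ref %in% absent))
    stop(sprintf("reference contains label(s) of absent class(es): %s",
                 paste(intersect(unique(ref), absent), collapse = ", ")))
  ref
}

.soft_dice <- function(p, g, eps = 1e-5) (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)

#' Marginalized partial-label segmentation loss
#'
#' Composite cross-entropy + soft-Dice loss that remains well defined when
#' some classes are unannotated in a frame. Each absent class's predicted
#' probability is folded into the background channel
#' (q_bg = p_bg + sum over absent classes of p_c); cross-entropy is then
#' taken against the reference over the present classes, and soft Dice
#' (2*sum(p*g) + eps) / (sum(p) + sum(g) + eps), eps = 1e-5, is averaged
#' over the present non-background classes. When all classes are present
#' this equals the standard composite loss.
#'
#' @param prob numeric matrix (voxels x 4), columns background, LVBP, MYO,
#'   RVBP; rows must sum to 1 within 1e-6.
#' @param ref reference labels: integer codes 0-3 or class names, one per
#'   row; must belong to present classes.
#' @param presentClasses character subset of the classes actually annotated
#'   in this frame; must include "background". Default: all.
#' @param ceWeight,diceWeight weights of the two terms (default 1 each).
#' @param eps additive Dice smoothing (default 1e-5).
#' @return a finite non-negative scalar loss.
#' @examples
#' p <- diag(4)[c(1, 2, 3, 4), ]  # perfect one-hot prediction
#' marginalizedLoss(p, c(0, 1, 2, 3))  # ~0
#' @export
marginalizedLoss <- function(prob, ref, presentClasses = .loss_classes,
                             ceWeight = 1, diceWeight = 1, eps = 1e-5) {
  if (is.null(colnames(prob)) && !is.null(dim(prob))) colnames(prob) <- .loss_classes
  ref <- .check_frame(prob, ref, presentClasses)
  absent <- setdiff(.loss_classes, presentClasses)
  q <- prob
  if (length(absent)) {
    q[, "background"] <- q[, "background"] + rowSums(q[, absent, drop = FALSE])
    q <- q[, setdiff(.loss_classes, absent), drop = FALSE]
  }
  ce <- mean(-log(pmax(q[cbind(seq_len(nrow(q)), match(ref, colnames(q)))], 1e-12)))
  fg <- setdiff(colnames(q), "background")
  dice <- if (length(fg)) {
    mean(vapply(fg, function(cl) .soft_dice(q[, cl], as.numeric(ref == cl), eps),
                numeric(1)))
  } else 1
  ceWeight * ce + diceWeight * (1 - dice)
}

#' Standard composite segmentation loss (cross-entropy + soft Dice)
#'
#' The fully-annotated baseline the marginalized loss reduces to: mean
#' cross-entropy of the reference class plus one minus the mean soft Dice
#' over the non-background classes. Implemented directly (no folding) so it
#' serves as an independent cross-check of [marginalizedLoss()].
#'
#' @inheritParams marginalizedLoss
#' @return a finite non-negative scalar loss.
#' @export
standardCompositeLoss <- function(prob, ref, ceWeight = 1, diceWeight = 1,
                                  eps = 1e-5) {
  if (is.null(colnames(prob)) && !is.null(dim(prob))) colnames(prob) <- .loss_classes
  ref <- .check_frame(prob, ref, .loss_classes)
  ce <- mean(-log(pmax(prob[cbind(seq_len(nrow(prob)), match(ref, .loss_classes))],
                       1e-12)))
  fg <- setdiff(.loss_classes, "background")
  dice <- mean(vapply(fg, function(cl) .soft_dice(prob[, cl], as.numeric(ref == cl), eps),
                      numeric(1)))
  ceWeight * ce + diceWeight * (1 - dice)
}
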