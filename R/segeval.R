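#' Evaluate a predicted segmentation against ground truth
#'
#' Two metrics validate any upstream segmenter: the binary error
#' `e_binary = |A_gt - A_pred| / A_gt` over foreground areas, and the
#' object count error `e_object = |N_gt - N_pred| / N_gt` over cell
#' counts. Both are 0 when prediction equals ground truth; either is
#' reported missing when its denominator is 0.
#'
#' @param gt,pred [label_image()] objects of identical dimensions and
#'   pixel size.
#' @return A one-row tibble: `e_binary`, `e_object`, `A_gt`, `A_pred`
#'   (um^2), `N_gt`, `N_pred`.
#' @export
evaluate_segmentation <- function(gt, pred) {
  stopifnot(inherits(gt, "label_image"), inherits(pred, "label_image"))
  if (!identical(dim(gt$pixels), dim(pred$pixels)))
    stop("gt and pred must share dimensions")
  if (!isTRUE(all.equal(gt$pixel_size, pred$pixel_size)))
    stop("gt and pred must share pixel size")
  a_gt <- sum(gt$pixels > 0L) * gt$pixel_size^2
  a_pred <- sum(pred$pixels > 0L) * pred$pixel_size^2
  n_gt <- n_cells(gt)
  n_pred <- n_cells(pred)
  tibble::tibble(
    e_binary = if (a_gt > 0) abs(a_gt - a_pred) / a_gt else NA_real_,
    e_object = if (n_gt > 0) abs(n_gt - n_pred) / n_gt else NA_real_,
    A_gt = a_gt, A_pred = a_pred, N_gt = n_gt, N_pred = n_pred
  )
}

#' Prune duplicate mask predictions by greedy IoU suppression
#'
#' Instance segmenters can emit near-duplicate masks for one cell. Masks
#' are visited in descending confidence (ties broken by smaller index) and
#' a mask is dropped when its intersection-over-union with any already
#' kept mask exceeds `iou_threshold`. The procedure is deterministic and
#' idempotent.
#'
#' @param masks List of logical/binary matrices sharing dimensions.
#' @param scores Numeric confidences in [0, 1], one per mask.
#' @param iou_threshold IoU above which a lower-scoring mask is a
#'   duplicate (default 0.5).
#' @return A tibble with columns `index` (position in the input list),
#'   `score`, and `kept`; kept masks are ordered by descending score.
#' @export
prune_duplicates <- function(masks, scores, iou_threshold = 0.5) {
  stopifnot(length(masks) == length(scores),
            all(scores >= 0 & scores <= 1))
  if (!length(masks)) {
    return(tibble::tibble(index = integer(), score = double(),
                          kept = logical()))
  }
  dims <- unique(lapply(masks, dim))
  if (length(dims) != 1L) stop("masks must share dimensions")
  ord <- order(-scores, seq_along(scores))
  kept <- logical(length(masks))
  kept_idx <- integer(0)
  for (i in ord) {
    mi <- masks[[i]] > 0
    dup <- FALSE
    for (j in kept_idx) {
      mj <- masks[[j]] > 0
      inter <- sum(mi & mj)
      uni <- sum(mi | mj)
      if (uni > 0 && inter / uni > iou_threshold) {
        dup <- TRUE
        break
      }
    }
    if (!dup) {
      kept[i] <- TRUE
      kept_idx <- c(kept_idx, i)
    }
  }
  tibble::tibble(index = ord, score = scores[ord], kept = kept[ord])
}
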