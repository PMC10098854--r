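#' Binarize a prediction image
#'
#' Collapses a 3-channel prediction to luminance (1-channel maps are used
#' directly) and thresholds it; values equal to the threshold map to
#' foreground.
#'
#' @param prediction_image array `H x W x C` or matrix in `[0, 1]`.
#' @param threshold scalar in `[0, 1]`.
#' @return Binary `H x W` matrix.
#' @export
binarize <- function(prediction_image, threshold = 0.5) {
  if (length(dim(prediction_image)) == 3L && dim(prediction_image)[3L] == 1L)
    prediction_image <- prediction_image[, , 1L]
  binarize_mask(luminance(prediction_image), threshold)
}

#' Pixel confusion counts
#'
#' @param pred_mask,true_mask equal-shape binary matrices (1 = lesion).
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`; their sum equals the number of evaluated pixels.
#' @export
confusion <- function(pred_mask, true_mask) {
  if (!all(dim(pred_mask) == dim(true_mask)))
    stop("pred_mask and true_mask must have identical shape")
  if (!all(pred_mask %in% c(0, 1)) || !all(true_mask %in% c(0, 1)))
    stop("masks must be binary")
  p <- pred_mask == 1
  t <- true_mask == 1
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

# 0/0 convention: 1 when the masks agree on the relevant class, else 0;
# such metrics are flagged in the result.
safe_ratio <- function(num, den, agree) {
  if (den > 0) return(list(value = num / den, flagged = FALSE))
  list(value = if (agree) 1 else 0, flagged = TRUE)
}

#' Segmentation metrics from confusion counts
#'
#' Computes accuracy `(TP+TN)/total`, Dice `2TP/(2TP+FP+FN)`, Jaccard
#' `TP/(TP+FP+FN)` and sensitivity `TP/(TP+FN)`, plus two specificity
#' variants: `specificity_paper = TP/(TP+FP)` — the formula as printed in
#' the source tables, mathematically a precision — and the standard
#' `specificity_standard = TN/(TN+FP)`. Any 0/0 denominator yields 1 when
#' prediction and truth agree on the relevant class (else 0) and the metric
#' name is recorded in `flagged`.
#'
#' @param counts a `confusion_counts` (from [confusion()]), or a list with
#'   fields `tp`, `fp`, `tn`, `fn`.
#' @return An object of class `segmentation_metrics`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (any(c(tp, fp, tn, fn) < 0)) stop("confusion counts must be >= 0")
  total <- tp + fp + tn + fn
  if (total == 0) stop("no pixels to evaluate")
  flagged <- character(0)
  take <- function(name, r) {
    if (r$flagged) flagged <<- c(flagged, name)
    r$value
  }
  m <- list(
    accuracy = (tp + tn) / total,
    dice = take("dice", safe_ratio(2 * tp, 2 * tp + fp + fn,
                                   agree = (fp == 0 && fn == 0))),
    jaccard = take("jaccard", safe_ratio(tp, tp + fp + fn,
                                         agree = (fp == 0 && fn == 0))),
    sensitivity = take("sensitivity", safe_ratio(tp, tp + fn,
                                                 agree = (fp == 0))),
    specificity_paper = take("specificity_paper",
                             safe_ratio(tp, tp + fp, agree = (fn == 0))),
    specificity_standard = take("specificity_standard",
                                safe_ratio(tn, tn + fp, agree = (fn == 0))))
  structure(c(m, list(counts = counts, flagged = flagged)),
            class = "segmentation_metrics")
}

#' @export
print.segmentation_metrics <- function(x, ...) {
  cat(sprintf(paste0("<segmentation_metrics> accuracy %.4f  dice %.4f  ",
                     "jaccard %.4f\n  sensitivity %.4f  specificity(paper) ",
                     "%.4f  specificity(standard) %.4f\n"),
              x$accuracy, x$dice, x$jaccard, x$sensitivity,
              x$specificity_paper, x$specificity_standard))
  if (length(x$flagged))
    cat("  0/0 convention applied to:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Compare one predicted and true mask pair
#'
#' @param pred_mask,true_mask binary matrices.
#' @return A `segmentation_metrics`.
#' @export
evaluate_masks <- function(pred_mask, true_mask) {
  compute_metrics(confusion(pred_mask, true_mask))
}

#' Evaluate a generator over a dataset
#'
#' Runs deterministic-mode predictions (dropout off; pass a `seed` for
#' stochastic mode), binarizes them, and tabulates per-sample metrics plus
#' their unweighted means.
#'
#' @param G a `cgan_generator`.
#' @param pairs list of [image_pair()] objects or a [dataset_manifest()].
#' @param threshold binarization threshold.
#' @param deterministic disable dropout at prediction time (the default for
#'   evaluation).
#' @param seed seed for stochastic predictions.
#' @param csv_path if non-`NULL`, the per-sample table (with a final `mean`
#'   row) is written here as CSV.
#' @return List with `samples` (per-sample data frame) and `means` (named
#'   numeric vector of unweighted column means).
#' @export
evaluate_dataset <- function(G, pairs, threshold = 0.5, deterministic = TRUE,
                             seed = NULL, csv_path = NULL) {
  if (inherits(pairs, "dataset_manifest")) {
    sz <- G$spec$input_size
    pairs <- load_manifest_pairs(pairs, target_size = c(sz, sz))
  }
  rows <- lapply(pairs, function(pair) {
    pred <- predict_mask(G, pair$image, deterministic = deterministic,
                         seed = seed)
    m <- evaluate_masks(binarize(pred, threshold), pair$mask)
    data.frame(id = pair$id, accuracy = m$accuracy, dice = m$dice,
               jaccard = m$jaccard, sensitivity = m$sensitivity,
               specificity_paper = m$specificity_paper,
               specificity_standard = m$specificity_standard,
               stringsAsFactors = FALSE)
  })
  samples <- do.call(rbind, rows)
  num_cols <- setdiff(names(samples), "id")
  means <- colMeans(samples[num_cols])
  if (!is.null(csv_path)) {
    out <- rbind(samples,
                 cbind(data.frame(id = "mean"),
                       as.data.frame(as.list(means))))
    utils::write.csv(out, csv_path, row.names = FALSE)
  }
  list(samples = samples, means = means)
}

#' Overlay the mask contour on an image
#'
#' Recolors the boundary pixels of the mask — foreground pixels 4-adjacent
#' to background (pixels beyond the frame count as background) — on a copy
#' of the image; the mask itself is untouched.
#'
#' @param image array `H x W x 3` in `[0, 1]`.
#' @param mask binary matrix of matching size.
#' @param color RGB triple for the contour (default red).
#' @return The annotated image array.
#' @export
contour_overlay <- function(image, mask, color = c(1, 0, 0)) {
  if (!all(dim(image)[1:2] == dim(mask)))
    stop("image and mask must have identical height and width")
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  up <- pad[1:H, 2:(W + 1L)]
  down <- pad[3:(H + 2L), 2:(W + 1L)]
  left <- pad[2:(H + 1L), 1:W]
  right <- pad[2:(H + 1L), 3:(W + 2L)]
  boundary <- mask == 1 & (up == 0 | down == 0 | left == 0 | right == 0)
  out <- image
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[boundary] <- color[ch]
    out[, , ch] <- plane
  }
  out
}
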