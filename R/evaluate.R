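#' Pixel-wise confusion counts
#'
#' A true positive is a pixel labelled vessel in the ground truth and
#' predicted vessel; false negative a vessel pixel predicted non-vessel;
#' true negative a non-vessel pixel predicted non-vessel; false positive a
#' non-vessel pixel predicted vessel. Counts are taken over `eval_region`
#' only (default: every pixel; the retinal literature sometimes restricts
#' to the circular field of view, so an optional region mask is accepted).
#'
#' @param pred_mask,gt_mask binary matrices of identical dims.
#' @param eval_region optional logical/binary matrix selecting pixels.
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion <- function(pred_mask, gt_mask, eval_region = NULL) {
  if (!identical(dim(pred_mask), dim(gt_mask)))
    stop("prediction and ground truth dims differ")
  .check_binary(pred_mask); .check_binary(gt_mask)
  keep <- if (is.null(eval_region)) TRUE else {
    if (!identical(dim(eval_region), dim(gt_mask)))
      stop("eval_region dims differ")
    as.logical(eval_region)
  }
  p <- pred_mask[keep]; g <- gt_mask[keep]
  c(tp = sum(p == 1 & g == 1), fp = sum(p == 1 & g == 0),
    tn = sum(p == 0 & g == 0), fn = sum(p == 0 & g == 1))
}

#' Sensitivity, specificity, and accuracy
#'
#' `Se = tp/(tp+fn)`, `Sp = tn/(tn+fp)`, `Acc = (tp+tn)/(tp+fp+fn+tn)`.
#' A zero denominator yields `NA` for that metric.
#'
#' @param counts named vector with `tp`, `fp`, `tn`, `fn` (see
#'   [confusion()]).
#' @return Named numeric vector `c(Se, Sp, Acc)`.
#' @export
se_sp_acc <- function(counts) {
  counts <- as.list(counts)
  div <- function(a, b) if (b > 0) a / b else NA_real_
  with(counts, c(Se = div(tp, tp + fn), Sp = div(tn, tn + fp),
                 Acc = div(tp + tn, tp + fp + fn + tn)))
}

#' Area under the pixel-wise ROC curve
#'
#' Trapezoidal area under the ROC traced by sweeping every distinct
#' vessel-probability threshold over the pooled pixels (the standard
#' trapezoid rule, delegated to \pkg{pROC}); equals the Mann-Whitney
#' pairwise-concordance statistic.
#'
#' @param vessel_prob numeric matrix or `H x W x 2` probability array (the
#'   vessel channel is used) with values in `[0, 1]`.
#' @param gt_mask binary ground-truth matrix.
#' @param eval_region optional region mask as in [confusion()].
#' @return AUC as a fraction in `[0, 1]`.
#' @export
roc_auc <- function(vessel_prob, gt_mask, eval_region = NULL) {
  if (length(dim(vessel_prob)) == 3L) vessel_prob <- vessel_prob[, , 2]
  if (!identical(dim(vessel_prob), dim(gt_mask)))
    stop("probability map and ground truth dims differ")
  .check_binary(gt_mask)
  keep <- if (is.null(eval_region)) TRUE else as.logical(eval_region)
  g <- gt_mask[keep]; p <- vessel_prob[keep]
  if (length(unique(g)) < 2L)
    stop("ROC undefined: ground truth contains a single class")
  as.numeric(pROC::auc(pROC::roc(response = g, predictor = p,
                                 direction = "<", quiet = TRUE)))
}

#' Overlay colouring for segmentation errors
#'
#' Defaults follow the published convention: true positives blue, false
#' positives green, false negatives black; colours are configurable because
#' published figures are not fully consistent about the miss colour.
#'
#' @param tp_color,fp_color,fn_color RGB triples in `[0, 1]`, pairwise
#'   distinct.
#' @return A `vn_overlay_style` list.
#' @export
overlay_style <- function(tp_color = c(0, 0, 1), fp_color = c(0, 1, 0),
                          fn_color = c(0, 0, 0)) {
  cols <- list(tp = tp_color, fp = fp_color, fn = fn_color)
  if (anyDuplicated(vapply(cols, paste, "", collapse = ",")))
    stop("overlay colors must be distinct")
  structure(cols, class = "vn_overlay_style")
}

#' Render a segmentation-error overlay
#'
#' Paints tp/fp/fn pixels in the style's colours over a dimmed grayscale
#' version of the input; true negatives keep the dimmed gray. The gray ramp
#' is kept strictly inside (0, 1) and off the pure overlay colours, so
#' recounting coloured pixels reproduces the confusion counts exactly.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param pred_mask,gt_mask binary matrices.
#' @param style an [overlay_style()].
#' @return `H x W x 3` RGB array.
#' @export
render_overlay <- function(image, pred_mask, gt_mask,
                           style = overlay_style()) {
  if (!identical(dim(image)[1:2], dim(gt_mask)))
    stop("image and mask dims differ")
  gray <- 0.1 + 0.5 * (0.299 * image[, , 1] + 0.587 * image[, , 2] +
                         0.114 * image[, , 3])
  out <- array(rep(gray, 3L), dim = dim(image))
  paint <- function(out, sel, col) {
    for (c in 1:3) {
      ch <- out[, , c]; ch[sel] <- col[c]; out[, , c] <- ch
    }
    out
  }
  out <- paint(out, pred_mask == 1 & gt_mask == 1, style$tp)
  out <- paint(out, pred_mask == 1 & gt_mask == 0, style$fp)
  out <- paint(out, pred_mask == 0 & gt_mask == 1, style$fn)
  out
}

#' Evaluate a model over a dataset
#'
#' Per-image confusion counts, Se/Sp/Acc and AUC, plus a pooled-pixel
#' aggregate row (counts summed and the ROC swept over all pixels of all
#' images together; `auc_mode = "mean"` averages per-image AUCs instead).
#'
#' @param model a trained `vn_model`.
#' @param pairs non-empty list of [sample_pair()]s at the model input size.
#' @param eval_region optional region mask applied per image.
#' @param auc_mode `"pooled"` (default) or `"mean"`.
#' @param out optional TSV path for the report.
#' @return Data frame with one row per image and a final `"pooled"` row.
#' @export
evaluate_dataset <- function(model, pairs, eval_region = NULL,
                             auc_mode = c("pooled", "mean"), out = NULL) {
  auc_mode <- match.arg(auc_mode)
  if (length(pairs) == 0L) stop("empty evaluation set")
  rows <- list()
  total <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  pool_p <- pool_g <- list()
  for (i in seq_along(pairs)) {
    prob <- vn_forward(model, pairs[[i]]$image)
    pred <- prob_to_mask(prob)
    cc <- confusion(pred, pairs[[i]]$mask, eval_region)
    met <- se_sp_acc(cc)
    keep <- if (is.null(eval_region)) TRUE else as.logical(eval_region)
    pool_p[[i]] <- prob[, , 2][keep]
    pool_g[[i]] <- pairs[[i]]$mask[keep]
    auc_i <- if (length(unique(pool_g[[i]])) > 1L)
      roc_auc(prob, pairs[[i]]$mask, eval_region) else NA_real_
    total <- total + cc
    rows[[i]] <- data.frame(id = as.character(i), t(cc), Se = met["Se"],
                            Sp = met["Sp"], Acc = met["Acc"], AUC = auc_i)
  }
  agg <- se_sp_acc(total)
  g <- unlist(pool_g); p <- unlist(pool_p)
  pooled_auc <- if (auc_mode == "pooled") {
    as.numeric(pROC::auc(pROC::roc(response = g, predictor = p,
                                   direction = "<", quiet = TRUE)))
  } else {
    mean(vapply(rows, function(r) r$AUC, numeric(1)), na.rm = TRUE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    id = "pooled", t(total), Se = agg["Se"], Sp = agg["Sp"],
    Acc = agg["Acc"], AUC = pooled_auc)
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(out))
    utils::write.table(report, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  report
}
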