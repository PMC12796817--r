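# Instance-level segmentation evaluation: IoU matching of predicted vs
# ground-truth label masks and the five headline metrics
# (precision, recall, F1, Jaccard, Dice), per image and aggregated.

#' Pairwise IoU table between ground-truth and predicted instances
#'
#' Computes, for every (ground-truth label, predicted label) pair whose pixel
#' sets overlap, the intersection, union, and intersection-over-union.
#' Pairs with zero intersection are omitted.
#'
#' @param gt,pred Integer instance masks of identical size (0 = background).
#' @return Data frame with columns `gt_label`, `pred_label`,
#'   `intersection_px`, `union_px`, `iou`.
#' @export
iou_matrix <- function(gt, pred) {
  check_mask(gt, "gt"); check_mask(pred, "pred")
  if (!identical(dim(gt), dim(pred))) {
    stop(sprintf("mask shapes differ: %dx%d vs %dx%d",
                 nrow(gt), ncol(gt), nrow(pred), ncol(pred)))
  }
  both <- gt > 0 & pred > 0
  empty <- data.frame(gt_label = integer(0), pred_label = integer(0),
                      intersection_px = integer(0), union_px = integer(0),
                      iou = numeric(0))
  if (!any(both)) return(empty)
  g <- gt[both]; p <- pred[both]
  key <- paste(g, p)
  agg <- rowsum(rep(1L, length(key)), key)
  parts <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
  gl <- as.numeric(parts[, 1]); pl <- as.numeric(parts[, 2])
  area_gt <- as.vector(table(gt[gt > 0]))
  names(area_gt) <- names(table(gt[gt > 0]))
  area_pred <- as.vector(table(pred[pred > 0]))
  names(area_pred) <- names(table(pred[pred > 0]))
  inter <- as.vector(agg)
  uni <- area_gt[as.character(gl)] + area_pred[as.character(pl)] - inter
  out <- data.frame(gt_label = gl, pred_label = pl,
                    intersection_px = inter, union_px = as.vector(uni),
                    iou = inter / as.vector(uni))
  out <- out[order(out$gt_label, out$pred_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match instances one-to-one at an IoU threshold
#'
#' Greedy one-to-one matching over the IoU pair table in descending IoU,
#' ties broken by ascending (gt_label, pred_label). For IoU strictly above
#' 0.5 each instance has at most one partner above threshold, so the greedy
#' result equals the optimal assignment; at the threshold boundary the tie
#' break makes the result deterministic.
#'
#' @param pairs IoU table from [iou_matrix()].
#' @param n_gt,n_pred Total ground-truth / predicted instance counts
#'   (needed because instances without any overlap never enter `pairs`).
#' @param threshold Minimum IoU for a match, in `(0, 1]`. Default 0.5.
#' @return An object of class `match_counts`: list with `tp`, `fp`, `fn`,
#'   and `matches` (data frame gt_label, pred_label, iou).
#' @export
match_instances <- function(pairs, n_gt, n_pred, threshold = 0.5) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  cand <- pairs[pairs$iou >= threshold, , drop = FALSE]
  cand <- cand[order(-cand$iou, cand$gt_label, cand$pred_label), , drop = FALSE]
  used_gt <- used_pred <- character(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    gl <- as.character(cand$gt_label[i]); pl <- as.character(cand$pred_label[i])
    if (!(gl %in% used_gt) && !(pl %in% used_pred)) {
      keep[i] <- TRUE
      used_gt <- c(used_gt, gl)
      used_pred <- c(used_pred, pl)
    }
  }
  matches <- cand[keep, c("gt_label", "pred_label", "iou"), drop = FALSE]
  rownames(matches) <- NULL
  tp <- nrow(matches)
  structure(list(tp = tp, fp = n_pred - tp, fn = n_gt - tp, matches = matches),
            class = "match_counts")
}

#' @export
print.match_counts <- function(x, ...) {
  cat(sprintf("Instance matches: TP = %d, FP = %d, FN = %d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Five segmentation metrics from match counts
#'
#' Computes precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2PR/(P+R), Jaccard = TP/(TP+FP+FN) and Dice = 2TP/(2TP+FP+FN)
#' from instance-level match counts. Degenerate cases: if both masks were
#' empty (TP=FP=FN=0) all five metrics are 1; any other 0/0 ratio is 0.
#' F1 and Dice are algebraically identical at the instance level.
#'
#' @param counts A `match_counts` object, or a list with `tp`, `fp`, `fn`.
#' @param image_id Optional identifier carried into the report.
#' @return An object of class `metric_report`: one-row data frame with
#'   columns image_id, tp, fp, fn, precision, recall, f1, jaccard, dice.
#' @export
compute_metrics <- function(counts, image_id = NA_character_) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (min(tp, fp, fn) < 0) stop("counts must be non-negative")
  if (tp + fp + fn == 0) {
    prec <- rec <- f1 <- jac <- dice <- 1
  } else {
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    jac <- tp / (tp + fp + fn)
    dice <- 2 * tp / (2 * tp + fp + fn)
  }
  out <- data.frame(image_id = image_id, tp = tp, fp = fp, fn = fn,
                    precision = prec, recall = rec, f1 = f1,
                    jaccard = jac, dice = dice, stringsAsFactors = FALSE)
  class(out) <- c("metric_report", "data.frame")
  out
}

#' Evaluate one predicted mask against ground truth
#'
#' Convenience wrapper: IoU table, one-to-one matching at the threshold,
#' metric computation.
#'
#' @param gt,pred Instance masks of identical size.
#' @param threshold IoU threshold (default 0.5).
#' @param image_id Optional identifier.
#' @return A `metric_report` (one-row data frame).
#' @export
evaluate_masks <- function(gt, pred, threshold = 0.5, image_id = NA_character_) {
  pairs <- iou_matrix(gt, pred)
  n_gt <- length(setdiff(unique(as.vector(gt)), 0))
  n_pred <- length(setdiff(unique(as.vector(pred)), 0))
  counts <- match_instances(pairs, n_gt, n_pred, threshold)
  compute_metrics(counts, image_id)
}

#' Evaluate a batch of mask pairs and aggregate
#'
#' Evaluates each (ground truth, prediction) pair, then aggregates with the
#' unweighted per-image mean, median and standard deviation of each metric.
#' A pair that fails to load is recorded as a failure and the batch
#' continues.
#'
#' @param gt_paths,pred_paths Equal-length vectors of mask file paths, or
#'   lists of in-memory masks.
#' @param threshold IoU threshold (default 0.5).
#' @param out_csv Optional path: per-image table written here, and the
#'   aggregate to `<stem>_summary.csv`.
#' @return List with `per_image` (data frame), `summary` (data frame of
#'   mean/median/sd rows), and `failures` (character vector of image ids
#'   that could not be evaluated).
#' @export
evaluate_batch <- function(gt_paths, pred_paths, threshold = 0.5, out_csv = NULL) {
  if (length(gt_paths) != length(pred_paths)) stop("path vectors differ in length")
  if (length(gt_paths) == 0L) stop("no mask pairs supplied")
  rows <- list(); failures <- character(0)
  for (i in seq_along(gt_paths)) {
    id <- if (is.character(gt_paths)) basename(gt_paths[[i]]) else sprintf("pair_%d", i)
    rep_i <- tryCatch({
      gt <- if (is.character(gt_paths)) read_mask(gt_paths[[i]]) else gt_paths[[i]]
      pred <- if (is.character(pred_paths)) read_mask(pred_paths[[i]]) else pred_paths[[i]]
      evaluate_masks(gt, pred, threshold, image_id = id)
    }, error = function(e) {
      warning(sprintf("pair '%s' failed: %s", id, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(rep_i)) failures <- c(failures, id) else rows[[length(rows) + 1L]] <- rep_i
  }
  per_image <- do.call(rbind, rows)
  metrics <- c("precision", "recall", "f1", "jaccard", "dice")
  summary_df <- NULL
  if (!is.null(per_image)) {
    m <- per_image[, metrics, drop = FALSE]
    summary_df <- data.frame(
      stat = c("mean", "median", "sd"),
      rbind(colMeans(m), apply(m, 2, stats::median), apply(m, 2, stats::sd))
    )
  }
  if (!is.null(out_csv) && !is.null(per_image)) {
    utils::write.csv(per_image, out_csv, row.names = FALSE)
    utils::write.csv(summary_df,
                     sub("\\.csv$", "_summary.csv", out_csv), row.names = FALSE)
  }
  list(per_image = per_image, summary = summary_df, failures = failures)
}
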