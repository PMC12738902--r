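#' Detection metrics from confusion counts
#'
#' Standard detection ratios: precision `TP / (TP + FP)`, recall
#' `TP / (TP + FN)` and their harmonic mean F1. A zero denominator makes
#' the metric undefined and `NA` is returned.
#'
#' @param tp,fp,fn Non-negative integer confusion counts.
#' @return Numeric scalar (or `NA` when undefined).
#' @name detection_metrics
#' @export
precision_score <- function(tp, fp, fn = 0L) {
  stopifnot(tp >= 0, fp >= 0)
  if (tp + fp == 0) return(NA_real_)
  tp / (tp + fp)
}

#' @rdname detection_metrics
#' @export
recall_score <- function(tp, fn, fp = 0L) {
  stopifnot(tp >= 0, fn >= 0)
  if (tp + fn == 0) return(NA_real_)
  tp / (tp + fn)
}

#' @rdname detection_metrics
#' @export
f1_score <- function(tp, fp, fn) {
  p <- precision_score(tp, fp)
  r <- recall_score(tp, fn)
  if (is.na(p) || is.na(r) || p + r == 0) return(NA_real_)
  2 * p * r / (p + r)
}

#' Average precision of scored detections
#'
#' Computes AP as the area under the precision-recall curve with
#' all-point interpolation: predictions are sorted by descending
#' confidence and matched greedily to ground-truth boxes of the same
#' image at IoU >= `iou_cut` (each ground truth consumed at most once);
#' the precision curve is replaced by its monotone non-increasing
#' envelope and integrated over recall.
#'
#' @param predictions Data frame with columns `image`, `score`, `x1`,
#'   `y1`, `x2`, `y2`.
#' @param truth Data frame with columns `image`, `x1`, `y1`, `x2`, `y2`.
#' @param iou_cut IoU threshold for a prediction to count as a true
#'   positive (default 0.5).
#' @return AP in \[0, 1\]; `NA` when there is no ground truth.
#' @export
average_precision <- function(predictions, truth, iou_cut = 0.5) {
  n_gt <- nrow(truth)
  if (n_gt == 0L) return(NA_real_)
  if (nrow(predictions) == 0L) return(0)
  ord <- order(-predictions$score)
  predictions <- predictions[ord, , drop = FALSE]
  used <- logical(n_gt)
  tp <- numeric(nrow(predictions))
  for (i in seq_len(nrow(predictions))) {
    cand <- which(truth$image == predictions$image[[i]] & !used)
    if (length(cand) == 0L) next
    ious <- iou_one_many(c(predictions$x1[[i]], predictions$y1[[i]],
                           predictions$x2[[i]], predictions$y2[[i]]),
                         as.matrix(truth[cand, c("x1", "y1", "x2", "y2")]))
    best <- which.max(ious)
    if (ious[[best]] >= iou_cut) {
      tp[[i]] <- 1
      used[[cand[[best]]]] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / seq_along(tp)
  # monotone precision envelope over recall, integrated at all points
  mrec <- c(0, recall)
  mpre <- c(1, precision)
  for (i in rev(seq_len(length(mpre) - 1L)))
    mpre[[i]] <- max(mpre[[i]], mpre[[i + 1L]])
  sum(diff(mrec) * mpre[-1L])
}

#' Mean average precision over classes
#'
#' Unweighted mean of per-class APs; classes with undefined AP (no
#' ground truth) are excluded.
#'
#' @param aps Numeric vector of per-class average precisions.
#' @return mAP in \[0, 1\].
#' @export
mean_ap <- function(aps) {
  aps <- aps[!is.na(aps)]
  if (length(aps) == 0L) return(NA_real_)
  mean(aps)
}

#' Counting error metrics
#'
#' `rmse()` is the root mean square of the count errors and `mae()` their
#' mean absolute value, each over the stated number of items (categories
#' within a video, or videos within a category). For any error vector
#' RMSE >= MAE.
#'
#' @param errors Numeric vector of count errors (predicted minus manual).
#' @return Non-negative numeric scalar.
#' @name count_errors
#' @export
rmse <- function(errors) {
  if (length(errors) == 0L) return(NA_real_)
  sqrt(mean(errors^2))
}

#' @rdname count_errors
#' @export
mae <- function(errors) {
  if (length(errors) == 0L) return(NA_real_)
  mean(abs(errors))
}

#' Counting accuracy of a manual/predicted count pair
#'
#' The per-item counting accuracy is the symmetric ratio
#' `100 * min(manual, predicted) / max(manual, predicted)` — 100 when the
#' counts agree exactly, and penalizing over- and under-counting alike.
#' When both counts are zero the accuracy is undefined (reported `NA`
#' and excluded from averages).
#'
#' @param manual Non-negative integer ground-truth count.
#' @param predicted Non-negative integer predicted count.
#' @return Percentage in (0, 100\], or `NA` when both counts are zero.
#' @export
#' @examples
#' mca(169, 163) # 96.4
mca <- function(manual, predicted) {
  if (manual < 0 || predicted < 0)
    stop("counts must be non-negative", call. = FALSE)
  if (manual == 0 && predicted == 0) return(NA_real_)
  100 * min(manual, predicted) / max(manual, predicted)
}

#' Evaluate a manual-vs-predicted count table
#'
#' Takes a table of manual and predicted counts per video and per
#' transplanting state and computes the counting-quality report:
#' \itemize{
#'   \item per video: the RMSE of the per-category count errors (n =
#'     number of categories) and the counting accuracy of the video's
#'     total count;
#'   \item per category: MAE and RMSE of the errors across videos (n =
#'     number of videos), and the mean of the defined per-video
#'     accuracies (a category absent from a video — both counts zero —
#'     is excluded from the mean);
#'   \item overall: the mean of the per-video total-count accuracies.
#' }
#'
#' @param table Data frame with columns `video`, `cname`, `manual`,
#'   `predicted` (one row per video x state).
#' @return List of class `eval_report` with elements `per_video_category`
#'   (the input plus a per-cell `mca` column), `per_video` (columns
#'   `video`, `rmse`, `total_manual`, `total_predicted`, `total_mca`),
#'   `per_category` (columns `cname`, `mca`, `mae`, `rmse`) and
#'   `overall_mca`.
#' @export
evaluate_count_table <- function(table) {
  required <- c("video", "cname", "manual", "predicted")
  if (!all(required %in% names(table)))
    stop("count table must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  if (nrow(table) == 0L) stop("empty count table", call. = FALSE)
  if (any(table$manual < 0 | table$predicted < 0))
    stop("counts must be non-negative", call. = FALSE)
  table$cname <- canonical_state(table$cname)

  cells <- table
  cells$mca <- mapply(mca, cells$manual, cells$predicted)

  videos <- unique(cells$video)
  per_video <- do.call(rbind, lapply(videos, function(v) {
    sub <- cells[cells$video == v, , drop = FALSE]
    err <- sub$predicted - sub$manual
    data.frame(video = v,
               rmse = rmse(err),
               total_manual = sum(sub$manual),
               total_predicted = sum(sub$predicted),
               total_mca = mca(sum(sub$manual), sum(sub$predicted)),
               stringsAsFactors = FALSE)
  }))

  cats <- intersect(transplant_states(), unique(cells$cname))
  per_category <- do.call(rbind, lapply(cats, function(s) {
    sub <- cells[cells$cname == s, , drop = FALSE]
    err <- sub$predicted - sub$manual
    data.frame(cname = s,
               mca = mean(sub$mca, na.rm = TRUE),
               mae = mae(err),
               rmse = rmse(err),
               stringsAsFactors = FALSE)
  }))

  structure(list(per_video_category = cells,
                 per_video = per_video,
                 per_category = per_category,
                 overall_mca = mean(per_video$total_mca, na.rm = TRUE)),
            class = "eval_report")
}

#' Read a count table CSV
#'
#' Count tables are exchanged as CSV with header
#' `video,cname,manual,predicted`. The table of manual vs machine counts
#' for four field videos that ships with the package can be loaded with
#' `read_count_table(system.file("extdata", "video_counts.csv",
#' package = "transplantQC"))`.
#'
#' @param path CSV path.
#' @return Data frame suitable for [evaluate_count_table()].
#' @export
read_count_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("video", "cname", "manual", "predicted")
  if (!all(required %in% names(df)))
    stop("count table CSV must have header ", paste(required, collapse = ","),
         call. = FALSE)
  df$cname <- canonical_state(df$cname)
  df$manual <- as.integer(df$manual)
  df$predicted <- as.integer(df$predicted)
  df
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Counting evaluation\n")
  cat(sprintf("  overall mean counting accuracy: %.1f%%\n", x$overall_mca))
  cat("  per video:\n")
  for (i in seq_len(nrow(x$per_video))) {
    r <- x$per_video[i, ]
    cat(sprintf("    video %-4s RMSE %.2f  total %d/%d  MCA %.1f%%\n",
                r$video, r$rmse, r$total_predicted, r$total_manual,
                r$total_mca))
  }
  cat("  per category:\n")
  for (i in seq_len(nrow(x$per_category))) {
    r <- x$per_category[i, ]
    cat(sprintf("    %-16s MCA %.1f%%  MAE %.2f  RMSE %.2f\n",
                r$cname, r$mca, r$mae, r$rmse))
  }
  invisible(x)
}
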