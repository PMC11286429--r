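#' Tracking and counting evaluation metrics
#'
#' CLEAR-MOT tracking metrics (MOTA, MOTP, identity switches) computed by
#' frame-wise matching of predicted to ground-truth boxes, plus the
#' counting metrics ACP, MAE and RMSE over per-video (ground truth, count)
#' pairs, and small detection-arithmetic utilities.
#'
#' @name metrics
NULL

# per-frame lookup tables from a segment list
frame_tables <- function(segments) {
  df <- segments_to_frame(segments)
  split(df, df$frame)
}

#' CLEAR-MOT evaluation
#'
#' Frame by frame, ground-truth objects are matched to predicted boxes:
#' matches from the previous frames persist while their overlap stays at or
#' above `iou_threshold`; remaining candidates are assigned by maximizing
#' total overlap (Hungarian method on `1 - IOU`, pairs below the overlap
#' threshold infeasible). Unmatched predictions count as false positives,
#' unmatched ground truth as false negatives, and a ground-truth object whose
#' newly assigned identity differs from its last known identity counts one
#' identity switch. Then
#' `MOTA = (1 - (FP + FN + IDSW) / GT) * 100` with `GT` the total number of
#' ground-truth boxes, and MOTP summarizes the quality of the matches: mean
#' overlap of matched pairs in percent (`motp_mode = "overlap"`, the default)
#' or mean normalized center distance in percent (`motp_mode = "distance"`).
#'
#' @param predicted,ground_truth lists of [track_segment()] objects in the
#'   same frame index space.
#' @param iou_threshold minimum overlap for a valid match.
#' @param motp_mode `"overlap"` or `"distance"`.
#' @return object of class `mot_report`: list with `FP`, `FN`, `IDSW`, `GT`,
#'   `MOTA` (percent), `MOTP` (percent), `matches` (total matched pairs) and
#'   `per_frame` (data.frame with frame, gt, matched).
#' @export
clear_mot_evaluate <- function(predicted, ground_truth, iou_threshold = 0.5,
                               motp_mode = c("overlap", "distance")) {
  motp_mode <- match.arg(motp_mode)
  gt_tab <- segments_to_frame(ground_truth)
  if (nrow(gt_tab) == 0L) {
    stop("ground truth is empty; MOTA is undefined")
  }
  pred_tab <- segments_to_frame(predicted)
  frames <- sort(unique(c(gt_tab$frame, pred_tab$frame)))
  gt_split <- split(gt_tab, gt_tab$frame)
  pred_split <- split(pred_tab, pred_tab$frame)

  fp <- 0L
  fn <- 0L
  idsw <- 0L
  gt_total <- 0L
  dist_sum <- 0
  match_total <- 0L
  last_match <- list() # gt id -> last associated prediction id
  per_frame <- vector("list", length(frames))

  for (fi in seq_along(frames)) {
    f <- frames[fi]
    g <- gt_split[[as.character(f)]]
    p <- pred_split[[as.character(f)]]
    n_g <- if (is.null(g)) 0L else nrow(g)
    n_p <- if (is.null(p)) 0L else nrow(p)
    gt_total <- gt_total + n_g
    if (n_g == 0L) {
      fp <- fp + n_p
      per_frame[[fi]] <- data.frame(frame = f, gt = 0L, matched = 0L)
      next
    }
    if (n_p == 0L) {
      fn <- fn + n_g
      per_frame[[fi]] <- data.frame(frame = f, gt = n_g, matched = 0L)
      next
    }
    g_boxes <- as.matrix(g[, c("left", "top", "width", "height")])
    p_boxes <- as.matrix(p[, c("left", "top", "width", "height")])
    overlaps <- iou_matrix(g_boxes, p_boxes)

    pairs <- matrix(integer(0), ncol = 2L)
    # persistence: keep still-valid pairings from previous frames
    for (gi in seq_len(n_g)) {
      prev <- last_match[[as.character(g$id[gi])]]
      if (is.null(prev)) next
      pi <- match(prev, p$id)
      if (!is.na(pi) && overlaps[gi, pi] >= iou_threshold &&
        !(pi %in% pairs[, 2L])) {
        pairs <- rbind(pairs, c(gi, pi))
      }
    }
    free_g <- setdiff(seq_len(n_g), pairs[, 1L])
    free_p <- setdiff(seq_len(n_p), pairs[, 2L])
    if (length(free_g) > 0L && length(free_p) > 0L) {
      cost <- 1 - overlaps[free_g, free_p, drop = FALSE]
      cost[overlaps[free_g, free_p, drop = FALSE] < iou_threshold] <-
        INFEASIBLE_COST
      res <- solve_assignment(cost, 1 - iou_threshold)
      if (nrow(res$matches) > 0L) {
        pairs <- rbind(pairs, cbind(
          free_g[res$matches[, 1L]],
          free_p[res$matches[, 2L]]
        ))
      }
    }

    n_m <- nrow(pairs)
    fp <- fp + (n_p - n_m)
    fn <- fn + (n_g - n_m)
    for (k in seq_len(n_m)) {
      gi <- pairs[k, 1L]
      pi <- pairs[k, 2L]
      gid <- as.character(g$id[gi])
      pid <- p$id[pi]
      prev <- last_match[[gid]]
      if (!is.null(prev) && prev != pid) idsw <- idsw + 1L
      last_match[[gid]] <- pid
      if (motp_mode == "overlap") {
        dist_sum <- dist_sum + overlaps[gi, pi]
      } else {
        dist_sum <- dist_sum +
          normalized_center_distance(g_boxes[gi, ], p_boxes[pi, ])
      }
    }
    match_total <- match_total + n_m
    per_frame[[fi]] <- data.frame(frame = f, gt = n_g, matched = n_m)
  }

  motp <- if (match_total > 0L) 100 * dist_sum / match_total else NA_real_
  structure(
    list(
      FP = fp, FN = fn, IDSW = idsw, GT = gt_total,
      MOTA = (1 - (fp + fn + idsw) / gt_total) * 100,
      MOTP = motp, matches = match_total, motp_mode = motp_mode,
      per_frame = do.call(rbind, per_frame)
    ),
    class = "mot_report"
  )
}

#' @export
print.mot_report <- function(x, ...) {
  cat(sprintf(
    "<mot_report> GT %d | FP %d FN %d IDSW %d | MOTA %.1f%% MOTP %.1f%% (%s)\n",
    x$GT, x$FP, x$FN, x$IDSW, x$MOTA, x$MOTP, x$motp_mode
  ))
  invisible(x)
}

# round half away from zero (printed-table convention)
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Counting metrics over videos
#'
#' For per-video pairs of true fruit count `GT` and predicted unique-ID count
#' `COUNT`:
#' \deqn{ACP = \frac{100}{N} \sum \left(1 - \frac{|GT - COUNT|}{GT}\right),
#'   \quad MAE = \frac{1}{N} \sum |GT - COUNT|, \quad
#'   RMSE = \sqrt{\frac{1}{N} \sum (GT - COUNT)^2}.}
#' Full precision is kept in the returned fields; the print method rounds ACP
#' to two decimals (half up).
#'
#' @param gt integer vector of true counts per video, all > 0.
#' @param count integer vector of predicted counts per video.
#' @return object of class `count_report`: `per_video` data.frame plus `N`,
#'   `ACP` (percent), `MAE`, `RMSE`.
#' @examples
#' counting_metrics(c(57, 95, 96), c(62, 96, 100))
#' @export
counting_metrics <- function(gt, count) {
  stopifnot(length(gt) == length(count), length(gt) >= 1L)
  if (any(gt <= 0)) {
    stop("all ground-truth counts must be positive")
  }
  err <- abs(gt - count)
  per_video <- data.frame(
    GT = gt, COUNT = count,
    ACP = 100 * (1 - err / gt), MAE = err
  )
  structure(
    list(
      per_video = per_video,
      N = length(gt),
      ACP = 100 * mean(1 - err / gt),
      MAE = mean(err),
      RMSE = sqrt(mean((gt - count)^2))
    ),
    class = "count_report"
  )
}

#' @export
print.count_report <- function(x, ...) {
  cat(sprintf("<count_report> over %d video(s)\n", x$N))
  pv <- x$per_video
  pv$ACP <- sprintf("%.2f%%", round_half_up(pv$ACP))
  print(pv, row.names = FALSE)
  cat(sprintf(
    "ACP %.2f%% | MAE %.2f | RMSE %.2f\n",
    round_half_up(x$ACP), round_half_up(x$MAE), round_half_up(x$RMSE)
  ))
  invisible(x)
}

#' Percent reduction between two counts
#'
#' `100 * (before - after) / before`; reporting helper for ablation tables
#' (e.g. identity-switch reductions).
#'
#' @param before,after counts; `before` must be positive.
#' @return percent reduction.
#' @export
percent_reduction <- function(before, after) {
  if (any(before <= 0)) {
    stop("'before' must be positive")
  }
  100 * (before - after) / before
}

#' Detection precision/recall arithmetic
#'
#' @param tp,fp,fn nonnegative counts.
#' @return list with `TP`, `FP`, `FN`, `precision` and `recall` in percent
#'   (`NA` where the denominator is zero).
#' @export
detection_pr <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  list(
    TP = tp, FP = fp, FN = fn,
    precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  )
}
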