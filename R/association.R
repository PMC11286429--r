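#' Track-detection association costs and cascade matching
#'
#' Candidate matches are scored with two complementary features: appearance
#' (cosine distance between a detection's re-identification embedding and a
#' track's gallery of past embeddings) and motion (squared Mahalanobis distance
#' between the detection and the Kalman-predicted box). In the cascade the
#' appearance cost is primary and the motion distance acts only as a
#' chi-square gate; unmatched leftovers fall back to an IOU cost.
#'
#' @name association
NULL

#' Cosine appearance cost matrix
#'
#' Entry `(t, d)` is the smallest cosine distance `1 - <g, f_d>` over track
#' `t`'s embedding gallery, so one good historical view is enough to keep the
#' cost low. All embeddings must be unit-norm (ingest renormalizes). Tracks
#' with an empty gallery get the infeasible sentinel.
#'
#' @param galleries list (one per track) of g x D matrices of unit embeddings.
#' @param features D-column matrix of detection embeddings, one row each.
#' @return length(galleries) x nrow(features) cost matrix with values in
#'   `[0, 2]` (or the infeasible sentinel).
#' @export
cosine_cost_matrix <- function(galleries, features) {
  features <- as.matrix(features)
  n_t <- length(galleries)
  n_d <- nrow(features)
  out <- matrix(INFEASIBLE_COST, n_t, n_d)
  if (n_d == 0L) {
    return(out)
  }
  for (t in seq_len(n_t)) {
    g <- galleries[[t]]
    if (is.null(g) || nrow(g) == 0L) next
    sims <- g %*% t(features) # g x D times D x n_d
    out[t, ] <- pmax(1 - apply(sims, 2L, max), 0)
  }
  out
}

#' IOU cost matrix
#'
#' Entry `(t, d) = 1 - IOU(track box, detection box)`; 0 for identical boxes,
#' 1 for disjoint ones.
#'
#' @param track_boxes n x 4 tlwh matrix of (predicted) track boxes.
#' @param detection_boxes m x 4 tlwh matrix.
#' @return n x m cost matrix.
#' @export
iou_cost_matrix <- function(track_boxes, detection_boxes) {
  1 - iou_matrix(track_boxes, detection_boxes)
}

#' Apply a Mahalanobis gate to a cost matrix
#'
#' Entries whose squared Mahalanobis motion distance exceeds the chi-square
#' threshold are made infeasible; all other entries pass through unchanged.
#' The default threshold elsewhere in the package is the 0.95 quantile of a
#' chi-square with 4 degrees of freedom (9.4877), matching the 4-dimensional
#' measurement.
#'
#' @param cost T x D cost matrix.
#' @param gating T x D matrix of squared Mahalanobis distances.
#' @param chi2_threshold gate value.
#' @return the gated cost matrix.
#' @export
gate_cost_matrix <- function(cost, gating, chi2_threshold) {
  stopifnot(all(dim(cost) == dim(gating)))
  cost[gating > chi2_threshold] <- INFEASIBLE_COST
  cost
}

#' Cascade matching over track age levels
#'
#' Matches detections to tracks in order of increasing `time_since_update`:
#' tracks seen in the previous frame get first pick, tracks missed for longer
#' compete only for what is left. At each age level the Mahalanobis-gated
#' cosine cost is solved by the Hungarian method.
#'
#' @param galleries list of per-track embedding galleries.
#' @param ages integer vector of per-track `time_since_update` values (>= 1).
#' @param gating_fn function(track_index, measurements) returning squared
#'   Mahalanobis distances of each measurement row to that track's predicted
#'   state.
#' @param features detection embedding matrix (rows).
#' @param measurements detection xyah matrix (rows).
#' @param max_age largest age level considered.
#' @param max_cosine cosine-distance acceptance threshold.
#' @param chi2_threshold Mahalanobis gate.
#' @return a `match_result` over all tracks/detections given.
#' @export
cascade_match <- function(galleries, ages, gating_fn, features, measurements,
                          max_age, max_cosine, chi2_threshold) {
  n_t <- length(galleries)
  n_d <- if (is.null(features)) 0L else nrow(features)
  matches <- matrix(integer(0), ncol = 2L)
  unmatched_d <- seq_len(n_d)
  matched_t <- integer(0)
  for (level in seq_len(max_age)) {
    if (length(unmatched_d) == 0L) break
    level_t <- which(ages == level)
    if (length(level_t) == 0L) next
    cost <- cosine_cost_matrix(galleries[level_t],
      features[unmatched_d, , drop = FALSE]
    )
    gating <- t(vapply(
      level_t,
      function(ti) gating_fn(ti, measurements[unmatched_d, , drop = FALSE]),
      numeric(length(unmatched_d))
    ))
    if (length(unmatched_d) == 1L) gating <- matrix(gating, ncol = 1L)
    cost <- gate_cost_matrix(cost, gating, chi2_threshold)
    res <- solve_assignment(cost, max_cosine)
    if (nrow(res$matches) > 0L) {
      new_pairs <- cbind(
        level_t[res$matches[, 1L]],
        unmatched_d[res$matches[, 2L]]
      )
      matches <- rbind(matches, new_pairs)
      matched_t <- c(matched_t, new_pairs[, 1L])
      unmatched_d <- setdiff(unmatched_d, new_pairs[, 2L])
    }
  }
  if (nrow(matches) > 0L) {
    matches <- matches[order(matches[, 1L]), , drop = FALSE]
  }
  match_result(matches, setdiff(seq_len(n_t), matched_t), unmatched_d)
}
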