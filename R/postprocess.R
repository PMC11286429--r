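#' Offline track optimization
#'
#' After a run, the finalized segments are cleaned up to remove duplicate
#' identities: unstable segments (short, or with erratic appearance) are
#' dropped from the count; pairs of stable segments that look like the same
#' fruit — by a majority vote over all pairwise frame-feature similarities,
#' and by consistency of position (linear extrapolation over the gap) and box
#' shape — are merged under the earlier identity. This removes both identity
#' switches inside a continuous run of frames and switches across a
#' disappearance/reappearance gap with one mechanism, the two regimes
#' differing only in the size of the temporal gap.
#'
#' @name postprocess
NULL

#' Classify the stability of a segment
#'
#' A segment is `unstable` if it is shorter than `l_min` frames or the
#' variance of its per-frame cosine similarity to its own mean feature exceeds
#' `v_max`; `partially_stable` if that variance is in `(v_partial, v_max]`;
#' otherwise `stable`. Only stable segments may be merged; partially stable
#' segments are kept for counting but not merged; unstable segments are
#' removed from the count.
#'
#' @param segment a [track_segment()].
#' @param l_min minimum length in frames.
#' @param v_partial,v_max similarity-variance thresholds.
#' @return list with `label` (one of `"stable"`, `"partially_stable"`,
#'   `"unstable"`), `length` and `similarity_variance`.
#' @export
segment_stability <- function(segment, l_min = 5L, v_partial = 0.01,
                              v_max = 0.05) {
  m <- length(segment$frames)
  sims <- as.vector(segment$features %*% segment$mean_feature)
  v <- if (m >= 2L) stats::var(sims) else 0
  label <- if (m < l_min || v > v_max) {
    "unstable"
  } else if (v > v_partial) {
    "partially_stable"
  } else {
    "stable"
  }
  list(label = label, length = m, similarity_variance = v)
}

# temporal gap in missing frames between two segments (0 = contiguous);
# negative values mean temporal overlap
segment_gap <- function(seg_a, seg_b) {
  seg_b$frames[1L] - seg_a$frames[length(seg_a$frames)] - 1L
}

#' Majority vote over the pairwise similarity matrix of two segments
#'
#' For a segment pair ordered in time (`seg_a` ends before `seg_b` starts; the
#' arguments are swapped if given the other way around), computes the M x N
#' matrix of cosine similarities between every frame feature of one and every
#' frame feature of the other. The pair is `eligible` for merging when the
#' number of entries at or above `s_min` strictly exceeds half of `M * N`.
#' Pairs that overlap in time or are separated by more than `g_max` missing
#' frames are ineligible outright.
#'
#' @param seg_a,seg_b [track_segment()] objects.
#' @param s_min similarity counted as a vote.
#' @param g_max largest bridgeable temporal gap in frames.
#' @return list with `eligible`, `votes`, `total` (= M * N), `gap` and
#'   `mean_similarity`.
#' @export
pair_similarity_vote <- function(seg_a, seg_b, s_min = 0.8, g_max = 45L) {
  if (seg_b$frames[1L] < seg_a$frames[1L]) {
    tmp <- seg_a
    seg_a <- seg_b
    seg_b <- tmp
  }
  gap <- segment_gap(seg_a, seg_b)
  m <- length(seg_a$frames)
  n <- length(seg_b$frames)
  if (gap < 0L || gap > g_max) {
    return(list(
      eligible = FALSE, votes = NA_integer_, total = m * n,
      gap = gap, mean_similarity = NA_real_
    ))
  }
  sims <- seg_a$features %*% t(seg_b$features)
  votes <- sum(sims >= s_min)
  list(
    eligible = votes > m * n / 2, votes = votes, total = m * n,
    gap = gap, mean_similarity = mean(sims)
  )
}

#' Position and shape consistency of a segment pair
#'
#' Assuming near-uniform linear motion, extrapolates the last center of the
#' earlier segment with its mean per-frame velocity across the gap and checks
#' that it lands within `p_max` normalized-diagonal units of the later
#' segment's first center ([normalized_center_distance()]), and that the two
#' boxes have compatible shape (width ratio and height ratio, larger over
#' smaller, both at most `r_max`).
#'
#' @param seg_a,seg_b [track_segment()] objects, `seg_a` earlier.
#' @param p_max position tolerance in mean-diagonal units.
#' @param r_max shape-ratio tolerance.
#' @return `TRUE` if both checks pass.
#' @export
position_shape_match <- function(seg_a, seg_b, p_max = 1.0, r_max = 1.5) {
  if (seg_b$frames[1L] < seg_a$frames[1L]) {
    tmp <- seg_a
    seg_a <- seg_b
    seg_b <- tmp
  }
  m <- length(seg_a$frames)
  last_a <- seg_a$boxes[m, ]
  first_b <- seg_b$boxes[1L, ]
  centers_a <- cbind(
    seg_a$boxes[, 1L] + seg_a$boxes[, 3L] / 2,
    seg_a$boxes[, 2L] + seg_a$boxes[, 4L] / 2
  )
  velocity <- if (m >= 2L) {
    (centers_a[m, ] - centers_a[1L, ]) /
      (seg_a$frames[m] - seg_a$frames[1L])
  } else {
    c(0, 0)
  }
  dt <- seg_b$frames[1L] - seg_a$frames[m]
  predicted_center <- centers_a[m, ] + velocity * dt
  predicted_box <- c(
    predicted_center[1L] - last_a[3L] / 2,
    predicted_center[2L] - last_a[4L] / 2,
    last_a[3L], last_a[4L]
  )
  pos_ok <- normalized_center_distance(predicted_box, first_b) <= p_max
  wr <- max(last_a[3L], first_b[3L]) / min(last_a[3L], first_b[3L])
  hr <- max(last_a[4L], first_b[4L]) / min(last_a[4L], first_b[4L])
  pos_ok && wr <= r_max && hr <= r_max
}

# merge two temporally ordered segments into one under seg_a's id, linearly
# interpolating the gap boxes in tlwh space; interpolated frames carry the
# combined mean feature and are flagged
merge_pair <- function(seg_a, seg_b) {
  m <- length(seg_a$frames)
  gap_frames <- setdiff(
    seq(seg_a$frames[m] + 1L, seg_b$frames[1L] - 1L),
    integer(0)
  )
  if (seg_a$frames[m] + 1L > seg_b$frames[1L] - 1L) gap_frames <- integer(0)
  frames <- c(seg_a$frames, gap_frames, seg_b$frames)
  features_obs <- rbind(seg_a$features, seg_b$features)
  mf <- colMeans(features_obs)
  nrm <- sqrt(sum(mf^2))
  if (nrm > 0) mf <- mf / nrm
  if (length(gap_frames) > 0L) {
    span <- seg_b$frames[1L] - seg_a$frames[m]
    frac <- (gap_frames - seg_a$frames[m]) / span
    last_a <- seg_a$boxes[m, ]
    first_b <- seg_b$boxes[1L, ]
    gap_boxes <- outer(1 - frac, last_a) + outer(frac, first_b)
    gap_features <- matrix(mf, length(gap_frames), length(mf), byrow = TRUE)
  } else {
    gap_boxes <- matrix(numeric(0), 0L, 4L)
    gap_features <- matrix(numeric(0), 0L, ncol(seg_a$features))
  }
  track_segment(
    id = seg_a$id,
    frames = frames,
    boxes = rbind(seg_a$boxes, gap_boxes, seg_b$boxes),
    features = rbind(seg_a$features, gap_features, seg_b$features),
    interpolated = c(
      seg_a$interpolated,
      rep(TRUE, length(gap_frames)),
      seg_b$interpolated
    )
  )
}

#' Merge duplicate track segments
#'
#' Removes unstable segments, then repeatedly merges the most closely spaced
#' eligible pair of stable segments (pairs must pass both the similarity vote
#' and the position/shape check) until no eligible pair remains. After each
#' merge the combined segment re-enters the pool, so chains of fragments
#' collapse to one identity. Ties in temporal gap are broken toward the higher
#' mean pairwise similarity, then the lower identity. Merged gap frames are
#' linearly interpolated and flagged.
#'
#' @param segments list of [track_segment()] objects (from
#'   [tracker_finalize()]).
#' @param config configuration list, see [default_config()].
#' @return list with:
#'   \item{segments}{merged segment list (stable and partially stable).}
#'   \item{id_map}{named integer vector mapping every input id to its output
#'     id (dropped segments map to `NA`).}
#'   \item{dropped}{ids of removed unstable segments (audit trail).}
#'   \item{log}{data.frame of every pair considered: ids, gap, votes, vote
#'     total, position/shape result and decision.}
#' @export
merge_segments <- function(segments, config = default_config()) {
  config <- validate_config(config)
  ids_in <- vapply(segments, function(s) s$id, integer(1))
  id_map <- stats::setNames(ids_in, ids_in)

  labels <- vapply(segments, function(s) {
    segment_stability(
      s,
      l_min = config$stability_min_length,
      v_partial = config$stability_v_partial,
      v_max = config$stability_v_max
    )$label
  }, character(1))
  dropped <- ids_in[labels == "unstable"]
  id_map[as.character(dropped)] <- NA_integer_
  keep_partial <- segments[labels == "partially_stable"]
  pool <- segments[labels == "stable"]

  log_rows <- list()
  repeat {
    if (length(pool) < 2L) break
    starts <- vapply(pool, function(s) s$frames[1L], integer(1))
    ord <- order(starts)
    candidates <- list()
    for (ai in seq_along(pool)) {
      for (bi in seq_along(pool)) {
        if (ai == bi) next
        a <- pool[[ai]]
        b <- pool[[bi]]
        if (b$frames[1L] <= a$frames[length(a$frames)]) next
        vote <- pair_similarity_vote(
          a, b,
          s_min = config$vote_s_min,
          g_max = config$merge_max_gap
        )
        if (vote$gap < 0L || vote$gap > config$merge_max_gap) next
        ps <- if (vote$eligible) {
          position_shape_match(
            a, b,
            p_max = config$merge_p_max,
            r_max = config$merge_r_max
          )
        } else {
          NA
        }
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          id_a = a$id, id_b = b$id, gap = vote$gap,
          votes = vote$votes, total = vote$total,
          position_shape = ps,
          merged = isTRUE(vote$eligible) && isTRUE(ps)
        )
        if (isTRUE(vote$eligible) && isTRUE(ps)) {
          candidates[[length(candidates) + 1L]] <- list(
            ai = ai, bi = bi, gap = vote$gap,
            sim = vote$mean_similarity, id = a$id
          )
        }
      }
    }
    if (length(candidates) == 0L) break
    gaps <- vapply(candidates, function(c) c$gap, numeric(1))
    sims <- vapply(candidates, function(c) c$sim, numeric(1))
    cand_ids <- vapply(candidates, function(c) c$id, integer(1))
    pick <- candidates[[order(gaps, -sims, cand_ids)[1L]]]
    merged <- merge_pair(pool[[pick$ai]], pool[[pick$bi]])
    absorbed <- pool[[pick$bi]]$id
    id_map[!is.na(id_map) & id_map == absorbed] <- merged$id
    pool[[pick$ai]] <- merged
    pool[[pick$bi]] <- NULL
  }

  out <- c(pool, keep_partial)
  out <- out[order(vapply(out, function(s) s$id, integer(1)))]
  log <- if (length(log_rows) > 0L) {
    do.call(rbind, log_rows)
  } else {
    data.frame(
      id_a = integer(0), id_b = integer(0), gap = integer(0),
      votes = integer(0), total = integer(0),
      position_shape = logical(0), merged = logical(0)
    )
  }
  list(segments = out, id_map = id_map, dropped = dropped, log = log)
}
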