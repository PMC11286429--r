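#' Online multi-object fruit tracker
#'
#' Tracking-by-detection with an improved matching flow. Each frame is
#' processed in stages:
#' \enumerate{
#'   \item Kalman-predict every live track.
#'   \item Cascade matching of confirmed tracks: Mahalanobis-gated cosine
#'     appearance cost, solved per age level with the Hungarian method.
#'   \item IOU fallback matching for just-missed confirmed tracks (age 1) and
#'     tentative tracks.
#'   \item Appearance re-matching: still-unmatched detections are compared by
#'     pure cosine distance (no motion gate) against confirmed tracks that
#'     lost their detection this frame or earlier. A sudden motion change
#'     ("motion feature mutation" — camera bump, occlusion exit at a shifted
#'     position) breaks the Mahalanobis gate even when the fruit looks the
#'     same; this stage re-attaches such detections to their old identity at a
#'     stricter cosine threshold and re-initializes the track's motion state
#'     from the detection, since the old velocity is no longer trusted.
#'   \item Matched tracks are Kalman-updated and their galleries appended;
#'     unmatched tentative tracks are deleted, unmatched confirmed tracks are
#'     deleted once `time_since_update > max_age`; unmatched detections start
#'     new tentative tracks; tentative tracks with `n_init` consecutive hits
#'     become confirmed.
#' }
#' Identities are assigned in increasing order of first appearance and the
#' whole tracker is deterministic: identical input streams give identical
#' output.
#'
#' @param config configuration list, see [default_config()].
#' @return a tracker object (an environment of class `fruit_tracker`).
#' @seealso [tracker_step()], [tracker_finalize()], [track_detections()]
#' @export
fruit_tracker <- function(config = default_config()) {
  config <- validate_config(config)
  trk <- new.env(parent = emptyenv())
  trk$config <- config
  trk$model <- kalman_model(w_pos = config$w_pos, w_vel = config$w_vel)
  trk$tracks <- list()
  trk$next_id <- 1L
  trk$last_frame <- 0L
  class(trk) <- "fruit_tracker"
  trk
}

#' @export
print.fruit_tracker <- function(x, ...) {
  states <- vapply(x$tracks, function(t) t$status, character(1))
  cat(sprintf(
    "<fruit_tracker> frame %d: %d confirmed, %d tentative, %d ids issued\n",
    x$last_frame, sum(states == "confirmed"), sum(states == "tentative"),
    x$next_id - 1L
  ))
  invisible(x)
}

new_track <- function(trk, frame, box, feature) {
  id <- trk$next_id
  trk$next_id <- id + 1L
  state <- kf_initiate(trk$model, tlwh_to_xyah(box))
  list(
    id = id, status = "tentative", ever_confirmed = FALSE,
    mean = state$mean, cov = state$cov,
    gallery = matrix(feature, nrow = 1L),
    hits = 1L, time_since_update = 0L,
    frames = frame, boxes = matrix(box, nrow = 1L),
    features = matrix(feature, nrow = 1L)
  )
}

mark_hit <- function(trk, track, frame, box, feature, reinitiate = FALSE) {
  z <- tlwh_to_xyah(box)
  if (reinitiate) {
    # motion state untrusted after a mutation: restart from the detection
    state <- kf_initiate(trk$model, z)
  } else {
    state <- kf_update(
      trk$model,
      structure(list(mean = track$mean, cov = track$cov),
        class = "kalman_state"
      ), z
    )$state
  }
  track$mean <- state$mean
  track$cov <- state$cov
  track$gallery <- rbind(track$gallery, feature)
  budget <- trk$config$gallery_size
  if (nrow(track$gallery) > budget) {
    track$gallery <- track$gallery[
      (nrow(track$gallery) - budget + 1L):nrow(track$gallery), ,
      drop = FALSE
    ]
  }
  track$hits <- track$hits + 1L
  track$time_since_update <- 0L
  track$frames <- c(track$frames, frame)
  track$boxes <- rbind(track$boxes, box)
  track$features <- rbind(track$features, feature)
  if (track$status == "tentative" && track$hits >= trk$config$n_init) {
    track$status <- "confirmed"
    track$ever_confirmed <- TRUE
  }
  track
}

# predicted tlwh box of a track
track_box <- function(track) {
  xyah_to_tlwh(track$mean[1:4])
}

normalize_rows <- function(m) {
  if (nrow(m) == 0L) {
    return(m)
  }
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Advance the tracker by one frame
#'
#' @param trk a [fruit_tracker()].
#' @param frame 1-based frame index; must be larger than the previous call's.
#' @param boxes n x 4 tlwh matrix of detection boxes (may have zero rows).
#' @param conf numeric vector of detection confidences in `[0, 1]`.
#' @param features n x D matrix of appearance embeddings (renormalized here).
#' @return data.frame of the confirmed tracks matched this frame:
#'   columns `frame`, `id`, `left`, `top`, `width`, `height`.
#' @export
tracker_step <- function(trk, frame, boxes, conf = NULL, features = NULL) {
  frame <- as.integer(frame)
  if (frame <= trk$last_frame) {
    stop(
      "frames must be presented in increasing order (got ", frame,
      " after ", trk$last_frame, ")"
    )
  }
  trk$last_frame <- frame
  config <- trk$config

  boxes <- if (is.null(boxes) || length(boxes) == 0L) {
    matrix(numeric(0), ncol = 4L)
  } else if (is.null(dim(boxes))) {
    matrix(boxes, nrow = 1L)
  } else {
    as.matrix(boxes)
  }
  n_raw <- nrow(boxes)
  if (is.null(conf)) conf <- rep(1, n_raw)
  if (is.null(features)) features <- matrix(numeric(0), n_raw, 0L)
  features <- as.matrix(features)

  # ingest filtering: junk geometry and low-confidence detections
  keep <- rep(TRUE, n_raw)
  if (n_raw > 0L) {
    bad_geom <- boxes[, 3L] <= 0 | boxes[, 4L] <= 0 |
      !apply(is.finite(boxes), 1L, all)
    if (any(bad_geom)) {
      warning(
        sum(bad_geom), " degenerate detection box(es) dropped in frame ",
        frame
      )
    }
    keep <- !bad_geom & conf >= config$min_confidence
  }
  boxes <- boxes[keep, , drop = FALSE]
  features <- features[keep, , drop = FALSE]
  features <- normalize_rows(features)
  n_det <- nrow(boxes)
  measurements <- if (n_det > 0L) tlwh_to_xyah(boxes) else
    matrix(numeric(0), ncol = 4L)
  if (n_det == 1L) measurements <- matrix(measurements, nrow = 1L)

  # (1) predict all live tracks; ageing happens here
  trk$tracks <- lapply(trk$tracks, function(track) {
    state <- kf_predict(
      trk$model,
      structure(list(mean = track$mean, cov = track$cov),
        class = "kalman_state"
      )
    )
    track$mean <- state$mean
    track$cov <- state$cov
    track$time_since_update <- track$time_since_update + 1L
    track
  })

  statuses <- vapply(trk$tracks, function(t) t$status, character(1))
  ages <- vapply(trk$tracks, function(t) t$time_since_update, integer(1))
  confirmed_idx <- which(statuses == "confirmed")

  matched <- matrix(integer(0), ncol = 2L) # (track list index, det index)
  rematched <- matrix(integer(0), ncol = 2L)
  unmatched_d <- seq_len(n_det)

  # (2) cascade matching on confirmed tracks
  if (length(confirmed_idx) > 0L && n_det > 0L) {
    res <- cascade_match(
      galleries = lapply(trk$tracks[confirmed_idx], function(t) t$gallery),
      ages = ages[confirmed_idx],
      gating_fn = function(local_i, z) {
        track <- trk$tracks[[confirmed_idx[local_i]]]
        kf_gating_distance(
          trk$model,
          structure(list(mean = track$mean, cov = track$cov),
            class = "kalman_state"
          ), z
        )
      },
      features = features, measurements = measurements,
      max_age = config$max_age, max_cosine = config$max_cosine,
      chi2_threshold = config$chi2_gate
    )
    if (nrow(res$matches) > 0L) {
      matched <- cbind(confirmed_idx[res$matches[, 1L]], res$matches[, 2L])
      unmatched_d <- setdiff(unmatched_d, matched[, 2L])
    }
  }

  # (3) IOU fallback: tentative tracks and confirmed tracks missed just now
  iou_idx <- which(
    (statuses == "tentative" | (statuses == "confirmed" & ages == 1L)) &
      !(seq_along(trk$tracks) %in% matched[, 1L])
  )
  if (length(iou_idx) > 0L && length(unmatched_d) > 0L) {
    pred_boxes <- t(vapply(trk$tracks[iou_idx], track_box, numeric(4)))
    cost <- iou_cost_matrix(pred_boxes, boxes[unmatched_d, , drop = FALSE])
    res <- solve_assignment(cost, config$iou_max_cost)
    if (nrow(res$matches) > 0L) {
      new_pairs <- cbind(
        iou_idx[res$matches[, 1L]],
        unmatched_d[res$matches[, 2L]]
      )
      matched <- rbind(matched, new_pairs)
      unmatched_d <- setdiff(unmatched_d, new_pairs[, 2L])
    }
  }

  # (4) appearance re-matching of motion-orphaned detections to lost tracks
  if (config$enable_rematch && length(unmatched_d) > 0L) {
    lost_idx <- which(
      statuses == "confirmed" & ages >= 1L & ages <= config$max_age &
        !(seq_along(trk$tracks) %in% matched[, 1L])
    )
    if (length(lost_idx) > 0L) {
      cost <- cosine_cost_matrix(
        lapply(trk$tracks[lost_idx], function(t) t$gallery),
        features[unmatched_d, , drop = FALSE]
      )
      res <- solve_assignment(cost, config$rematch_threshold)
      if (nrow(res$matches) > 0L) {
        rematched <- cbind(
          lost_idx[res$matches[, 1L]],
          unmatched_d[res$matches[, 2L]]
        )
        unmatched_d <- setdiff(unmatched_d, rematched[, 2L])
      }
    }
  }

  # (5) apply matches
  for (k in seq_len(nrow(matched))) {
    ti <- matched[k, 1L]
    di <- matched[k, 2L]
    trk$tracks[[ti]] <- mark_hit(
      trk, trk$tracks[[ti]], frame,
      boxes[di, ], features[di, ]
    )
  }
  for (k in seq_len(nrow(rematched))) {
    ti <- rematched[k, 1L]
    di <- rematched[k, 2L]
    trk$tracks[[ti]] <- mark_hit(
      trk, trk$tracks[[ti]], frame,
      boxes[di, ], features[di, ],
      reinitiate = TRUE
    )
  }

  # (6) lifecycle of unmatched tracks
  hit_idx <- c(matched[, 1L], rematched[, 1L])
  trk$tracks <- lapply(seq_along(trk$tracks), function(i) {
    track <- trk$tracks[[i]]
    if (i %in% hit_idx || track$status == "deleted") {
      return(track)
    }
    if (track$status == "tentative") {
      track$status <- "deleted"
    } else if (track$time_since_update > trk$config$max_age) {
      track$status <- "deleted"
    }
    track
  })

  # (7) births from unmatched detections
  for (di in unmatched_d) {
    trk$tracks <- c(
      trk$tracks,
      list(new_track(trk, frame, boxes[di, ], features[di, ]))
    )
  }

  # online output: confirmed tracks matched this frame
  out_idx <- vapply(trk$tracks, function(t) {
    t$status == "confirmed" && t$time_since_update == 0L
  }, logical(1))
  out <- trk$tracks[out_idx]
  if (length(out) == 0L) {
    return(data.frame(
      frame = integer(0), id = integer(0), left = numeric(0),
      top = numeric(0), width = numeric(0), height = numeric(0)
    ))
  }
  out_boxes <- t(vapply(
    out,
    function(t) t$boxes[nrow(t$boxes), ], numeric(4)
  ))
  data.frame(
    frame = frame,
    id = vapply(out, function(t) t$id, integer(1)),
    left = out_boxes[, 1L], top = out_boxes[, 2L],
    width = out_boxes[, 3L], height = out_boxes[, 4L]
  )
}

#' Export finalized track segments
#'
#' Every track that ever reached the confirmed state is exported as a
#' [track_segment()] covering all frames it was matched in (including its
#' tentative warm-up frames, so offline evaluation and merging see the full
#' evidence). Tracks that never left the tentative state are discarded.
#'
#' @param trk a [fruit_tracker()] whose input stream has been fully consumed.
#' @return list of `track_segment` objects, ordered by id.
#' @export
tracker_finalize <- function(trk) {
  keep <- Filter(function(t) isTRUE(t$ever_confirmed), trk$tracks)
  keep <- keep[order(vapply(keep, function(t) t$id, integer(1)))]
  lapply(keep, function(t) {
    track_segment(t$id, t$frames, t$boxes, t$features)
  })
}

#' Run the tracker over a detection table
#'
#' Convenience driver: feeds per-frame detections through [tracker_step()] in
#' frame order and finalizes. Frames are taken from the detection table; empty
#' frames between the minimum and maximum frame still age the tracks.
#'
#' @param detections data.frame with columns `frame`, `left`, `top`, `width`,
#'   `height`, `conf` (as returned by [read_detections()] or found in a
#'   [generate_scenario()] result).
#' @param features matrix of appearance embeddings aligned row-for-row with
#'   `detections`.
#' @param config configuration list, see [default_config()].
#' @return list with `segments` (finalized [track_segment()] list), `online`
#'   (data.frame of per-frame confirmed output) and `tracker`.
#' @export
track_detections <- function(detections, features, config = default_config()) {
  trk <- fruit_tracker(config)
  online <- list()
  if (nrow(detections) > 0L) {
    frames <- seq(min(detections$frame), max(detections$frame))
    split_idx <- split(seq_len(nrow(detections)), detections$frame)
    for (f in frames) {
      idx <- split_idx[[as.character(f)]]
      if (is.null(idx)) {
        online[[length(online) + 1L]] <- tracker_step(
          trk, f, NULL, NULL,
          matrix(numeric(0), 0L, ncol(features))
        )
      } else {
        online[[length(online) + 1L]] <- tracker_step(
          trk, f,
          as.matrix(detections[idx, c("left", "top", "width", "height")]),
          detections$conf[idx],
          features[idx, , drop = FALSE]
        )
      }
    }
  }
  list(
    segments = tracker_finalize(trk),
    online = do.call(rbind, online),
    tracker = trk
  )
}
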