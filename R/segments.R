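#' Track segments
#'
#' A track segment is the offline, finalized form of one tracked identity: its
#' id, the strictly increasing frames it covers, one tlwh box and one
#' unit-norm appearance embedding per frame, and a flag marking frames whose
#' box was filled in by interpolation rather than observed.
#'
#' @param id positive integer identity.
#' @param frames strictly increasing integer vector of 1-based frame indices.
#' @param boxes M x 4 tlwh matrix, one row per frame.
#' @param features M x D matrix of unit embeddings, one row per frame.
#' @param interpolated logical vector of length M (default all `FALSE`).
#' @return an object of class `track_segment` with an additional
#'   `mean_feature` field (unit-normalized mean of the feature rows).
#' @export
track_segment <- function(id, frames, boxes, features, interpolated = NULL) {
  frames <- as.integer(frames)
  boxes <- as_box_matrix(boxes)
  features <- as.matrix(features)
  m <- length(frames)
  stopifnot(m >= 1L, nrow(boxes) == m, nrow(features) == m)
  if (is.unsorted(frames, strictly = TRUE)) {
    stop("segment frames must be strictly increasing")
  }
  if (is.null(interpolated)) interpolated <- rep(FALSE, m)
  stopifnot(length(interpolated) == m)
  mf <- colMeans(features)
  nrm <- sqrt(sum(mf^2))
  if (nrm > 0) mf <- mf / nrm
  structure(
    list(
      id = as.integer(id), frames = frames, boxes = boxes,
      features = features, interpolated = as.logical(interpolated),
      mean_feature = mf
    ),
    class = "track_segment"
  )
}

#' @export
print.track_segment <- function(x, ...) {
  cat(sprintf(
    "<track_segment> id %d: frames %d-%d (%d observed, %d interpolated)\n",
    x$id, min(x$frames), max(x$frames),
    sum(!x$interpolated), sum(x$interpolated)
  ))
  invisible(x)
}

#' Count unique track identities
#'
#' Fruit counting by unique ID: the number of distinct segment identities in a
#' finalized (and, usually, post-processed) segment list.
#'
#' @param segments list of `track_segment` objects.
#' @return integer count.
#' @export
count_unique_ids <- function(segments) {
  length(unique(vapply(segments, function(s) s$id, integer(1))))
}

# Flatten segments to a data.frame (frame, id, left, top, width, height,
# interpolated), sorted by (frame, id).
segments_to_frame <- function(segments) {
  if (length(segments) == 0L) {
    return(data.frame(
      frame = integer(0), id = integer(0), left = numeric(0),
      top = numeric(0), width = numeric(0), height = numeric(0),
      interpolated = logical(0)
    ))
  }
  out <- do.call(rbind, lapply(segments, function(s) {
    data.frame(
      frame = s$frames, id = s$id,
      left = s$boxes[, 1L], top = s$boxes[, 2L],
      width = s$boxes[, 3L], height = s$boxes[, 4L],
      interpolated = s$interpolated
    )
  }))
  out <- out[order(out$frame, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
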