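#' Bounding-box geometry
#'
#' Boxes are plain numeric vectors `(left, top, width, height)` in continuous
#' pixel coordinates with the image origin at the top-left corner, x pointing
#' right and y pointing down ("tlwh" form). Collections of boxes are n x 4
#' matrices, one box per row. Internally the tracker works in measurement form
#' `(cx, cy, aspect, height)` ("xyah"), where `aspect = width / height`.
#' No rounding happens inside the pipeline; coordinates are only rounded to two
#' decimals when written to MOT text files.
#'
#' @name geometry
NULL

#' Validate tlwh boxes
#'
#' @param boxes numeric vector of length 4 or an n x 4 matrix in tlwh form.
#' @return an n x 4 matrix; an error is raised if any width or height is not
#'   strictly positive or any coordinate is non-finite.
#' @keywords internal
as_box_matrix <- function(boxes) {
  if (is.null(dim(boxes))) {
    stopifnot(length(boxes) == 4L)
    boxes <- matrix(as.numeric(boxes), nrow = 1L)
  }
  boxes <- as.matrix(boxes)
  storage.mode(boxes) <- "double"
  stopifnot(ncol(boxes) == 4L)
  if (nrow(boxes) > 0L) {
    if (!all(is.finite(boxes))) {
      stop("boxes must have finite coordinates")
    }
    if (any(boxes[, 3L] <= 0) || any(boxes[, 4L] <= 0)) {
      stop("boxes must have strictly positive width and height")
    }
  }
  colnames(boxes) <- c("left", "top", "width", "height")
  boxes
}

#' Convert tlwh boxes to xyah measurement vectors
#'
#' @param boxes length-4 vector or n x 4 matrix `(left, top, width, height)`.
#' @return measurement in the same shape: `(cx, cy, aspect, height)` with
#'   `cx = left + width/2`, `cy = top + height/2`, `aspect = width/height`.
#' @examples
#' tlwh_to_xyah(c(0, 0, 10, 20)) # 5 10 0.5 20
#' @export
tlwh_to_xyah <- function(boxes) {
  single <- is.null(dim(boxes))
  b <- as_box_matrix(boxes)
  out <- cbind(
    b[, 1L] + b[, 3L] / 2,
    b[, 2L] + b[, 4L] / 2,
    b[, 3L] / b[, 4L],
    b[, 4L]
  )
  colnames(out) <- c("cx", "cy", "aspect", "height")
  if (single) out[1L, ] else out
}

#' Convert xyah measurement vectors back to tlwh boxes
#'
#' Inverse of [tlwh_to_xyah()]; the round trip is the identity to floating
#' tolerance.
#'
#' @param xyah length-4 vector or n x 4 matrix `(cx, cy, aspect, height)`.
#' @return boxes in tlwh form, same shape as the input.
#' @export
xyah_to_tlwh <- function(xyah) {
  single <- is.null(dim(xyah))
  m <- if (single) matrix(as.numeric(xyah), nrow = 1L) else as.matrix(xyah)
  w <- m[, 3L] * m[, 4L]
  h <- m[, 4L]
  out <- cbind(m[, 1L] - w / 2, m[, 2L] - h / 2, w, h)
  colnames(out) <- c("left", "top", "width", "height")
  if (single) out[1L, ] else out
}

#' Intersection over union of two boxes
#'
#' @param box_a,box_b tlwh boxes (length-4 vectors).
#' @return overlap ratio in `[0, 1]`; 0 for disjoint boxes, 1 iff identical.
#' @examples
#' box_iou(c(0, 0, 10, 10), c(5, 0, 10, 10)) # 1/3
#' @export
box_iou <- function(box_a, box_b) {
  a <- as_box_matrix(box_a)[1L, ]
  b <- as_box_matrix(box_b)[1L, ]
  ix <- min(a[1L] + a[3L], b[1L] + b[3L]) - max(a[1L], b[1L])
  iy <- min(a[2L] + a[4L], b[2L] + b[4L]) - max(a[2L], b[2L])
  if (ix <= 0 || iy <= 0) {
    return(0)
  }
  inter <- ix * iy
  unname(inter / (a[3L] * a[4L] + b[3L] * b[4L] - inter))
}

#' Pairwise intersection over union
#'
#' @param boxes_a n x 4 tlwh matrix.
#' @param boxes_b m x 4 tlwh matrix.
#' @return n x m matrix of IOU values.
#' @export
iou_matrix <- function(boxes_a, boxes_b) {
  a <- as_box_matrix(boxes_a)
  b <- as_box_matrix(boxes_b)
  n <- nrow(a)
  m <- nrow(b)
  out <- matrix(0, n, m)
  if (n == 0L || m == 0L) {
    return(out)
  }
  ar <- a[, 1L] + a[, 3L]
  ab <- a[, 2L] + a[, 4L]
  br <- b[, 1L] + b[, 3L]
  bb <- b[, 2L] + b[, 4L]
  area_a <- a[, 3L] * a[, 4L]
  area_b <- b[, 3L] * b[, 4L]
  for (j in seq_len(m)) {
    ix <- pmin(ar, br[j]) - pmax(a[, 1L], b[j, 1L])
    iy <- pmin(ab, bb[j]) - pmax(a[, 2L], b[j, 2L])
    inter <- pmax(ix, 0) * pmax(iy, 0)
    out[, j] <- inter / (area_a + area_b[j] - inter)
  }
  out
}

#' Normalized distance between box centers
#'
#' Euclidean distance between the two box centers divided by the mean of the
#' two box diagonals, so the value is scale-free: 0 when centers coincide,
#' about 1 when the centers are one typical box diagonal apart. Used by the
#' position check of the track-segment merger.
#'
#' @param box_a,box_b tlwh boxes (length-4 vectors).
#' @return nonnegative scalar.
#' @export
normalized_center_distance <- function(box_a, box_b) {
  a <- as_box_matrix(box_a)[1L, ]
  b <- as_box_matrix(box_b)[1L, ]
  ca <- c(a[1L] + a[3L] / 2, a[2L] + a[4L] / 2)
  cb <- c(b[1L] + b[3L] / 2, b[2L] + b[4L] / 2)
  diag_a <- sqrt(a[3L]^2 + a[4L]^2)
  diag_b <- sqrt(b[3L]^2 + b[4L]^2)
  unname(sqrt(sum((ca - cb)^2)) / ((diag_a + diag_b) / 2))
}
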