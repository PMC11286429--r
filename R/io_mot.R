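#' MOT-format text file input/output
#'
#' Detections and tracks travel in the 10-column comma-separated MOT dialect
#' `frame,id,bb_left,bb_top,bb_width,bb_height,conf,x,y,z` with 1-based
#' frames, `id = -1` for raw detections and `-1` placeholders in the last
#' three columns (the first placeholder is set to 1 on interpolated track
#' rows). Appearance embeddings ride in a separate whitespace-delimited
#' numeric sidecar file with exactly one row per detection line, in the same
#' order, since no MOT dialect carries features. Coordinates are written with
#' two decimals; all writes are deterministic.
#'
#' @name io_mot
NULL

parse_mot_file <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(
      frame = integer(0), id = integer(0), left = numeric(0),
      top = numeric(0), width = numeric(0), height = numeric(0),
      conf = numeric(0), p1 = numeric(0), p2 = numeric(0), p3 = numeric(0)
    ))
  }
  fields <- strsplit(lines, ",", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 7L)
  if (length(bad) > 0L) {
    stop("malformed MOT line ", bad[1L], " in ", path, ": ", lines[bad[1L]])
  }
  num <- suppressWarnings(
    lapply(fields, function(f) as.numeric(f[1:min(10L, length(f))]))
  )
  bad <- which(vapply(num, function(x) any(is.na(x[1:7])), logical(1)))
  if (length(bad) > 0L) {
    stop("malformed MOT line ", bad[1L], " in ", path, ": ", lines[bad[1L]])
  }
  num <- lapply(num, function(x) c(x, rep(-1, 10L - length(x))))
  tab <- do.call(rbind, num)
  data.frame(
    frame = as.integer(tab[, 1L]), id = as.integer(tab[, 2L]),
    left = tab[, 3L], top = tab[, 4L],
    width = tab[, 5L], height = tab[, 6L], conf = tab[, 7L],
    p1 = tab[, 8L], p2 = tab[, 9L], p3 = tab[, 10L]
  )
}

#' Read raw detections (and their embedding sidecar)
#'
#' Rows are sorted by frame; degenerate boxes (non-positive width or height)
#' are dropped with a warning. If a sidecar is given it must hold exactly one
#' numeric row per detection line, in file order; rows are renormalized to
#' unit length. Without a sidecar, embeddings are derived deterministically
#' from a hash of the box geometry — unrelated boxes then get (almost surely)
#' distinct pseudo-embeddings, which effectively disables appearance matching
#' and leaves the motion/IOU stages in charge.
#'
#' @param det_path MOT detection file.
#' @param sidecar_path optional embedding matrix file.
#' @param embed_dim embedding dimension of the hash fallback.
#' @return list with `detections` (data.frame `frame, left, top, width,
#'   height, conf`) and `features` (aligned matrix).
#' @export
read_detections <- function(det_path, sidecar_path = NULL, embed_dim = 32L) {
  tab <- parse_mot_file(det_path)
  if (!is.null(sidecar_path)) {
    if (!file.exists(sidecar_path)) {
      stop("sidecar file not found: ", sidecar_path)
    }
    emb <- as.matrix(utils::read.table(sidecar_path))
    if (nrow(tab) == 0L && (is.null(dim(emb)) || nrow(emb) == 0L)) {
      emb <- matrix(numeric(0), 0L, embed_dim)
    }
    if (nrow(emb) != nrow(tab)) {
      stop(
        "sidecar row count (", nrow(emb),
        ") does not match detection line count (", nrow(tab), ")"
      )
    }
  } else {
    emb <- t(vapply(seq_len(nrow(tab)), function(i) {
      hash_embedding(
        c(tab$left[i], tab$top[i], tab$width[i], tab$height[i]),
        embed_dim
      )
    }, numeric(embed_dim)))
    if (nrow(tab) == 0L) emb <- matrix(numeric(0), 0L, embed_dim)
  }
  bad <- tab$width <= 0 | tab$height <= 0
  if (any(bad)) {
    warning(sum(bad), " degenerate detection box(es) dropped at ingest")
    tab <- tab[!bad, , drop = FALSE]
    emb <- emb[!bad, , drop = FALSE]
  }
  ord <- order(tab$frame)
  tab <- tab[ord, , drop = FALSE]
  emb <- normalize_rows(emb[ord, , drop = FALSE])
  dimnames(emb) <- NULL
  rownames(tab) <- NULL
  list(
    detections = tab[, c("frame", "left", "top", "width", "height", "conf")],
    features = emb
  )
}

# deterministic pseudo-embedding from box geometry (documented fallback for
# IOU-only operation when no sidecar exists)
hash_embedding <- function(box, embed_dim) {
  key <- sum(round(box, 2L) * c(1, 1e3, 1e6, 1e9)) %% 2147483647
  phase <- (key * seq_len(embed_dim) * 0.61803398875) %% 1
  v <- cos(2 * pi * phase)
  v / sqrt(sum(v^2))
}

#' Read ground-truth or predicted tracks from a MOT file
#'
#' @param path MOT file with valid (non-negative) ids.
#' @param features optional aligned embedding matrix; defaults to a constant
#'   unit vector per row (track files usually carry no features).
#' @param embed_dim embedding dimension of the default features.
#' @return list of [track_segment()] objects.
#' @export
read_tracks <- function(path, features = NULL, embed_dim = 8L) {
  tab <- parse_mot_file(path)
  if (nrow(tab) == 0L) {
    return(list())
  }
  if (is.null(features)) {
    features <- matrix(0, nrow(tab), embed_dim)
    features[, 1L] <- 1
  }
  out <- lapply(sort(unique(tab$id)), function(id) {
    rows <- which(tab$id == id)
    rows <- rows[order(tab$frame[rows])]
    track_segment(
      id = id, frames = tab$frame[rows],
      boxes = as.matrix(tab[rows, c("left", "top", "width", "height")]),
      features = features[rows, , drop = FALSE],
      interpolated = tab$p1[rows] == 1
    )
  })
  out
}

format_mot_rows <- function(frame, id, boxes, conf, p1) {
  sprintf(
    "%d,%d,%.2f,%.2f,%.2f,%.2f,%.2f,%d,-1,-1",
    frame, id, boxes[, 1L], boxes[, 2L], boxes[, 3L], boxes[, 4L], conf, p1
  )
}

#' Write track segments to a MOT file
#'
#' One line per (segment, frame) with `conf = 1`, sorted by (frame, id);
#' interpolated frames are marked by writing 1 in the first placeholder
#' column.
#'
#' @param segments list of [track_segment()] objects.
#' @param path output file.
#' @export
write_tracks <- function(segments, path) {
  df <- segments_to_frame(segments)
  lines <- format_mot_rows(
    df$frame, df$id,
    as.matrix(df[, c("left", "top", "width", "height")]),
    rep(1, nrow(df)), as.integer(df$interpolated)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write raw detections (and embedding sidecar)
#'
#' @param detections data.frame `frame, left, top, width, height, conf`.
#' @param path output MOT file (`id` written as -1).
#' @param features optional embedding matrix; written to `sidecar_path` one
#'   row per line.
#' @param sidecar_path embedding sidecar file.
#' @export
write_detections <- function(detections, path, features = NULL,
                             sidecar_path = NULL) {
  ord <- order(detections$frame)
  detections <- detections[ord, , drop = FALSE]
  lines <- format_mot_rows(
    detections$frame, rep(-1L, nrow(detections)),
    as.matrix(detections[, c("left", "top", "width", "height")]),
    detections$conf, rep(-1L, nrow(detections))
  )
  writeLines(lines, path)
  if (!is.null(features) && !is.null(sidecar_path)) {
    features <- features[ord, , drop = FALSE]
    utils::write.table(
      format(features, digits = 8L, scientific = FALSE, trim = TRUE),
      sidecar_path,
      row.names = FALSE, col.names = FALSE, quote = FALSE
    )
  }
  invisible(path)
}

#' Write a synthetic scenario as MOT files
#'
#' Creates `gt.txt` (ground-truth tracks), `det.txt` (detections) and
#' `emb.txt` (embedding sidecar) in `dir`, so synthetic and real data enter
#' the pipeline identically.
#'
#' @param scenario a [generate_scenario()] result.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tracks(scenario$gt_segments, file.path(dir, "gt.txt"))
  write_detections(
    scenario$detections[
      ,
      c("frame", "left", "top", "width", "height", "conf")
    ],
    file.path(dir, "det.txt"),
    features = scenario$features,
    sidecar_path = file.path(dir, "emb.txt")
  )
  invisible(dir)
}
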