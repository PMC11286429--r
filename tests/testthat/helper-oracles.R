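# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: exhaustive enumeration and plain dense linear algebra.

all_perms <- function(v) {
  if (length(v) <= 1L) {
    return(matrix(v, nrow = 1L))
  }
  out <- NULL
  for (i in seq_along(v)) {
    out <- rbind(out, cbind(v[i], all_perms(v[-i])))
  }
  out
}

# minimum total cost over every complete assignment of min(n, m) pairs
# (same sentinel semantics as the solver: sentinel entries may be picked but
# are dropped from the reported pairs)
brute_force_assignment <- function(cost, max_cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  k <- min(n, m)
  best_total <- Inf
  best_pairs <- NULL
  rows <- utils::combn(seq_len(n), k)
  cols <- utils::combn(seq_len(m), k)
  for (ri in seq_len(ncol(rows))) {
    for (ci in seq_len(ncol(cols))) {
      p <- all_perms(seq_len(k))
      for (pi in seq_len(nrow(p))) {
        idx <- cbind(rows[, ri], cols[, ci][p[pi, ]])
        total <- sum(cost[idx])
        if (total < best_total - 1e-12) {
          best_total <- total
          best_pairs <- idx
        }
      }
    }
  }
  keep <- cost[best_pairs] <= max_cost & cost[best_pairs] < 1e5
  list(total = best_total, pairs = best_pairs[keep, , drop = FALSE])
}

# plain-textbook Kalman recursion with explicit matrix inversion
naive_kalman_predict <- function(mean, cov, f, q) {
  list(mean = as.vector(f %*% mean), cov = f %*% cov %*% t(f) + q)
}

naive_kalman_update <- function(mean, cov, h, r, z) {
  s <- h %*% cov %*% t(h) + r
  k <- cov %*% t(h) %*% solve(s)
  y <- z - as.vector(h %*% mean)
  list(
    mean = as.vector(mean + k %*% y),
    cov = (diag(nrow(cov)) - k %*% h) %*% cov
  )
}

naive_mahalanobis <- function(mean, cov, h, r, z) {
  s <- h %*% cov %*% t(h) + r
  d <- z - as.vector(h %*% mean)
  as.numeric(t(d) %*% solve(s) %*% d)
}

# Independent CLEAR-MOT accumulator: per-frame brute-force assignment that
# first maximizes the number of above-threshold matches, then maximizes total
# overlap; previous-frame pairings persist while still valid. Suitable for
# scenes with few objects per frame.
reference_clear_mot <- function(predicted, ground_truth, iou_threshold = 0.5) {
  seg_frame <- function(segs) {
    do.call(rbind, lapply(segs, function(s) {
      data.frame(
        frame = s$frames, id = s$id, left = s$boxes[, 1], top = s$boxes[, 2],
        width = s$boxes[, 3], height = s$boxes[, 4]
      )
    }))
  }
  gt <- seg_frame(ground_truth)
  pr <- seg_frame(predicted)
  frames <- sort(unique(c(gt$frame, if (!is.null(pr)) pr$frame)))
  fp <- 0L; fn <- 0L; idsw <- 0L; gt_total <- 0L
  ov_sum <- 0; n_match <- 0L
  last <- list()
  for (f in frames) {
    g <- gt[gt$frame == f, , drop = FALSE]
    p <- if (is.null(pr)) gt[0, ] else pr[pr$frame == f, , drop = FALSE]
    gt_total <- gt_total + nrow(g)
    if (nrow(g) == 0L) {
      fp <- fp + nrow(p)
      next
    }
    if (nrow(p) == 0L) {
      fn <- fn + nrow(g)
      next
    }
    ov <- matrix(0, nrow(g), nrow(p))
    for (i in seq_len(nrow(g))) {
      for (j in seq_len(nrow(p))) {
        ov[i, j] <- fruitmot::box_iou(
          as.numeric(g[i, c("left", "top", "width", "height")]),
          as.numeric(p[j, c("left", "top", "width", "height")])
        )
      }
    }
    pairs <- matrix(integer(0), ncol = 2L)
    for (i in seq_len(nrow(g))) {
      prev <- last[[as.character(g$id[i])]]
      if (is.null(prev)) next
      j <- match(prev, p$id)
      if (!is.na(j) && ov[i, j] >= iou_threshold && !(j %in% pairs[, 2L])) {
        pairs <- rbind(pairs, c(i, j))
      }
    }
    fg <- setdiff(seq_len(nrow(g)), pairs[, 1L])
    fp_idx <- setdiff(seq_len(nrow(p)), pairs[, 2L])
    if (length(fg) > 0L && length(fp_idx) > 0L) {
      sub <- ov[fg, fp_idx, drop = FALSE]
      cost <- 1 - sub
      cost[sub < iou_threshold] <- 1e5
      bf <- brute_force_assignment(cost, 1 - iou_threshold)
      if (nrow(bf$pairs) > 0L) {
        pairs <- rbind(pairs, cbind(fg[bf$pairs[, 1L]], fp_idx[bf$pairs[, 2L]]))
      }
    }
    fp <- fp + nrow(p) - nrow(pairs)
    fn <- fn + nrow(g) - nrow(pairs)
    for (k in seq_len(nrow(pairs))) {
      gid <- as.character(g$id[pairs[k, 1L]])
      pid <- p$id[pairs[k, 2L]]
      if (!is.null(last[[gid]]) && last[[gid]] != pid) idsw <- idsw + 1L
      last[[gid]] <- pid
      ov_sum <- ov_sum + ov[pairs[k, 1L], pairs[k, 2L]]
      n_match <- n_match + 1L
    }
  }
  list(
    FP = fp, FN = fn, IDSW = idsw, GT = gt_total,
    MOTA = (1 - (fp + fn + idsw) / gt_total) * 100,
    MOTP = if (n_match > 0) 100 * ov_sum / n_match else NA_real_
  )
}
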