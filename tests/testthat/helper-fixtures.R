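# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk.

unit_vec <- function(d, axis = 1L) {
  v <- numeric(d)
  v[axis] <- 1
  v
}

random_unit <- function(d) {
  v <- rnorm(d)
  v / sqrt(sum(v^2))
}

random_box <- function(max_xy = 500, size = c(5, 80)) {
  c(runif(2, 0, max_xy), runif(2, size[1], size[2]))
}

# a straight-line segment with constant appearance
line_segment <- function(id, frames, x0, y0, vx, vy, w = 50, h = 50,
                         feature = unit_vec(8)) {
  k <- seq_along(frames) - 1
  boxes <- cbind(x0 + vx * k, y0 + vy * k, w, h)
  track_segment(
    id = id, frames = frames, boxes = boxes,
    features = matrix(feature, length(frames), length(feature), byrow = TRUE)
  )
}

# detection stream of one linearly moving object whose position jumps
# permanently at `jump_frame` (a motion mutation) while its appearance stays
# identical; returns args for track_detections
mutating_object_stream <- function(n_frames = 20, jump_frame = 11,
                                   jump = c(200, 0), d = 8) {
  t <- seq_len(n_frames)
  x <- 100 + 5 * (t - 1) + ifelse(t >= jump_frame, jump[1], 0)
  y <- 100 + ifelse(t >= jump_frame, jump[2], 0)
  detections <- data.frame(
    frame = t, left = x, top = y, width = 50, height = 50, conf = 1
  )
  features <- matrix(unit_vec(d), n_frames, d, byrow = TRUE)
  list(detections = detections, features = features)
}

noiseless_scenario <- function(n_fruits = 3, n_frames = 40, seed = 7) {
  generate_scenario(scenario_config(
    n_frames = n_frames, n_fruits = n_fruits,
    p_miss = 0, fp_rate = 0, jitter_pos = 0, jitter_size = 0,
    embed_noise = 0, seed = seed
  ))
}
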