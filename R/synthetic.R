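#' Synthetic orchard-scene simulator
#'
#' Fabricates ground-truth fruit tracks and noisy detections with appearance
#' embeddings, emulating a fruit-row video survey: a camera on a vehicle
#' moving at constant speed past fruit that is (near-)uniformly linearly
#' moving in image coordinates, with configurable density, detector dropout,
#' false positives, box jitter, embedding noise and scripted occlusion events.
#' Everything is a deterministic function of the seed.
#'
#' @name synthetic
NULL

# evaluate code under a given seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_unit_vectors <- function(n, d) {
  m <- matrix(stats::rnorm(n * d), n, d)
  normalize_rows(m)
}

#' Occlusion event descriptor
#'
#' During `[start, end]` the fruit's detections are dropped with probability
#' `drop` (1 = fully hidden). From `end + 1` onward the fruit's true position
#' is displaced by `jump` — a persistent motion mutation, as caused by a
#' camera bump or an occlusion exit at a shifted position. Embedding noise is
#' multiplied by `noise_mult` for frames in `[start, noise_until]`, modelling
#' appearance corruption around the occluder.
#'
#' @param fruit fruit index the event applies to.
#' @param start,end 1-based frame interval of the occlusion.
#' @param drop detection-drop probability during the event.
#' @param noise_mult embedding-noise multiplier.
#' @param noise_until last frame the multiplier applies to (default `end`;
#'   set past `end` to corrupt the reappearance frames).
#' @param jump length-2 pixel displacement `(dx, dy)` applied from `end + 1`.
#' @return a list of class `occlusion_event`.
#' @export
occlusion_event <- function(fruit, start, end, drop = 1, noise_mult = 1,
                            noise_until = end, jump = c(0, 0)) {
  stopifnot(start >= 1L, end >= start, noise_until >= end, length(jump) == 2L,
    drop >= 0, drop <= 1
  )
  structure(
    list(
      fruit = as.integer(fruit), start = as.integer(start),
      end = as.integer(end), drop = drop, noise_mult = noise_mult,
      noise_until = as.integer(noise_until), jump = as.numeric(jump)
    ),
    class = "occlusion_event"
  )
}

#' Scenario configuration
#'
#' Defaults mirror the assumed capture regime: 1920 x 1080 frames at 30 fps,
#' camera on a vehicle at constant speed so fruit drifts horizontally at
#' `camera_speed` pixels per frame with a small per-fruit drift on top.
#'
#' @param n_frames number of frames.
#' @param n_fruits number of fruits placed in the scene.
#' @param frame_width,frame_height frame size in pixels.
#' @param fps frame rate (informational).
#' @param camera_speed horizontal image motion in px/frame.
#' @param size_range range of fruit box heights in px.
#' @param aspect_range range of fruit width/height ratios.
#' @param min_visible every fruit is placed so that it is visible for at
#'   least this many frames.
#' @param occlusions list of [occlusion_event()] objects.
#' @param jitter_pos detection box position noise std in px.
#' @param jitter_size relative box size noise std.
#' @param p_miss baseline missed-detection probability.
#' @param fp_rate expected false positives per frame (Poisson).
#' @param embed_dim embedding dimension D.
#' @param embed_noise embedding angular-noise scale (std of the Gaussian
#'   perturbation added to the unit identity vector before renormalizing).
#' @param drift_sd per-fruit residual velocity std in px/frame.
#' @param fixed_fruits optional list of lists with fields `world_x`, `y`,
#'   `height`, `aspect` pinning the layout of the first fruits (used by the
#'   scripted occlusion suite); remaining fruits are sampled.
#' @param seed integer seed; fully determines the scenario.
#' @return a validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_frames, n_fruits,
                            frame_width = 1920, frame_height = 1080,
                            fps = 30, camera_speed = 6,
                            size_range = c(50, 110),
                            aspect_range = c(0.75, 1.05),
                            min_visible = 20L,
                            occlusions = list(),
                            jitter_pos = 1, jitter_size = 0.01,
                            p_miss = 0.05, fp_rate = 0.1,
                            embed_dim = 32L, embed_noise = 0.05,
                            drift_sd = 0.1,
                            fixed_fruits = list(),
                            seed = 1L) {
  config <- list(
    n_frames = as.integer(n_frames), n_fruits = as.integer(n_fruits),
    frame_width = frame_width, frame_height = frame_height, fps = fps,
    camera_speed = camera_speed, size_range = size_range,
    aspect_range = aspect_range, min_visible = as.integer(min_visible),
    occlusions = occlusions, jitter_pos = jitter_pos,
    jitter_size = jitter_size, p_miss = p_miss, fp_rate = fp_rate,
    embed_dim = as.integer(embed_dim), embed_noise = embed_noise,
    drift_sd = drift_sd, fixed_fruits = fixed_fruits, seed = as.integer(seed)
  )
  stopifnot(
    config$n_frames >= 1L, config$n_fruits >= 0L,
    config$frame_width > 0, config$frame_height > 0,
    config$camera_speed >= 0,
    length(config$size_range) == 2L, all(config$size_range > 0),
    config$p_miss >= 0, config$p_miss <= 1,
    config$fp_rate >= 0, config$embed_dim >= 2L,
    config$embed_noise >= 0, config$jitter_pos >= 0, config$jitter_size >= 0
  )
  for (ev in config$occlusions) {
    stopifnot(inherits(ev, "occlusion_event"), ev$fruit <= config$n_fruits)
  }
  class(config) <- "scenario_config"
  config
}

#' Generate a synthetic scenario
#'
#' Each fruit gets a fixed unit identity embedding and a linear image-space
#' trajectory (horizontal speed `-camera_speed` plus small per-fruit drift),
#' possibly displaced by scripted occlusion jumps. Per frame, each visible
#' fruit is detected with probability `(1 - p_miss) * (1 - drop)`; a detection
#' is the true box plus Gaussian jitter, and its embedding is the identity
#' vector perturbed by Gaussian noise (scaled up around occlusion events) and
#' renormalized. False positives are drawn uniformly over the frame with
#' random unit embeddings.
#'
#' @param config a [scenario_config()].
#' @return object of class `scenario`: list with
#'   \item{gt_segments}{noise-free [track_segment()] list, one per fruit that
#'     appears (clean identity embeddings as features).}
#'   \item{detections}{data.frame `frame, left, top, width, height, conf,
#'     gt_id` (`NA` for false positives), sorted by frame.}
#'   \item{features}{embedding matrix aligned row-for-row with `detections`.}
#'   \item{true_count}{number of fruits that actually appear.}
#'   \item{config}{the input configuration.}
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed, {
    w_img <- config$frame_width
    h_img <- config$frame_height
    n <- config$n_fruits
    speed <- config$camera_speed

    heights <- stats::runif(n, config$size_range[1L], config$size_range[2L])
    aspects <- stats::runif(n, config$aspect_range[1L], config$aspect_range[2L])
    widths <- aspects * heights
    ys <- stats::runif(n, 0.05 * h_img, h_img - heights - 0.05 * h_img)
    v <- config$min_visible
    if (speed > 0) {
      lo <- (v - 1) * speed
      hi <- (w_img - widths) + speed * (config$n_frames - v)
      world_x <- stats::runif(n, lo, pmax(lo, hi))
    } else {
      world_x <- stats::runif(n, 0, w_img - widths)
    }
    drift <- matrix(stats::rnorm(2L * n, 0, config$drift_sd), n, 2L)
    for (i in seq_along(config$fixed_fruits)) {
      ff <- config$fixed_fruits[[i]]
      world_x[i] <- ff$world_x
      ys[i] <- ff$y
      heights[i] <- ff$height
      aspects[i] <- ff$aspect
      widths[i] <- ff$aspect * ff$height
      drift[i, ] <- 0
    }
    identities <- random_unit_vectors(n, config$embed_dim)

    # per-fruit occlusion bookkeeping
    ev_by_fruit <- vector("list", n)
    for (ev in config$occlusions) {
      ev_by_fruit[[ev$fruit]] <- c(ev_by_fruit[[ev$fruit]], list(ev))
    }

    true_box <- function(i, t) {
      jump <- c(0, 0)
      for (ev in ev_by_fruit[[i]]) {
        if (t > ev$end) jump <- jump + ev$jump
      }
      c(
        world_x[i] - speed * (t - 1) + drift[i, 1L] * (t - 1) + jump[1L],
        ys[i] + drift[i, 2L] * (t - 1) + jump[2L],
        widths[i], heights[i]
      )
    }
    visible <- function(box) {
      box[1L] >= 0 && box[1L] + box[3L] <= w_img &&
        box[2L] >= 0 && box[2L] + box[4L] <= h_img
    }

    # ground truth
    gt_segments <- list()
    n_appear <- 0L
    vis <- matrix(FALSE, n, config$n_frames)
    for (i in seq_len(n)) {
      frames <- integer(0)
      boxes <- NULL
      for (t in seq_len(config$n_frames)) {
        b <- true_box(i, t)
        if (visible(b)) {
          vis[i, t] <- TRUE
          frames <- c(frames, t)
          boxes <- rbind(boxes, b)
        }
      }
      if (length(frames) > 0L) {
        n_appear <- n_appear + 1L
        gt_segments[[length(gt_segments) + 1L]] <- track_segment(
          id = i, frames = frames, boxes = boxes,
          features = matrix(identities[i, ], length(frames),
            config$embed_dim,
            byrow = TRUE
          )
        )
      }
    }

    # detections
    rows <- list()
    feats <- list()
    for (t in seq_len(config$n_frames)) {
      for (i in seq_len(n)) {
        if (!vis[i, t]) next
        drop <- 0
        mult <- 1
        for (ev in ev_by_fruit[[i]]) {
          if (t >= ev$start && t <= ev$end) drop <- max(drop, ev$drop)
          if (t >= ev$start && t <= ev$noise_until) {
            mult <- max(mult, ev$noise_mult)
          }
        }
        if (stats::runif(1) >= (1 - config$p_miss) * (1 - drop)) next
        b <- true_box(i, t)
        b[1L] <- b[1L] + stats::rnorm(1, 0, config$jitter_pos)
        b[2L] <- b[2L] + stats::rnorm(1, 0, config$jitter_pos)
        b[3L] <- b[3L] * max(0.1, 1 + stats::rnorm(1, 0, config$jitter_size))
        b[4L] <- b[4L] * max(0.1, 1 + stats::rnorm(1, 0, config$jitter_size))
        f <- identities[i, ] +
          config$embed_noise * mult * stats::rnorm(config$embed_dim)
        f <- f / sqrt(sum(f^2))
        rows[[length(rows) + 1L]] <- c(t, b, stats::runif(1, 0.6, 1), i)
        feats[[length(feats) + 1L]] <- f
      }
      n_fp <- stats::rpois(1, config$fp_rate)
      for (k in seq_len(n_fp)) {
        fh <- stats::runif(1, config$size_range[1L], config$size_range[2L])
        fw <- fh * stats::runif(1, config$aspect_range[1L],
          config$aspect_range[2L]
        )
        b <- c(
          stats::runif(1, 0, w_img - fw), stats::runif(1, 0, h_img - fh),
          fw, fh
        )
        rows[[length(rows) + 1L]] <- c(
          t, b, stats::runif(1, 0.3, 0.7),
          NA_real_
        )
        feats[[length(feats) + 1L]] <-
          as.vector(random_unit_vectors(1L, config$embed_dim))
      }
    }
    if (length(rows) > 0L) {
      tab <- do.call(rbind, rows)
      detections <- data.frame(
        frame = as.integer(tab[, 1L]),
        left = tab[, 2L], top = tab[, 3L],
        width = tab[, 4L], height = tab[, 5L],
        conf = tab[, 6L], gt_id = as.integer(tab[, 7L])
      )
      features <- do.call(rbind, feats)
    } else {
      detections <- data.frame(
        frame = integer(0), left = numeric(0), top = numeric(0),
        width = numeric(0), height = numeric(0), conf = numeric(0),
        gt_id = integer(0)
      )
      features <- matrix(numeric(0), 0L, config$embed_dim)
    }

    structure(
      list(
        gt_segments = gt_segments, detections = detections,
        features = features, true_count = n_appear, config = config
      ),
      class = "scenario"
    )
  })
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "<scenario> %d frames, %d fruit(s) appearing, %d detection rows\n",
    x$config$n_frames, x$true_count, nrow(x$detections)
  ))
  invisible(x)
}

#' Scenario presets
#'
#' Named scene regimes keyed by fruit density and light level. Density maps
#' to the number of fruits (57, 95 or 96 across the three survey regimes);
#' lower light maps to higher detector dropout and embedding noise. The
#' `occlusion_suite` preset returns a list of 20 seeded scenario
#' configurations scripted to provoke both identity-switch modes: motion
#' mutations that are recoverable from appearance alone (large position jumps
#' with a clean reappearance) and fragmentations whose reappearance frames
#' are appearance-corrupted, recoverable only by offline segment merging.
#'
#' @param name one of `"low_density_medium_light"`,
#'   `"high_density_medium_light"`, `"high_density_low_light"`,
#'   `"occlusion_suite"`.
#' @param seed base seed; suite members derive sub-seeds by fixed offsets.
#' @return a [scenario_config()], or a list of 20 of them for
#'   `"occlusion_suite"`.
#' @export
preset <- function(name, seed = 1L) {
  seed <- as.integer(seed)
  switch(name,
    low_density_medium_light = scenario_config(
      n_frames = 360L, n_fruits = 57L, camera_speed = 6,
      p_miss = 0.03, embed_noise = 0.06, fp_rate = 0.2, seed = seed
    ),
    high_density_medium_light = scenario_config(
      n_frames = 510L, n_fruits = 95L, camera_speed = 6,
      p_miss = 0.05, embed_noise = 0.06, fp_rate = 0.3, seed = seed
    ),
    high_density_low_light = scenario_config(
      n_frames = 600L, n_fruits = 96L, camera_speed = 6,
      p_miss = 0.08, embed_noise = 0.12, fp_rate = 0.4, seed = seed
    ),
    occlusion_suite = lapply(seq_len(20L), function(k) {
      occlusion_suite_member(k, seed)
    }),
    stop("unknown preset: ", name)
  )
}

# One member of the scripted occlusion suite. Four fruits carry scripted
# events; jumps are quoted relative to a typical box diagonal of ~110 px
# (heights 70-90, aspect 0.8-1.0): ~250 px (>2 diagonals) defeats the
# position check of segment merging, ~65 px (~0.6 diagonals) stays within it.
occlusion_suite_member <- function(k, seed) {
  shift <- (k - 1L) %% 5L
  speed <- 5
  # place the scripted fruits mid-screen at their event midpoints
  mid_x <- function(t_mid) 900 + speed * (t_mid - 1)
  fixed <- list(
    list(world_x = mid_x(53 + shift), y = 150, height = 82, aspect = 0.9),
    list(world_x = mid_x(43 + shift), y = 380, height = 78, aspect = 0.85),
    list(world_x = mid_x(65 + shift), y = 610, height = 86, aspect = 0.95),
    list(world_x = mid_x(78 + shift), y = 840, height = 74, aspect = 0.88)
  )
  events <- list(
    # clean reappearance, jump beyond the merge position gate:
    # only appearance re-matching can keep the identity
    occlusion_event(1L, 50L + shift, 56L + shift, jump = c(-250, 20)),
    # corrupted reappearance (noise x6 for two frames past the gap), small
    # jump: re-matching fails, segment merging recovers it
    occlusion_event(2L, 40L + shift, 45L + shift,
      noise_mult = 6, noise_until = 47L + shift, jump = c(-65, 25)
    ),
    # clean reappearance, moderate jump: outside the motion gate but inside
    # the merge position gate, so either improvement recovers it
    occlusion_event(3L, 62L + shift, 68L + shift, jump = c(-85, -30)),
    # second appearance-only case
    occlusion_event(4L, 75L + shift, 80L + shift, jump = c(-240, -25))
  )
  scenario_config(
    n_frames = 140L, n_fruits = 12L, camera_speed = speed,
    size_range = c(70, 90), aspect_range = c(0.8, 1.0),
    min_visible = 30L, occlusions = events,
    jitter_pos = 1, jitter_size = 0.01,
    p_miss = 0.01, fp_rate = 0.05,
    embed_dim = 32L, embed_noise = 0.05,
    fixed_fruits = fixed, seed = seed + 1000L * k
  )
}
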