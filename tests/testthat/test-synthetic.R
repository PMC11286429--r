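test_that("zero-noise scenarios detect every visible fruit exactly once", {
  sc <- noiseless_scenario(n_fruits = 5, n_frames = 40)
  expect_equal(sc$true_count, 5L)
  expect_length(sc$gt_segments, 5L)
  # detections per frame equal visible fruits per frame
  gt_per_frame <- table(fruitmot:::segments_to_frame(sc$gt_segments)$frame)
  det_per_frame <- table(sc$detections$frame)
  expect_equal(det_per_frame, gt_per_frame)
  expect_equal(sort(unique(sc$detections$gt_id)), 1:5)
  # unit embeddings
  expect_equal(rowSums(sc$features^2), rep(1, nrow(sc$features)),
    tolerance = 1e-9
  )
})

test_that("the same seed reproduces the scenario bit for bit", {
  cfg <- scenario_config(n_frames = 30, n_fruits = 6, seed = 5)
  a <- generate_scenario(cfg)
  b <- generate_scenario(cfg)
  expect_identical(a$detections, b$detections)
  expect_identical(a$features, b$features)
  other <- generate_scenario(scenario_config(
    n_frames = 30, n_fruits = 6,
    seed = 6
  ))
  expect_false(identical(a$detections, other$detections))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_scenario(scenario_config(
    n_frames = 10, n_fruits = 2,
    seed = 77
  )))
  expect_identical(runif(1), before)
})

test_that("detection counts follow the dropout rate binomially", {
  sc <- generate_scenario(scenario_config(
    n_frames = 1000, n_fruits = 1, camera_speed = 0, p_miss = 0.1,
    fp_rate = 0, jitter_pos = 0, jitter_size = 0, embed_noise = 0, seed = 3
  ))
  n <- nrow(sc$detections)
  sigma <- sqrt(1000 * 0.1 * 0.9)
  expect_gt(n, 900 - 3 * sigma)
  expect_lt(n, 900 + 3 * sigma)
})

test_that("detections overlap their ground-truth boxes under default jitter", {
  sc <- generate_scenario(scenario_config(
    n_frames = 60, n_fruits = 8,
    seed = 9
  ))
  gt_tab <- fruitmot:::segments_to_frame(sc$gt_segments)
  tp <- which(!is.na(sc$detections$gt_id))
  ious <- vapply(tp, function(i) {
    d <- sc$detections[i, ]
    g <- gt_tab[gt_tab$frame == d$frame & gt_tab$id == d$gt_id, ]
    box_iou(
      c(d$left, d$top, d$width, d$height),
      c(g$left, g$top, g$width, g$height)
    )
  }, numeric(1))
  expect_true(all(ious >= 0.5))
})

test_that("presets encode the density/light regimes and validate", {
  expect_equal(preset("low_density_medium_light")$n_fruits, 57L)
  expect_equal(preset("high_density_medium_light")$n_fruits, 95L)
  low_light <- preset("high_density_low_light")
  expect_equal(low_light$n_fruits, 96L)
  medium_light <- preset("high_density_medium_light")
  expect_gt(low_light$embed_noise, medium_light$embed_noise)
  expect_gt(low_light$p_miss, medium_light$p_miss)
  suite <- preset("occlusion_suite", seed = 2)
  expect_length(suite, 20L)
  for (cfg in suite) expect_s3_class(cfg, "scenario_config")
  expect_error(preset("nope"), "unknown preset")
})

test_that("count error grows with dropout and embedding noise", {
  run_err <- function(p_miss, embed_noise, seed) {
    sc <- generate_scenario(scenario_config(
      n_frames = 80, n_fruits = 10, camera_speed = 5,
      p_miss = p_miss, embed_noise = embed_noise, fp_rate = 0.05,
      seed = seed
    ))
    res <- run_pipeline(sc$detections, sc$features)
    abs(sc$true_count - res$count)
  }
  seeds <- 101:104
  miss_levels <- c(0.02, 0.25, 0.45)
  err_by_miss <- vapply(
    miss_levels,
    function(p) sum(vapply(seeds, function(s) run_err(p, 0.05, s), numeric(1))),
    numeric(1)
  )
  expect_gt(cor(miss_levels, err_by_miss, method = "spearman"), 0)

  noise_levels <- c(0.05, 0.3, 0.6)
  err_by_noise <- vapply(
    noise_levels,
    function(e) {
      sum(vapply(seeds, function(s) run_err(0.15, e, s), numeric(1)))
    },
    numeric(1)
  )
  expect_gt(cor(noise_levels, err_by_noise, method = "spearman"), 0)
})
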