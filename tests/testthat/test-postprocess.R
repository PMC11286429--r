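test_that("stability labels follow length and similarity variance", {
  v <- unit_vec(8)
  single <- track_segment(1, 1, rbind(c(0, 0, 10, 10)), rbind(v))
  expect_equal(segment_stability(single, l_min = 5)$label, "unstable")

  same <- line_segment(2, 1:10, 0, 0, 2, 0)
  verdict <- segment_stability(same)
  expect_equal(verdict$label, "stable")
  expect_equal(verdict$similarity_variance, 0)

  # features alternating between two orthogonal vectors: similarity to the
  # normalized mean is 2/sqrt(5), 1/sqrt(5), 2/sqrt(5); hand variance 0.0666
  alt <- track_segment(
    3, 1:3, cbind(0, 0, 10, 10)[rep(1, 3), ],
    rbind(unit_vec(8, 1), unit_vec(8, 2), unit_vec(8, 1))
  )
  sims <- c(2, 1, 2) / sqrt(5)
  expect_equal(
    segment_stability(alt, l_min = 3)$similarity_variance,
    var(sims),
    tolerance = 1e-12
  )
  expect_gt(var(sims), 0.05)
  expect_equal(segment_stability(alt, l_min = 3)$label, "unstable")
})

test_that("the M x N similarity vote needs a strict majority", {
  a <- line_segment(1, 1:2, 0, 0, 2, 0)
  b <- line_segment(2, 10:11, 18, 0, 2, 0)
  vote <- pair_similarity_vote(a, b, s_min = 0.8)
  expect_true(vote$eligible)
  expect_equal(vote$votes, 4L)

  b_orth <- line_segment(2, 10:11, 18, 0, 2, 0, feature = unit_vec(8, 2))
  expect_false(pair_similarity_vote(a, b_orth, s_min = 0.8)$eligible)

  # exactly half the votes is not enough ("exceed half")
  a2 <- track_segment(
    1, 1:2, cbind(0, 0, 10, 10)[rep(1, 2), ],
    rbind(unit_vec(8, 1), unit_vec(8, 2))
  )
  b2 <- track_segment(
    2, 10:11, cbind(0, 0, 10, 10)[rep(1, 2), ],
    rbind(unit_vec(8, 1), unit_vec(8, 2))
  )
  vote2 <- pair_similarity_vote(a2, b2, s_min = 0.8)
  expect_equal(vote2$votes, vote2$total / 2)
  expect_false(vote2$eligible)

  # overlapping or too-distant segments are ineligible outright
  overlap <- line_segment(3, 2:5, 0, 0, 2, 0)
  expect_false(pair_similarity_vote(a, overlap)$eligible)
  far <- line_segment(4, 100:105, 0, 0, 2, 0)
  expect_false(pair_similarity_vote(a, far, g_max = 45)$eligible)
})

test_that("position/shape check extrapolates linear motion across the gap", {
  # velocity (2, 0) px/frame, 5-frame gap: lands exactly on b's first center
  a <- line_segment(1, 1:10, 0, 0, 2, 0)
  b <- line_segment(2, 16:25, 18 + 2 * 5, 0, 2, 0)
  expect_true(position_shape_match(a, b))

  # same position, width ratio 3 fails the shape check
  b_wide <- line_segment(2, 16:25, 28, 0, 2, 0, w = 150)
  expect_false(position_shape_match(a, b_wide, r_max = 1.5))

  # landing far from the extrapolation fails the position check
  b_far <- line_segment(2, 16:25, 300, 0, 2, 0)
  expect_false(position_shape_match(a, b_far, p_max = 1.0))
})

test_that("merge is a no-op without eligible pairs", {
  segs <- list(
    line_segment(1, 1:10, 0, 0, 2, 0, feature = unit_vec(8, 1)),
    line_segment(2, 20:29, 500, 300, 2, 0, feature = unit_vec(8, 2))
  )
  out <- merge_segments(segs)
  expect_length(out$segments, 2L)
  expect_equal(unname(out$id_map), c(1L, 2L))
  expect_length(out$dropped, 0L)
})

test_that("a fragmented identity merges back into one segment", {
  # one fruit split by a 10-frame occlusion; same appearance, linear motion
  a <- line_segment(1, 1:30, 0, 100, 2, 0)
  b <- line_segment(2, 41:70, 2 * 40, 100, 2, 0)
  out <- merge_segments(list(a, b))
  expect_length(out$segments, 1L)
  merged <- out$segments[[1]]
  expect_equal(merged$id, 1L)
  expect_equal(out$id_map[["2"]], 1L)
  expect_equal(merged$frames, 1:70)
  expect_equal(sum(merged$interpolated), 10L)
  # interpolated boxes continue the linear motion
  expect_equal(merged$boxes[31:40, 1], 2 * (30:39), tolerance = 1e-9)
  expect_equal(count_unique_ids(out$segments), 1L)

  # idempotence: merging the merged output changes nothing
  again <- merge_segments(out$segments)
  expect_length(again$segments, 1L)
  expect_equal(again$segments[[1]]$frames, merged$frames)
})

test_that("a chain of three compatible fragments collapses to one id", {
  segs <- list(
    line_segment(1, 1:15, 0, 50, 3, 0),
    line_segment(2, 21:35, 3 * 20, 50, 3, 0),
    line_segment(3, 41:55, 3 * 40, 50, 3, 0)
  )
  out <- merge_segments(segs)
  expect_length(out$segments, 1L)
  expect_equal(out$segments[[1]]$id, 1L)
  expect_equal(unname(out$id_map[c("1", "2", "3")]), c(1L, 1L, 1L))
  expect_equal(out$segments[[1]]$frames, 1:55)
})

test_that("unstable segments are dropped from the count but logged", {
  # five frames of one appearance and one of another: similarities to the
  # mean are 5/sqrt(26) (x5) and 1/sqrt(26); hand variance 0.1026 > 0.05
  noisy_feats <- rbind(
    unit_vec(8, 1), unit_vec(8, 1), unit_vec(8, 1),
    unit_vec(8, 1), unit_vec(8, 1), unit_vec(8, 2)
  )
  noisy <- track_segment(
    7, 1:6, cbind(100, 400, 20, 20)[rep(1, 6), ],
    noisy_feats
  )
  expect_equal(
    segment_stability(noisy)$similarity_variance,
    var(c(rep(5, 5), 1) / sqrt(26)),
    tolerance = 1e-12
  )
  stable <- line_segment(8, 1:20, 0, 0, 2, 0)
  out <- merge_segments(list(noisy, stable))
  expect_equal(out$dropped, 7L)
  expect_true(is.na(out$id_map[["7"]]))
  expect_equal(count_unique_ids(out$segments), 1L)
})

test_that("merging never increases the number of ids or breaks frame order", {
  set.seed(41)
  for (trial in 1:5) {
    n <- sample(3:6, 1)
    segs <- lapply(seq_len(n), function(i) {
      f0 <- sample(1:40, 1)
      line_segment(
        i, f0:(f0 + sample(5:15, 1)),
        runif(1, 0, 400), runif(1, 0, 400), runif(1, -3, 3), runif(1, -1, 1),
        feature = random_unit(8)
      )
    })
    out <- merge_segments(segs)
    expect_lte(count_unique_ids(out$segments), count_unique_ids(segs))
    for (s in out$segments) {
      expect_false(is.unsorted(s$frames, strictly = TRUE))
    }
  }
})
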