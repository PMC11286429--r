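test_that("cosine cost takes the best gallery view", {
  v <- unit_vec(8)
  w <- unit_vec(8, 2)
  expect_equal(cosine_cost_matrix(list(rbind(v)), rbind(v))[1, 1], 0)
  expect_equal(cosine_cost_matrix(list(rbind(v)), rbind(w))[1, 1], 1)
  # gallery {v, -v} against v: the min over the gallery wins
  expect_equal(cosine_cost_matrix(list(rbind(v, -v)), rbind(v))[1, 1], 0)
  # empty gallery is infeasible
  empty <- cosine_cost_matrix(list(matrix(numeric(0), 0, 8)), rbind(v))
  expect_gte(empty[1, 1], fruitmot:::INFEASIBLE_COST)
})

test_that("iou cost complements overlap", {
  a <- rbind(c(0, 0, 10, 10))
  expect_equal(iou_cost_matrix(a, a)[1, 1], 0)
  expect_equal(iou_cost_matrix(a, rbind(c(50, 50, 5, 5)))[1, 1], 1)
  expect_equal(iou_cost_matrix(a, rbind(c(5, 0, 10, 10)))[1, 1], 2 / 3,
    tolerance = 1e-12
  )
})

test_that("gating keeps exactly the entries within the threshold", {
  cost <- matrix(runif(6), 2, 3)
  gating <- matrix(c(1, 5, 11, 2, 9.8, 0.3), 2, 3)
  expect_equal(gate_cost_matrix(cost, gating, Inf), cost)
  blocked <- gate_cost_matrix(cost, gating, 0)
  expect_true(all(blocked >= fruitmot:::INFEASIBLE_COST))
  mixed <- gate_cost_matrix(cost, gating, 9.4877)
  expect_equal(
    mixed >= fruitmot:::INFEASIBLE_COST,
    gating > 9.4877
  )
  expect_equal(mixed[gating <= 9.4877], cost[gating <= 9.4877])
})

test_that("assignment solves small cases and demotes over-threshold pairs", {
  r <- solve_assignment(matrix(0.3), 0.5)
  expect_equal(nrow(r$matches), 1L)
  r <- solve_assignment(matrix(c(1, 3, 2, 1), 2, 2), 10)
  expect_equal(r$matches[, "detection"], c(1L, 2L), ignore_attr = TRUE)
  r <- solve_assignment(matrix(0.9), 0.5)
  expect_equal(nrow(r$matches), 0L)
  expect_equal(r$unmatched_tracks, 1L)
  expect_equal(r$unmatched_detections, 1L)
})

test_that("every index appears exactly once across matches and unmatched", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(0:5, 1)
    m <- sample(0:5, 1)
    cost <- matrix(runif(n * m), n, m)
    r <- solve_assignment(cost, 0.8)
    tr <- c(r$matches[, 1], r$unmatched_tracks)
    de <- c(r$matches[, 2], r$unmatched_detections)
    expect_setequal(tr, seq_len(n))
    expect_equal(anyDuplicated(tr), 0L)
    expect_setequal(de, seq_len(m))
    expect_equal(anyDuplicated(de), 0L)
  }
})

test_that("assignment equals exhaustive minimization on random matrices", {
  set.seed(32)
  for (i in 1:60) {
    n <- sample(1:5, 1)
    m <- sample(1:5, 1)
    cost <- matrix(runif(n * m, 0, 2), n, m)
    got <- solve_assignment(cost, 5)
    want <- brute_force_assignment(cost, 5)
    expect_equal(sum(cost[got$matches]), want$total, tolerance = 1e-6)
  }
})

test_that("assignment total is invariant under row/column permutation", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(2:5, 1)
    cost <- matrix(runif(n * n), n, n)
    base <- sum(cost[solve_assignment(cost, 10)$matches])
    pr <- sample(n)
    pc <- sample(n)
    perm <- cost[pr, pc]
    expect_equal(sum(perm[solve_assignment(perm, 10)$matches]), base,
      tolerance = 1e-6
    )
  }
})

make_gating_fn <- function(model, states) {
  function(i, z) kf_gating_distance(model, states[[i]], z)
}

test_that("cascade matches by appearance within the motion gate", {
  model <- kalman_model()
  v <- unit_vec(8)
  st <- kf_predict(model, kf_initiate(model, c(100, 100, 1, 50)))
  res <- cascade_match(
    galleries = list(rbind(v)), ages = 1L,
    gating_fn = make_gating_fn(model, list(st)),
    features = rbind(v), measurements = rbind(c(100, 100, 1, 50)),
    max_age = 30, max_cosine = 0.2, chi2_threshold = 9.4877
  )
  expect_equal(nrow(res$matches), 1L)

  # detection far outside every gate stays unmatched
  res <- cascade_match(
    galleries = list(rbind(v)), ages = 1L,
    gating_fn = make_gating_fn(model, list(st)),
    features = rbind(v), measurements = rbind(c(900, 900, 1, 50)),
    max_age = 30, max_cosine = 0.2, chi2_threshold = 9.4877
  )
  expect_equal(nrow(res$matches), 0L)
  expect_equal(res$unmatched_detections, 1L)
})

test_that("cascade gives priority to recently updated tracks", {
  model <- kalman_model()
  v <- unit_vec(8)
  st <- kf_predict(model, kf_initiate(model, c(100, 100, 1, 50)))
  # two identical tracks, ages 1 and 5, competing for one detection
  res <- cascade_match(
    galleries = list(rbind(v), rbind(v)), ages = c(5L, 1L),
    gating_fn = make_gating_fn(model, list(st, st)),
    features = rbind(v), measurements = rbind(c(100, 100, 1, 50)),
    max_age = 30, max_cosine = 0.2, chi2_threshold = 100
  )
  expect_equal(res$matches[, "track"], 2L, ignore_attr = TRUE)
  expect_equal(res$unmatched_tracks, 1L)
})

test_that("cascade never matches one detection to two tracks", {
  model <- kalman_model()
  set.seed(34)
  for (trial in 1:10) {
    n_t <- sample(2:5, 1)
    n_d <- sample(1:5, 1)
    states <- lapply(seq_len(n_t), function(i) {
      kf_predict(model, kf_initiate(
        model,
        c(runif(1, 0, 500), runif(1, 0, 500), 1, 50)
      ))
    })
    galleries <- lapply(seq_len(n_t), function(i) rbind(random_unit(8)))
    res <- cascade_match(
      galleries = galleries, ages = sample(1:6, n_t, replace = TRUE),
      gating_fn = make_gating_fn(model, states),
      features = t(vapply(seq_len(n_d), function(i) random_unit(8),
        numeric(8)
      )),
      measurements = cbind(runif(n_d, 0, 500), runif(n_d, 0, 500), 1, 50),
      max_age = 30, max_cosine = 0.6, chi2_threshold = 50
    )
    expect_equal(anyDuplicated(res$matches[, "detection"]), 0L)
    expect_equal(anyDuplicated(res$matches[, "track"]), 0L)
  }
})
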