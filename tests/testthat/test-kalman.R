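model <- kalman_model()

test_that("initiation copies the measurement, zero velocity, PSD covariance", {
  s <- kf_initiate(model, c(5, 10, 0.5, 20))
  expect_equal(s$mean, c(5, 10, 0.5, 20, 0, 0, 0, 0))
  expect_true(all(diag(s$cov) > 0))
  expect_identical(s, kf_initiate(model, c(5, 10, 0.5, 20)))
})

test_that("prediction applies the constant-velocity transition", {
  s <- kf_initiate(model, c(0, 0, 1, 10))
  p <- kf_predict(model, s)
  expect_equal(p$mean[1:4], c(0, 0, 1, 10)) # zero velocity: position stays
  s$mean <- c(0, 0, 1, 10, 2, 0, 0, 0)
  p <- kf_predict(model, s)
  expect_equal(p$mean[1], 2)
  expect_equal(p$mean[2:4], c(0, 1, 10))
  # Q is PSD, so predicted covariance trace cannot shrink below F P F^T
  fpf <- model$F %*% s$cov %*% t(model$F)
  expect_gte(sum(diag(p$cov)), sum(diag(fpf)))
})

test_that("update with the predicted measurement leaves the mean unchanged", {
  s <- kf_predict(model, kf_initiate(model, c(5, 10, 0.5, 20)))
  u <- kf_update(model, s, c(5, 10, 0.5, 20))
  expect_equal(u$residual, rep(0, 4))
  expect_equal(u$state$mean, s$mean, tolerance = 1e-12)
})

test_that("scalar update reproduces the closed form K = P / (P + R)", {
  out <- fruitmot:::kf_linear_update(
    mean = 0, cov = matrix(1), h = matrix(1), r = matrix(1), z = 2
  )
  expect_equal(as.numeric(out$gain), 0.5)
  expect_equal(out$mean, 1)
  expect_equal(as.numeric(out$cov), 0.5)
})

test_that("a huge measurement noise makes the update a no-op", {
  s <- kf_predict(model, kf_initiate(model, c(100, 100, 1, 50)))
  r_big <- diag(fruitmot:::kf_measurement_std(model, 50)^2) * 1e9
  out <- fruitmot:::kf_linear_update(s$mean, s$cov, model$H, r_big,
    z = c(140, 90, 1.2, 60)
  )
  expect_equal(out$mean, s$mean, tolerance = 1e-6)
})

test_that("gating distance is zero at the prediction and order-invariant", {
  s <- kf_predict(model, kf_initiate(model, c(5, 10, 0.5, 20)))
  z <- rbind(c(5, 10, 0.5, 20), c(9, 10, 0.5, 20), c(5, 14, 0.4, 25))
  d <- kf_gating_distance(model, s, z)
  expect_equal(d[1], 0)
  expect_true(all(d >= 0))
  perm <- c(3, 1, 2)
  expect_equal(kf_gating_distance(model, s, z[perm, ]), d[perm])
})

test_that("gating distance matches dense matrix-inverse evaluation", {
  set.seed(21)
  for (i in 1:20) {
    s <- kf_initiate(model, c(runif(1, 0, 500), runif(1, 0, 500),
      runif(1, 0.5, 1.5), runif(1, 20, 100)
    ))
    s <- kf_predict(model, s)
    z <- s$mean[1:4] + rnorm(4, 0, c(5, 5, 0.05, 5))
    r <- diag(fruitmot:::kf_measurement_std(model, s$mean[4])^2)
    expect_equal(
      kf_gating_distance(model, s, z),
      naive_mahalanobis(s$mean, s$cov, model$H, r, z),
      tolerance = 1e-8
    )
  }
})

test_that("predict/update recursion matches an independent implementation", {
  set.seed(22)
  for (trial in 1:10) {
    z0 <- c(runif(1, 0, 1000), runif(1, 0, 600), runif(1, 0.6, 1.4),
      runif(1, 30, 120)
    )
    s <- kf_initiate(model, z0)
    mean_ref <- s$mean
    cov_ref <- s$cov
    for (step in 1:20) {
      q <- diag(fruitmot:::kf_process_std(model, mean_ref[4])^2)
      ref <- naive_kalman_predict(mean_ref, cov_ref, model$F, q)
      s <- kf_predict(model, s)
      expect_equal(s$mean, ref$mean, tolerance = 1e-8)
      expect_equal(s$cov, ref$cov, tolerance = 1e-8)
      z <- ref$mean[1:4] + rnorm(4, 0, c(3, 3, 0.02, 3))
      r <- diag(fruitmot:::kf_measurement_std(model, ref$mean[4])^2)
      ref_u <- naive_kalman_update(ref$mean, ref$cov, model$H, r, z)
      s <- kf_update(model, s, z)$state
      expect_equal(s$mean, ref_u$mean, tolerance = 1e-8)
      expect_equal(s$cov, ref_u$cov, tolerance = 1e-8)
      mean_ref <- ref_u$mean
      cov_ref <- ref_u$cov
    }
  }
})

test_that("covariance stays symmetric and PSD over many random cycles", {
  set.seed(23)
  s <- kf_initiate(model, c(200, 200, 1, 60))
  for (i in 1:1000) {
    s <- kf_predict(model, s)
    z <- s$mean[1:4] + rnorm(4, 0, c(4, 4, 0.03, 4))
    z[3] <- max(z[3], 0.1)
    z[4] <- max(z[4], 5)
    s <- kf_update(model, s, z)$state
    expect_lte(max(abs(s$cov - t(s$cov))), 1e-8)
    expect_gte(min(eigen(s$cov, symmetric = TRUE, only.values = TRUE)$values),
      -1e-8
    )
  }
})

test_that("with zero process noise and vanishing measurement noise the
           prediction converges to exact uniform linear motion", {
  model <- kalman_model()
  q0 <- matrix(0, 8, 8)
  r_tiny <- diag(1e-12, 4)
  mean <- c(100, 50, 1, 40, 0, 0, 0, 0)
  cov <- diag(c(1, 1, 1e-4, 1, 25, 25, 1e-6, 25))
  for (t in 1:8) {
    p <- fruitmot:::kf_linear_predict(mean, cov, model$F, q0)
    z <- c(100 + 3 * t, 50 + 1 * t, 1, 40) # exact uniform linear motion
    u <- fruitmot:::kf_linear_update(p$mean, p$cov, model$H, r_tiny, z)
    mean <- u$mean
    cov <- u$cov
    if (t >= 5) {
      pred <- fruitmot:::kf_linear_predict(mean, cov, model$F, q0)
      truth <- c(100 + 3 * (t + 1), 50 + (t + 1))
      expect_lt(max(abs(pred$mean[1:2] - truth)), 1e-6)
    }
  }
})
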