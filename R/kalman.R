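#' Constant-velocity Kalman motion model
#'
#' Per-track motion is estimated with a linear Kalman filter over the
#' eight-dimensional state `(cx, cy, a, h, vcx, vcy, va, vh)`: box center,
#' aspect ratio and height plus their per-frame velocities. The transition
#' matrix couples each position component to its velocity with a unit time step
#' (one frame); there is no control input (camera motion is absorbed by the
#' velocity states). Process and measurement noise are height-proportional so
#' that gating behaves the same for near and far fruit: position standard
#' deviations scale as `w_pos * h` and velocity standard deviations as
#' `w_vel * h`, with small constants for the dimensionless aspect component.
#'
#' @param w_pos position noise weight (standard deviation per unit box height);
#'   default 1/20.
#' @param w_vel velocity noise weight; default 1/160.
#' @param std_aspect process/initiation standard deviation of the aspect state.
#' @param std_vaspect process/initiation standard deviation of the aspect
#'   velocity state.
#' @param std_aspect_meas measurement standard deviation of the aspect
#'   component.
#' @return an object of class `kalman_model`.
#' @export
kalman_model <- function(w_pos = 1 / 20, w_vel = 1 / 160,
                         std_aspect = 1e-2, std_vaspect = 1e-5,
                         std_aspect_meas = 1e-2) {
  ndim <- 4L
  f <- diag(2L * ndim)
  for (i in seq_len(ndim)) f[i, ndim + i] <- 1
  h <- cbind(diag(ndim), matrix(0, ndim, ndim))
  structure(
    list(
      F = f, H = h, ndim = ndim,
      w_pos = w_pos, w_vel = w_vel,
      std_aspect = std_aspect, std_vaspect = std_vaspect,
      std_aspect_meas = std_aspect_meas
    ),
    class = "kalman_model"
  )
}

# Height-scaled noise standard deviations for the current state.
kf_process_std <- function(model, height) {
  c(
    model$w_pos * height, model$w_pos * height, model$std_aspect,
    model$w_pos * height,
    model$w_vel * height, model$w_vel * height, model$std_vaspect,
    model$w_vel * height
  )
}

kf_measurement_std <- function(model, height) {
  c(
    model$w_pos * height, model$w_pos * height, model$std_aspect_meas,
    model$w_pos * height
  )
}

# Generic linear Kalman steps, shared by the 8-dim model and usable with any
# (F, Q, H, R); kept separate so the recursion can be exercised directly.
kf_linear_predict <- function(mean, cov, f, q) {
  mean <- as.vector(f %*% mean)
  cov <- f %*% cov %*% t(f) + q
  list(mean = mean, cov = (cov + t(cov)) / 2)
}

kf_linear_update <- function(mean, cov, h, r, z) {
  s <- h %*% cov %*% t(h) + r
  s <- (s + t(s)) / 2
  cs <- tryCatch(chol(s), error = function(e) {
    stop("innovation covariance is not positive definite")
  })
  s_inv <- chol2inv(cs)
  k <- t(h %*% cov) %*% s_inv # cov symmetric: cov %*% t(h) = t(h %*% cov)
  residual <- as.vector(z) - as.vector(h %*% mean)
  mean <- as.vector(mean) + as.vector(k %*% residual)
  cov <- (diag(nrow(cov)) - k %*% h) %*% cov
  list(
    mean = mean, cov = (cov + t(cov)) / 2,
    residual = residual, gain = k
  )
}

#' Start a track state from one measurement
#'
#' Position components are taken from the measurement, velocities start at
#' zero; the covariance diagonal is initialized from height-scaled standard
#' deviations (twice the position weight, ten times the velocity weight, so a
#' fresh track is loosely gated until its velocity settles).
#'
#' @param model a [kalman_model()].
#' @param measurement xyah vector `(cx, cy, aspect, height)`.
#' @return a `kalman_state`: list with `mean` (length 8) and `cov` (8 x 8).
#' @export
kf_initiate <- function(model, measurement) {
  z <- as.numeric(measurement)
  stopifnot(length(z) == model$ndim)
  mean <- c(z, rep(0, model$ndim))
  h <- z[4L]
  std <- c(
    2 * model$w_pos * h, 2 * model$w_pos * h, model$std_aspect,
    2 * model$w_pos * h,
    10 * model$w_vel * h, 10 * model$w_vel * h, model$std_vaspect,
    10 * model$w_vel * h
  )
  structure(list(mean = mean, cov = diag(std^2)), class = "kalman_state")
}

#' Predict a track state one frame ahead
#'
#' Applies the constant-velocity transition: `mean' = F mean` and
#' `cov' = F cov F^T + Q`, with `Q` built from the current height.
#'
#' @param model a [kalman_model()].
#' @param state a `kalman_state`.
#' @return the predicted `kalman_state`.
#' @export
kf_predict <- function(model, state) {
  q <- diag(kf_process_std(model, state$mean[4L])^2)
  out <- kf_linear_predict(state$mean, state$cov, model$F, q)
  structure(list(mean = out$mean, cov = out$cov), class = "kalman_state")
}

#' Correct a predicted state with a measurement
#'
#' Standard Kalman update: residual `y = z - H x`, gain
#' `K = P H^T (H P H^T + R)^-1` solved through a Cholesky factorization of the
#' innovation covariance, then `x' = x + K y` and `P' = (I - K H) P`.
#'
#' @param model a [kalman_model()].
#' @param state a predicted `kalman_state`.
#' @param measurement xyah vector.
#' @return list with `state` (updated `kalman_state`), `residual` (length 4)
#'   and `gain` (8 x 4 matrix).
#' @export
kf_update <- function(model, state, measurement) {
  z <- as.numeric(measurement)
  stopifnot(length(z) == model$ndim)
  r <- diag(kf_measurement_std(model, state$mean[4L])^2)
  out <- kf_linear_update(state$mean, state$cov, model$H, r, z)
  list(
    state = structure(list(mean = out$mean, cov = out$cov),
      class = "kalman_state"
    ),
    residual = out$residual,
    gain = out$gain
  )
}

#' Squared Mahalanobis distance from a predicted state to measurements
#'
#' For each measurement `z` computes `d^T S^-1 d` with `d = z - H x` and
#' `S = H P H^T + R` — the motion-feature discrepancy between the predicted
#' box and each detection box, used for gating candidate matches.
#'
#' @param model a [kalman_model()].
#' @param state a predicted `kalman_state`.
#' @param measurements n x 4 matrix of xyah rows (or a single length-4 vector).
#' @return numeric vector of n nonnegative squared distances.
#' @export
kf_gating_distance <- function(model, state, measurements) {
  z <- if (is.null(dim(measurements))) {
    matrix(as.numeric(measurements), nrow = 1L)
  } else {
    as.matrix(measurements)
  }
  if (nrow(z) == 0L) {
    return(numeric(0))
  }
  stopifnot(ncol(z) == model$ndim)
  r <- diag(kf_measurement_std(model, state$mean[4L])^2)
  s <- model$H %*% state$cov %*% t(model$H) + r
  s <- (s + t(s)) / 2
  cs <- tryCatch(chol(s), error = function(e) {
    stop("innovation covariance is not positive definite")
  })
  d <- sweep(z, 2L, as.vector(model$H %*% state$mean))
  # solve L w = d^T per column, squared distance = colSums(w^2)
  w <- forwardsolve(t(cs), t(d))
  colSums(w^2)
}
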