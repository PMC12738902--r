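#' Constant-velocity Kalman filter over box measurements
#'
#' The tracker's motion model is an 8-dimensional constant-velocity
#' Kalman filter over the measurement `(cx, cy, a, h)` — box center,
#' aspect ratio (width/height) and height — augmented with their
#' velocities. Process and observation noise follow the DeepSort
#' convention of scaling with the box height: position-like standard
#' deviations use weight 1/20 x h, velocity-like ones 1/160 x h, which
#' makes the filter scale-free with respect to apparent object size.
#'
#' `kalman_initiate()` builds a state from a first measurement (zero
#' initial velocity, inflated covariance); `kalman_predict()` advances
#' one frame; `kalman_update()` folds in a new measurement;
#' `kalman_project()` returns the predicted measurement distribution;
#' `kalman_gating_distance()` computes squared Mahalanobis distances of
#' candidate measurements under that distribution (4 degrees of
#' freedom), used to gate implausible associations.
#'
#' @param measurement Numeric vector `c(cx, cy, a, h)` with `h > 0`.
#' @return A `kalman_state` list with elements `mean` (length-8 numeric)
#'   and `cov` (8 x 8 symmetric positive semi-definite matrix).
#' @name kalman
#' @export
kalman_initiate <- function(measurement) {
  m <- as.numeric(measurement)
  if (length(m) != 4L || !all(is.finite(m)))
    stop("measurement must be four finite numbers (cx, cy, a, h)", call. = FALSE)
  h <- m[[4]]
  if (h <= 0) stop("measurement height must be positive", call. = FALSE)
  wp <- 1 / 20; wv <- 1 / 160
  mean <- c(m, rep(0, 4))
  std <- c(2 * wp * h, 2 * wp * h, 1e-2, 2 * wp * h,
           10 * wv * h, 10 * wv * h, 1e-5, 10 * wv * h)
  structure(list(mean = mean, cov = diag(std^2)), class = "kalman_state")
}

# One-frame transition matrix: position += velocity.
.kf_transition <- local({
  F8 <- diag(8)
  F8[1:4, 5:8] <- diag(4)
  F8
})

.kf_observation <- cbind(diag(4), matrix(0, 4, 4))

#' @rdname kalman
#' @param state A `kalman_state`.
#' @param noise_scale Multiplier on the process/observation noise
#'   standard deviations (default 1). With `noise_scale = 0` the filter
#'   is exact: two noise-free updates lock onto a constant-velocity
#'   trajectory and reproduce it without error.
#' @export
kalman_predict <- function(state, noise_scale = 1) {
  h <- state$mean[[4]]
  wp <- 1 / 20; wv <- 1 / 160
  std <- noise_scale *
    c(wp * h, wp * h, 1e-2, wp * h, wv * h, wv * h, 1e-5, wv * h)
  Q <- diag(std^2)
  mean <- as.numeric(.kf_transition %*% state$mean)
  cov <- .kf_transition %*% state$cov %*% t(.kf_transition) + Q
  structure(list(mean = mean, cov = symmetrize(cov)), class = "kalman_state")
}

#' @rdname kalman
#' @export
kalman_project <- function(state, noise_scale = 1) {
  h <- state$mean[[4]]
  wp <- 1 / 20
  std <- noise_scale * c(wp * h, wp * h, 1e-1, wp * h)
  R <- diag(std^2)
  mean <- as.numeric(.kf_observation %*% state$mean)
  cov <- .kf_observation %*% state$cov %*% t(.kf_observation) + R
  list(mean = mean, cov = symmetrize(cov))
}

#' @rdname kalman
#' @export
kalman_update <- function(state, measurement, noise_scale = 1) {
  m <- as.numeric(measurement)
  if (length(m) != 4L || !all(is.finite(m)))
    stop("measurement must be four finite numbers (cx, cy, a, h)", call. = FALSE)
  proj <- kalman_project(state, noise_scale)
  ch <- tryCatch(chol(proj$cov),
                 error = function(e) stop("singular innovation covariance", call. = FALSE))
  # Kalman gain via Cholesky solves: K = P H' S^{-1}
  PHt <- state$cov %*% t(.kf_observation)
  K <- t(backsolve(ch, forwardsolve(t(ch), t(PHt))))
  innovation <- m - proj$mean
  mean <- state$mean + as.numeric(K %*% innovation)
  cov <- state$cov - K %*% proj$cov %*% t(K)
  if (mean[[4]] <= 0)
    stop("non-positive height after update; inconsistent measurement", call. = FALSE)
  structure(list(mean = mean, cov = symmetrize(cov)), class = "kalman_state")
}

#' @rdname kalman
#' @param measurements Numeric matrix with one `c(cx, cy, a, h)`
#'   measurement per row (or a single measurement vector).
#' @return `kalman_gating_distance()`: numeric vector of squared
#'   Mahalanobis distances, one per measurement row.
#' @export
kalman_gating_distance <- function(state, measurements) {
  if (is.null(dim(measurements))) measurements <- matrix(measurements, nrow = 1L)
  proj <- kalman_project(state)
  ch <- tryCatch(chol(proj$cov),
                 error = function(e) stop("singular innovation covariance", call. = FALSE))
  d <- sweep(measurements, 2L, proj$mean)
  z <- forwardsolve(t(ch), t(d))
  colSums(z^2)
}

# Chi-square 0.95 quantile at 4 degrees of freedom: the default
# Mahalanobis gate for (cx, cy, a, h) measurements.
CHI2_GATE_95_4DOF <- 9.487729

symmetrize <- function(S) (S + t(S)) / 2
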