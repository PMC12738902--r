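test_that("kalman_initiate seeds position from the measurement", {
  s <- kalman_initiate(c(50, 50, 1, 20))
  expect_equal(s$mean[1:4], c(50, 50, 1, 20))
  expect_equal(s$mean[5:8], rep(0, 4))
  expect_true(isSymmetric(s$cov))
  expect_true(all(eigen(s$cov, only.values = TRUE)$values >= 0))
  expect_identical(s, kalman_initiate(c(50, 50, 1, 20)))
  expect_error(kalman_initiate(c(50, 50, 1, 0)), "positive")
})

test_that("predict keeps a zero-velocity state in place; zero innovation keeps the mean", {
  s <- kalman_initiate(c(50, 50, 1, 20))
  p <- kalman_predict(s)
  expect_equal(p$mean, s$mean)
  # measurement equal to the predicted measurement: mean unchanged
  u <- kalman_update(p, p$mean[1:4])
  expect_equal(u$mean, p$mean, tolerance = 1e-12)
})

test_that("the filter matches a textbook matrix recursion over 10 steps", {
  set.seed(11)
  s0 <- kalman_initiate(c(100, 200, 1, 30))
  meas <- cbind(100 + cumsum(rnorm(10, 2, 0.5)),
                200 + cumsum(rnorm(10, 3, 0.5)),
                1 + rnorm(10, 0, 0.01),
                30 + rnorm(10, 0, 0.5))
  s <- s0
  for (i in 1:10) {
    s <- kalman_predict(s)
    s <- kalman_update(s, meas[i, ])
  }
  oracle <- textbook_kalman(s0, meas)
  expect_equal(s$mean, oracle$mean, tolerance = 1e-9)
  expect_equal(s$cov, oracle$cov, tolerance = 1e-9)
})

test_that("a noiseless constant-velocity track is locked after two updates", {
  v <- c(3, 5)
  pos <- function(t) c(10 + v[1] * t, 20 + v[2] * t, 1, 16)
  s <- kalman_initiate(pos(0))
  for (t in 1:2) {
    s <- kalman_predict(s, noise_scale = 0)
    s <- kalman_update(s, pos(t), noise_scale = 0)
  }
  # with zero noise two updates pin down position and velocity exactly
  p <- kalman_predict(s, noise_scale = 0)
  expect_equal(p$mean[1:2], pos(3)[1:2], tolerance = 1e-9)
  expect_equal(p$mean[5:6], v, tolerance = 1e-9)
})

test_that("predict/update preserve covariance symmetry and PSD", {
  set.seed(8)
  s <- kalman_initiate(c(50, 50, 1, 20))
  for (t in 1:20) {
    s <- kalman_predict(s)
    expect_true(isSymmetric(s$cov))
    expect_gte(min(eigen(s$cov, only.values = TRUE)$values), -1e-10)
    s <- kalman_update(s, c(50 + t + rnorm(1), 50 + rnorm(1), 1, 20))
    expect_true(isSymmetric(s$cov))
    expect_gte(min(eigen(s$cov, only.values = TRUE)$values), -1e-10)
    expect_gt(s$mean[[4]], 0)
  }
})

test_that("gating distance is a squared Mahalanobis form", {
  s <- kalman_predict(kalman_initiate(c(50, 50, 1, 20)))
  proj_mean <- kalman_project(s)$mean
  expect_equal(kalman_gating_distance(s, proj_mean), 0)
  # quadratic scaling along an eigendirection of the projected covariance
  proj <- kalman_project(s)
  e <- eigen(proj$cov)
  dir <- e$vectors[, 1]
  d1 <- kalman_gating_distance(s, proj_mean + dir)
  d2 <- kalman_gating_distance(s, proj_mean + 2 * dir)
  expect_equal(d2 / d1, 4, tolerance = 1e-9)
  expect_equal(d1, 1 / e$values[1], tolerance = 1e-9)
  # far measurements exceed the chi-square 95% gate at 4 dof
  far <- proj_mean + c(1000, 1000, 0, 0)
  expect_gt(kalman_gating_distance(s, far), 9.4877)
})

test_that("linear assignment solves small anchors and respects max_cost", {
  sol <- linear_assignment(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(sol$matches, cbind(row = 1:2, col = 1:2))

  sol <- linear_assignment(matrix(5, 3, 3), max_cost = 4)
  expect_equal(nrow(sol$matches), 0L)
  expect_equal(sol$unmatched_rows, 1:3)
  expect_equal(sol$unmatched_cols, 1:3)

  sol <- linear_assignment(matrix(numeric(), 0, 0))
  expect_equal(nrow(sol$matches), 0L)
})

test_that("assignment total cost equals the brute-force minimum", {
  set.seed(21)
  for (rep in 1:60) {
    nr <- sample(2:5, 1); nc <- sample(2:6, 1)
    cost <- matrix(runif(nr * nc, 0, 10), nr, nc)
    sol <- linear_assignment(cost)
    expect_equal(nrow(sol$matches), min(nr, nc))
    total <- sum(cost[sol$matches])
    expect_equal(total, brute_force_assignment(cost), tolerance = 1e-9)
    # one-to-one
    expect_false(any(duplicated(sol$matches[, 1])))
    expect_false(any(duplicated(sol$matches[, 2])))
  }
})

make_step_dets <- function(frame, boxes, cname = "normal", conf = 0.9) {
  if (is.null(boxes)) {
    return(data.frame(frame = integer(), cname = character(), conf = numeric(),
                      x1 = numeric(), y1 = numeric(), x2 = numeric(),
                      y2 = numeric(), stringsAsFactors = FALSE))
  }
  if (is.null(dim(boxes))) boxes <- matrix(boxes, ncol = 4)
  data.frame(frame = frame, cname = cname, conf = conf,
             x1 = boxes[, 1], y1 = boxes[, 2], x2 = boxes[, 3], y2 = boxes[, 4],
             stringsAsFactors = FALSE)
}

test_that("cascade matching pairs tracks with compatible detections", {
  cfg <- tracker_config()
  emb <- function(id) synthetic_embedder(id, 0, 0L)
  # build one confirmed track via three steps
  trk <- new_tracker(cfg)
  for (f in 0:2) {
    st <- tracker_step(trk, make_step_dets(f, c(40, 40 + 6 * f, 60, 60 + 6 * f)),
                       matrix(emb(1L), nrow = 1))
    trk <- st$tracker
  }
  expect_equal(trk$tracks[[1]]$status, "confirmed")
  tracks <- lapply(trk$tracks, function(t) { t$kf <- kalman_predict(t$kf);
                                             t$time_since_update <- t$time_since_update + 1L; t })
  # detection at the predicted position with a gallery-identical embedding
  sol <- cascade_match(tracks, matrix(c(40, 58, 60, 78), 1), matrix(emb(1L), nrow = 1), cfg)
  expect_equal(sol$matches, cbind(track = 1L, detection = 1L))

  # same appearance but far beyond the motion gate: never matched
  sol <- cascade_match(tracks, matrix(c(400, 400, 420, 420), 1),
                       matrix(emb(1L), nrow = 1), cfg)
  expect_equal(nrow(sol$matches), 0L)
  expect_equal(sol$unmatched_detections, 1L)
})

test_that("crossed appearance costs resolve to the Hungarian optimum", {
  cfg <- tracker_config()
  e1 <- synthetic_embedder(1L, 0, 0L); e2 <- synthetic_embedder(2L, 0, 0L)
  trk <- new_tracker(cfg)
  b1 <- c(40, 40, 60, 60); b2 <- c(140, 40, 160, 60)
  for (f in 0:2) {
    d <- rbind(b1 + c(0, 6 * f, 0, 6 * f), b2 + c(0, 6 * f, 0, 6 * f))
    st <- tracker_step(trk, make_step_dets(f, d), rbind(e1, e2))
    trk <- st$tracker
  }
  tracks <- lapply(trk$tracks, function(t) { t$kf <- kalman_predict(t$kf);
                                             t$time_since_update <- t$time_since_update + 1L; t })
  # detections listed in swapped spatial order; appearance decides
  boxes <- rbind(c(140, 58, 160, 78), c(40, 58, 60, 78))
  sol <- cascade_match(tracks, boxes, rbind(e2, e1), cfg)
  got <- sol$matches[order(sol$matches[, "track"]), , drop = FALSE]
  expect_equal(got, cbind(track = 1:2, detection = 2:1))
})

test_that("track lifecycle: confirmation, coasting, deletion, id non-reuse", {
  cfg <- tracker_config(n_init = 3L, max_age = 5L)
  trk <- new_tracker(cfg)
  e <- matrix(synthetic_embedder(1L, 0, 0L), nrow = 1)
  confirmed_at <- NA
  for (f in 0:2) {
    st <- tracker_step(trk, make_step_dets(f, c(10, 10 + 6 * f, 40, 40 + 6 * f)), e)
    trk <- st$tracker
    if (is.na(confirmed_at) && nrow(st$tracks) > 0) confirmed_at <- f
  }
  expect_equal(confirmed_at, 2)   # frames 0,1,2 = n_init hits
  first_id <- trk$tracks[[1]]$id

  # starve the tracker: after max_age + 1 empty frames the track is gone
  for (f in 3:(3 + cfg$max_age)) {
    st <- tracker_step(trk, make_step_dets(f, NULL), NULL, frame = f)
    trk <- st$tracker
  }
  expect_length(trk$tracks, 0L)
  expect_equal(nrow(st$tracks), 0L)

  # a new object never reuses the dead id
  st <- tracker_step(trk, make_step_dets(20, c(10, 10, 40, 40)), e)
  expect_gt(st$tracker$tracks[[1]]$id, first_id)

  # non-monotone frames are rejected
  expect_error(tracker_step(st$tracker, make_step_dets(20, c(10, 10, 40, 40)), e),
               "non-monotone")
})

test_that("a clean 5-plant sequence yields 5 stable identities", {
  sc <- simulate_scene(scene_config(n_plants = 5L, frame_size = c(400L, 360L),
                                    miss_prob = 0, fp_rate_per_frame = 0,
                                    jitter_sd = 0, seed = 13L))
  tracks <- track_detections(sc$detections[, c("frame", "cname", "conf",
                                               "x1", "y1", "x2", "y2")],
                             sc$embeddings)
  expect_equal(length(unique(tracks$id)), 5L)
  sw <- count_id_switches(tracks, sc$truth)
  expect_equal(sw$switches, 0)
  expect_equal(sw$n_pred_ids, 5L)
})

test_that("majority vote fixes the track label, most recent label breaks ties", {
  cfg <- tracker_config(n_init = 1L)
  trk <- new_tracker(cfg)
  e <- matrix(synthetic_embedder(1L, 0, 0L), nrow = 1)
  labs <- c("normal", "bare_root", "bare_root", "normal", "buried_seedling")
  for (f in seq_along(labs) - 1L) {
    st <- tracker_step(trk, make_step_dets(f, c(10, 10 + 6 * f, 40, 40 + 6 * f),
                                           cname = labs[f + 1L]), e)
    trk <- st$tracker
  }
  # votes: normal 2, bare_root 2, buried 1 -> tie between the leaders is
  # broken by recency: normal (frame 3) was seen after bare_root (frame 2)
  expect_equal(st$tracks$cname, "normal")
})
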