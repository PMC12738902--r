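#' Tracker configuration
#'
#' Association thresholds and lifecycle parameters for the
#' tracking-by-detection pipeline. Defaults follow the DeepSort lineage;
#' every knob is surfaced because field deployments differ in camera
#' speed, detector quality and occlusion structure.
#'
#' @param max_cosine_distance Appearance gate: a detection whose smallest
#'   cosine distance to a track's gallery exceeds this can not be matched
#'   by appearance (default 0.2).
#' @param gating_threshold Squared-Mahalanobis motion gate at 4 degrees of
#'   freedom; the default 9.4877 is the chi-square 0.95 quantile.
#' @param iou_threshold Minimum IoU for the fallback IoU matching stage
#'   (default 0.3).
#' @param max_age Frames a confirmed track may coast unmatched before it
#'   is deleted and its tracking information removed (default 30).
#' @param n_init Consecutive hits required before a tentative track is
#'   confirmed (default 3); tentative tracks that miss once are dropped,
#'   which is the mechanism that suppresses spurious detections.
#' @param nn_budget Appearance gallery ring-buffer size per track
#'   (default 100).
#' @param min_confidence Detections below this confidence are ignored
#'   (default 0.5).
#' @return Named list of class `tracker_config`.
#' @export
tracker_config <- function(max_cosine_distance = 0.2,
                           gating_threshold = CHI2_GATE_95_4DOF,
                           iou_threshold = 0.3,
                           max_age = 30L,
                           n_init = 3L,
                           nn_budget = 100L,
                           min_confidence = 0.5) {
  cfg <- list(max_cosine_distance = max_cosine_distance,
              gating_threshold = gating_threshold,
              iou_threshold = iou_threshold,
              max_age = as.integer(max_age),
              n_init = as.integer(n_init),
              nn_budget = as.integer(nn_budget),
              min_confidence = min_confidence)
  if (any(unlist(cfg[1:6]) <= 0) || min_confidence < 0)
    stop("tracker_config values must be positive", call. = FALSE)
  if (cfg$n_init < 1L) stop("n_init must be >= 1", call. = FALSE)
  structure(cfg, class = "tracker_config")
}

#' Create an empty multi-object tracker
#'
#' @param config A [tracker_config()].
#' @return A `tracker` object (list) to be threaded through
#'   [tracker_step()].
#' @export
new_tracker <- function(config = tracker_config()) {
  structure(list(config = config, tracks = list(), next_id = 1L,
                 last_frame = -1L),
            class = "tracker")
}

new_track <- function(id, measurement, embedding, label, frame, config) {
  list(id = id,
       status = if (config$n_init <= 1L) "confirmed" else "tentative",
       kf = kalman_initiate(measurement),
       gallery = matrix(embedding / sqrt(sum(embedding^2)), nrow = 1L),
       votes = stats::setNames(as.integer(transplant_states() == label),
                               transplant_states()),
       last_seen = stats::setNames(as.integer(transplant_states() == label),
                                   transplant_states()),
       vote_seq = 1L,
       hits = 1L, time_since_update = 0L, age = 1L, born = frame)
}

# Majority vote over observed detection labels; a tie between leading
# classes goes to the one observed most recently.
track_label <- function(track) {
  v <- track$votes
  top <- names(v)[v == max(v)]
  if (length(top) == 1L) return(top)
  top[which.max(track$last_seen[top])]
}

track_box <- function(track) {
  cah_to_box(track$kf$mean[1:4])
}

#' Cascade matching of tracks to detections
#'
#' Association proceeds in two stages. First, confirmed tracks are
#' matched by appearance in rounds of increasing time-since-update
#' (the matching cascade), so recently seen tracks get priority; the
#' appearance cost of a pair is the minimum cosine distance between the
#' detection embedding and the track's gallery, and pairs whose squared
#' Mahalanobis motion distance exceeds the gate can never match
#' regardless of appearance. Second, the leftovers — tentative tracks
#' plus confirmed tracks unmatched for exactly one frame — are matched
#' against remaining detections by IoU cost (`1 - IoU`, matches require
#' IoU >= `iou_threshold`). Each stage solves a Hungarian assignment.
#'
#' @param tracks List of track records (internal representation held by a
#'   `tracker`), already predicted to the current frame.
#' @param boxes Numeric matrix of detection boxes, one `x1,y1,x2,y2` row
#'   per detection.
#' @param embeddings Numeric matrix of detection embeddings, one row per
#'   detection.
#' @param config A [tracker_config()].
#' @return List with `matches` (integer matrix with columns `track`,
#'   `detection`), `unmatched_tracks`, `unmatched_detections` (indices).
#' @export
cascade_match <- function(tracks, boxes, embeddings, config) {
  n_trk <- length(tracks)
  n_det <- if (is.null(boxes)) 0L else nrow(boxes)
  no_match <- cbind(track = integer(), detection = integer())
  if (n_trk == 0L || n_det == 0L)
    return(list(matches = no_match,
                unmatched_tracks = seq_len(n_trk),
                unmatched_detections = seq_len(n_det)))

  status <- vapply(tracks, `[[`, "", "status")
  tsu <- vapply(tracks, `[[`, 0L, "time_since_update")
  confirmed <- which(status == "confirmed")
  unconfirmed <- which(status != "confirmed")
  meas <- t(vapply(seq_len(n_det),
                   function(i) box_to_cah(boxes[i, ]), numeric(4)))

  matches <- no_match
  unmatched_det <- seq_len(n_det)
  BIG <- config$max_cosine_distance + 1e-5

  # stage 1: appearance cascade over confirmed tracks by age
  for (level in seq_len(config$max_age)) {
    if (length(unmatched_det) == 0L) break
    cand <- confirmed[tsu[confirmed] == level]
    if (length(cand) == 0L) next
    cost <- matrix(BIG, length(cand), length(unmatched_det))
    for (ti in seq_along(cand)) {
      trk <- tracks[[cand[[ti]]]]
      gate <- kalman_gating_distance(trk$kf, meas[unmatched_det, , drop = FALSE])
      for (di in seq_along(unmatched_det)) {
        if (gate[[di]] > config$gating_threshold) next
        d <- min(cosine_distance_many(trk$gallery,
                                      embeddings[unmatched_det[[di]], ]))
        cost[ti, di] <- min(d, BIG)
      }
    }
    sol <- linear_assignment(cost, max_cost = config$max_cosine_distance)
    if (nrow(sol$matches) > 0L) {
      matches <- rbind(matches,
                       cbind(track = cand[sol$matches[, 1L]],
                             detection = unmatched_det[sol$matches[, 2L]]))
      unmatched_det <- unmatched_det[-sol$matches[, 2L]]
    }
  }

  # stage 2: IoU association for tentative tracks and just-missed
  # confirmed tracks
  matched_tracks <- matches[, 1L]
  iou_cand <- c(unconfirmed,
                setdiff(confirmed[tsu[confirmed] == 1L], matched_tracks))
  iou_cand <- sort(iou_cand)
  if (length(iou_cand) > 0L && length(unmatched_det) > 0L) {
    cost <- matrix(1, length(iou_cand), length(unmatched_det))
    det_boxes <- boxes[unmatched_det, , drop = FALSE]
    for (ti in seq_along(iou_cand)) {
      cost[ti, ] <- 1 - iou_one_many(track_box(tracks[[iou_cand[[ti]]]]), det_boxes)
    }
    sol <- linear_assignment(cost, max_cost = 1 - config$iou_threshold)
    if (nrow(sol$matches) > 0L) {
      matches <- rbind(matches,
                       cbind(track = iou_cand[sol$matches[, 1L]],
                             detection = unmatched_det[sol$matches[, 2L]]))
      unmatched_det <- unmatched_det[-sol$matches[, 2L]]
    }
  }

  list(matches = matches,
       unmatched_tracks = setdiff(seq_len(n_trk), matches[, 1L]),
       unmatched_detections = unmatched_det)
}

#' Advance the tracker by one frame
#'
#' Runs one cycle of the tracking loop: predict every track forward with
#' its Kalman filter, associate the frame's detections via
#' [cascade_match()], update matched tracks (filter update, gallery
#' append, class vote, hit count), spawn tentative tracks from unmatched
#' detections, and age out the rest. A tentative track is confirmed after
#' `n_init` consecutive hits and dropped at its first miss; a confirmed
#' track unmatched for more than `max_age` frames is deleted and its id
#' is never reused.
#'
#' @param tracker A `tracker` from [new_tracker()] (or a previous step).
#' @param detections Data frame with columns `frame`, `cname`, `conf`,
#'   `x1`, `y1`, `x2`, `y2`, all rows from the same frame; the frame index
#'   must be strictly greater than the previous step's.
#' @param embeddings Numeric matrix, one appearance embedding per
#'   detection row; `NULL` disables appearance matching (a constant
#'   embedding is substituted, so association falls back to motion + IoU).
#' @param frame Frame index when `detections` has zero rows (otherwise
#'   taken from the data).
#' @return List with `tracker` (updated state) and `tracks`: a data frame
#'   of the active confirmed tracks at this frame with columns `frame`,
#'   `cname` (majority-vote state), `id`, `x1`, `y1`, `x2`, `y2`,
#'   `time_since_update`.
#' @export
tracker_step <- function(tracker, detections, embeddings = NULL, frame = NULL) {
  cfg <- tracker$config
  if (nrow(detections) > 0L) {
    f <- unique(as.integer(detections$frame))
    if (length(f) != 1L)
      stop("all detections passed to tracker_step must share one frame index",
           call. = FALSE)
    frame <- f
  } else if (is.null(frame)) {
    frame <- tracker$last_frame + 1L
  }
  frame <- as.integer(frame)
  if (frame <= tracker$last_frame)
    stop("non-monotone frame index: got ", frame, " after ",
         tracker$last_frame, call. = FALSE)
  tracker$last_frame <- frame

  keep <- detections$conf >= cfg$min_confidence
  detections <- detections[keep, , drop = FALSE]
  if (!is.null(embeddings)) {
    embeddings <- embeddings[keep, , drop = FALSE]
  } else {
    d <- 8L
    embeddings <- matrix(rep(c(1, rep(0, d - 1L)), each = nrow(detections)),
                         nrow = nrow(detections))
  }
  n_det <- nrow(detections)
  boxes <- if (n_det > 0L)
    as.matrix(detections[, c("x1", "y1", "x2", "y2")]) else NULL

  # predict
  tracker$tracks <- lapply(tracker$tracks, function(trk) {
    trk$kf <- kalman_predict(trk$kf)
    trk$age <- trk$age + 1L
    trk$time_since_update <- trk$time_since_update + 1L
    trk
  })

  assoc <- cascade_match(tracker$tracks, boxes, embeddings, cfg)

  # update matched tracks
  if (nrow(assoc$matches) > 0L) {
    for (k in seq_len(nrow(assoc$matches))) {
      ti <- assoc$matches[k, 1L]; di <- assoc$matches[k, 2L]
      trk <- tracker$tracks[[ti]]
      trk$kf <- kalman_update(trk$kf, box_to_cah(boxes[di, ]))
      e <- embeddings[di, ]
      trk$gallery <- rbind(trk$gallery, e / sqrt(sum(e^2)))
      if (nrow(trk$gallery) > cfg$nn_budget)
        trk$gallery <- trk$gallery[
          (nrow(trk$gallery) - cfg$nn_budget + 1L):nrow(trk$gallery), ,
          drop = FALSE]
      lab <- detections$cname[[di]]
      trk$votes[[lab]] <- trk$votes[[lab]] + 1L
      trk$vote_seq <- trk$vote_seq + 1L
      trk$last_seen[[lab]] <- trk$vote_seq
      trk$hits <- trk$hits + 1L
      trk$time_since_update <- 0L
      if (trk$status == "tentative" && trk$hits >= cfg$n_init)
        trk$status <- "confirmed"
      tracker$tracks[[ti]] <- trk
    }
  }

  # age out unmatched tracks
  deleted <- logical(length(tracker$tracks))
  for (ti in assoc$unmatched_tracks) {
    trk <- tracker$tracks[[ti]]
    if (trk$status == "tentative" || trk$time_since_update > cfg$max_age)
      deleted[[ti]] <- TRUE
  }
  tracker$tracks <- tracker$tracks[!deleted]

  # spawn tentative tracks from unmatched detections
  for (di in assoc$unmatched_detections) {
    tracker$tracks[[length(tracker$tracks) + 1L]] <-
      new_track(tracker$next_id, box_to_cah(boxes[di, ]), embeddings[di, ],
                detections$cname[[di]], frame, cfg)
    tracker$next_id <- tracker$next_id + 1L
  }

  list(tracker = tracker, tracks = active_tracks(tracker, frame))
}

active_tracks <- function(tracker, frame) {
  keep <- Filter(function(trk) trk$status == "confirmed", tracker$tracks)
  if (length(keep) == 0L) {
    return(data.frame(frame = integer(), cname = character(), id = integer(),
                      x1 = numeric(), y1 = numeric(), x2 = numeric(),
                      y2 = numeric(), time_since_update = integer(),
                      stringsAsFactors = FALSE))
  }
  boxes <- t(vapply(keep, track_box, numeric(4)))
  data.frame(
    frame = frame,
    cname = vapply(keep, track_label, ""),
    id = vapply(keep, `[[`, 0L, "id"),
    x1 = boxes[, 1L], y1 = boxes[, 2L], x2 = boxes[, 3L], y2 = boxes[, 4L],
    time_since_update = vapply(keep, `[[`, 0L, "time_since_update"),
    stringsAsFactors = FALSE
  )
}

#' Run the tracker over a full detection stream
#'
#' Convenience driver: groups a detection data frame by frame index,
#' steps the tracker through every frame in ascending order (including
#' empty frames between the first and last), and concatenates the active
#' confirmed tracks of every frame into one DarkLabel-compatible dump.
#'
#' @param detections Detection data frame (see [read_detections()]).
#' @param embeddings Optional numeric matrix of embeddings aligned with
#'   `detections` rows.
#' @param config A [tracker_config()].
#' @return Data frame `frame`, `cname`, `id`, `x1`, `y1`, `x2`, `y2`,
#'   `time_since_update` over all frames (writable with
#'   [write_darklabel_csv()]).
#' @export
track_detections <- function(detections, embeddings = NULL,
                             config = tracker_config()) {
  if (nrow(detections) == 0L) return(active_tracks(new_tracker(config), 0L)[0L, ])
  frames <- seq(min(detections$frame), max(detections$frame))
  trk <- new_tracker(config)
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    rows <- which(detections$frame == f)
    step <- tracker_step(trk, detections[rows, , drop = FALSE],
                         if (is.null(embeddings)) NULL
                         else embeddings[rows, , drop = FALSE],
                         frame = f)
    trk <- step$tracker
    out[[i]] <- step$tracks
  }
  do.call(rbind, out)
}
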