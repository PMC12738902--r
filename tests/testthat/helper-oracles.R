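# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the implementation it checks.

# Exhaustive minimum-cost assignment by enumerating all permutations of
# the smaller dimension (feasible for n <= 6).
brute_force_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  transposed <- nr > nc
  C <- if (transposed) t(cost) else cost
  n <- nrow(C); m <- ncol(C)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[[i]], p)
    }
    out
  }
  best <- Inf
  for (cols in utils::combn(m, n, simplify = FALSE)) {
    for (p in perms(cols)) {
      s <- sum(C[cbind(seq_len(n), p)])
      if (s < best) best <- s
    }
  }
  best
}

# Textbook Kalman recursion with explicit matrix inversion via solve();
# same model parameters as the package filter, different numerics.
textbook_kalman <- function(state, measurements) {
  F8 <- diag(8); F8[1:4, 5:8] <- diag(4)
  H <- cbind(diag(4), matrix(0, 4, 4))
  wp <- 1 / 20; wv <- 1 / 160
  mean <- state$mean; P <- state$cov
  for (i in seq_len(nrow(measurements))) {
    h <- mean[[4]]
    Q <- diag(c(wp * h, wp * h, 1e-2, wp * h,
                wv * h, wv * h, 1e-5, wv * h)^2)
    mean <- as.numeric(F8 %*% mean)
    P <- F8 %*% P %*% t(F8) + Q
    h <- mean[[4]]
    R <- diag(c(wp * h, wp * h, 1e-1, wp * h)^2)
    S <- H %*% P %*% t(H) + R
    K <- P %*% t(H) %*% solve(S)
    mean <- mean + as.numeric(K %*% (measurements[i, ] - H %*% mean))
    P <- P - K %*% H %*% P
  }
  list(mean = mean, cov = P)
}

# Average precision by direct enumeration: walk every prefix of the
# confidence-ranked prediction list, record (recall, precision) points,
# and integrate the running-maximum precision over recall increments.
ap_enumerate <- function(tp_flags, n_gt) {
  n <- length(tp_flags)
  pts <- data.frame(recall = 0, precision = 1)
  for (k in seq_len(n)) {
    tp <- sum(tp_flags[seq_len(k)])
    pts <- rbind(pts, data.frame(recall = tp / n_gt, precision = tp / k))
  }
  ap <- 0
  for (k in 2:nrow(pts)) {
    dr <- pts$recall[[k]] - pts$recall[[k - 1L]]
    if (dr > 0) {
      # best precision attainable at recall >= current level
      env <- max(pts$precision[pts$recall >= pts$recall[[k]]])
      ap <- ap + dr * env
    }
  }
  ap
}

# Identity switches of a track dump against ground-truth trajectories:
# per frame each truth box is matched to the predicted box of highest
# IoU (>= 0.5); a switch is an id change in a truth plant's matched
# sequence. Also returns the number of distinct matched predicted ids.
count_id_switches <- function(tracks, truth) {
  matched <- list()
  for (f in sort(unique(truth$frame))) {
    tr <- truth[truth$frame == f, , drop = FALSE]
    pr <- tracks[tracks$frame == f, , drop = FALSE]
    if (nrow(pr) == 0L) next
    pb <- as.matrix(pr[, c("x1", "y1", "x2", "y2")])
    for (i in seq_len(nrow(tr))) {
      ious <- apply(pb, 1L, function(b)
        transplantQC::iou(c(tr$x1[[i]], tr$y1[[i]], tr$x2[[i]], tr$y2[[i]]), b))
      j <- which.max(ious)
      if (ious[[j]] >= 0.5) {
        key <- as.character(tr$id[[i]])
        matched[[key]] <- c(matched[[key]], pr$id[[j]])
      }
    }
  }
  switches <- sum(vapply(matched, function(ids) sum(diff(ids) != 0), 0))
  list(switches = switches,
       n_pred_ids = length(unique(unlist(matched))))
}

random_box <- function() {
  x1 <- runif(1, 0, 80); y1 <- runif(1, 0, 80)
  c(x1, y1, x1 + runif(1, 1, 40), y1 + runif(1, 1, 40))
}

table4_fixture <- function() {
  read_count_table(system.file("extdata", "video_counts.csv",
                               package = "transplantQC"))
}
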