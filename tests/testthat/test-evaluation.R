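test_that("precision, recall and F1 follow the standard ratios", {
  expect_equal(precision_score(10, 10), 0.5)
  expect_equal(recall_score(10, 10), 0.5)
  expect_equal(f1_score(10, 10, 10), 0.5)
  expect_equal(f1_score(10, 0, 0), 1)
  # P = 0.8, R = 0.6 -> harmonic mean 24/35
  expect_equal(2 * 0.8 * 0.6 / (0.8 + 0.6), 24 / 35)
  expect_equal(f1_score(24, 6, 16), 24 / 35)
  expect_true(is.na(precision_score(0, 0)))
  expect_true(is.na(recall_score(0, 0)))
})

test_that("average precision traces the interpolated PR curve", {
  gt <- data.frame(image = 1L, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  hit <- data.frame(image = 1L, score = 0.9, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  miss <- data.frame(image = 1L, score = 0.8, x1 = 50, y1 = 50, x2 = 60, y2 = 60)
  # all predictions correct
  expect_equal(average_precision(hit, gt), 1)
  # a false positive ranked below the hit does not reduce AP
  expect_equal(average_precision(rbind(hit, miss), gt), 1)
  # a false positive ranked above halves the attainable precision at r=1
  miss$score <- 0.95
  expect_equal(average_precision(rbind(hit, miss), gt), 0.5)
  expect_true(is.na(average_precision(hit, gt[0, ])))
  expect_equal(average_precision(hit[0, ], gt), 0)
})

test_that("AP equals exhaustive PR enumeration on random toy sets", {
  set.seed(29)
  for (rep in 1:30) {
    n_gt <- sample(1:4, 1)
    gt <- do.call(rbind, lapply(seq_len(n_gt), function(i) {
      cx <- 100 * i
      data.frame(image = 1L, x1 = cx, y1 = 0, x2 = cx + 20, y2 = 20)
    }))
    n_pred <- sample(1:8, 1)
    pred <- do.call(rbind, lapply(seq_len(n_pred), function(j) {
      if (runif(1) < 0.6) {           # near a ground-truth box
        i <- sample(n_gt, 1)
        jit <- runif(2, -3, 3)
        data.frame(image = 1L, score = runif(1),
                   x1 = 100 * i + jit[1], y1 = jit[2],
                   x2 = 100 * i + 20 + jit[1], y2 = 20 + jit[2])
      } else {                        # background
        x <- runif(1, 500, 900)
        data.frame(image = 1L, score = runif(1),
                   x1 = x, y1 = 50, x2 = x + 20, y2 = 70)
      }
    }))
    got <- average_precision(pred, gt)
    # oracle: recompute the greedy TP flags, then enumerate the PR curve
    ord <- order(-pred$score)
    p <- pred[ord, ]
    used <- logical(n_gt)
    tp <- numeric(n_pred)
    for (i in seq_len(n_pred)) {
      ious <- vapply(seq_len(n_gt), function(g)
        iou(c(p$x1[i], p$y1[i], p$x2[i], p$y2[i]),
            c(gt$x1[g], gt$y1[g], gt$x2[g], gt$y2[g])), 0)
      ious[used] <- -1
      g <- which.max(ious)
      if (ious[g] >= 0.5) { tp[i] <- 1; used[g] <- TRUE }
    }
    expect_equal(got, ap_enumerate(tp, n_gt), tolerance = 1e-12)
  }
  expect_equal(mean_ap(c(0.9, 0.8, NA)), 0.85)
})

test_that("count error metrics reproduce hand-computed values", {
  expect_equal(rmse(c(6, 2, 1)), sqrt(41 / 3))   # prints as 3.7
  expect_equal(rmse(c(10, 4, 1)), sqrt(39))      # prints as 6.24
  expect_equal(rmse(c(0, 0, 0)), 0)
  expect_equal(mae(c(6, 2, 1)), 3)
  expect_equal(mae(numeric(0)), NA_real_)
})

test_that("RMSE dominates MAE for any error vector", {
  set.seed(31)
  for (rep in 1:100) {
    e <- rnorm(sample(1:10, 1), sd = 5)
    expect_gte(rmse(e), mae(e) - 1e-12)
  }
})

test_that("counting accuracy is the symmetric min/max ratio", {
  expect_equal(mca(169, 163), 100 * 163 / 169)
  expect_equal(mca(18, 20), 90)
  expect_equal(mca(9, 8), 100 * 8 / 9)
  expect_equal(mca(7, 7), 100)
  expect_true(is.na(mca(0, 0)))
  expect_error(mca(-1, 5), "non-negative")
  set.seed(37)
  for (rep in 1:100) {
    a <- sample(1:200, 1); b <- sample(1:200, 1)
    expect_identical(mca(a, b), mca(b, a))
    expect_gt(mca(a, b), 0)
    expect_lte(mca(a, b), 100)
  }
})

test_that("a count-table evaluation aggregates per video and per category", {
  tab <- table4_fixture()
  rep <- evaluate_count_table(tab)
  # a perfect single-video table
  perfect <- data.frame(video = 1L, cname = transplant_states(),
                        manual = c(10L, 2L, 1L), predicted = c(10L, 2L, 1L))
  prep <- evaluate_count_table(perfect)
  expect_equal(prep$overall_mca, 100)
  expect_equal(prep$per_video$rmse, 0)
  expect_equal(prep$per_category$mae, rep(0, 3))
  # the empty-category cell is excluded, not zero-scored
  expect_true(is.na(rep$per_video_category$mca[
    rep$per_video_category$video == 2 &
    rep$per_video_category$cname == "bare_root"]))
  expect_error(evaluate_count_table(perfect[0, ]), "empty")
})
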