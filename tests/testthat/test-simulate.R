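test_that("a noiseless scene emits detections identical to the truth", {
  sc <- simulate_scene(scene_config(n_plants = 8L, frame_size = c(400L, 300L),
                                    miss_prob = 0, fp_rate_per_frame = 0,
                                    jitter_sd = 0, seed = 3L))
  expect_equal(nrow(sc$detections), nrow(sc$truth))
  expect_equal(sc$detections[, c("frame", "cname", "x1", "y1", "x2", "y2")],
               sc$truth[, c("frame", "cname", "x1", "y1", "x2", "y2")],
               ignore_attr = TRUE)
  expect_equal(sc$detections$identity, sc$truth$id)
  expect_true(all(sc$detections$conf >= 0.5 & sc$detections$conf <= 1))
  # every plant enters above the frame and exits below it
  first <- tapply(sc$truth$y1, sc$truth$id, min)
  last <- tapply(sc$truth$y2, sc$truth$id, max)
  expect_true(all(first < 30))
  expect_true(all(last > 270))
})

test_that("scenes are byte-identical under the same config and seed", {
  cfg <- scene_config(n_plants = 10L, miss_prob = 0.2, fp_rate_per_frame = 0.2,
                      jitter_sd = 1.5, seed = 23L)
  a <- simulate_scene(cfg)
  b <- simulate_scene(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$detections, b$detections)
  expect_identical(a$embeddings, b$embeddings)
  # a different seed changes the realization
  c <- simulate_scene(scene_config(n_plants = 10L, miss_prob = 0.2,
                                   fp_rate_per_frame = 0.2, jitter_sd = 1.5,
                                   seed = 24L))
  expect_false(identical(a$detections, c$detections))
})

test_that("the miss rate is binomially calibrated", {
  # ~100 plants x ~96 visible frames each gives ~10^4 Bernoulli trials
  sc <- simulate_scene(scene_config(n_plants = 100L, miss_prob = 0.2,
                                    fp_rate_per_frame = 0, jitter_sd = 0,
                                    embed_dim = 4L, seed = 5L))
  n_vis <- nrow(sc$truth)
  expect_gt(n_vis, 5000)
  frac <- nrow(sc$detections) / n_vis
  tol <- 3 * sqrt(0.8 * 0.2 / n_vis)
  expect_lt(abs(frac - 0.8), tol)
})

test_that("state proportions obey the law of large numbers", {
  # miss_prob = 1 suppresses the detection stream so only the plant
  # population is generated; n = 2000 plants, 3-sigma band per state
  props <- c(normal = 0.82, buried_seedling = 0.11, bare_root = 0.07)
  sc <- simulate_scene(scene_config(n_plants = 2000L, miss_prob = 1,
                                    state_proportions = props,
                                    embed_dim = 4L, seed = 9L))
  expect_equal(nrow(sc$detections), 0L)
  for (s in transplant_states()) {
    p_hat <- sc$true_counts[[s]] / 2000
    expect_lt(abs(p_hat - props[[s]]), 3 * sqrt(props[[s]] * (1 - props[[s]]) / 2000))
  }
})

test_that("exact state splits are honored when requested", {
  sc <- simulate_scene(scene_config(n_plants = 20L,
                                    state_counts = c(normal = 14L,
                                                     buried_seedling = 4L,
                                                     bare_root = 2L),
                                    seed = 2L))
  expect_equal(sc$true_counts,
               c(normal = 14L, buried_seedling = 4L, bare_root = 2L))
  expect_error(scene_config(n_plants = 10L,
                            state_counts = c(normal = 5L, buried_seedling = 4L,
                                             bare_root = 2L)),
               "sum to n_plants")
})

test_that("infeasible geometry is rejected", {
  expect_error(scene_config(plant_spacing_px = 30, box_side_mean = 48),
               "infeasible")
  expect_error(scene_config(state_proportions = c(normal = 0.5,
                                                  buried_seedling = 0.5,
                                                  bare_root = 0.5)),
               "sum to 1")
})

test_that("the pipeline on an empty scene reports zero counts", {
  sc <- simulate_scene(scene_config(n_plants = 0L, seed = 1L))
  res <- run_pipeline(sc)
  expect_equal(res$count_report$total, 0L)
  expect_null(res$count_report$rates)
})

test_that("false positives are suppressed by the tentative-track filter", {
  # clutter-only scene: transient false positives never survive n_init
  sc <- simulate_scene(scene_config(n_plants = 6L, frame_size = c(400L, 300L),
                                    miss_prob = 0, fp_rate_per_frame = 0.5,
                                    jitter_sd = 0, seed = 19L))
  res <- run_pipeline(sc)
  expect_equal(unname(res$count_report$counts[transplant_states()]),
               unname(as.integer(sc$true_counts[transplant_states()])))
})

test_that("true crossing counts honor the line's horizontal span", {
  sc <- simulate_scene(scene_config(n_plants = 10L, frame_size = c(400L, 300L),
                                    seed = 29L))
  full <- true_crossing_counts(sc, counting_line(0, 400, 180))
  expect_equal(sum(full), 10L)
  none <- true_crossing_counts(sc, counting_line(390, 400, 180))
  expect_equal(sum(none), 0L)
})
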