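lat13 <- get_skeleton("lateral_13")
fix50 <- metric_config(k = 0.5, scale_mode = "fixed", fixed_scale = 50)

test_that("instance_scale follows the bbox and fixed conventions", {
  sk <- skeleton("quad", "lateral", c("a", "b", "c", "d"))
  pose <- make_pose(sk, c(0, 30, 0, 30), c(0, 0, 40, 40))
  expect_equal(instance_scale(pose, metric_config()), sqrt(1200))
  expect_identical(instance_scale(pose, metric_config(scale_mode = "fixed",
                                                      fixed_scale = 10)), 10)
  # < 2 visible keypoints in bbox mode
  solo <- make_pose(sk, c(0, 30, 0, 30), c(0, 0, 40, 40),
                    visible = c(TRUE, FALSE, FALSE, FALSE))
  expect_error(instance_scale(solo, metric_config()), "2 visible")
  # collinear keypoints: error by default, floored when configured
  flat <- make_pose(sk, c(0, 10, 20, 30), c(5, 5, 5, 5))
  expect_error(instance_scale(flat, metric_config()), "degenerate")
  expect_identical(instance_scale(flat, metric_config(scale_floor = 2)), 2)
})

test_that("compute_oks matches its closed forms", {
  sk <- skeleton("one", "lateral", "snout")
  cfg <- metric_config(k = 0.5, scale_mode = "fixed", fixed_scale = 10)
  # perfect prediction
  pr <- eval_pair(make_pose(sk, 5, 5), make_pose(sk, 5, 5), cfg)
  expect_identical(compute_oks(pr, cfg), 1)
  # one keypoint at distance s*k*sqrt(2) -> exp(-1)
  d <- 10 * 0.5 * sqrt(2)
  pr <- eval_pair(make_pose(sk, 0, 0), make_pose(sk, d, 0), cfg)
  expect_equal(compute_oks(pr, cfg), exp(-1))
  # a gt-visible keypoint missing from the prediction: 0 in the numerator,
  # 1 in the denominator
  sk2 <- skeleton("two", "lateral", c("a", "b"))
  pr <- eval_pair(make_pose(sk2, c(0, 0), c(0, 1)),
                  make_pose(sk2, c(0, 0), c(0, 1), visible = c(TRUE, FALSE)),
                  cfg)
  expect_equal(compute_oks(pr, cfg), 0.5)
  # no visible gt keypoints is rejected at pairing time
  expect_error(eval_pair(make_pose(sk2, c(0, 0), c(0, 1), visible = c(FALSE, FALSE)),
                         make_pose(sk2, c(0, 0), c(0, 1)), cfg),
               "no visible")
})

test_that("AP / mAP / mAR behave per definition", {
  expect_identical(average_precision(c(1, 1, 1), 0.5), 1)
  expect_equal(average_precision(c(0.96, 0.60, 0.40), 0.5), 2 / 3)
  expect_error(average_precision(numeric(), 0.5), "empty")
  # single instance with OKS 0.72 on the default grid -> mAP 0.5
  mm <- mean_average_precision(0.72)
  expect_equal(mm$map, 0.5)
  expect_identical(mean_average_precision(rep(1, 4))$map, 1)
  expect_identical(mean_average_precision(rep(1, 4))$mar, 1)
  # unpredicted instances count against recall only
  mm2 <- mean_average_precision(c(1, 1), n_gt = 4)
  expect_identical(mm2$map, 1)
  expect_identical(mm2$mar, 0.5)
  # AP non-increasing in T; brute-force equality on a random list
  set.seed(21)
  oks <- runif(200)
  grid <- metric_config()$oks_thresholds
  ap <- vapply(grid, function(T) average_precision(oks, T), numeric(1))
  expect_true(all(diff(ap) <= 0))
  for (i in seq_along(grid))
    expect_identical(ap[i], oracle_ap(oks, grid[i]))
  expect_identical(mean_average_precision(oks)$map, oracle_map(oks, grid))
})

test_that("distance_average and PCK match their definitions", {
  sk2 <- skeleton("two", "lateral", c("a", "b"))
  cfg <- metric_config(scale_mode = "fixed", fixed_scale = 100)
  pr <- eval_pair(make_pose(sk2, c(0, 0), c(0, 50)),
                  make_pose(sk2, c(3, 0), c(0, 55)), cfg)
  expect_equal(distance_average(pr), 4)  # distances 3 and 5
  expect_identical(distance_average(eval_pair(make_pose(sk2, c(0, 0), c(0, 9)),
                                              make_pose(sk2, c(0, 0), c(0, 9)),
                                              cfg)), 0)
  # PCK: perfect prediction -> 1 everywhere; boundary d/s == alpha is incorrect
  perfect <- eval_pair(make_pose(sk2, c(1, 2), c(3, 40)),
                       make_pose(sk2, c(1, 2), c(3, 40)), cfg)
  expect_equal(unname(pck(list(perfect), cfg)$pck_by_keypoint), c(1, 1))
  boundary <- eval_pair(make_pose(sk2, c(0, 0), c(0, 50)),
                        make_pose(sk2, c(5, 0), c(0, 50)), cfg)
  # d/s = 5/100 = alpha exactly -> strict '<' counts it incorrect
  pk <- pck(list(boundary), metric_config(scale_mode = "fixed",
                                          fixed_scale = 100, pck_alpha = 0.05))
  expect_identical(unname(pk$pck_by_keypoint["a"]), 0)
  expect_error(metric_config(pck_alpha = 0), "pck_alpha")
})

test_that("vectorized metrics equal brute-force oracles to 1e-12", {
  pairs <- make_random_pairs(20, lat13, sigma = 6, fix50, seed = 77,
                             vis_prob = 0.85, miss_prob = 0.1)
  oks <- vapply(pairs, compute_oks, numeric(1), cfg = fix50)
  for (i in seq_along(pairs))
    expect_equal(oks[i], oracle_oks(pairs[[i]], s = 50, k = 0.5),
                 tolerance = 1e-12)
  mm <- mean_average_precision(oks, fix50)
  expect_equal(mm$map, oracle_map(oks, fix50$oks_thresholds), tolerance = 1e-12)
  expect_equal(distance_average(pairs), oracle_dist_avg(pairs),
               tolerance = 1e-12)
  pk <- pck(pairs, fix50)
  ora <- oracle_pck(pairs, fix50$pck_alpha)
  expect_equal(pk$pck_by_keypoint[names(ora)], ora, tolerance = 1e-12)
})

test_that("per-keypoint errors and ranking recover the noisy keypoint", {
  sk3 <- skeleton("tri", "lateral", c("a", "b", "c"))
  cfg <- metric_config(scale_mode = "fixed", fixed_scale = 50)
  set.seed(5)
  sig <- c(2, 2, 6)
  pairs <- lapply(1:10000, function(i) {
    gx <- runif(3, 0, 100); gy <- runif(3, 0, 100)
    eval_pair(make_pose(sk3, gx, gy),
              make_pose(sk3, gx + rnorm(3, 0, sig), gy + rnorm(3, 0, sig)),
              cfg)
  })
  errs <- per_keypoint_pixel_errors(pairs)
  expect_true(all(abs(errs$summary$mean - sig * sqrt(pi / 2)) < 0.15))
  expect_identical(rank_keypoints_by_error(errs)[1], "c")
  # never-predicted keypoint: empty sample, full missing count
  drop_b <- lapply(1:20, function(i) {
    gx <- runif(3); gy <- runif(3)
    eval_pair(make_pose(sk3, gx, gy),
              make_pose(sk3, gx, gy, visible = c(TRUE, FALSE, TRUE)), cfg)
  })
  eb <- per_keypoint_pixel_errors(drop_b)
  expect_identical(eb$summary$n[2], 0L)
  expect_identical(eb$summary$n_missing[2], 20L)
  # identical sigmas -> stable input-order tie break
  zero <- lapply(1:5, function(i)
    eval_pair(make_pose(sk3, c(1, 2, 3), c(1, 2, 3)),
              make_pose(sk3, c(1, 2, 3), c(1, 2, 3)), cfg))
  expect_identical(rank_keypoints_by_error(per_keypoint_pixel_errors(zero)),
                   c("a", "b", "c"))
  single <- per_keypoint_pixel_errors(list(eval_pair(
    make_pose(skeleton("s1", "lateral", "a"), 1, 1),
    make_pose(skeleton("s1", "lateral", "a"), 1, 1),
    metric_config(scale_mode = "fixed", fixed_scale = 10))))
  expect_error(rank_keypoints_by_error(single), ">= 2 keypoints")
})

test_that("evaluate aggregates sequences end to end", {
  p <- gait_params(1, occlusion_prob = 0)
  gt <- simulate_sequence(p, lat13, 30, seed = 6, video_id = "v1")
  # identical prediction -> perfect report
  perfect <- evaluate(gt, gt, fix50)
  expect_identical(unique(perfect$oks_values), 1)
  expect_identical(perfect$map, 1)
  expect_identical(perfect$dist_avg, 0)
  expect_identical(perfect$pck_mean, 1)
  # disjoint ids -> error; frame mismatch -> error
  gt2 <- simulate_sequence(p, lat13, 30, seed = 7, video_id = "v2")
  expect_error(evaluate(gt, gt2, fix50), "unmatched video ids")
  short <- simulate_sequence(p, lat13, 20, seed = 6, video_id = "v1")
  expect_error(evaluate(gt, short, fix50), "frame count mismatch")
  # translation invariance of the full report
  pred <- apply_prediction_error(gt, prediction_error_model(sd = 3), seed = 8)
  shift <- function(s, dx, dy)
    tracked_sequence(s$video_id, s$skeleton, s$x + dx, s$y + dy, s$visible,
                     s$frames)
  cfg <- metric_config()
  base <- evaluate(gt, pred, cfg)
  moved <- evaluate(shift(gt, 37, -12), shift(pred, 37, -12), cfg)
  expect_equal(base$oks_values, moved$oks_values)
  expect_equal(base$dist_avg, moved$dist_avg)
  expect_equal(base$pck_by_keypoint, moved$pck_by_keypoint)
  # scale covariance: OKS and PCK unchanged, dist_avg scaled
  scale_seq <- function(s, c)
    tracked_sequence(s$video_id, s$skeleton, s$x * c, s$y * c, s$visible,
                     s$frames)
  scaled <- evaluate(scale_seq(gt, 2), scale_seq(pred, 2), cfg)
  expect_equal(base$oks_values, scaled$oks_values)
  expect_equal(base$pck_mean, scaled$pck_mean)
  expect_equal(scaled$dist_avg, 2 * base$dist_avg)
})
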