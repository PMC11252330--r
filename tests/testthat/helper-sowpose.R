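# Shared fixtures and independent brute-force oracles.  The oracles are
# written as plain loops over the metric definitions and never call the
# package's vectorized implementations.

make_pose <- function(skeleton, x, y, visible = rep(TRUE, length(x))) {
  instance_pose(skeleton, x, y, visible)
}

# random gt/pred pose pairs with isotropic Gaussian error
make_random_pairs <- function(n, skeleton, sigma, cfg, seed,
                              vis_prob = 1, miss_prob = 0) {
  set.seed(seed)
  k <- length(skeleton$keypoints)
  lapply(seq_len(n), function(i) {
    gx <- runif(k, 100, 500); gy <- runif(k, 100, 500)
    vis <- runif(k) < vis_prob
    if (!any(vis)) vis[sample.int(k, 2)] <- TRUE
    if (sum(vis) < 2) vis[which(!vis)[1]] <- TRUE
    px <- gx + rnorm(k, 0, sigma); py <- gy + rnorm(k, 0, sigma)
    pvis <- runif(k) >= miss_prob
    eval_pair(make_pose(skeleton, gx, gy, vis),
              make_pose(skeleton, px, py, pvis), cfg)
  })
}

# --- oracles -------------------------------------------------------------

oracle_oks <- function(pair, s, k) {
  num <- 0; den <- 0
  for (i in seq_along(pair$d)) {
    if (!pair$gt_visible[i]) next
    den <- den + 1
    if (is.finite(pair$d[i]))
      num <- num + exp(-unname(pair$d[i])^2 / (2 * s^2 * k^2))
  }
  unname(num / den)
}

oracle_ap <- function(oks, T) {
  hits <- 0
  for (o in oks) if (o >= T) hits <- hits + 1
  hits / length(oks)
}

oracle_map <- function(oks, thresholds) {
  total <- 0
  for (T in thresholds) total <- total + oracle_ap(oks, T)
  total / length(thresholds)
}

oracle_dist_avg <- function(pairs) {
  acc <- c()
  for (p in pairs)
    for (i in seq_along(p$d))
      if (p$gt_visible[i] && p$predicted[i] && is.finite(p$d[i]))
        acc <- c(acc, p$d[i])
  mean(acc)
}

oracle_pck <- function(pairs, alpha) {
  kp <- pairs[[1]]$skeleton$keypoints
  res <- numeric(0)
  for (j in seq_along(kp)) {
    hits <- 0; n <- 0
    for (p in pairs) {
      if (!p$gt_visible[j]) next
      n <- n + 1
      if (is.finite(p$d[j]) && p$d[j] / p$s < alpha) hits <- hits + 1
    }
    if (n > 0) res[kp[j]] <- hits / n
  }
  res
}

# single-keypoint sequence pair with known Gaussian error, for the
# closed-form metric oracles
gaussian_error_run <- function(n, sigma, seed) {
  sk <- skeleton(sprintf("probe_%d", n), "lateral", "snout")
  gt <- tracked_sequence("probe", sk,
                         matrix(200, n, 1), matrix(300, n, 1),
                         matrix(TRUE, n, 1))
  pred <- apply_prediction_error(gt, prediction_error_model(sd = sigma),
                                 seed = seed)
  list(gt = gt, pred = pred)
}
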