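# Keypoint evaluation metrics: object keypoint similarity (OKS), AP/mAP/mAR
# over an OKS threshold grid, average pixel distance, PCK and per-keypoint
# pixel-error summaries.
#
# OKS = sum_i exp(-d_i^2 / (2 s^2 k_i^2)) delta(v_i > 0) / sum_i delta(v_i > 0)
# with d_i the prediction error in px, v_i the ground-truth visibility flag,
# s the instance scale and k_i a per-keypoint falloff constant.  AP at
# threshold T is implemented as the fraction of instances with OKS >= T
# (the printed formula's "<" would reward bad predictions; see vignette).
# PCK_i is the fraction of targets with d_i / s_n < alpha (strict).

#' Metric configuration
#'
#' @param k Per-keypoint falloff constant(s): scalar or named vector.  The
#'   source study does not publish its values; the default 0.1 is uniform
#'   and fully configurable.
#' @param scale_mode `"bbox_sqrt_area"` (default: square root of the tight
#'   bounding-box area over visible ground-truth keypoints) or `"fixed"`.
#' @param fixed_scale Instance scale in px when `scale_mode = "fixed"`.
#' @param oks_thresholds Ordered OKS thresholds for AP/AR (default
#'   0.50-0.95 step 0.05).
#' @param pck_alpha PCK correctness threshold alpha (> 0; the literature's
#'   working range is 0.05-0.3).
#' @param scale_floor Optional lower bound for the bbox scale; degenerate
#'   (zero-area) boxes are errors when unset.
#' @return An object of class `metric_config`.
#' @export
metric_config <- function(k = 0.1, scale_mode = c("bbox_sqrt_area", "fixed"),
                          fixed_scale = NULL,
                          oks_thresholds = seq(0.5, 0.95, by = 0.05),
                          pck_alpha = 0.05, scale_floor = NULL) {
  scale_mode <- match.arg(scale_mode)
  if (any(k <= 0) || anyNA(k)) stop_validation("`k` must be positive")
  if (scale_mode == "fixed") {
    if (is.null(fixed_scale)) stop_validation("fixed scale mode needs `fixed_scale`")
    assert_scalar_number(fixed_scale, "fixed_scale", lower = 1e-12)
  }
  if (length(oks_thresholds) == 0L)
    stop_validation("`oks_thresholds` must be nonempty")
  if (any(oks_thresholds <= 0 | oks_thresholds > 1))
    stop_validation("OKS thresholds must lie in (0, 1]")
  assert_scalar_number(pck_alpha, "pck_alpha", lower = 1e-12)
  if (!is.null(scale_floor)) assert_scalar_number(scale_floor, "scale_floor", lower = 0)
  structure(list(k = k, scale_mode = scale_mode, fixed_scale = fixed_scale,
                 oks_thresholds = sort(oks_thresholds),
                 pck_alpha = pck_alpha, scale_floor = scale_floor),
            class = "metric_config")
}

.k_for <- function(cfg, keypoints) {
  k <- cfg$k
  if (length(k) == 1L && is.null(names(k)))
    return(stats::setNames(rep(k, length(keypoints)), keypoints))
  if (is.null(names(k)) || !all(keypoints %in% names(k)))
    stop_validation("per-keypoint `k` must name every skeleton keypoint")
  k[keypoints]
}

#' Instance scale of a ground-truth pose
#'
#' In `"bbox_sqrt_area"` mode: the square root of the area of the tight
#' axis-aligned bounding box over visible ground-truth keypoints (the
#' sow-sized analogue of the COCO person scale).  In `"fixed"` mode the
#' configured constant is returned regardless of the pose.
#'
#' @param gt Ground-truth `instance_pose`.
#' @param cfg A [metric_config()].
#' @return Scale in px.
#' @export
instance_scale <- function(gt, cfg = metric_config()) {
  if (!inherits(gt, "instance_pose")) stop_validation("`gt` must be an instance_pose")
  if (cfg$scale_mode == "fixed") return(cfg$fixed_scale)
  vis <- gt$visible
  if (sum(vis) < 2L)
    stop_validation("bbox scale needs >= 2 visible keypoints (got %d)", sum(vis))
  w <- diff(range(gt$coords[vis, "x"]))
  h <- diff(range(gt$coords[vis, "y"]))
  s <- sqrt(w * h)
  if (s <= 0) {
    if (is.null(cfg$scale_floor))
      stop_validation("degenerate (zero-area) bounding box; set `scale_floor`")
    s <- cfg$scale_floor
  }
  max(s, if (is.null(cfg$scale_floor)) 0 else cfg$scale_floor)
}

#' Pair a ground-truth and a predicted pose
#'
#' Computes the per-keypoint Euclidean error `d_i` (defined where the
#' ground truth is visible; `Inf` marks a keypoint missing from the
#' prediction) and the instance scale `s`.
#'
#' @param gt,pred `instance_pose`s on the same skeleton.
#' @param cfg A [metric_config()].
#' @return An object of class `eval_pair` with fields `d` (named vector),
#'   `gt_visible`, `predicted`, `s`, `skeleton`.
#' @export
eval_pair <- function(gt, pred, cfg = metric_config()) {
  if (!inherits(gt, "instance_pose") || !inherits(pred, "instance_pose"))
    stop_validation("`gt` and `pred` must be instance_poses")
  if (!identical(gt$skeleton$keypoints, pred$skeleton$keypoints))
    stop_validation("gt and pred are on different skeletons")
  if (!any(gt$visible))
    stop_validation("no visible ground-truth keypoints in instance")
  d <- sqrt((gt$coords[, "x"] - pred$coords[, "x"])^2 +
            (gt$coords[, "y"] - pred$coords[, "y"])^2)
  d[!pred$visible] <- Inf          # missing prediction
  d[!gt$visible] <- NA_real_       # undefined: no ground truth
  names(d) <- gt$skeleton$keypoints
  structure(list(d = d, gt_visible = gt$visible, predicted = pred$visible,
                 s = instance_scale(gt, cfg), skeleton = gt$skeleton),
            class = "eval_pair")
}

#' Object keypoint similarity of one instance
#'
#' Ground-truth-visible keypoints missing from the prediction contribute 0
#' to the numerator and 1 to the denominator.
#'
#' @param pair An [eval_pair()].
#' @param cfg A [metric_config()].
#' @return OKS in `[0, 1]`.
#' @export
compute_oks <- function(pair, cfg = metric_config()) {
  if (!inherits(pair, "eval_pair")) stop_validation("`pair` must be an eval_pair")
  vis <- pair$gt_visible
  if (!any(vis)) stop_validation("no visible ground-truth keypoints")
  k <- .k_for(cfg, pair$skeleton$keypoints)
  term <- exp(-pair$d[vis]^2 / (2 * pair$s^2 * k[vis]^2))
  term[!is.finite(pair$d[vis])] <- 0
  sum(term) / sum(vis)
}

#' Average precision at one OKS threshold
#'
#' Fraction of predicted instances whose OKS meets the threshold
#' (`OKS >= T`); the standard true-positive counting, see the vignette for
#' the printed-formula discrepancy.
#'
#' @param oks_values Nonempty numeric vector of per-instance OKS values.
#' @param T Threshold in `(0, 1]`.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(oks_values, T) {
  if (length(oks_values) == 0L) stop_validation("empty OKS list")
  assert_scalar_number(T, "T", lower = 1e-12, upper = 1)
  mean(oks_values >= T)
}

#' Mean average precision and recall over the threshold grid
#'
#' `mAP` is the mean over thresholds of [average_precision()]; `mAR` is
#' the mean over thresholds of recall, where recall at `T` counts
#' ground-truth instances matched at `OKS >= T` over all ground-truth
#' instances (`n_gt`); unpredicted instances count against recall only.
#'
#' @param oks_values Per-instance OKS values of predicted instances.
#' @param cfg A [metric_config()].
#' @param n_gt Total number of ground-truth instances (defaults to
#'   `length(oks_values)`).
#' @return List with `ap_by_threshold`, `map`, `recall_by_threshold`, `mar`.
#' @export
mean_average_precision <- function(oks_values, cfg = metric_config(),
                                   n_gt = length(oks_values)) {
  if (length(cfg$oks_thresholds) == 0L) stop_validation("empty threshold set")
  if (length(oks_values) == 0L) stop_validation("empty OKS list")
  if (n_gt < length(oks_values))
    stop_validation("`n_gt` cannot be smaller than the number of predictions")
  ap <- vapply(cfg$oks_thresholds, function(T) average_precision(oks_values, T),
               numeric(1))
  rec <- vapply(cfg$oks_thresholds, function(T) sum(oks_values >= T) / n_gt,
                numeric(1))
  names(ap) <- names(rec) <- sprintf("%.2f", cfg$oks_thresholds)
  list(ap_by_threshold = ap, map = mean(ap),
       recall_by_threshold = rec, mar = mean(rec))
}

.pair_list <- function(pairs) {
  if (inherits(pairs, "eval_pair")) pairs <- list(pairs)
  if (!length(pairs) || !all(vapply(pairs, inherits, logical(1), "eval_pair")))
    stop_validation("`pairs` must be a list of eval_pair objects")
  pairs
}

#' Average pixel distance
#'
#' Mean Euclidean error over all (instance, keypoint) cells where the
#' ground truth is visible and a prediction is present.
#'
#' @param pairs List of [eval_pair()]s (or a single one).
#' @return Mean distance in px.
#' @export
distance_average <- function(pairs) {
  pairs <- .pair_list(pairs)
  d <- unlist(lapply(pairs, function(p) p$d[p$gt_visible & p$predicted]))
  d <- d[is.finite(d)]
  if (length(d) == 0L) stop_validation("no evaluable keypoints")
  mean(d)
}

#' Percentage of correct keypoints
#'
#' `PCK_i` is the fraction of targets (instances with keypoint `i` visible
#' in the ground truth) for which `d_i / s_n < alpha`, strictly; missing
#' predictions count as incorrect.  The normalizing scalar `s_n` is the
#' instance scale stored in each pair.  The scalar PCK is the unweighted
#' mean of `PCK_i` over keypoints with at least one sample.
#'
#' @param pairs List of [eval_pair()]s.
#' @param cfg A [metric_config()].
#' @return List with `pck_by_keypoint` (named vector, NA where no sample)
#'   and `pck_mean`.
#' @export
pck <- function(pairs, cfg = metric_config()) {
  pairs <- .pair_list(pairs)
  if (cfg$pck_alpha <= 0) stop_validation("`pck_alpha` must be > 0")
  kp <- pairs[[1L]]$skeleton$keypoints
  correct <- stats::setNames(numeric(length(kp)), kp)
  count <- stats::setNames(integer(length(kp)), kp)
  for (p in pairs) {
    vis <- unname(p$gt_visible)
    d <- unname(p$d)
    ok <- vis & is.finite(d) & d / p$s < cfg$pck_alpha
    correct <- correct + as.numeric(ok)
    count <- count + as.integer(vis)
  }
  pck_i <- ifelse(count > 0L, correct / count, NA_real_)
  list(pck_by_keypoint = pck_i, pck_mean = mean(pck_i[count > 0L]))
}

#' Per-keypoint pixel-error samples and summaries
#'
#' @param pairs List of [eval_pair()]s.
#' @return List of class `keypoint_errors`: `samples` (named list of raw
#'   error vectors) and `summary` (data.frame with keypoint, n, mean,
#'   median, iqr, n_missing), suitable for box-plot rendering.
#' @export
per_keypoint_pixel_errors <- function(pairs) {
  pairs <- .pair_list(pairs)
  kp <- pairs[[1L]]$skeleton$keypoints
  samples <- stats::setNames(vector("list", length(kp)), kp)
  n_missing <- stats::setNames(integer(length(kp)), kp)
  for (p in pairs) {
    vis <- p$gt_visible
    for (j in seq_along(kp)) {
      if (!vis[j]) next
      if (is.finite(p$d[j])) samples[[j]] <- c(samples[[j]], unname(p$d[j]))
      else n_missing[j] <- n_missing[j] + 1L
    }
  }
  summary <- data.frame(
    keypoint = kp,
    n = vapply(samples, length, integer(1)),
    mean = vapply(samples, function(s) if (length(s)) mean(s) else NA_real_,
                  numeric(1)),
    median = vapply(samples, function(s) if (length(s)) stats::median(s) else NA_real_,
                    numeric(1)),
    iqr = vapply(samples, function(s) if (length(s)) stats::IQR(s) else NA_real_,
                 numeric(1)),
    n_missing = n_missing,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(samples = samples, summary = summary),
            class = "keypoint_errors")
}

#' Rank keypoints by error dispersion
#'
#' Orders keypoints by descending error IQR, ties broken by descending
#' mean error (stable in input order).  This is the screening used to
#' reduce a skeleton to its reliably locatable keypoints.
#'
#' @param report A `keypoint_errors` object, or an evaluation report
#'   containing one as `$pixel_errors`.
#' @return Character vector of keypoint names, worst first.
#' @export
rank_keypoints_by_error <- function(report) {
  if (inherits(report, "pose_evaluation")) report <- report$pixel_errors
  if (!inherits(report, "keypoint_errors"))
    stop_validation("`report` must be a keypoint_errors or pose_evaluation object")
  s <- report$summary[report$summary$n > 0L, , drop = FALSE]
  if (nrow(s) < 2L)
    stop_validation("need >= 2 keypoints with error samples (got %d)", nrow(s))
  ord <- order(-s$iqr, -s$mean)
  s$keypoint[ord]
}

#' Evaluate predicted tracks against ground truth
#'
#' Aligns ground-truth and predicted sequences by video id (frame counts
#' must match), builds one evaluation pair per frame (frames with no
#' visible ground-truth keypoint are skipped and counted), and aggregates
#' the full metric suite.
#'
#' @param gt,pred A `tracked_sequence` or list of them.
#' @param cfg A [metric_config()].
#' @return List of class `pose_evaluation`: `oks_values`,
#'   `ap_by_threshold`, `map`, `mar`, `dist_avg`, `pck_by_keypoint`,
#'   `pck_mean`, `pixel_errors`, `n_instances`, `n_skipped`.
#' @export
evaluate <- function(gt, pred, cfg = metric_config()) {
  as_list <- function(x) if (inherits(x, "tracked_sequence")) list(x) else x
  gt <- as_list(gt); pred <- as_list(pred)
  gt_ids <- vapply(gt, `[[`, character(1), "video_id")
  pred_ids <- vapply(pred, `[[`, character(1), "video_id")
  if (anyDuplicated(gt_ids) || anyDuplicated(pred_ids))
    stop_validation("duplicate video ids")
  if (!setequal(gt_ids, pred_ids))
    stop_validation("unmatched video ids between gt and pred: %s",
                    paste(c(setdiff(gt_ids, pred_ids),
                            setdiff(pred_ids, gt_ids)), collapse = ", "))
  pred <- pred[match(gt_ids, pred_ids)]
  pairs <- list()
  n_skipped <- 0L
  for (i in seq_along(gt)) {
    g <- gt[[i]]; p <- pred[[i]]
    if (nrow(g$x) != nrow(p$x))
      stop_validation("frame count mismatch for video '%s' (%d vs %d)",
                      g$video_id, nrow(g$x), nrow(p$x))
    for (f in seq_len(nrow(g$x))) {
      if (!any(g$visible[f, ])) { n_skipped <- n_skipped + 1L; next }
      pairs[[length(pairs) + 1L]] <- eval_pair(frame_pose(g, f),
                                               frame_pose(p, f), cfg)
    }
  }
  if (!length(pairs)) stop_validation("no evaluable frames")
  if (n_skipped > 0L)
    message(sprintf("evaluate: skipped %d frame(s) with no visible ground truth",
                    n_skipped))
  oks <- vapply(pairs, compute_oks, numeric(1), cfg = cfg)
  mm <- mean_average_precision(oks, cfg)
  pk <- pck(pairs, cfg)
  errs <- per_keypoint_pixel_errors(pairs)
  structure(
    list(oks_values = oks, ap_by_threshold = mm$ap_by_threshold,
         map = mm$map, mar = mm$mar,
         dist_avg = distance_average(pairs),
         pck_by_keypoint = pk$pck_by_keypoint, pck_mean = pk$pck_mean,
         pixel_errors = errs,
         n_instances = length(pairs), n_skipped = n_skipped),
    class = "pose_evaluation"
  )
}

#' @export
print.pose_evaluation <- function(x, ...) {
  cat(sprintf(paste0("<pose_evaluation> %d instances (%d frames skipped)\n",
                     "  mean OKS %.3f | mAP %.3f | mAR %.3f | ",
                     "dist.avg %.2f px | PCK %.3f\n"),
              x$n_instances, x$n_skipped, mean(x$oks_values), x$map, x$mar,
              x$dist_avg, x$pck_mean))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes the scalar metrics and OKS distribution as JSON and the
#' per-keypoint error summary as CSV.
#'
#' @param report A `pose_evaluation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_evaluation_report <- function(report, dir) {
  if (!inherits(report, "pose_evaluation"))
    stop_validation("`report` must be a pose_evaluation")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "report.json")
  csv_path <- file.path(dir, "keypoint_errors.csv")
  doc <- list(
    n_instances = report$n_instances, n_skipped = report$n_skipped,
    mean_oks = mean(report$oks_values), map = report$map, mar = report$mar,
    dist_avg = report$dist_avg, pck_mean = report$pck_mean,
    ap_by_threshold = as.list(report$ap_by_threshold),
    pck_by_keypoint = as.list(report$pck_by_keypoint),
    oks_values = report$oks_values
  )
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$pixel_errors$summary, csv_path, row.names = FALSE)
  invisible(c(json_path, csv_path))
}
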