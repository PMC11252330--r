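# Synthetic sow gait generator.
#
# The labelled video repository behind the published models is not publicly
# available, so downstream stages are exercised against simulated data.  The
# walk model is kinematic, not biomechanical: body keypoints translate at
# constant speed, limb keypoints follow a four-phase sinusoidal stride
# (right fore / left fore / right hind / left hind at cycle phases
# 0, 0.5, 0.25, 0.75), and the 0-3 locomotion score maps onto controllable
# lameness signatures: reduced stride amplitude on the affected side, head
# dipping phase-locked to the affected forelimb, back arching, and (dorsal
# view) lateral sway.  Per-score presets are invented (the scoring system is
# behavioural, not kinematic) and documented in the methods vignette.

.limb_keypoints <- list(
  front_right = c("hoof_front_right", "pastern_right"),
  front_left  = c("hoof_front_left", "pastern_left"),
  hind_right  = c("hoof_posterior_right", "hock_right"),
  hind_left   = c("hoof_posterior_left", "hock_left")
)

.limb_phase <- c(front_right = 0, front_left = 0.5,
                 hind_right = 0.25, hind_left = 0.75)

# Neutral body template, px offsets from the body anchor (rump), for a sow
# filmed at 1920x1080.  Lateral: y is height (down-positive); dorsal: y is
# the lateral direction seen from above.
.lateral_template <- rbind(
  snout = c(520, 620), hoof_front_right = c(430, 900),
  hoof_front_left = c(410, 905), hoof_posterior_right = c(50, 900),
  hoof_posterior_left = c(30, 905), rump = c(0, 520),
  neck = c(430, 560), pastern_right = c(425, 840), pastern_left = c(405, 845),
  hock_right = c(55, 780), hock_left = c(35, 785),
  dorsal_neck = c(380, 470), dorsal_rump = c(60, 460)
)

.dorsal_template <- rbind(
  head = c(540, 540), neck = c(450, 540), scapula_right = c(400, 505),
  scapula_left = c(400, 575), thoracic = c(330, 540), middle = c(220, 540),
  lumbar = c(120, 540), pelvic_right = c(60, 505), pelvic_left = c(60, 575),
  tail = c(-20, 540)
)

.mid_spine_lateral <- c("dorsal_neck", "dorsal_rump")

.load_gait_presets <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "gait_presets.csv", package = "sowpose")
      if (!nzchar(path)) stop_io("gait preset table not found")
      cache <<- utils::read.csv(path, stringsAsFactors = FALSE)
    }
    cache
  }
})

#' Score-dependent gait parameters
#'
#' Builds the parameter set driving [simulate_sequence()].  Unspecified
#' arguments default to the per-score preset shipped with the package
#' (`inst/extdata/gait_presets.csv`); presets are a modelling choice, since
#' the locomotion scoring system describes behaviour, not kinematics.
#'
#' @param score Locomotion score, integer 0-3 (0 = sound, 3 = severe
#'   reluctance to walk).
#' @param view Camera view the parameters describe, `"lateral"` or
#'   `"dorsal"`.
#' @param speed Body translation, px/frame.
#' @param stride_freq Stride cycles per frame.
#' @param stride_amp Horizontal hoof swing amplitude, px.
#' @param lift_amp Vertical hoof lift amplitude, px.
#' @param affected_limb `"front_right"`, `"front_left"`, `"hind_right"`,
#'   `"hind_left"`, or `"none"` (required, and only allowed, for score 0).
#' @param asymmetry Fractional stride-amplitude reduction in `[0, 1)`
#'   applied to the limbs on the affected side.
#' @param head_amp Vertical snout oscillation amplitude, px.
#' @param arch_amp Constant upward offset of the mid-spine keypoints, px.
#' @param sway_amp Lateral oscillation amplitude in the dorsal view, px.
#' @param noise_sd Gaussian labelling noise, px.
#' @param occlusion_prob Per-keypoint probability a keypoint is invisible:
#'   a scalar, a named vector over keypoints, or `NULL` for the
#'   view-dependent default (see [default_occlusion()]).
#' @param frame_size Frame `c(width, height)` in px.
#' @return An object of class `gait_params`.
#' @export
gait_params <- function(score = 0, view = c("lateral", "dorsal"),
                        speed = NULL, stride_freq = NULL, stride_amp = NULL,
                        lift_amp = NULL, affected_limb = NULL,
                        asymmetry = NULL, head_amp = NULL, arch_amp = NULL,
                        sway_amp = NULL, noise_sd = NULL,
                        occlusion_prob = NULL, frame_size = c(1920, 1080)) {
  view <- match.arg(view)
  if (!is.numeric(score) || length(score) != 1L || !(score %in% 0:3))
    stop_validation("`score` must be an integer in 0..3")
  preset <- .load_gait_presets()
  preset <- preset[preset$score == score, , drop = FALSE]
  pick <- function(arg, col) if (is.null(arg)) preset[[col]][1L] else arg
  p <- list(
    score = as.integer(score), view = view,
    speed = pick(speed, "speed"),
    stride_freq = pick(stride_freq, "stride_freq"),
    stride_amp = pick(stride_amp, "stride_amp"),
    lift_amp = pick(lift_amp, "lift_amp"),
    affected_limb = pick(affected_limb, "affected_limb"),
    asymmetry = pick(asymmetry, "asymmetry"),
    head_amp = pick(head_amp, "head_amp"),
    arch_amp = pick(arch_amp, "arch_amp"),
    sway_amp = pick(sway_amp, "sway_amp"),
    noise_sd = pick(noise_sd, "noise_sd"),
    occlusion_prob = occlusion_prob,
    frame_size = frame_size
  )
  for (nm in c("speed", "stride_freq", "stride_amp", "lift_amp", "head_amp",
               "arch_amp", "sway_amp", "noise_sd"))
    assert_scalar_number(p[[nm]], nm, lower = 0)
  assert_scalar_number(p$asymmetry, "asymmetry", lower = 0, upper = 1 - 1e-12)
  if (!p$affected_limb %in% c(names(.limb_keypoints), "none"))
    stop_validation("unknown affected_limb '%s'", p$affected_limb)
  if (length(frame_size) != 2L || any(frame_size < 1))
    stop_validation("`frame_size` must be c(width, height), both >= 1")
  if (p$score == 0L) {
    if (p$asymmetry != 0 || p$head_amp != 0 || p$arch_amp != 0)
      stop_validation("score 0 requires asymmetry = head_amp = arch_amp = 0")
    if (p$affected_limb != "none")
      stop_validation("score 0 requires affected_limb = 'none'")
  } else if (p$affected_limb == "none") {
    stop_validation("score %d requires an affected limb", p$score)
  }
  if (!is.null(occlusion_prob)) {
    if (any(occlusion_prob < 0 | occlusion_prob > 1))
      stop_validation("`occlusion_prob` must be in [0, 1]")
  }
  structure(p, class = "gait_params")
}

#' Default per-keypoint occlusion probabilities
#'
#' Lateral-view defaults are side-asymmetric: the left (far-side) hoof
#' family is occluded by the body far more often than the rest, matching
#' what is observed when filming the animal's right side.
#'
#' @param skeleton A `sow_skeleton`.
#' @return Named numeric vector over the skeleton's keypoints.
#' @export
default_occlusion <- function(skeleton) {
  if (!inherits(skeleton, "sow_skeleton"))
    stop_validation("`skeleton` must be a sow_skeleton")
  kp <- skeleton$keypoints
  if (skeleton$view == "lateral") {
    occ <- rep(0.02, length(kp))
    left <- kp %in% c("hoof_front_left", "hoof_posterior_left",
                      "pastern_left", "hock_left")
    occ[left] <- 0.15
  } else {
    occ <- rep(0.01, length(kp))
  }
  names(occ) <- kp
  occ
}

.resolve_occlusion <- function(params, skeleton) {
  occ <- params$occlusion_prob
  kp <- skeleton$keypoints
  if (is.null(occ)) return(default_occlusion(skeleton))
  if (length(occ) == 1L && is.null(names(occ)))
    return(stats::setNames(rep(occ, length(kp)), kp))
  if (!is.null(names(occ))) {
    full <- stats::setNames(rep(0, length(kp)), kp)
    unknown <- setdiff(names(occ), kp)
    if (length(unknown))
      stop_validation("occlusion_prob names not in skeleton: %s",
                      paste(unknown, collapse = ", "))
    full[names(occ)] <- occ
    return(full)
  }
  stop_validation("`occlusion_prob` must be a scalar or a named vector")
}

.limb_side <- function(limb) if (grepl("right$", limb)) "right" else "left"

#' Simulate a ground-truth gait sequence
#'
#' Generates a deterministic (for fixed seed) keypoint track of a sow
#' walking left-to-right.  Body keypoints translate at `speed` px/frame;
#' limb keypoints swing sinusoidally with the four-phase cycle offsets
#' (0, 0.5, 0.25, 0.75 for RF/LF/RH/LH), with swing and lift amplitude
#' scaled by `(1 - asymmetry)` on both limbs of the affected side; the
#' snout oscillates vertically with amplitude `head_amp` phase-locked to
#' the affected-side forelimb; mid-spine keypoints are offset upward by
#' `arch_amp`; dorsal-view keypoints sway laterally with amplitude
#' `sway_amp`, the off-side half-cycle damped by `asymmetry`.  Gaussian
#' labelling noise and per-keypoint occlusion are applied last and all
#' coordinates are clamped to the frame.
#'
#' @param params A [gait_params()] object.
#' @param skeleton A `sow_skeleton` whose view matches `params$view`.
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer RNG seed.
#' @param video_id Identifier for the output sequence.
#' @param start_x Body anchor x at frame 0, px.
#' @return A `tracked_sequence` (ground truth).
#' @export
simulate_sequence <- function(params, skeleton, n_frames, seed,
                              video_id = sprintf("sim_%s_seed%d",
                                                 skeleton$name, seed),
                              start_x = 80) {
  if (!inherits(params, "gait_params"))
    stop_validation("`params` must be a gait_params object")
  if (!inherits(skeleton, "sow_skeleton"))
    stop_validation("`skeleton` must be a sow_skeleton")
  if (params$view != skeleton$view)
    stop_validation("view mismatch: params are %s, skeleton '%s' is %s",
                    params$view, skeleton$name, skeleton$view)
  if (!is.numeric(n_frames) || length(n_frames) != 1L || n_frames < 1)
    stop_validation("`n_frames` must be >= 1")
  n_frames <- as.integer(n_frames)

  kp <- skeleton$keypoints
  template <- if (skeleton$view == "lateral") .lateral_template else .dorsal_template
  miss <- setdiff(kp, rownames(template))
  if (length(miss))
    stop_validation("no template coordinates for keypoint(s): %s",
                    paste(miss, collapse = ", "))
  tmpl <- template[kp, , drop = FALSE]

  t <- seq_len(n_frames) - 1
  nk <- length(kp)
  x <- outer(start_x + params$speed * t, tmpl[, 1L], `+`)
  y <- matrix(tmpl[, 2L], n_frames, nk, byrow = TRUE)
  colnames(x) <- colnames(y) <- kp

  aff_side <- if (params$affected_limb == "none") NA_character_
              else .limb_side(params$affected_limb)

  if (skeleton$view == "lateral") {
    for (limb in names(.limb_keypoints)) {
      cols <- intersect(.limb_keypoints[[limb]], kp)
      if (!length(cols)) next
      damp <- if (!is.na(aff_side) && .limb_side(limb) == aff_side)
        1 - params$asymmetry else 1
      theta <- 2 * pi * (params$stride_freq * t + .limb_phase[[limb]])
      swing <- damp * params$stride_amp * sin(theta)
      lift <- damp * params$lift_amp * pmax(0, sin(theta))
      for (cc in cols) {
        x[, cc] <- x[, cc] + swing
        y[, cc] <- y[, cc] - lift
      }
    }
    if ("snout" %in% kp && params$head_amp > 0) {
      front_phase <- if (identical(aff_side, "left")) .limb_phase[["front_left"]]
                     else .limb_phase[["front_right"]]
      y[, "snout"] <- y[, "snout"] +
        params$head_amp * sin(2 * pi * (params$stride_freq * t + front_phase))
    }
    spine <- intersect(.mid_spine_lateral, kp)
    if (length(spine)) y[, spine] <- y[, spine] - params$arch_amp
  } else {
    s <- sin(2 * pi * params$stride_freq * t)
    sway <- params$sway_amp * ifelse(s > 0, s, (1 - params$asymmetry) * s)
    y <- y + matrix(sway, n_frames, nk)
  }

  occ <- .resolve_occlusion(params, skeleton)
  out <- with_seed(seed, {
    if (params$noise_sd > 0) {
      x <- x + matrix(stats::rnorm(n_frames * nk, sd = params$noise_sd),
                      n_frames, nk)
      y <- y + matrix(stats::rnorm(n_frames * nk, sd = params$noise_sd),
                      n_frames, nk)
    }
    u <- matrix(stats::runif(n_frames * nk), n_frames, nk)
    visible <- u >= matrix(occ, n_frames, nk, byrow = TRUE)
    list(x = x, y = y, visible = visible)
  })
  w <- params$frame_size[1L]; h <- params$frame_size[2L]
  out$x <- pmin(pmax(out$x, 0), w - 1)
  out$y <- pmin(pmax(out$y, 0), h - 1)
  tracked_sequence(video_id, skeleton, out$x, out$y, out$visible)
}

.cycle_excursion <- function(rel) {
  m <- rel - mean(rel)
  n <- length(m)
  starts <- which(m[-n] <= 0 & m[-1L] > 0)
  if (length(starts) < 3L) return(NULL)  # fewer than 2 complete cycles
  ranges <- vapply(seq_len(length(starts) - 1L), function(i) {
    seg <- rel[starts[i]:(starts[i + 1L] - 1L)]
    max(seg) - min(seg)
  }, numeric(1))
  mean(ranges)
}

#' Stride asymmetry index
#'
#' `SA = |L_R - L_L| / (L_R + L_L)`, where `L_R` (`L_L`) is the mean
#' per-cycle horizontal excursion of the right (left) hoof, measured
#' relative to the rump to remove body translation and averaged over the
#' front and hind hoof pairs.  For the generator's sinusoidal stride with
#' side amplitude reduction `lambda`, `SA = lambda / (2 - lambda)`.
#'
#' @param seq A lateral-view `tracked_sequence` containing the four hoof
#'   keypoints and the rump, spanning at least two complete stride cycles.
#' @return Asymmetry index in `[0, 1]`.
#' @export
stride_asymmetry_index <- function(seq) {
  if (!inherits(seq, "tracked_sequence"))
    stop_validation("`seq` must be a tracked_sequence")
  need <- c("hoof_front_right", "hoof_front_left",
            "hoof_posterior_right", "hoof_posterior_left", "rump")
  miss <- setdiff(need, seq$skeleton$keypoints)
  if (length(miss))
    stop_validation("missing hoof/rump keypoint(s): %s",
                    paste(miss, collapse = ", "))
  ref <- seq$x[, "rump"]
  exc <- lapply(need[1:4], function(kp) .cycle_excursion(seq$x[, kp] - ref))
  if (any(vapply(exc, is.null, logical(1))))
    stop_validation("fewer than 2 complete stride cycles detected")
  names(exc) <- need[1:4]
  l_r <- (exc$hoof_front_right + exc$hoof_posterior_right) / 2
  l_l <- (exc$hoof_front_left + exc$hoof_posterior_left) / 2
  abs(l_r - l_l) / (l_r + l_l)
}

#' Vertical snout range of a lateral sequence
#'
#' Simple head-movement summary (max minus min snout height in px) used to
#' check that the generator's head-dipping signature grows with the
#' locomotion score.
#'
#' @param seq A lateral `tracked_sequence` containing the snout keypoint.
#' @return Range in px.
#' @export
head_vertical_range <- function(seq) {
  if (!inherits(seq, "tracked_sequence"))
    stop_validation("`seq` must be a tracked_sequence")
  if (!"snout" %in% seq$skeleton$keypoints)
    stop_validation("sequence has no snout keypoint")
  diff(range(seq$y[, "snout"]))
}

#' Prediction error model
#'
#' Stand-in for the error structure of a trained pose model: isotropic
#' Gaussian jitter per keypoint, occasional large outliers, and missed
#' detections.
#'
#' @param sd Per-keypoint standard deviation in px (scalar or named vector).
#' @param outlier_prob Probability a keypoint is displaced with
#'   `sd * outlier_scale` instead of `sd`.
#' @param outlier_scale Outlier standard-deviation multiplier.
#' @param miss_prob Probability a keypoint is absent from the prediction.
#' @return An object of class `prediction_error_model`.
#' @export
prediction_error_model <- function(sd = 3, outlier_prob = 0,
                                   outlier_scale = 8, miss_prob = 0) {
  if (any(sd < 0) || anyNA(sd)) stop_validation("`sd` must be >= 0")
  for (p in c(outlier_prob, miss_prob))
    if (is.na(p) || p < 0 || p > 1)
      stop_validation("probabilities must be in [0, 1]")
  if (outlier_scale < 0) stop_validation("`outlier_scale` must be >= 0")
  structure(list(sd = sd, outlier_prob = outlier_prob,
                 outlier_scale = outlier_scale, miss_prob = miss_prob),
            class = "prediction_error_model")
}

#' Perturb a ground-truth sequence into a predicted one
#'
#' Each ground-truth-visible keypoint is displaced by isotropic Gaussian
#' error (occasionally inflated by `outlier_scale`), or dropped from the
#' prediction with probability `miss_prob`.  Keypoints invisible in the
#' ground truth stay invisible.  Deterministic for fixed seed.
#'
#' @param seq Ground-truth `tracked_sequence`.
#' @param model A [prediction_error_model()].
#' @param seed Integer RNG seed.
#' @return A `tracked_sequence` playing the role of the model prediction;
#'   its `visible` matrix is the predicted-present flag.
#' @export
apply_prediction_error <- function(seq, model, seed) {
  if (!inherits(seq, "tracked_sequence"))
    stop_validation("`seq` must be a tracked_sequence")
  if (!inherits(model, "prediction_error_model"))
    stop_validation("`model` must be a prediction_error_model")
  kp <- seq$skeleton$keypoints
  nk <- length(kp); nf <- nrow(seq$x)
  sd_vec <- model$sd
  if (length(sd_vec) == 1L && is.null(names(sd_vec))) {
    sd_vec <- stats::setNames(rep(sd_vec, nk), kp)
  } else {
    if (is.null(names(sd_vec)) || !all(kp %in% names(sd_vec)))
      stop_validation("per-keypoint `sd` must name every skeleton keypoint")
    sd_vec <- sd_vec[kp]
  }
  sd_mat <- matrix(sd_vec, nf, nk, byrow = TRUE)
  out <- with_seed(seed, {
    missed <- matrix(stats::runif(nf * nk) < model$miss_prob, nf, nk)
    outl <- matrix(stats::runif(nf * nk) < model$outlier_prob, nf, nk)
    dx <- matrix(stats::rnorm(nf * nk), nf, nk)
    dy <- matrix(stats::rnorm(nf * nk), nf, nk)
    list(missed = missed, outl = outl, dx = dx, dy = dy)
  })
  scale <- sd_mat * ifelse(out$outl, model$outlier_scale, 1)
  apply_to <- seq$visible & !out$missed
  x <- seq$x; y <- seq$y
  x[apply_to] <- x[apply_to] + (out$dx * scale)[apply_to]
  y[apply_to] <- y[apply_to] + (out$dy * scale)[apply_to]
  tracked_sequence(seq$video_id, seq$skeleton, x, y,
                   visible = apply_to, frames = seq$frames)
}

#' Expert confusion model
#'
#' 4x4 row-stochastic matrix; entry `(t + 1, a + 1)` is the probability an
#' expert answers score `a` for a video of true score `t`.
#'
#' @param confusion 4x4 numeric matrix with nonnegative entries and rows
#'   summing to 1 (within 1e-9).
#' @return An object of class `expert_model`.
#' @export
expert_model <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(4L, 4L)))
    stop_validation("`confusion` must be a 4x4 matrix")
  if (any(confusion < 0) || anyNA(confusion))
    stop_validation("`confusion` entries must be nonnegative")
  if (any(abs(rowSums(confusion) - 1) > 1e-9))
    stop_validation("`confusion` rows must each sum to 1")
  dimnames(confusion) <- list(true = 0:3, answer = 0:3)
  structure(list(confusion = confusion), class = "expert_model")
}

#' Diagonally dominant expert model
#'
#' Convenience constructor: probability `p` of answering the true score,
#' the remainder spread uniformly over the other three scores.
#'
#' @param p Probability of the correct answer, in `(1/4, 1]`.
#' @return An `expert_model`.
#' @export
diagonal_expert_model <- function(p = 0.9) {
  assert_scalar_number(p, "p", lower = 0, upper = 1)
  m <- matrix((1 - p) / 3, 4, 4)
  diag(m) <- p
  expert_model(m)
}

#' Simulate an expert voting panel
#'
#' One vote per (expert, video), drawn independently from the confusion row
#' of the video's true score.  Deterministic for fixed seed.
#'
#' @param true_scores Integer vector of true scores in 0..3; names, if
#'   present, are used as video ids (otherwise `V001`, ...).
#' @param model An [expert_model()].
#' @param n_experts Number of experts (>= 1).
#' @param seed Integer RNG seed.
#' @return A [vote_table()] with `n_experts * length(true_scores)` rows.
#' @export
simulate_votes <- function(true_scores, model, n_experts, seed) {
  if (!inherits(model, "expert_model"))
    stop_validation("`model` must be an expert_model")
  if (length(true_scores) < 1L || !all(true_scores %in% 0:3))
    stop_validation("`true_scores` must be integers in 0..3")
  if (!is.numeric(n_experts) || n_experts < 1)
    stop_validation("`n_experts` must be >= 1")
  n_experts <- as.integer(n_experts)
  video_ids <- names(true_scores)
  if (is.null(video_ids))
    video_ids <- sprintf("V%03d", seq_along(true_scores))
  expert_ids <- sprintf("E%02d", seq_len(n_experts))
  votes <- with_seed(seed, {
    unlist(lapply(seq_along(true_scores), function(i) {
      probs <- model$confusion[true_scores[[i]] + 1L, ]
      sample(0:3, n_experts, replace = TRUE, prob = probs)
    }))
  })
  vote_table(data.frame(
    video_id = rep(video_ids, each = n_experts),
    expert_id = rep(expert_ids, times = length(true_scores)),
    score = as.integer(votes),
    stringsAsFactors = FALSE
  ))
}
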