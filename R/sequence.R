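# TrackedSequence: per-frame keypoint coordinates + visibility for one
# video, either ground truth or predicted.

#' Per-video keypoint track
#'
#' @param video_id Video identifier (single string).
#' @param skeleton A `sow_skeleton`.
#' @param x,y Numeric matrices, frames x keypoints, pixel coordinates
#'   (origin top-left, y down).  Columns follow skeleton keypoint order.
#' @param visible Logical matrix of the same shape; ground-truth visibility
#'   or predicted-present flags.
#' @param frames Integer vector of original 0-based frame indices (kept
#'   through filtering for traceability).
#' @return An object of class `tracked_sequence`.
#' @export
tracked_sequence <- function(video_id, skeleton, x, y, visible,
                             frames = seq_len(nrow(x)) - 1L) {
  if (!is.character(video_id) || length(video_id) != 1L || !nzchar(video_id))
    stop_validation("`video_id` must be a nonempty string")
  if (!inherits(skeleton, "sow_skeleton"))
    stop_validation("`skeleton` must be a sow_skeleton")
  x <- as.matrix(x); y <- as.matrix(y); visible <- as.matrix(visible)
  k <- length(skeleton$keypoints)
  if (ncol(x) != k || ncol(y) != k || ncol(visible) != k)
    stop_validation("matrix width does not match skeleton '%s' (%d keypoints)",
                    skeleton$name, k)
  if (nrow(y) != nrow(x) || nrow(visible) != nrow(x))
    stop_validation("x, y and visible must have the same number of frames")
  if (length(frames) != nrow(x))
    stop_validation("`frames` must have one entry per frame")
  storage.mode(visible) <- "logical"
  colnames(x) <- colnames(y) <- colnames(visible) <- skeleton$keypoints
  structure(
    list(video_id = video_id, view = skeleton$view, skeleton = skeleton,
         x = x, y = y, visible = visible, frames = as.integer(frames)),
    class = "tracked_sequence"
  )
}

#' @export
print.tracked_sequence <- function(x, ...) {
  cat(sprintf("<tracked_sequence> %s: %d frames x %d keypoints (%s, %s view)\n",
              x$video_id, nrow(x$x), ncol(x$x), x$skeleton$name, x$view))
  cat(sprintf("  visible: %.1f%% of keypoint-frames\n", 100 * mean(x$visible)))
  invisible(x)
}

#' Number of frames in a sequence
#' @param seq A `tracked_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) {
  if (!inherits(seq, "tracked_sequence"))
    stop_validation("`seq` must be a tracked_sequence")
  nrow(seq$x)
}

#' Extract one frame of a sequence as a pose
#' @param seq A `tracked_sequence`.
#' @param i Frame row index (1-based position, not original frame number).
#' @return An `instance_pose`.
#' @export
frame_pose <- function(seq, i) {
  if (!inherits(seq, "tracked_sequence"))
    stop_validation("`seq` must be a tracked_sequence")
  if (i < 1L || i > nrow(seq$x)) stop_validation("frame index out of range")
  instance_pose(seq$skeleton, seq$x[i, ], seq$y[i, ], seq$visible[i, ])
}
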