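# Skeleton registry and subset algebra for the lateral and dorsal sow views.
#
# A skeleton is an ordered set of named anatomical keypoints tracked in one
# camera view.  The five built-ins (lateral_6/11/13, dorsal_7/10) are related
# by keypoint removal: each smaller skeleton is the larger one minus a stated
# set of landmarks, order preserved.  Bone/edge structure is cosmetic only
# and unused by every metric here.

# Canonical keypoint vocabulary, lateral view, nose-to-tail order of the
# published numbering: snout(1), four hooves(2-5), rump(6), neck(7),
# pasterns(8-9), hocks(10-11), dorsal neck(12), dorsal rump(13).
.lateral_13_keypoints <- c(
  "snout", "hoof_front_right", "hoof_front_left",
  "hoof_posterior_right", "hoof_posterior_left", "rump",
  "neck", "pastern_right", "pastern_left",
  "hock_right", "hock_left", "dorsal_neck", "dorsal_rump"
)

.dorsal_10_keypoints <- c(
  "head", "neck", "scapula_right", "scapula_left", "thoracic",
  "middle", "lumbar", "pelvic_right", "pelvic_left", "tail"
)

# Accepted input aliases -> canonical names.  "metacarpal" and "pastern"
# name the same forelimb landmark; "dorsal tail" and "dorsal rump" the same
# spine landmark (the dorsal-view "tail" keypoint is distinct).
.keypoint_aliases <- c(
  metacarpal_right = "pastern_right",
  metacarpal_left  = "pastern_left",
  dorsal_tail      = "dorsal_rump"
)

#' Canonicalize keypoint names
#'
#' Lower-cases, converts spaces/hyphens to underscores and resolves the
#' accepted aliases (`metacarpal_*` for `pastern_*`, `dorsal_tail` for
#' `dorsal_rump`).
#'
#' @param names Character vector of keypoint names.
#' @return Character vector of canonical names.
#' @export
canonical_keypoints <- function(names) {
  if (!is.character(names)) stop_validation("keypoint names must be character")
  x <- tolower(trimws(names))
  x <- gsub("[ -]+", "_", x)
  hit <- x %in% names(.keypoint_aliases)
  x[hit] <- unname(.keypoint_aliases[x[hit]])
  x
}

#' Construct a skeleton
#'
#' @param name Skeleton identifier.
#' @param view `"lateral"` or `"dorsal"`.
#' @param keypoints Ordered character vector of keypoint names (unique,
#'   nonempty); aliases are canonicalized.
#' @param parent Optional name of the parent skeleton this one was derived
#'   from.
#' @param removed Keypoint names absent relative to `parent`.
#' @param edges Optional two-column character matrix of cosmetic bone edges.
#' @return An object of class `sow_skeleton`.
#' @export
skeleton <- function(name, view = c("lateral", "dorsal"), keypoints,
                     parent = NULL, removed = character(), edges = NULL) {
  view <- match.arg(view)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_validation("skeleton `name` must be a nonempty string")
  keypoints <- canonical_keypoints(keypoints)
  if (length(keypoints) == 0L)
    stop_validation("skeleton '%s' must have at least one keypoint", name)
  if (anyDuplicated(keypoints))
    stop_validation("duplicate keypoint names in skeleton '%s'", name)
  structure(
    list(name = name, view = view, keypoints = keypoints,
         parent = parent, removed = canonical_keypoints(removed),
         edges = edges),
    class = "sow_skeleton"
  )
}

#' @export
print.sow_skeleton <- function(x, ...) {
  cat(sprintf("<sow_skeleton> %s (%s view, %d keypoints)\n",
              x$name, x$view, length(x$keypoints)))
  cat("  ", paste(x$keypoints, collapse = ", "), "\n", sep = "")
  if (!is.null(x$parent))
    cat(sprintf("  derived from %s minus {%s}\n", x$parent,
                paste(x$removed, collapse = ", ")))
  invisible(x)
}

#' Derive a sub-skeleton by removing keypoints
#'
#' Produces a child skeleton whose keypoints are the parent's minus
#' `removed`, relative order preserved, with the parent/removed provenance
#' recorded.
#'
#' @param parent A `sow_skeleton`.
#' @param removed Character vector of keypoint names to drop (aliases ok).
#' @param new_name Name for the derived skeleton.
#' @return A `sow_skeleton`.
#' @export
derive_subskeleton <- function(parent, removed, new_name) {
  if (!inherits(parent, "sow_skeleton"))
    stop_validation("`parent` must be a sow_skeleton")
  removed <- canonical_keypoints(removed)
  unknown <- setdiff(removed, parent$keypoints)
  if (length(unknown) > 0L)
    stop_validation("cannot remove keypoint(s) not in '%s': %s",
                    parent$name, paste(unknown, collapse = ", "))
  keep <- setdiff(parent$keypoints, removed)
  if (length(keep) == 0L)
    stop_validation("removing all keypoints of '%s' leaves an empty skeleton",
                    parent$name)
  skeleton(new_name, parent$view, keep,
           parent = parent$name, removed = removed)
}

.skeleton_registry <- local({
  lat13 <- skeleton("lateral_13", "lateral", .lateral_13_keypoints)
  lat11 <- derive_subskeleton(lat13, c("dorsal_neck", "dorsal_rump"),
                              "lateral_11")
  lat6 <- derive_subskeleton(
    lat13,
    c("dorsal_neck", "dorsal_rump", "hock_right", "hock_left",
      "neck", "pastern_right", "pastern_left"),
    "lateral_6")
  dor10 <- skeleton("dorsal_10", "dorsal", .dorsal_10_keypoints)
  dor7 <- derive_subskeleton(dor10, c("head", "thoracic", "lumbar"),
                             "dorsal_7")
  list(lateral_13 = lat13, lateral_11 = lat11, lateral_6 = lat6,
       dorsal_10 = dor10, dorsal_7 = dor7)
})

#' Look up a built-in skeleton
#'
#' The registry holds the five published sow skeletons: `lateral_13`,
#' `lateral_11` (minus dorsal neck/rump), `lateral_6` (snout, four hooves,
#' rump), `dorsal_10` and `dorsal_7` (minus head, thoracic, lumbar).
#'
#' @param name Skeleton identifier.
#' @return A `sow_skeleton`.
#' @export
#' @examples
#' get_skeleton("lateral_6")$keypoints
get_skeleton <- function(name) {
  if (!is.character(name) || length(name) != 1L)
    stop_validation("skeleton name must be a single string")
  sk <- .skeleton_registry[[name]]
  if (is.null(sk))
    stop_validation("unknown skeleton '%s' (built-ins: %s)", name,
                    paste(names(.skeleton_registry), collapse = ", "))
  sk
}

#' Names of the built-in skeletons
#' @return Character vector.
#' @export
list_skeletons <- function() names(.skeleton_registry)

#' Serialize / deserialize a skeleton to JSON
#'
#' @param x A `sow_skeleton`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `skeleton_to_json()`: JSON string (invisibly, if written to a
#'   file); `skeleton_from_json()`: a `sow_skeleton`.
#' @export
skeleton_to_json <- function(x, path = NULL) {
  if (!inherits(x, "sow_skeleton")) stop_validation("not a sow_skeleton")
  doc <- list(name = x$name, view = x$view, keypoints = x$keypoints,
              parent = x$parent, removed = x$removed)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @rdname skeleton_to_json
#' @param json JSON string or path to a JSON file.
#' @export
skeleton_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  skeleton(doc$name, doc$view, as.character(unlist(doc$keypoints)),
           parent = doc$parent,
           removed = as.character(unlist(doc$removed)))
}

#' Single-frame pose on a skeleton
#'
#' @param skeleton A `sow_skeleton`.
#' @param x,y Numeric vectors of pixel coordinates (image origin top-left,
#'   y increasing downward), one per keypoint in skeleton order.
#' @param visible Logical vector: ground-truth visibility flag, or
#'   predicted-present flag for predicted poses.
#' @return An object of class `instance_pose`.
#' @export
instance_pose <- function(skeleton, x, y, visible = rep(TRUE, length(x))) {
  if (!inherits(skeleton, "sow_skeleton"))
    stop_validation("`skeleton` must be a sow_skeleton")
  k <- length(skeleton$keypoints)
  if (length(x) != k || length(y) != k || length(visible) != k)
    stop_validation("pose length %d does not match skeleton '%s' (%d keypoints)",
                    length(x), skeleton$name, k)
  visible <- as.logical(visible)
  if (anyNA(visible)) stop_validation("visibility flags must not be NA")
  if (any(visible & (!is.finite(x) | !is.finite(y))))
    stop_validation("visible keypoints must have finite coordinates")
  structure(
    list(skeleton = skeleton,
         coords = cbind(x = as.numeric(x), y = as.numeric(y)),
         visible = visible),
    class = "instance_pose"
  )
}

#' Restrict a pose to a target skeleton
#'
#' Coordinates and visibility are restricted and reordered to the target's
#' keypoints; no coordinate value is altered.  The target's keypoints must
#' be a subset of the pose's skeleton and share its view.
#'
#' @param pose An `instance_pose`.
#' @param target A `sow_skeleton`.
#' @return An `instance_pose` on `target`.
#' @export
project_pose <- function(pose, target) {
  if (!inherits(pose, "instance_pose"))
    stop_validation("`pose` must be an instance_pose")
  if (!inherits(target, "sow_skeleton"))
    stop_validation("`target` must be a sow_skeleton")
  if (pose$skeleton$view != target$view)
    stop_validation("view mismatch: pose is %s, target skeleton '%s' is %s",
                    pose$skeleton$view, target$name, target$view)
  idx <- match(target$keypoints, pose$skeleton$keypoints)
  if (anyNA(idx))
    stop_validation("target keypoint(s) absent from source skeleton: %s",
                    paste(target$keypoints[is.na(idx)], collapse = ", "))
  instance_pose(target, pose$coords[idx, "x"], pose$coords[idx, "y"],
                pose$visible[idx])
}

#' Restrict a tracked sequence to a target skeleton
#'
#' Sequence analogue of [project_pose()].
#'
#' @param seq A `tracked_sequence`.
#' @param target A `sow_skeleton`.
#' @return A `tracked_sequence` on `target`.
#' @export
project_sequence <- function(seq, target) {
  if (!inherits(seq, "tracked_sequence"))
    stop_validation("`seq` must be a tracked_sequence")
  if (!inherits(target, "sow_skeleton"))
    stop_validation("`target` must be a sow_skeleton")
  if (seq$skeleton$view != target$view)
    stop_validation("view mismatch: sequence is %s, target '%s' is %s",
                    seq$skeleton$view, target$name, target$view)
  idx <- match(target$keypoints, seq$skeleton$keypoints)
  if (anyNA(idx))
    stop_validation("target keypoint(s) absent from source skeleton: %s",
                    paste(target$keypoints[is.na(idx)], collapse = ", "))
  tracked_sequence(seq$video_id, target,
                   seq$x[, idx, drop = FALSE], seq$y[, idx, drop = FALSE],
                   seq$visible[, idx, drop = FALSE], frames = seq$frames)
}
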