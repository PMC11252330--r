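# Dataset bookkeeping: fully-visible-frame filtering, leakage-guarded
# train/test splits, the long-format annotation CSV dialect, wide-format
# trajectory export, and summary accounting.
#
# Annotation CSV dialect (long format): columns video_id, view, frame,
# keypoint, x, y, visible; frame 0-based; pixel origin top-left with y
# increasing downward; UTF-8, '.' decimal separator.  Coordinates are
# written with "%.17g" so write -> read round-trips are bit-exact.

.annotation_columns <- c("video_id", "view", "frame", "keypoint",
                         "x", "y", "visible")

#' Keep only fully visible frames
#'
#' Retains exactly the frames in which every skeleton keypoint is visible
#' (the criterion used to select trainable frames).  Original frame
#' indices are preserved in `$frames` for traceability.
#'
#' @param seq A ground-truth `tracked_sequence`.
#' @return A `tracked_sequence`, possibly with zero frames.
#' @export
filter_fully_visible_frames <- function(seq) {
  if (!inherits(seq, "tracked_sequence"))
    stop_validation("`seq` must be a tracked_sequence")
  keep <- rowSums(!seq$visible) == 0L
  if (!any(keep))
    message(sprintf("filter_fully_visible_frames: no fully visible frames in '%s'",
                    seq$video_id))
  tracked_sequence(seq$video_id, seq$skeleton,
                   seq$x[keep, , drop = FALSE], seq$y[keep, , drop = FALSE],
                   seq$visible[keep, , drop = FALSE],
                   frames = seq$frames[keep])
}

#' Train/validation vs test split specification
#'
#' @param train_val_fraction,test_fraction Positive fractions summing to 1
#'   (defaults 0.85 / 0.15).
#' @param seed Integer RNG seed.
#' @param stratify_by Optional manifest column name to stratify the split
#'   by (e.g. `"final_score"`); off by default.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_val_fraction = 0.85, test_fraction = 0.15,
                       seed = 1L, stratify_by = NULL) {
  assert_scalar_number(train_val_fraction, "train_val_fraction", lower = 1e-9)
  assert_scalar_number(test_fraction, "test_fraction", lower = 1e-9)
  if (abs(train_val_fraction + test_fraction - 1) > 1e-9)
    stop_validation("fractions must sum to 1 (got %g)",
                    train_val_fraction + test_fraction)
  structure(list(train_val_fraction = train_val_fraction,
                 test_fraction = test_fraction, seed = as.integer(seed),
                 stratify_by = stratify_by),
            class = "split_spec")
}

.split_units <- function(ids, paired) {
  # group mutually paired videos into indivisible units (leakage guard)
  unit <- seq_along(ids)
  names(unit) <- ids
  if (!is.null(paired)) {
    for (i in seq_along(ids)) {
      p <- paired[i]
      if (!is.na(p) && nzchar(p) && p %in% ids)
        unit[c(ids[i], p)] <- min(unit[ids[i]], unit[p])
    }
  }
  split(ids, unit[ids])
}

.sample_units <- function(units, n_test) {
  order <- sample.int(length(units))
  test <- character()
  for (u in order) {
    if (length(test) >= n_test) break
    test <- c(test, units[[u]])
  }
  test
}

#' Split a manifest into train/validation and test sets
#'
#' Samples videos uniformly without replacement; the test size is
#' round-half-up of `test_fraction * N` with a minimum of 1.  When the
#' manifest has a `paired_id` column, paired lateral/dorsal videos are
#' kept on the same side of the split.  Deterministic for a fixed seed.
#'
#' @param manifest data.frame with a `video_id` column and optionally
#'   `paired_id` and the stratification column.
#' @param spec A [split_spec()].
#' @return List with `train_val` and `test` character vectors of video ids.
#' @export
split_dataset <- function(manifest, spec = split_spec()) {
  manifest <- as.data.frame(manifest, stringsAsFactors = FALSE)
  if (!"video_id" %in% names(manifest))
    stop_validation("manifest must have a `video_id` column")
  ids <- as.character(manifest$video_id)
  if (anyDuplicated(ids)) stop_validation("duplicate video ids in manifest")
  n <- length(ids)
  if (n < 2L) stop_validation("need at least 2 videos to split (got %d)", n)
  paired <- if ("paired_id" %in% names(manifest))
    as.character(manifest$paired_id) else NULL
  strata <- if (!is.null(spec$stratify_by)) {
    if (!spec$stratify_by %in% names(manifest))
      stop_validation("stratification column '%s' not in manifest",
                      spec$stratify_by)
    as.character(manifest[[spec$stratify_by]])
  } else rep("all", n)
  test <- with_seed(spec$seed, {
    out <- character()
    for (g in unique(strata)) {
      in_g <- strata == g
      n_test_g <- max(1L, floor(spec$test_fraction * sum(in_g) + 0.5))
      units <- .split_units(ids[in_g],
                            if (is.null(paired)) NULL else paired[in_g])
      out <- c(out, .sample_units(units, n_test_g))
    }
    out
  })
  list(train_val = setdiff(ids, test), test = test)
}

.parse_visible <- function(v, rows) {
  out <- rep(NA, length(v))
  out[v %in% c("1", "TRUE", "true", "T")] <- TRUE
  out[v %in% c("0", "FALSE", "false", "F")] <- FALSE
  if (anyNA(out))
    stop_io("invalid `visible` value at row %d", rows[which(is.na(out))[1L]])
  out
}

#' Read keypoint annotations
#'
#' Reads the long-format annotation CSV dialect and reassembles one
#' `tracked_sequence` per video.  The keypoint set of each video is
#' matched against the built-in skeletons; otherwise an ad hoc skeleton in
#' file order is created.  Unknown columns, missing mandatory columns,
#' non-numeric coordinates on visible keypoints and duplicate
#' (video, frame, keypoint) rows are rejected with the offending row named.
#'
#' @param path CSV file path.
#' @return List of `tracked_sequence`s (empty for a header-only file).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_io("annotation file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  extra <- setdiff(names(df), .annotation_columns)
  if (length(extra))
    stop_io("unknown annotation column(s): %s", paste(extra, collapse = ", "))
  miss <- setdiff(.annotation_columns, names(df))
  if (length(miss))
    stop_io("missing mandatory column(s): %s", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) return(list())
  rows <- seq_len(nrow(df)) + 1L  # header is line 1
  df$frame <- suppressWarnings(as.integer(df$frame))
  if (anyNA(df$frame))
    stop_io("non-integer frame at row %d", rows[which(is.na(df$frame))[1L]])
  df$visible <- .parse_visible(df$visible, rows)
  xnum <- suppressWarnings(as.numeric(df$x))
  ynum <- suppressWarnings(as.numeric(df$y))
  bad <- df$visible & (is.na(xnum) | is.na(ynum))
  if (any(bad))
    stop_io("visible keypoint with missing/non-numeric coordinate at row %d",
            rows[which(bad)[1L]])
  key <- paste(df$video_id, df$frame, df$keypoint, sep = "\r")
  if (anyDuplicated(key))
    stop_io("duplicate (video, frame, keypoint) at row %d",
            rows[which(duplicated(key))[1L]])
  df$x <- xnum; df$y <- ynum
  lapply(unique(df$video_id), function(vid) {
    sub <- df[df$video_id == vid, , drop = FALSE]
    view <- unique(sub$view)
    if (length(view) != 1L || !view %in% c("lateral", "dorsal"))
      stop_io("video '%s' must have a single view of lateral/dorsal", vid)
    kp <- canonical_keypoints(unique(sub$keypoint))
    sk <- NULL
    for (nm in list_skeletons()) {
      cand <- get_skeleton(nm)
      if (cand$view == view && setequal(cand$keypoints, kp)) { sk <- cand; break }
    }
    if (is.null(sk))
      sk <- skeleton(sprintf("custom_%s_%d", view, length(kp)), view, kp)
    frames <- sort(unique(sub$frame))
    nf <- length(frames); nk <- length(sk$keypoints)
    x <- matrix(NA_real_, nf, nk); y <- matrix(NA_real_, nf, nk)
    vis <- matrix(FALSE, nf, nk)
    fi <- match(sub$frame, frames)
    ki <- match(canonical_keypoints(sub$keypoint), sk$keypoints)
    idx <- cbind(fi, ki)
    x[idx] <- sub$x; y[idx] <- sub$y; vis[idx] <- sub$visible
    x[is.na(x)] <- 0; y[is.na(y)] <- 0
    tracked_sequence(vid, sk, x, y, vis, frames = frames)
  })
}

#' Write keypoint annotations
#'
#' Writes sequences in the long-format dialect read by
#' [read_annotations()].  Coordinates are serialized with 17 significant
#' digits, so a write-then-read round trip is bit-exact.
#'
#' @param seqs A `tracked_sequence` or list of them.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(seqs, path) {
  if (inherits(seqs, "tracked_sequence")) seqs <- list(seqs)
  rows <- lapply(seqs, function(s) {
    kp <- s$skeleton$keypoints
    nf <- nrow(s$x)
    data.frame(
      video_id = rep(s$video_id, nf * length(kp)),
      view = s$view,
      frame = rep(s$frames, times = length(kp)),
      keypoint = rep(kp, each = nf),
      x = sprintf("%.17g", as.vector(s$x)),
      y = sprintf("%.17g", as.vector(s$y)),
      visible = as.integer(as.vector(s$visible)),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 7)),
                          .annotation_columns)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Export a coordinate-only trajectory table
#'
#' Wide-format CSV, one row per frame with two columns (`<kp>_x`,
#' `<kp>_y`) per keypoint; invisible keypoints are written as empty cells.
#' This is the coordinates-without-animal artifact used for trajectory
#' videos.
#'
#' @param seq A nonempty `tracked_sequence`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
export_trajectories <- function(seq, path) {
  if (!inherits(seq, "tracked_sequence"))
    stop_validation("`seq` must be a tracked_sequence")
  if (nrow(seq$x) == 0L) stop_validation("sequence has no frames")
  kp <- seq$skeleton$keypoints
  out <- data.frame(frame = seq$frames)
  for (j in seq_along(kp)) {
    xs <- sprintf("%.17g", seq$x[, j]); ys <- sprintf("%.17g", seq$y[, j])
    xs[!seq$visible[, j]] <- ""; ys[!seq$visible[, j]] <- ""
    out[[paste0(kp[j], "_x")]] <- xs
    out[[paste0(kp[j], "_y")]] <- ys
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Dataset accounting summary
#'
#' Per view: video count, total frames, labelled-frame count and per-score
#' video counts, mirroring the published repository accounting.
#'
#' @param manifest data.frame with columns `video_id`, `view`, `n_frames`
#'   and optionally `final_score`.
#' @param annotations List of labelled `tracked_sequence`s (may be empty);
#'   every annotated video must appear in the manifest.
#' @param path Optional CSV output path.
#' @return data.frame, one row per view, with columns `view`, `n_videos`,
#'   `total_frames`, `labelled_frames`, `score_0` .. `score_3`.
#' @export
dataset_summary <- function(manifest, annotations = list(), path = NULL) {
  manifest <- as.data.frame(manifest, stringsAsFactors = FALSE)
  need <- c("video_id", "view", "n_frames")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stop_validation("manifest missing column(s): %s", paste(miss, collapse = ", "))
  if (inherits(annotations, "tracked_sequence")) annotations <- list(annotations)
  ann_ids <- vapply(annotations, `[[`, character(1), "video_id")
  unknown <- setdiff(ann_ids, manifest$video_id)
  if (length(unknown))
    stop_validation("annotation references video(s) absent from manifest: %s",
                    paste(unknown, collapse = ", "))
  labelled <- vapply(annotations, function(s) nrow(s$x), integer(1))
  views <- unique(manifest$view)
  out <- do.call(rbind, lapply(views, function(v) {
    m <- manifest[manifest$view == v, , drop = FALSE]
    in_view <- ann_ids %in% m$video_id
    score_counts <- if ("final_score" %in% names(m))
      as.integer(base::table(factor(m$final_score, levels = 0:3)))
    else rep(NA_integer_, 4L)
    data.frame(view = v, n_videos = nrow(m),
               total_frames = sum(m$n_frames),
               labelled_frames = sum(labelled[in_view]),
               score_0 = score_counts[1L], score_1 = score_counts[2L],
               score_2 = score_counts[3L], score_3 = score_counts[4L],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
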