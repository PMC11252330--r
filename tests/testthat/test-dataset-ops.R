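lat13 <- get_skeleton("lateral_13")

test_that("filter_fully_visible_frames keeps exactly the all-visible frames", {
  p <- gait_params(0, occlusion_prob = 0)
  s <- simulate_sequence(p, lat13, 12, seed = 1)
  expect_identical(n_frames(filter_fully_visible_frames(s)), 12L)
  # knock out one keypoint in frame 7 (0-based) only
  s$visible[8, "snout"] <- FALSE
  kept <- filter_fully_visible_frames(s)
  expect_identical(kept$frames, setdiff(0:11, 7L))
  # fully occluded sequence -> empty output, message not error
  p1 <- gait_params(0, occlusion_prob = 1)
  expect_message(
    empty <- filter_fully_visible_frames(simulate_sequence(p1, lat13, 5, seed = 2)),
    "no fully visible")
  expect_identical(n_frames(empty), 0L)
})

test_that("split_dataset hits the rounded test count deterministically", {
  man <- data.frame(video_id = sprintf("v%03d", 1:106))
  sp <- split_dataset(man, split_spec(seed = 3))
  expect_length(sp$test, 16L)          # round-half-up(0.15 * 106)
  expect_length(sp$train_val, 90L)
  # partition + determinism
  sp2 <- split_dataset(man, split_spec(seed = 3))
  expect_identical(sp, sp2)
  expect_identical(sort(c(sp$train_val, sp$test)), man$video_id)
  expect_length(intersect(sp$train_val, sp$test), 0L)
  # invalid fractions / too few videos
  expect_error(split_spec(0.8, 0.1), "sum to 1")
  expect_error(split_dataset(man[1, , drop = FALSE]), "at least 2")
  # partition property over many random (N, seed) draws
  set.seed(99)
  for (i in 1:250) {
    n <- sample(2:60, 1)
    m <- data.frame(video_id = sprintf("x%02d", 1:n))
    s <- split_dataset(m, split_spec(seed = sample.int(10000, 1)))
    expect_identical(sort(c(s$train_val, s$test)), m$video_id)
    expect_gte(length(s$test), 1L)
  }
})

test_that("paired lateral/dorsal videos never straddle the split", {
  man <- data.frame(
    video_id = c(sprintf("L%02d", 1:20), sprintf("D%02d", 1:20)),
    paired_id = c(sprintf("D%02d", 1:20), sprintf("L%02d", 1:20)))
  for (seed in 1:25) {
    sp <- split_dataset(man, split_spec(seed = seed))
    for (i in 1:20) {
      pair <- c(sprintf("L%02d", i), sprintf("D%02d", i))
      expect_true(all(pair %in% sp$test) || all(pair %in% sp$train_val))
    }
  }
})

test_that("annotation CSV round trips are lossless", {
  p <- gait_params(2, occlusion_prob = 0.2)
  seqs <- list(
    simulate_sequence(p, lat13, 15, seed = 5, video_id = "védeo_1"),
    simulate_sequence(gait_params(0, view = "dorsal"),
                      get_skeleton("dorsal_10"), 10, seed = 6,
                      video_id = "dorsal_1"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(seqs, path)
  back <- read_annotations(path)
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_identical(back[[i]]$video_id, seqs[[i]]$video_id)
    expect_identical(back[[i]]$skeleton$name, seqs[[i]]$skeleton$name)
    expect_identical(back[[i]]$x, seqs[[i]]$x)        # bit-exact
    expect_identical(back[[i]]$y, seqs[[i]]$y)
    expect_identical(back[[i]]$visible, seqs[[i]]$visible)
  }
  # header-only file -> empty list
  writeLines("video_id,view,frame,keypoint,x,y,visible", path)
  expect_length(read_annotations(path), 0L)
  # malformed inputs name the offending row
  writeLines(c("video_id,view,frame,keypoint,x,y,visible",
               "v1,lateral,0,snout,,100,1"), path)
  expect_error(read_annotations(path), "row 2")
  writeLines(c("video_id,view,frame,keypoint,x,y,visible",
               "v1,lateral,0,snout,1,2,1",
               "v1,lateral,0,snout,3,4,1"), path)
  expect_error(read_annotations(path), "duplicate")
  writeLines(c("video_id,view,frame,keypoint,x,y,visible,bogus",
               "v1,lateral,0,snout,1,2,1,z"), path)
  expect_error(read_annotations(path), "unknown annotation column")
})

test_that("export_trajectories writes the wide coordinate-only table", {
  p <- gait_params(0, occlusion_prob = 0)
  s <- simulate_sequence(p, get_skeleton("lateral_6"), 10, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  export_trajectories(s, path)
  wide <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  expect_identical(dim(wide), c(10L, 13L))  # frame + 6 keypoints x 2
  # values agree with the long format
  expect_equal(as.numeric(wide$snout_x), s$x[, "snout"], ignore_attr = TRUE)
  # invisible keypoints become empty cells
  s$visible[3, ] <- FALSE
  export_trajectories(s, path)
  wide <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  expect_true(all(wide[3, -1] == ""))
})

test_that("dataset_summary reports per-view accounting", {
  man <- data.frame(
    video_id = sprintf("v%03d", 1:106), view = "lateral", n_frames = 100L,
    final_score = rep(c(0, 1, 2, 3), times = c(33, 33, 33, 7)))
  s <- dataset_summary(man)
  expect_identical(unname(unlist(s[, c("score_0", "score_1", "score_2",
                                       "score_3")])),
                   c(33L, 33L, 33L, 7L))
  expect_identical(s$n_videos, 106L)
  expect_identical(s$labelled_frames, 0L)
  # labelled frames counted from annotations; unknown videos rejected
  ann <- simulate_sequence(gait_params(0), lat13, 40, seed = 1,
                           video_id = "v001")
  expect_identical(dataset_summary(man, list(ann))$labelled_frames, 40L)
  bad <- simulate_sequence(gait_params(0), lat13, 5, seed = 1,
                           video_id = "nope")
  expect_error(dataset_summary(man, list(bad)), "absent from manifest")
})

test_that("the CLI chains simulate -> consensus/split/evaluate/report", {
  dir <- withr::local_tempdir()
  expect_identical(run_cli(c("simulate", "--out", dir, "--videos-per-score", "1",
                             "--frames", "40", "--seed", "5")), 0L)
  expect_true(all(file.exists(file.path(dir, c("gt.csv", "pred.csv",
                                               "votes.csv", "manifest.json")))))
  out2 <- file.path(dir, "repo")
  expect_identical(run_cli(c("consensus", "--votes", file.path(dir, "votes.csv"),
                             "--manifest", file.path(dir, "manifest.json"),
                             "--out", out2)), 0L)
  expect_true(file.exists(file.path(out2, "repository.json")))
  expect_identical(run_cli(c("split", "--manifest",
                             file.path(dir, "manifest.json"),
                             "--out", file.path(dir, "split"))), 0L)
  expect_identical(run_cli(c("evaluate", "--gt", file.path(dir, "gt.csv"),
                             "--pred", file.path(dir, "pred.csv"),
                             "--out", file.path(dir, "eval"))), 0L)
  report <- jsonlite::fromJSON(file.path(dir, "eval", "report.json"))
  expect_true(report$mean_oks > 0 && report$mean_oks <= 1)
  expect_identical(run_cli(c("report", "--manifest",
                             file.path(dir, "manifest.json"),
                             "--annotations", file.path(dir, "gt.csv"),
                             "--out", file.path(dir, "rep"))), 0L)
  # exit codes: validation error 2, I/O error 3
  expect_identical(run_cli(c("nonsense")), 2L)
  expect_identical(run_cli(c("consensus", "--votes", "/no/such.csv",
                             "--manifest", file.path(dir, "manifest.json"),
                             "--out", out2)), 3L)
})

test_that("read_config parses flat key-value files", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "k = 0.1", "pck_alpha = 0.05", "name = probe"),
             path)
  cfg <- read_config(path)
  expect_identical(cfg$k, 0.1)
  expect_identical(cfg$name, "probe")
  expect_error(read_config("/no/such.cfg"), "not found")
})
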