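make_stream <- function(T_len, h = 8L, w = 10L, fps = 10) {
  frames <- array(runif(h * w * 3 * T_len), c(h, w, 3, T_len))
  lm <- array(runif(T_len * 106 * 2, 1, min(h, w) - 1), c(T_len, 106, 2))
  frame_stream(frames, lm, fps = fps, subject_id = "sX")
}

test_that("window segmentation matches brute-force start enumeration", {
  set.seed(5)
  for (i in 1:40) {
    T_len <- sample(1:120, 1); L <- sample(1:60, 1); s <- sample(1:20, 1)
    st <- make_stream(T_len, h = 3L, w = 3L)
    wins <- segment_windows(st, L, s)
    starts <- vapply(wins, function(w) w$start_frame, numeric(1))
    brute <- Filter(function(st0) st0 + L <= T_len, seq(0, max(T_len - 1, 0), by = s))
    expect_equal(starts, as.numeric(brute))
    expect_equal(length(wins),
                 if (T_len >= L) floor((T_len - L) / s) + 1 else 0)
  }
})

test_that("segmentation examples: exact fit, overlap and short streams", {
  st <- make_stream(300L)
  expect_length(segment_windows(st, 300, 30), 1)
  expect_identical(segment_windows(st, 300, 30)[[1]]$start_frame, 0L)
  w3 <- segment_windows(make_stream(360L), 300, 30)
  expect_equal(vapply(w3, `[[`, numeric(1), "start_frame"), c(0, 30, 60))
  expect_length(segment_windows(make_stream(299L), 300, 30), 0)
  # consecutive windows overlap in exactly L - s frames
  st2 <- make_stream(100L)
  ws <- segment_windows(st2, 40, 15)
  f1 <- ws[[1]]$frames[, , , 16:40]
  f2 <- ws[[2]]$frames[, , , 1:25]
  expect_identical(f1, f2)
})

test_that("mismatched frame/landmark lengths are rejected", {
  frames <- array(0, c(4, 4, 3, 10))
  lm <- array(0.5, c(9, 106, 2))
  expect_error(frame_stream(frames, lm, fps = 10), "equal length")
})

test_that("subregion crops have fixed shape and clamp at frame borders", {
  wnd <- pixel_window(fps = 10, L = 30L, noise_sigma = 0.01)
  vw <- structure(list(frames = wnd$frames, landmarks = wnd$landmarks_px,
                       start_frame = 0L, fps = 10, subject_id = "s",
                       trial_id = "t", labels = wnd$labels),
                  class = "video_window")
  le <- crop_subregion(vw, "left_eye")
  expect_s3_class(le, "subregion_clip")
  expect_equal(dim(le$pixels), c(30, 3, 25, 25))
  mo <- crop_subregion(vw, "mouth")
  expect_equal(dim(mo$pixels), c(30, 3, 15, 35))
  expect_true(all(le$pixels >= 0 & le$pixels <= 1))
  expect_error(crop_subregion(vw, "nose"), "unknown region")
  # landmarks 5 px from the left edge: box is clamped fully inside the frame
  vw2 <- vw
  vw2$landmarks[, , 1] <- 5
  le2 <- crop_subregion(vw2, "left_eye")
  expect_equal(dim(le2$pixels), c(30, 3, 25, 25))
})

test_that("landmark normalization maps pixels to the unit square and inverts", {
  frames <- array(0.5, c(480, 640, 3, 3))
  lm <- array(0, c(3, 106, 2))
  lm[, , 1] <- matrix(runif(3 * 106, 0, 640), 3)
  lm[, , 2] <- matrix(runif(3 * 106, 0, 480), 3)
  lm[1, 1, ] <- c(320, 240)
  lm[1, 2, ] <- c(0, 0)
  vw <- structure(list(frames = frames, landmarks = lm, start_frame = 0L,
                       fps = 30, subject_id = "s", trial_id = "t"),
                  class = "video_window")
  nl <- normalize_landmarks(vw)
  expect_equal(dim(nl), c(3, 106, 2))
  expect_equal(nl[1, 1, ], c(0.5, 0.5))
  expect_equal(nl[1, 2, ], c(0, 0))
  expect_true(all(nl >= 0 & nl <= 1))
  # invertible up to clamping for in-bounds inputs
  back <- unclass(nl)
  back[, , 1] <- back[, , 1] * 640
  back[, , 2] <- back[, , 2] * 480
  expect_equal(back, lm, tolerance = 1e-12)
  vw$landmarks[2, 3, 1] <- NaN
  expect_error(normalize_landmarks(vw), "non-finite")
})

test_that("window archives round-trip through disk", {
  ds <- tiny_dataset()
  path <- tempfile(fileext = ".rds")
  save_windows(ds, path)
  back <- load_windows(path)
  expect_identical(back$manifest, ds$manifest)
  expect_identical(back$windows[[1]]$tensors, ds$windows[[1]]$tensors)
  csv <- tempfile(fileext = ".csv")
  write_manifest_csv(ds, csv)
  expect_equal(nrow(read.csv(csv)), nrow(ds$manifest))
  unlink(c(path, csv))
})

test_that("frame directories round-trip through the disk reader", {
  dir <- tempfile("stream")
  dir.create(dir)
  h <- 12L; w <- 16L; T_len <- 4L
  frames <- array(runif(h * w * 3 * T_len), c(h, w, 3, T_len))
  frames <- round(frames * 255) / 255
  for (t in seq_len(T_len))
    png::writePNG(frames[, , , t], file.path(dir, sprintf("frame_%04d.png", t)))
  lm <- array(runif(T_len * 106 * 2, 1, 10), c(T_len, 106, 2))
  df <- data.frame(frame = rep(0:(T_len - 1), each = 106),
                   point_index = rep(0:105, T_len),
                   x = as.numeric(t(lm[, , 1])), y = as.numeric(t(lm[, , 2])))
  write.csv(df, file.path(dir, "landmarks.csv"), row.names = FALSE)
  jsonlite::write_json(list(fps = 10, subject_id = "sA", trial_id = "t7"),
                       file.path(dir, "metadata.json"), auto_unbox = TRUE)
  st <- read_frame_stream(dir)
  expect_s3_class(st, "frame_stream")
  expect_equal(dim(st$frames), c(h, w, 3, T_len))
  expect_equal(st$frames, frames, tolerance = 1e-7)
  expect_equal(st$landmarks, lm, tolerance = 1e-7)
  expect_identical(st$subject_id, "sA")
  expect_equal(st$fps, 10)
  unlink(dir, recursive = TRUE)
})
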