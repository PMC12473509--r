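#' Construct a frame stream
#'
#' Bundles an ordered RGB frame sequence with per-frame facial landmarks and
#' acquisition metadata.  Frames are given as an array `(h, w, 3, T)` with
#' values in `[0, 1]`, landmarks as a `T x P x 2` array of pixel coordinates.
#'
#' @param frames numeric array `(h, w, 3, T)`.
#' @param landmarks numeric array `(T, P, 2)` of (x, y) pixel coordinates.
#' @param fps frames per second, `> 0`.
#' @param subject_id,trial_id opaque identifiers.
#' @param labels optional list with `hr_bpm`, `rr_rpm`, `cog` attached to every
#'   window cut from this stream.
#' @return list of class `"frame_stream"`.
#' @export
frame_stream <- function(frames, landmarks, fps, subject_id = "s1",
                         trial_id = "t1", labels = NULL) {
  d <- dim(frames)
  if (length(d) != 4 || d[3] != 3) stop("`frames` must be (h, w, 3, T)")
  ld <- dim(landmarks)
  if (length(ld) != 3 || ld[3] != 2) stop("`landmarks` must be (T, P, 2)")
  if (ld[1] != d[4]) stop("frames and landmarks must have equal length")
  if (!is.numeric(fps) || fps <= 0) stop("`fps` must be positive")
  structure(list(frames = frames, landmarks = landmarks, fps = fps,
                 subject_id = subject_id, trial_id = trial_id, labels = labels),
            class = "frame_stream")
}

#' Read a frame stream from disk
#'
#' Expects a directory of numbered PNG frames (lexicographic order equals
#' temporal order), a `metadata.json` with `fps`, `subject_id`, `trial_id` and
#' optional `labels`, and landmarks either as `landmarks.csv` with columns
#' `frame, point_index, x, y` (both 0-based) or `landmarks.json` holding a
#' `T x P x 2` nested array.
#'
#' @param dir path to the frame directory.
#' @return a `"frame_stream"` object.
#' @export
read_frame_stream <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path)) stop("metadata.json not found in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG frames in ", dir)
  f1 <- png::readPNG(files[1])
  h <- dim(f1)[1]; w <- dim(f1)[2]
  frames <- array(0, c(h, w, 3, length(files)))
  for (i in seq_along(files)) {
    fr <- png::readPNG(files[i])
    frames[, , , i] <- fr[, , 1:3]
  }
  csv_path <- file.path(dir, "landmarks.csv")
  json_path <- file.path(dir, "landmarks.json")
  if (file.exists(csv_path)) {
    lm_df <- read.csv(csv_path)
    P <- max(lm_df$point_index) + 1L
    landmarks <- array(NA_real_, c(length(files), P, 2))
    landmarks[cbind(lm_df$frame + 1L, lm_df$point_index + 1L, 1L)] <- lm_df$x
    landmarks[cbind(lm_df$frame + 1L, lm_df$point_index + 1L, 2L)] <- lm_df$y
  } else if (file.exists(json_path)) {
    lm <- jsonlite::read_json(json_path, simplifyVector = TRUE)
    landmarks <- array(as.numeric(lm), dim = dim(lm))
  } else stop("no landmarks.csv or landmarks.json in ", dir)
  frame_stream(frames, landmarks, fps = meta$fps,
               subject_id = meta$subject_id %||% "s1",
               trial_id = meta$trial_id %||% "t1",
               labels = meta$labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cut a stream into fixed-length overlapping windows
#'
#' Windows start at frames `0, s, 2s, ...` (0-based, half-open
#' `[start, start + L)`); streams shorter than `L` yield no windows and
#' trailing partial windows are discarded, never padded.  Each window inherits
#' the stream's labels and identifiers.
#'
#' @param stream a `"frame_stream"`.
#' @param window_length window length L in frames (default 300).
#' @param stride step s in frames (default 30).
#' @return list of `"video_window"` objects, each holding `frames`
#'   `(h, w, 3, L)`, `landmarks` `(L, P, 2)`, `start_frame`, `fps`, ids and
#'   labels.
#' @export
segment_windows <- function(stream, window_length = 300L, stride = 30L) {
  stopifnot(inherits(stream, "frame_stream"))
  L <- as.integer(window_length); s <- as.integer(stride)
  if (L < 1 || s < 1) stop("window_length and stride must be >= 1")
  T_len <- dim(stream$frames)[4]
  if (dim(stream$landmarks)[1] != T_len)
    stop("frames and landmarks must have equal length")
  if (T_len < L) return(list())
  starts <- seq.int(0L, T_len - L, by = s)
  lapply(starts, function(st) {
    idx <- (st + 1L):(st + L)
    structure(list(frames = stream$frames[, , , idx, drop = FALSE],
                   landmarks = stream$landmarks[idx, , , drop = FALSE],
                   start_frame = st, fps = stream$fps,
                   subject_id = stream$subject_id, trial_id = stream$trial_id,
                   labels = stream$labels, stride = s),
              class = "video_window")
  })
}

#' Crop a fixed-size facial subregion from every frame of a window
#'
#' For each frame, a box of the region's fixed size is centered on the
#' centroid of the region's landmark indices and clamped fully inside the
#' frame (no padding), so the output shape is independent of head position.
#' Pixel values are rescaled to `[0, 1]`.
#'
#' @param window a `"video_window"`.
#' @param region one of `"left_eye"`, `"right_eye"`, `"mouth"`.
#' @param size optional `(height, width)`; defaults to 25 x 25 for eyes and
#'   15 x 35 for the mouth.
#' @param indices optional landmark index set for the region; defaults to
#'   [default_region_indices()].
#' @return list of class `"subregion_clip"` with `region` and `pixels`
#'   `(L, 3, h, w)` in `[0, 1]`.
#' @export
crop_subregion <- function(window, region, size = NULL, indices = NULL) {
  stopifnot(inherits(window, "video_window"))
  regions <- c("left_eye", "right_eye", "mouth")
  if (!region %in% regions)
    stop("unknown region: ", region, " (expected one of ",
         paste(regions, collapse = ", "), ")")
  if (is.null(size)) size <- if (region == "mouth") c(15L, 35L) else c(25L, 25L)
  if (is.null(indices)) indices <- default_region_indices()[[region]]
  d <- dim(window$frames)
  h <- d[1]; w <- d[2]; L <- d[4]
  bh <- size[1]; bw <- size[2]
  if (bh > h || bw > w) stop("frame smaller than crop box")
  pixels <- array(0, c(L, 3, bh, bw))
  for (t in seq_len(L)) {
    cen <- colMeans(window$landmarks[t, indices, , drop = FALSE][1, , ])
    if (any(!is.finite(cen))) stop("non-finite landmark coordinates")
    # cen = (x, y); rows index y, cols index x
    r0 <- round(cen[2]) - bh %/% 2L
    c0 <- round(cen[1]) - bw %/% 2L
    r0 <- min(max(r0, 1L), h - bh + 1L)
    c0 <- min(max(c0, 1L), w - bw + 1L)
    block <- window$frames[r0:(r0 + bh - 1L), c0:(c0 + bw - 1L), , t]
    pixels[t, , , ] <- aperm(block, c(3, 1, 2))
  }
  pixels[] <- pmin(pmax(pixels, 0), 1)
  structure(list(region = region, pixels = pixels, fps = window$fps),
            class = "subregion_clip")
}

#' Normalize a window's landmarks to the unit square
#'
#' Divides x by frame width and y by frame height, clamping to `[0, 1]`.
#'
#' @param window a `"video_window"`.
#' @return numeric array `(L, P, 2)` of class `"landmark_window"`.
#' @export
normalize_landmarks <- function(window) {
  stopifnot(inherits(window, "video_window"))
  if (any(!is.finite(window$landmarks))) stop("non-finite landmark coordinates")
  d <- dim(window$frames)
  out <- window$landmarks
  out[, , 1] <- out[, , 1] / d[2]
  out[, , 2] <- out[, , 2] / d[1]
  out[] <- pmin(pmax(out, 0), 1)
  class(out) <- "landmark_window"
  out
}
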