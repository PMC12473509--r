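#' Synthetic cohort configuration
#'
#' Parameters of the synthetic physiological-video generator.  Subjects draw a
#' baseline heart rate from Normal(70, 7) truncated to [50, 95] bpm and a
#' baseline respiration rate from Normal(15, 2) truncated to [10, 22] rpm;
#' high cognitive load shifts HR by `delta_hr_load` (+8 bpm) and RR by
#' `delta_rr_load` (+2 rpm) and raises the blink rate from `blink_rate_low` to
#' `blink_rate_high` blinks/min.  Windows embed a pulsatile skin-color
#' oscillation at the HR frequency, amplitude-modulated at the RR frequency
#' and accompanied by a direct low-frequency respiratory baseline, plus head
#' motion jitter, slow lighting drift and additive Gaussian sensor noise.
#'
#' @param n_subjects number of synthetic subjects.
#' @param windows_per_subject windows per subject (balanced between load
#'   classes).
#' @param fps frames per second.
#' @param L window length in frames.
#' @param delta_hr_load,delta_rr_load load-induced shifts (bpm / rpm).
#' @param pulse_amplitude green-channel pulse amplitude (fraction of full
#'   scale, before per-row normalization).
#' @param resp_mod_depth depth of the respiratory amplitude modulation.
#' @param resp_baseline_amp amplitude of the direct respiratory baseline
#'   oscillation, relative to the pulse amplitude.
#' @param noise_sigma additive Gaussian noise s.d. (SNR control).
#' @param lighting_drift amplitude of the slow illumination drift.
#' @param motion_amplitude head-motion random-walk amplitude in pixels.
#' @param blink_rate_low,blink_rate_high blinks/min under low/high load.
#' @param hr_mean,hr_sd,hr_range,rr_mean,rr_sd,rr_range cohort distributions.
#' @param canvas pixel-level canvas size (square).
#' @param level `"tensor"` (five aligned model inputs, fast) or `"pixel"`
#'   (toy face video exercising the full preprocessing path).
#' @param seed integer seed; every subject/window is a deterministic function
#'   of `(seed, subject, window)`.
#' @return list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_subjects = 10L, windows_per_subject = 20L,
                             fps = 30, L = 300L,
                             delta_hr_load = 8, delta_rr_load = 2,
                             pulse_amplitude = 0.05, resp_mod_depth = 0.25,
                             resp_baseline_amp = 0.3, noise_sigma = 0.01,
                             lighting_drift = 0.02, motion_amplitude = 1.5,
                             blink_rate_low = 12, blink_rate_high = 24,
                             hr_mean = 70, hr_sd = 7, hr_range = c(50, 95),
                             rr_mean = 15, rr_sd = 2, rr_range = c(10, 22),
                             canvas = 128L, level = c("tensor", "pixel"),
                             seed = 1L) {
  level <- match.arg(level)
  cfg <- as.list(environment())
  stopifnot(pulse_amplitude >= 0, resp_mod_depth >= 0, noise_sigma >= 0,
            lighting_drift >= 0, motion_amplitude >= 0, fps > 0, L >= 2)
  class(cfg) <- "synthetic_config"
  cfg
}

skin_palette <- function() {
  list(c(0.87, 0.68, 0.55), c(0.78, 0.58, 0.46),
       c(0.62, 0.45, 0.35), c(0.45, 0.31, 0.24))
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  for (i in 1:1000) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  (lo + hi) / 2
}

#' Draw a synthetic subject profile
#'
#' Deterministic in `(config$seed, subject_index)`.
#'
#' @param config a [synthetic_config()].
#' @param subject_index 1-based subject index.
#' @return list of class `"subject_profile"`.
#' @export
generate_subject <- function(config, subject_index) {
  stopifnot(inherits(config, "synthetic_config"),
            subject_index >= 1, subject_index <= config$n_subjects)
  with_seed(mix_seed(config$seed, 101, subject_index), {
    tone <- skin_palette()[[sample.int(4, 1)]]
    structure(list(
      subject_id = sprintf("S%02d", subject_index),
      subject_index = as.integer(subject_index),
      baseline_hr = rtruncnorm1(config$hr_mean, config$hr_sd,
                                config$hr_range[1], config$hr_range[2]),
      baseline_rr = rtruncnorm1(config$rr_mean, config$rr_sd,
                                config$rr_range[1], config$rr_range[2]),
      skin_tone = tone,
      blink_rate_low = config$blink_rate_low,
      blink_rate_high = config$blink_rate_high,
      motion_amplitude = config$motion_amplitude,
      pulse_scale = runif(1, 0.8, 1.2)), class = "subject_profile")
  })
}

# 106-point landmark template in relative [0,1] coordinates (x, y)
landmark_template <- function() {
  ell <- function(cx, cy, a, b, n, from = 0, to = 2 * pi) {
    th <- seq(from, to, length.out = n + 1)[seq_len(n)]
    cbind(cx + a * cos(th), cy + b * sin(th))
  }
  contour <- ell(0.5, 0.52, 0.22, 0.30, 33)
  brow_l <- cbind(seq(0.32, 0.46, length.out = 8),
                  0.36 - 0.02 * sin(seq(0, pi, length.out = 8)))
  brow_r <- cbind(seq(0.54, 0.68, length.out = 8),
                  0.36 - 0.02 * sin(seq(0, pi, length.out = 8)))
  nose <- rbind(cbind(rep(0.5, 6), seq(0.42, 0.58, length.out = 6)),
                cbind(seq(0.44, 0.56, length.out = 5), rep(0.60, 5)))
  eye_l <- ell(0.39, 0.44, 0.045, 0.025, 8)
  eye_r <- ell(0.61, 0.44, 0.045, 0.025, 8)
  mouth <- rbind(ell(0.5, 0.70, 0.09, 0.045, 18), ell(0.5, 0.70, 0.055, 0.02, 12))
  rbind(contour, brow_l, brow_r, nose, eye_l, eye_r, mouth)
}

# Poisson-process blink onsets over [0, dur); returns onset times (seconds)
blink_onsets <- function(rate_per_min, dur) {
  n <- rpois(1, rate_per_min / 60 * dur)
  if (n == 0) return(numeric(0))
  sort(runif(n, 0, dur))
}

quantize8 <- function(x) {
  r <- as.raw(pmin(pmax(round(x * 255), 0), 255))
  attr(r, "dims") <- dim(x)
  r
}

clip_values <- function(clip) {
  if (!is.raw(clip)) return(clip)          # already numeric (augmented)
  a <- as.integer(clip) / 255
  dim(a) <- attr(clip, "dims")
  a
}

#' Generate one synthetic window
#'
#' True HR is `baseline_hr + cog_state * delta_hr_load` plus unit-s.d. jitter
#' (analogously for RR); the labels equal the generating values exactly.  At
#' the tensor level the five model inputs are built directly: STMap rows carry
#' the pulse with respiratory amplitude modulation plus the respiratory
#' baseline, eye clips carry blink closures from a Poisson process at the
#' load-dependent rate, and landmarks follow a head-motion random walk.  At
#' the pixel level a flat-face toy video is rendered on a square canvas with
#' the same embedded signals, exercising the full preprocessing + STMap path.
#'
#' @param profile a `"subject_profile"`.
#' @param cog_state 0 (low load) or 1 (high load).
#' @param config a [synthetic_config()].
#' @param window_index 1-based window index (seeds the draw).
#' @return list of class `"window_sample"`: `level`, `tensors` (named list
#'   `leye`, `reye`, `mouth` as 8-bit-quantized clips with layout
#'   `(h, w, L, 3)`, `facial` `(L, 106, 2)`, `stmap` `(3, H, L)`), at pixel
#'   level also `frames` and pixel `landmarks`; `labels`, ids, `fps`, `L`.
#' @export
generate_window <- function(profile, cog_state, config, window_index = 1L) {
  stopifnot(inherits(profile, "subject_profile"), cog_state %in% c(0, 1))
  seed <- mix_seed(config$seed, 202, profile$subject_index, window_index, cog_state)
  with_seed(seed, {
    L <- config$L; fps <- config$fps
    dur <- L / fps
    tt <- (0:(L - 1)) / fps
    hr <- min(max(profile$baseline_hr + cog_state * config$delta_hr_load +
                    rnorm(1), 40), 180)
    rr <- min(max(profile$baseline_rr + cog_state * config$delta_rr_load +
                    rnorm(1), 6), 30)
    f_hr <- hr / 60; f_rr <- rr / 60
    rate <- if (cog_state == 1) profile$blink_rate_high else profile$blink_rate_low
    blinks <- blink_onsets(rate, dur)
    closed <- rep(FALSE, L)
    for (b in blinks) closed <- closed | (tt >= b & tt < b + 0.15)
    resp_phase <- runif(1, 0, 2 * pi)
    amp_mod <- 1 + config$resp_mod_depth * sin(2 * pi * f_rr * tt + resp_phase)
    drift <- config$lighting_drift * sin(2 * pi * 0.05 * tt + runif(1, 0, 2 * pi))
    cw <- c(0.5, 1, 0.3) * config$pulse_amplitude * profile$pulse_scale
    H <- 25L  # 5x5 grid
    # --- STMap ---
    straw <- array(0, c(3, H, L))
    phi <- runif(H, 0, 2 * pi)
    psi <- runif(H, 0, 2 * pi)
    for (cell in seq_len(H)) {
      pulse <- amp_mod * sin(2 * pi * f_hr * tt + phi[cell])
      resp <- config$resp_baseline_amp * sin(2 * pi * f_rr * tt + psi[cell])
      for (ch in 1:3)
        straw[ch, cell, ] <- cw[ch] * (pulse + resp) + drift +
          rnorm(L, sd = config$noise_sigma)
    }
    stmap <- normalize_stmap_rows(straw)
    # --- landmarks: template + random-walk head motion (normalized coords) ---
    tmpl <- landmark_template()
    step_sd <- config$motion_amplitude / config$canvas / sqrt(L)
    walk <- cbind(cumsum(rnorm(L, sd = step_sd)), cumsum(rnorm(L, sd = step_sd)))
    facial <- array(0, c(L, 106, 2))
    for (k in 1:2) facial[, , k] <-
      pmin(pmax(outer(walk[, k], tmpl[, k], `+`), 0), 1)
    # --- subregion clips ---
    pulse_mean <- amp_mod * sin(2 * pi * f_hr * tt)  # site-average BVP
    eye_clip <- function() {
      h <- 25L; w <- 25L
      shade <- outer(seq(0.95, 1.05, length.out = h), rep(1, w))
      pattern <- matrix(rnorm(h * w, sd = 0.02), h, w)
      ys <- matrix(seq_len(h), h, w); xs <- matrix(seq_len(w), h, w, byrow = TRUE)
      pupil <- ((ys - 13)^2 + (xs - 13)^2) <= 16
      arr <- array(0, c(h, w, L, 3))
      open_depth <- ifelse(closed, 0.05, 0.55)
      for (ch in 1:3) {
        base <- profile$skin_tone[ch] * shade + pattern
        for (t in seq_len(L)) {
          fr <- base + cw[ch] * 0.5 * pulse_mean[t] + drift[t]
          fr[pupil] <- fr[pupil] * (1 - open_depth[t])
          arr[, , t, ch] <- fr
        }
        arr[, , , ch] <- arr[, , , ch] +
          rnorm(h * w * L, sd = config$noise_sigma)
      }
      quantize8(pmin(pmax(arr, 0), 1))
    }
    mouth_clip <- function() {
      h <- 15L; w <- 35L
      shade <- outer(seq(0.97, 1.03, length.out = h), rep(1, w))
      pattern <- matrix(rnorm(h * w, sd = 0.02), h, w)
      ys <- matrix(seq_len(h), h, w); xs <- matrix(seq_len(w), h, w, byrow = TRUE)
      lips <- (((ys - 8) / 4)^2 + ((xs - 18) / 12)^2) <= 1
      arr <- array(0, c(h, w, L, 3))
      lip_tone <- c(0.75, 0.35, 0.35)
      for (ch in 1:3) {
        base <- profile$skin_tone[ch] * shade + pattern
        base[lips] <- lip_tone[ch]
        for (t in seq_len(L))
          arr[, , t, ch] <- base + cw[ch] * 0.5 * pulse_mean[t] + drift[t]
        arr[, , , ch] <- arr[, , , ch] +
          rnorm(h * w * L, sd = config$noise_sigma)
      }
      quantize8(pmin(pmax(arr, 0), 1))
    }
    sample <- list(level = config$level,
                   tensors = list(leye = eye_clip(), reye = eye_clip(),
                                  mouth = mouth_clip(), facial = facial,
                                  stmap = stmap),
                   labels = list(hr_bpm = hr, rr_rpm = rr, cog = cog_state),
                   subject_id = profile$subject_id,
                   window_id = sprintf("%s_w%03d", profile$subject_id, window_index),
                   fps = fps, L = L, n_blinks = length(blinks))
    if (config$level == "pixel") {
      px <- render_pixel_window(profile, config, tt, f_hr, f_rr, amp_mod,
                                drift, cw, closed, facial)
      sample$frames <- px$frames
      sample$landmarks_px <- px$landmarks
    }
    class(sample) <- "window_sample"
    sample
  })
}

# toy face renderer for the pixel-level generator
render_pixel_window <- function(profile, config, tt, f_hr, f_rr, amp_mod,
                                drift, cw, closed, facial_norm) {
  S <- config$canvas; L <- config$L
  frames <- array(0, c(S, S, 3, L))
  ys <- matrix(seq_len(S), S, S); xs <- matrix(seq_len(S), S, S, byrow = TRUE)
  tmpl_px <- landmark_template() * S
  landmarks <- array(0, c(L, 106, 2))
  pulse <- amp_mod * sin(2 * pi * f_hr * tt)
  resp <- config$resp_baseline_amp * sin(2 * pi * f_rr * tt)
  grad <- 1 + 0.08 * (ys - S / 2) / S
  for (t in seq_len(L)) {
    offx <- (facial_norm[t, , 1] - landmark_template()[, 1])[1] * config$canvas
    offy <- (facial_norm[t, , 2] - landmark_template()[, 2])[1] * config$canvas
    landmarks[t, , 1] <- tmpl_px[, 1] + offx
    landmarks[t, , 2] <- tmpl_px[, 2] + offy
    cx <- 0.5 * S + offx; cy <- 0.52 * S + offy
    face <- (((xs - cx) / (0.22 * S))^2 + ((ys - cy) / (0.30 * S))^2) <= 1
    eye_l <- ((xs - (0.39 * S + offx))^2 + (ys - (0.44 * S + offy))^2) <= (0.03 * S)^2
    eye_r <- ((xs - (0.61 * S + offx))^2 + (ys - (0.44 * S + offy))^2) <= (0.03 * S)^2
    mouth <- (((xs - (0.5 * S + offx)) / (0.09 * S))^2 +
                ((ys - (0.70 * S + offy)) / (0.045 * S))^2) <= 1
    eye_depth <- if (closed[t]) 0.05 else 0.55
    for (ch in 1:3) {
      fr <- matrix(0.08, S, S)
      fr[face] <- (profile$skin_tone[ch] * grad[face]) +
        cw[ch] * (pulse[t] + resp[t])
      fr[eye_l | eye_r] <- fr[eye_l | eye_r] * (1 - eye_depth)
      fr[mouth] <- c(0.75, 0.35, 0.35)[ch]
      fr <- fr + drift[t] + matrix(rnorm(S * S, sd = config$noise_sigma), S, S)
      frames[, , ch, t] <- pmin(pmax(fr, 0), 1)
    }
  }
  frames <- round(frames * 255) / 255  # 8-bit video
  list(frames = frames, landmarks = landmarks)
}

#' Generate a synthetic dataset
#'
#' Draws `n_subjects` profiles and `windows_per_subject` windows each, with
#' the cognitive-load state balanced within every subject.  The manifest
#' records all true labels, so every window's labels are exactly recoverable.
#' Regenerating with the same configuration reproduces the dataset.
#'
#' @param config a [synthetic_config()].
#' @return list of class `"facephys_data"` with `windows` (list of
#'   `"window_sample"`), `manifest` (data.frame with subject_id, window_id,
#'   cog, hr_bpm, rr_rpm, n_blinks) and `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  wps <- config$windows_per_subject
  windows <- list(); rows <- list()
  for (i in seq_len(config$n_subjects)) {
    prof <- generate_subject(config, i)
    cogs <- rep(c(0L, 1L), length.out = wps)
    cogs <- with_seed(mix_seed(config$seed, 303, i), sample(cogs))
    for (j in seq_len(wps)) {
      wnd <- generate_window(prof, cogs[j], config, j)
      windows[[length(windows) + 1L]] <- wnd
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = wnd$subject_id, window_id = wnd$window_id,
        cog = wnd$labels$cog, hr_bpm = wnd$labels$hr_bpm,
        rr_rpm = wnd$labels$rr_rpm, n_blinks = wnd$n_blinks,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(windows = windows, manifest = do.call(rbind, rows),
                 config = config), class = "facephys_data")
}

#' Convert a pixel-level window sample into the five aligned model inputs
#'
#' Runs the real preprocessing path (subregion crops, landmark normalization,
#' STMap construction) on a pixel-level `"window_sample"` so synthetic video
#' and directly generated tensors are interchangeable downstream.
#'
#' @param sample a pixel-level `"window_sample"`.
#' @param grid_rows,grid_cols STMap grid.
#' @return the same sample with `tensors` replaced by the preprocessed inputs
#'   and `level = "tensor"`.
#' @export
pixel_window_to_tensors <- function(sample, grid_rows = 5L, grid_cols = 5L) {
  stopifnot(inherits(sample, "window_sample"))
  if (sample$level != "pixel") stop("sample is not pixel-level")
  vw <- structure(list(frames = sample$frames, landmarks = sample$landmarks_px,
                       start_frame = 0L, fps = sample$fps,
                       subject_id = sample$subject_id, trial_id = "synthetic",
                       labels = sample$labels),
                  class = "video_window")
  clips <- lapply(c(left_eye = "left_eye", right_eye = "right_eye",
                    mouth = "mouth"), function(rg) crop_subregion(vw, rg))
  to_internal <- function(clip) quantize8(aperm(clip$pixels, c(3, 4, 1, 2)))
  st <- build_stmap(vw, grid_rows, grid_cols)
  sample$tensors <- list(leye = to_internal(clips$left_eye),
                         reye = to_internal(clips$right_eye),
                         mouth = to_internal(clips$mouth),
                         facial = unclass(normalize_landmarks(vw)),
                         stmap = st$values)
  sample$level <- "tensor"
  sample
}
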