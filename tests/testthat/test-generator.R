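test_that("subject profiles are deterministic and respect truncation bounds", {
  cfg <- synthetic_config(n_subjects = 1000L, seed = 9)
  p1 <- generate_subject(cfg, 17)
  p2 <- generate_subject(cfg, 17)
  expect_identical(p1, p2)
  hrs <- vapply(1:1000, function(i) generate_subject(cfg, i)$baseline_hr,
                numeric(1))
  rrs <- vapply(1:400, function(i) generate_subject(cfg, i)$baseline_rr,
                numeric(1))
  expect_true(all(hrs >= 50 & hrs <= 95))
  expect_true(all(rrs >= 10 & rrs <= 22))
  # Monte-Carlo check of the stated cohort distribution
  expect_lt(abs(mean(hrs) - 70), 1)
})

test_that("window labels equal the generating parameters", {
  cfg <- synthetic_config(n_subjects = 3L, fps = 10, L = 40L, seed = 12)
  prof <- generate_subject(cfg, 2)
  w_hi <- generate_window(prof, 1L, cfg, 1L)
  w_lo <- generate_window(prof, 0L, cfg, 2L)
  expect_identical(w_hi$labels$cog, 1L)
  expect_identical(w_lo$labels$cog, 0L)
  # label = baseline + load shift + unit-s.d. jitter
  expect_lt(abs(w_hi$labels$hr_bpm - (prof$baseline_hr + cfg$delta_hr_load)), 5)
  expect_lt(abs(w_lo$labels$hr_bpm - prof$baseline_hr), 5)
  expect_identical(generate_window(prof, 1L, cfg, 1L)$tensors,
                   w_hi$tensors)
})

test_that("dataset generation balances classes and reproduces byte-identically", {
  cfg <- synthetic_config(n_subjects = 5L, windows_per_subject = 4L,
                          fps = 10, L = 30L, seed = 13)
  ds <- generate_dataset(cfg)
  expect_length(ds$windows, 20)
  expect_equal(sum(ds$manifest$cog == 1), 10)
  expect_equal(unname(table(ds$manifest$subject_id)), rep(4L, 5),
               ignore_attr = TRUE)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds, ds2)
  # manifest labels exactly recoverable from the windows
  for (i in c(1, 7, 20))
    expect_identical(ds$windows[[i]]$labels$hr_bpm, ds$manifest$hr_bpm[i])
  sp <- subject_split(ds$manifest$subject_id, seed = 1)
  expect_equal(sum(sp == "train"), 3)
})

test_that("blink process matches its Poisson rate and darkens the eye clips", {
  # 200 high-load windows at 10-second span: mean count ~ rate * 10/60
  cfg <- synthetic_config(n_subjects = 1L, windows_per_subject = 1L,
                          fps = 6, L = 60L, noise_sigma = 0, seed = 14)
  prof <- generate_subject(cfg, 1)
  counts <- vapply(1:200, function(j)
    generate_window(prof, 1L, cfg, j)$n_blinks, numeric(1))
  expected <- cfg$blink_rate_high * (cfg$L / cfg$fps) / 60
  expect_lt(abs(mean(counts) - expected) / expected, 0.1)
  # a blink event visibly changes the eye clip brightness trace
  wnd <- generate_window(prof, 1L, cfg, which(counts > 0)[1])
  eye <- facephys:::clip_values(wnd$tensors$leye)
  trace <- apply(eye[10:16, 10:16, , 2], 3, mean)
  expect_gt(diff(range(trace)), 0.05)
})

test_that("load shifts the label distributions in the configured direction", {
  cfg8 <- synthetic_config(n_subjects = 8L, fps = 10, L = 30L, seed = 15)
  cfg16 <- synthetic_config(n_subjects = 8L, fps = 10, L = 30L, seed = 15,
                            delta_hr_load = 16)
  sep <- function(cfg) {
    hr <- vapply(1:8, function(i) {
      p <- generate_subject(cfg, i)
      c(generate_window(p, 0L, cfg, 1L)$labels$hr_bpm,
        generate_window(p, 1L, cfg, 2L)$labels$hr_bpm)
    }, numeric(2))
    mean(hr[2, ] - hr[1, ])
  }
  expect_gt(sep(cfg16), sep(cfg8))
  expect_gt(sep(cfg8), 0)
})

test_that("generator and FFT oracle agree at zero noise (tensor level)", {
  cfg <- synthetic_config(n_subjects = 2L, fps = 30, L = 300L,
                          noise_sigma = 0, lighting_drift = 0, seed = 16)
  prof <- generate_subject(cfg, 1)
  wnd <- generate_window(prof, 0L, cfg, 1L)
  st <- structure(list(values = wnd$tensors$stmap, H = 25L, fps = 30,
                       grid_rows = 5L, grid_cols = 5L), class = "stmap")
  hr <- oracle_rate_from_stmap(st, band = c(0.7, 3))
  expect_lt(abs(hr$rate - wnd$labels$hr_bpm), 60 * 30 / 300)
  rr <- oracle_rate_from_stmap(st, band = c(0.12, 0.5))
  expect_lt(abs(rr$rate - wnd$labels$rr_rpm), 60 * 30 / 300)
})

test_that("pixel-level windows run through the real preprocessing path", {
  wnd <- pixel_window(fps = 10, L = 30L, noise_sigma = 0.01)
  conv <- pixel_window_to_tensors(wnd)
  expect_identical(conv$level, "tensor")
  expect_equal(attr(conv$tensors$leye, "dims"), c(25, 25, 30, 3))
  expect_equal(attr(conv$tensors$mouth, "dims"), c(15, 35, 30, 3))
  expect_equal(dim(conv$tensors$stmap), c(3, 25, 30))
  expect_equal(dim(conv$tensors$facial), c(30, 106, 2))
  expect_true(all(conv$tensors$facial >= 0 & conv$tensors$facial <= 1))
})
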