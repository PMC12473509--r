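make_sin_stmap <- function(freq_hz, fps = 30, L = 300L, H = 25L, noise = 0) {
  tt <- (0:(L - 1)) / fps
  v <- array(0, c(3, H, L))
  for (cell in seq_len(H)) {
    s <- sin(2 * pi * freq_hz * tt + runif(1, 0, 2 * pi)) + rnorm(L, sd = noise)
    for (ch in 1:3) v[ch, cell, ] <- s
  }
  structure(list(values = facephys:::normalize_stmap_rows(v), H = H, fps = fps,
                 grid_rows = 5L, grid_cols = 5L), class = "stmap")
}

test_that("STMap construction: shape, row normalization and degenerate rows", {
  wnd <- pixel_window(fps = 10, L = 40L, noise_sigma = 0.01)
  vw <- structure(list(frames = wnd$frames, landmarks = wnd$landmarks_px,
                       start_frame = 0L, fps = 10, subject_id = "s",
                       trial_id = "t"), class = "video_window")
  st <- build_stmap(vw, 5, 5)
  expect_equal(dim(st$values), c(3, 25, 40))
  expect_true(all(st$values >= 0 & st$values <= 1))
  # non-degenerate rows hit 0 and 1 exactly
  rng <- apply(st$values, c(1, 2), range)
  nondeg <- apply(st$values, c(1, 2), function(v) diff(range(v)) > 0)
  expect_true(all(abs(rng[1, , ][nondeg]) < 1e-12))
  expect_true(all(abs(rng[2, , ][nondeg] - 1) < 1e-12))
  # constant-color video -> every row constant 0.5
  vw$frames[] <- 0.42
  stc <- build_stmap(vw, 5, 5)
  expect_true(all(stc$values == 0.5))
})

test_that("row normalization is equivariant under grid-cell permutation", {
  raw <- array(runif(3 * 10 * 20), c(3, 10, 20))
  perm <- sample(10)
  n1 <- facephys:::normalize_stmap_rows(raw)[, perm, ]
  n2 <- facephys:::normalize_stmap_rows(raw[, perm, , drop = FALSE])
  expect_identical(n1, n2)
})

test_that("FFT oracle recovers an embedded frequency within one bin", {
  set.seed(2)
  st <- make_sin_stmap(1.2, fps = 30, L = 300)
  r <- oracle_rate_from_stmap(st, band = c(0.7, 3))
  expect_false(r$undefined)
  expect_lt(abs(r$freq_hz - 1.2), 30 / 300)        # one nominal bin in Hz
  # 72 beats/min sinusoid
  st2 <- make_sin_stmap(72 / 60, fps = 30, L = 300)
  r2 <- oracle_rate_from_stmap(st2, band = c(0.7, 3))
  expect_lt(abs(r2$rate - 72), 60 * 30 / 300)
})

test_that("oracle flags flat maps and distrusts white noise", {
  flat <- structure(list(values = array(0.5, c(3, 25, 300)), H = 25L,
                         fps = 30, grid_rows = 5L, grid_cols = 5L),
                    class = "stmap")
  r <- oracle_rate_from_stmap(flat)
  expect_true(r$undefined)
  expect_identical(r$confidence, 0)
  expect_true(is.na(r$rate))
  # white-noise confidence is far below a clean sinusoid's
  set.seed(7)
  conf_noise <- replicate(20, {
    v <- array(rnorm(3 * 25 * 300), c(3, 25, 300))
    stn <- structure(list(values = facephys:::normalize_stmap_rows(v), H = 25L,
                          fps = 30, grid_rows = 5L, grid_cols = 5L),
                     class = "stmap")
    oracle_rate_from_stmap(stn)$confidence
  })
  conf_sig <- oracle_rate_from_stmap(make_sin_stmap(1.1))$confidence
  expect_gt(conf_sig, max(conf_noise) * 5)
  expect_error(oracle_rate_from_stmap(flat, band = c(1.0001, 1.0002),
                                      pad_factor = 1L), "empty")
})

test_that("band must be inside the Nyquist range", {
  st <- make_sin_stmap(1)
  expect_error(oracle_rate_from_stmap(st, band = c(0.5, 20)), "band")
})
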