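test_that("temporal shift moves channel groups by one frame with zero fill", {
  L <- 6L
  clip <- array(rnorm(L * 3 * 4 * 5), c(L, 3, 4, 5))
  out <- wtsm(clip, fold_div = 4)
  expect_equal(dim(out), dim(clip))
  # channel 1 shifted forward, channel 2 backward, channel 3 unchanged
  expect_equal(out[2:L, 1, , ], clip[1:(L - 1), 1, , ])
  expect_true(all(out[1, 1, , ] == 0))
  expect_equal(out[1:(L - 1), 2, , ], clip[2:L, 2, , ])
  expect_true(all(out[L, 2, , ] == 0))
  expect_identical(out[, 3, , ], clip[, 3, , ])
  # constant clip: only the vacated frames differ
  cc <- array(1, c(L, 3, 2, 2))
  oc <- wtsm(cc)
  expect_true(all(oc[2:L, 1, , ] == 1) && all(oc[1, 1, , ] == 0))
  expect_true(all(oc[1:(L - 1), 2, , ] == 1) && all(oc[L, 2, , ] == 0))
  # unit impulse in the forward-shifted channel lands one frame later
  im <- array(0, c(L, 3, 2, 2)); im[3, 1, 1, 1] <- 1
  oi <- wtsm(im)
  expect_equal(oi[4, 1, 1, 1], 1)
  expect_equal(sum(oi), 1)
})

test_that("temporal shift is linear and rejects incompatible fold_div", {
  L <- 5L
  a <- array(rnorm(L * 3 * 4), c(L, 3, 2, 2))
  b <- array(rnorm(L * 3 * 4), c(L, 3, 2, 2))
  expect_equal(wtsm(2 * a + 3 * b), 2 * wtsm(a) + 3 * wtsm(b))
  one_ch <- array(0, c(L, 1, 2, 2))
  expect_error(wtsm(one_ch), "incompatible")
})

test_that("subregion embedding maps clips to aligned L x d sequences", {
  set.seed(1)
  clip <- array(runif(300 * 3 * 25 * 25), c(300, 3, 25, 25))
  f <- embed_subregion(clip, d = 16, seed = 2)
  expect_equal(dim(f), c(300, 16))
  expect_true(all(is.finite(f)))
  mouth <- array(runif(50 * 3 * 15 * 35), c(50, 3, 15, 35))
  expect_equal(dim(embed_subregion(mouth, d = 8, seed = 2)), c(50, 8))
  expect_error(embed_subregion(clip, d = 0), "positive")
})

test_that("zero subregion input with zero parameters gives zero output", {
  cfg <- facephys_config(d = 8, c1 = 2, c2 = 3)
  par <- facephys:::with_seed(1, facephys:::init_subregion_params(25, 25, cfg))
  par <- zero_branch_params(par)
  clip <- array(0, c(20, 3, 25, 25))
  f <- embed_subregion(clip, d = 8, params = par, config = cfg)
  expect_true(all(f == 0))
})

test_that("without the temporal shift the embedding is per-frame deterministic", {
  set.seed(3)
  frame <- array(runif(3 * 25 * 25), c(3, 25, 25))
  clip <- array(0, c(10, 3, 25, 25))
  clip[2, , , ] <- frame
  clip[7, , , ] <- frame
  f <- embed_subregion(clip, d = 6, apply_wtsm = FALSE, seed = 4)
  expect_equal(f[2, ], f[7, ])
})

test_that("landmark embedding: shape, zero map and translation sensitivity", {
  set.seed(5)
  lm <- array(runif(300 * 106 * 2), c(300, 106, 2))
  f <- embed_landmarks(lm, d = 16, seed = 6)
  expect_equal(dim(f), c(300, 16))
  cfg <- facephys_config(d = 6, lm_channels = 2)
  par <- facephys:::with_seed(2, facephys:::init_landmark_params(cfg))
  par <- zero_branch_params(par)
  fz <- embed_landmarks(array(0, c(10, 106, 2)), d = 6, params = par,
                        config = cfg)
  expect_true(all(fz == 0))
  # no built-in translation invariance: a uniform shift changes the features
  shifted <- pmin(lm + 0.05, 1)
  fs <- embed_landmarks(shifted, d = 16, seed = 6)
  expect_gt(max(abs(fs - f)), 1e-6)
  expect_error(embed_landmarks(array(0, c(10, 50, 2)), d = 4), "landmark points")
})

test_that("STMap embedding collapses ROIs but preserves the time axis", {
  set.seed(8)
  st <- array(runif(3 * 25 * 300), c(3, 25, 300))
  f <- embed_stmap(st, d = 16, seed = 9)
  expect_equal(dim(f), c(300, 16))
  # time-constant map -> identical feature rows
  cst <- array(rep(runif(3 * 25), times = 40), c(3, 25, 40))
  fc <- embed_stmap(cst, d = 8, seed = 9)
  # interior frames are identical; the two frames at each end see the zero
  # padding of the two same-padded time convolutions
  interior <- fc[3:38, ]
  expect_lt(max(abs(sweep(interior, 2, interior[1, ]))), 1e-10)
  expect_error(embed_stmap(array(0, c(3, 2, 40)), d = 4), "kernel")
})

test_that("feature concatenation enforces alignment and fixed branch order", {
  mk <- function(L, d) matrix(rnorm(L * d), L, d)
  br <- list(left_eye = mk(30, 4), right_eye = mk(30, 4), mouth = mk(30, 4),
             facial = mk(30, 4), stmap = mk(30, 4))
  F1 <- concat_features(br)
  expect_equal(dim(F1), c(30, 20))
  expect_identical(F1[, 1:4], br$left_eye)
  expect_identical(F1[, 17:20], br$stmap)
  big <- lapply(br, function(x) mk(300, 64))
  expect_equal(dim(concat_features(big)), c(300, 320))
  br$mouth <- mk(29, 4)
  expect_error(concat_features(br), "disagree on L")
  expect_error(concat_features(br[-3]), "exactly")
})

test_that("gradient reaches every embedding branch", {
  cfg <- tiny_config()
  ds <- tiny_dataset()
  model <- facephys:::init_model(cfg, 1)
  batch <- facephys:::assemble_batch(ds$windows[1:2], cfg)
  lb <- list(hr = c(0.5, -0.5), rr = c(0.2, 0.1), cog = c(0, 1))
  res <- facephys:::model_loss_grads(model$par, list(), cfg, batch, lb, 1.5)
  for (key in c("sub.leye.conv1.W", "sub.reye.conv1.W", "sub.mouth.conv1.W",
                "lm.conv.W", "stmap.conv1.W", "enc.fwd1.in_proj.W",
                "enc.bwd1.in_proj.W", "head.hr.W1"))
    expect_gt(sum(abs(res$grads[[key]])), 0)
})
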