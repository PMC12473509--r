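test_that("mean pooling: constants, symmetry, permutation invariance", {
  cst <- matrix(rep(c(1, -2, 3), each = 5), 5, 3)
  expect_equal(mean_pool(cst), c(1, -2, 3))
  v <- rnorm(4)
  expect_equal(mean_pool(rbind(v, -v)), numeric(4))
  H <- matrix(rnorm(40), 8, 5)
  expect_equal(mean_pool(H), mean_pool(H[sample(8), ]))
  expect_error(mean_pool(matrix(numeric(0), 0, 3)), "empty")
})

test_that("prediction heads: sigmoid range, zero-parameter fixed point, monotonicity", {
  set.seed(20)
  h <- rnorm(16)
  pr <- predict_heads(h, hidden = 8, seed = 1)
  expect_true(pr$cog_prob > 0 && pr$cog_prob < 1)
  expect_true(is.finite(pr$hr_bpm) && is.finite(pr$rr_rpm))
  # zero final layers: cog_prob = sigmoid(0) = 0.5, regressions 0
  cfg <- list(d_out = 8, head_hidden = 4L)
  par <- facephys:::with_seed(2, facephys:::init_head_params(cfg))
  for (task in c("hr", "rr", "cog")) {
    par[[paste0("head.", task, ".W2")]][] <- 0
    par[[paste0("head.", task, ".b2")]][] <- 0
  }
  pr0 <- predict_heads(rnorm(16), params = par)
  expect_equal(pr0$cog_prob, 0.5)
  expect_equal(pr0$hr_bpm, 0)
  expect_equal(pr0$rr_rpm, 0)
  # raising the pre-sigmoid logit strictly raises the probability
  par2 <- par
  par2[["head.cog.b2"]][] <- 1.3
  expect_gt(predict_heads(h, params = par2)$cog_prob, 0.5)
  expect_error(predict_heads(c(1, NA)), "non-finite")
})

test_that("heads share no parameters: editing one task leaves the others fixed", {
  set.seed(21)
  cfg <- list(d_out = 6, head_hidden = 5L)
  par <- facephys:::init_head_params(cfg)
  nm <- names(par)
  expect_length(unique(nm), length(nm))
  expect_length(grep("^head\\.(hr|rr|cog)\\.", nm), length(nm))
  h <- rnorm(12)
  base <- predict_heads(h, params = par)
  par$head.hr.W1 <- par$head.hr.W1 + 1
  mod <- predict_heads(h, params = par)
  expect_false(isTRUE(all.equal(base$hr_bpm, mod$hr_bpm)))
  expect_identical(base$rr_rpm, mod$rr_rpm)
  expect_identical(base$cog_prob, mod$cog_prob)
})

test_that("end-to-end shape contract on one synthetic window", {
  wnd <- tiny_dataset()$windows[[1]]
  d <- 16L
  seed <- 31L
  leye <- aperm(facephys:::clip_values(wnd$tensors$leye), c(3, 4, 1, 2))
  reye <- aperm(facephys:::clip_values(wnd$tensors$reye), c(3, 4, 1, 2))
  mouth <- aperm(facephys:::clip_values(wnd$tensors$mouth), c(3, 4, 1, 2))
  L <- dim(leye)[1]
  Fm <- concat_features(list(
    left_eye = embed_subregion(leye, d, seed = seed),
    right_eye = embed_subregion(reye, d, seed = seed),
    mouth = embed_subregion(mouth, d, seed = seed),
    facial = embed_landmarks(wnd$tensors$facial, d, seed = seed),
    stmap = embed_stmap(wnd$tensors$stmap, d, seed = seed)))
  expect_equal(dim(Fm), c(L, 5 * d))
  enc <- bidirectional_encode(Fm, depth = 1, seed = seed)
  expect_equal(dim(enc$H_bi), c(L, 2 * 5 * d))
  pr <- predict_heads(mean_pool(enc$H_bi), hidden = 16, seed = seed)
  expect_true(pr$cog_prob > 0 && pr$cog_prob < 1)
  expect_length(pr$hr_bpm, 1)
})
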