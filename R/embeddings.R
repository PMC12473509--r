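# Embedding branches.  Internal activations use the layout (h, w, M, c) with
# M = n_windows * L frames (window-major); feature sequences are (d x M)
# matrices.  Branch parameters are flat named lists of arrays.

# ---- parameter initialization -------------------------------------------------

init_subregion_params <- function(h, w, cfg) {
  c1 <- cfg$c1; c2 <- cfg$c2; d <- cfg$d
  h1 <- (h - 2) %/% 2; w1 <- (w - 2) %/% 2
  h2 <- (h1 - 2) %/% 2; w2 <- (w1 - 2) %/% 2
  if (h2 < 1 || w2 < 1) stop("subregion too small for two conv+pool stages")
  nflat <- h2 * w2 * c2
  list(conv1.W = init_mat(27, c1, 27), conv1.b = numeric(c1),
       conv2.W = init_mat(9 * c1, c2, 9 * c1), conv2.b = numeric(c2),
       fc.W = init_mat(d, nflat, nflat), fc.b = numeric(d))
}

init_landmark_params <- function(cfg) {
  c <- cfg$lm_channels; d <- cfg$d; P <- cfg$landmark_points
  list(conv.W = init_mat(c, 6, 6), conv.b = numeric(c),
       bn.gamma = rep(1, c), bn.beta = numeric(c),
       fc.W = init_mat(d, P * c, P * c), fc.b = numeric(d))
}

init_stmap_params <- function(cfg) {
  c1 <- cfg$stmap_channels; d <- cfg$d
  W1 <- init_mat(27, c1, 27)
  # Signal-processing-informed initialization of the first channels: temporal
  # derivative, temporal curvature and pass-through taps on the green channel
  # (weight row index q = ki + 3*kj + 9*c; kj is the time-axis offset).  The
  # rate information in a min-max-normalized STMap row lives in its temporal
  # derivative amplitude, so seeding these filters makes the oscillation
  # frequency linearly available to the heads from the first iteration.
  kern <- function(time_taps, h_taps = c(0, 1, 0), chan_w = c(0.3, 1, 0.3)) {
    w <- numeric(27)
    for (c in 0:2) for (kj in 0:2) for (ki in 0:2)
      w[ki + 3 * kj + 9 * c + 1] <- chan_w[c + 1] * time_taps[kj + 1] * h_taps[ki + 1]
    w
  }
  if (c1 >= 1) W1[, 1] <- kern(c(-1, 0, 1))
  if (c1 >= 2) W1[, 2] <- kern(c(1, -2, 1))
  if (c1 >= 3) W1[, 3] <- kern(c(0, 1, 0))
  if (c1 >= 4) W1[, 4] <- kern(c(-1, 0, 1), h_taps = c(1, 1, 1) / 3)
  list(conv1.W = W1, conv1.b = numeric(c1),
       bn1.gamma = rep(1, c1), bn1.beta = numeric(c1),
       conv2.W = init_mat(9 * c1, d, 9 * c1), conv2.b = numeric(d),
       bn2.gamma = rep(1, d), bn2.beta = numeric(d))
}

# ---- subregion branch ---------------------------------------------------------

# x: (h, w, M, 3) in [0,1]
subregion_fw <- function(x, par, cfg, L, want_cache = TRUE) {
  d <- dim(x); h <- d[1]; w <- d[2]; M <- d[3]
  xs <- if (cfg$wtsm) wtsm_batch(x, L, cfg$fold_div) else x
  a1 <- conv2d_fw(xs, h, w, M, 3L, par$conv1.W, par$conv1.b, 0L)
  s1 <- silu(a1)
  p1 <- avgpool2_fw(s1, h - 2L, w - 2L, M, cfg$c1)
  dp1 <- dim(p1)
  a2 <- conv2d_fw(p1, dp1[1], dp1[2], M, cfg$c1, par$conv2.W, par$conv2.b, 0L)
  s2 <- silu(a2)
  p2 <- avgpool2_fw(s2, dp1[1] - 2L, dp1[2] - 2L, M, cfg$c2)
  dp2 <- dim(p2)
  # flatten to (h2*w2*c2) x M : need channel-last -> per-frame vector
  flat <- matrix(aperm(p2, c(1, 2, 4, 3)), dp2[1] * dp2[2] * dp2[4], M)
  out <- par$fc.W %*% flat + par$fc.b
  cache <- if (want_cache) list(xs = xs, a1 = a1, p1 = p1, a2 = a2, p2 = p2,
                                flat = flat, dims = list(d, dp1, dp2)) else NULL
  list(out = out, cache = cache)
}

subregion_bw <- function(dout, cache, par, cfg, L) {
  d <- cache$dims[[1]]; dp1 <- cache$dims[[2]]; dp2 <- cache$dims[[3]]
  h <- d[1]; w <- d[2]; M <- d[3]
  g <- list()
  g$fc.W <- tcrossprod(dout, cache$flat)
  g$fc.b <- rowSums(dout)
  dflat <- crossprod(par$fc.W, dout)
  dp2a <- aperm(array(dflat, c(dp2[1], dp2[2], dp2[4], M)), c(1, 2, 4, 3))
  ds2 <- avgpool2_bw(dp2a, dp1[1] - 2L, dp1[2] - 2L, M, cfg$c2)
  da2 <- silu_bw(ds2, cache$a2)
  bw2 <- conv2d_bw(cache$p1, dp1[1], dp1[2], M, cfg$c1, par$conv2.W, da2, 0L, TRUE)
  g$conv2.W <- bw2$dW; g$conv2.b <- as.numeric(bw2$db)
  ds1 <- avgpool2_bw(bw2$dx, h - 2L, w - 2L, M, cfg$c1)
  da1 <- silu_bw(ds1, cache$a1)
  bw1 <- conv2d_bw(cache$xs, h, w, M, 3L, par$conv1.W, da1, 0L, FALSE)
  g$conv1.W <- bw1$dW; g$conv1.b <- as.numeric(bw1$db)
  g
}

# ---- landmark branch ----------------------------------------------------------

# x: (L_total=M frames) landmark array (P, M, 2) -> features (d x M)
landmark_fw <- function(x, par, cfg, bn_state, key, training, want_cache = TRUE) {
  P <- dim(x)[1]; M <- dim(x)[2]
  c <- cfg$lm_channels
  # 'same' 1-D conv over the point axis, 2 coordinate channels, kernel 3
  R6 <- matrix(0, 6, P * M)
  for (ch in 1:2) {
    xm <- x[, , ch]  # P x M
    R6[(ch - 1) * 3 + 1, ] <- as.numeric(rbind(0, xm[-P, , drop = FALSE]))
    R6[(ch - 1) * 3 + 2, ] <- as.numeric(xm)
    R6[(ch - 1) * 3 + 3, ] <- as.numeric(rbind(xm[-1, , drop = FALSE], 0))
  }
  a <- par$conv.W %*% R6 + par$conv.b      # c x (P*M)
  bn <- bn_fw(t(a), par$bn.gamma, par$bn.beta, bn_state, key, training)
  s0 <- t(bn$out)
  s <- silu(s0)
  flat <- matrix(array(s, c(c, P, M)), c * P, M)
  out <- par$fc.W %*% flat + par$fc.b
  cache <- if (want_cache) list(R6 = R6, bncache = bn$cache, s0 = s0,
                                flat = flat, P = P, M = M) else NULL
  list(out = out, cache = cache, state = bn$state)
}

landmark_bw <- function(dout, cache, par, cfg) {
  P <- cache$P; M <- cache$M; c <- cfg$lm_channels
  g <- list()
  g$fc.W <- tcrossprod(dout, cache$flat)
  g$fc.b <- rowSums(dout)
  dflat <- crossprod(par$fc.W, dout)
  ds <- matrix(array(dflat, c(c, P, M)), c, P * M)
  ds0 <- silu_bw(ds, cache$s0)
  bnb <- bn_bw(t(ds0), cache$bncache, par$bn.gamma)
  g$bn.gamma <- bnb$dgamma; g$bn.beta <- bnb$dbeta
  da <- t(bnb$dx)
  g$conv.W <- tcrossprod(da, cache$R6)
  g$conv.b <- rowSums(da)
  g
}

# ---- STMap branch -------------------------------------------------------------

# x: (H, L, B, 3) -> features (d x M), M = B*L window-major
stmap_fw <- function(x, par, cfg, bn_state, training, want_cache = TRUE) {
  d <- dim(x); H <- d[1]; Lw <- d[2]; B <- d[3]
  dd <- cfg$d; c1 <- cfg$stmap_channels
  a1 <- conv2d_fw(x, H, Lw, B, 3L, par$conv1.W, par$conv1.b, 1L)
  bn1 <- bn_fw(matrix(a1, H * Lw * B, c1), par$bn1.gamma, par$bn1.beta,
               bn_state, "stmap.bn1", training)
  s1c <- array(bn1$out, c(H, Lw, B, c1))
  s1 <- silu(s1c)
  a2 <- conv2d_fw(s1, H, Lw, B, c1, par$conv2.W, par$conv2.b, 1L)
  bn2 <- bn_fw(matrix(a2, H * Lw * B, dd), par$bn2.gamma, par$bn2.beta,
               bn1$state, "stmap.bn2", training)
  s2c <- array(bn2$out, c(H, Lw, B, dd))
  s2 <- silu(s2c)
  pooled <- colMeans(matrix(s2, H, Lw * B * dd))      # adaptive pool over H
  pooled <- array(pooled, c(Lw, B, dd))
  out <- matrix(aperm(pooled, c(3, 1, 2)), dd, Lw * B)
  cache <- if (want_cache) list(x = x, bn1cache = bn1$cache, s1pre = s1c,
                                s1 = s1, bn2cache = bn2$cache, s2pre = s2c,
                                dims = d) else NULL
  list(out = out, cache = cache, state = bn2$state)
}

stmap_bw <- function(dout, cache, par, cfg) {
  d <- cache$dims; H <- d[1]; Lw <- d[2]; B <- d[3]
  dd <- cfg$d; c1 <- cfg$stmap_channels
  g <- list()
  dpool <- aperm(array(dout, c(dd, Lw, B)), c(2, 3, 1))     # (Lw, B, dd)
  ds2 <- array(rep(as.numeric(dpool) / H, each = H), c(H, Lw, B, dd))
  ds2pre <- silu_bw(ds2, cache$s2pre)
  bn2b <- bn_bw(matrix(ds2pre, H * Lw * B, dd), cache$bn2cache, par$bn2.gamma)
  g$bn2.gamma <- bn2b$dgamma; g$bn2.beta <- bn2b$dbeta
  da2 <- array(bn2b$dx, c(H, Lw, B, dd))
  bw2 <- conv2d_bw(cache$s1, H, Lw, B, c1, par$conv2.W, da2, 1L, TRUE)
  g$conv2.W <- bw2$dW; g$conv2.b <- as.numeric(bw2$db)
  ds1pre <- silu_bw(bw2$dx, cache$s1pre)
  bn1b <- bn_bw(matrix(ds1pre, H * Lw * B, c1), cache$bn1cache, par$bn1.gamma)
  g$bn1.gamma <- bn1b$dgamma; g$bn1.beta <- bn1b$dbeta
  da1 <- array(bn1b$dx, c(H, Lw, B, c1))
  bw1 <- conv2d_bw(cache$x, H, Lw, B, 3L, par$conv1.W, da1, 1L, FALSE)
  g$conv1.W <- bw1$dW; g$conv1.b <- as.numeric(bw1$db)
  g
}

# ---- user-facing single-window ops -------------------------------------------

#' Embed a subregion clip into a per-frame feature sequence
#'
#' Applies the temporal shift (optional), two 3x3 convolution + SiLU + 2x2
#' average-pooling stages and a per-frame fully connected map to `d`
#' dimensions.  Every frame is embedded independently, so the output length
#' equals the clip length with no interpolation.
#'
#' @param clip a `"subregion_clip"` or `(L, 3, h, w)` array in `[0, 1]`.
#' @param d output feature dimension.
#' @param params optional branch parameters (as created internally); a fresh
#'   seeded initialization is drawn when `NULL`.
#' @param config optional `"facephys_config"`; defaults to
#'   `facephys_config(d = d)` sizes.
#' @param apply_wtsm logical, apply the temporal shift first.
#' @param seed seed for the fresh initialization.
#' @return `L x d` feature matrix with attribute `source`.
#' @export
embed_subregion <- function(clip, d = 64L, params = NULL, config = NULL,
                            apply_wtsm = TRUE, seed = 1L) {
  if (d <= 0) stop("`d` must be positive")
  x <- if (inherits(clip, "subregion_clip")) clip$pixels else clip
  dd <- dim(x)
  if (length(dd) != 4 || dd[2] != 3) stop("clip must be (L, 3, h, w)")
  cfg <- config %||% facephys_config(d = d, window_length = dd[1])
  cfg$wtsm <- isTRUE(apply_wtsm)
  if (is.null(params))
    params <- with_seed(seed, init_subregion_params(dd[3], dd[4], cfg))
  xi <- aperm(x, c(3, 4, 1, 2))
  out <- subregion_fw(xi, params, cfg, L = dd[1], want_cache = FALSE)$out
  res <- t(out)
  attr(res, "source") <- if (inherits(clip, "subregion_clip")) clip$region else "subregion"
  res
}

#' Embed normalized landmarks into a per-frame feature sequence
#'
#' Treats each frame's `P x 2` landmark array as a 2-channel 1-D signal over
#' the point axis: a kernel-3 convolution with batch normalization and SiLU,
#' flattened and mapped to `d` dimensions per frame.  Note there is no built-in
#' translation invariance: shifting all landmarks changes the features.
#'
#' @param lm a `"landmark_window"` or `(L, P, 2)` array in `[0, 1]`.
#' @param d output feature dimension.
#' @param params optional branch parameters.
#' @param config optional configuration.
#' @param seed seed for fresh initialization.
#' @return `L x d` feature matrix with attribute `source = "facial"`.
#' @export
embed_landmarks <- function(lm, d = 64L, params = NULL, config = NULL,
                            seed = 1L) {
  x <- unclass(lm)
  dd <- dim(x)
  if (length(dd) != 3 || dd[3] != 2) stop("landmarks must be (L, P, 2)")
  cfg <- config %||% facephys_config(d = d, window_length = dd[1])
  if (dd[2] != cfg$landmark_points)
    stop("expected ", cfg$landmark_points, " landmark points, got ", dd[2])
  if (is.null(params)) params <- with_seed(seed, init_landmark_params(cfg))
  xi <- aperm(x, c(2, 1, 3))      # (P, M=L, 2)
  st <- new.env(parent = emptyenv())
  state <- list()
  res <- landmark_fw(xi, params, cfg, state, "lm.bn", training = TRUE)
  out <- t(res$out)
  attr(out, "source") <- "facial"
  out
}

#' Embed an STMap into a per-frame feature sequence
#'
#' Two 3x3 same-padded convolution + batch-normalization + SiLU stages over
#' the `H x L` map (channels 3 to `stmap_channels` to `d`), followed by
#' adaptive average pooling that collapses the ROI axis, leaving an `L x d`
#' sequence aligned with the other branches.
#'
#' @param stmap an `"stmap"` object or `(3, H, L)` array.
#' @param d output feature dimension.
#' @param params optional branch parameters.
#' @param config optional configuration.
#' @param seed seed for fresh initialization.
#' @return `L x d` feature matrix with attribute `source = "stmap"`.
#' @export
embed_stmap <- function(stmap, d = 64L, params = NULL, config = NULL,
                        seed = 1L) {
  v <- if (inherits(stmap, "stmap")) stmap$values else stmap
  dd <- dim(v)
  if (length(dd) != 3 || dd[1] != 3) stop("stmap values must be (3, H, L)")
  if (dd[2] < 3) stop("H smaller than kernel size")
  cfg <- config %||% facephys_config(d = d, window_length = dd[3])
  if (is.null(params)) params <- with_seed(seed, init_stmap_params(cfg))
  xi <- array(aperm(v, c(2, 3, 1)), c(dd[2], dd[3], 1, 3))
  res <- stmap_fw(xi, params, cfg, list(), training = TRUE)
  out <- t(res$out)
  attr(out, "source") <- "stmap"
  out
}

#' Concatenate the five branch feature sequences
#'
#' Column-wise concatenation in the fixed order left eye, right eye, mouth,
#' facial landmarks, STMap, giving `F` of width `D = 5 d`.  All branches must
#' share the same length and feature dimension and each tag must appear
#' exactly once.
#'
#' @param branches named list with elements `left_eye`, `right_eye`, `mouth`,
#'   `facial`, `stmap`, each an `L x d` matrix.
#' @return `L x D` matrix of class `"concat_features"` with attribute
#'   `branch_order`.
#' @export
concat_features <- function(branches) {
  order <- c("left_eye", "right_eye", "mouth", "facial", "stmap")
  if (!setequal(names(branches), order) || anyDuplicated(names(branches)))
    stop("branches must be exactly: ", paste(order, collapse = ", "))
  mats <- branches[order]
  dims <- vapply(mats, dim, integer(2))
  if (length(unique(dims[1, ])) != 1) stop("branches disagree on L")
  if (length(unique(dims[2, ])) != 1) stop("branches disagree on d")
  out <- do.call(cbind, mats)
  class(out) <- c("concat_features", class(out))
  attr(out, "branch_order") <- order
  out
}
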