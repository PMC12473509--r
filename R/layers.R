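# Elementary differentiable layers used by the embedding branches, encoder and
# heads.  Every *_fw returns a list(out, cache); the matching *_bw consumes the
# upstream gradient and the cache.  Parameters live in flat named lists; the
# backward passes return gradients under the same names.

silu <- function(x) silu_fw_cpp(x)

silu_fw <- function(x) list(out = silu_fw_cpp(x), cache = x)
silu_bw <- function(dout, cache) silu_bw_cpp(dout, cache)

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

# y = W %*% x + b ; x: (din x M)
linear_fw <- function(x, W, b = NULL) {
  out <- W %*% x
  if (!is.null(b)) out <- out + b
  list(out = out, cache = x)
}
linear_bw <- function(dout, cache, W, has_bias = TRUE) {
  list(dx = crossprod(W, dout), dW = tcrossprod(dout, cache),
       db = if (has_bias) rowSums(dout) else NULL)
}

# Batch normalization over all but the channel axis.
# x: matrix (n x C) where rows pool batch and spatial positions.
bn_fw <- function(x, gamma, beta, state, key, training, momentum = 0.1,
                  eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- colMeans(xc^2)
    state[[key]] <- list(
      mean = if (is.null(state[[key]])) mu else
        (1 - momentum) * state[[key]]$mean + momentum * mu,
      var = if (is.null(state[[key]])) v else
        (1 - momentum) * state[[key]]$var + momentum * v)
  } else {
    st <- state[[key]]
    if (is.null(st)) st <- list(mean = rep(0, ncol(x)), var = rep(1, ncol(x)))
    mu <- st$mean; v <- st$var
    xc <- sweep(x, 2, mu)
  }
  istd <- 1 / sqrt(v + eps)
  xn <- sweep(xc, 2, istd, `*`)
  out <- sweep(sweep(xn, 2, gamma, `*`), 2, beta, `+`)
  list(out = out, cache = list(xn = xn, istd = istd, training = training),
       state = state)
}
bn_bw <- function(dout, cache, gamma) {
  xn <- cache$xn; istd <- cache$istd
  n <- nrow(dout)
  dgamma <- colSums(dout * xn)
  dbeta <- colSums(dout)
  dxn <- sweep(dout, 2, gamma, `*`)
  if (cache$training) {
    # full batch-norm backward (mean/var depend on x)
    dx <- sweep(dxn - matrix(colMeans(dxn), n, ncol(dxn), byrow = TRUE) -
                  sweep(xn, 2, colMeans(dxn * xn), `*`), 2, istd, `*`)
  } else {
    dx <- sweep(dxn, 2, istd, `*`)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# RMS normalization per column of x (D x M) with gain g (D)
rmsnorm_fw <- function(x, g, eps = 1e-6) {
  ms <- sqrt(colMeans(x^2) + eps)
  xn <- sweep(x, 2, ms, `/`)
  list(out = xn * g, cache = list(x = x, xn = xn, ms = ms))
}
rmsnorm_bw <- function(dout, cache, g) {
  xn <- cache$xn; ms <- cache$ms
  D <- nrow(dout)
  dxn <- dout * g
  dg <- rowSums(dout * xn)
  # d/dx of x / sqrt(mean(x^2)+eps)
  dot <- colSums(dxn * xn) / D
  dx <- sweep(dxn, 2, ms, `/`) - sweep(xn, 2, dot / ms, `*`)
  list(dx = dx, dg = dg)
}

#' Temporal shift (WTSM) of a subregion clip
#'
#' Splits the channels into three groups: the first group is shifted forward
#' one frame, the second backward one frame, the remainder left in place;
#' vacated frames are zero-filled.  The operation is linear and
#' shape-preserving, and mixes adjacent-frame information into each frame
#' before the spatial convolutions.  The number of shifted channels per
#' direction is `max(1, floor(C / fold_div))`; `fold_div` is incompatible with
#' the channel count if twice that exceeds `C`.
#'
#' @param clip a `"subregion_clip"` (or a numeric array `(L, C, h, w)`).
#' @param fold_div fold divisor (default 4).
#' @return object of the same shape and class as the input.
#' @export
wtsm <- function(clip, fold_div = 4L) {
  x <- if (inherits(clip, "subregion_clip")) clip$pixels else clip
  d <- dim(x)
  if (length(d) != 4) stop("expected a (L, C, h, w) clip")
  L <- d[1]; C <- d[2]
  if (L < 2) stop("clip must have at least 2 frames")
  # internal layout (h, w, M, c)
  xi <- aperm(x, c(3, 4, 1, 2))
  out <- wtsm_batch(xi, L = L, fold_div = fold_div)
  res <- aperm(out, c(3, 4, 1, 2))
  if (inherits(clip, "subregion_clip")) {
    clip$pixels <- res
    clip
  } else res
}

wtsm_fold <- function(C, fold_div) {
  if (fold_div < 1) stop("fold_div must be >= 1")
  fold <- max(1L, C %/% as.integer(fold_div))
  if (2L * fold > C)
    stop("fold_div incompatible with channel count: 2*", fold, " > ", C)
  fold
}

# x: (h, w, M, C) with M = n_windows * L; shift along frames within windows
wtsm_batch <- function(x, L, fold_div = 4L) {
  d <- dim(x)
  C <- d[4]; M <- d[3]
  fold <- wtsm_fold(C, fold_div)
  nwin <- M %/% L
  out <- x
  first <- (seq_len(nwin) - 1L) * L + 1L
  last <- (seq_len(nwin)) * L
  fwd <- seq_len(fold); bwd <- fold + seq_len(fold)
  # forward shift: frame t receives frame t-1
  out[, , -first, fwd] <- x[, , -last, fwd]
  out[, , first, fwd] <- 0
  # backward shift: frame t receives frame t+1
  out[, , -last, bwd] <- x[, , -first, bwd]
  out[, , last, bwd] <- 0
  out
}

# transpose of wtsm_batch (shift directions swapped)
wtsm_batch_bw <- function(dout, L, fold_div = 4L) {
  d <- dim(dout)
  C <- d[4]; M <- d[3]
  fold <- wtsm_fold(C, fold_div)
  nwin <- M %/% L
  dx <- dout
  first <- (seq_len(nwin) - 1L) * L + 1L
  last <- (seq_len(nwin)) * L
  fwd <- seq_len(fold); bwd <- fold + seq_len(fold)
  dx[, , -last, fwd] <- dout[, , -first, fwd]
  dx[, , last, fwd] <- 0
  dx[, , -first, bwd] <- dout[, , -last, bwd]
  dx[, , first, bwd] <- 0
  dx
}

# He-style initialization helpers (caller controls the RNG state)
init_mat <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}
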