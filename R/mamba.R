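# Mamba block and bidirectional encoder.  Internal feature matrices are
# (D x M) with M = n_windows * L, window-major; the selective scan and the
# depthwise causal convolution reset their state at window boundaries.

# inverse softplus
softplus_inv <- function(y) log(expm1(y))

init_mamba_params <- function(cfg, prefix = "") {
  D <- cfg$D; E <- cfg$E; N <- cfg$n_state; r <- cfg$dt_rank; K <- cfg$conv_width
  dt_init <- softplus_inv(exp(runif(E, log(1e-3), log(1e-1))))
  p <- list(
    norm.g = rep(1, D),
    in_proj.W = init_mat(2L * E, D, D),
    conv.w = matrix(rnorm(E * K, sd = sqrt(1 / K)), E, K),
    conv.b = numeric(E),
    x_proj.W = init_mat(r + 2L * N, E, E),
    dt_proj.W = matrix(rnorm(E * r, sd = r^-0.5), E, r),
    dt_proj.b = dt_init,
    A_log = matrix(rep(log(seq_len(N)), each = E), E, N),
    D_skip = rep(1, E),
    # residual-branch output scaled down so a depth-L stack keeps unit scale
    out_proj.W = init_mat(D, E, E) / sqrt(2 * max(1, cfg$depth)))
  if (nzchar(prefix)) names(p) <- paste0(prefix, names(p))
  p
}

# forward through one block; x: D x M
mamba_block_fw <- function(x, par, cfg, L, want_cache = TRUE) {
  E <- cfg$E; N <- cfg$n_state; r <- cfg$dt_rank
  rn <- rmsnorm_fw(x, par$norm.g)
  U <- par$in_proj.W %*% rn$out
  Xp <- U[seq_len(E), , drop = FALSE]
  Z <- U[E + seq_len(E), , drop = FALSE]
  Xc0 <- dwconv_fw(Xp, par$conv.w, par$conv.b, L)
  Xc <- silu(Xc0)
  P <- par$x_proj.W %*% Xc
  dtin <- P[seq_len(r), , drop = FALSE]
  Bm <- P[r + seq_len(N), , drop = FALSE]
  Cm <- P[r + N + seq_len(N), , drop = FALSE]
  dt0 <- par$dt_proj.W %*% dtin + par$dt_proj.b
  delta <- softplus(dt0)
  A <- -exp(par$A_log)
  y <- selective_scan_fw(Xc, delta, A, Bm, Cm, par$D_skip, L, cfg$bbar_exact)
  sz <- silu(Z)
  G <- y * sz
  out <- par$out_proj.W %*% G + x
  cache <- if (want_cache) list(rn = rn, Xp = Xp, Xc0 = Xc0, Xc = Xc,
                                dtin = dtin, Bm = Bm, Cm = Cm, dt0 = dt0,
                                delta = delta, A = A, y = y, Z = Z, sz = sz,
                                G = G) else NULL
  list(out = out, cache = cache)
}

mamba_block_bw <- function(dout, cache, par, cfg, L) {
  E <- cfg$E; N <- cfg$n_state; r <- cfg$dt_rank
  g <- list()
  g$out_proj.W <- tcrossprod(dout, cache$G)
  dG <- crossprod(par$out_proj.W, dout)
  dy <- dG * cache$sz
  dZ <- silu_bw(dG * cache$y, cache$Z)
  sb <- selective_scan_bw(cache$Xc, cache$delta, cache$A, cache$Bm, cache$Cm,
                          par$D_skip, L, cfg$bbar_exact, dy)
  g$D_skip <- as.numeric(sb$dD)
  g$A_log <- sb$dA * (-exp(par$A_log))
  ddt0 <- sb$ddelta * plogis(cache$dt0)
  g$dt_proj.W <- tcrossprod(ddt0, cache$dtin)
  g$dt_proj.b <- rowSums(ddt0)
  dP <- rbind(crossprod(par$dt_proj.W, ddt0), sb$dB, sb$dC)
  g$x_proj.W <- tcrossprod(dP, cache$Xc)
  dXc <- sb$du + crossprod(par$x_proj.W, dP)
  dXc0 <- silu_bw(dXc, cache$Xc0)
  cb <- dwconv_bw(cache$Xp, par$conv.w, dXc0, L)
  g$conv.w <- cb$dw
  g$conv.b <- as.numeric(cb$db)
  dU <- rbind(cb$dx, dZ)
  g$in_proj.W <- tcrossprod(dU, cache$rn$out)
  drn <- crossprod(par$in_proj.W, dU)
  rb <- rmsnorm_bw(drn, cache$rn$cache, par$norm.g)
  g$norm.g <- rb$dg
  list(dx = dout + rb$dx, grads = g)
}

#' Apply one Mamba block to a feature sequence
#'
#' Pre-normalization, input projection to an expanded width, depthwise causal
#' convolution with SiLU, a selective state-space scan (diagonal A with
#' negative entries via `A = -exp(A_log)`, input-dependent `delta`, `B`, `C`,
#' ZOH discretization), a multiplicative SiLU gate and an output projection
#' with residual connection.  Shape-preserving and causal: outputs at time `t`
#' depend only on inputs at times `<= t`.
#'
#' @param x `L x D` feature matrix (a single window).
#' @param params optional block parameters; freshly initialized when `NULL`.
#' @param config a `"facephys_config"` (its `D` must equal `ncol(x)`);
#'   defaults to a config with `d = ncol(x)/5` when compatible.
#' @param seed seed for fresh initialization.
#' @return `L x D` matrix.
#' @export
mamba_block <- function(x, params = NULL, config = NULL, seed = 1L) {
  if (!is.matrix(x)) stop("x must be an L x D matrix")
  D <- ncol(x)
  cfg <- config %||% {
    if (D %% 5 == 0) facephys_config(d = D / 5, window_length = nrow(x))
    else stop("provide `config` when D is not a multiple of 5")
  }
  if (cfg$D != D) stop("config width D = ", cfg$D, " does not match input ", D)
  if (any(!is.finite(x))) stop("non-finite input")
  if (is.null(params)) params <- with_seed(seed, init_mamba_params(cfg))
  t(mamba_block_fw(t(x), params, cfg, L = nrow(x), want_cache = FALSE)$out)
}

# reverse the time axis of each window in a (D x M) matrix
reverse_time <- function(x, L) {
  M <- ncol(x)
  nwin <- M %/% L
  idx <- as.integer(outer(L:1, (seq_len(nwin) - 1L) * L, `+`))
  x[, idx, drop = FALSE]
}

init_encoder_params <- function(cfg) {
  par <- list()
  for (dir in c("fwd", "bwd")) {
    for (b in seq_len(cfg$depth)) {
      bp <- init_mamba_params(cfg)
      names(bp) <- paste0("enc.", dir, b, ".", names(bp))
      par <- c(par, bp)
    }
    zp <- list(W = init_mat(cfg$d_out, cfg$D, cfg$D), b = numeric(cfg$d_out))
    names(zp) <- paste0("enc.", dir, ".zmap.", names(zp))
    par <- c(par, zp)
  }
  par
}

block_par <- function(par, prefix) {
  sel <- startsWith(names(par), prefix)
  bp <- par[sel]
  names(bp) <- substring(names(bp), nchar(prefix) + 1L)
  bp
}

# encoder forward; Fmat: D x M. Returns H_bi (2*d_out x M) and caches.
encoder_fw <- function(Fmat, par, cfg, L, want_cache = TRUE) {
  caches <- list(fwd = vector("list", cfg$depth),
                 bwd = vector("list", cfg$depth))
  h <- Fmat
  for (b in seq_len(cfg$depth)) {
    res <- mamba_block_fw(h, block_par(par, sprintf("enc.fwd%d.", b)), cfg, L,
                          want_cache)
    caches$fwd[[b]] <- res$cache
    h <- res$out
  }
  H_fwd <- h
  h <- reverse_time(Fmat, L)
  for (b in seq_len(cfg$depth)) {
    res <- mamba_block_fw(h, block_par(par, sprintf("enc.bwd%d.", b)), cfg, L,
                          want_cache)
    caches$bwd[[b]] <- res$cache
    h <- res$out
  }
  H_bwd <- reverse_time(h, L)   # re-align to forward time order
  Zf <- par[["enc.fwd.zmap.W"]] %*% H_fwd + par[["enc.fwd.zmap.b"]]
  Zb <- par[["enc.bwd.zmap.W"]] %*% H_bwd + par[["enc.bwd.zmap.b"]]
  list(H_bi = rbind(Zf, Zb), H_fwd = H_fwd, H_bwd = H_bwd,
       caches = if (want_cache) caches else NULL)
}

encoder_bw <- function(dHbi, enc, par, cfg, L) {
  dd <- cfg$d_out
  g <- list()
  dZf <- dHbi[seq_len(dd), , drop = FALSE]
  dZb <- dHbi[dd + seq_len(dd), , drop = FALSE]
  g[["enc.fwd.zmap.W"]] <- tcrossprod(dZf, enc$H_fwd)
  g[["enc.fwd.zmap.b"]] <- rowSums(dZf)
  g[["enc.bwd.zmap.W"]] <- tcrossprod(dZb, enc$H_bwd)
  g[["enc.bwd.zmap.b"]] <- rowSums(dZb)
  dh <- crossprod(par[["enc.fwd.zmap.W"]], dZf)
  for (b in rev(seq_len(cfg$depth))) {
    prefix <- sprintf("enc.fwd%d.", b)
    res <- mamba_block_bw(dh, enc$caches$fwd[[b]], block_par(par, prefix),
                          cfg, L)
    names(res$grads) <- paste0(prefix, names(res$grads))
    g <- c(g, res$grads)
    dh <- res$dx
  }
  dF <- dh
  dh <- reverse_time(crossprod(par[["enc.bwd.zmap.W"]], dZb), L)
  for (b in rev(seq_len(cfg$depth))) {
    prefix <- sprintf("enc.bwd%d.", b)
    res <- mamba_block_bw(dh, enc$caches$bwd[[b]], block_par(par, prefix),
                          cfg, L)
    names(res$grads) <- paste0(prefix, names(res$grads))
    g <- c(g, res$grads)
    dh <- res$dx
  }
  dF <- dF + reverse_time(dh, L)
  list(dF = dF, grads = g)
}

#' Bidirectional Mamba encoding of a concatenated feature sequence
#'
#' Runs `depth` Mamba blocks forward over `F` and an independent stack over
#' the time-reversed sequence, re-reverses the backward output so both share
#' the forward time order, applies a per-direction linear map to `d_out`
#' dimensions and concatenates: `H_bi = [Z_forward || Z_backward]` of width
#' `2 d_out`.
#'
#' @param F `L x D` feature matrix (e.g. from [concat_features()]).
#' @param depth blocks per direction (default 3).
#' @param params optional encoder parameters; freshly initialized when `NULL`.
#' @param config optional `"facephys_config"` matching `D`.
#' @param seed seed for fresh initialization.
#' @return list with `H_bi` (`L x 2 d_out`), `H_forward`, `H_backward`,
#'   `Z_forward`, `Z_backward`.
#' @export
bidirectional_encode <- function(F, depth = 3L, params = NULL, config = NULL,
                                 seed = 1L) {
  if (depth < 1) stop("depth must be >= 1")
  D <- ncol(F)
  cfg <- config %||% {
    if (D %% 5 == 0) facephys_config(d = D / 5, depth = depth,
                                     window_length = nrow(F))
    else stop("provide `config` when D is not a multiple of 5")
  }
  cfg$depth <- as.integer(depth)
  if (is.null(params)) params <- with_seed(seed, init_encoder_params(cfg))
  enc <- encoder_fw(t(unclass(F)), params, cfg, L = nrow(F), want_cache = FALSE)
  dd <- cfg$d_out
  list(H_bi = t(enc$H_bi),
       H_forward = t(enc$H_fwd), H_backward = t(enc$H_bwd),
       Z_forward = t(enc$H_bi[seq_len(dd), , drop = FALSE]),
       Z_backward = t(enc$H_bi[dd + seq_len(dd), , drop = FALSE]))
}
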