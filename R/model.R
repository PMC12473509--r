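# Full model assembly: five embedding branches -> concatenation -> bidirectional
# encoder -> mean pooling -> three heads.  Parameters are one flat named list.

#' Initialize the full model
#'
#' Draws all parameters from the configured architecture with a single seed,
#' so two models initialized with the same `(config, seed)` are identical.
#'
#' @param config a [facephys_config()].
#' @param seed integer seed.
#' @return list of class `"facephys_model"` with `par` (flat named parameter
#'   list), `bn_state` (batch-normalization running statistics) and `config`.
#' @export
init_model <- function(config = facephys_config(), seed = 1L) {
  stopifnot(inherits(config, "facephys_config"))
  par <- with_seed(mix_seed(seed, 11), {
    p <- list()
    for (rg in c("leye", "reye")) {
      bp <- init_subregion_params(config$eye_size[1], config$eye_size[2], config)
      names(bp) <- paste0("sub.", rg, ".", names(bp))
      p <- c(p, bp)
    }
    bp <- init_subregion_params(config$mouth_size[1], config$mouth_size[2], config)
    names(bp) <- paste0("sub.mouth.", names(bp))
    p <- c(p, bp)
    bp <- init_landmark_params(config)
    names(bp) <- paste0("lm.", names(bp))
    p <- c(p, bp)
    bp <- init_stmap_params(config)
    names(bp) <- paste0("stmap.", names(bp))
    p <- c(p, bp)
    p <- c(p, init_encoder_params(config))
    c(p, init_head_params(config))
  })
  structure(list(par = par, bn_state = list(), config = config),
            class = "facephys_model")
}

#' Count trainable parameters
#'
#' @param x a `"facephys_model"`, a fitted `"facephys"` object, or a
#'   `"facephys_config"` (a model is initialized to count).
#' @return integer parameter count.
#' @export
n_parameters <- function(x) {
  if (inherits(x, "facephys_config")) x <- init_model(x, seed = 1L)
  par <- if (inherits(x, "facephys")) x$par else x$par
  sum(vapply(par, length, integer(1)))
}

# ---- batch assembly -----------------------------------------------------------

# Assemble internal batch arrays from a list of tensor-level window samples.
assemble_batch <- function(windows, cfg) {
  B <- length(windows)
  L <- windows[[1]]$L
  eh <- cfg$eye_size[1]; ew <- cfg$eye_size[2]
  mh <- cfg$mouth_size[1]; mw <- cfg$mouth_size[2]
  H <- cfg$grid_rows * cfg$grid_cols
  M <- B * L
  leye <- array(0, c(eh, ew, M, 3)); reye <- array(0, c(eh, ew, M, 3))
  mouth <- array(0, c(mh, mw, M, 3))
  facial <- array(0, c(cfg$landmark_points, M, 2))
  stm <- array(0, c(H, L, B, 3))
  for (b in seq_len(B)) {
    wnd <- windows[[b]]
    if (wnd$level != "tensor")
      stop("window ", wnd$window_id, " is not tensor-level; run ",
           "pixel_window_to_tensors() first")
    idx <- (b - 1L) * L + seq_len(L)
    le <- clip_values(wnd$tensors$leye)
    re <- clip_values(wnd$tensors$reye)
    mo <- clip_values(wnd$tensors$mouth)
    for (ch in 1:3) {
      leye[, , idx, ch] <- le[, , , ch]
      reye[, , idx, ch] <- re[, , , ch]
      mouth[, , idx, ch] <- mo[, , , ch]
      stm[, , b, ch] <- wnd$tensors$stmap[ch, , ]
    }
    facial[, idx, ] <- aperm(wnd$tensors$facial, c(2, 1, 3))
  }
  list(leye = leye, reye = reye, mouth = mouth, facial = facial, stmap = stm,
       B = B, L = L)
}

# ---- full forward / backward --------------------------------------------------

model_forward <- function(par, bn_state, cfg, batch, training,
                          want_cache = TRUE) {
  L <- batch$L; B <- batch$B
  sub_le <- subregion_fw(batch$leye, block_par(par, "sub.leye."), cfg, L, want_cache)
  sub_re <- subregion_fw(batch$reye, block_par(par, "sub.reye."), cfg, L, want_cache)
  sub_mo <- subregion_fw(batch$mouth, block_par(par, "sub.mouth."), cfg, L, want_cache)
  lm <- landmark_fw(batch$facial, block_par(par, "lm."), cfg, bn_state,
                    "lm.bn", training, want_cache)
  bn_state <- lm$state
  st <- stmap_fw(batch$stmap, block_par(par, "stmap."), cfg, bn_state,
                 training, want_cache)
  bn_state <- st$state
  Fmat <- rbind(sub_le$out, sub_re$out, sub_mo$out, lm$out, st$out)
  enc <- encoder_fw(Fmat, par, cfg, L, want_cache)
  # mean pooling over time, per window
  pool <- matrix(0, 2L * cfg$d_out, B)
  for (b in seq_len(B))
    pool[, b] <- rowMeans(enc$H_bi[, (b - 1L) * L + seq_len(L), drop = FALSE])
  hd <- heads_fw(pool, par, want_cache)
  list(preds = hd$out, bn_state = bn_state,
       cache = if (want_cache)
         list(sub_le = sub_le$cache, sub_re = sub_re$cache,
              sub_mo = sub_mo$cache, lm = lm$cache, st = st$cache,
              enc = enc, pool = pool, heads = hd$cache, Fmat = Fmat) else NULL)
}

model_backward <- function(par, cfg, batch, cache, douts) {
  L <- batch$L; B <- batch$B
  hb <- heads_bw(douts, cache$heads, cache$pool, par)
  g <- hb$grads
  # distribute pooled gradient uniformly over time
  dHbi <- matrix(0, 2L * cfg$d_out, B * L)
  for (b in seq_len(B))
    dHbi[, (b - 1L) * L + seq_len(L)] <- hb$dhf[, b] / L
  eb <- encoder_bw(dHbi, cache$enc, par, cfg, L)
  g <- c(g, eb$grads)
  d <- cfg$d
  dF <- eb$dF
  gs <- subregion_bw(dF[seq_len(d), , drop = FALSE], cache$sub_le,
                     block_par(par, "sub.leye."), cfg, L)
  names(gs) <- paste0("sub.leye.", names(gs)); g <- c(g, gs)
  gs <- subregion_bw(dF[d + seq_len(d), , drop = FALSE], cache$sub_re,
                     block_par(par, "sub.reye."), cfg, L)
  names(gs) <- paste0("sub.reye.", names(gs)); g <- c(g, gs)
  gs <- subregion_bw(dF[2 * d + seq_len(d), , drop = FALSE], cache$sub_mo,
                     block_par(par, "sub.mouth."), cfg, L)
  names(gs) <- paste0("sub.mouth.", names(gs)); g <- c(g, gs)
  gs <- landmark_bw(dF[3 * d + seq_len(d), , drop = FALSE], cache$lm,
                    block_par(par, "lm."), cfg)
  names(gs) <- paste0("lm.", names(gs)); g <- c(g, gs)
  gs <- stmap_bw(dF[4 * d + seq_len(d), , drop = FALSE], cache$st,
                 block_par(par, "stmap."), cfg)
  names(gs) <- paste0("stmap.", names(gs)); g <- c(g, gs)
  g
}

# loss + gradients for one minibatch; labels: list(hr, rr, cog) vectors (B)
# target_stats: NULL or list(hr = c(mu, sd), rr = c(mu, sd))
model_loss_grads <- function(par, bn_state, cfg, batch, labels, lambda,
                             target_stats = NULL, training = TRUE) {
  fw <- model_forward(par, bn_state, cfg, batch, training, want_cache = TRUE)
  pr <- fw$preds
  hr_t <- labels$hr; rr_t <- labels$rr
  if (!is.null(target_stats)) {
    hr_t <- (hr_t - target_stats$hr[1]) / target_stats$hr[2]
    rr_t <- (rr_t - target_stats$rr[1]) / target_stats$rr[2]
  }
  B <- batch$B
  L_cog <- truncated_ce(pr$cog_prob, labels$cog, cfg$epsilon)
  L_hr <- smooth_l1(pr$hr, hr_t)
  L_rr <- smooth_l1(pr$rr, rr_t)
  # gradients of the batch-mean losses
  dp <- truncated_ce_grad(pr$cog_prob, labels$cog, cfg$epsilon) / B
  dcog_logit <- dp * pr$cog_prob * (1 - pr$cog_prob)
  douts <- list(hr = lambda * smooth_l1_grad(pr$hr, hr_t) / B,
                rr = lambda * smooth_l1_grad(pr$rr, rr_t) / B,
                cog = dcog_logit)
  grads <- model_backward(par, cfg, batch, fw$cache, douts)
  list(bundle = total_loss(L_cog, L_hr, L_rr, lambda), grads = grads,
       preds = pr, bn_state = fw$bn_state)
}

# ---- checkpoints --------------------------------------------------------------

#' Save / load a fitted model
#'
#' Checkpoints hold every parameter array, the batch-normalization running
#' statistics, the full configuration and the target-normalization statistics;
#' a save/load round trip restores the object bit-exactly.
#'
#' @param object a fitted `"facephys"` object or `"facephys_model"`.
#' @param path file path.
#' @return `load_model` returns the restored object.
#' @export
save_model <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
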