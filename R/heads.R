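# Temporal fusion and prediction heads.

#' Mean-pool a feature sequence over time
#'
#' `h_fused = (1/L) sum_t H_bi(t)`: the arithmetic mean of the rows, a
#' permutation-invariant temporal aggregation.
#'
#' @param H `L x K` matrix (e.g. `H_bi` from [bidirectional_encode()]).
#' @return numeric vector of length K.
#' @export
mean_pool <- function(H) {
  if (!is.matrix(H) || nrow(H) < 1) stop("empty sequence")
  colMeans(H)
}

init_head_params <- function(cfg) {
  din <- 2L * cfg$d_out; hid <- cfg$head_hidden
  par <- list()
  for (task in c("hr", "rr", "cog")) {
    # small output layer: initial logits near 0 keep the truncated CE out of
    # its flat region and start the regressions near the target mean
    p <- list(W1 = init_mat(hid, din, din), b1 = numeric(hid),
              W2 = init_mat(1, hid, hid) * 0.1, b2 = numeric(1))
    names(p) <- paste0("head.", task, ".", names(p))
    par <- c(par, p)
  }
  par
}

# hf: (2*d_out x B) fused vectors; returns list of task outputs and cache
heads_fw <- function(hf, par, want_cache = TRUE) {
  out <- list(); cache <- list()
  for (task in c("hr", "rr", "cog")) {
    W1 <- par[[paste0("head.", task, ".W1")]]
    b1 <- par[[paste0("head.", task, ".b1")]]
    W2 <- par[[paste0("head.", task, ".W2")]]
    b2 <- par[[paste0("head.", task, ".b2")]]
    a1 <- W1 %*% hf + b1
    s1 <- silu(a1)
    out[[task]] <- as.numeric(W2 %*% s1 + b2)
    if (want_cache) cache[[task]] <- list(a1 = a1, s1 = s1)
  }
  out$cog_prob <- plogis(out$cog)
  list(out = out, cache = if (want_cache) cache else NULL)
}

# douts: list(hr, rr, cog) of per-window gradients w.r.t. head outputs
# (cog gradient is w.r.t. the pre-sigmoid logit)
heads_bw <- function(douts, cache, hf, par) {
  g <- list()
  dhf <- matrix(0, nrow(hf), ncol(hf))
  for (task in c("hr", "rr", "cog")) {
    W1 <- par[[paste0("head.", task, ".W1")]]
    W2 <- par[[paste0("head.", task, ".W2")]]
    dsc <- matrix(douts[[task]], 1)
    g[[paste0("head.", task, ".W2")]] <- tcrossprod(dsc, cache[[task]]$s1)
    g[[paste0("head.", task, ".b2")]] <- sum(dsc)
    ds1 <- crossprod(W2, dsc)
    da1 <- silu_bw(ds1, cache[[task]]$a1)
    g[[paste0("head.", task, ".W1")]] <- tcrossprod(da1, hf)
    g[[paste0("head.", task, ".b1")]] <- rowSums(da1)
    dhf <- dhf + crossprod(W1, da1)
  }
  list(dhf = dhf, grads = g)
}

#' Multi-task prediction heads
#'
#' Three independent two-layer MLPs (SiLU hidden activation) mapping a fused
#' feature vector to the heart-rate and respiration-rate regressions and to
#' the cognitive-load probability (via a sigmoid).  The heads share no
#' parameters: the tasks branch only at the prediction layer.
#'
#' @param h fused feature vector (length `2 d_out`) or a matrix with one
#'   column per window.
#' @param params optional head parameters; freshly initialized when `NULL`.
#' @param hidden hidden width of each MLP (default 128).
#' @param seed seed for fresh initialization.
#' @return list with `hr_bpm`, `rr_rpm`, `cog_prob` (each one value per
#'   window); `cog_prob` lies strictly inside (0, 1).
#' @export
predict_heads <- function(h, params = NULL, hidden = 128L, seed = 1L) {
  hm <- if (is.matrix(h)) h else matrix(h, ncol = 1)
  if (any(!is.finite(hm))) stop("non-finite input")
  if (is.null(params)) {
    cfg <- list(d_out = nrow(hm) / 2, head_hidden = as.integer(hidden))
    params <- with_seed(seed, init_head_params(cfg))
  }
  res <- heads_fw(hm, params, want_cache = FALSE)$out
  list(hr_bpm = res$hr, rr_rpm = res$rr, cog_prob = res$cog_prob)
}
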