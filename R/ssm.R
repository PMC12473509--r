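#' Zero-order-hold discretization of a diagonal state-space model
#'
#' For a continuous system `h' = A h + B x` with diagonal `A` (negative
#' entries) and step size `delta`, the ZOH discretization is
#' `A_bar = exp(A delta)` element-wise and, exactly integrating the input-hold
#' over the step, `B_bar = (A_bar - 1) / A * B`.  The Euler simplification
#' `B_bar = delta * B` is available via `exact = FALSE`.
#'
#' Either pass `A` directly (negative diagonal entries) or `A_log`, the
#' stability-enforcing parameterization `A = -exp(A_log)`.
#'
#' @param A numeric vector/matrix of diagonal entries of A (all `< 0`).
#' @param B input map, recycled against `A`.
#' @param delta step size(s), `> 0`; recycled.
#' @param A_log alternative parameterization; used when `A` is `NULL`.
#' @param exact logical; exact ZOH integral (default) or Euler `delta * B`.
#' @return list with `A_bar`, `B_bar`, and the `A`, `delta` used.
#' @examples
#' discretize_zoh(A = -1, B = 1, delta = log(2))  # A_bar = B_bar = 0.5
#' @export
discretize_zoh <- function(A = NULL, B = 1, delta, A_log = NULL, exact = TRUE) {
  if (is.null(A)) {
    if (is.null(A_log)) stop("supply either `A` or `A_log`")
    A <- -exp(A_log)
  }
  if (any(delta <= 0)) stop("`delta` must be positive")
  if (any(A >= 0)) stop("diagonal entries of `A` must be negative")
  A_bar <- exp(A * delta)
  B_bar <- if (exact) (A_bar - 1) / A * B else delta * B
  list(A_bar = A_bar, B_bar = B_bar, A = A, delta = delta)
}

#' Linear time-invariant SSM parameters
#'
#' Convenience constructor for the single-channel LTI instance used by
#' [ssm_scan()] and [ssm_conv_kernel()]: diagonal `A` (length N), input and
#' output maps `B`, `C` (length N), skip scalar `D_skip` and step `delta`.
#'
#' @param A negative diagonal entries (length N), or `NULL` with `A_log`.
#' @param B,C input/state projections, length N.
#' @param D_skip residual skip scalar.
#' @param delta positive step size.
#' @param A_log optional `A = -exp(A_log)` parameterization.
#' @return list of class `"ssm_params"`.
#' @export
ssm_params <- function(A = NULL, B, C, D_skip = 0, delta = 1, A_log = NULL) {
  if (is.null(A)) A <- -exp(A_log)
  stopifnot(length(B) == length(A), length(C) == length(A), delta > 0)
  structure(list(A = A, B = B, C = C, D_skip = D_skip, delta = delta),
            class = "ssm_params")
}

#' Run the discrete SSM recurrence on a sequence
#'
#' Computes `h_k = A_bar h_{k-1} + B_bar x_k`, `y_k = C . h_k + D_skip x_k`
#' sequentially from `h_0` (default zero).  This is the reference recurrent
#' path; for input-independent parameters it agrees with the convolution path
#' ([ssm_conv_kernel()] + [ssm_conv_apply()]) to numerical precision.
#'
#' @param x numeric input sequence (length L).
#' @param params an [ssm_params()] object.
#' @param h0 initial state, default zeros.
#' @param exact logical, exact ZOH `B_bar` (default) or Euler.
#' @return numeric output sequence of length L.
#' @export
ssm_scan <- function(x, params, h0 = NULL, exact = TRUE) {
  stopifnot(inherits(params, "ssm_params"))
  if (any(!is.finite(x))) stop("non-finite input")
  dz <- discretize_zoh(A = params$A, B = params$B, delta = params$delta,
                       exact = exact)
  N <- length(params$A)
  h <- if (is.null(h0)) numeric(N) else h0
  y <- numeric(length(x))
  for (k in seq_along(x)) {
    h <- dz$A_bar * h + dz$B_bar * x[k]
    y[k] <- sum(params$C * h) + params$D_skip * x[k]
  }
  y
}

#' Convolution kernel of a frozen LTI SSM
#'
#' `K_t = C . A_bar^t B_bar` for `t = 0 .. L-1`; the recurrence applied to an
#' input sequence is exactly the causal convolution with this kernel (plus the
#' skip term).  Only defined for input-independent (LTI) parameters.
#'
#' @param params an [ssm_params()] object.
#' @param L kernel length.
#' @param exact logical, exact ZOH `B_bar`.
#' @return numeric vector `K` of length L.
#' @export
ssm_conv_kernel <- function(params, L, exact = TRUE) {
  stopifnot(inherits(params, "ssm_params"), L >= 1)
  dz <- discretize_zoh(A = params$A, B = params$B, delta = params$delta,
                       exact = exact)
  K <- numeric(L)
  pow <- dz$B_bar
  for (t in seq_len(L)) {
    K[t] <- sum(params$C * pow)
    pow <- pow * dz$A_bar
  }
  K
}

#' Apply a causal convolution kernel to an input sequence
#'
#' `y_k = sum_{t=0}^{k} K_t x_{k-t} + D_skip x_k`.  `K` longer than `x` is
#' truncated; `K` must be at least as long as `x` otherwise.
#'
#' @param x input sequence.
#' @param K kernel from [ssm_conv_kernel()].
#' @param D_skip skip scalar.
#' @return numeric output sequence, length of `x`.
#' @export
ssm_conv_apply <- function(x, K, D_skip = 0) {
  L <- length(x)
  if (length(K) < L) stop("kernel shorter than input; provide length >= L")
  K <- K[seq_len(L)]
  y <- vapply(seq_len(L), function(k)
    sum(K[seq_len(k)] * x[k - seq_len(k) + 1]), numeric(1))
  y + D_skip * x
}
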