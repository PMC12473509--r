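#' Truncated cross-entropy loss
#'
#' Cross-entropy for binary labels with a probability floor: the loss is
#' `-log(max(p_y, epsilon))` where `p_y` is the predicted probability of the
#' true label.  Capping at `-log(epsilon)` removes the unbounded gradient of
#' badly mispredicted (possibly mislabeled) samples: for `p_y < epsilon` the
#' loss is constant, so its gradient is exactly zero.
#'
#' @param p predicted probabilities in `[0, 1]`.
#' @param y labels in `{0, 1}` (recycled against `p`).
#' @param epsilon probability floor, `0 < epsilon < 1`.
#' @param reduce `"mean"` (default) or `"none"`.
#' @return scalar mean loss, or a vector of per-sample losses.
#' @examples
#' truncated_ce(1, 1)                 # 0
#' truncated_ce(0.001, 1, 0.01)       # capped at -log(0.01)
#' truncated_ce(0.2, 0)               # -log(0.8)
#' @export
truncated_ce <- function(p, y, epsilon = 0.01, reduce = c("mean", "none")) {
  reduce <- match.arg(reduce)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("`p` must contain probabilities in [0, 1]")
  if (!(epsilon > 0 && epsilon < 1)) stop("`epsilon` must lie in (0, 1)")
  if (!all(y %in% c(0, 1))) stop("`y` must be binary (0/1)")
  py <- ifelse(y == 1, p, 1 - p)
  loss <- -log(pmax(py, epsilon))
  if (reduce == "mean") mean(loss) else loss
}

# d loss / d p for the truncated cross-entropy (zero below the floor)
truncated_ce_grad <- function(p, y, epsilon = 0.01) {
  py <- ifelse(y == 1, p, 1 - p)
  g <- ifelse(py > epsilon, -1 / py, 0)
  ifelse(y == 1, g, -g)
}

#' Smooth L1 (Huber-like) regression loss
#'
#' Quadratic for errors below 1, linear above: `0.5 e^2` if `|e| < 1`, else
#' `|e| - 0.5`.  Continuous and once-differentiable everywhere with gradient
#' magnitude at most 1, which bounds the influence of outlying labels.
#'
#' @param pred,target numeric vectors (recycled).
#' @param reduce `"mean"` (default) or `"none"`.
#' @return scalar mean loss or per-sample vector.
#' @examples
#' smooth_l1(3, 0)   # 2.5
#' smooth_l1(1, 0)   # 0.5 (knee)
#' @export
smooth_l1 <- function(pred, target, reduce = c("mean", "none")) {
  reduce <- match.arg(reduce)
  if (any(!is.finite(pred)) || any(!is.finite(target)))
    stop("inputs must be finite")
  e <- pred - target
  loss <- ifelse(abs(e) < 1, 0.5 * e^2, abs(e) - 0.5)
  if (reduce == "mean") mean(loss) else loss
}

# d loss / d pred
smooth_l1_grad <- function(pred, target) {
  e <- pred - target
  ifelse(abs(e) < 1, e, sign(e))
}

#' Multi-task weight schedule
#'
#' Computes the time factor `t = 2 * iter_current / iter_total` and the
#' adaptation weight `lambda = 2 / (1 + exp(-10 t))`, which ramps
#' monotonically from 1 (at iteration 0) towards 2 over training.  With
#' `start_zero = TRUE` the shifted variant `lambda - 1` is returned, ramping
#' from 0 to 1 instead (some users prefer regression losses to be switched
#' off at the start; the printed formula itself starts at 1).
#'
#' @param iter_current current iteration, `0 <= iter_current <= iter_total`.
#' @param iter_total total iterations, `> 0`.
#' @param start_zero logical, see above.
#' @return list with elements `t` and `lambda`.
#' @examples
#' lambda_schedule(0, 100)$lambda      # exactly 1
#' lambda_schedule(100, 100)$lambda    # ~2
#' @export
lambda_schedule <- function(iter_current, iter_total, start_zero = FALSE) {
  if (length(iter_total) != 1 || iter_total <= 0)
    stop("`iter_total` must be a positive scalar")
  if (any(iter_current < 0) || any(iter_current > iter_total))
    stop("`iter_current` must lie in [0, iter_total]")
  t <- 2 * iter_current / iter_total
  lambda <- 2 / (1 + exp(-10 * t))
  if (start_zero) lambda <- lambda - 1
  list(t = t, lambda = lambda)
}

#' Compose the total multi-task objective
#'
#' `L_total = L_cog + lambda * L_hr + lambda * L_rr`, with a single shared
#' weight applied to both regression losses.
#'
#' @param L_cog,L_hr,L_rr finite loss components.
#' @param lambda schedule weight.
#' @param t optional time factor, carried through for logging.
#' @return a list of class `"loss_bundle"` with the components, `lambda`, `t`
#'   and `L_total`.
#' @export
total_loss <- function(L_cog, L_hr, L_rr, lambda, t = NA_real_) {
  if (!all(is.finite(c(L_cog, L_hr, L_rr, lambda))))
    stop("loss components and lambda must be finite")
  out <- list(L_cog = L_cog, L_hr = L_hr, L_rr = L_rr, lambda = lambda, t = t,
              L_total = L_cog + lambda * L_hr + lambda * L_rr)
  class(out) <- "loss_bundle"
  out
}
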