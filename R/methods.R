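#' @export
print.facephys <- function(x, ...) {
  cfg <- x$config
  cat("Multi-task facial-video physiology model (facephys)\n")
  cat(sprintf("  branches d = %d (D = %d), encoder depth = %d x 2 directions, N = %d\n",
              cfg$d, cfg$D, cfg$depth, cfg$n_state))
  cat(sprintf("  window L = %d frames @ %g fps; %s trainable parameters\n",
              cfg$window_length, cfg$fps, format(x$n_parameters, big.mark = ",")))
  cat(sprintf("  trained %d iterations (best validation at iter %d: %.4f)\n",
              cfg$iter_total, x$best_iter,
              if (is.finite(x$best_val)) x$best_val else NA))
  invisible(x)
}

#' @export
summary.facephys <- function(object, ...) {
  h <- object$history
  last <- tail(h, 1)
  out <- list(config = object$config, n_parameters = object$n_parameters,
              split = table(object$split),
              final_loss = last$L_total, best_val = object$best_val,
              best_iter = object$best_iter,
              loss_head = head(h, 3), loss_tail = tail(h, 3))
  class(out) <- "summary.facephys"
  out
}

#' @export
print.summary.facephys <- function(x, ...) {
  cat("facephys fit summary\n")
  cat(sprintf("  parameters: %s\n", format(x$n_parameters, big.mark = ",")))
  cat("  subjects per split: ")
  print(x$split)
  cat(sprintf("  final training loss %.4f; best validation %.4f at iter %d\n",
              x$final_loss, x$best_val, x$best_iter))
  invisible(x)
}

#' @export
coef.facephys <- function(object, ...) object$par

#' Plot training loss history
#'
#' @param x fitted `"facephys"`.
#' @param ... passed to [plot()].
#' @export
plot.facephys <- function(x, ...) {
  h <- x$history
  plot(h$iter, h$L_total, type = "l", xlab = "iteration", ylab = "loss",
       main = "training objective", ...)
  lines(h$iter, h$L_cog, col = "steelblue")
  lines(h$iter, h$lambda * (h$L_hr + h$L_rr), col = "tomato")
  vi <- which(is.finite(h$val_total))
  if (length(vi)) lines(h$iter[vi], h$val_total[vi], col = "darkgreen", lty = 2)
  legend("topright", c("total", "cognitive", "weighted regression", "validation"),
         col = c("black", "steelblue", "tomato", "darkgreen"),
         lty = c(1, 1, 1, 2), bty = "n", cex = 0.8)
  invisible(x)
}

#' @export
print.loss_bundle <- function(x, ...) {
  cat(sprintf("loss bundle: total %.5f = cog %.5f + %.4f * (hr %.5f + rr %.5f)\n",
              x$L_total, x$L_cog, x$lambda, x$L_hr, x$L_rr))
  invisible(x)
}

#' @export
print.facephys_config <- function(x, ...) {
  cat("facephys configuration\n")
  cat(sprintf("  d=%d D=%d depth=%d N=%d expand=%d d_out=%d heads=%d\n",
              x$d, x$D, x$depth, x$n_state, x$expand, x$d_out, x$head_hidden))
  cat(sprintf("  L=%d stride=%d fps=%g; lr=%g batch=%d iters=%d eps=%g\n",
              x$window_length, x$stride, x$fps, x$lr, x$batch_size,
              x$iter_total, x$epsilon))
  invisible(x)
}

#' @export
print.stmap <- function(x, ...) {
  cat(sprintf("STMap: %d x %d ROI grid (H=%d), L=%d frames @ %g fps\n",
              x$grid_rows, x$grid_cols, x$H, dim(x$values)[3], x$fps))
  invisible(x)
}
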