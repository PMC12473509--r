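#' Model and training configuration
#'
#' Builds the configuration list consumed by [facephys()] and the lower-level
#' model constructors.  Defaults correspond to the full-scale model: per-branch
#' feature dimension `d = 64` (so the concatenated width is `D = 5 d = 320`),
#' three Mamba blocks per direction, state dimension 16, expansion factor 2 and
#' a depthwise causal convolution of width 4 inside each block.  The defaults
#' keep the trainable parameter count within the 5.95 M budget of the reference
#' design.
#'
#' @param d per-branch feature dimension; the encoder width is `D = 5 * d`.
#' @param depth number of Mamba blocks per direction.
#' @param n_state state dimension N of the diagonal SSM.
#' @param expand expansion factor of the block's inner width `E = expand * D`.
#' @param conv_width width of the depthwise causal convolution.
#' @param dt_rank rank of the delta projection; `"auto"` gives `ceiling(D/16)`.
#' @param c1,c2 channel widths of the two subregion convolutions.
#' @param stmap_channels first-stage channel width of the STMap embedding
#'   (its second stage outputs `d` channels).
#' @param lm_channels channel width of the landmark embedding convolution.
#' @param d_out width D'' of the per-direction linear map before
#'   concatenation; defaults to `D`.
#' @param head_hidden hidden width of the three prediction MLPs.
#' @param epsilon probability floor of the truncated cross-entropy.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size (windows).
#' @param iter_total total training iterations (also drives the loss-weight
#'   schedule).
#' @param threshold classification threshold on the cognitive probability.
#' @param window_length,stride sliding-window length L and step s in frames.
#' @param fps frames per second of the source video.
#' @param grid_rows,grid_cols STMap facial grid (H = rows * cols).
#' @param fold_div temporal-shift fold divisor of the WTSM module.
#' @param wtsm logical; apply the temporal shift before the subregion convs.
#' @param bbar_exact logical; use the exact diagonal ZOH integral for B-bar
#'   (`FALSE` selects the Euler simplification `delta * B`).
#' @param normalize_targets logical; train the regression heads against
#'   z-scored labels (statistics taken from the training split and stored in
#'   the fitted object; predictions are always reported in physical units).
#' @param lambda_start_zero logical; shift the task-weight schedule so that it
#'   ramps from 0 instead of 1.
#' @param clip_norm global gradient-norm clip applied before the Adam update
#'   (`Inf` disables clipping).
#' @param weight_decay decoupled (AdamW-style) weight decay coefficient.
#' @param augment logical; apply training-time augmentation (temporal speed
#'   resampling with matching HR/RR label rescaling, per-window color jitter
#'   on the crops, landmark translation jitter).  Speed resampling is the
#'   standard rPPG trick that forces the model to read rates from oscillation
#'   frequency rather than subject appearance.
#' @param speed_range range of the temporal resampling factor.
#' @param color_jitter amplitude of the per-window channel scale/offset jitter.
#' @param val_every validation cadence in iterations.
#' @param eye_size,mouth_size crop sizes (height, width) in pixels.
#' @param landmark_points number of facial landmarks per frame.
#' @param region_indices named list of landmark index sets defining the crop
#'   centers for `left_eye`, `right_eye` and `mouth`.
#' @return a list of class `"facephys_config"`.
#' @seealso [facephys_desk_config()] for the reduced configuration used by the
#'   package's synthetic benchmark.
#' @export
facephys_config <- function(d = 64L, depth = 3L, n_state = 16L, expand = 2L,
                            conv_width = 4L, dt_rank = "auto",
                            c1 = 16L, c2 = 32L, stmap_channels = 16L,
                            lm_channels = 8L, d_out = NULL, head_hidden = 128L,
                            epsilon = 0.01, lr = 1e-5, batch_size = 250L,
                            iter_total = 20000L, threshold = 0.5,
                            window_length = 300L, stride = 30L, fps = 30,
                            grid_rows = 5L, grid_cols = 5L,
                            fold_div = 4L, wtsm = TRUE, bbar_exact = TRUE,
                            normalize_targets = FALSE, lambda_start_zero = FALSE,
                            clip_norm = Inf, weight_decay = 1e-4,
                            augment = TRUE, speed_range = c(0.7, 1.4),
                            color_jitter = 0.1, val_every = 50L,
                            eye_size = c(25L, 25L), mouth_size = c(15L, 35L),
                            landmark_points = 106L,
                            region_indices = NULL) {
  D <- 5L * as.integer(d)
  if (identical(dt_rank, "auto")) dt_rank <- as.integer(ceiling(D / 16))
  if (is.null(d_out)) d_out <- D
  if (is.null(region_indices)) region_indices <- default_region_indices()
  cfg <- list(d = as.integer(d), D = D, depth = as.integer(depth),
              n_state = as.integer(n_state), expand = as.integer(expand),
              E = as.integer(expand) * D, conv_width = as.integer(conv_width),
              dt_rank = as.integer(dt_rank), c1 = as.integer(c1),
              c2 = as.integer(c2), stmap_channels = as.integer(stmap_channels),
              lm_channels = as.integer(lm_channels), d_out = as.integer(d_out),
              head_hidden = as.integer(head_hidden), epsilon = epsilon,
              lr = lr, batch_size = as.integer(batch_size),
              iter_total = as.integer(iter_total), threshold = threshold,
              window_length = as.integer(window_length),
              stride = as.integer(stride), fps = fps,
              grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
              fold_div = as.integer(fold_div), wtsm = isTRUE(wtsm),
              bbar_exact = isTRUE(bbar_exact),
              normalize_targets = isTRUE(normalize_targets),
              lambda_start_zero = isTRUE(lambda_start_zero),
              clip_norm = clip_norm, weight_decay = weight_decay,
              augment = isTRUE(augment), speed_range = speed_range,
              color_jitter = color_jitter, val_every = as.integer(val_every),
              eye_size = as.integer(eye_size), mouth_size = as.integer(mouth_size),
              landmark_points = as.integer(landmark_points),
              region_indices = region_indices)
  stopifnot(cfg$d > 0, cfg$depth >= 1, cfg$n_state >= 1, cfg$expand >= 1,
            cfg$iter_total > 0, cfg$batch_size >= 1, cfg$lr > 0,
            cfg$epsilon > 0, cfg$epsilon < 1)
  class(cfg) <- "facephys_config"
  cfg
}

#' Reduced desk-scale configuration
#'
#' A small configuration for CPU-scale experiments on synthetic data: 10-second
#' windows sampled at 15 fps (L = 150), per-branch dimension 16, narrow
#' convolutional stems, batch 8, and a learning rate suited to short Adam runs
#' with z-scored regression targets.  These are the sizes used throughout the
#' package's tests and synthetic benchmark; see the methods vignette.
#'
#' @param ... overrides forwarded to [facephys_config()].
#' @return a `"facephys_config"` list.
#' @export
facephys_desk_config <- function(...) {
  args <- list(d = 16L, depth = 3L, c1 = 4L, c2 = 8L, stmap_channels = 8L,
               lm_channels = 4L, head_hidden = 32L, n_state = 8L, lr = 1e-3,
               batch_size = 8L, iter_total = 400L, window_length = 150L,
               stride = 15L, fps = 15, normalize_targets = TRUE,
               val_every = 50L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(facephys_config, args)
}

#' Default landmark index sets for the 106-point scheme
#'
#' The synthetic generator lays out its 106-point template as: face contour
#' 1--33, left brow 34--41, right brow 42--49, nose 50--60, left eye 61--68,
#' right eye 69--76, mouth 77--106.  Crops are centered on the per-frame
#' centroid of each region's indices, which keeps the pipeline agnostic to the
#' landmark scheme: supply your own sets for a different detector.
#'
#' @return named list with elements `left_eye`, `right_eye`, `mouth`.
#' @export
default_region_indices <- function() {
  list(left_eye = 61:68, right_eye = 69:76, mouth = 77:106)
}
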