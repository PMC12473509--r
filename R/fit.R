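#' Fit the multi-task facial-video model
#'
#' Trains the five-branch embedding + bidirectional selective state-space
#' encoder + three-head model on tensor-level window samples with Adam,
#' minimizing the truncated cross-entropy for cognitive load plus
#' smooth-L1 losses for HR and RR under the sigmoid-ramp weight schedule
#' `lambda(iter) = 2 / (1 + exp(-20 iter / iter_total))`.  Subjects are split
#' 6:2:2 into train/validation/test unless a split is supplied; the best
#' checkpoint by validation total loss is returned.  The run is fully
#' reproducible from `(data, config, seed)`.
#'
#' @param data a `"facephys_data"` object from [generate_dataset()] (or a list
#'   with `windows` and `manifest` in the same format; pixel-level windows
#'   must be converted with [pixel_window_to_tensors()] first).
#' @param config a [facephys_config()]; [facephys_desk_config()] is the
#'   CPU-scale profile used in the package's tests.
#' @param seed integer seed controlling initialization, the subject split and
#'   minibatch sampling.
#' @param split optional named vector mapping subject ids to
#'   `"train"/"val"/"test"` (as from [subject_split()]).
#' @param verbose print progress every validation cycle.
#' @return an object of class `"facephys"`: the best parameters, running BN
#'   statistics, configuration, per-iteration loss history, the split, target
#'   normalization statistics and the parameter count.  Methods: `print`,
#'   `summary`, `coef`, `predict`, `plot`.
#' @export
facephys <- function(data, config = facephys_desk_config(), seed = 1L,
                     split = NULL, verbose = FALSE) {
  stopifnot(!is.null(data$windows), !is.null(data$manifest))
  cfg <- config
  manifest <- data$manifest
  if (is.null(split)) split <- subject_split(manifest$subject_id, seed = seed)
  wsplit <- split[manifest$subject_id]
  tr_idx <- which(wsplit == "train")
  va_idx <- which(wsplit == "val")
  if (length(tr_idx) == 0) stop("empty training split")
  has_labels <- vapply(data$windows[tr_idx], function(w)
    all(c("hr_bpm", "rr_rpm", "cog") %in% names(w$labels)), logical(1))
  if (!all(has_labels)) stop("training windows must carry all three labels")
  target_stats <- NULL
  if (cfg$normalize_targets) {
    target_stats <- list(
      hr = c(mean(manifest$hr_bpm[tr_idx]), max(sd(manifest$hr_bpm[tr_idx]), 1e-6)),
      rr = c(mean(manifest$rr_rpm[tr_idx]), max(sd(manifest$rr_rpm[tr_idx]), 1e-6)))
  }
  model <- init_model(cfg, seed)
  par <- model$par
  bn_state <- model$bn_state
  m <- lapply(par, function(p) p * 0)
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- data.frame(iter = integer(0), L_cog = numeric(0),
                        L_hr = numeric(0), L_rr = numeric(0),
                        lambda = numeric(0), L_total = numeric(0),
                        val_total = numeric(0))
  best <- list(val = Inf, par = par, bn_state = bn_state, iter = 0L)
  rng_seed <- mix_seed(seed, 77)
  labels_of <- function(idx) list(hr = manifest$hr_bpm[idx],
                                  rr = manifest$rr_rpm[idx],
                                  cog = manifest$cog[idx])
  val_loss <- function(par, bn_state, lambda) {
    tot <- 0; n <- 0
    for (chunk in split_chunks(va_idx, cfg$batch_size)) {
      bt <- assemble_batch(data$windows[chunk], cfg)
      fw <- model_forward(par, bn_state, cfg, bt, training = FALSE,
                          want_cache = FALSE)
      lb <- labels_of(chunk)
      hr_t <- lb$hr; rr_t <- lb$rr
      if (!is.null(target_stats)) {
        hr_t <- (hr_t - target_stats$hr[1]) / target_stats$hr[2]
        rr_t <- (rr_t - target_stats$rr[1]) / target_stats$rr[2]
      }
      l <- truncated_ce(fw$preds$cog_prob, lb$cog, cfg$epsilon) +
        lambda * (smooth_l1(fw$preds$hr, hr_t) + smooth_l1(fw$preds$rr, rr_t))
      tot <- tot + l * length(chunk); n <- n + length(chunk)
    }
    if (n == 0) NA_real_ else tot / n
  }
  set.seed(rng_seed)
  for (iter in seq_len(cfg$iter_total)) {
    sched <- lambda_schedule(iter - 1L, cfg$iter_total, cfg$lambda_start_zero)
    bidx <- sample(tr_idx, min(cfg$batch_size, length(tr_idx)),
                   replace = length(tr_idx) < cfg$batch_size)
    wins <- data$windows[bidx]
    labels <- labels_of(bidx)
    if (cfg$augment) {
      wins <- lapply(wins, augment_window, cfg = cfg)
      labels <- list(hr = vapply(wins, function(w) w$labels$hr_bpm, numeric(1)),
                     rr = vapply(wins, function(w) w$labels$rr_rpm, numeric(1)),
                     cog = labels$cog)
    }
    batch <- assemble_batch(wins, cfg)
    res <- model_loss_grads(par, bn_state, cfg, batch, labels,
                            sched$lambda, target_stats, training = TRUE)
    bn_state <- res$bn_state
    if (!is.finite(res$bundle$L_total))
      stop("non-finite loss at iteration ", iter,
           " (L_cog=", res$bundle$L_cog, ", L_hr=", res$bundle$L_hr,
           ", L_rr=", res$bundle$L_rr, ")")
    # global gradient-norm clipping, then Adam
    if (is.finite(cfg$clip_norm)) {
      gn <- sqrt(sum(vapply(res$grads, function(g) sum(g * g), numeric(1))))
      if (gn > cfg$clip_norm) {
        sc <- cfg$clip_norm / gn
        res$grads <- lapply(res$grads, function(g) g * sc)
      }
    }
    bc1 <- 1 - b1^iter; bc2 <- 1 - b2^iter
    for (nm in names(res$grads)) {
      gr <- res$grads[[nm]]
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gr
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gr * gr
      par[[nm]] <- par[[nm]] - cfg$lr * ((m[[nm]] / bc1) /
        (sqrt(v[[nm]] / bc2) + eps) + cfg$weight_decay * par[[nm]])
    }
    vt <- NA_real_
    if (iter %% cfg$val_every == 0 || iter == cfg$iter_total) {
      vt <- val_loss(par, bn_state, sched$lambda)
      if (is.finite(vt) && vt < best$val)
        best <- list(val = vt, par = par, bn_state = bn_state, iter = iter)
      if (verbose)
        message(sprintf("iter %d  L=%.4f (cog %.4f hr %.4f rr %.4f)  val=%.4f",
                        iter, res$bundle$L_total, res$bundle$L_cog,
                        res$bundle$L_hr, res$bundle$L_rr, vt))
    }
    history[nrow(history) + 1L, ] <- list(iter, res$bundle$L_cog,
                                          res$bundle$L_hr, res$bundle$L_rr,
                                          sched$lambda, res$bundle$L_total, vt)
  }
  if (!is.finite(best$val)) {  # no validation windows: keep final parameters
    best <- list(val = NA_real_, par = par, bn_state = bn_state,
                 iter = cfg$iter_total)
  }
  structure(list(par = best$par, bn_state = best$bn_state,
                 final_par = par, config = cfg, history = history,
                 split = split, target_stats = target_stats, seed = seed,
                 best_iter = best$iter, best_val = best$val,
                 n_parameters = sum(vapply(par, length, integer(1))),
                 call = match.call()),
            class = "facephys")
}

split_chunks <- function(idx, size) {
  if (length(idx) == 0) return(list())
  split(idx, ceiling(seq_along(idx) / size))
}

# fold indices into [1, L] by reflection at the ends
reflect_fold <- function(u, L) {
  v <- (u - 1) %% (2 * (L - 1))
  ifelse(v > (L - 1), 2 * (L - 1) - v, v) + 1
}

# linear resampling of an array along its time axis (axis index within dims);
# works on a (pre, L, post) reshaped view to avoid generic indexing overhead
resample_time <- function(arr, axis, r) {
  d <- dim(arr)
  L <- d[axis]
  u <- reflect_fold(1 + (seq_len(L) - 1) * r, L)
  lo <- pmin(floor(u), L - 1L)
  frac <- u - lo
  pre <- prod(d[seq_len(axis - 1)])
  post <- prod(d)[1] / (pre * L) * 1  # placeholder, recomputed below
  post <- prod(d) / (pre * L)
  v <- arr
  dim(v) <- c(pre, L, post)
  wl <- rep(1 - frac, each = pre)
  wh <- rep(frac, each = pre)
  out <- v[, lo, , drop = FALSE] * wl + v[, lo + 1, , drop = FALSE] * wh
  dim(out) <- d
  out
}

# training-time augmentation of one tensor-level window; draws from the
# current RNG stream, so runs are reproducible from the training seed
augment_window <- function(wnd, cfg) {
  r <- runif(1, cfg$speed_range[1], cfg$speed_range[2])
  jit <- cfg$color_jitter
  for (nm in c("leye", "reye", "mouth")) {
    a <- clip_values(wnd$tensors[[nm]])
    d <- dim(a)
    sc <- if (jit > 0) runif(3, 1 - jit, 1 + jit) else rep(1, 3)
    off <- if (jit > 0) runif(3, -jit / 2, jit / 2) else numeric(3)
    a <- augment_clip_cpp(a, d[1], d[2], d[3], r, sc, off)
    attr(a, "dims") <- dim(a)
    wnd$tensors[[nm]] <- a
  }
  st <- resample_time(wnd$tensors$stmap, 3L, r)
  wnd$tensors$stmap <- normalize_stmap_rows(st)
  fac <- resample_time(wnd$tensors$facial, 1L, r)
  shift <- runif(2, -0.02, 0.02)
  fac[, , 1] <- pmin(pmax(fac[, , 1] + shift[1], 0), 1)
  fac[, , 2] <- pmin(pmax(fac[, , 2] + shift[2], 0), 1)
  wnd$tensors$facial <- fac
  wnd$labels$hr_bpm <- wnd$labels$hr_bpm * r
  wnd$labels$rr_rpm <- wnd$labels$rr_rpm * r
  wnd
}

#' Predict on new windows
#'
#' Runs the fitted model in evaluation mode (batch-normalization running
#' statistics) and reports predictions in physical units.
#'
#' @param object a fitted `"facephys"` object.
#' @param newdata a `"facephys_data"` object or list of tensor-level
#'   `"window_sample"`s.
#' @param ... unused.
#' @return data.frame with `window_id`, `subject_id`, `hr_bpm`, `rr_rpm`,
#'   `cog_prob`, `cog_class`.
#' @export
predict.facephys <- function(object, newdata, ...) {
  windows <- if (!is.null(newdata$windows)) newdata$windows else newdata
  cfg <- object$config
  out <- list()
  for (chunk in split_chunks(seq_along(windows), cfg$batch_size)) {
    bt <- assemble_batch(windows[chunk], cfg)
    fw <- model_forward(object$par, object$bn_state, cfg, bt,
                        training = FALSE, want_cache = FALSE)
    hr <- fw$preds$hr; rr <- fw$preds$rr
    if (!is.null(object$target_stats)) {
      hr <- hr * object$target_stats$hr[2] + object$target_stats$hr[1]
      rr <- rr * object$target_stats$rr[2] + object$target_stats$rr[1]
    }
    out[[length(out) + 1L]] <- data.frame(
      window_id = vapply(windows[chunk], function(w) w$window_id %||% NA_character_, character(1)),
      subject_id = vapply(windows[chunk], function(w) w$subject_id %||% NA_character_, character(1)),
      hr_bpm = hr, rr_rpm = rr, cog_prob = fw$preds$cog_prob,
      cog_class = as.integer(fw$preds$cog_prob >= cfg$threshold),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Evaluate a fitted model on a data split
#'
#' Computes the full evaluation report: classification metrics for cognitive
#' load and regression metrics for HR and RR over the windows of the chosen
#' split (or all windows when `split_name = NULL`).
#'
#' @param object fitted `"facephys"`.
#' @param data a `"facephys_data"` object with manifest labels.
#' @param split_name `"test"` (default), `"train"`, `"val"`, or `NULL`.
#' @return list with elements `cog` (accuracy, f1, sensitivity, specificity),
#'   `hr`, `rr` (mae, rmse, pearson_r), `n_windows`, `n_subjects`.
#' @export
evaluate_facephys <- function(object, data, split_name = "test") {
  manifest <- data$manifest
  idx <- seq_len(nrow(manifest))
  if (!is.null(split_name)) {
    wsplit <- object$split[manifest$subject_id]
    idx <- which(wsplit == split_name)
  }
  if (length(idx) == 0) stop("no windows in split ", split_name)
  pr <- predict(object, data$windows[idx])
  list(cog = classification_metrics(pr$cog_prob, manifest$cog[idx],
                                    object$config$threshold),
       hr = regression_metrics(pr$hr_bpm, manifest$hr_bpm[idx]),
       rr = regression_metrics(pr$rr_rpm, manifest$rr_rpm[idx]),
       n_windows = length(idx),
       n_subjects = length(unique(manifest$subject_id[idx])))
}

#' Sweep the encoder depth on a fixed synthetic benchmark
#'
#' Trains one model per depth on the same data, split and seed (a controlled
#' comparison) and reports all evaluation metrics per depth and seed.
#'
#' @param data a `"facephys_data"` object.
#' @param config base configuration; its `depth` is overridden per run.
#' @param depths integer vector of depths to test.
#' @param seeds integer vector of training seeds.
#' @param split_seed seed of the shared subject split.
#' @param verbose forwarded to [facephys()].
#' @return data.frame with one row per (depth, seed) holding accuracy, F1,
#'   HR/RR MAE, RMSE and Pearson r on the test split.
#' @export
depth_sweep <- function(data, config = facephys_desk_config(),
                        depths = c(1L, 3L), seeds = 1L, split_seed = 1L,
                        verbose = FALSE) {
  split <- subject_split(data$manifest$subject_id, seed = split_seed)
  rows <- list()
  for (dep in depths) for (sd_ in seeds) {
    cfg <- config; cfg$depth <- as.integer(dep)
    fit <- facephys(data, cfg, seed = sd_, split = split, verbose = verbose)
    ev <- evaluate_facephys(fit, data, "test")
    rows[[length(rows) + 1L]] <- data.frame(
      depth = dep, seed = sd_, accuracy = ev$cog$accuracy, f1 = ev$cog$f1,
      hr_mae = ev$hr$mae, hr_rmse = ev$hr$rmse, hr_r = ev$hr$pearson_r,
      rr_mae = ev$rr$mae, rr_rmse = ev$rr$rmse, rr_r = ev$rr$pearson_r)
  }
  do.call(rbind, rows)
}
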