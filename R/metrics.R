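#' Subject-wise train/validation/test split
#'
#' Shuffles the subjects with the given seed and assigns them to train,
#' validation and test sets in a 6:2:2 ratio by subject count (rounded), so
#' that no subject contributes windows to more than one split.
#'
#' @param subject_ids character or integer vector of unique subject ids
#'   (duplicates are removed).
#' @param seed integer seed controlling the shuffle.
#' @param ratio length-3 positive weights, default `c(0.6, 0.2, 0.2)`.
#' @return named character vector mapping each subject to
#'   `"train"`, `"val"` or `"test"`.
#' @export
subject_split <- function(subject_ids, seed = 1L, ratio = c(0.6, 0.2, 0.2)) {
  ids <- unique(as.character(subject_ids))
  n <- length(ids)
  if (n < 5) stop("need at least 5 subjects for a 6:2:2 split")
  stopifnot(length(ratio) == 3, all(ratio > 0))
  ratio <- ratio / sum(ratio)
  ord <- with_seed(seed, sample.int(n))
  n_train <- round(ratio[1] * n)
  n_val <- round(ratio[2] * n)
  if (n_train + n_val >= n) n_val <- max(1L, n - n_train - 1L)
  split <- rep("test", n)
  split[ord[seq_len(n_train)]] <- "train"
  split[ord[n_train + seq_len(n_val)]] <- "val"
  names(split) <- ids
  split
}

#' Binary classification metrics
#'
#' Thresholds the probabilities and reports accuracy, F1, sensitivity (true
#' positive rate) and specificity (true negative rate) from the confusion
#' matrix.  Ratios with a zero denominator are returned as `NA` rather than
#' `NaN`.
#'
#' @param probs predicted probabilities of the positive class.
#' @param labels true labels in `{0, 1}`.
#' @param threshold decision threshold, default 0.5.
#' @return list with `accuracy`, `f1`, `sensitivity`, `specificity` and the
#'   confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
classification_metrics <- function(probs, labels, threshold = 0.5) {
  if (length(probs) == 0) stop("empty input")
  if (length(probs) != length(labels)) stop("length mismatch")
  pred <- as.integer(probs >= threshold)
  labels <- as.integer(labels)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  list(accuracy = (tp + tn) / length(labels), f1 = f1,
       sensitivity = sens, specificity = spec,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Regression metrics for rate estimation
#'
#' Mean absolute error, root mean squared error and the Pearson correlation
#' between predictions and targets.  The correlation of a constant series is
#' undefined and reported as `NA`.
#'
#' @param preds,targets numeric vectors of equal length.
#' @return list with `mae`, `rmse`, `pearson_r` and `n`.
#' @export
regression_metrics <- function(preds, targets) {
  if (length(preds) < 1) stop("empty input")
  if (length(preds) != length(targets)) stop("length mismatch")
  e <- preds - targets
  r <- NA_real_
  if (length(preds) >= 2 && sd(preds) > 0 && sd(targets) > 0)
    r <- cor(preds, targets)
  list(mae = mean(abs(e)), rmse = sqrt(mean(e^2)), pearson_r = r,
       n = length(preds))
}

#' Binarize NASA-TLX workload scores
#'
#' Applies the labeling rules of the two driving corpora the model targets:
#' under the `"edream"` scheme, scores below 30 are low load and scores above
#' 60 high load, with the 30--60 mid-range excluded from classification; under
#' the `"mcdd"` scheme, a normalized score above 10 accompanied by a
#' non-driving-related task (NDRT) is high load, everything else low.
#'
#' @param score numeric NASA-TLX score(s).
#' @param scheme `"edream"` or `"mcdd"`.
#' @param ndrt_present logical flag(s), used by the `"mcdd"` scheme.
#' @return character vector in `{"low", "high", "excluded"}`.
#' @export
nasa_tlx_label <- function(score, scheme = c("edream", "mcdd"),
                           ndrt_present = FALSE) {
  scheme <- match.arg(scheme)
  if (any(!is.finite(score))) stop("`score` must be finite")
  if (scheme == "edream") {
    out <- rep("excluded", length(score))
    out[score < 30] <- "low"
    out[score > 60] <- "high"
  } else {
    ndrt <- rep_len(as.logical(ndrt_present), length(score))
    out <- ifelse(score > 10 & ndrt, "high", "low")
  }
  out
}

# run expr under a local RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic integer seed mixing, kept below 2^31
mix_seed <- function(...) {
  vals <- as.numeric(c(...))
  Reduce(function(a, b) ((a * 69069 + b + 1) %% 2147483629), vals, accumulate = FALSE)
}
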