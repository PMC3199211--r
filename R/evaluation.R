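# Pixel-wise evaluation: confusion counts, sensitivity/specificity, ROC
# sweeps over the likelihood-map threshold, and the k-fold
# cross-validation harness.

#' Pixel-wise confusion counts
#'
#' @param pred,truth aligned [label_field]s.
#' @param positive_label the label counted as positive (default: second
#'   label of the truth's label set, the lesion).
#' @return object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion <- function(pred, truth, positive_label = NULL) {
  stopifnot(inherits(pred, "label_field"), inherits(truth, "label_field"))
  if (pred$height != truth$height || pred$width != truth$width)
    stopf("prediction (%dx%d) and truth (%dx%d) differ in shape",
          pred$height, pred$width, truth$height, truth$width)
  if (is.null(positive_label)) positive_label <- truth$labelset$labels[2]
  p <- pred$labels == positive_label
  t <- truth$labels == positive_label
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' @noRd
add_confusion <- function(a, b) {
  structure(list(tp = a$tp + b$tp, fp = a$fp + b$fp,
                 tn = a$tn + b$tn, fn = a$fn + b$fn),
            class = "confusion_counts")
}

#' @noRd
empty_confusion <- function()
  structure(list(tp = 0L, fp = 0L, tn = 0L, fn = 0L),
            class = "confusion_counts")

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion: tp=%d fp=%d tn=%d fn=%d>\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Sensitivity and specificity from confusion counts
#'
#' Sensitivity = tp/(tp+fn), specificity = tn/(tn+fp). A side with no
#' pixels yields `NA` for the corresponding rate.
#'
#' @param counts a `confusion_counts`.
#' @return named numeric vector `c(sensitivity =, specificity =)`.
#' @export
sens_spec <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  sens <- if (counts$tp + counts$fn > 0)
    counts$tp / (counts$tp + counts$fn) else NA_real_
  spec <- if (counts$tn + counts$fp > 0)
    counts$tn / (counts$tn + counts$fp) else NA_real_
  c(sensitivity = sens, specificity = spec)
}

#' ROC sweep over likelihood-map thresholds
#'
#' Sweeps a threshold T over \[0, 1\] on the normalized likelihood of the
#' positive label, pooling pixel counts across all images at each
#' threshold. The grid is `n_thresholds` evenly spaced values including
#' the exact endpoints 0 (everything positive) and 1.
#'
#' @param lmaps list of `likelihood_map`s.
#' @param truths list of aligned [label_field]s.
#' @param positive_label positive label (default: second label).
#' @param n_thresholds number of thresholds (default 256).
#' @return object of class `roc_curve`: data frame `points` with columns
#'   `threshold` (descending), `fpr` (1 - specificity), `sensitivity`,
#'   `specificity`.
#' @export
roc_sweep <- function(lmaps, truths, positive_label = NULL,
                      n_thresholds = 256L) {
  stopifnot(length(lmaps) == length(truths), length(lmaps) > 0)
  labs <- lmaps[[1]]$labelset$labels
  if (is.null(positive_label)) positive_label <- labs[2]
  j <- match(positive_label, labs)
  if (is.na(j)) stopf("positive label %s not in label set", positive_label)
  scores <- unlist(lapply(lmaps, function(m) m$L_mat[, j]))
  truth <- unlist(lapply(truths, function(t) t$labels)) == positive_label
  thr <- sort(unique(c(0, seq(0, 1, length.out = n_thresholds), 1)),
              decreasing = TRUE)
  n_pos <- sum(truth); n_neg <- sum(!truth)
  pts <- t(vapply(thr, function(T) {
    pred <- scores >= T
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    c(sensitivity = if (n_pos > 0) tp / n_pos else NA_real_,
      specificity = if (n_neg > 0) (n_neg - fp) / n_neg else NA_real_)
  }, numeric(2)))
  structure(list(points = data.frame(threshold = thr,
                                     fpr = 1 - pts[, "specificity"],
                                     sensitivity = pts[, "sensitivity"],
                                     specificity = pts[, "specificity"])),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve: %d thresholds, AUC ~ %.4f>\n",
              nrow(x$points), roc_auc(x)))
  invisible(x)
}

#' Trapezoidal area under an ROC curve
#'
#' @param curve a `roc_curve`.
#' @return scalar AUC.
#' @export
roc_auc <- function(curve) {
  p <- curve$points[order(curve$points$fpr, curve$points$sensitivity), ]
  sum(diff(p$fpr) * (utils::head(p$sensitivity, -1) +
                     utils::tail(p$sensitivity, -1)) / 2)
}

#' Nearest curve point to a reference operating point
#'
#' Finds the ROC point minimizing Euclidean distance in
#' (1 - specificity, sensitivity) space to a reference method's operating
#' point — the standard way to compare a thresholded curve against a
#' method that produces a single (sens, spec) pair.
#'
#' @param curve a `roc_curve`.
#' @param point numeric `c(sensitivity, specificity)` of the reference.
#' @return named vector `c(sensitivity =, specificity =, distance =)`.
#' @export
nearest_point_comparison <- function(curve, point) {
  stopifnot(inherits(curve, "roc_curve"), length(point) == 2L)
  p <- curve$points
  d <- sqrt((p$fpr - (1 - point[2]))^2 + (p$sensitivity - point[1])^2)
  i <- which.min(d)
  c(sensitivity = p$sensitivity[i], specificity = p$specificity[i],
    distance = d[i])
}

#' Interpolated sensitivity at a given specificity
#'
#' Linear interpolation along the ROC curve; used to compare models at a
#' matched specificity.
#'
#' @param curve a `roc_curve`.
#' @param specificity target specificity in \[0, 1\].
#' @return interpolated sensitivity.
#' @export
sens_at_spec <- function(curve, specificity) {
  p <- curve$points[order(curve$points$specificity), ]
  stats::approx(p$specificity, p$sensitivity, xout = specificity,
                ties = max, rule = 2)$y
}

#' Assign images to cross-validation folds
#'
#' Seeded random partition into k folds whose sizes differ by at most 1.
#'
#' @param n_images number of images.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold indices in 1..k.
#' @export
fold_assignment <- function(n_images, k, seed) {
  if (k > n_images) stopf("k = %d exceeds the %d images", k, n_images)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  folds <- rep(seq_len(k), length.out = n_images)
  sample(folds)
}

#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

#' @noRd
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' k-fold cross-validation of the segmentation pipeline
#'
#' Features are computed once per image; everything downstream — the LDA
#' projection, class-conditionals, prior and (optionally) the CRF weights
#' — is refitted inside each fold on the other k-1 folds only, and the
#' held-out images are predicted with the fold's model. Pixel counts are
#' pooled (micro-averaged) across all held-out predictions; per-image
#' counts are also returned for macro-averaging.
#'
#' @param images list of sRGB [raster_image]s.
#' @param truths list of aligned [label_field]s.
#' @param k number of folds.
#' @param seed integer seed for the fold shuffle.
#' @param scales a [scale_set] for the filter bank.
#' @param normalize_lstar subtract the mean L* before filtering.
#' @param model `"pp"` (per-pixel MAP) or `"crf"` (min-cut MAP with
#'   weights trained per fold by SPA gradient ascent).
#' @param crf_config a [training_config] for `model = "crf"`.
#' @param labelset the [label_set].
#' @param keep_lmaps also return each held-out image's likelihood map
#'   (needed for ROC sweeps).
#' @return object of class `crossval_result`: `folds`, `predictions`
#'   (list of [label_field]s), `per_image` (data frame of counts),
#'   `pooled` (confusion), `metrics` (pooled sens/spec), optionally
#'   `lmaps`, and for CRF runs `fold_weights`.
#' @export
cross_validate <- function(images, truths, k = 10L, seed = 1L,
                           scales = scale_set(), normalize_lstar = TRUE,
                           model = c("pp", "crf"),
                           crf_config = training_config(n_itr = 25L),
                           labelset = label_set(), keep_lmaps = FALSE) {
  model <- match.arg(model)
  stopifnot(length(images) == length(truths))
  n <- length(images)
  folds <- fold_assignment(n, k, seed)
  stacks <- lapply(images, compute_features, scales = scales,
                   normalize_lstar = normalize_lstar)
  labs <- lapply(images, function(im) {
    l <- rgb_to_lab(im)
    if (normalize_lstar) normalize_lstar(l) else l
  })
  predictions <- vector("list", n)
  lmaps <- if (keep_lmaps) vector("list", n) else NULL
  fold_weights <- if (model == "crf") vector("list", k) else NULL
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    for (l in labelset$labels) {
      if (!any(unlist(lapply(truths[tr], function(t) t$labels)) == l))
        stopf("fold %d: training split lacks label %d", f, l)
    }
    ppm <- fit_pp_model(stacks[tr], truths[tr], labelset)
    wts <- NULL
    if (model == "crf") {
      insts <- lapply(tr, function(m) {
        lm <- likelihood_map(stacks[[m]], ppm$projection, ppm$conditionals)
        list(features = crf_features_from_pp(lm, labs[[m]]),
             truth = truths[[m]])
      })
      trace <- train_weights(insts, crf_config, gradient = "spa")
      wts <- trace$best_w
      fold_weights[[f]] <- wts
    }
    for (m in te) {
      lm <- likelihood_map(stacks[[m]], ppm$projection, ppm$conditionals)
      if (keep_lmaps) lmaps[[m]] <- lm
      predictions[[m]] <- if (model == "pp") {
        predict(ppm, stacks[[m]], mode = "map")
      } else {
        map_inference(crf_features_from_pp(lm, labs[[m]]), wts)
      }
    }
  }
  per_image <- do.call(rbind, lapply(seq_len(n), function(m) {
    cc <- confusion(predictions[[m]], truths[[m]])
    data.frame(image = m, fold = folds[m], tp = cc$tp, fp = cc$fp,
               tn = cc$tn, fn = cc$fn)
  }))
  pooled <- Reduce(add_confusion,
                   lapply(seq_len(n),
                          function(m) confusion(predictions[[m]],
                                                truths[[m]])),
                   empty_confusion())
  structure(list(folds = folds, predictions = predictions,
                 per_image = per_image, pooled = pooled,
                 metrics = sens_spec(pooled), lmaps = lmaps,
                 fold_weights = fold_weights, model = model, seed = seed),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf(
    "<crossval_result: %s model, %d images, %d folds, sens %.4f spec %.4f>\n",
    x$model, length(x$predictions), max(x$folds),
    x$metrics["sensitivity"], x$metrics["specificity"]))
  invisible(x)
}
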