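# File-level plumbing: versioned model persistence and the train/segment
# pipelines the CLI exposes.

MODEL_FORMAT_VERSION <- "1"

#' Save a fitted per-pixel model to a portable JSON file
#'
#' The file is versioned and stores the LDA projection, the per-label
#' Gaussian parameters, the prior and the feature configuration with full
#' double precision.
#'
#' @param model a `pp_model`.
#' @param path output path.
#' @param feature_config optional list recording `scales`,
#'   `normalize_lstar`, `log_scale_normalized` used to build the features.
#' @return `path`, invisibly.
#' @export
write_pp_model <- function(model, path, feature_config = NULL) {
  stopifnot(inherits(model, "pp_model"))
  obj <- list(
    format = "lesioncrf-pp-model",
    version = MODEL_FORMAT_VERSION,
    labels = model$labelset$labels,
    projection = list(Q = model$projection$Q,
                      mu_global = model$projection$mu_global,
                      eigenvalues = model$projection$eigenvalues),
    conditionals = lapply(model$conditionals$params, function(p)
      list(mean = p$mean, cov = p$cov)),
    prior = as.list(model$prior$p),
    feature_config = feature_config)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a per-pixel model saved by [write_pp_model()]
#'
#' @param path file path.
#' @return a `pp_model` (with `feature_config` attached as an attribute).
#' @export
read_pp_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "lesioncrf-pp-model"))
    stopf("%s is not a per-pixel model file", path)
  ls <- label_set(obj$labels)
  proj <- structure(list(Q = as.matrix(obj$projection$Q),
                         mu_global = obj$projection$mu_global,
                         eigenvalues = obj$projection$eigenvalues),
                    class = "lda_projection")
  params <- lapply(obj$conditionals, function(p) {
    list(mean = as.numeric(p$mean),
         cov = as.matrix(p$cov))
  })
  names(params) <- as.character(ls$labels)
  cc <- structure(list(params = params, labelset = ls,
                       dim = length(params[[1]]$mean)),
                  class = "class_conditionals")
  p <- unlist(obj$prior)[as.character(ls$labels)]
  prior <- structure(list(p = p, labelset = ls),
                     class = "prior_distribution")
  model <- structure(list(projection = proj, conditionals = cc,
                          prior = prior, labelset = ls),
                     class = "pp_model")
  attr(model, "feature_config") <- obj$feature_config
  model
}

#' Save trained CRF weights (and optionally the training trace)
#'
#' @param w a [crf_weights].
#' @param path output path.
#' @param trace optional `training_trace` to embed.
#' @return `path`, invisibly.
#' @export
write_crf_weights <- function(w, path, trace = NULL) {
  stopifnot(inherits(w, "crf_weights"))
  obj <- list(format = "lesioncrf-crf-weights",
              version = MODEL_FORMAT_VERSION,
              w = w$w, n_node = length(w$node_indices))
  if (!is.null(trace))
    obj$trace <- list(w = trace$w, gradient = trace$gradient,
                      score = trace$score, best_iter = trace$best_iter,
                      converged = trace$converged)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load CRF weights saved by [write_crf_weights()]
#'
#' @param path file path.
#' @return a [crf_weights].
#' @export
read_crf_weights <- function(path) {
  if (!file.exists(path)) stopf("weights file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "lesioncrf-crf-weights"))
    stopf("%s is not a CRF weights file", path)
  crf_weights(obj$w, n_node = obj$n_node)
}

#' @noRd
load_training_pairs <- function(image_paths, mask_paths, labelset) {
  if (length(image_paths) != length(mask_paths))
    stopf("%d images but %d masks", length(image_paths), length(mask_paths))
  for (p in c(image_paths, mask_paths))
    if (!file.exists(p)) stopf("missing file: %s", p)
  list(images = lapply(image_paths, read_image_png),
       truths = lapply(mask_paths, read_mask_png, labelset = labelset))
}

#' Train a per-pixel model from image/mask files
#'
#' Reads paired images and masks, computes features, fits the LDA
#' projection, class-conditionals and prior, and writes a versioned model
#' file.
#'
#' @param image_paths,mask_paths parallel vectors of PNG paths.
#' @param model_path output model file.
#' @param scales a [scale_set].
#' @param normalize_lstar subtract mean L* before filtering.
#' @param log_scale_normalized scale-normalize the LoG responses.
#' @param labelset binary [label_set].
#' @return the fitted `pp_model`, invisibly.
#' @export
run_train_pp <- function(image_paths, mask_paths, model_path,
                         scales = scale_set(), normalize_lstar = TRUE,
                         log_scale_normalized = FALSE,
                         labelset = label_set()) {
  d <- load_training_pairs(image_paths, mask_paths, labelset)
  stacks <- lapply(d$images, compute_features, scales = scales,
                   normalize_lstar = normalize_lstar,
                   log_scale_normalized = log_scale_normalized)
  model <- fit_pp_model(stacks, d$truths, labelset)
  write_pp_model(model, model_path,
                 feature_config = list(
                   scales = scales$scales,
                   normalize_lstar = normalize_lstar,
                   log_scale_normalized = log_scale_normalized))
  invisible(model)
}

#' Train CRF weights from image/mask files and a per-pixel model
#'
#' Builds per-image CRF features (node costs from the per-pixel
#' likelihood map, edge costs from L* differences) and runs saddle-point
#' gradient ascent.
#'
#' @inheritParams run_train_pp
#' @param pp_model_path path to a model written by [run_train_pp()].
#' @param weights_path output weights file.
#' @param config a [training_config].
#' @param verbose per-iteration logging.
#' @return the `training_trace`, invisibly.
#' @export
run_train_crf <- function(image_paths, mask_paths, pp_model_path,
                          weights_path, config = training_config(),
                          verbose = FALSE) {
  model <- read_pp_model(pp_model_path)
  fc <- feature_config_of(model)
  d <- load_training_pairs(image_paths, mask_paths, model$labelset)
  instances <- lapply(seq_along(d$images), function(m) {
    stack <- compute_features(d$images[[m]], scales = scale_set(fc$scales),
                              normalize_lstar = fc$normalize_lstar,
                              log_scale_normalized = fc$log_scale_normalized)
    lab <- rgb_to_lab(d$images[[m]])
    if (fc$normalize_lstar) lab <- normalize_lstar(lab)
    lm <- likelihood_map(stack, model$projection, model$conditionals)
    list(features = crf_features_from_pp(lm, lab), truth = d$truths[[m]])
  })
  trace <- train_weights(instances, config, gradient = "spa",
                         verbose = verbose)
  write_crf_weights(trace$best_w, weights_path, trace = trace)
  invisible(trace)
}

#' @noRd
feature_config_of <- function(model) {
  fc <- attr(model, "feature_config")
  if (is.null(fc))
    fc <- list(scales = scale_set()$scales, normalize_lstar = TRUE,
               log_scale_normalized = FALSE)
  fc
}

#' Segment images with a trained model
#'
#' Writes one binary mask PNG per input image. Modes: `"pp-map"`
#' (posterior argmax with the fitted prior), `"pp-threshold"` (threshold
#' on the lesion likelihood), `"crf"` (min-cut MAP with trained weights).
#'
#' @param image_paths input PNGs.
#' @param out_paths output mask PNGs (parallel to `image_paths`).
#' @param pp_model_path model file from [run_train_pp()].
#' @param mode segmentation mode.
#' @param weights_path CRF weights file (required for `mode = "crf"`).
#' @param threshold threshold for `mode = "pp-threshold"`.
#' @return invisible list of predicted [label_field]s.
#' @export
run_segment <- function(image_paths, out_paths, pp_model_path,
                        mode = c("pp-map", "pp-threshold", "crf"),
                        weights_path = NULL, threshold = 0.5) {
  mode <- match.arg(mode)
  if (length(image_paths) != length(out_paths))
    stopf("%d images but %d output paths", length(image_paths),
          length(out_paths))
  model <- read_pp_model(pp_model_path)
  fc <- feature_config_of(model)
  w <- NULL
  if (mode == "crf") {
    if (is.null(weights_path)) stopf("crf mode needs a weights file")
    w <- read_crf_weights(weights_path)
  }
  preds <- vector("list", length(image_paths))
  for (m in seq_along(image_paths)) {
    img <- read_image_png(image_paths[m])
    stack <- compute_features(img, scales = scale_set(fc$scales),
                              normalize_lstar = fc$normalize_lstar,
                              log_scale_normalized = fc$log_scale_normalized)
    pred <- switch(mode,
      "pp-map" = predict(model, stack, mode = "map"),
      "pp-threshold" = {
        lm <- likelihood_map(stack, model$projection, model$conditionals)
        threshold_labeling(lm, threshold = threshold)
      },
      "crf" = {
        lab <- rgb_to_lab(img)
        if (fc$normalize_lstar) lab <- normalize_lstar(lab)
        lm <- likelihood_map(stack, model$projection, model$conditionals)
        map_inference(crf_features_from_pp(lm, lab), w)
      })
    write_mask_png(pred, out_paths[m])
    preds[[m]] <- pred
  }
  invisible(preds)
}
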