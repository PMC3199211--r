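# Maximum-likelihood estimation of the CRF weight vector. With
# P(y | x; w) = exp(-E(y, x; w)) / Z(x, w), the regularized log-likelihood
# over training instances is
#   l(w) = sum_m [ -E(y^m, x^m; w) - ln Z(x^m, w) ] - ||w||^2 / (2 sigma^2)
# and its gradient
#   dl/dw_k = sum_m [ E_{P(y|x^m;w)} Phi_k(y) - Phi_k(y^m) ] - w_k / sigma^2.
# The model expectation is exact (enumeration) on tiny grids; at image
# scale it is replaced by the saddle-point approximation, which collapses
# the expectation onto the single MAP labeling y*.

#' Training configuration for CRF weight learning
#'
#' @param w0 initial [crf_weights] (edge entries strictly positive).
#' @param sigma2 regularization variance of the squared-L2 penalty
#'   `||w||^2 / (2 sigma2)`; `Inf` disables regularization.
#' @param gamma base step size for gradient ascent. Each weight's step is
#'   scaled by the average magnitude of its feature over the ground-truth
#'   labelings, so features on different scales train at comparable rates.
#' @param epsilon convergence tolerance on the gradient norm.
#' @param n_itr iteration cap.
#' @param edge_floor positive floor that edge weights are clipped to after
#'   every step, enforcing the submodularity constraint.
#' @return object of class `training_config`.
#' @export
training_config <- function(w0 = crf_weights(c(1, 0.1)), sigma2 = 10,
                            gamma = 1e-3, epsilon = 1e-4, n_itr = 200L,
                            edge_floor = 1e-8) {
  if (!inherits(w0, "crf_weights")) w0 <- crf_weights(w0)
  if (!is.numeric(sigma2) || sigma2 <= 0)
    stopf("sigma2 must be positive (Inf allowed)")
  if (gamma <= 0) stopf("gamma must be positive")
  if (n_itr < 1L) stopf("n_itr must be >= 1")
  if (edge_floor <= 0) stopf("edge_floor must be positive")
  structure(list(w0 = w0, sigma2 = sigma2, gamma = gamma,
                 epsilon = epsilon, n_itr = as.integer(n_itr),
                 edge_floor = edge_floor),
            class = "training_config")
}

#' @noRd
check_instances <- function(instances) {
  if (length(instances) == 0L) stopf("no training instances")
  for (m in seq_along(instances)) {
    inst <- instances[[m]]
    if (!inherits(inst$features, "crf_features") ||
        !inherits(inst$truth, "label_field"))
      stopf("instance %d must be list(features = crf_features, truth = label_field)", m)
  }
  invisible(instances)
}

#' @noRd
all_tiny <- function(instances)
  all(vapply(instances, function(i) i$features$graph$n_nodes <= 20L,
             logical(1)))

#' Regularized log-likelihood of the training data
#'
#' Exact (via the enumerated partition function) when every instance has
#' at most 20 pixels; otherwise the saddle-point surrogate
#' `sum_m [E(y*) - E(y^m)] - ||w||^2/(2 sigma2)` is returned, which
#' replaces `ln Z` by the energy of the MAP labeling.
#'
#' @param w a [crf_weights] or numeric vector.
#' @param instances list of `list(features =, truth =)` pairs.
#' @param sigma2 regularization variance (> 0, `Inf` allowed).
#' @param method `"auto"` (exact iff all instances tiny), `"exact"`, or
#'   `"spa"`.
#' @return scalar score (higher is better).
#' @export
regularized_log_likelihood <- function(w, instances, sigma2 = 10,
                                       method = c("auto", "exact", "spa")) {
  method <- match.arg(method)
  check_instances(instances)
  if (!is.numeric(sigma2) || is.na(sigma2) || sigma2 <= 0)
    stopf("sigma2 must be positive (Inf allowed)")
  wv <- if (inherits(w, "crf_weights")) w$w else as.numeric(w)
  if (method == "auto") method <- if (all_tiny(instances)) "exact" else "spa"
  total <- 0
  for (inst in instances) {
    e_m <- crf_energy(inst$truth, inst$features, wv)
    if (method == "exact") {
      lz <- partition_function(inst$features, wv, log = TRUE)
      total <- total + (-e_m - lz)
    } else {
      ystar <- map_inference(inst$features, crf_weights_like(wv, inst))
      total <- total + (crf_energy(ystar, inst$features, wv) - e_m)
    }
  }
  pen <- if (is.finite(sigma2)) sum(wv^2) / (2 * sigma2) else 0
  total - pen
}

# Rewrap a numeric weight vector with the node/edge split of an instance.
#' @noRd
crf_weights_like <- function(wv, inst) {
  crf_weights(wv, n_node = length(inst$features$node))
}

#' Exact gradient of the regularized log-likelihood
#'
#' Computes the model expectation of each feature function by exhaustive
#' enumeration, so every instance must have at most 20 pixels. Returns the
#' ascent direction: moving `w` along it increases the regularized
#' log-likelihood.
#'
#' @inheritParams regularized_log_likelihood
#' @return numeric gradient, one entry per weight.
#' @export
exact_gradient <- function(w, instances, sigma2 = 10) {
  check_instances(instances)
  if (!all_tiny(instances))
    stopf("exact_gradient requires all instances with N_P <= 20")
  wv <- if (inherits(w, "crf_weights")) w$w else as.numeric(w)
  g <- numeric(length(wv))
  for (inst in instances) {
    ae <- all_energies(inst$features, wv, with_phi = TRUE)
    lp <- -ae$E - logsumexp(-ae$E)
    expect <- as.vector(crossprod(ae$Phi, exp(lp)))
    g <- g + (expect - phi_vector(inst$truth, inst$features))
  }
  if (is.finite(sigma2)) g <- g - wv / sigma2
  g
}

#' Saddle-point-approximated gradient
#'
#' Replaces the model expectation of each feature with its value at the
#' single MAP labeling `y*` of each instance, found by min-cut. Exact in
#' the low-temperature limit where the MAP labeling carries all the
#' probability mass; at image scale it is the only tractable choice.
#'
#' @inheritParams regularized_log_likelihood
#' @return numeric gradient, one entry per weight (ascent direction).
#' @export
spa_gradient <- function(w, instances, sigma2 = 10) {
  check_instances(instances)
  wv <- if (inherits(w, "crf_weights")) w$w else as.numeric(w)
  g <- numeric(length(wv))
  for (inst in instances) {
    ystar <- map_inference(inst$features, crf_weights_like(wv, inst))
    g <- g + (phi_vector(ystar, inst$features) -
              phi_vector(inst$truth, inst$features))
  }
  if (is.finite(sigma2)) g <- g - wv / sigma2
  g
}

#' Learn CRF weights by projected gradient ascent
#'
#' Iterates `w <- w + step * gradient` with per-weight step scaling, then
#' clips edge-feature weights to a small positive floor so the energy
#' stays submodular. Because the saddle-point gradient oscillates rather
#' than converging smoothly, the weights of the best-scoring iteration are
#' recorded and returned, not the final iterate. Terminates when the
#' projected gradient norm (gradient components pointing into the clipped
#' edge-weight constraint count as zero) drops below `epsilon`, or after
#' `n_itr` iterations.
#'
#' @param instances list of `list(features =, truth =)` pairs over binary
#'   label sets.
#' @param config a [training_config].
#' @param gradient `"spa"` (default; scales to full images) or `"exact"`
#'   (tiny instances only).
#' @param verbose print per-iteration scores.
#' @return object of class `training_trace`: `w` (iterations x N_W matrix
#'   of the evaluated iterates, first row = `w0`), `gradient` (matrix),
#'   `score` (regularized score at each iterate; exact when all instances
#'   are tiny and the exact gradient is used, otherwise the saddle-point
#'   surrogate), `best_w`, `best_iter`, `converged`.
#' @export
train_weights <- function(instances, config = training_config(),
                          gradient = c("spa", "exact"), verbose = FALSE) {
  gradient <- match.arg(gradient)
  check_instances(instances)
  stopifnot(inherits(config, "training_config"))
  if (gradient == "exact" && !all_tiny(instances))
    stopf("exact-gradient training requires all instances with N_P <= 20")
  n_node <- length(instances[[1]]$features$node)
  n_w <- instances[[1]]$features$n_features
  wv <- config$w0$w
  if (length(wv) != n_w)
    stopf("w0 has %d entries; features expect %d", length(wv), n_w)
  edge_idx <- if (n_node < n_w) (n_node + 1L):n_w else integer(0)
  use_exact <- gradient == "exact"
  # per-weight step scale: feature magnitude over the ground truths
  phi_gt <- vapply(instances,
                   function(i) phi_vector(i$truth, i$features),
                   numeric(n_w))
  phi_gt <- matrix(phi_gt, nrow = n_w)
  step <- config$gamma / pmax(rowMeans(abs(phi_gt)), 1)
  pen <- function(w) if (is.finite(config$sigma2))
    sum(w^2) / (2 * config$sigma2) else 0
  # joint gradient + score at one iterate: the exact route reuses the
  # enumeration for both, the SPA route reuses each instance's single
  # MAP labeling for both (one min-cut per instance per iteration)
  evaluate <- function(w) {
    g <- numeric(n_w); ll <- 0
    for (m in seq_along(instances)) {
      inst <- instances[[m]]
      if (use_exact) {
        ae <- all_energies(inst$features, w, with_phi = TRUE)
        lp <- -ae$E - logsumexp(-ae$E)
        g <- g + as.vector(crossprod(ae$Phi, exp(lp))) - phi_gt[, m]
        ll <- ll + (-sum(w * phi_gt[, m]) - logsumexp(-ae$E))
      } else {
        ystar <- map_inference(inst$features,
                               crf_weights(w, n_node = n_node))
        dphi <- phi_vector(ystar, inst$features) - phi_gt[, m]
        g <- g + dphi
        ll <- ll + sum(w * dphi)
      }
    }
    if (is.finite(config$sigma2)) g <- g - w / config$sigma2
    list(gradient = g, score = ll - pen(w))
  }
  W <- matrix(NA_real_, config$n_itr, n_w)
  G <- matrix(NA_real_, config$n_itr, n_w)
  score <- rep(NA_real_, config$n_itr)
  best_score <- -Inf; best_w <- wv; best_iter <- 0L
  converged <- FALSE
  it <- 0L
  for (it in seq_len(config$n_itr)) {
    ev <- evaluate(wv)
    g <- ev$gradient
    W[it, ] <- wv
    G[it, ] <- g
    score[it] <- ev$score
    if (score[it] > best_score) {
      best_score <- score[it]; best_w <- wv; best_iter <- it
    }
    # projected gradient: a clipped edge weight with an inward-pointing
    # gradient is stationary under the positivity constraint
    g_proj <- g
    at_floor <- intersect(edge_idx, which(wv <= config$edge_floor))
    g_proj[at_floor][g[at_floor] < 0] <- 0
    if (verbose)
      message(sprintf("iter %3d  score %.6g  |grad| %.3g  w = [%s]",
                      it, score[it], sqrt(sum(g_proj^2)),
                      paste(signif(wv, 4), collapse = ", ")))
    if (sqrt(sum(g_proj^2)) < config$epsilon) { converged <- TRUE; break }
    wv <- wv + step * g
    wv[edge_idx] <- pmax(wv[edge_idx], config$edge_floor)
    if (any(!is.finite(wv)))
      stop(structure(class = c("crf_divergence", "error", "condition"),
                     list(message = sprintf(
                            "weights diverged at iteration %d", it),
                          call = NULL,
                          trace = list(w = W[seq_len(it), , drop = FALSE],
                                       gradient = G[seq_len(it), ,
                                                    drop = FALSE]))))
  }
  keep <- seq_len(it)
  structure(list(w = W[keep, , drop = FALSE],
                 gradient = G[keep, , drop = FALSE],
                 score = score[keep],
                 best_w = crf_weights(best_w, n_node = n_node),
                 best_iter = best_iter,
                 best_score = best_score,
                 converged = converged,
                 n_iterations = it,
                 config = config,
                 gradient_type = gradient),
            class = "training_trace")
}

#' @export
print.training_trace <- function(x, ...) {
  cat(sprintf(
    "<training_trace: %d iterations (%s gradient), best iter %d, score %.6g>\n",
    x$n_iterations, x$gradient_type, x$best_iter, x$best_score))
  cat(sprintf("  best_w = [%s]\n",
              paste(signif(x$best_w$w, 6), collapse = ", ")))
  invisible(x)
}

#' Export a training trace as a data frame
#'
#' One row per iteration with weights, gradients and score; suitable for
#' CSV export and plotting.
#'
#' @param trace a `training_trace`.
#' @return a `data.frame`.
#' @export
trace_as_data_frame <- function(trace) {
  stopifnot(inherits(trace, "training_trace"))
  n_w <- ncol(trace$w)
  df <- data.frame(iteration = seq_len(nrow(trace$w)))
  for (k in seq_len(n_w)) df[[paste0("w", k)]] <- trace$w[, k]
  for (k in seq_len(n_w)) df[[paste0("grad", k)]] <- trace$gradient[, k]
  df$score <- trace$score
  df
}
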