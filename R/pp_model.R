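# Per-pixel MAP labeling: LDA projection, Gaussian class-conditionals,
# discrete prior. Pixels are labeled independently; the CRF module adds
# the spatial coupling.

#' Fit a linear discriminant projection
#'
#' Pools pixels across all training images and solves the generalized
#' eigenproblem of the between-class scatter `S_b` against the within-class
#' scatter `S_w` (the sum of per-class covariance matrices). The projection
#' `Q` holds the `N_L - 1` leading eigenvectors of `S_w^{-1} S_b`, the
#' directions that best separate the classes; observations are projected as
#' `x Q`. Solved as a symmetric eigenproblem through the Cholesky factor of
#' `S_w` rather than by explicit inversion; if `S_w` is ill-conditioned a
#' shrinkage ridge `1e-6 * tr(S_w)/N_C` is added with a warning.
#'
#' @param stacks list of `feature_stack`s.
#' @param truths list of [label_field]s aligned pixel-for-pixel with
#'   `stacks`.
#' @param labelset the [label_set]; every label must occur in the truths.
#' @return object of class `lda_projection` with fields `Q`
#'   (N_C x (N_L - 1)), `mu_global` (overall feature mean) and
#'   `eigenvalues`.
#' @export
fit_lda <- function(stacks, truths, labelset = label_set()) {
  xy <- pool_pixels(stacks, truths, labelset)
  X <- xy$X
  y <- xy$y
  n_c <- ncol(X)
  labs <- labelset$labels
  mu <- colMeans(X)
  Sw <- matrix(0, n_c, n_c)
  Sb <- matrix(0, n_c, n_c)
  for (l in labs) {
    sel <- y == l
    n_l <- sum(sel)
    if (n_l == 0L) stopf("label %d absent from training data", l)
    if (n_l < n_c + 1L)
      stopf("label %d has %d pixels; need at least N_C + 1 = %d",
            l, n_l, n_c + 1L)
    Xl <- X[sel, , drop = FALSE]
    mul <- colMeans(Xl)
    Xc <- sweep(Xl, 2L, mul)
    Sw <- Sw + crossprod(Xc) / n_l          # per-class ML covariance
    Sb <- Sb + tcrossprod(mul - mu)
  }
  R <- tryCatch(chol(Sw), error = function(e) NULL)
  if (is.null(R) || rcond(Sw) < 1e-12) {
    warning("within-class scatter ill-conditioned; applying shrinkage",
            call. = FALSE)
    Sw <- Sw + diag(1e-6 * sum(diag(Sw)) / n_c, n_c)
    R <- chol(Sw)
  }
  # S_w^{-1} S_b shares eigenvalues with the symmetric R^{-T} S_b R^{-1}
  C <- backsolve(R, t(backsolve(R, Sb, transpose = TRUE)), transpose = TRUE)
  C <- (C + t(C)) / 2
  eg <- eigen(C, symmetric = TRUE)
  k <- length(labs) - 1L
  Q <- backsolve(R, eg$vectors[, seq_len(k), drop = FALSE])
  # deterministic sign: largest-magnitude entry of each column positive
  for (j in seq_len(k)) {
    i <- which.max(abs(Q[, j]))
    if (Q[i, j] < 0) Q[, j] <- -Q[, j]
  }
  structure(list(Q = Q, mu_global = mu,
                 eigenvalues = eg$values[seq_len(k)]),
            class = "lda_projection")
}

# Stack pixels of all images into one matrix + label vector.
#' @noRd
pool_pixels <- function(stacks, truths, labelset) {
  if (length(stacks) != length(truths))
    stopf("got %d stacks but %d truths", length(stacks), length(truths))
  if (length(stacks) == 0L) stopf("empty training set")
  for (m in seq_along(stacks)) {
    if (nrow(stacks[[m]]$values) != length(truths[[m]]$labels))
      stopf("image %d: %d feature rows vs %d truth pixels", m,
            nrow(stacks[[m]]$values), length(truths[[m]]$labels))
  }
  list(X = do.call(rbind, lapply(stacks, function(s) s$values)),
       y = unlist(lapply(truths, function(t) t$labels)))
}

#' Project a feature stack through a fitted LDA projection
#'
#' @param stack a `feature_stack`.
#' @param proj an `lda_projection`.
#' @return N_P x (N_L - 1) matrix of projected observations.
#' @export
project_features <- function(stack, proj) {
  stopifnot(inherits(proj, "lda_projection"))
  stack$values %*% proj$Q
}

#' Fit Gaussian class-conditional densities in the projected space
#'
#' Per-label sample mean and maximum-likelihood covariance (divide by N)
#' over all pixels carrying that ground-truth label, pooled across images.
#' Near-singular covariances are ridge-regularized with a warning.
#'
#' @param projected list of projected feature matrices
#'   (see [project_features()]).
#' @param truths list of aligned [label_field]s.
#' @param labelset the [label_set].
#' @param unbiased use the N-1 denominator instead of the
#'   maximum-likelihood N (default `FALSE`).
#' @return object of class `class_conditionals`: per label, `mean` and
#'   `cov`.
#' @export
fit_class_conditionals <- function(projected, truths,
                                   labelset = label_set(),
                                   unbiased = FALSE) {
  X <- do.call(rbind, lapply(projected, as.matrix))
  y <- unlist(lapply(truths, function(t) t$labels))
  if (nrow(X) != length(y)) stopf("projected data and truths misaligned")
  d <- ncol(X)
  out <- vector("list", length(labelset$labels))
  names(out) <- as.character(labelset$labels)
  for (l in labelset$labels) {
    sel <- y == l
    n_l <- sum(sel)
    if (n_l < 2L) stopf("label %d has %d samples; need at least 2", l, n_l)
    Xl <- X[sel, , drop = FALSE]
    mul <- colMeans(Xl)
    Xc <- sweep(Xl, 2L, mul)
    S <- crossprod(Xc) / if (unbiased) (n_l - 1) else n_l
    scale <- mean(diag(S))
    floor_ridge <- max(1e-12, 1e-9 * max(scale, 1))
    ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < floor_ridge) {
      warning(sprintf("near-singular covariance for label %d; ridge added",
                      l), call. = FALSE)
      S <- S + diag(floor_ridge - min(ev_min, 0) + 1e-12 * max(scale, 1), d)
    }
    out[[as.character(l)]] <- list(mean = mul, cov = S)
  }
  structure(list(params = out, labelset = labelset, dim = d),
            class = "class_conditionals")
}

#' Fit the discrete label prior from pooled pixel counts
#'
#' `P(y = l_j)` is the fraction of all training pixels labeled `l_j`,
#' pooled over images without per-image reweighting.
#'
#' @param truths list of [label_field]s.
#' @param labelset the [label_set].
#' @return object of class `prior_distribution` with field `p`
#'   (named, sums to 1).
#' @export
fit_prior <- function(truths, labelset = label_set()) {
  if (length(truths) == 0L) stopf("empty training set")
  y <- unlist(lapply(truths, function(t) t$labels))
  counts <- vapply(labelset$labels, function(l) sum(y == l), numeric(1))
  p <- counts / sum(counts)
  names(p) <- as.character(labelset$labels)
  structure(list(p = p, labelset = labelset), class = "prior_distribution")
}

# Per-label log densities of a projected stack: N_P x N_L matrix.
#' @noRd
class_log_densities <- function(xq, cc) {
  xq <- as.matrix(xq)
  labs <- cc$labelset$labels
  ld <- matrix(NA_real_, nrow(xq), length(labs))
  for (j in seq_along(labs)) {
    par <- cc$params[[as.character(labs[j])]]
    ld[, j] <- mvn_logpdf(xq, par$mean, par$cov)
  }
  ld
}

#' Normalized per-pixel likelihood map
#'
#' Evaluates the Gaussian class-conditional density of every pixel under
#' every label and normalizes across the label set, so each row is a
#' probability vector. Computed in log space with log-sum-exp
#' normalization, so simultaneous underflow of all densities cannot occur.
#'
#' @param stack a `feature_stack`.
#' @param proj an `lda_projection`.
#' @param cc a `class_conditionals`.
#' @return object of class `likelihood_map`: `L_mat` (N_P x N_L, rows sum
#'   to 1), `height`, `width`, `labelset`.
#' @export
likelihood_map <- function(stack, proj, cc) {
  xq <- project_features(stack, proj)
  ld <- class_log_densities(xq, cc)
  L <- exp(ld - row_logsumexp(ld))
  structure(list(L_mat = L, height = stack$height, width = stack$width,
                 labelset = cc$labelset),
            class = "likelihood_map")
}

#' Independent per-pixel MAP labeling
#'
#' Assigns each pixel the label maximizing density times prior,
#' independently of its neighbors. Ties break toward the lowest label
#' index. Labels with prior 0 can never be assigned.
#'
#' @inheritParams likelihood_map
#' @param prior a `prior_distribution`.
#' @return a [label_field].
#' @export
map_label <- function(stack, proj, cc, prior) {
  xq <- project_features(stack, proj)
  ld <- class_log_densities(xq, cc)
  lp <- sweep(ld, 2L, log(prior$p), `+`)
  idx <- max.col(lp, ties.method = "first")
  label_field(cc$labelset$labels[idx], stack$height, stack$width,
              cc$labelset)
}

#' Threshold a binary likelihood map
#'
#' Labels pixel i with `target_label` iff its normalized likelihood for
#' that label is at least `threshold`; otherwise the other label.
#'
#' @param lmap a `likelihood_map` over a binary label set.
#' @param target_label the label to threshold for (default: second label).
#' @param threshold value in \[0, 1\].
#' @return a [label_field].
#' @export
threshold_labeling <- function(lmap, target_label = NULL, threshold = 0.5) {
  stopifnot(inherits(lmap, "likelihood_map"))
  labs <- lmap$labelset$labels
  if (length(labs) != 2L) stopf("threshold_labeling requires a binary task")
  if (is.null(target_label)) target_label <- labs[2]
  if (!target_label %in% labs) stopf("unknown target label %s", target_label)
  if (!is.finite(threshold) || threshold < 0 || threshold > 1)
    stopf("threshold must lie in [0, 1], got %g", threshold)
  j <- match(target_label, labs)
  other <- labs[labs != target_label][1]
  lab <- ifelse(lmap$L_mat[, j] >= threshold, target_label, other)
  label_field(lab, lmap$height, lmap$width, lmap$labelset)
}

#' Fit the full per-pixel model
#'
#' Convenience wrapper chaining [fit_lda()], [project_features()],
#' [fit_class_conditionals()] and [fit_prior()].
#'
#' @param stacks list of `feature_stack`s.
#' @param truths list of aligned [label_field]s.
#' @param labelset the [label_set].
#' @return object of class `pp_model` with fields `projection`,
#'   `conditionals`, `prior`, `labelset`.
#' @export
fit_pp_model <- function(stacks, truths, labelset = label_set()) {
  proj <- fit_lda(stacks, truths, labelset)
  projected <- lapply(stacks, project_features, proj = proj)
  cc <- fit_class_conditionals(projected, truths, labelset)
  prior <- fit_prior(truths, labelset)
  structure(list(projection = proj, conditionals = cc, prior = prior,
                 labelset = labelset),
            class = "pp_model")
}

#' Predict with a fitted per-pixel model
#'
#' @param object a `pp_model`.
#' @param stack a `feature_stack` for the image to label.
#' @param mode `"map"` (posterior argmax with the fitted prior),
#'   `"map-uniform"` (likelihood argmax) or `"threshold"`.
#' @param threshold threshold for `mode = "threshold"`.
#' @param ... unused.
#' @return a [label_field].
#' @export
predict.pp_model <- function(object, stack, mode = c("map", "map-uniform",
                                                     "threshold"),
                             threshold = 0.5, ...) {
  mode <- match.arg(mode)
  if (mode == "map")
    return(map_label(stack, object$projection, object$conditionals,
                     object$prior))
  lmap <- likelihood_map(stack, object$projection, object$conditionals)
  if (mode == "threshold")
    return(threshold_labeling(lmap, threshold = threshold))
  # uniform prior: per-row argmax of the likelihood map
  idx <- max.col(lmap$L_mat, ties.method = "first")
  label_field(object$labelset$labels[idx], stack$height, stack$width,
              object$labelset)
}
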