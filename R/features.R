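#' Filter scale set
#'
#' @param scales strictly increasing positive filter scales (sigma, pixels).
#'   The default is the five-octave bank used throughout the package.
#' @return an object of class `scale_set`.
#' @export
scale_set <- function(scales = c(1.25, 2.5, 5, 10, 20)) {
  scales <- as.numeric(scales)
  if (length(scales) == 0L) stopf("scale set must be nonempty")
  if (any(!is.finite(scales)) || any(scales <= 0))
    stopf("all scales must be positive and finite")
  if (is.unsorted(scales, strictly = TRUE))
    stopf("scales must be strictly increasing")
  structure(list(scales = scales), class = "scale_set")
}

# 1-D Gaussian taps on -r..r, truncated at 4 sigma, normalized to sum 1.
#' @noRd
gauss_taps <- function(sigma) {
  r <- ceiling(4 * sigma)
  x <- seq.int(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 1-D second-derivative-of-Gaussian taps. Zero-mean corrected so that the
# separable Laplacian-of-Gaussian annihilates constant images exactly in
# discrete arithmetic.
#' @noRd
gauss_d2_taps <- function(sigma) {
  r <- ceiling(4 * sigma)
  x <- seq.int(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- (x^2 - sigma^2) / sigma^4 * g
  k - mean(k)
}

# Dense n x n matrix applying a 1-D convolution with reflective padding:
# (K %*% v)[i] = sum_t taps[t] * v[reflect(i + offset_t)].
# Dense is deliberate: image sides here are a few hundred at most, and a
# matrix product handles kernels wider than the image transparently.
#' @noRd
conv_matrix <- function(taps, n) {
  r <- (length(taps) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (t in seq_along(taps)) {
    off <- t - r - 1L
    src <- reflect_index(seq_len(n) + off, n)
    K[cbind(seq_len(n), src)] <- K[cbind(seq_len(n), src)] + taps[t]
  }
  K
}

# Separable filtering of an H x W matrix: rows filtered with `kr`,
# columns with `kc` (both conv_matrix outputs).
#' @noRd
sep_filter <- function(M, kr, kc) kr %*% M %*% t(kc)

#' Gaussian / Laplacian-of-Gaussian filter-bank features
#'
#' Computes, for each of the three color channels and each scale, a
#' Gaussian-smoothed response and a Laplacian-of-Gaussian response, giving
#' `2 * length(scales) * 3` feature channels (30 for the default bank).
#' Filtering uses reflective boundary padding and kernels truncated at
#' 4 sigma. Channel order is stable: channels vary slowest, then scale,
#' with the Gaussian response preceding the LoG response at each
#' (channel, scale) pair.
#'
#' @param img a [raster_image] in CIELab (convert and optionally
#'   normalize first; see [rgb_to_lab()], [normalize_lstar()]).
#' @param scales a [scale_set].
#' @param log_scale_normalized if `TRUE`, LoG responses are multiplied by
#'   sigma^2 (scale-normalized derivatives). Default `FALSE`: plain
#'   Laplacian of Gaussian.
#' @return an object of class `feature_stack` with fields `values`
#'   (N_P x N_C matrix, rows in row-major pixel order), `height`, `width`
#'   and `channel_names`.
#' @export
filter_bank <- function(img, scales = scale_set(),
                        log_scale_normalized = FALSE) {
  stopifnot(inherits(img, "raster_image"))
  if (img$color_space != "CIELab")
    stopf("filter_bank expects a CIELab image; call rgb_to_lab() first")
  if (!inherits(scales, "scale_set")) scales <- scale_set(scales)
  sig <- scales$scales
  h <- dim(img$pixels)[1]
  w <- dim(img$pixels)[2]
  n_c <- 2L * length(sig) * 3L
  vals <- matrix(NA_real_, h * w, n_c)
  nms <- character(n_c)
  ch_names <- c("L", "a", "b")
  col <- 0L
  for (ch in 1:3) {
    M <- img$pixels[, , ch]
    for (s in sig) {
      g <- gauss_taps(s)
      d2 <- gauss_d2_taps(s)
      Kg_r <- conv_matrix(g, h)
      Kg_c <- conv_matrix(g, w)
      Kd_r <- conv_matrix(d2, h)
      Kd_c <- conv_matrix(d2, w)
      smooth <- sep_filter(M, Kg_r, Kg_c)
      log_resp <- sep_filter(M, Kd_r, Kg_c) + sep_filter(M, Kg_r, Kd_c)
      if (log_scale_normalized) log_resp <- s^2 * log_resp
      col <- col + 1L
      vals[, col] <- matrix_to_field(smooth)
      nms[col] <- sprintf("G(%s,%g)", ch_names[ch], s)
      col <- col + 1L
      vals[, col] <- matrix_to_field(log_resp)
      nms[col] <- sprintf("LoG(%s,%g)", ch_names[ch], s)
    }
  }
  structure(list(values = vals, height = h, width = w, channel_names = nms),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack %d x %d pixels, %d channels>\n",
              x$height, x$width, ncol(x$values)))
  invisible(x)
}

#' Full feature pipeline from an sRGB image
#'
#' Convenience wrapper: sRGB to CIELab, optional L* mean-normalization,
#' filter bank.
#'
#' @inheritParams filter_bank
#' @param img a [raster_image] in sRGB.
#' @param normalize_lstar subtract the mean of L* before filtering
#'   (default `TRUE`); compensates for per-image exposure differences.
#' @return a `feature_stack`.
#' @export
compute_features <- function(img, scales = scale_set(),
                             normalize_lstar = TRUE,
                             log_scale_normalized = FALSE) {
  lab <- rgb_to_lab(img)
  if (normalize_lstar) lab <- normalize_lstar(lab)
  filter_bank(lab, scales, log_scale_normalized = log_scale_normalized)
}
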