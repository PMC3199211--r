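# Synthetic dermoscopy-like scenes: a darker, roughly elliptical lesion on
# lighter skin, per-channel Gaussian sensor noise, a global exposure (L*)
# offset emulating uncalibrated cameras, and optional dark hair-like
# streaks. Ground truth is the exact analytic ellipse; noise, exposure and
# hair never touch the mask.

#' Specification of one synthetic lesion scene
#'
#' @param height,width image size in pixels.
#' @param center lesion ellipse center `c(row, col)` (pixel centers at
#'   integer coordinates).
#' @param axes ellipse semi-axes `c(a, b)` in pixels (both > 0).
#' @param rotation ellipse rotation in radians.
#' @param skin_color,lesion_color sRGB triples in \[0, 1\].
#' @param noise_sd per-channel Gaussian noise standard deviation (sRGB
#'   units, >= 0).
#' @param lstar_offset global exposure offset added to L* after
#'   composition (CIELab units).
#' @param n_hairs number of dark hair streaks.
#' @param hair_width streak width in pixels (1-3 typical).
#' @param hair_darkness blend strength toward the hair color in \[0, 1\].
#' @param boundary_blur Gaussian sigma (pixels) softening the skin/lesion
#'   color transition; 0 gives a hard two-color boundary. The mask is
#'   never blurred.
#' @param seed mandatory integer seed; identical specs produce identical
#'   scenes.
#' @return object of class `lesion_scene_spec`.
#' @export
lesion_scene_spec <- function(height = 48L, width = 48L,
                              center = c(height / 2, width / 2),
                              axes = c(height * 0.28, width * 0.22),
                              rotation = 0,
                              skin_color = c(0.80, 0.62, 0.52),
                              lesion_color = c(0.38, 0.24, 0.20),
                              noise_sd = 0.02,
                              lstar_offset = 0,
                              n_hairs = 0L,
                              hair_width = 2,
                              hair_darkness = 0.7,
                              boundary_blur = 1,
                              seed) {
  if (missing(seed)) stopf("a seed is mandatory for scene generation")
  if (any(axes <= 0)) stopf("degenerate ellipse: axes must be positive")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (any(skin_color < 0 | skin_color > 1) ||
      any(lesion_color < 0 | lesion_color > 1))
    stopf("colors must be sRGB triples in [0, 1]")
  if (center[1] < 1 - axes[1] - axes[2] ||
      center[1] > height + axes[1] + axes[2] ||
      center[2] < 1 - axes[1] - axes[2] ||
      center[2] > width + axes[1] + axes[2])
    stopf("lesion lies entirely outside the frame")
  structure(list(height = as.integer(height), width = as.integer(width),
                 center = center, axes = axes, rotation = rotation,
                 skin_color = skin_color, lesion_color = lesion_color,
                 noise_sd = noise_sd, lstar_offset = lstar_offset,
                 n_hairs = as.integer(n_hairs), hair_width = hair_width,
                 hair_darkness = hair_darkness,
                 boundary_blur = boundary_blur, seed = as.integer(seed)),
            class = "lesion_scene_spec")
}

# Distance from pixel centers to a segment p1-p2 (rows/cols as points).
#' @noRd
segment_distance <- function(rows, cols, p1, p2) {
  v <- p2 - p1
  len2 <- sum(v^2)
  if (len2 == 0) return(sqrt((rows - p1[1])^2 + (cols - p1[2])^2))
  t <- ((rows - p1[1]) * v[1] + (cols - p1[2]) * v[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((rows - (p1[1] + t * v[1]))^2 + (cols - (p1[2] + t * v[2]))^2)
}

#' Generate one synthetic dermoscopy scene
#'
#' Composes the lesion ellipse over the skin color (optionally with a
#' blurred color transition), draws hair streaks, adds per-channel
#' Gaussian noise, and finally applies the global L* exposure offset in
#' CIELab — exposure acts on the whole composed scene, as a camera would.
#' The returned ground-truth mask is exact ellipse membership, unaffected
#' by blur, noise, hair or exposure.
#'
#' @param spec a [lesion_scene_spec].
#' @param labelset binary [label_set]; first label = skin, second =
#'   lesion.
#' @return list with `image` (sRGB [raster_image]), `mask`
#'   ([label_field]) and `spec`.
#' @export
generate_scene <- function(spec, labelset = label_set()) {
  stopifnot(inherits(spec, "lesion_scene_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  rows <- matrix(rep(seq_len(h), w), h, w)
  cols <- matrix(rep(seq_len(w), each = h), h, w)
  dr <- rows - spec$center[1]; dc <- cols - spec$center[2]
  u <- dr * cos(spec$rotation) + dc * sin(spec$rotation)
  v <- -dr * sin(spec$rotation) + dc * cos(spec$rotation)
  inside <- (u / spec$axes[1])^2 + (v / spec$axes[2])^2 <= 1
  weight <- inside * 1.0
  if (spec$boundary_blur > 0) {
    g <- gauss_taps(spec$boundary_blur)
    weight <- sep_filter(weight, conv_matrix(g, h), conv_matrix(g, w))
  }
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3)
    px[, , ch] <- spec$skin_color[ch] * (1 - weight) +
                  spec$lesion_color[ch] * weight
  if (spec$n_hairs > 0) {
    hair_color <- c(0.10, 0.08, 0.06)
    for (i in seq_len(spec$n_hairs)) {
      p1 <- c(stats::runif(1, 1, h), stats::runif(1, 1, w))
      ang <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, 0.5, 1.2) * max(h, w)
      p2 <- p1 + len * c(sin(ang), cos(ang))
      d <- segment_distance(rows, cols, p1, p2)
      alpha <- pmin(pmax(spec$hair_width / 2 + 0.5 - d, 0), 1)
      blend <- spec$hair_darkness * alpha
      for (ch in 1:3)
        px[, , ch] <- px[, , ch] * (1 - blend) + hair_color[ch] * blend
    }
  }
  if (spec$noise_sd > 0)
    px <- px + array(stats::rnorm(length(px), sd = spec$noise_sd),
                     dim = dim(px))
  px <- pmin(pmax(px, 0), 1)
  img <- raster_image(px, "sRGB")
  if (spec$lstar_offset != 0) {
    lab <- rgb_to_lab(img)
    lab$pixels[, , 1] <- pmin(pmax(lab$pixels[, , 1] + spec$lstar_offset,
                                   0), 100)
    img <- lab_to_rgb(lab)
  }
  mask <- label_field(matrix_to_field(
    ifelse(inside, labelset$labels[2], labelset$labels[1])),
    h, w, labelset)
  list(image = img, mask = mask, spec = spec)
}

#' Generate a reproducible synthetic dataset
#'
#' Draws `n_images` scenes whose per-scene parameters are sampled
#' uniformly from the given ranges using a seed-derived stream; each image
#' receives its own exposure offset, emulating a set of uncalibrated
#' acquisitions. Defaults describe a moderately easy segmentation task:
#' well-separated skin/lesion colors, mild sensor noise, modest exposure
#' spread and no hair.
#'
#' @param n_images number of scenes (>= 1).
#' @param seed integer master seed.
#' @param height,width image size.
#' @param axis_frac range of ellipse semi-axes as a fraction of image
#'   size.
#' @param center_jitter_frac ellipse center uniform jitter around the
#'   image center, as a fraction of image size.
#' @param skin_color,lesion_color base sRGB colors.
#' @param color_jitter per-channel uniform jitter half-width applied to
#'   both colors independently per image.
#' @param noise_sd noise level (single value or range).
#' @param offset_range range of per-image L* exposure offsets.
#' @param n_hairs_range integer range of hair counts per image.
#' @param hair_width_range,hair_darkness_range hair geometry ranges.
#' @param boundary_blur transition softness (single value or range).
#' @param labelset binary [label_set].
#' @return list of scenes (each `list(image, mask, spec)`) with the
#'   sampled specs attached.
#' @export
generate_dataset <- function(n_images, seed,
                             height = 48L, width = 48L,
                             axis_frac = c(0.18, 0.32),
                             center_jitter_frac = 0.10,
                             skin_color = c(0.80, 0.62, 0.52),
                             lesion_color = c(0.38, 0.24, 0.20),
                             color_jitter = 0.03,
                             noise_sd = 0.02,
                             offset_range = c(-10, 10),
                             n_hairs_range = c(0L, 0L),
                             hair_width_range = c(1, 3),
                             hair_darkness_range = c(0.5, 0.8),
                             boundary_blur = 1,
                             labelset = label_set()) {
  if (n_images < 1L) stopf("n_images must be >= 1")
  rng <- function(x) if (length(x) == 1L) c(x, x) else range(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  scene_seeds <- sample.int(.Machine$integer.max, n_images)
  specs <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    jit <- function(col) pmin(pmax(col + stats::runif(3, -color_jitter,
                                                      color_jitter), 0), 1)
    specs[[i]] <- lesion_scene_spec(
      height = height, width = width,
      center = c(height / 2 + stats::runif(1, -1, 1) * center_jitter_frac * height,
                 width / 2 + stats::runif(1, -1, 1) * center_jitter_frac * width),
      axes = c(stats::runif(1, axis_frac[1], axis_frac[2]) * height,
               stats::runif(1, axis_frac[1], axis_frac[2]) * width),
      rotation = stats::runif(1, 0, pi),
      skin_color = jit(skin_color),
      lesion_color = jit(lesion_color),
      noise_sd = stats::runif(1, rng(noise_sd)[1], rng(noise_sd)[2]),
      lstar_offset = stats::runif(1, offset_range[1], offset_range[2]),
      n_hairs = if (max(n_hairs_range) > 0)
        sample(seq.int(n_hairs_range[1], n_hairs_range[2]), 1) else 0L,
      hair_width = stats::runif(1, hair_width_range[1],
                                hair_width_range[2]),
      hair_darkness = stats::runif(1, hair_darkness_range[1],
                                   hair_darkness_range[2]),
      boundary_blur = stats::runif(1, rng(boundary_blur)[1],
                                   rng(boundary_blur)[2]),
      seed = scene_seeds[i])
  }
  lapply(specs, generate_scene, labelset = labelset)
}
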