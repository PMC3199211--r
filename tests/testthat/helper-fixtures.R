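# Shared fixtures: all synthetic, built in code at test time.

# Wrap a plain feature matrix as a feature_stack (for model-level tests
# that do not need the filter bank).
make_stack <- function(X, height, width) {
  structure(list(values = as.matrix(X), height = height, width = width,
                 channel_names = paste0("f", seq_len(ncol(X)))),
            class = "feature_stack")
}

# Independent sRGB -> CIELab conversion (hand-coded D65 pipeline),
# kept deliberately separate from the package implementation.
reference_srgb_to_lab <- function(rgb) {
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92,
                ((rgb + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041),
              3, 3, byrow = TRUE)
  xyz <- as.vector(M %*% lin)
  white <- c(0.95047, 1.0, 1.08883)
  t <- xyz / white
  f <- ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  c(L = 116 * f[2] - 16,
    a = 500 * (f[1] - f[2]),
    b = 200 * (f[2] - f[3]))
}

# Random binary CRF instance on an h x w grid: uniform node costs in
# [0, 1], uniform nonnegative edge costs, one node + one edge feature.
random_crf_instance <- function(h, w, n_l = 2L) {
  g <- build_grid(h, w)
  n <- g$n_nodes
  feats <- crf_features(node = list(matrix(runif(n * n_l), n, n_l)),
                        edge = list(runif(nrow(g$edges))),
                        graph = g,
                        labelset = label_set(seq_len(n_l) - 1L))
  wts <- crf_weights(c(runif(1, 0.2, 2), runif(1, 0.05, 1.5)))
  list(features = feats, weights = wts, graph = g)
}

# Sample a labeling from the exact CRF distribution (tiny grids only).
sample_crf_labeling <- function(feats, w) {
  ae <- lesioncrf:::all_energies(feats, w)
  p <- exp(-ae$E - lesioncrf:::logsumexp(-ae$E))
  k <- sample.int(length(p), 1L, prob = p)
  label_field(feats$labelset$labels[ae$Y[k, ]],
              feats$graph$height, feats$graph$width, feats$labelset)
}

# Scale all feature functions of an instance by a constant (lowers the
# temperature of the induced distribution).
scale_crf_features <- function(feats, c) {
  feats$node <- lapply(feats$node, function(N) N * c)
  feats$edge <- lapply(feats$edge, function(e) e * c)
  feats
}

# Small, easy synthetic study set shared by several tests.
easy_dataset <- function(n, seed, size = 32L, offset = 5,
                         n_hairs = c(0L, 0L)) {
  generate_dataset(n, seed = seed, height = size, width = size,
                   noise_sd = 0.02, offset_range = c(-offset, offset),
                   n_hairs_range = n_hairs)
}

flip_rows_field <- function(v, h, w) {
  M <- matrix(v, h, w, byrow = TRUE)
  as.vector(t(M[h:1, , drop = FALSE]))
}
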