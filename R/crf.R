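# Grid-structured conditional random field: P(y | x; w) propto exp(-E),
# E(y, x; w) = sum_k w_k Phi_k(y, x) over node and edge feature functions.
# Edge features cost only across differing labels and carry positive
# weights, so binary MAP inference is an exact s-t min-cut.

#' 4-connected grid graph
#'
#' Nodes are pixels in row-major order; edges join horizontal and vertical
#' neighbors. Edge order is stable: all right-neighbor edges (row by row),
#' then all down-neighbor edges.
#'
#' @param height,width grid dimensions (>= 1).
#' @return object of class `grid_graph` with fields `height`, `width`,
#'   `n_nodes` and `edges` (n_edges x 2 matrix, `edges[e,1] < edges[e,2]`).
#' @export
build_grid <- function(height, width) {
  if (height < 1L || width < 1L) stopf("grid dimensions must be >= 1")
  height <- as.integer(height); width <- as.integer(width)
  idx <- function(r, c) (r - 1L) * width + c
  h_from <- h_to <- integer(0)
  if (width > 1L) {
    r <- rep(seq_len(height), each = width - 1L)
    c <- rep(seq_len(width - 1L), times = height)
    h_from <- idx(r, c); h_to <- idx(r, c + 1L)
  }
  v_from <- v_to <- integer(0)
  if (height > 1L) {
    r <- rep(seq_len(height - 1L), each = width)
    c <- rep(seq_len(width), times = height - 1L)
    v_from <- idx(r, c); v_to <- idx(r + 1L, c)
  }
  structure(list(height = height, width = width,
                 n_nodes = height * width,
                 edges = cbind(from = c(h_from, v_from),
                               to = c(h_to, v_to)),
                 # memo for the s-t flow topology (capacities vary per
                 # call, the structure never does)
                 cache = new.env(parent = emptyenv())),
            class = "grid_graph")
}

# igraph flow network for a grid: nodes 1..n, source n+1, sink n+2, with
# arcs s->i, i->t and both directions of every grid edge, in that order.
# Built once per grid_graph and memoized.
#' @noRd
flow_graph <- function(graph) {
  fg <- graph$cache$flow_graph
  if (!is.null(fg)) return(fg)
  n <- graph$n_nodes
  s <- n + 1L; t <- n + 2L
  el <- rbind(cbind(s, seq_len(n)),
              cbind(seq_len(n), t),
              graph$edges,
              graph$edges[, 2:1, drop = FALSE])
  fg <- igraph::graph_from_edgelist(el, directed = TRUE)
  graph$cache$flow_graph <- fg
  fg
}

#' CRF feature functions from a per-pixel likelihood map
#'
#' Builds the two-feature CRF used for lesion segmentation: the node
#' feature is the complement `1 - L_{i,j}` of the normalized per-pixel
#' likelihood (a cost, so that minimizing the energy favors likely labels
#' and weights `[1, 0]` reproduce the per-pixel model exactly), and the
#' edge feature is the absolute L* difference across each 4-neighbor pair,
#' incurred only when the endpoint labels differ. L* differences are
#' invariant to the global mean, so normalized and raw L* give the same
#' edge costs.
#'
#' @param lmap a `likelihood_map`.
#' @param lab_img the corresponding [raster_image] in CIELab.
#' @param graph optional [build_grid()] result (rebuilt if `NULL`).
#' @return object of class `crf_features`: `node` (list of N_P x N_L cost
#'   matrices, one per node feature), `edge` (list of per-edge nonnegative
#'   cost vectors), `graph`, `labelset`.
#' @export
crf_features_from_pp <- function(lmap, lab_img, graph = NULL) {
  stopifnot(inherits(lmap, "likelihood_map"))
  if (is.null(graph)) graph <- build_grid(lmap$height, lmap$width)
  if (graph$height != lmap$height || graph$width != lmap$width)
    stopf("graph (%dx%d) does not match likelihood map (%dx%d)",
          graph$height, graph$width, lmap$height, lmap$width)
  d <- dim(lab_img$pixels)
  if (lab_img$color_space != "CIELab")
    stopf("edge features need a CIELab image")
  if (d[1] != lmap$height || d[2] != lmap$width)
    stopf("image (%dx%d) does not match likelihood map (%dx%d)",
          d[1], d[2], lmap$height, lmap$width)
  lstar <- matrix_to_field(lab_img$pixels[, , 1])
  ec <- abs(lstar[graph$edges[, 1]] - lstar[graph$edges[, 2]])
  crf_features(node = list(1 - lmap$L_mat), edge = list(ec),
               graph = graph, labelset = lmap$labelset)
}

#' Assemble CRF features
#'
#' Lower-level constructor for arbitrary numbers of node and edge feature
#' functions. Node features are N_P x N_L cost matrices (entry (i, j) is
#' the contribution of assigning label j to pixel i); edge features are
#' per-edge nonnegative costs incurred iff the endpoint labels differ.
#'
#' @param node list of N_P x N_L matrices.
#' @param edge list of length-n_edges nonnegative vectors.
#' @param graph a `grid_graph`.
#' @param labelset the [label_set].
#' @return a `crf_features` object.
#' @export
crf_features <- function(node, edge, graph, labelset = label_set()) {
  stopifnot(inherits(graph, "grid_graph"))
  if (length(node) == 0L) stopf("at least one node feature is required")
  for (N in node) {
    if (nrow(N) != graph$n_nodes || ncol(N) != length(labelset$labels))
      stopf("node feature must be %d x %d", graph$n_nodes,
            length(labelset$labels))
    if (!all(is.finite(N))) stopf("node potentials must be finite")
  }
  for (e in edge) {
    if (length(e) != nrow(graph$edges))
      stopf("edge feature must have %d entries", nrow(graph$edges))
    if (!all(is.finite(e)) || any(e < 0))
      stopf("edge costs must be finite and nonnegative")
  }
  structure(list(node = node, edge = edge, graph = graph,
                 labelset = labelset,
                 n_features = length(node) + length(edge)),
            class = "crf_features")
}

#' CRF weight vector
#'
#' Weights for the node features followed by the edge features. Edge
#' weights must be nonnegative: together with nonnegative edge costs
#' incurred only across differing labels this keeps the binary energy
#' submodular, so min-cut inference is exact. (Training additionally
#' keeps edge weights strictly positive via a floor; weight 0 is allowed
#' here so that `[1, 0]` — the per-pixel model as a CRF — is expressible.)
#'
#' @param w numeric vector, node-feature weights then edge-feature weights.
#' @param n_node number of node features (the rest weight edge features).
#' @return object of class `crf_weights` with fields `w`, `node_indices`,
#'   `edge_indices`.
#' @export
crf_weights <- function(w = c(1, 0.1), n_node = 1L) {
  w <- as.numeric(w)
  if (any(!is.finite(w))) stopf("weights must be finite")
  if (n_node < 1L || n_node > length(w)) stopf("invalid n_node")
  edge_idx <- if (n_node < length(w)) (n_node + 1L):length(w) else integer(0)
  if (any(w[edge_idx] < 0))
    stopf("edge-feature weights must not be negative")
  structure(list(w = w, node_indices = seq_len(n_node),
                 edge_indices = edge_idx),
            class = "crf_weights")
}

# Feature-function values Phi_k(y) for one labeling: length-N_W vector.
#' @noRd
phi_vector <- function(y, feats) {
  stopifnot(inherits(feats, "crf_features"))
  lab <- if (inherits(y, "label_field")) y$labels else as.integer(y)
  j <- match(lab, feats$labelset$labels)
  if (anyNA(j)) stopf("labeling contains labels outside the label set")
  pick <- cbind(seq_along(j), j)
  node_vals <- vapply(feats$node, function(N) sum(N[pick]), numeric(1))
  if (length(feats$edge)) {
    mism <- lab[feats$graph$edges[, 1]] != lab[feats$graph$edges[, 2]]
    edge_vals <- vapply(feats$edge, function(e) sum(e[mism]), numeric(1))
  } else edge_vals <- numeric(0)
  c(node_vals, edge_vals)
}

#' CRF energy of a labeling
#'
#' `E(y, x; w) = sum_k w_k Phi_k(y, x)`: the weighted node costs of the
#' assigned labels plus the weighted edge costs across label
#' discontinuities. Lower energy means a more probable labeling.
#'
#' @param y a [label_field] (or plain label vector).
#' @param feats a `crf_features`.
#' @param w a `crf_weights` (or plain numeric vector).
#' @return scalar energy.
#' @export
crf_energy <- function(y, feats, w) {
  wv <- if (inherits(w, "crf_weights")) w$w else as.numeric(w)
  if (length(wv) != feats$n_features)
    stopf("weight vector has %d entries; features expect %d",
          length(wv), feats$n_features)
  sum(wv * phi_vector(y, feats))
}

# Aggregate weighted node costs (N_P x N_L) and edge costs (per edge).
#' @noRd
aggregate_potentials <- function(feats, w) {
  wv <- if (inherits(w, "crf_weights")) w$w else as.numeric(w)
  n_node <- length(feats$node)
  node <- matrix(0, nrow(feats$node[[1]]), ncol(feats$node[[1]]))
  for (k in seq_len(n_node)) node <- node + wv[k] * feats$node[[k]]
  edge <- numeric(nrow(feats$graph$edges))
  for (k in seq_along(feats$edge))
    edge <- edge + wv[n_node + k] * feats$edge[[k]]
  list(node = node, edge = edge)
}

#' Exact MAP inference by s-t min-cut
#'
#' Finds a global minimizer of the CRF energy for a binary label set.
#' Each pixel becomes a graph node between a source (first label) and a
#' sink (second label); weighted edge costs become undirected capacities
#' between neighbors. Because edge costs are nonnegative, incurred only
#' across differing labels, and carry positive weights, the energy is
#' submodular and the minimum cut is a global optimum. When several
#' labelings share the minimum energy any one of them may be returned.
#'
#' @param feats a `crf_features` over a binary label set.
#' @param w a `crf_weights`.
#' @param graph optional override of `feats$graph`.
#' @return a [label_field] minimizing the energy.
#' @export
map_inference <- function(feats, w, graph = feats$graph) {
  stopifnot(inherits(feats, "crf_features"))
  labs <- feats$labelset$labels
  if (length(labs) != 2L)
    stopf("map_inference supports binary label sets only (N_L = 2)")
  if (!inherits(w, "crf_weights")) w <- crf_weights(w)
  if (length(w$w) != feats$n_features)
    stopf("weight vector has %d entries; features expect %d",
          length(w$w), feats$n_features)
  pot <- aggregate_potentials(feats, w)
  n <- graph$n_nodes
  a <- pot$node[, 1]                       # cost of assigning label 1
  b <- pot$node[, 2]                       # cost of assigning label 2
  # shift per-node costs to be nonnegative; constant offsets do not move
  # the argmin
  m <- pmin(a, b)
  a <- a - m; b <- b - m
  s <- n + 1L; t <- n + 2L
  g <- flow_graph(graph)
  # s->i cut when i takes label 2; i->t cut when i takes label 1
  caps <- c(b, a, pot$edge, pot$edge)
  mf <- igraph::max_flow(g, source = s, target = t, capacity = caps)
  src_side <- as.integer(mf$partition1)
  y <- rep(labs[2], n)
  y[src_side[src_side <= n]] <- labs[1]
  label_field(y, graph$height, graph$width, feats$labelset)
}

# Enumerate all labelings of n pixels over n_l labels in lexicographic
# order (pixel 1 most significant): N^n x n integer matrix of label
# *indices* (1-based).
#' @noRd
enumerate_labelings <- function(n, n_l) {
  total <- n_l^n
  if (total > 2^21) stopf("refusing to enumerate %g labelings", total)
  k <- seq_len(total) - 1L
  Y <- matrix(0L, total, n)
  for (p in seq_len(n)) {
    Y[, p] <- (k %/% n_l^(n - p)) %% n_l + 1L
  }
  Y
}

# Energies of every enumerated labeling (vector aligned with
# enumerate_labelings rows), plus optionally the Phi matrix.
#' @noRd
all_energies <- function(feats, w, with_phi = FALSE) {
  wv <- if (inherits(w, "crf_weights")) w$w else as.numeric(w)
  graph <- feats$graph
  n <- graph$n_nodes
  n_l <- length(feats$labelset$labels)
  Y <- enumerate_labelings(n, n_l)
  n_node <- length(feats$node)
  Phi <- matrix(0, nrow(Y), feats$n_features)
  for (k in seq_len(n_node)) {
    N <- feats$node[[k]]
    acc <- numeric(nrow(Y))
    for (j in seq_len(n_l)) acc <- acc + (Y == j) %*% N[, j]
    Phi[, k] <- acc
  }
  if (length(feats$edge)) {
    M <- Y[, graph$edges[, 1], drop = FALSE] !=
         Y[, graph$edges[, 2], drop = FALSE]
    for (k in seq_along(feats$edge))
      Phi[, n_node + k] <- M %*% feats$edge[[k]]
  }
  E <- as.vector(Phi %*% wv)
  if (with_phi) list(E = E, Phi = Phi, Y = Y) else list(E = E, Y = Y)
}

#' MAP inference by exhaustive enumeration
#'
#' Independent oracle for [map_inference()]: evaluates the energy of every
#' labeling. Ties break toward the lexicographically smallest labeling
#' (pixel 1 most significant, labels in label-set order). Only feasible on
#' tiny grids.
#'
#' @inheritParams map_inference
#' @return a [label_field].
#' @export
brute_force_inference <- function(feats, w, graph = feats$graph) {
  if (graph$n_nodes > 20L)
    stopf("brute force limited to N_P <= 20 (got %d)", graph$n_nodes)
  ae <- all_energies(feats, w)
  best <- which.min(ae$E)                  # first minimum = lexicographic
  y <- feats$labelset$labels[ae$Y[best, ]]
  label_field(y, graph$height, graph$width, feats$labelset)
}

#' Exact partition function on a tiny grid
#'
#' `Z(x, w) = sum_y exp(-E(y, x; w))`, computed by exhaustive enumeration
#' in log space. Only feasible for `N_P <= 20`.
#'
#' @inheritParams map_inference
#' @param log return `log Z` instead of `Z`.
#' @return scalar `Z` (or `log Z`).
#' @export
partition_function <- function(feats, w, graph = feats$graph, log = FALSE) {
  if (graph$n_nodes > 20L)
    stopf("exact partition function limited to N_P <= 20 (got %d)",
          graph$n_nodes)
  lz <- logsumexp(-all_energies(feats, w)$E)
  if (log) lz else exp(lz)
}

#' Exact probability of a labeling on a tiny grid
#'
#' `P(y | x; w) = exp(-E(y, x; w)) / Z(x, w)` by enumeration.
#'
#' @inheritParams map_inference
#' @param y a [label_field] or label vector.
#' @return probability in (0, 1\].
#' @export
label_probability <- function(y, feats, w, graph = feats$graph) {
  lz <- partition_function(feats, w, graph, log = TRUE)
  exp(-crf_energy(y, feats, w) - lz)
}
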