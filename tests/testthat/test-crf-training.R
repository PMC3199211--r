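# Regularized log-likelihood, exact and saddle-point gradients, and
# projected gradient-ascent weight learning.

test_that("the regularized log-likelihood has its closed form on a single
           pixel and the penalty scales quadratically", {
  g1 <- build_grid(1, 1)
  a <- 0.8; b <- 0.3
  f1 <- crf_features(node = list(matrix(c(a, b), 1, 2)),
                     edge = list(numeric(0)), g1)
  y <- label_field(0L, 1, 1)
  w <- c(1.2, 0.4); s2 <- 3
  want <- -(1.2 * a) - log(exp(-1.2 * a) + exp(-1.2 * b)) -
    sum(w^2) / (2 * s2)
  inst <- list(list(features = f1, truth = y))
  expect_equal(regularized_log_likelihood(w, inst, s2), want,
               tolerance = 1e-12)
  # sigma2 = Inf drops the penalty
  expect_equal(regularized_log_likelihood(w, inst, Inf),
               want + sum(w^2) / (2 * s2), tolerance = 1e-12)
  # scaling w by c > 1 grows the penalty by (c^2 - 1)||w||^2 / (2 sigma2)
  l1 <- regularized_log_likelihood(w, inst, s2)
  l2 <- regularized_log_likelihood(2 * w, inst, s2)
  pen1 <- regularized_log_likelihood(w, inst, Inf) - l1
  pen2 <- regularized_log_likelihood(2 * w, inst, Inf) - l2
  expect_equal(pen2 - pen1, (4 - 1) * sum(w^2) / (2 * s2),
               tolerance = 1e-12)
  expect_error(regularized_log_likelihood(w, inst, -1), "sigma2")
})

test_that("the exact gradient matches central finite differences", {
  set.seed(201)
  h <- 1e-5
  for (trial in 1:25) {
    ri <- random_crf_instance(sample(2:3, 1), sample(2:3, 1))
    y <- sample_crf_labeling(ri$features, ri$weights$w)
    inst <- list(list(features = ri$features, truth = y))
    wv <- c(runif(1, 0.2, 2), runif(1, 0.05, 1.5))
    s2 <- sample(c(2, 10, Inf), 1)
    gr <- exact_gradient(wv, inst, s2)
    fd <- vapply(1:2, function(k) {
      e <- c(0, 0); e[k] <- h
      (regularized_log_likelihood(wv + e, inst, s2, method = "exact") -
       regularized_log_likelihood(wv - e, inst, s2, method = "exact")) /
        (2 * h)
    }, numeric(1))
    expect_equal(gr, fd, tolerance = 1e-6)
  }
})

test_that("at w = 0 the model expectation is the uniform average of the
           feature functions", {
  set.seed(202)
  ri <- random_crf_instance(2, 2)
  y <- label_field(c(0L, 0L, 1L, 1L), 2, 2)
  inst <- list(list(features = ri$features, truth = y))
  gr <- exact_gradient(c(0, 0), inst, Inf)
  ae <- lesioncrf:::all_energies(ri$features, c(0, 0), with_phi = TRUE)
  unif_mean <- colMeans(ae$Phi)
  phi_gt <- lesioncrf:::phi_vector(y, ri$features)
  expect_equal(gr, unif_mean - phi_gt, tolerance = 1e-12)
})

test_that("regularization pulls the stationary point toward the origin", {
  set.seed(203)
  ri <- random_crf_instance(2, 2)
  y <- sample_crf_labeling(ri$features, c(1, 0.5))
  inst <- list(list(features = ri$features, truth = y))
  w <- c(0.9, 0.7)
  g_unreg <- exact_gradient(w, inst, Inf)
  g_reg <- exact_gradient(w, inst, 4)
  expect_equal(g_reg, g_unreg - w / 4, tolerance = 1e-12)
})

test_that("the SPA gradient cancels the data term when the truth is the
           MAP labeling and approaches the exact gradient at low
           temperature", {
  set.seed(204)
  ri <- random_crf_instance(2, 3)
  ystar <- brute_force_inference(ri$features, ri$weights)
  inst <- list(list(features = ri$features, truth = ystar))
  expect_equal(spa_gradient(ri$weights, inst, Inf), c(0, 0),
               tolerance = 1e-12)
  s2 <- 5
  expect_equal(spa_gradient(ri$weights, inst, s2), -ri$weights$w / s2,
               tolerance = 1e-12)
  # low-temperature limit: scale potentials up, compare on instances whose
  # MAP labeling concentrates almost all probability mass
  set.seed(205)
  rel_errs <- c()
  for (trial in 1:40) {
    ri <- random_crf_instance(2, 2)
    for (scale in c(1, 10, 100)) {
      fs <- scale_crf_features(ri$features, scale)
      ystar <- brute_force_inference(fs, ri$weights)
      p_map <- label_probability(ystar, fs, ri$weights)
      if (p_map < 0.999) next
      # generic truth distinct from the MAP labeling (otherwise both
      # gradients vanish and the ratio is meaningless)
      y <- label_field(1L - ystar$labels, 2, 2)
      inst <- list(list(features = fs, truth = y))
      ge <- exact_gradient(ri$weights, inst, Inf)
      gs <- spa_gradient(ri$weights, inst, Inf)
      if (sqrt(sum(ge^2)) < 1e-8) next
      rel_errs <- c(rel_errs,
                    sqrt(sum((gs - ge)^2)) / sqrt(sum(ge^2)))
    }
  }
  expect_gt(length(rel_errs), 20)
  expect_lt(max(rel_errs), 0.05)
  # and the error shrinks as the scale grows on a fixed instance
  set.seed(206)
  ri <- random_crf_instance(2, 2)
  y <- label_field(1L - brute_force_inference(ri$features,
                                              ri$weights)$labels, 2, 2)
  errs <- vapply(c(2, 8, 32), function(scale) {
    fs <- scale_crf_features(ri$features, scale)
    ge <- exact_gradient(ri$weights, list(list(features = fs, truth = y)),
                         Inf)
    gs <- spa_gradient(ri$weights, list(list(features = fs, truth = y)),
                       Inf)
    sqrt(sum((gs - ge)^2)) / sqrt(sum(ge^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("gradient ascent with exact gradients monotonically improves the
           score and stops near a stationary point", {
  set.seed(207)
  insts <- lapply(1:8, function(i) {
    ri <- random_crf_instance(2, 2)
    list(features = ri$features,
         truth = sample_crf_labeling(ri$features, c(1, 0.5)))
  })
  cfg <- training_config(w0 = crf_weights(c(0.5, 0.5)), sigma2 = 5,
                         gamma = 0.05, epsilon = 1e-3, n_itr = 1500)
  tr <- train_weights(insts, cfg, gradient = "exact")
  expect_true(tr$converged)
  expect_true(all(diff(tr$score) > -1e-8))
  # best iterate really is the best recorded score
  expect_equal(tr$best_score, max(tr$score))
  expect_equal(regularized_log_likelihood(tr$best_w, insts, 5,
                                          method = "exact"),
               tr$best_score, tolerance = 1e-12)
  # recorded edge weights all satisfy the positivity constraint
  expect_true(all(tr$w[, 2] > 0))
})

test_that("training does not move when the truths are already MAP under w0
           and the gradient vanishes", {
  set.seed(208)
  insts <- lapply(1:4, function(i) {
    ri <- random_crf_instance(2, 2)
    fs <- scale_crf_features(ri$features, 50)  # sharply peaked
    list(features = fs, truth = map_inference(fs, crf_weights(c(1, 0.3))))
  })
  cfg <- training_config(w0 = crf_weights(c(1, 0.3)), sigma2 = Inf,
                         gamma = 0.01, epsilon = 1e-4, n_itr = 50)
  tr <- train_weights(insts, cfg, gradient = "spa")
  expect_true(tr$converged)
  expect_equal(tr$n_iterations, 1L)
  expect_equal(tr$w[1, ], c(1, 0.3), tolerance = 1e-9)
})

test_that("edge weights pushed negative are clipped to the positive
           floor", {
  # a ground truth with *more* boundary than the MAP drives the edge
  # weight down; the projection must keep it at the floor
  set.seed(209)
  g <- build_grid(2, 2)
  N <- matrix(c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5), 4, 2)
  feats <- crf_features(node = list(N), edge = list(rep(1, 4)), g)
  checker <- label_field(c(0L, 1L, 1L, 0L), 2, 2)
  cfg <- training_config(w0 = crf_weights(c(1, 0.05)), sigma2 = Inf,
                         gamma = 0.5, epsilon = 1e-8, n_itr = 25)
  tr <- train_weights(list(list(features = feats, truth = checker)), cfg,
                      gradient = "exact")
  expect_true(all(tr$w[, 2] >= cfg$edge_floor))
  expect_equal(min(tr$w[, 2]), cfg$edge_floor, tolerance = 1e-12)
})

test_that("training recovers the direction of known generating weights", {
  set.seed(210)
  w_true <- c(1, 0.6)
  # informative instances: costs at segmentation-feature magnitudes
  insts <- lapply(1:50, function(i) {
    g <- build_grid(3, 3)
    feats <- crf_features(node = list(matrix(6 * runif(18), 9, 2)),
                          edge = list(6 * runif(nrow(g$edges))), g)
    list(features = feats, truth = sample_crf_labeling(feats, w_true))
  })
  cfg <- training_config(w0 = crf_weights(c(1, 0.1)), sigma2 = Inf,
                         gamma = 0.01, epsilon = 1e-4, n_itr = 600)
  tr <- train_weights(insts, cfg, gradient = "exact")
  u <- tr$best_w$w / sqrt(sum(tr$best_w$w^2))
  v <- w_true / sqrt(sum(w_true^2))
  expect_lt(sqrt(sum((u - v)^2)), 0.1)
})

test_that("training traces export as data frames capped at n_itr", {
  set.seed(211)
  ri <- random_crf_instance(2, 2)
  insts <- list(list(features = ri$features,
                     truth = sample_crf_labeling(ri$features, c(1, 0.5))))
  cfg <- training_config(n_itr = 7, gamma = 0.05, epsilon = 1e-12)
  tr <- train_weights(insts, cfg, gradient = "exact")
  df <- trace_as_data_frame(tr)
  expect_lte(nrow(df), 7)
  expect_named(df, c("iteration", "w1", "w2", "grad1", "grad2", "score"))
})
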