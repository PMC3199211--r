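# LDA projection, Gaussian class-conditionals, prior, likelihood maps and
# independent MAP labeling.

two_class_stack <- function(n_per, d, shift, seed, sd = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d, 0, sd), n_per, d),
             matrix(rnorm(n_per * d, 0, sd), n_per, d))
  X[(n_per + 1):(2 * n_per), 1] <- X[(n_per + 1):(2 * n_per), 1] + shift
  y <- rep(c(0L, 1L), each = n_per)
  list(stack = make_stack(X, 2 * n_per, 1),
       truth = label_field(y, 2 * n_per, 1))
}

test_that("LDA finds the separating axis for axis-aligned classes", {
  d <- two_class_stack(n_per = 120, d = 2, shift = 6, seed = 1)
  proj <- fit_lda(list(d$stack), list(d$truth))
  expect_equal(dim(proj$Q), c(2L, 1L))
  q <- proj$Q[, 1] / sqrt(sum(proj$Q[, 1]^2))
  expect_gt(abs(q[1]), 0.99)   # parallel to axis 1, within sign
})

test_that("LDA projection beats random directions on the Fisher criterion
           and agrees with an independent LDA implementation", {
  set.seed(42)
  n <- 90
  mus <- rbind(c(0, 0, 0, 0, 0), c(3, 1, 0, 0, 0), c(0, 4, 1, 0, 0))
  X <- do.call(rbind, lapply(1:3, function(j)
    sweep(matrix(rnorm(n * 5), n, 5), 2, mus[j, ], `+`)))
  y <- rep(0:2, each = n)
  stack <- make_stack(X, 3 * n, 1)
  truth <- label_field(y, 3 * n, 1, label_set(0:2))
  proj <- fit_lda(list(stack), list(truth), label_set(0:2))
  expect_equal(dim(proj$Q), c(5L, 2L))
  # Fisher criterion oracle: brute-force random unit directions
  Sw <- matrix(0, 5, 5); Sb <- matrix(0, 5, 5); mu <- colMeans(X)
  for (j in 0:2) {
    Xl <- X[y == j, ]; mul <- colMeans(Xl)
    Sw <- Sw + crossprod(sweep(Xl, 2, mul)) / nrow(Xl)
    Sb <- Sb + tcrossprod(mul - mu)
  }
  fisher <- function(v) as.numeric((v %*% Sb %*% v) / (v %*% Sw %*% v))
  rand_best <- max(vapply(1:200, function(i) {
    v <- rnorm(5); fisher(v / sqrt(sum(v^2)))
  }, numeric(1)))
  expect_gte(fisher(proj$Q[, 1] / sqrt(sum(proj$Q[, 1]^2))), rand_best)
  # binary restriction cross-checked against MASS::lda's discriminant
  skip_if_not_installed("MASS")
  bstack <- make_stack(X[y < 2, ], 2 * n, 1)
  btruth <- label_field(y[y < 2], 2 * n, 1)
  bq <- fit_lda(list(bstack), list(btruth))$Q[, 1]
  mq <- MASS::lda(X[y < 2, ], grouping = y[y < 2])$scaling[, 1]
  cosine <- abs(sum(bq * mq)) / sqrt(sum(bq^2) * sum(mq^2))
  expect_gt(cosine, 1 - 1e-6)
})

test_that("LDA errors on absent labels and N_L = 2, N_C = 30 gives a
           30 x 1 projection", {
  ds <- easy_dataset(3, seed = 2, size = 24)
  stacks <- lapply(ds, function(s) compute_features(s$image))
  truths <- lapply(ds, function(s) s$mask)
  proj <- fit_lda(stacks, truths)
  expect_equal(dim(proj$Q), c(30L, 1L))
  all0 <- label_field(rep(0L, 24 * 24), 24, 24)
  expect_error(fit_lda(stacks[1], list(all0)), "absent")
})

test_that("class-conditional estimates recover known Gaussian parameters", {
  set.seed(9)
  n <- 1e5
  mu <- c(2, -1); S <- matrix(c(1.5, 0.4, 0.4, 0.8), 2)
  R <- chol(S)
  X0 <- matrix(rnorm(n * 2), n, 2) %*% R
  X1 <- sweep(matrix(rnorm(n * 2), n, 2) %*% R, 2, mu, `+`)
  stack <- rbind(X0, X1)
  truth <- label_field(rep(c(0L, 1L), each = n), 2 * n, 1)
  cc <- fit_class_conditionals(list(stack), list(truth))
  se_mean <- sqrt(diag(S) / n)
  expect_lt(max(abs(cc$params[["1"]]$mean - mu) / se_mean), 3)
  expect_equal(cc$params[["1"]]$cov, S, tolerance = 0.05)
  expect_lt(max(abs(cc$params[["0"]]$mean) / se_mean), 3)
})

test_that("degenerate and duplicated class-conditional inputs behave", {
  X <- matrix(c(rep(1.5, 6), rep(4.2, 6)), ncol = 1)
  truth <- label_field(rep(c(0L, 1L), each = 6), 12, 1)
  expect_warning(cc <- fit_class_conditionals(list(X), list(truth)),
                 "near-singular")
  expect_equal(cc$params[["0"]]$mean, 1.5, ignore_attr = TRUE)
  expect_gt(cc$params[["0"]]$cov[1, 1], 0)  # regularization floor
  # duplicating an image leaves pooled ML estimates unchanged
  set.seed(4)
  Xr <- matrix(rnorm(40), ncol = 1)
  tr <- label_field(rep(c(0L, 1L), 20), 40, 1)
  c1 <- fit_class_conditionals(list(Xr), list(tr))
  c2 <- fit_class_conditionals(list(Xr, Xr), list(tr, tr))
  expect_equal(c1$params, c2$params, tolerance = 1e-12)
  expect_error(fit_class_conditionals(list(matrix(1, 1, 1)),
                                      list(label_field(c(0L), 1, 1))),
               "at least 2")
})

test_that("the prior is the pooled pixel fraction", {
  t1 <- label_field(rep(c(0L, 1L), c(40, 60)), 10, 10)
  p <- fit_prior(list(t1))
  expect_equal(unname(p$p), c(0.4, 0.6))
  # pooling across images of different sizes matches an independent tally
  t2 <- label_field(rep(c(0L, 1L), c(3, 1)), 2, 2)
  t3 <- label_field(rep(1L, 9), 3, 3)
  pooled <- fit_prior(list(t1, t2, t3))
  total <- 100 + 4 + 9
  expect_equal(unname(pooled$p), c((40 + 3) / total, (60 + 1 + 9) / total))
  # uniform truth gives a uniform prior
  expect_equal(unname(fit_prior(list(label_field(rep(c(0L, 1L), 8),
                                                 4, 4)))$p),
               c(0.5, 0.5))
})

fitted_toy_model <- function(seed = 10, shift = 5) {
  d <- two_class_stack(n_per = 200, d = 3, shift = shift, seed = seed)
  proj <- fit_lda(list(d$stack), list(d$truth))
  xq <- project_features(d$stack, proj)
  cc <- fit_class_conditionals(list(xq), list(d$truth))
  prior <- fit_prior(list(d$truth))
  list(data = d, proj = proj, cc = cc, prior = prior)
}

test_that("likelihood maps are row-normalized probabilities with symmetric
           behavior between the class means", {
  m <- fitted_toy_model()
  lm <- likelihood_map(m$data$stack, m$proj, m$cc)
  expect_lt(max(abs(rowSums(lm$L_mat) - 1)), 1e-9)
  expect_true(all(lm$L_mat >= 0 & lm$L_mat <= 1))
  # a pixel exactly at a class mean favors that class
  at_mean <- make_stack(matrix(0, 1, 3), 1, 1)
  at_mean$values[1, ] <- 0  # class-0 raw mean is the origin
  lm0 <- likelihood_map(at_mean, m$proj, m$cc)
  expect_gt(lm0$L_mat[1, 1], 0.5)
  # equal-covariance symmetric midpoint: force equal covariances
  cc_eq <- m$cc
  pooled_cov <- (m$cc$params[["0"]]$cov + m$cc$params[["1"]]$cov) / 2
  cc_eq$params[["0"]]$cov <- pooled_cov
  cc_eq$params[["1"]]$cov <- pooled_cov
  mid <- (m$cc$params[["0"]]$mean + m$cc$params[["1"]]$mean) / 2
  # build a raw observation projecting exactly to the midpoint
  q <- m$proj$Q[, 1]
  raw <- matrix(mid / sum(q^2) * q, 1, 3, byrow = TRUE)
  lmid <- likelihood_map(make_stack(raw, 1, 1), m$proj, cc_eq)
  expect_equal(as.vector(lmid$L_mat), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("MAP labeling follows the posterior product and the prior can
           dominate", {
  m <- fitted_toy_model()
  # uniform prior equals the likelihood-map argmax
  up <- m$prior; up$p[] <- 0.5
  lm <- likelihood_map(m$data$stack, m$proj, m$cc)
  map_u <- map_label(m$data$stack, m$proj, m$cc, up)
  expect_identical(map_u$labels,
                   c(0L, 1L)[max.col(lm$L_mat, ties.method = "first")])
  # a degenerate prior annihilates the other label
  p0 <- m$prior; p0$p <- c(`0` = 1, `1` = 0)
  expect_true(all(map_label(m$data$stack, m$proj, m$cc, p0)$labels == 0L))
  # tiny image: labels match exhaustive evaluation of density * prior
  small <- make_stack(m$data$stack$values[c(1, 2, 201, 202), ], 2, 2)
  got <- map_label(small, m$proj, m$cc, m$prior)$labels
  xq <- project_features(small, m$proj)
  want <- apply(xq, 1, function(z) {
    post <- vapply(c("0", "1"), function(l) {
      par <- m$cc$params[[l]]
      stats::dnorm(z, par$mean, sqrt(par$cov[1, 1])) * m$prior$p[[l]]
    }, numeric(1))
    c(0L, 1L)[which.max(post)]
  })
  expect_identical(got, unname(want))
})

test_that("thresholding is monotone, respects bounds and reduces to MAP at
           0.5", {
  m <- fitted_toy_model()
  lm <- likelihood_map(m$data$stack, m$proj, m$cc)
  expect_error(threshold_labeling(lm, threshold = 1.2), "\\[0, 1\\]")
  expect_true(all(threshold_labeling(lm, threshold = 0)$labels == 1L))
  at1 <- threshold_labeling(lm, threshold = 1)
  expect_identical(at1$labels == 1L, lm$L_mat[, 2] >= 1)
  counts <- vapply(seq(0, 1, by = 0.05), function(T)
    sum(threshold_labeling(lm, threshold = T)$labels == 1L), numeric(1))
  expect_true(all(diff(counts) <= 0))
  up <- m$prior; up$p[] <- 0.5
  expect_identical(threshold_labeling(lm, threshold = 0.5)$labels,
                   map_label(m$data$stack, m$proj, m$cc, up)$labels)
})

test_that("well-separated synthetic classes are labeled at > 95% accuracy", {
  m <- fitted_toy_model(seed = 20, shift = 8)
  pred <- map_label(m$data$stack, m$proj, m$cc, m$prior)
  acc <- mean(pred$labels == m$data$truth$labels)
  expect_gt(acc, 0.95)
})

test_that("LDA output is invariant (up to sign) to channel reordering", {
  d <- two_class_stack(n_per = 80, d = 4, shift = 5, seed = 30)
  q1 <- fit_lda(list(d$stack), list(d$truth))$Q[, 1]
  perm <- c(3, 1, 4, 2)
  s2 <- make_stack(d$stack$values[, perm], d$stack$height, d$stack$width)
  q2 <- fit_lda(list(s2), list(d$truth))$Q[, 1]
  cosine <- abs(sum(q1[perm] * q2)) / sqrt(sum(q1^2) * sum(q2^2))
  expect_gt(cosine, 1 - 1e-9)
})
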