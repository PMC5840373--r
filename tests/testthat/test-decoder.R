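test_that("GCV ridge handles degenerate and limiting cases", {
  set.seed(1)
  X <- matrix(rnorm(30 * 4), 30, 4)

  # constant response: zero coefficients, intercept = the constant
  fit <- fit_ridge_gcv(X, rep(3.5, 30))
  expect_equal(fit$b, rep(0, 4))
  expect_equal(fit$b0, 3.5)

  # enormous penalty: coefficients vanish, predictions collapse to mean
  z <- rnorm(30)
  fit2 <- fit_ridge_gcv(X, z, lambda_grid = 1e12)
  expect_lt(sqrt(sum(fit2$b^2)), 1e-6)
  pred <- drop(X %*% fit2$b) + fit2$b0
  expect_equal(pred, rep(mean(z), 30), tolerance = 1e-4)

  expect_error(fit_ridge_gcv(X[1:2, ], z[1:2]), "at least 3")
  expect_error(fit_ridge_gcv(X, z, lambda_grid = numeric(0)), "non-empty")
  expect_error(fit_ridge_gcv(X, z, lambda_grid = c(1, -1)), "positive")
})

test_that("SVD-path GCV equals the brute-force hat-matrix criterion", {
  for (s in 1:5) {
    set.seed(100 + s)
    X <- matrix(rnorm(12 * 4), 12, 4)
    z <- rnorm(12)
    fit <- fit_ridge_gcv(X, z)
    xc <- scale(X, scale = FALSE)
    zc <- z - mean(z)
    n <- nrow(X)
    brute <- vapply(fit$gcv$lambda, function(lam) {
      H <- xc %*% solve(crossprod(xc) + lam * diag(ncol(X))) %*% t(xc)
      sum(((diag(n) - H) %*% zc)^2) / (n * (1 - sum(diag(H)) / n)^2)
    }, numeric(1))
    expect_equal(fit$gcv$score, brute, tolerance = 1e-10)
    expect_equal(fit$lambda, fit$gcv$lambda[which.min(brute)])
  }
})

test_that("training residuals are non-increasing as lambda decreases", {
  set.seed(2)
  X <- matrix(rnorm(40 * 6), 40, 6)
  z <- drop(X %*% rnorm(6)) + rnorm(40, sd = 0.5)
  grid <- sort(default_lambda_grid(), decreasing = TRUE)
  rss <- vapply(grid, function(lam) {
    fit <- fit_ridge_gcv(X, z, lambda_grid = lam)
    sum((z - drop(X %*% fit$b) - fit$b0)^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("the decoder recovers a planted one-dimensional signal", {
  set.seed(3)
  nv <- prod(c(4, 4, 3))
  geom <- volume_geometry(c(4, 4, 3), 1:nv)
  x <- matrix(rnorm(60 * nv), 60, nv)
  z <- matrix(x[, 10], ncol = 1)  # dimension 1 equals voxel 10 exactly
  em <- example_matrix(x, sprintf("s%02d", 1:60), geom)
  model <- semantic_decoder(em, z)
  dec <- predict(model, em)
  expect_gt(cor(dec[, 1], z[, 1]), 0.99)
})

test_that("decoding the training mean image returns the dimension means", {
  set.seed(4)
  nv <- prod(c(4, 3, 3))
  geom <- volume_geometry(c(4, 3, 3), 1:nv)
  x <- matrix(rnorm(30 * nv), 30, nv)
  z <- matrix(rnorm(30 * 5), 30, 5)
  em <- example_matrix(x, sprintf("s%02d", 1:30), geom)
  model <- semantic_decoder(em, z)
  dec <- predict(model, matrix(colMeans(x), 1))
  expect_equal(drop(dec), colMeans(z), tolerance = 1e-10)
})

test_that("duplicated examples leave training-row predictions unchanged", {
  set.seed(5)
  n <- 40; p <- 15; d <- 4
  A <- matrix(rnorm(p * d), p, d)
  z <- matrix(rnorm(n * d), n, d)
  x <- z %*% t(A)  # noiseless, exactly linear
  m1 <- semantic_decoder(x, z)
  m2 <- semantic_decoder(rbind(x, x), rbind(z, z))
  p1 <- predict(m1, x)
  p2 <- predict(m2, x)
  # duplication changes the GCV effective n, hence the selected penalty can
  # differ slightly; on a noiseless linear system the fits still coincide
  expect_equal(p1, p2, tolerance = 1e-4)
})

test_that("degenerate semantic dimensions decode to their mean", {
  set.seed(6)
  x <- matrix(rnorm(20 * 8), 20, 8)
  z <- cbind(rnorm(20), rep(2, 20))
  expect_message(model <- semantic_decoder(x, z), "constant in training")
  dec <- predict(model, matrix(rnorm(5 * 8), 5, 8))
  expect_equal(dec[, 2], rep(2, 5))
  expect_true(all(model$lambdas > 0))
})

test_that("decoder models serialize bit-exactly", {
  set.seed(7)
  nv <- prod(c(4, 4, 3))
  geom <- volume_geometry(c(4, 4, 3), 1:nv)
  em <- example_matrix(matrix(rnorm(25 * nv), 25, nv),
                       sprintf("s%02d", 1:25), geom)
  z <- matrix(rnorm(25 * 6), 25, 6)
  model <- semantic_decoder(em, z, voxels = 1:20)
  path <- tempfile(fileext = ".rds")
  write_decoder(model, path)
  back <- read_decoder(path)
  xnew <- matrix(rnorm(4 * nv), 4, nv)
  expect_identical(predict(model, xnew), predict(back, xnew))
  expect_identical(coef(model), coef(back))
  f <- tempfile()
  saveRDS(list(a = 1), f)
  expect_error(read_decoder(f), "not a decoder")
})

test_that("geometry fingerprints are enforced at decode time", {
  set.seed(8)
  nv <- prod(c(4, 3, 3))
  geom <- volume_geometry(c(4, 3, 3), 1:nv)
  em <- example_matrix(matrix(rnorm(20 * nv), 20, nv),
                       sprintf("s%02d", 1:20), geom)
  z <- matrix(rnorm(20 * 3), 20, 3)
  model <- semantic_decoder(em, z)
  other <- volume_geometry(c(3, 4, 3), 1:nv)
  em2 <- example_matrix(matrix(rnorm(2 * nv), 2, nv), c("a", "b"), other)
  expect_error(predict(model, em2), "geometry")
})

test_that("cross-validation partitions stimuli into leave-k-out folds", {
  cfg <- synthetic_config(n_words = 30, n_dims = 8, grid_shape = c(6, 5, 4),
                          n_informative = 15, noise_sd = 0.5,
                          n_clusters = 5, seed = 31)
  sim <- simulate_experiment(cfg, "words")
  cv <- crossval_decode(sim$examples, sim$Z, k = 10, n_select = 30,
                        inner_folds = 5)
  expect_equal(length(unique(cv$fold_assignment)), 3L)   # 30 stimuli / 10
  expect_equal(tabulate(cv$fold_assignment), rep(10L, 3L))
  expect_false(anyNA(cv$decoded))                        # every row decoded once
  expect_equal(rownames(cv$decoded), sim$examples$stimulus_ids)

  # the reference word design: 180 stimuli in folds of 10 gives 18 folds
  cfg2 <- synthetic_config(n_words = 180, n_dims = 5, grid_shape = c(4, 3, 3),
                           n_informative = 10, noise_sd = 1,
                           n_clusters = 5, seed = 32)
  sim2 <- simulate_experiment(cfg2, "words")
  cv2 <- crossval_decode(sim2$examples, sim2$Z, k = 10, n_select = 20,
                         inner_folds = 5)
  expect_equal(length(cv2$selections), 18L)
})

test_that("held-out correlation improves monotonically as noise falls", {
  noise_levels <- c(8, 2, 0.5)
  mean_cors <- sapply(noise_levels, function(ns) {
    mean(sapply(1:5, function(s) {
      cfg <- synthetic_config(n_words = 80, n_dims = 10,
                              grid_shape = c(8, 8, 5), n_informative = 30,
                              noise_sd = ns, n_clusters = 8, seed = 40 + s)
      sim <- simulate_experiment(cfg, "words")
      tr <- 1:60; te <- 61:80
      xtr <- example_matrix(sim$examples$values[tr, ],
                            sim$examples$stimulus_ids[tr],
                            sim$examples$geometry)
      model <- semantic_decoder(xtr, sim$Z[tr, ])
      dec <- predict(model, sim$examples$values[te, ])
      mean(sapply(seq_len(ncol(dec)), function(j) cor(dec[, j], sim$Z[te, j])))
    }))
  })
  expect_true(all(diff(mean_cors) > 0))
})
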