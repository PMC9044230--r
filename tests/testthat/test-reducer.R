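make_study_data <- function(n, seed, structure = "high", scenario = "s1") {
  x <- generate_dataset(structure, scenario, n = n, seed = seed)
  standardize_apply(standardize_fit(x), x)
}

test_that("PCA components are orthonormal and the full basis reconstructs exactly", {
  z <- make_study_data(300, 1)
  fit <- reducer(z, "pca", k = 3)
  V <- fit$fit$rotation
  expect_lt(max(abs(crossprod(V) - diag(3))), 1e-10)
  full <- reducer(z, "pca", k = 15)
  expect_lt(mse(z, reconstruct(full, z)), 1e-10)
  expect_error(reducer(z, "pca", k = 16), "'k' must be between")
  expect_error(reducer(z, "tied_ae", k = 15), "'k' must be between")
})

test_that("PCA reconstruction error matches the population eigen-spectrum residual", {
  # top-3 residual of the high matrix: 12 * 0.3 / 15 = 0.24
  z <- make_study_data(2e4, 2)
  fit <- reducer(z, "pca", k = 3)
  expect_equal(mse(z, reconstruct(fit, z)), 0.24, tolerance = 0.02)
})

test_that("encode and reconstruct respect the shape contract", {
  z <- make_study_data(100, 3)
  for (v in c("pca", "simple_ae")) {
    fit <- reducer(z, v, k = 3,
                   control = reducer_control(epochs = 5))
    h <- encode(fit, z)
    expect_equal(dim(h), c(100L, 3L))
    y <- reconstruct(fit, z)
    expect_equal(dim(y), dim(z))
    expect_error(encode(fit, z[, 1:7]), "7 columns")
  }
})

test_that("autoencoder fits are reproducible given a seed", {
  z <- make_study_data(150, 4)
  ctrl <- reducer_control(epochs = 20)
  for (v in c("simple_ae", "tied_ae", "deep_ae", "independent_ae")) {
    f1 <- reducer(z, v, k = 3, control = ctrl, seed = 11)
    f2 <- reducer(z, v, k = 3, control = ctrl, seed = 11)
    expect_identical(f1$fit$weights, f2$fit$weights)
    f3 <- reducer(z, v, k = 3, control = ctrl, seed = 12)
    expect_false(identical(f1$fit$weights, f3$fit$weights))
  }
})

test_that("the tied decoder weight is the encoder transpose throughout", {
  z <- make_study_data(200, 5)
  fit <- reducer(z, "tied_ae", k = 3,
                 control = reducer_control(epochs = 30), seed = 1)
  expect_identical(fit$fit$weights[[2]], t(fit$fit$weights[[1]]))
})

test_that("converged linear autoencoders respect the rank-3 PCA floor", {
  x <- generate_dataset("high", "s1", n = 1500, seed = 6)
  train <- x[1:1200, ]
  test <- x[1201:1500, ]
  sc <- standardize_fit(train)
  trz <- standardize_apply(sc, train)
  tez <- standardize_apply(sc, test)
  pca_mse <- mse(tez, reconstruct(reducer(trz, "pca", k = 3), tez))
  tied <- reducer(trz, "tied_ae", k = 3, seed = 2)
  tied_mse <- mse(tez, reconstruct(tied, tez))
  expect_gte(tied_mse, pca_mse - 0.02)
  expect_lte(tied_mse, pca_mse + 0.02)
})

test_that("the tied encoder recovers the top-3 principal subspace", {
  z <- make_study_data(1e4, 7)
  tied <- reducer(z, "tied_ae", k = 3, seed = 3)
  W <- qr.Q(qr(coef(tied)))
  V <- eigen(study_structures()$high$matrix, symmetric = TRUE)$vectors[, 1:3]
  # all principal angles below 5 degrees
  angles <- acos(pmin(svd(crossprod(W, V))$d, 1)) * 180 / pi
  expect_lt(max(angles), 5)
})

test_that("the deep autoencoder represents noiseless rank-3 linear data", {
  x <- rank3_data(n = 400, seed = 42)
  z <- standardize_apply(standardize_fit(x), x)
  fit <- reducer(z, "deep_ae", k = 3,
                 control = reducer_control(epochs = 4000, patience = 500,
                                           batch_size = 400,
                                           learning_rate = 5e-3),
                 seed = 3)
  expect_lt(mse(z, reconstruct(fit, z)), 1e-3)
})

test_that("the covariance penalty shrinks off-diagonal latent covariance", {
  z <- make_study_data(500, 8)
  offdiag_cov <- function(lambda) {
    fit <- reducer(z, "independent_ae", k = 3,
                   control = reducer_control(epochs = 120,
                                             penalty_covariance = lambda,
                                             penalty_orthogonality = 0),
                   seed = 21)
    C <- cov(encode(fit, z))
    mean(abs(C[upper.tri(C)]))
  }
  vals <- vapply(c(0, 0.1, 1), offdiag_cov, numeric(1))
  expect_true(all(diff(vals) <= 1e-8))
})

test_that("epoch-end training loss trends monotonically downward", {
  z <- make_study_data(300, 9)
  fit <- reducer(z, "simple_ae", k = 3,
                 control = reducer_control(epochs = 200, batch_size = 300,
                                           learning_rate = 5e-3),
                 seed = 4)
  loss <- fit$fit$loss$loss
  burn <- ceiling(length(loss) * 0.1)
  expect_true(all(diff(loss[burn:length(loss)]) <= 1e-6))
})

test_that("items are assigned to their largest absolute bottleneck weight", {
  # bottleneck-weight rows from a published questionnaire analysis
  a <- assign_items(rbind(c(0.329, 0.029, 0.237),
                          c(0.104, 0.190, 0.581)))
  expect_equal(a$construct, c(1L, 3L))
  ident <- assign_items(diag(3))
  expect_equal(ident$construct, 1:3)
  expect_warning(a2 <- assign_items(matrix(c(0.5, 0.5, 0.1), 1)), "tie")
  expect_equal(a2$construct, 1L)
})

test_that("reducer methods print, summarize and expose residuals coherently", {
  z <- make_study_data(120, 10)
  fit <- reducer(z, "pca", k = 3)
  expect_output(print(fit), "pca reducer: 15 -> 3 -> 15")
  s <- summary(fit)
  expect_output(print(s), "variance explained")
  expect_equal(s$training_metrics$mse, mean(residuals(fit)^2))
  expect_equal(dim(coef(fit)), c(15L, 3L))
  ae <- reducer(z, "simple_ae", k = 3,
                control = reducer_control(epochs = 5), seed = 1)
  expect_output(print(ae), "epochs")
  expect_equal(fitted(ae), reconstruct(ae, z))
})
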