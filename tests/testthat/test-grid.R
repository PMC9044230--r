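fast_ctrl <- reducer_control(epochs = 40)

test_that("the sample-size ladder follows the increment rule", {
  ladder <- sample_size_ladder()
  expect_length(ladder, 27)
  expect_equal(ladder[1], 100L)
  expect_equal(ladder[27], 1000L)
  expect_true(all(diff(ladder) > 0))
  expect_equal(unique(diff(ladder[ladder < 200])), 10L)
  expect_equal(unique(diff(ladder[ladder >= 200])), 50L)
})

test_that("condition enumeration is the Cartesian product of the factors", {
  expect_equal(nrow(enumerate_conditions(grid_spec())), 243)
  small <- grid_spec(structures = "high", scenarios = "s1", sample_sizes = 100)
  expect_equal(nrow(enumerate_conditions(small)), 1)
  two <- grid_spec(structures = c("high", "low"), sample_sizes = c(100, 200,
                                                                   300, 400,
                                                                   500))
  expect_equal(nrow(enumerate_conditions(two)), 30)
  expect_error(grid_spec(sample_sizes = integer(0)), "non-empty")
  expect_error(grid_spec(sample_sizes = c(200, 100)), "strictly increasing")
  expect_error(grid_spec(train_fraction = 1), "between 0 and 1")
})

test_that("one condition produces one row per replicate and algorithm", {
  spec <- grid_spec(structures = "high", scenarios = "s1", sample_sizes = 100,
                    replicates = 1, variants = c("pca", "simple_ae", "tied_ae",
                                                 "deep_ae", "independent_ae"),
                    control = reducer_control(epochs = 3))
  res <- run_condition("high", "s1", 100, spec)
  expect_equal(nrow(res), 5)
  expect_setequal(res$algorithm, spec$variants)
  expect_true(all(!res$failed))
  expect_true(all(res$mse > 0))
})

test_that("the test partition holds round(0.2 n) rows", {
  # n = 110 gives a 22-row test partition; metrics must be computed on it,
  # which we observe through the determinism of the whole pipeline
  spec <- grid_spec(structures = "high", scenarios = "s1", sample_sizes = 110,
                    replicates = 1, variants = "pca")
  res <- run_condition("high", "s1", 110, spec)
  expect_equal(nrow(res), 1)
  x <- simulate(nonnormal_population("high", "s1"), nsim = 1,
                seed = res$seed, n = 110)
  n_test <- round(0.2 * 110)
  perm <- sample.int(110)
  test_idx <- perm[seq_len(n_test)]
  sc <- standardize_fit(x[-test_idx, ])
  fit <- reducer(standardize_apply(sc, x[-test_idx, ]), "pca", k = 3,
                 seed = res$seed)
  tez <- standardize_apply(sc, x[test_idx, , drop = FALSE])
  expect_equal(res$mse, mse(tez, reconstruct(fit, tez)))
  expect_equal(length(test_idx), 22L)
})

test_that("the same master seed reproduces the full result table", {
  spec <- grid_spec(structures = "low", scenarios = c("s1", "s2"),
                    sample_sizes = c(100, 150), replicates = 2,
                    variants = c("pca", "tied_ae"), control = fast_ctrl,
                    master_seed = 7)
  r1 <- run_grid(spec)
  r2 <- run_grid(spec)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 2 * 2 * 2 * 2)
  # different master seed changes the draws
  spec2 <- grid_spec(structures = "low", scenarios = c("s1", "s2"),
                     sample_sizes = c(100, 150), replicates = 2,
                     variants = c("pca", "tied_ae"), control = fast_ctrl,
                     master_seed = 8)
  r3 <- run_grid(spec2)
  expect_false(identical(r1$mse, r3$mse))
})

test_that("summaries aggregate means and standard deviations per level", {
  res <- data.frame(structure = rep(c("high", "low"), each = 4),
                    scenario = "s1", n = rep(c(100, 200), 4),
                    replicate = 1, algorithm = rep(c("pca", "tied_ae"), 4),
                    mse = c(0.2, 0.4, 0.3, 0.5, 0.4, 0.6, 0.5, 0.7),
                    mae = 0.1, ned = 1, failed = FALSE)
  s <- summarize_results(res, by = "communality")
  expect_equal(nrow(s), 4)
  high_pca <- s[s$level == "high" & s$algorithm == "pca", ]
  expect_equal(high_pca$mse_mean, 0.25)
  expect_equal(high_pca$mse_sd, sd(c(0.2, 0.3)))
  expect_equal(high_pca$mae_sd, 0)
  s2 <- summarize_results(res, by = "sample_size")
  expect_setequal(s2$level, c(100, 200))
  # grand consistency: with a balanced design, the unweighted mean of the
  # communality-level means equals the unweighted mean of the normality-level
  # means (both pool the same rows)
  s_norm <- summarize_results(res, by = "normality")
  pca_c <- s[s$algorithm == "pca", "mse_mean"]
  pca_n <- s_norm[s_norm$algorithm == "pca", "mse_mean"]
  expect_equal(mean(pca_c), mean(pca_n))
  expect_error(summarize_results(res, by = "bottleneck"))
  # failed fits are dropped with a message
  res$failed[1] <- TRUE
  expect_message(summarize_results(res, by = "normality"), "1 failed")
})
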