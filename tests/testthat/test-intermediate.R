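normal_cf <- solve_fleishman(moment_spec(0, 1, 0, 0))

test_that("intermediate correlation is the identity map for normal margins", {
  expect_equal(intermediate_correlation(0.7, normal_cf, normal_cf), 0.7)
  expect_equal(intermediate_correlation(0, normal_cf, normal_cf), 0)
  expect_equal(intermediate_correlation(-0.4, normal_cf, normal_cf), -0.4)
})

test_that("the Newton solution matches an independent bisection oracle", {
  cf3 <- solve_fleishman(moment_spec(0, 1, 2, 20))
  rho <- intermediate_correlation(0.7, cf3, cf3)
  # oracle: direct root bracketing of the cubic, independent of the solver
  alpha <- cf3$b^2 + 6 * cf3$b * cf3$d + 9 * cf3$d^2
  beta <- 2 * cf3$c^2
  gamma <- 6 * cf3$d^2
  g <- function(r) r * alpha + r^2 * beta + r^3 * gamma - 0.7
  oracle <- uniroot(g, c(-1, 1), tol = 1e-13)$root
  expect_equal(rho, oracle, tolerance = 1e-10)
  expect_gt(rho, 0.7)  # pre-transform correlation must exceed the target here

  # Monte Carlo confirmation that the target correlation is attained
  set.seed(5)
  z1 <- rnorm(1e6)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(1e6)
  y1 <- cf3$a + cf3$b * z1 + cf3$c * z1^2 + cf3$d * z1^3
  y2 <- cf3$a + cf3$b * z2 + cf3$c * z2^2 + cf3$d * z2^3
  expect_equal(cor(y1, y2), 0.7, tolerance = 0.01)
})

test_that("an unreachable target correlation raises an infeasibility error", {
  # two strongly right-skewed margins cannot be almost perfectly anticorrelated
  cf3 <- solve_fleishman(moment_spec(0, 1, 2, 20))
  expect_error(intermediate_correlation(-0.95, cf3, cf3), "no intermediate")
})

test_that("the assembled intermediate matrix is the target under normal margins", {
  st <- study_structures()
  im <- build_intermediate_matrix(st$high, moment_spec(0, 1, 0, 0))
  expect_equal(im$matrix, st$high$matrix, tolerance = 1e-12)
  expect_false(im$repaired)

  two <- correlation_structure(matrix(c(1, 0.5, 0.5, 1), 2), "toy",
                               n_blocks = 1, block_size = 2)
  im2 <- build_intermediate_matrix(two, moment_spec(0, 1, 0, 0))
  expect_equal(unname(im2$matrix), matrix(c(1, 0.5, 0.5, 1), 2))
})

test_that("non-normal margins give a symmetric positive-definite intermediate matrix", {
  im <- build_intermediate_matrix("high", moment_scenarios()$s2)
  expect_symmetric_unit_diag(im$matrix)
  ev <- eigen(im$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # non-normality strengthens the required pre-transform correlations
  expect_true(all(im$matrix[upper.tri(im$matrix)] >
                    study_structures()$high$matrix[upper.tri(im$matrix)]))
})

test_that("factor patterns reproduce their input matrix", {
  Fi <- factor_pattern(diag(3))  # identity up to column order and sign
  expect_equal(Fi %*% t(Fi), diag(3), tolerance = 1e-12)
  expect_true(all(abs(Fi)[abs(Fi) > 1e-12] > 1 - 1e-12))
  m <- matrix(c(1, 0.5, 0.5, 1), 2)
  FF <- factor_pattern(m)
  expect_lt(max(abs(FF %*% t(FF) - m)), 1e-10)
  Fh <- factor_pattern(study_structures()$high$matrix)
  expect_equal(rowSums(Fh^2), rep(1, 15), tolerance = 1e-8)
  expect_error(factor_pattern(matrix(c(1, 2, 2, 1), 2)), "positive semi-definite")
})
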