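# Shared test utilities.

# Independent oracle for the moments of Y = a + bZ + cZ^2 + dZ^3: the classic
# closed-form system in (b, c, d) on the unit-variance manifold. Valid as a
# variance for any coefficients; skewness/kurtosis lines assume variance 1.
classic_fleishman_system <- function(b, c, d) {
  c(variance = b^2 + 6 * b * d + 2 * c^2 + 15 * d^2,
    skewness = 2 * c * (b^2 + 24 * b * d + 105 * d^2 + 2),
    kurtosis = 24 * (b * d + c^2 * (1 + b^2 + 28 * b * d) +
                       d^2 * (12 + 48 * b * d + 141 * c^2 + 225 * d^2)))
}

sample_skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
sample_exkurt <- function(x) mean((x - mean(x))^4) / stats::sd(x)^4 - 3

# Best-permutation block recovery count for a 15-item, 3-block assignment.
block_recovery <- function(construct, block_size = 5) {
  truth <- rep(1:3, each = block_size)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  max(apply(perms, 1, function(p) sum(p[construct] == truth)))
}

# Noiseless data whose 15 columns are exact linear combinations of 3 normals.
rank3_data <- function(n = 300, seed = 42) {
  set.seed(seed)
  scores <- matrix(rnorm(n * 3), n)
  loadings <- matrix(rnorm(45), 3, 15)
  scores %*% loadings
}

expect_symmetric_unit_diag <- function(m, tol = 1e-12) {
  expect_lt(max(abs(m - t(m))), tol)
  expect_lt(max(abs(diag(m) - 1)), tol)
}
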