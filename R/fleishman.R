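#' Marginal moment specification
#'
#' Describes the target first four moments of one generated variable. The
#' kurtosis is on the excess convention (a normal variable has kurtosis 0).
#'
#' @param mean target mean.
#' @param sd target standard deviation; must be positive.
#' @param skewness target skewness.
#' @param kurtosis target excess kurtosis.
#'
#' @return An object of class `"moment_spec"`.
#' @seealso [moment_scenarios()] for the three study scenarios.
#' @export
#' @examples
#' moment_spec(skewness = 2, kurtosis = 20)
moment_spec <- function(mean = 0, sd = 1, skewness = 0, kurtosis = 0) {
  stopifnot(is.numeric(mean), is.numeric(sd), is.numeric(skewness),
            is.numeric(kurtosis))
  if (sd <= 0) stop("'sd' must be positive")
  structure(list(mean = mean, sd = sd, skewness = skewness,
                 kurtosis = kurtosis),
            class = "moment_spec")
}

#' The three non-normality scenarios of the simulation study
#'
#' Scenario `s1` is standard normal, `s2` has skewness 1 and excess kurtosis 3
#' (mildly non-normal), and `s3` has skewness 2 and excess kurtosis 20
#' (strongly non-normal). All have mean 0 and standard deviation 1.
#'
#' @return A named list of three [moment_spec()] objects (`s1`, `s2`, `s3`).
#' @export
moment_scenarios <- function() {
  list(s1 = moment_spec(0, 1, 0, 0),
       s2 = moment_spec(0, 1, 1, 3),
       s3 = moment_spec(0, 1, 2, 20))
}

#' @export
print.moment_spec <- function(x, ...) {
  cat(sprintf("moment spec: mean %g, sd %g, skewness %g, excess kurtosis %g\n",
              x$mean, x$sd, x$skewness, x$kurtosis))
  invisible(x)
}

# E[Z^n] for standard normal Z: 0 for odd n, (n-1)!! for even n.
.normal_moment <- function(n) {
  if (n %% 2 == 1) return(0)
  if (n == 0) return(1)
  prod(seq(1, n - 1, by = 2))
}

# Raise a polynomial in Z (coefficient vector, constant term first) to an
# integer power by repeated convolution.
.poly_power <- function(p, k) {
  out <- 1
  for (i in seq_len(k)) out <- convolve(out, rev(p), type = "open")
  out
}

.poly_expectation <- function(p) {
  sum(p * vapply(seq_along(p) - 1L, .normal_moment, numeric(1)))
}

#' Exact moments of a Fleishman cubic transform
#'
#' Computes the population variance, skewness and excess kurtosis of
#' \eqn{Y = a + bZ + cZ^2 + dZ^3} for standard normal \eqn{Z}, by expanding
#' the centred polynomial and taking expectations against the normal moments
#' \eqn{E[Z^n] = (n-1)!!}. The computation is exact up to floating point.
#'
#' @param coef a [fleishman()] object, or a numeric vector `c(a, b, c, d)`.
#'
#' @return Named numeric vector with elements `variance`, `skewness`,
#'   `kurtosis` (excess).
#' @export
#' @examples
#' fleishman_moments(c(0, 1, 0, 0))  # identity: 1, 0, 0
#' fleishman_moments(c(0, 0, 0, 1))  # Z^3: variance 15
fleishman_moments <- function(coef) {
  p <- .coef_vector(coef)
  mu <- p[1] + p[3]                       # E[Y] = a + c
  q <- c(p[1] - mu, p[2], p[3], p[4])     # centred polynomial in Z
  m2 <- .poly_expectation(.poly_power(q, 2))
  m3 <- .poly_expectation(.poly_power(q, 3))
  m4 <- .poly_expectation(.poly_power(q, 4))
  c(variance = m2, skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

.coef_vector <- function(coef) {
  if (inherits(coef, "fleishman")) {
    c(coef$a, coef$b, coef$c, coef$d)
  } else {
    stopifnot(is.numeric(coef), length(coef) == 4)
    as.numeric(coef)
  }
}

#' Solve for Fleishman cubic-transform coefficients
#'
#' Finds coefficients \eqn{(a, b, c, d)} with \eqn{a = -c} such that
#' \eqn{Y = a + bZ + cZ^2 + dZ^3} has unit variance and the skewness and
#' excess kurtosis requested by `spec`. The three-equation moment system is
#' solved by damped Newton-Raphson started at \eqn{(b, c, d) = (1,
#' \mathrm{skew}/6, 0)}.
#'
#' A necessary feasibility condition is \eqn{\mathrm{kurtosis} \ge
#' \mathrm{skewness}^2 - 2}; infeasible or non-convergent specifications
#' raise an error naming the requested moments.
#'
#' @param spec a [moment_spec()] (its mean/sd are carried along but the cubic
#'   itself is solved on the zero-mean unit-variance scale).
#' @param tol convergence tolerance on the moment residuals.
#' @param max_iter maximum Newton iterations.
#'
#' @return An object of class `"fleishman"` with elements `a`, `b`, `c`, `d`,
#'   the originating `spec`, the iteration count and the final residual.
#' @export
#' @examples
#' solve_fleishman(moment_spec(skewness = 1, kurtosis = 3))
solve_fleishman <- function(spec, tol = 1e-10, max_iter = 200) {
  stopifnot(inherits(spec, "moment_spec"))
  sk <- spec$skewness
  ku <- spec$kurtosis
  if (ku < sk^2 - 2) {
    stop(sprintf(
      "infeasible moment spec (skewness %g, kurtosis %g): requires kurtosis >= skewness^2 - 2",
      sk, ku))
  }
  if (sk == 0 && ku == 0) {
    return(.new_fleishman(0, 1, 0, 0, spec, 0L, 0))
  }

  resid <- function(p) {
    m <- fleishman_moments(c(-p[2], p[1], p[2], p[3]))
    c(m[["variance"]] - 1, m[["skewness"]] - sk, m[["kurtosis"]] - ku)
  }
  jac <- function(p, f0) {
    h <- 1e-7
    J <- matrix(0, 3, 3)
    for (j in 1:3) {
      pj <- p
      pj[j] <- pj[j] + h
      J[, j] <- (resid(pj) - f0) / h
    }
    J
  }

  p <- c(1, sk / 6, 0)
  f <- resid(p)
  it <- 0L
  while (max(abs(f)) > tol && it < max_iter) {
    it <- it + 1L
    step <- tryCatch(solve(jac(p, f), -f), error = function(e) NULL)
    if (is.null(step)) {
      stop(sprintf("Fleishman solver: singular Jacobian for (skewness %g, kurtosis %g)",
                   sk, ku))
    }
    # damped update: halve the step until the residual norm decreases
    lambda <- 1
    repeat {
      pn <- p + lambda * step
      fn <- resid(pn)
      if (sum(fn^2) < sum(f^2) || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    if (lambda < 1e-8) {
      stop(sprintf("Fleishman solver diverged for (skewness %g, kurtosis %g)",
                   sk, ku))
    }
    p <- pn
    f <- fn
  }
  if (max(abs(f)) > tol) {
    stop(sprintf(
      "Fleishman solver did not converge in %d iterations for (skewness %g, kurtosis %g)",
      max_iter, sk, ku))
  }
  .new_fleishman(-p[2], p[1], p[2], p[3], spec, it, max(abs(f)))
}

.new_fleishman <- function(a, b, c, d, spec, iterations, residual) {
  structure(list(a = a, b = b, c = c, d = d, spec = spec,
                 iterations = iterations, residual = residual),
            class = "fleishman")
}

#' @export
print.fleishman <- function(x, ...) {
  cat(sprintf("Fleishman coefficients (a = %.6g, b = %.6g, c = %.6g, d = %.6g)\n",
              x$a, x$b, x$c, x$d))
  cat(sprintf("  target skewness %g, excess kurtosis %g (%d iterations, residual %.2g)\n",
              x$spec$skewness, x$spec$kurtosis, x$iterations, x$residual))
  invisible(x)
}

# Apply the cubic transform to a vector of standard normal values and move it
# onto the mean/sd of the spec.
.fleishman_apply <- function(coef, z) {
  y <- coef$a + coef$b * z + coef$c * z^2 + coef$d * z^3
  coef$spec$mean + coef$spec$sd * y
}
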