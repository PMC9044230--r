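.check_shapes <- function(original, reconstructed) {
  original <- as.matrix(original)
  reconstructed <- as.matrix(reconstructed)
  if (!all(dim(original) == dim(reconstructed))) {
    stop(sprintf("shape mismatch: original is %d x %d, reconstruction is %d x %d",
                 nrow(original), ncol(original),
                 nrow(reconstructed), ncol(reconstructed)))
  }
  if (anyNA(original) || anyNA(reconstructed)) stop("missing values are not supported")
  list(x = original, xhat = reconstructed)
}

#' Mean squared reconstruction error
#'
#' The average of the squared elementwise errors,
#' \eqn{\frac{1}{nm}\sum_i\sum_j (x_{ij} - \hat{x}_{ij})^2}.
#'
#' @param original,reconstructed numeric matrices of identical shape.
#' @return A non-negative number.
#' @export
#' @examples
#' mse(matrix(c(0, 0, 3, 4), 2, byrow = TRUE),
#'     matrix(c(1, 0, 3, 0), 2, byrow = TRUE))  # 4.25
mse <- function(original, reconstructed) {
  m <- .check_shapes(original, reconstructed)
  mean((m$x - m$xhat)^2)
}

#' Mean absolute reconstruction error
#'
#' The average of the absolute elementwise errors,
#' \eqn{\frac{1}{nm}\sum_i\sum_j |\hat{x}_{ij} - x_{ij}|}.
#'
#' @inheritParams mse
#' @return A non-negative number.
#' @export
mae <- function(original, reconstructed) {
  m <- .check_shapes(original, reconstructed)
  mean(abs(m$xhat - m$x))
}

#' Normalized Euclidean distance between sign patterns
#'
#' Compares the sign patterns of a matrix and its reconstruction. By default,
#' each entry is normalized to its sign (\eqn{x/|x|}; the sign of an exact 0
#' is taken as 0), the per-row Euclidean distances
#' \eqn{d_i = \sqrt{\sum_j (\mathrm{sgn}\,\hat{x}_{ij} - \mathrm{sgn}\,x_{ij})^2}}
#' are computed, and their mean over rows is returned. A single sign
#' disagreement in a row contributes 4 under the root (distance 2 for a
#' one-row matrix); full agreement gives 0. The statistic is invariant to
#' positive rescaling of either matrix.
#'
#' With `literal = TRUE` the unsquared, unaveraged form
#' \eqn{\sqrt{\sum_i \sum_j (\mathrm{sgn}\,\hat{x}_{ij} - \mathrm{sgn}\,x_{ij})}}
#' is computed instead, and an error is raised when the radicand is negative;
#' this form is retained for auditability only.
#'
#' @inheritParams mse
#' @param literal compute the unsquared-sum form instead of the default.
#' @return A non-negative number.
#' @export
ned <- function(original, reconstructed, literal = FALSE) {
  m <- .check_shapes(original, reconstructed)
  s <- sign(m$xhat) - sign(m$x)
  if (literal) {
    radicand <- sum(s)
    if (radicand < 0) {
      stop("literal NED: negative radicand (sum of unsquared sign differences)")
    }
    return(sqrt(radicand))
  }
  mean(sqrt(rowSums(s^2)))
}

#' All three reconstruction metrics at once
#'
#' @inheritParams ned
#' @return Named list with elements `mse`, `mae`, `ned`.
#' @export
reconstruction_metrics <- function(original, reconstructed, literal = FALSE) {
  list(mse = mse(original, reconstructed),
       mae = mae(original, reconstructed),
       ned = ned(original, reconstructed, literal = literal))
}
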