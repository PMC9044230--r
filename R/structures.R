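#' Construct a correlation structure
#'
#' A correlation structure is a labelled target population correlation matrix
#' organised in equally sized latent blocks (the study uses 15 items in three
#' blocks of five).
#'
#' @param matrix symmetric positive-definite correlation matrix with unit
#'   diagonal.
#' @param label short name for the structure.
#' @param n_blocks number of latent blocks.
#' @param block_size items per block; `n_blocks * block_size` must equal
#'   `ncol(matrix)`.
#'
#' @return An object of class `"correlation_structure"`.
#' @export
correlation_structure <- function(matrix, label = "custom", n_blocks = 3,
                                  block_size = ncol(matrix) / n_blocks) {
  m <- as.matrix(matrix)
  k <- ncol(m)
  if (nrow(m) != k) stop("correlation matrix must be square")
  if (max(abs(m - t(m))) > 1e-12) stop("correlation matrix must be symmetric")
  if (any(abs(diag(m) - 1) > 1e-12)) stop("correlation matrix must have a unit diagonal")
  if (any(abs(m) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop(sprintf("correlation matrix is not positive definite (min eigenvalue %.3g)", min(ev)))
  if (n_blocks * block_size != k) stop("'n_blocks' * 'block_size' must equal the matrix dimension")
  items <- sprintf("item%02d", seq_len(k))
  dimnames(m) <- list(items, items)
  structure(list(label = label, matrix = m, n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size)),
            class = "correlation_structure")
}

#' @export
as.matrix.correlation_structure <- function(x, ...) x$matrix

#' @export
print.correlation_structure <- function(x, ...) {
  cat(sprintf("correlation structure '%s': %d items in %d blocks of %d\n",
              x$label, ncol(x$matrix), x$n_blocks, x$block_size))
  invisible(x)
}

# Repeat one 5x5 within-block pattern down the diagonal, constant elsewhere.
.block_matrix <- function(block, between, n_blocks = 3) {
  size <- ncol(block)
  k <- size * n_blocks
  m <- matrix(between, k, k)
  for (g in seq_len(n_blocks) - 1L) {
    idx <- g * size + seq_len(size)
    m[idx, idx] <- block
  }
  diag(m) <- 1
  m
}

#' The three study correlation structures
#'
#' Returns the three 15-item, three-block population correlation matrices used
#' throughout the simulation study, keyed by communality regime:
#' \describe{
#'   \item{`high`}{all within-block correlations 0.7, between-block 0.2
#'     (communalities 0.8).}
#'   \item{`wide`}{within-block correlations decreasing from 0.9 to 0.3
#'     following \eqn{r_{ij} = 1 - 0.1(i + j - 2)}, between-block 0.1
#'     (communalities between 0.6 and 0.9).}
#'   \item{`low`}{within-block correlations 0.5 except entries (3,5) = 0.4 and
#'     (4,5) = 0.3, between-block 0.3 (communalities between 0.3 and 0.5).}
#' }
#'
#' @return Named list of three [correlation_structure()] objects.
#' @export
#' @examples
#' study_structures()$high$matrix[1, c(2, 6)]  # 0.7 within, 0.2 between
study_structures <- function() {
  high_block <- matrix(0.7, 5, 5)
  diag(high_block) <- 1

  wide_block <- outer(1:5, 1:5, function(i, j) 1 - 0.1 * (i + j - 2))
  diag(wide_block) <- 1

  low_block <- matrix(0.5, 5, 5)
  low_block[3, 5] <- low_block[5, 3] <- 0.4
  low_block[4, 5] <- low_block[5, 4] <- 0.3
  diag(low_block) <- 1

  list(
    high = correlation_structure(.block_matrix(high_block, 0.2), "high"),
    wide = correlation_structure(.block_matrix(wide_block, 0.1), "wide"),
    low  = correlation_structure(.block_matrix(low_block, 0.3), "low")
  )
}

.get_structure <- function(structure) {
  if (inherits(structure, "correlation_structure")) return(structure)
  if (is.character(structure) && length(structure) == 1) {
    all <- study_structures()
    if (!structure %in% names(all)) {
      stop(sprintf("unknown structure '%s'; expected one of %s", structure,
                   paste(sQuote(names(all)), collapse = ", ")))
    }
    return(all[[structure]])
  }
  stop("'structure' must be a correlation_structure or one of 'high', 'wide', 'low'")
}

.get_scenario <- function(scenario) {
  if (inherits(scenario, "moment_spec")) return(scenario)
  if (is.character(scenario) && length(scenario) == 1) {
    all <- moment_scenarios()
    if (!scenario %in% names(all)) {
      stop(sprintf("unknown scenario '%s'; expected one of %s", scenario,
                   paste(sQuote(names(all)), collapse = ", ")))
    }
    return(all[[scenario]])
  }
  stop("'scenario' must be a moment_spec or one of 's1', 's2', 's3'")
}
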