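#' Column standardization fitted on training data
#'
#' Learns per-column means and standard deviations from a training matrix so
#' that held-out data can be z-scored with the training statistics only.
#'
#' @param train numeric matrix with at least two rows.
#' @return An object of class `"standardizer"` with elements `mean` and `sd`.
#' @export
#' @examples
#' sc <- standardize_fit(matrix(rnorm(40), 10))
#' z <- standardize_apply(sc, matrix(rnorm(8), 2))
standardize_fit <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) < 2) stop("need at least 2 rows to fit a standardizer")
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  zero <- which(sd <= .Machine$double.eps * 100)
  if (length(zero)) {
    nm <- colnames(train)[zero]
    if (is.null(nm)) nm <- as.character(zero)
    stop(sprintf("zero-variance column(s): %s", paste(nm, collapse = ", ")))
  }
  structure(list(mean = mu, sd = sd), class = "standardizer")
}

#' @rdname standardize_fit
#' @param scaler a fitted `"standardizer"`.
#' @param data matrix with the same columns as the training data.
#' @export
standardize_apply <- function(scaler, data) {
  stopifnot(inherits(scaler, "standardizer"))
  data <- as.matrix(data)
  if (ncol(data) != length(scaler$mean)) {
    stop(sprintf("data has %d columns; standardizer was fitted on %d",
                 ncol(data), length(scaler$mean)))
  }
  sweep(sweep(data, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}
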