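#' Training options for the autoencoder variants
#'
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size (capped at the number of rows).
#' @param learning_rate step size; default 1e-2 for the plain SGD variant and
#'   1e-3 for the adaptive-moment variants.
#' @param penalty_covariance weight of the latent covariance penalty
#'   (independent variant only).
#' @param penalty_orthogonality weight of the encoder/decoder orthogonality
#'   penalty (independent variant only).
#' @param patience epochs without an improvement of at least `min_delta` in
#'   the epoch-end training objective before stopping early.
#' @param min_delta minimum improvement counted by `patience`.
#' @param optimizer `"sgd"` or `"adam"`; default depends on the variant.
#'
#' @return A list of class `"reducer_control"`.
#' @export
reducer_control <- function(epochs = 500, batch_size = 32,
                            learning_rate = NULL,
                            penalty_covariance = 0.1,
                            penalty_orthogonality = 0.1,
                            patience = 50, min_delta = 1e-6,
                            optimizer = NULL) {
  stopifnot(epochs >= 1, batch_size >= 1,
            penalty_covariance >= 0, penalty_orthogonality >= 0,
            patience >= 1, min_delta >= 0)
  if (!is.null(optimizer)) optimizer <- match.arg(optimizer, c("sgd", "adam"))
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 penalty_covariance = penalty_covariance,
                 penalty_orthogonality = penalty_orthogonality,
                 patience = as.integer(patience), min_delta = min_delta,
                 optimizer = optimizer),
            class = "reducer_control")
}

#' Fit a dimension reducer
#'
#' Fits one of five dimension-reduction models to a numeric matrix under a
#' common encode/reconstruct contract with a `k`-dimensional latent space:
#'
#' \describe{
#'   \item{`pca`}{principal component analysis; the latent basis is the top-`k`
#'     eigenvectors of the training correlation matrix, and reconstruction is
#'     projection followed by back-projection plus the training means.}
#'   \item{`simple_ae`}{single-hidden-layer linear autoencoder trained with
#'     minibatch SGD.}
#'   \item{`tied_ae`}{as `simple_ae` but with the decoder weight constrained to
#'     the transpose of the encoder weight throughout training (Adam).}
#'   \item{`deep_ae`}{a seven-hidden-layer autoencoder (11-6-6-`k`-6-6-11
#'     neurons) with tanh hidden activations and a linear output layer (Adam).}
#'   \item{`independent_ae`}{single-hidden-layer autoencoder (tanh bottleneck,
#'     linear output) with an L1 penalty on the off-diagonal latent covariance
#'     and squared-Frobenius orthogonality penalties on the encoder and decoder
#'     weights (Adam).}
#' }
#'
#' All variants minimize the mean squared reconstruction error on the scale of
#' the input; in the study pipeline the input is z-scored with training
#' statistics (see [standardize_fit()]) so errors are comparable across
#' algorithms.
#'
#' @param x numeric matrix or data frame, observations in rows.
#' @param variant which reducer to fit.
#' @param k latent dimension (bottleneck width); at least 1 and smaller than
#'   the number of columns, except that `k = ncol(x)` is allowed for `pca`
#'   (full-rank reconstruction).
#' @param control a [reducer_control()] with training options.
#' @param seed integer seed making autoencoder initialization and batching
#'   reproducible.
#'
#' @return An object of class `"reducer"` with methods [print()], [summary()],
#'   [coef()] (per-item bottleneck weights), [predict()], [fitted()],
#'   [residuals()] and [plot()], plus [encode()], [reconstruct()] and
#'   [assign_items()].
#' @export
#' @examples
#' x <- generate_dataset("high", "s1", n = 200, seed = 1)
#' z <- standardize_apply(standardize_fit(x), x)
#' fit <- reducer(z, "pca", k = 3)
#' mse(z, reconstruct(fit, z))
reducer <- function(x, variant = c("pca", "simple_ae", "tied_ae", "deep_ae",
                                   "independent_ae"),
                    k = 3, control = reducer_control(), seed = NULL) {
  variant <- match.arg(variant)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be numeric")
  if (anyNA(x)) stop("'x' contains missing values")
  m <- ncol(x)
  kmax <- if (variant == "pca") m else m - 1L
  if (k < 1 || k > kmax) {
    stop(sprintf("'k' must be between 1 and %d for variant '%s'", kmax, variant))
  }
  stopifnot(inherits(control, "reducer_control"))
  if (!is.null(seed)) set.seed(seed)

  fit <- if (variant == "pca") {
    center <- colMeans(x)
    ev <- eigen(stats::cor(x), symmetric = TRUE)
    list(center = center, rotation = ev$vectors[, seq_len(k), drop = FALSE],
         eigenvalues = ev$values)
  } else {
    .train_autoencoder(x, variant, k, control)
  }

  structure(list(variant = variant, k = as.integer(k), m = m,
                 n = nrow(x), fit = fit, x = x, control = control,
                 seed = seed, call = match.call()),
            class = "reducer")
}

#' Latent scores of new data under a fitted reducer
#'
#' @param model a fitted [reducer()].
#' @param data matrix with the same columns as the training data.
#' @return `encode()` returns an `n` by `k` score matrix; `reconstruct()`
#'   returns an `n` by `m` reconstruction on the training scale.
#' @export
encode <- function(model, data) predict(model, data, type = "scores")

#' @rdname encode
#' @export
reconstruct <- function(model, data) predict(model, data, type = "reconstruction")

#' @export
predict.reducer <- function(object, newdata = NULL,
                            type = c("reconstruction", "scores"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$x else as.matrix(newdata)
  if (ncol(x) != object$m) {
    stop(sprintf("newdata has %d columns; model was trained on %d",
                 ncol(x), object$m))
  }
  if (object$variant == "pca") {
    xc <- sweep(x, 2, object$fit$center, "-")
    scores <- xc %*% object$fit$rotation
    if (type == "scores") return(scores)
    sweep(scores %*% t(object$fit$rotation), 2, object$fit$center, "+")
  } else {
    h <- .net_encode(object$fit, x)
    if (type == "scores") return(h)
    .net_decode(object$fit, h)
  }
}

#' @export
fitted.reducer <- function(object, ...) predict(object, object$x)

#' @export
residuals.reducer <- function(object, ...) object$x - fitted(object)

#' Per-item bottleneck weights of a fitted reducer
#'
#' Returns the `m` by `k` matrix of item-to-latent weights: the component
#' loadings for PCA, the encoder weight matrix for the single-hidden-layer
#' autoencoders, and the product of the encoder layer weight matrices (the
#' linearized item-to-bottleneck map) for the deep variant.
#'
#' @param object a fitted [reducer()].
#' @param ... unused.
#' @export
coef.reducer <- function(object, ...) {
  w <- if (object$variant == "pca") {
    object$fit$rotation
  } else {
    Reduce(`%*%`, object$fit$weights[seq_len(object$fit$bottleneck)])
  }
  rownames(w) <- colnames(object$x)
  colnames(w) <- sprintf("latent%d", seq_len(ncol(w)))
  w
}

#' @export
print.reducer <- function(x, ...) {
  cat(sprintf("%s reducer: %d -> %d -> %d\n", x$variant, x$m, x$k, x$m))
  cat(sprintf("  trained on %d observations", x$n))
  if (x$variant != "pca") {
    cat(sprintf("; %d epochs (%s, lr %g), final training loss %.5f",
                nrow(x$fit$loss), x$fit$optimizer, x$fit$learning_rate,
                x$fit$loss$loss[nrow(x$fit$loss)]))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.reducer <- function(object, ...) {
  rec <- fitted(object)
  out <- list(variant = object$variant, k = object$k, m = object$m,
              n = object$n,
              training_metrics = reconstruction_metrics(object$x, rec))
  if (object$variant == "pca") {
    ev <- object$fit$eigenvalues
    out$variance_explained <- sum(ev[seq_len(object$k)]) / sum(ev)
  } else {
    out$epochs <- nrow(object$fit$loss)
    out$final_loss <- object$fit$loss$loss[out$epochs]
  }
  class(out) <- "summary.reducer"
  out
}

#' @export
print.summary.reducer <- function(x, ...) {
  cat(sprintf("%s reducer with %d latent dimensions (%d items, n = %d)\n",
              x$variant, x$k, x$m, x$n))
  tm <- x$training_metrics
  cat(sprintf("  training reconstruction: MSE %.4f, MAE %.4f, NED %.4f\n",
              tm$mse, tm$mae, tm$ned))
  if (!is.null(x$variance_explained)) {
    cat(sprintf("  variance explained by %d components: %.1f%%\n",
                x$k, 100 * x$variance_explained))
  } else {
    cat(sprintf("  %d training epochs, final objective %.5f\n",
                x$epochs, x$final_loss))
  }
  invisible(x)
}

#' @export
plot.reducer <- function(x, ...) {
  if (x$variant == "pca") {
    graphics::barplot(x$fit$eigenvalues, names.arg = seq_along(x$fit$eigenvalues),
                      xlab = "component", ylab = "eigenvalue",
                      main = "PCA eigen-spectrum", ...)
  } else {
    graphics::plot(x$fit$loss$epoch, x$fit$loss$loss, type = "l",
                   xlab = "epoch", ylab = "training objective",
                   main = sprintf("%s training loss", x$variant), ...)
  }
  invisible(x)
}

#' Assign questionnaire items to latent constructs
#'
#' Classifies each item into the latent construct on which it has the largest
#' absolute bottleneck weight. Ties are broken toward the lowest construct
#' index with a warning.
#'
#' @param x a fitted [reducer()] or a numeric item-by-construct weight matrix.
#' @param ... unused.
#' @return A data frame of class `"construct_assignment"` with one row per
#'   item: the assigned construct and the absolute weights.
#' @export
#' @examples
#' assign_items(rbind(c(0.329, 0.029, 0.237), c(0.104, 0.19, 0.581)))
assign_items <- function(x, ...) UseMethod("assign_items")

#' @export
assign_items.reducer <- function(x, ...) assign_items(coef(x), ...)

#' @export
assign_items.default <- function(x, ...) {
  w <- abs(as.matrix(x))
  if (is.null(rownames(w))) rownames(w) <- sprintf("item%02d", seq_len(nrow(w)))
  ties <- apply(w, 1, function(r) sum(r == max(r)) > 1)
  if (any(ties)) {
    warning(sprintf("tie in absolute weights for %s; assigned to the lowest construct index",
                    paste(rownames(w)[ties], collapse = ", ")))
  }
  construct <- apply(w, 1, which.max)
  out <- data.frame(item = rownames(w), construct = as.integer(construct))
  colnames(w) <- sprintf("weight%d", seq_len(ncol(w)))
  out <- cbind(out, as.data.frame(w, row.names = FALSE))
  class(out) <- c("construct_assignment", "data.frame")
  out
}
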