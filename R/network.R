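# Internal feed-forward network machinery for the autoencoder variants.
# Row convention: data rows are observations, so a layer maps A -> f(A W + b)
# with W of shape (in x out). All variants minimize the mean squared
# reconstruction error; the independent variant adds a latent-covariance
# penalty and encoder/decoder orthogonality penalties.

.act_fun <- function(z, act) {
  switch(act, linear = z, tanh = tanh(z),
         stop(sprintf("unknown activation '%s'", act)))
}

# derivative as a function of the activation output
.act_deriv <- function(a, act) {
  switch(act, linear = 1, tanh = 1 - a^2)
}

.ae_architecture <- function(variant, m, k) {
  switch(variant,
    simple_ae = list(dims = c(m, k, m), acts = c("linear", "linear"),
                     tied = FALSE),
    tied_ae = list(dims = c(m, k, m), acts = c("linear", "linear"),
                   tied = TRUE),
    independent_ae = list(dims = c(m, k, m), acts = c("tanh", "linear"),
                          tied = FALSE),
    deep_ae = list(
      dims = c(m, 11L, 6L, 6L, k, 6L, 6L, 11L, m),
      acts = c(rep("tanh", 7), "linear"),
      tied = FALSE),
    stop(sprintf("unknown autoencoder variant '%s'", variant))
  )
}

.init_network <- function(arch) {
  L <- length(arch$dims) - 1L
  weights <- vector("list", L)
  biases <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- arch$dims[l]
    s <- 1 / sqrt(fan_in)
    weights[[l]] <- matrix(runif(fan_in * arch$dims[l + 1], -s, s),
                           fan_in, arch$dims[l + 1])
    biases[[l]] <- rep(0, arch$dims[l + 1])
  }
  if (arch$tied) weights[[2]] <- t(weights[[1]])
  c(arch, list(weights = weights, biases = biases,
               bottleneck = which.min(arch$dims[-c(1, length(arch$dims))])))
}

.net_forward <- function(net, X) {
  L <- length(net$weights)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% net$weights[[l]]
    Z <- sweep(Z, 2, net$biases[[l]], "+")
    A[[l + 1]] <- .act_fun(Z, net$acts[l])
  }
  A
}

.net_encode <- function(net, X) {
  A <- X
  for (l in seq_len(net$bottleneck)) {
    Z <- sweep(A %*% net$weights[[l]], 2, net$biases[[l]], "+")
    A <- .act_fun(Z, net$acts[l])
  }
  A
}

.net_decode <- function(net, H) {
  L <- length(net$weights)
  A <- H
  for (l in (net$bottleneck + 1):L) {
    Z <- sweep(A %*% net$weights[[l]], 2, net$biases[[l]], "+")
    A <- .act_fun(Z, net$acts[l])
  }
  A
}

# latent covariance penalty sum_{i != j} |Cov(H)_{ij}| and its gradient in H
.cov_penalty <- function(H) {
  nb <- nrow(H)
  if (nb < 2) return(list(value = 0, grad = H * 0))
  Hc <- sweep(H, 2, colMeans(H), "-")
  C <- crossprod(Hc) / (nb - 1)
  S <- sign(C)
  diag(S) <- 0
  list(value = sum(abs(C) * (1 - diag(ncol(C)))),
       grad = 2 * (Hc %*% S) / (nb - 1))
}

# one backward pass; returns weight/bias gradients for the batch
.net_backward <- function(net, A, penalties = NULL) {
  L <- length(net$weights)
  X <- A[[1]]
  Y <- A[[L + 1]]
  n <- nrow(X)
  m <- ncol(X)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- 2 * (Y - X) / (n * m)              # dLoss/dY, loss = mean sq error
  for (l in L:1) {
    delta <- delta * .act_deriv(A[[l + 1]], net$acts[l])
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(net$weights[[l]])
      if (!is.null(penalties) && (l - 1) == net$bottleneck) {
        cp <- .cov_penalty(A[[net$bottleneck + 1]])
        delta <- delta + penalties$covariance * cp$grad
      }
    }
  }
  if (!is.null(penalties) && penalties$orthogonality > 0) {
    We <- net$weights[[net$bottleneck]]
    Wd <- net$weights[[net$bottleneck + 1]]
    Ik <- diag(ncol(We))
    gW[[net$bottleneck]] <- gW[[net$bottleneck]] +
      penalties$orthogonality * 4 * We %*% (crossprod(We) - Ik)
    gW[[net$bottleneck + 1]] <- gW[[net$bottleneck + 1]] +
      penalties$orthogonality * 4 * (tcrossprod(Wd) - Ik) %*% Wd
  }
  list(W = gW, b = gb)
}

.penalty_value <- function(net, H, penalties) {
  if (is.null(penalties)) return(0)
  We <- net$weights[[net$bottleneck]]
  Wd <- net$weights[[net$bottleneck + 1]]
  Ik <- diag(ncol(We))
  penalties$covariance * .cov_penalty(H)$value +
    penalties$orthogonality * (sum((crossprod(We) - Ik)^2) +
                               sum((tcrossprod(Wd) - Ik)^2))
}

.train_autoencoder <- function(X, variant, k, control) {
  n <- nrow(X)
  m <- ncol(X)
  arch <- .ae_architecture(variant, m, k)
  net <- .init_network(arch)
  penalties <- if (variant == "independent_ae") {
    list(covariance = control$penalty_covariance,
         orthogonality = control$penalty_orthogonality)
  } else NULL

  optimizer <- control$optimizer
  if (is.null(optimizer)) optimizer <- if (variant == "simple_ae") "sgd" else "adam"
  lr <- control$learning_rate
  if (is.null(lr)) lr <- if (optimizer == "sgd") 1e-2 else 1e-3

  L <- length(net$weights)
  if (optimizer == "adam") {
    mW <- lapply(net$weights, function(w) w * 0); vW <- mW
    mB <- lapply(net$biases, function(b) b * 0); vB <- mB
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  }

  batch <- max(1L, min(control$batch_size, n))
  loss_log <- numeric(control$epochs)
  recon_log <- numeric(control$epochs)
  best <- Inf
  stall <- 0L
  epochs_run <- 0L

  for (epoch in seq_len(control$epochs)) {
    idx <- sample.int(n)
    for (start in seq(1, n, by = batch)) {
      rows <- idx[start:min(start + batch - 1, n)]
      A <- .net_forward(net, X[rows, , drop = FALSE])
      g <- .net_backward(net, A, penalties)
      if (net$tied) {
        # shared parameter: decoder weight is the encoder transpose
        gshared <- g$W[[1]] + t(g$W[[2]])
        g$W[[1]] <- gshared
        g$W[[2]] <- t(gshared)
      }
      if (optimizer == "sgd") {
        for (l in seq_len(L)) {
          net$weights[[l]] <- net$weights[[l]] - lr * g$W[[l]]
          net$biases[[l]] <- net$biases[[l]] - lr * g$b[[l]]
        }
      } else {
        t <- t + 1
        for (l in seq_len(L)) {
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$W[[l]]
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$W[[l]]^2
          mB[[l]] <- b1 * mB[[l]] + (1 - b1) * g$b[[l]]
          vB[[l]] <- b2 * vB[[l]] + (1 - b2) * g$b[[l]]^2
          mhW <- mW[[l]] / (1 - b1^t); vhW <- vW[[l]] / (1 - b2^t)
          mhB <- mB[[l]] / (1 - b1^t); vhB <- vB[[l]] / (1 - b2^t)
          net$weights[[l]] <- net$weights[[l]] - lr * mhW / (sqrt(vhW) + eps)
          net$biases[[l]] <- net$biases[[l]] - lr * mhB / (sqrt(vhB) + eps)
        }
      }
      if (net$tied) net$weights[[2]] <- t(net$weights[[1]])
    }

    A <- .net_forward(net, X)
    recon <- mean((A[[L + 1]] - X)^2)
    total <- recon + .penalty_value(net, A[[net$bottleneck + 1]], penalties)
    if (!is.finite(total)) {
      stop(sprintf("non-finite training loss at epoch %d (learning rate %g)",
                   epoch, lr))
    }
    recon_log[epoch] <- recon
    loss_log[epoch] <- total
    epochs_run <- epoch
    if (total < best - control$min_delta) {
      best <- total
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= control$patience) break
    }
  }

  net$loss <- data.frame(epoch = seq_len(epochs_run),
                         loss = loss_log[seq_len(epochs_run)],
                         reconstruction = recon_log[seq_len(epochs_run)])
  net$optimizer <- optimizer
  net$learning_rate <- lr
  net$penalties <- penalties
  net
}
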