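# Dense feed-forward classifier: input -> ReLU(40) -> ReLU(40) -> softmax.
# Trained with minibatch Adam on categorical cross-entropy. Inputs are the
# integer positional codes scaled to [0, 1] by the largest code in the
# training inventory (the scale is stored with the fit so prediction matches).
#
# Written in plain matrix algebra: the network is small (tens of units, tens
# of features) and dominated by the matrix products, which BLAS handles.

mlp_init <- function(sizes) {
  # He-uniform initialisation, biases at zero
  params <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    limit <- sqrt(6 / sizes[l])
    params[[paste0("W", l)]] <- matrix(
      stats::runif(sizes[l] * sizes[l + 1L], -limit, limit),
      nrow = sizes[l]
    )
    params[[paste0("b", l)]] <- rep(0, sizes[l + 1L])
  }
  params
}

mlp_forward <- function(params, X, n_layers) {
  acts <- list(X)
  A <- X
  for (l in seq_len(n_layers)) {
    Z <- sweep(A %*% params[[paste0("W", l)]], 2L, params[[paste0("b", l)]], "+")
    A <- if (l < n_layers) pmax(Z, 0) else softmax_rows(Z)
    acts[[l + 1L]] <- A
  }
  acts
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Train the neural-network classifier
#'
#' A four-layer fully connected network (input, two hidden layers of
#' `hidden` units with ReLU, softmax output) trained with the Adam optimizer
#' on categorical cross-entropy. Layer widths follow the usual rule of thumb
#' of a fixed modest hidden size; the input width is the number of kept
#' positional features and the output width the number of classes.
#'
#' @param X numeric feature matrix (integer positional codes).
#' @param y factor of class labels.
#' @param hidden hidden layer sizes (default `c(40, 40)`).
#' @param epochs passes over the training data (default 64).
#' @param batch_size minibatch size (default 128).
#' @param lr Adam step size (default 1e-3).
#' @param seed integer seed controlling initialisation and shuffling.
#' @param verbose print the epoch losses.
#' @return An object of class `mlp_fit` with the weights, the class levels,
#'   the input scale, and the per-epoch mean training loss (`loss_history`).
#' @export
mlp_train <- function(X, y, hidden = c(40L, 40L), epochs = 64L,
                      batch_size = 128L, lr = 1e-3, seed = 1L,
                      verbose = FALSE) {
  y <- as.factor(y)
  classes <- levels(y)
  K <- length(classes)
  if (K < 2L) stopf("training requires at least 2 classes")
  scale <- max(X, 1)
  Xs <- X / scale
  n <- nrow(Xs)
  sizes <- c(ncol(Xs), hidden, K)
  n_layers <- length(sizes) - 1L
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1

  with_seed(seed, {
    params <- mlp_init(sizes)
    m <- lapply(params, function(p) p * 0)
    v <- lapply(params, function(p) p * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    t <- 0L
    loss_history <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      n_batches <- ceiling(n / batch_size)
      for (bi in seq_len(n_batches)) {
        rows <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, n)]
        Xb <- Xs[rows, , drop = FALSE]
        Yb <- Y[rows, , drop = FALSE]
        acts <- mlp_forward(params, Xb, n_layers)
        P <- acts[[n_layers + 1L]]
        ep_loss <- ep_loss - sum(log(pmax(P[Yb == 1], 1e-12))) / n
        grads <- list()
        delta <- (P - Yb) / nrow(Xb) # softmax + CE gradient
        for (l in n_layers:1) {
          grads[[paste0("W", l)]] <- crossprod(acts[[l]], delta)
          grads[[paste0("b", l)]] <- colSums(delta)
          if (l > 1L) {
            delta <- (delta %*% t(params[[paste0("W", l)]])) * (acts[[l]] > 0)
          }
        }
        t <- t + 1L
        for (nm in names(params)) {
          g <- grads[[nm]]
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
          v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g^2
          mhat <- m[[nm]] / (1 - b1^t)
          vhat <- v[[nm]] / (1 - b2^t)
          params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      loss_history[ep] <- ep_loss
      if (verbose) message(sprintf("epoch %d: loss %.5f", ep, ep_loss))
    }
    structure(
      list(
        params = params, sizes = sizes, classes = classes,
        scale = scale, loss_history = loss_history
      ),
      class = "mlp_fit"
    )
  })
}

#' Predict with a trained neural network
#'
#' @param object an `mlp_fit`.
#' @param newdata numeric feature matrix on the training feature set.
#' @param ... unused.
#' @return Matrix of class probabilities (rows sum to 1), columns named by
#'   class.
#' @export
predict.mlp_fit <- function(object, newdata, ...) {
  acts <- mlp_forward(object$params, newdata / object$scale,
    length(object$sizes) - 1L)
  P <- acts[[length(acts)]]
  colnames(P) <- object$classes
  P
}
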