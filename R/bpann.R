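#' Low-level network state
#'
#' Allocates the weight matrices of a three-layer feedforward network with
#' sigmoid hidden units and a linear output. Weights are drawn uniformly from
#' `[-init_scale, init_scale]` with the given seed; biases and momentum
#' velocity buffers start at zero. Scalers are identity until fitted by
#' [bpann()].
#'
#' @param n_input,n_hidden,n_output layer sizes.
#' @param init_scale half-width of the uniform weight initialization.
#' @param seed integer RNG seed (mandatory: silent nondeterminism is a bug).
#' @return A list of class `bpann_state` with `W1` (hidden x input), `b1`,
#'   `W2` (output x hidden), `b2`, velocity buffers, and identity scalers.
#' @export
bpann_init <- function(n_input = 9, n_hidden = 18, n_output = 1,
                       init_scale = 0.5, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(n_input >= 1, n_hidden >= 1, n_output >= 1, init_scale >= 0)
  with_preserved_rng({
    set.seed(as.integer(seed))
    state <- list(
      W1 = matrix(runif(n_hidden * n_input, -init_scale, init_scale),
                  n_hidden, n_input),
      b1 = numeric(n_hidden),
      W2 = matrix(runif(n_output * n_hidden, -init_scale, init_scale),
                  n_output, n_hidden),
      b2 = numeric(n_output),
      vW1 = matrix(0, n_hidden, n_input), vb1 = numeric(n_hidden),
      vW2 = matrix(0, n_output, n_hidden), vb2 = numeric(n_output),
      x_min = numeric(n_input), x_range = rep(1, n_input),
      y_min = 0, y_range = 1, fitted_scalers = FALSE
    )
    class(state) <- "bpann_state"
    state
  })
}

scale_x <- function(state, X) {
  sweep(sweep(X, 2, state$x_min, "-"), 2, state$x_range, "/")
}

# Forward pass on already-scaled inputs; returns list(H, pred) on the scaled
# output scale.
forward_scaled <- function(state, Xs) {
  Z <- Xs %*% t(state$W1)
  Z <- sweep(Z, 2, state$b1, "+")
  H <- 1 / (1 + exp(-Z))
  pred <- H %*% t(state$W2) + state$b2[1]
  list(H = H, pred = pred)
}

#' Forward pass of a network state
#'
#' Maps feature vectors through input scaling, the sigmoid hidden layer, the
#' linear output, and inverse target scaling. For a freshly initialized state
#' the scalers are the identity.
#'
#' @param state a [bpann_init()] state (or a fitted [bpann()] model).
#' @param x numeric feature vector of length `n_input`, or a matrix with one
#'   row per observation.
#' @return Predicted concentration(s) in uM.
#' @export
bpann_forward <- function(state, x) {
  if (inherits(state, "bpann")) state <- state$state
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != ncol(state$W1))
    stop(sprintf("expected %d features, got %d", ncol(state$W1), ncol(X)))
  pred <- forward_scaled(state, scale_x(state, X))$pred
  as.vector(pred * state$y_range + state$y_min)
}

# Full-batch gradient of mean squared error on the scaled problem.
bpann_gradient <- function(state, Xs, ys) {
  n <- nrow(Xs)
  fw <- forward_scaled(state, Xs)
  e <- fw$pred[, 1] - ys
  dpred <- 2 * e / n
  gW2 <- matrix(dpred %*% fw$H, nrow = 1)
  gb2 <- sum(dpred)
  dH <- outer(dpred, state$W2[1, ]) * fw$H * (1 - fw$H)
  gW1 <- t(dH) %*% Xs
  gb1 <- colSums(dH)
  list(gW1 = gW1, gb1 = gb1, gW2 = gW2, gb2 = gb2,
       mse_scaled = mean(e^2))
}

#' Fit a backpropagation neural-network concentration regressor
#'
#' Trains a three-layer feedforward network (default 9-18-1: nine color
#' moments in, eighteen sigmoid hidden units, one linear output) by gradient
#' descent with momentum (`v <- momentum * v - learning_rate * grad;
#' w <- w + v`) on the squared prediction error. Features and target are
#' min-max scaled to `[0, 1]` on the training data; after every epoch the
#' training mean squared error is recorded on the original uM scale, and
#' training stops at the earlier of `max_epochs` or the epoch whose MSE first
#' reaches `target_mse`.
#'
#' Two batch schemes are provided. `"incremental"` (the default, and the
#' classic backpropagation convention) updates the weights after every
#' pattern, visiting the training patterns in a freshly shuffled order each
#' epoch; the shuffle is driven by `seed`, so the fit is fully deterministic.
#' `"full"` performs one update per epoch on the full-batch gradient; it is
#' smoother (monotone at small learning rates) but converges far too slowly
#' to reach typical targets within a 1000-epoch budget.
#'
#' @param x numeric matrix (or data frame) of features, one row per image.
#' @param y numeric vector of true concentrations in uM.
#' @param hidden number of hidden neurons.
#' @param learning_rate,momentum gradient-descent step size and momentum
#'   factor, both in `[0, 1]` (`learning_rate = 0` is allowed and performs no
#'   updates).
#' @param max_epochs maximum number of training epochs (full passes).
#' @param target_mse early-stopping threshold on the training MSE, uM^2.
#' @param init_scale half-width of the uniform weight initialization.
#' @param seed integer seed for weight initialization and pattern shuffling
#'   (mandatory).
#' @param batch `"incremental"` (per-pattern updates) or `"full"`
#'   (one full-batch update per epoch).
#' @return An object of class `bpann`: a list with the fitted `state`, the
#'   per-epoch `trace` (training MSE, uM^2), `epoch_reached_target` (NA if the
#'   budget ran out first), `config`, `fitted.values` and `call`. Supports
#'   `predict`, `print`, `summary`, `coef`, `fitted`, `residuals`, `plot`.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(runif(60 * 9), 60, 9)
#' y <- 2 * x[, 1] + rnorm(60, 0, 0.05)
#' fit <- bpann(x, y, max_epochs = 200, seed = 42)
#' fit
bpann <- function(x, y, hidden = 18, learning_rate = 0.1, momentum = 0.1,
                  max_epochs = 1000, target_mse = 0.07, init_scale = 0.5,
                  seed, batch = c("incremental", "full")) {
  if (missing(seed)) stop("an explicit seed is required")
  batch <- match.arg(batch)
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("x and y sizes disagree")
  if (nrow(X) < 2) stop("need at least two training samples")
  stopifnot(learning_rate >= 0, learning_rate <= 1,
            momentum >= 0, momentum <= 1, max_epochs >= 1)
  if (max(y) == min(y))
    stop("target has zero variance; the target scaler is undefined")

  state <- bpann_init(ncol(X), hidden, 1, init_scale, seed)
  state$x_min <- apply(X, 2, min)
  state$x_range <- apply(X, 2, max) - state$x_min
  state$x_range[state$x_range == 0] <- 1   # constant feature maps to 0
  state$y_min <- min(y)
  state$y_range <- max(y) - min(y)
  state$fitted_scalers <- TRUE

  Xs <- scale_x(state, X)
  ys <- (y - state$y_min) / state$y_range
  n <- nrow(Xs)

  # local copies for the hot loop
  W1 <- state$W1; b1 <- state$b1
  w2 <- as.vector(state$W2); b2 <- state$b2[1]
  vW1 <- state$vW1; vb1 <- state$vb1
  vw2 <- as.vector(state$vW2); vb2 <- state$vb2[1]
  lr <- learning_rate; mom <- momentum

  trace <- numeric(max_epochs)
  reached <- NA_integer_
  n_epochs <- 0L
  with_preserved_rng({
    set.seed(as.integer(seed))
    for (epoch in seq_len(max_epochs)) {
      if (batch == "incremental") {
        ord <- sample.int(n)
        for (i in ord) {
          xi <- Xs[i, ]
          h <- 1 / (1 + exp(-(as.vector(W1 %*% xi) + b1)))
          dpred <- 2 * (sum(w2 * h) + b2 - ys[i])
          dh <- dpred * w2 * h * (1 - h)
          vw2 <- mom * vw2 - lr * dpred * h
          vb2 <- mom * vb2 - lr * dpred
          vW1 <- mom * vW1 - lr * outer(dh, xi)
          vb1 <- mom * vb1 - lr * dh
          w2 <- w2 + vw2; b2 <- b2 + vb2
          W1 <- W1 + vW1; b1 <- b1 + vb1
        }
      } else {
        st <- list(W1 = W1, b1 = b1, W2 = matrix(w2, 1), b2 = b2)
        g <- bpann_gradient(st, Xs, ys)
        vW1 <- mom * vW1 - lr * g$gW1
        vb1 <- mom * vb1 - lr * g$gb1
        vw2 <- mom * vw2 - lr * as.vector(g$gW2)
        vb2 <- mom * vb2 - lr * g$gb2
        W1 <- W1 + vW1; b1 <- b1 + vb1
        w2 <- w2 + vw2; b2 <- b2 + vb2
      }
      H <- 1 / (1 + exp(-sweep(Xs %*% t(W1), 2, b1, "+")))
      mse_scaled <- mean((as.vector(H %*% w2) + b2 - ys)^2)
      trace[epoch] <- mse_scaled * state$y_range^2
      n_epochs <- epoch
      if (trace[epoch] <= target_mse) {
        reached <- epoch
        break
      }
    }
  })
  trace <- trace[seq_len(n_epochs)]
  state$W1 <- W1; state$b1 <- b1
  state$W2 <- matrix(w2, 1); state$b2 <- b2
  state$vW1 <- vW1; state$vb1 <- vb1
  state$vW2 <- matrix(vw2, 1); state$vb2 <- vb2

  fit <- structure(list(
    state = state,
    trace = trace,
    epoch_reached_target = reached,
    config = list(n_input = ncol(X), n_hidden = hidden, n_output = 1,
                  learning_rate = learning_rate, momentum = momentum,
                  max_epochs = max_epochs, target_mse = target_mse,
                  init_scale = init_scale, seed = seed, batch = batch),
    y = y,
    call = match.call()
  ), class = "bpann")
  fit$fitted.values <- predict(fit, X)
  fit
}

#' Predict concentrations from a fitted network
#'
#' @param object a [bpann()] fit.
#' @param newdata feature matrix/data frame (rows = images) or a single
#'   feature vector. Omitted: returns fitted values.
#' @param ... unused.
#' @return Numeric vector of predicted concentrations (uM), one per row,
#'   order-preserving; an empty input gives an empty vector.
#' @export
predict.bpann <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  X <- if (is.null(dim(newdata))) matrix(as.numeric(newdata), nrow = 1)
       else as.matrix(newdata)
  storage.mode(X) <- "double"
  if (nrow(X) == 0) return(numeric(0))
  bpann_forward(object$state, X)
}

#' @export
print.bpann <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Backpropagation network regressor (%d-%d-%d)\n",
              cfg$n_input, cfg$n_hidden, cfg$n_output))
  cat(sprintf("  epochs run: %d (target MSE %.4g uM^2 %s)\n",
              length(x$trace), cfg$target_mse,
              if (is.na(x$epoch_reached_target)) "not reached"
              else sprintf("reached at epoch %d", x$epoch_reached_target)))
  cat(sprintf("  final training MSE: %.4f uM^2\n", tail_trace(x)))
  invisible(x)
}

tail_trace <- function(fit) fit$trace[length(fit$trace)]

#' @export
summary.bpann <- function(object, ...) {
  out <- list(
    config = object$config,
    epochs = length(object$trace),
    epoch_reached_target = object$epoch_reached_target,
    final_mse = tail_trace(object),
    evaluation = evaluate_predictions(fitted(object), object$y)
  )
  class(out) <- "summary.bpann"
  out
}

#' @export
print.summary.bpann <- function(x, ...) {
  cat(sprintf("Backpropagation network regressor (%d-%d-%d)\n",
              x$config$n_input, x$config$n_hidden, x$config$n_output))
  cat(sprintf("  learning rate %.3g, momentum %.3g, %d/%d epochs\n",
              x$config$learning_rate, x$config$momentum, x$epochs,
              x$config$max_epochs))
  cat(sprintf("  training MSE %.4f uM^2%s\n", x$final_mse,
              if (is.na(x$epoch_reached_target)) ""
              else sprintf(" (target reached at epoch %d)",
                           x$epoch_reached_target)))
  cat("Training-set fit:\n")
  print(x$evaluation)
  invisible(x)
}

#' @export
coef.bpann <- function(object, ...) {
  s <- object$state
  list(W1 = s$W1, b1 = s$b1, W2 = s$W2, b2 = s$b2)
}

#' @export
fitted.bpann <- function(object, ...) object$fitted.values

#' @export
residuals.bpann <- function(object, ...) object$y - object$fitted.values

#' Training-curve plot
#'
#' Plots the per-epoch training mean squared error (uM^2) on a log scale with
#' the early-stopping target marked.
#'
#' @param x a [bpann()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bpann <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "l", log = "y",
                 xlab = "epoch", ylab = expression(MSE ~ (mu * M^2)),
                 main = "Training curve", ...)
  graphics::abline(h = x$config$target_mse, lty = 2, col = "grey40")
  invisible(x)
}

#' Persist and restore a fitted network
#'
#' The model is written as a JSON document holding the layer shapes, weights,
#' scalers, training configuration and trace at full floating-point precision,
#' so that a reloaded model reproduces predictions bit-for-bit.
#'
#' @param fit a [bpann()] model.
#' @param path output file.
#' @return `write_bpann` returns `path` invisibly; `read_bpann` the model.
#' @export
write_bpann <- function(fit, path) {
  stopifnot(inherits(fit, "bpann"))
  s <- fit$state
  doc <- list(
    shapes = list(n_input = ncol(s$W1), n_hidden = nrow(s$W1), n_output = 1),
    W1 = s$W1, b1 = s$b1, W2 = s$W2, b2 = s$b2,
    x_min = s$x_min, x_range = s$x_range,
    y_min = s$y_min, y_range = s$y_range,
    config = fit$config,
    trace = fit$trace,
    epoch_reached_target = fit$epoch_reached_target
  )
  # I(17) = 17 *significant* digits: lossless for IEEE-754 doubles
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' @rdname write_bpann
#' @export
read_bpann <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sh <- doc$shapes
  state <- list(
    W1 = matrix(as.numeric(doc$W1), sh$n_hidden, sh$n_input),
    b1 = as.numeric(doc$b1),
    W2 = matrix(as.numeric(doc$W2), sh$n_output, sh$n_hidden),
    b2 = as.numeric(doc$b2),
    vW1 = matrix(0, sh$n_hidden, sh$n_input), vb1 = numeric(sh$n_hidden),
    vW2 = matrix(0, sh$n_output, sh$n_hidden), vb2 = numeric(sh$n_output),
    x_min = as.numeric(doc$x_min), x_range = as.numeric(doc$x_range),
    y_min = doc$y_min, y_range = doc$y_range, fitted_scalers = TRUE
  )
  class(state) <- "bpann_state"
  fit <- structure(list(
    state = state,
    trace = as.numeric(doc$trace),
    epoch_reached_target = if (is.null(doc$epoch_reached_target))
      NA_integer_ else doc$epoch_reached_target,
    config = doc$config,
    y = NULL, fitted.values = NULL,
    call = quote(read_bpann())
  ), class = "bpann")
  fit
}
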