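test_that("initialization is seeded, bounded, and correctly shaped", {
  s1 <- bpann_init(seed = 5)
  s2 <- bpann_init(seed = 5)
  expect_identical(s1$W1, s2$W1)
  expect_identical(s1$W2, s2$W2)
  expect_equal(dim(s1$W1), c(18, 9))
  expect_equal(dim(s1$W2), c(1, 18))
  expect_true(all(abs(s1$W1) <= 0.5) && all(abs(s1$W2) <= 0.5))
  expect_true(all(s1$b1 == 0) && all(s1$b2 == 0))
  expect_false(identical(s1$W1, bpann_init(seed = 6)$W1))

  z <- bpann_init(init_scale = 0, seed = 1)
  expect_true(all(z$W1 == 0) && all(z$W2 == 0))
  expect_error(bpann_init(), "seed")
})

test_that("forward pass follows the sigmoid-linear contract", {
  z <- bpann_init(init_scale = 0, seed = 1)
  expect_equal(bpann_forward(z, runif(9)), 0)

  # zero W1 and b1: hidden activations are all 0.5
  s <- bpann_init(seed = 3)
  s$W1[] <- 0; s$b1[] <- 0
  x <- runif(9)
  expect_equal(bpann_forward(s, x), 0.5 * sum(s$W2) + s$b2[1],
               tolerance = 1e-12)

  expect_equal(bpann_forward(s, x), bpann_forward(s, x))
  expect_error(bpann_forward(s, runif(5)), "expected 9 features")
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  state <- bpann_init(n_input = 4, n_hidden = 3, init_scale = 0.8, seed = 19)
  state$b1 <- rnorm(3, 0, 0.3)
  state$b2 <- rnorm(1, 0, 0.3)
  X <- matrix(runif(12), 3, 4)   # the 3-sample probe
  y <- runif(3)
  g <- aptacolor:::bpann_gradient(state, X, y)

  mse_at <- function(st) {
    fw <- aptacolor:::forward_scaled(st, X)
    mean((fw$pred[, 1] - y)^2)
  }
  h <- 1e-6
  check <- function(field, analytic) {
    num <- analytic
    for (i in seq_along(analytic)) {
      sp <- state; sm <- state
      sp[[field]][i] <- sp[[field]][i] + h
      sm[[field]][i] <- sm[[field]][i] - h
      num[i] <- (mse_at(sp) - mse_at(sm)) / (2 * h)
    }
    expect_equal(as.vector(analytic), as.vector(num), tolerance = 1e-5)
  }
  check("W1", g$gW1)
  check("b1", g$gb1)
  check("W2", g$gW2)
  check("b2", g$gb2)
})

test_that("training degenerates correctly at the edges", {
  set.seed(2)
  X <- matrix(runif(40 * 9), 40, 9)
  y <- rowSums(X[, 1:2])

  # zero learning rate: weights never move
  f0 <- bpann(X, y, learning_rate = 0, max_epochs = 5, seed = 8)
  init <- bpann_init(seed = 8)
  expect_equal(f0$state$W1, init$W1)
  expect_equal(f0$state$W2, init$W2)

  # a tiny training set is memorized to arbitrary precision
  f1 <- bpann(matrix(runif(18), 2, 9), c(0.4, 2.2), max_epochs = 2000,
              target_mse = 1e-10, seed = 4)
  expect_lt(f1$trace[length(f1$trace)], 1e-8)

  expect_error(bpann(X, rep(1, 40), seed = 1), "zero variance")
  expect_error(bpann(X, y), "seed")
})

test_that("training is reproducible and the trace drives early stopping", {
  set.seed(3)
  X <- matrix(runif(60 * 9), 60, 9)
  y <- 3 * X[, 1] + 0.5 * X[, 5]
  a <- bpann(X, y, max_epochs = 50, target_mse = 0.01, seed = 12)
  b <- bpann(X, y, max_epochs = 50, target_mse = 0.01, seed = 12)
  expect_identical(a$state$W1, b$state$W1)
  expect_identical(a$trace, b$trace)
  if (!is.na(a$epoch_reached_target)) {
    expect_equal(a$epoch_reached_target, length(a$trace))
    expect_lte(a$trace[length(a$trace)], 0.01)
    expect_true(all(a$trace[-length(a$trace)] > 0.01))
  }
  expect_lte(length(a$trace), 50)
})

test_that("full-batch training MSE is non-increasing at a small learning rate", {
  set.seed(9)
  X <- matrix(runif(50 * 9), 50, 9)
  y <- 2 * X[, 2] - X[, 7]
  fit <- bpann(X, y, learning_rate = 0.01, momentum = 0, max_epochs = 200,
               target_mse = 0, seed = 6, batch = "full")
  expect_true(all(diff(fit$trace) <= 1e-12))
})

test_that("prediction is vectorized, order-preserving, and batch-consistent", {
  set.seed(5)
  X <- matrix(runif(30 * 9), 30, 9)
  y <- rowSums(X)
  fit <- bpann(X, y, max_epochs = 20, seed = 2)

  expect_identical(predict(fit, X[0, , drop = FALSE]), numeric(0))
  expect_equal(predict(fit, X[3, ]), predict(fit, X)[3])
  perm <- sample(30)
  expect_equal(predict(fit, X[perm, ]), predict(fit, X)[perm])
  expect_length(residuals(fit), 30)
  expect_equal(fitted(fit) + residuals(fit), y)
})

test_that("models round-trip through JSON with bit-identical predictions", {
  set.seed(11)
  X <- matrix(runif(25 * 9), 25, 9)
  y <- X[, 1] * 2 + 0.3
  fit <- bpann(X, y, max_epochs = 30, seed = 14)
  path <- withr::local_tempfile(fileext = ".json")
  write_bpann(fit, path)
  back <- read_bpann(path)
  expect_identical(predict(back, X), predict(fit, X))
  expect_equal(back$trace, fit$trace)
  expect_equal(back$config$n_hidden, fit$config$n_hidden)
})
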