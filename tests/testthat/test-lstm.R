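# LSTM regressor: cell equations, stacked forward pass, training backend.

# Scalar-loop oracle for one cell update: every gate written as an explicit
# double loop over units and inputs, independent of the vectorized path.
cell_oracle <- function(x_t, state_prev, p) {
  H <- p$hidden_size
  v <- c(state_prev$h, x_t)
  gate <- function(W, b, act) {
    out <- numeric(H)
    for (u in seq_len(H)) {
      acc <- b[u]
      for (j in seq_along(v)) acc <- acc + W[u, j] * v[j]
      out[u] <- act(acc)
    }
    out
  }
  sig <- function(z) 1 / (1 + exp(-z))
  f <- gate(p$W_f, p$b_f, sig)
  i <- gate(p$W_i, p$b_i, sig)
  o <- gate(p$W_o, p$b_o, sig)
  g <- gate(p$W_c, p$b_c, tanh)
  C_t <- numeric(H)
  h_t <- numeric(H)
  for (u in seq_len(H)) {
    C_t[u] <- f[u] * state_prev$C[u] + i[u] * g[u]
    h_t[u] <- o[u] * tanh(C_t[u])
  }
  list(h = h_t, C = C_t)
}

zero_params <- function(input = 1, hidden = 1) {
  p <- lstm_layer_params(input, hidden)
  for (nm in c("W_f", "W_i", "W_o", "W_c")) p[[nm]][] <- 0
  for (nm in c("b_f", "b_i", "b_o", "b_c")) p[[nm]][] <- 0
  p
}

test_that("cell step reproduces the hand-computed zero-weight case", {
  # all weights and biases zero, C_prev = 2: every gate is sigma(0) = 0.5,
  # the candidate is tanh(0) = 0, so C_t = 0.5 * 2 = 1 and
  # h_t = 0.5 * tanh(1) ~ 0.380797
  st <- lstm_cell_step(0, list(h = 0, C = 2), zero_params())
  expect_equal(st$C, 1)
  expect_equal(st$h, 0.5 * tanh(1), tolerance = 1e-12)
})

test_that("a saturated forget gate preserves the cell state", {
  p <- zero_params()
  p$b_f[] <- 50   # sigma(50) ~ 1
  set.seed(50)
  C_prev <- 3.7
  st <- lstm_cell_step(1.2, list(h = 0.4, C = C_prev), p)
  # with zero W_i/W_c, candidate = 0, so C_t -> C_prev exactly
  expect_equal(st$C, C_prev, tolerance = 1e-12)
})

test_that("vectorized cell step matches the scalar-loop oracle", {
  set.seed(51)
  for (i in 1:1000) {
    H <- sample(1:4, 1)
    D <- sample(1:3, 1)
    p <- lstm_layer_params(D, H)
    x <- rnorm(D)
    s0 <- list(h = rnorm(H), C = rnorm(H))
    got <- lstm_cell_step(x, s0, p)
    want <- cell_oracle(x, s0, p)
    expect_equal(drop(got$h), want$h, tolerance = 1e-10)
    expect_equal(drop(got$C), want$C, tolerance = 1e-10)
  }
})

test_that("gates are bounded and hidden outputs stay inside (-1, 1)", {
  set.seed(52)
  for (i in 1:50) {
    p <- lstm_layer_params(3, 5)
    st <- list(h = rnorm(5, sd = 5), C = rnorm(5, sd = 5))
    out <- lstm_cell_step(rnorm(3, sd = 10), st, p)
    expect_true(all(abs(out$h) < 1))
    expect_true(all(is.finite(out$C)))
  }
})

test_that("analytic cell gradient agrees with numerical differentiation", {
  set.seed(53)
  p <- lstm_layer_params(2, 3)
  x <- rnorm(2)
  s0 <- list(h = rnorm(3), C = rnorm(3))
  tgt <- rnorm(3)
  g <- lstm_cell_gradient(x, s0, p, tgt)
  lossf <- function(pp) {
    h <- lstm_cell_step(x, s0, pp)$h
    0.5 * sum((h - tgt)^2)
  }
  eps <- 1e-6
  for (nm in c("W_f", "W_i", "W_o", "W_c", "b_f", "b_i", "b_o", "b_c")) {
    num <- p[[nm]]
    for (k in seq_along(num)) {
      pp <- p; pp[[nm]][k] <- pp[[nm]][k] + eps
      pm <- p; pm[[nm]][k] <- pm[[nm]][k] - eps
      num[k] <- (lossf(pp) - lossf(pm)) / (2 * eps)
    }
    expect_equal(as.vector(g[[nm]]), as.vector(num), tolerance = 1e-5)
  }
})

test_that("stacked forward pass: head bias, determinism, dropout contract", {
  set.seed(54)
  layers <- list(lstm_layer_params(3, 6), lstm_layer_params(6, 6))
  head <- list(W = matrix(0, 2, 6), b = c(0.3, -0.2))
  X <- matrix(rnorm(3 * 40), 3, 40)
  out <- lstm_forward(X, layers, head)
  expect_equal(out, matrix(c(0.3, -0.2), 2, 40), tolerance = 1e-12)
  # eval mode is deterministic and draws nothing from the RNG
  head$W <- matrix(rnorm(12), 2, 6)
  seed_before <- .Random.seed
  o1 <- lstm_forward(X, layers, head, dropout_p = 0.5, mode = "eval")
  expect_identical(seed_before, .Random.seed)
  o2 <- lstm_forward(X, layers, head, dropout_p = 0.5, mode = "eval")
  expect_identical(o1, o2)
  # train mode with p = 0 equals eval mode
  o3 <- lstm_forward(X, layers, head, dropout_p = 0, mode = "train")
  expect_identical(o1, o3)
})

test_that("compiled forward pass agrees with the R reference", {
  set.seed(55)
  layers <- list(lstm_layer_params(5, 9), lstm_layer_params(9, 9))
  head <- list(W = matrix(rnorm(18), 2, 9), b = rnorm(2))
  X <- matrix(rnorm(5 * 120), 5, 120)
  ref <- lstm_forward(X, layers, head)
  pk <- lapply(layers, emgkin:::pack_layer)
  got <- emgkin:::cpp_lstm_forward(lapply(pk, `[[`, "W"),
                                   lapply(pk, `[[`, "b"),
                                   head$W, head$b, array(X, c(5, 120, 1)))
  # the backend computes in single precision
  expect_equal(matrix(got, 2, 120), ref, tolerance = 1e-4)
})

test_that("training learns a constant target and reproduces its trace", {
  set.seed(56)
  X <- matrix(runif(5 * 100 * 100), 5, 10000)
  Y <- matrix(0.5, 2, 10000)
  cfg <- model_config(n_layers = 2, hidden = 8, max_epochs = 30,
                      seq_len = 100, seed = 2)
  m <- train_lstm(X, Y, cfg)
  expect_lt(tail(m$loss_trace, 1), 1e-3)
  m2 <- train_lstm(X, Y, cfg)
  expect_identical(m$loss_trace, m2$loss_trace)
  expect_identical(m$head, m2$head)
  p <- predict(m, X)
  expect_identical(dim(p), c(2L, 10000L))
  expect_equal(mean(p), 0.5, tolerance = 0.05)
})

test_that("training loss is non-increasing in most epoch transitions", {
  # Adam is not monotone; require >= 90% decreasing transitions on a
  # smoothly learnable sequence task
  set.seed(57)
  tt <- seq(0, 2 * pi, length.out = 200)
  X <- do.call(cbind, lapply(1:20, function(i) {
    rbind(sin(tt + i / 10), cos(tt), sin(2 * tt), cos(3 * tt),
          runif(200)) * 0.5 + 0.5
  }))
  Y <- rbind(X[1, ] * 0.8 + 0.1, 1 - X[1, ] * 0.6)
  cfg <- model_config(n_layers = 2, hidden = 16, max_epochs = 25,
                      seq_len = 200, seed = 3)
  m <- train_lstm(X, Y, cfg)
  frac_dec <- mean(diff(m$loss_trace) <= 0)
  expect_gte(frac_dec, 0.9)
  expect_error(train_lstm(X * NA, Y, cfg), "finite")
})
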