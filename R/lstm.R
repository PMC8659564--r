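# LSTM sequence regressor, written from the gate equations up. The R
# functions here are the reference implementation (used directly for small
# inputs and verification); training and bulk prediction run through the
# RcppArmadillo backend, which is checked against this path in the tests.

#' Regressor configuration
#'
#' The `"desk"` profile (2 stacked layers x 32 units, 30 epochs) is the
#' default and is sized so that a full leave-one-subject-out experiment runs
#' on one CPU core in minutes; the `"full"` profile (10 x 200, 200 epochs)
#' is the full-scale deep architecture for GPU-class runs.
#'
#' @param profile `"desk"` or `"full"`; sets defaults for `n_layers`,
#'   `hidden` and `max_epochs` which the explicit arguments override.
#' @param n_layers Number of stacked recurrent layers.
#' @param hidden Units per layer.
#' @param dropout_p Dropout probability on inter-layer hidden sequences
#'   (training mode only; never inside the cell recurrence).
#' @param lr Adam learning rate.
#' @param max_epochs Training epochs.
#' @param batch_size Sequences per minibatch.
#' @param seq_len Points per training sequence; the design matrix is chunked
#'   into cycle-length sequences and the state is reset at cycle boundaries.
#' @param optimizer Only `"adam"` is implemented.
#' @param beta1,beta2,eps Adam moment decays and stabilizer.
#' @param input_dim,output_dim Network input/output widths.
#' @param seed Seed for weight initialization, shuffling and dropout.
#' @return List of class `model_config`.
#' @export
model_config <- function(profile = c("desk", "full"),
                         n_layers = NULL, hidden = NULL, dropout_p = 0.2,
                         lr = 0.005, max_epochs = NULL, batch_size = 8L,
                         seq_len = 1000L, optimizer = "adam",
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         input_dim = 5L, output_dim = 2L, seed = 1L) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    desk  = list(n_layers = 2L, hidden = 32L, max_epochs = 30L),
    full  = list(n_layers = 10L, hidden = 200L, max_epochs = 200L)
  )
  stopifnot(dropout_p >= 0, dropout_p < 1, lr > 0)
  if (!identical(optimizer, "adam")) {
    stop("optimizer must be 'adam'", call. = FALSE)
  }
  structure(list(
    profile = profile,
    n_layers = as.integer(n_layers %||% defaults$n_layers),
    hidden = as.integer(hidden %||% defaults$hidden),
    dropout_p = dropout_p, lr = lr,
    max_epochs = as.integer(max_epochs %||% defaults$max_epochs),
    batch_size = as.integer(batch_size), seq_len = as.integer(seq_len),
    optimizer = optimizer, beta1 = beta1, beta2 = beta2, eps = eps,
    input_dim = as.integer(input_dim), output_dim = as.integer(output_dim),
    seed = as.integer(seed)
  ), class = "model_config")
}

#' Initialize one LSTM layer's parameters
#'
#' Weight matrices `W_f`, `W_i`, `W_o`, `W_c` act on the concatenated
#' `[h_{t-1}, x_t]` vector (hidden part first); entries are drawn uniformly
#' from `[-1/sqrt(hidden), 1/sqrt(hidden)]` using the current RNG stream.
#' The forget-gate bias starts at 1 so early training does not erase the
#' cell state.
#'
#' @param input_size,hidden_size Layer dimensions.
#' @return List of class `lstm_layer_params`.
#' @export
lstm_layer_params <- function(input_size, hidden_size) {
  H <- as.integer(hidden_size)
  D <- as.integer(input_size)
  r <- 1 / sqrt(H)
  w <- function() matrix(runif(H * (H + D), -r, r), H, H + D)
  structure(list(
    W_f = w(), W_i = w(), W_o = w(), W_c = w(),
    b_f = rep(1, H), b_i = numeric(H), b_o = numeric(H), b_c = numeric(H),
    hidden_size = H, input_size = D
  ), class = "lstm_layer_params")
}

#' One LSTM cell update
#'
#' Implements the gate equations: sigmoid forget, input and output gates on
#' `[h_{t-1}, x_t]`, a tanh candidate, cell state
#' `C_t = f (*) C_{t-1} + i (*) tanh(W_c [h_{t-1}, x_t] + b_c)` and hidden
#' output `h_t = o (*) tanh(C_t)` (all products elementwise). Accepts a
#' single input vector or a `D x B` matrix batch (state shaped to match).
#'
#' @param x_t Input vector (length D) or `D x B` matrix.
#' @param state_prev List with `h` and `C` (vector of length H or `H x B`
#'   matrix).
#' @param p An [lstm_layer_params()] object.
#' @return List with updated `h` and `C`.
#' @export
lstm_cell_step <- function(x_t, state_prev, p) {
  v <- if (is.matrix(x_t)) rbind(state_prev$h, x_t) else c(state_prev$h, x_t)
  f <- sigmoid(p$W_f %*% v + p$b_f)
  i <- sigmoid(p$W_i %*% v + p$b_i)
  o <- sigmoid(p$W_o %*% v + p$b_o)
  g <- tanh(p$W_c %*% v + p$b_c)
  C_t <- f * state_prev$C + i * g
  h_t <- o * tanh(C_t)
  if (!is.matrix(x_t)) {
    C_t <- drop(C_t)
    h_t <- drop(h_t)
  }
  list(h = h_t, C = C_t)
}

#' Run a stacked LSTM over one sequence (reference implementation)
#'
#' Initial hidden and cell states are zero; layer l consumes layer l-1's
#' hidden sequence; in training mode, inverted dropout is applied to the
#' hidden sequences between layers (never to the top layer's output or
#' inside the recurrence). The linear head maps each time step's top hidden
#' vector to the output. Evaluation mode draws no random numbers and is
#' deterministic.
#'
#' @param sequence `input_dim x L` matrix.
#' @param layers List of [lstm_layer_params()] whose dimensions chain.
#' @param head List with `W` (`output_dim x hidden`) and `b`.
#' @param dropout_p Dropout probability (used in `"train"` mode only).
#' @param mode `"eval"` or `"train"`.
#' @return `output_dim x L` matrix.
#' @export
lstm_forward <- function(sequence, layers, head, dropout_p = 0,
                         mode = c("eval", "train")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(sequence))
  L <- ncol(sequence)
  x <- sequence
  n_layers <- length(layers)
  for (li in seq_len(n_layers)) {
    p <- layers[[li]]
    H <- p$hidden_size
    state <- list(h = numeric(H), C = numeric(H))
    out <- matrix(0, H, L)
    for (t in seq_len(L)) {
      state <- lstm_cell_step(x[, t], state, p)
      out[, t] <- state$h
    }
    if (mode == "train" && dropout_p > 0 && li < n_layers) {
      keep <- 1 - dropout_p
      mask <- matrix((runif(H * L) < keep) / keep, H, L)
      out <- out * mask
    }
    x <- out
  }
  head$W %*% x + head$b
}

# Pack a layer's four weight matrices into the backend's 4H x (H+D) block
# layout (row blocks f, i, g=c, o) and back.
pack_layer <- function(p) {
  list(W = rbind(p$W_f, p$W_i, p$W_c, p$W_o),
       b = c(p$b_f, p$b_i, p$b_c, p$b_o))
}

unpack_layer <- function(W, b, p) {
  H <- p$hidden_size
  p$W_f <- W[1:H, , drop = FALSE]
  p$W_i <- W[(H + 1):(2 * H), , drop = FALSE]
  p$W_c <- W[(2 * H + 1):(3 * H), , drop = FALSE]
  p$W_o <- W[(3 * H + 1):(4 * H), , drop = FALSE]
  p$b_f <- b[1:H]
  p$b_i <- b[(H + 1):(2 * H)]
  p$b_c <- b[(2 * H + 1):(3 * H)]
  p$b_o <- b[(3 * H + 1):(4 * H)]
  p
}

# Chunk a channels x M matrix into an array (channels, seq_len, n_seq).
chunk_sequences <- function(x, seq_len) {
  M <- ncol(x)
  if (M %% seq_len != 0) {
    stop("column count ", M, " is not a multiple of the sequence length ",
         seq_len, call. = FALSE)
  }
  array(x, dim = c(nrow(x), seq_len, M / seq_len))
}

#' Train the LSTM regressor
#'
#' Minimizes mean-squared error between the network output and the
#' normalized targets with Adam, treating each `seq_len`-point cycle as one
#' training sequence (state reset at cycle boundaries). Training runs in the
#' compiled backend; weights, shuffling and dropout all derive from
#' `cfg$seed`, so a configuration reproduces its loss trace exactly.
#'
#' @param features `input_dim x M` matrix of normalized, lag-aligned
#'   envelope features.
#' @param targets `output_dim x M` matrix of normalized joint angles.
#' @param cfg A [model_config()].
#' @return An `lstm_model`: layer parameters, head, config and the
#'   per-epoch training loss trace.
#' @export
train_lstm <- function(features, targets, cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"),
            is.matrix(features), is.matrix(targets),
            ncol(features) == ncol(targets),
            nrow(features) == cfg$input_dim,
            nrow(targets) == cfg$output_dim)
  if (!all(is.finite(features)) || !all(is.finite(targets))) {
    stop("features/targets must be finite", call. = FALSE)
  }
  X <- chunk_sequences(features, cfg$seq_len)
  Y <- chunk_sequences(targets, cfg$seq_len)
  init <- with_seed(cfg$seed, {
    layers <- vector("list", cfg$n_layers)
    for (li in seq_len(cfg$n_layers)) {
      din <- if (li == 1L) cfg$input_dim else cfg$hidden
      layers[[li]] <- lstm_layer_params(din, cfg$hidden)
    }
    r <- 1 / sqrt(cfg$hidden)
    list(layers = layers,
         head = list(W = matrix(runif(cfg$output_dim * cfg$hidden, -r, r),
                                cfg$output_dim, cfg$hidden),
                     b = numeric(cfg$output_dim)))
  })
  layers <- init$layers
  head <- init$head
  packed <- lapply(layers, pack_layer)
  fit <- cpp_lstm_train(
    lapply(packed, `[[`, "W"), lapply(packed, `[[`, "b"),
    head$W, head$b, X, Y,
    cfg$lr, cfg$max_epochs, cfg$dropout_p, cfg$batch_size,
    cfg$seed, cfg$beta1, cfg$beta2, cfg$eps
  )
  if (fit$diverged >= 0) {
    stop("training diverged (non-finite loss) at epoch ", fit$diverged + 1L,
         call. = FALSE)
  }
  for (li in seq_len(cfg$n_layers)) {
    layers[[li]] <- unpack_layer(fit$W[[li]], drop(fit$b[[li]]), layers[[li]])
  }
  structure(list(
    layers = layers,
    head = list(W = fit$W_out, b = drop(fit$b_out)),
    cfg = cfg, loss_trace = drop(fit$loss)
  ), class = "lstm_model")
}

#' Predict joint-angle series with a trained LSTM
#'
#' @param object An `lstm_model`.
#' @param features `input_dim x M` matrix (M a multiple of the training
#'   sequence length); each cycle is decoded independently.
#' @param chunk Sequences decoded per backend call (memory control).
#' @param ... Unused.
#' @return `output_dim x M` matrix of normalized predictions.
#' @export
predict.lstm_model <- function(object, features, chunk = 64L, ...) {
  cfg <- object$cfg
  X <- chunk_sequences(features, cfg$seq_len)
  packed <- lapply(object$layers, pack_layer)
  S <- dim(X)[3]
  out <- matrix(0, cfg$output_dim, ncol(features))
  for (grp in split(seq_len(S), ceiling(seq_len(S) / chunk))) {
    Yp <- cpp_lstm_forward(
      lapply(packed, `[[`, "W"), lapply(packed, `[[`, "b"),
      object$head$W, object$head$b,
      X[, , grp, drop = FALSE]
    )
    cols <- as.vector(vapply(grp, function(s) {
      ((s - 1L) * cfg$seq_len + 1L):(s * cfg$seq_len)
    }, integer(cfg$seq_len)))
    out[, cols] <- matrix(Yp, cfg$output_dim, length(cols))
  }
  rownames(out) <- JOINTS[seq_len(min(cfg$output_dim, length(JOINTS)))]
  out
}

#' Analytic gradient of a single-cell squared-error loss
#'
#' Backpropagates the loss `0.5 * ||h_t - target||^2` of one
#' [lstm_cell_step()] through the gate equations, returning gradients for
#' every weight matrix and bias plus the previous state. Written for
#' verification against numerical differentiation.
#'
#' @param x_t Input vector.
#' @param state_prev List with `h`, `C`.
#' @param p An [lstm_layer_params()].
#' @param target Target vector for `h_t`.
#' @return List of gradients named like the parameters.
#' @export
lstm_cell_gradient <- function(x_t, state_prev, p, target) {
  v <- c(state_prev$h, x_t)
  af <- drop(p$W_f %*% v + p$b_f)
  ai <- drop(p$W_i %*% v + p$b_i)
  ao <- drop(p$W_o %*% v + p$b_o)
  ac <- drop(p$W_c %*% v + p$b_c)
  f <- sigmoid(af); i <- sigmoid(ai); o <- sigmoid(ao); g <- tanh(ac)
  C_t <- f * state_prev$C + i * g
  tc <- tanh(C_t)
  h_t <- o * tc

  dh <- h_t - target
  do_ <- dh * tc
  dC <- dh * o * (1 - tc^2)
  df <- dC * state_prev$C
  di <- dC * g
  dg <- dC * i
  daf <- df * f * (1 - f)
  dai <- di * i * (1 - i)
  dao <- do_ * o * (1 - o)
  dac <- dg * (1 - g^2)
  H <- p$hidden_size
  dv <- drop(t(p$W_f) %*% daf + t(p$W_i) %*% dai +
             t(p$W_o) %*% dao + t(p$W_c) %*% dac)
  list(
    W_f = outer(daf, v), W_i = outer(dai, v),
    W_o = outer(dao, v), W_c = outer(dac, v),
    b_f = daf, b_i = dai, b_o = dao, b_c = dac,
    h_prev = dv[seq_len(H)], x_t = dv[-seq_len(H)],
    C_prev = dC * f
  )
}
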