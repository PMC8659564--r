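# MLP baseline: a stateless per-time-point map from the five envelope
# features to the two joint angles, one tanh hidden layer of 160 units.

#' MLP baseline configuration
#'
#' @param hidden Hidden-layer width.
#' @param lr Adam learning rate.
#' @param max_epochs Training epochs.
#' @param batch_size Time points per minibatch.
#' @param beta1,beta2,eps Adam constants.
#' @param input_dim,output_dim Network widths.
#' @param seed Seed for initialization and shuffling.
#' @return List of class `mlp_config`.
#' @export
mlp_config <- function(hidden = 160L, lr = 0.005, max_epochs = 40L,
                       batch_size = 4096L, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, input_dim = 5L, output_dim = 2L,
                       seed = 1L) {
  structure(list(hidden = as.integer(hidden), lr = lr,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 input_dim = as.integer(input_dim),
                 output_dim = as.integer(output_dim),
                 seed = as.integer(seed)),
            class = "mlp_config")
}

#' Initialize MLP parameters
#'
#' @param input_dim,hidden,output_dim Layer widths.
#' @return List with `W1`, `b1`, `W2`, `b2` (class `mlp_params`), drawn from
#'   the current RNG stream with 1/sqrt(fan-in) uniform scaling.
#' @export
mlp_params <- function(input_dim = 5L, hidden = 160L, output_dim = 2L) {
  r1 <- 1 / sqrt(input_dim)
  r2 <- 1 / sqrt(hidden)
  structure(list(
    W1 = matrix(runif(hidden * input_dim, -r1, r1), hidden, input_dim),
    b1 = numeric(hidden),
    W2 = matrix(runif(output_dim * hidden, -r2, r2), output_dim, hidden),
    b2 = numeric(output_dim)
  ), class = "mlp_params")
}

#' MLP forward pass
#'
#' `linear(input -> hidden) -> tanh -> linear(hidden -> output)`, applied
#' independently to every column (time point): the baseline has no temporal
#' context by construction.
#'
#' @param x `input_dim x M` matrix (or vector of length `input_dim`).
#' @param params An [mlp_params()] object.
#' @return `output_dim x M` matrix.
#' @export
mlp_forward <- function(x, params) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  params$W2 %*% tanh(params$W1 %*% x + params$b1) + params$b2
}

#' Train the MLP baseline
#'
#' Minimizes mean-squared error with minibatch Adam over shuffled time
#' points. Deterministic given `cfg$seed`.
#'
#' @param features `input_dim x M` matrix of normalized features.
#' @param targets `output_dim x M` matrix of normalized targets.
#' @param cfg An [mlp_config()].
#' @return An `mlp_model` with fitted `params`, `cfg` and `loss_trace`.
#' @export
train_mlp <- function(features, targets, cfg = mlp_config()) {
  stopifnot(inherits(cfg, "mlp_config"),
            nrow(features) == cfg$input_dim,
            nrow(targets) == cfg$output_dim,
            ncol(features) == ncol(targets))
  if (!all(is.finite(features)) || !all(is.finite(targets))) {
    stop("features/targets must be finite", call. = FALSE)
  }
  params <- with_seed(cfg$seed,
                      mlp_params(cfg$input_dim, cfg$hidden, cfg$output_dim))
  fit <- cpp_mlp_train(params$W1, params$b1, params$W2, params$b2,
                       features, targets, cfg$lr, cfg$max_epochs,
                       cfg$batch_size, cfg$seed, cfg$beta1, cfg$beta2,
                       cfg$eps)
  if (fit$diverged >= 0) {
    stop("training diverged (non-finite loss) at epoch ", fit$diverged + 1L,
         call. = FALSE)
  }
  params$W1 <- fit$W1
  params$b1 <- drop(fit$b1)
  params$W2 <- fit$W2
  params$b2 <- drop(fit$b2)
  structure(list(params = params, cfg = cfg, loss_trace = drop(fit$loss)),
            class = "mlp_model")
}

#' Predict with a trained MLP
#'
#' @param object An `mlp_model`.
#' @param features `input_dim x M` matrix.
#' @param ... Unused.
#' @return `output_dim x M` matrix of normalized predictions.
#' @export
predict.mlp_model <- function(object, features, ...) {
  out <- mlp_forward(features, object$params)
  rownames(out) <- JOINTS[seq_len(min(nrow(out), length(JOINTS)))]
  out
}
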