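# Three-hidden-layer fully connected binary classifier: ReLU
# activations, inverted dropout on the last hidden layer, a single
# sigmoid output, binary cross-entropy loss, Adam updates.  Sized for
# the 2048-point spectral-vector input (2048 -> 2000 -> 1500 -> 1000
# -> 1).  The minibatch training loop runs in compiled code (see
# src/nn.cpp) drawing all randomness from R's RNG, so fits are pure
# functions of the seed.

#' Neural-network configuration
#'
#' Defaults reproduce the reference architecture: three hidden layers
#' of 2000, 1500 and 1000 rectified-linear units, dropout rate 0.5 on
#' the last hidden layer only, a single sigmoid output trained with
#' cross-entropy loss and the Adam (adaptive momentum) optimizer.
#' The training schedule (learning rate 1e-3, 30 epochs, batch 32) is
#' this package's choice of standard values.  Smaller
#' \code{layer_sizes} give a proportionally faster classifier for
#' large fold grids.
#'
#' @param layer_sizes Integer vector of three hidden-layer widths.
#' @param learning_rate Adam step size.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param dropout Dropout rate on the last hidden layer.
#' @return An object of class \code{wb_nn_config}.
#' @export
nn_config <- function(layer_sizes = c(2000L, 1500L, 1000L),
                      learning_rate = 1e-3,
                      epochs = 30L,
                      batch_size = 32L,
                      dropout = 0.5) {
  if (length(layer_sizes) != 3L || any(layer_sizes < 1))
    stop("exactly three hidden layers required", call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("dropout must lie in [0, 1)", call. = FALSE)
  structure(list(layer_sizes = as.integer(layer_sizes),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 dropout = dropout),
            class = "wb_nn_config")
}

# Train the network.  x: n x p matrix, y: 0/1 (or logical) vector.
nn_fit <- function(x, y, config = nn_config(), seed = 1L) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  y <- as.numeric(y)
  net <- withr::with_seed(seed,
    .nn_fit_cpp(x, y, config$layer_sizes, config$learning_rate,
                config$epochs, config$batch_size, config$dropout))
  net$sizes <- c(ncol(x), config$layer_sizes, 1L)
  net$config <- config
  class(net) <- "wb_nn"
  net
}

nn_predict <- function(net, x) {
  stopifnot(inherits(net, "wb_nn"))
  as.vector(.nn_predict_cpp(net$W, net$b, x))
}
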