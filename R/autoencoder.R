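#' Autoencoder hyperparameters
#'
#' Architecture and optimization settings of the stacked sparse autoencoder
#' used for dimensionality reduction of the per-bin normalized spectra:
#' an encoder of 256/128/64 units (batch normalization + ReLU each), a
#' 32-unit linear latent code, a mirrored decoder, mean-squared-error loss
#' with an L1 sparsity penalty on the code, and Adam.
#'
#' @param encoder_widths Hidden-layer widths of the encoder (decreasing).
#' @param latent Latent code width.
#' @param lambda L1 regularization weight.
#' @param lr,beta1,beta2,eps_adam Adam settings.
#' @param batch Minibatch size.
#' @param epochs Training epochs.
#' @param bn_latent Logical: apply batch normalization + ReLU to the latent
#'   layer like the other encoder layers (`FALSE` keeps a plain linear code).
#' @param seed Integer seed for initialization and shuffling.
#' @return An `autoencoder_config`.
#' @export
autoencoder_config <- function(encoder_widths = c(256, 128, 64), latent = 32,
                               lambda = 1e-5, lr = 1e-3, beta1 = 0.9,
                               beta2 = 0.999, eps_adam = 1e-8, batch = 64,
                               epochs = 300, bn_latent = FALSE, seed = 1L) {
  if (any(encoder_widths <= 0) || latent <= 0) {
    stop("layer widths must be positive", call. = FALSE)
  }
  if (is.unsorted(rev(encoder_widths))) {
    stop("encoder widths must decrease through the encoder", call. = FALSE)
  }
  if (lambda < 0 || lr <= 0) stop("lambda must be >= 0 and lr > 0", call. = FALSE)
  structure(
    list(encoder_widths = as.integer(encoder_widths), latent = as.integer(latent),
         lambda = lambda, lr = lr, beta1 = beta1, beta2 = beta2,
         eps_adam = eps_adam, batch = as.integer(batch),
         epochs = as.integer(epochs), bn_latent = isTRUE(bn_latent),
         seed = as.integer(seed)),
    class = "autoencoder_config"
  )
}

feature_matrix <- function(features) {
  if (inherits(features, "somn_features")) features$X
  else as.matrix(features)
}

#' Train the stacked sparse autoencoder
#'
#' @param features A `somn_features` object from [normalize_mean_psd()] or a
#'   bins x features numeric matrix.
#' @param cfg An [autoencoder_config()].
#' @return A `somn_autoencoder` holding the trained network and the per-epoch
#'   training loss.
#' @export
train_autoencoder <- function(features, cfg = autoencoder_config()) {
  X <- feature_matrix(features)
  if (!all(is.finite(X))) stop("features must be finite", call. = FALSE)
  model <- ae_train_cpp(X, cfg$encoder_widths, cfg$latent, cfg$epochs,
                        cfg$batch, cfg$lr, cfg$beta1, cfg$beta2,
                        cfg$eps_adam, cfg$lambda, cfg$seed,
                        cfg$bn_latent %||% FALSE)
  structure(
    list(model = model, loss = model$loss, cfg = cfg, input_dim = ncol(X)),
    class = "somn_autoencoder"
  )
}

#' @export
print.somn_autoencoder <- function(x, ...) {
  cat("<somn_autoencoder> ", x$input_dim, " -> ",
      paste(x$cfg$encoder_widths, collapse = "/"), " -> ", x$cfg$latent,
      " latent; ", x$cfg$epochs, " epochs, final loss ",
      signif(tail(x$loss, 1), 4), "\n", sep = "")
  invisible(x)
}

#' @method glance somn_autoencoder
#' @export
glance.somn_autoencoder <- function(x, ...) {
  tibble::tibble(
    epochs = x$cfg$epochs,
    initial_loss = x$loss[1],
    final_loss = tail(x$loss, 1),
    loss_reduction = 1 - tail(x$loss, 1) / x$loss[1]
  )
}

#' Encode feature vectors into the latent space
#'
#' Deterministic inference-mode forward pass (batch normalization uses
#' running statistics) through the trained encoder.
#'
#' @param encoder A `somn_autoencoder`.
#' @param features `somn_features` or bins x features matrix with the same
#'   dimensionality the encoder was trained on.
#' @return A bins x latent matrix.
#' @export
encode_features <- function(encoder, features) {
  stopifnot(inherits(encoder, "somn_autoencoder"))
  X <- feature_matrix(features)
  if (ncol(X) != encoder$input_dim) {
    stop("feature dimensionality (", ncol(X), ") does not match the encoder (",
         encoder$input_dim, ")", call. = FALSE)
  }
  ae_forward_cpp(encoder$model, X, TRUE)
}

# Full reconstruction (inference mode); used for diagnostics and tests.
reconstruct_features <- function(encoder, features) {
  X <- feature_matrix(features)
  ae_forward_cpp(encoder$model, X, FALSE)
}
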