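#' Fingerprint auto-encoder specification
#'
#' Describes one of the three auto-encoders that compress a reaction's
#' 8 x `n_bits` fingerprint matrix into a dense latent vector:
#'
#' * `ffnn` — a single latent layer over the flattened 1 x 4096 input
#'   (4096 -> latent -> 4096);
#' * `cnn1d` — three convolutions of 256, 128 and 64 filters with kernels
#'   12, 10, 10 and pooling 2, 2, 2 laid along the fingerprint-bit axis
#'   (the 8 molecules are the input channels), flattened into the latent
#'   layer; the decoder restores the shape with nearest-neighbour resizing
#'   and four kernel-1 convolutions;
#' * `lstm` — one LSTM layer of `latent_dim` units reading the 8 molecule
#'   rows as a sequence; the decoder repeats the latent vector 8 times
#'   through a second LSTM and a per-row sigmoid readout.
#'
#' All three reconstruct the binary fingerprint under binary cross-entropy.
#' The default latent dimension 512 compresses the 4096-bit input by a
#' factor of 8.
#'
#' @param flavour `"ffnn"`, `"cnn1d"` or `"lstm"`.
#' @param latent_dim Latent width; one of 32, 64, 128, 256, 512.
#' @param n_bits Fingerprint length per molecule (default 512).
#' @param max_molecules Fingerprint rows per reaction (default 8).
#' @return A spec list of class `eluent_ae_spec`.
#' @export
autoencoder_spec <- function(flavour = c("ffnn", "cnn1d", "lstm"),
                             latent_dim = 512L, n_bits = 512L,
                             max_molecules = 8L) {
  flavour <- match.arg(flavour)
  if (!latent_dim %in% c(32L, 64L, 128L, 256L, 512L)) {
    stop("latent_dim must be one of 32, 64, 128, 256, 512")
  }
  structure(list(
    flavour = flavour, latent_dim = as.integer(latent_dim),
    n_bits = as.integer(n_bits), max_molecules = as.integer(max_molecules)
  ), class = "eluent_ae_spec")
}

# Arrange fingerprint matrices for a flavour's input layout:
# ffnn: flat n x (8*n_bits); lstm: molecules as timesteps (B, 8, n_bits);
# cnn1d: bits as the sequence axis, molecules as channels (B, n_bits, 8).
ae_arrange <- function(fps, spec) {
  if (is.matrix(fps) && !is.list(fps)) {
    # already flattened n x (m*n_bits)
    flat <- fps
  } else {
    flat <- do.call(rbind, purrr::map(fps, flatten_fingerprint))
  }
  B <- nrow(flat)
  m <- spec$max_molecules; nb <- spec$n_bits
  switch(spec$flavour,
    ffnn = flat,
    lstm = {
      x <- array(0, dim = c(B, m, nb))
      for (i in seq_len(m)) x[, i, ] <- flat[, ((i - 1) * nb + 1):(i * nb), drop = FALSE]
      x
    },
    cnn1d = {
      x <- array(0, dim = c(B, nb, m))
      for (i in seq_len(m)) x[, , i] <- flat[, ((i - 1) * nb + 1):(i * nb), drop = FALSE]
      x
    }
  )
}

#' Build an untrained fingerprint auto-encoder
#'
#' @param spec An [autoencoder_spec()].
#' @param seed Weight-initialization seed.
#' @return List with the full `net` (`eluent_nn`), the `spec`, and
#'   `encoder_depth` (how many leading layers form the encoder).
#' @export
build_autoencoder <- function(spec, seed = 1L) {
  m <- spec$max_molecules; nb <- spec$n_bits; L <- spec$latent_dim
  if (spec$flavour == "ffnn") {
    net <- nn_sequential(
      m * nb,
      list(
        layer_dense(L, "relu"),
        layer_dense(m * nb, "sigmoid")
      ),
      loss = "bce", seed = seed
    )
    depth <- 1L
  } else if (spec$flavour == "lstm") {
    net <- nn_sequential(
      c(m, nb),
      list(
        layer_lstm(L),
        layer_repeat(m),
        layer_lstm(L, return_sequences = TRUE),
        layer_conv1d(nb, 1, "sigmoid")
      ),
      loss = "bce", seed = seed
    )
    depth <- 1L
  } else {
    # encoder: conv 256/128/64, kernels 12/10/10, pooling 2/2/2, then the
    # flattened map feeds the latent layer
    enc <- list(
      layer_conv1d(256, 12), layer_max_pool1d(2),
      layer_conv1d(128, 10), layer_max_pool1d(2),
      layer_conv1d(64, 10), layer_max_pool1d(2),
      layer_flatten()
    )
    # trace the post-conv shape to size the latent and decoder reshape
    probe <- nn_sequential(c(nb, m), enc, loss = "bce", seed = seed)
    flat_dim <- probe$output_shape
    t_dim <- probe$layers[[6]]$out_shape[1]
    c_dim <- probe$layers[[6]]$out_shape[2]
    net <- nn_sequential(
      c(nb, m),
      c(enc, list(
        layer_dense(L, "relu"),
        # decoder: restore the map, then four kernel-1 convolutions
        layer_dense(flat_dim, "relu"),
        layer_reshape(t_dim, c_dim),
        layer_resize1d(nb),
        layer_conv1d(256, 1), layer_conv1d(128, 1), layer_conv1d(64, 1),
        layer_conv1d(m, 1, "sigmoid")
      )),
      loss = "bce", seed = seed
    )
    depth <- 8L
  }
  list(net = net, spec = spec, encoder_depth = depth)
}

#' Train a fingerprint auto-encoder and freeze its encoder
#'
#' Trains the full encoder-decoder on reaction fingerprints under binary
#' cross-entropy (a 10% held-out slice reports reconstruction loss), then
#' extracts the encoder layers as a frozen, pure encoding function.
#'
#' @param ae From [build_autoencoder()], or an [autoencoder_spec()].
#' @param fingerprints Either a flattened n x 4096 matrix or a list of
#'   8 x 512 matrices ([vectorize_fingerprints()]).
#' @param epochs,batch_size,lr Training settings (defaults 40, 256, 1e-3).
#' @param holdout Fraction used for reconstruction-loss reporting
#'   (default 0.1).
#' @param seed RNG seed for splitting/shuffling.
#' @param verbose Print per-epoch losses.
#' @return An object of class `eluent_encoder`: `spec`, frozen
#'   `encoder_net`, full `net`, `history`, `frozen = TRUE`.
#' @export
train_autoencoder <- function(ae, fingerprints, epochs = 40L, batch_size = 256L,
                              lr = 1e-3, holdout = 0.1, seed = 1L,
                              verbose = FALSE) {
  if (inherits(ae, "eluent_ae_spec")) ae <- build_autoencoder(ae, seed = seed)
  x <- ae_arrange(fingerprints, ae$spec)
  net <- nn_train(ae$net, x, x,
    epochs = epochs, batch_size = batch_size, lr = lr,
    validation_split = holdout, seed = seed, verbose = verbose
  )
  enc_layers <- net$layers[seq_len(ae$encoder_depth)]
  enc_layers <- lapply(enc_layers, function(l) {
    l$opt <- NULL
    l
  })
  encoder_net <- structure(
    list(
      layers = enc_layers, loss = net$loss, input_shape = net$input_shape,
      output_shape = ae$spec$latent_dim, seed = net$seed, history = NULL
    ),
    class = "eluent_nn"
  )
  structure(list(
    spec = ae$spec, encoder_net = encoder_net, net = net,
    history = net$history, frozen = TRUE
  ), class = "eluent_encoder")
}

#' Encode fingerprints into latent vectors
#'
#' Pure function of the frozen encoder: the same input always yields the
#' same latent vector, and no downstream training can alter the encoder's
#' weights.
#'
#' @param encoder An `eluent_encoder` from [train_autoencoder()].
#' @param fingerprints Flattened matrix or list of fingerprint matrices.
#' @return Numeric matrix, n x `latent_dim`.
#' @export
encode <- function(encoder, fingerprints) {
  stopifnot(inherits(encoder, "eluent_encoder"), isTRUE(encoder$frozen))
  x <- ae_arrange(fingerprints, encoder$spec)
  out <- nn_predict(encoder$encoder_net, x)
  if (encoder$spec$flavour == "lstm" && length(dim(out)) > 2) {
    dim(out) <- dim(out)[c(1, 3)]
  }
  out
}

#' @export
print.eluent_encoder <- function(x, ...) {
  cat(
    "Frozen ", x$spec$flavour, " fingerprint encoder: ",
    x$spec$max_molecules, " x ", x$spec$n_bits, " -> ", x$spec$latent_dim,
    " (compression x",
    round(x$spec$max_molecules * x$spec$n_bits / x$spec$latent_dim), ")\n",
    sep = ""
  )
  invisible(x)
}
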