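#' Model configuration for the two prediction tasks
#'
#' Fixes the task (multilabel solvent classification or ratio regression),
#' the input vectorization (learned character embedding `"le"`, raw
#' fingerprint matrices `"ecfp"`, or auto-encoder latents `"ecfp_e"`) and
#' the network type. Output layers are task-determined: 10 sigmoid units
#' under binary cross-entropy for solvents, 1 linear unit under MSE for the
#' ratio. Hidden activations are ReLU; training uses Adam, batch size 256,
#' 40 epochs and a 90/10 train/validation split by default.
#'
#' For `"ecfp_e"` the head is always the three-layer feed-forward network;
#' the `net` argument is ignored in that case (the encoder's own flavour is
#' chosen when training the auto-encoder).
#'
#' @param task `"solvents"` or `"ratio"`.
#' @param vectorization `"le"`, `"ecfp"` or `"ecfp_e"`.
#' @param net `"ffnn"`, `"cnn1d"` or `"lstm"`.
#' @param hidden Feed-forward head layer widths (default 256, 128, 64).
#' @param embedding_dim Learned-embedding width (default 12).
#' @param max_len Token sequence length (default 200).
#' @param n_bits,radius Fingerprint parameters.
#' @param lstm_units LSTM layer width (default 512).
#' @param epochs,batch_size,lr,validation_split Training hyperparameters.
#' @param seed Integer seed.
#' @return A list of class `eluent_config`.
#' @export
model_config <- function(task = c("solvents", "ratio"),
                         vectorization = c("ecfp", "le", "ecfp_e"),
                         net = c("ffnn", "cnn1d", "lstm"),
                         hidden = c(256L, 128L, 64L),
                         embedding_dim = 12L, max_len = 200L,
                         n_bits = 512L, radius = 2L, lstm_units = 512L,
                         epochs = 40L, batch_size = 256L, lr = 1e-3,
                         validation_split = 0.1, seed = 1L) {
  task <- match.arg(task)
  vectorization <- match.arg(vectorization)
  net <- match.arg(net)
  if (vectorization == "ecfp_e" && net != "ffnn") {
    net <- "ffnn" # head over latents is always the FFNN
  }
  structure(list(
    task = task, vectorization = vectorization, net = net,
    hidden = as.integer(hidden), embedding_dim = as.integer(embedding_dim),
    max_len = as.integer(max_len), n_bits = as.integer(n_bits),
    radius = as.integer(radius), lstm_units = as.integer(lstm_units),
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    lr = lr, validation_split = validation_split, seed = as.integer(seed)
  ), class = "eluent_config")
}

model_output_layer <- function(config) {
  if (config$task == "solvents") {
    list(layer = layer_dense(10L, "sigmoid"), loss = "bce")
  } else {
    list(layer = layer_dense(1L, "linear"), loss = "mse")
  }
}

#' Build an untrained prediction network from a configuration
#'
#' @param config An [model_config()].
#' @param vocab Token vocabulary (required for `"le"`).
#' @param encoder Trained `eluent_encoder` (required for `"ecfp_e"`).
#' @return An `eluent_nn`.
#' @export
build_model <- function(config, vocab = NULL, encoder = NULL) {
  out <- model_output_layer(config)
  head_dense <- purrr::map(config$hidden, layer_dense, activation = "relu")
  if (config$vectorization == "le") {
    if (is.null(vocab)) stop("learned-embedding models need a vocabulary")
    emb <- layer_embedding(vocab$size, config$embedding_dim)
    layers <- switch(config$net,
      ffnn = c(list(emb, layer_flatten()), head_dense, list(out$layer)),
      cnn1d = list(
        emb,
        layer_conv1d(64, 12), layer_avg_pool1d(3),
        layer_conv1d(64, 12), layer_avg_pool1d(3),
        layer_conv1d(64, 5), layer_avg_pool1d(3),
        layer_flatten(), out$layer
      ),
      lstm = list(emb, layer_lstm(config$lstm_units), out$layer)
    )
    nn_sequential(config$max_len, layers, loss = out$loss, seed = config$seed)
  } else if (config$vectorization == "ecfp") {
    m <- 8L
    switch(config$net,
      ffnn = nn_sequential(
        m * config$n_bits, c(head_dense, list(out$layer)),
        loss = out$loss, seed = config$seed
      ),
      cnn1d = nn_sequential(
        c(config$n_bits, m),
        list(
          layer_conv1d(64, 12), layer_avg_pool1d(3),
          layer_conv1d(64, 12), layer_avg_pool1d(3),
          layer_conv1d(64, 5), layer_avg_pool1d(3),
          layer_flatten(), out$layer
        ),
        loss = out$loss, seed = config$seed
      ),
      lstm = nn_sequential(
        c(m, config$n_bits),
        list(layer_lstm(config$lstm_units), out$layer),
        loss = out$loss, seed = config$seed
      )
    )
  } else {
    if (is.null(encoder)) stop("ecfp_e models need a trained encoder")
    nn_sequential(
      encoder$spec$latent_dim, c(head_dense, list(out$layer)),
      loss = out$loss, seed = config$seed
    )
  }
}

#' Vectorize dataset inputs for a model configuration
#'
#' @param config An [model_config()].
#' @param dataset Dataset tibble.
#' @param vocab Vocabulary for `"le"`.
#' @param encoder Frozen encoder for `"ecfp_e"`.
#' @return Input matrix or array shaped for [build_model()]'s network.
#' @export
model_inputs <- function(config, dataset, vocab = NULL, encoder = NULL) {
  if (config$vectorization == "le") {
    if (is.null(vocab)) stop("learned-embedding models need a vocabulary")
    return(tokenize(dataset$reaction_smiles, vocab, max_len = config$max_len))
  }
  flat <- vectorize_fingerprints(
    dataset,
    n_bits = config$n_bits, radius = config$radius, flatten = TRUE
  )
  if (config$vectorization == "ecfp_e") {
    if (is.null(encoder)) stop("ecfp_e models need a trained encoder")
    return(encode(encoder, flat))
  }
  switch(config$net,
    ffnn = flat,
    lstm = ae_arrange(flat, list(
      flavour = "lstm", n_bits = config$n_bits, max_molecules = 8L
    )),
    cnn1d = ae_arrange(flat, list(
      flavour = "cnn1d", n_bits = config$n_bits, max_molecules = 8L
    ))
  )
}

# 10-column binary indicator matrix over the canonical label space
labels_to_matrix <- function(labels_list) {
  space <- solvent_labels()
  y <- matrix(0, length(labels_list), length(space))
  for (i in seq_along(labels_list)) {
    y[i, match(labels_list[[i]], space)] <- 1
  }
  colnames(y) <- space
  y
}

#' Train a prediction model on a dataset
#'
#' Vectorizes the training split of the dataset per the configuration,
#' builds the network and trains it. For the ratio task the dataset must be
#' a DS2-style two-solvent dataset (the regressor is only ever trained on
#' two-solvent instances).
#'
#' @param config An [model_config()].
#' @param dataset Split dataset tibble; only `split == "train"` rows are
#'   used.
#' @param vocab Vocabulary for `"le"` (built from the training corpus if
#'   missing).
#' @param encoder Frozen `eluent_encoder` for `"ecfp_e"`.
#' @param verbose Print epoch losses.
#' @return An object of class `eluent_model`: `config`, trained `net`,
#'   `vocab`, `encoder`, training `history`.
#' @export
train_model <- function(config, dataset, vocab = NULL, encoder = NULL,
                        verbose = FALSE) {
  train <- dataset[dataset$split == "train", ]
  if (nrow(train) == 0) stop("no training instances (is the split assigned?)")
  if (config$task == "ratio") {
    if (dataset_task(dataset) != "DS2") {
      stop("ratio models are trained on a DS2 dataset")
    }
    y <- matrix(train$ratio, ncol = 1)
  } else {
    y <- labels_to_matrix(train$labels)
  }
  if (config$vectorization == "le" && is.null(vocab)) {
    vocab <- build_vocabulary(train$reaction_smiles)
  }
  x <- model_inputs(config, train, vocab = vocab, encoder = encoder)
  net <- build_model(config, vocab = vocab, encoder = encoder)
  net <- nn_train(net, x, y,
    epochs = config$epochs, batch_size = config$batch_size, lr = config$lr,
    validation_split = config$validation_split, seed = config$seed,
    verbose = verbose
  )
  structure(list(
    config = config, net = net, vocab = vocab, encoder = encoder,
    history = net$history
  ), class = "eluent_model")
}

#' Predict label scores or ratios for a dataset
#'
#' @param object Trained `eluent_model`.
#' @param dataset Dataset tibble (any split).
#' @param ... Unused.
#' @return For the solvents task an n x 10 score matrix; for the ratio task
#'   an n x 1 matrix.
#' @export
predict.eluent_model <- function(object, dataset, ...) {
  x <- model_inputs(object$config, dataset,
    vocab = object$vocab, encoder = object$encoder
  )
  nn_predict(object$net, x)
}

#' Turn label scores into a solvent-label decision
#'
#' Decision rule for the multilabel output: labels scoring at least
#' `threshold` are predicted, clipped to the top two by score (solvent
#' systems have at most two solvents); if none passes, the single best
#' label is predicted. Score ties break by canonical priority. Returned
#' labels are canonically ordered.
#'
#' @param scores Numeric matrix n x 10 of per-label sigmoid scores (or a
#'   length-10 vector).
#' @param threshold Decision threshold (default 0.5).
#' @return List of character vectors (1-2 labels each).
#' @export
decide_labels <- function(scores, threshold = 0.5) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  space <- solvent_labels()
  purrr::map(seq_len(nrow(scores)), function(i) {
    s <- scores[i, ]
    ord <- order(-s, seq_along(s)) # ties -> canonical priority
    pass <- which(s >= threshold)
    pick <- if (length(pass) == 0) {
      ord[1]
    } else {
      intersect(ord, pass)[seq_len(min(2, length(pass)))]
    }
    canonical_order(space[pick])
  })
}

#' Hierarchical two-stage prediction of a purification system
#'
#' Runs the two trained models in sequence: the classifier proposes the
#' solvent labels; when exactly two solvents are predicted, the ratio
#' regressor is activated and its output (clipped into (0, 1), with a
#' warning if clipping was needed) is reported as the fraction of the
#' first label in canonical order, with complement `1 - ratio` for the
#' second.
#'
#' @param classifier Trained solvents `eluent_model`.
#' @param regressor Trained ratio `eluent_model`.
#' @param reactions Character vector of reaction SMILES, or a dataset
#'   tibble with `reaction_smiles`.
#' @param threshold Label decision threshold.
#' @return Tibble with `reaction_smiles`, `labels` (list), `scores` (list),
#'   `ratio` (NA for single-solvent predictions), `complement`.
#' @export
predict_system <- function(classifier, regressor, reactions, threshold = 0.5) {
  stopifnot(classifier$config$task == "solvents", regressor$config$task == "ratio")
  if (!identical(
    classifier$config$vectorization, regressor$config$vectorization
  )) {
    stop("classifier and regressor use different vectorizations")
  }
  ds <- if (is.character(reactions)) {
    tibble::tibble(reaction_smiles = gsub("[[:space:]]+", "", reactions))
  } else {
    reactions
  }
  scores <- predict(classifier, ds)
  labels <- decide_labels(scores, threshold = threshold)
  ratio <- rep(NA_real_, nrow(ds))
  two <- which(lengths(labels) == 2)
  if (length(two) > 0) {
    raw <- as.vector(predict(regressor, ds[two, ]))
    eps <- 1e-3
    if (any(raw <= 0 | raw >= 1)) {
      warning(sum(raw <= 0 | raw >= 1), " ratio prediction(s) outside (0,1) clipped")
    }
    ratio[two] <- pmin(pmax(raw, eps), 1 - eps)
  }
  tibble::tibble(
    reaction_smiles = ds$reaction_smiles,
    labels = labels,
    scores = purrr::map(seq_len(nrow(scores)), function(i) {
      stats::setNames(scores[i, ], solvent_labels())
    }),
    ratio = ratio,
    complement = 1 - ratio
  )
}
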