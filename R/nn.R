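# Minimal neural-network engine: sequential models built from dense,
# embedding, 1D-convolution, pooling, LSTM and reshaping layers, trained
# with Adam on binary cross-entropy or mean squared error. All heavy
# arithmetic is BLAS matrix multiplication; sequence data is held as
# B x T x C arrays (batch, time, channels).
#
# The engine exists because the networks themselves are the substance of
# this package; it is deliberately small (no autodiff graph, a fixed layer
# vocabulary) and every layer's backward pass is verified against finite
# differences in the test suite.

act_fun <- function(z, type) {
  switch(type,
    relu = pmax(z, 0),
    sigmoid = 1 / (1 + exp(-z)),
    tanh = tanh(z),
    linear = z,
    stop("unknown activation: ", type)
  )
}

# derivative wrt pre-activation, expressed through the activated value a
act_grad <- function(a, type) {
  switch(type,
    relu = (a > 0) * 1,
    sigmoid = a * (1 - a),
    tanh = 1 - a^2,
    linear = array(1, dim = dim(a) %||% length(a)),
    stop("unknown activation: ", type)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

glorot <- function(nin, nout, dims) {
  lim <- sqrt(6 / (nin + nout))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# --- layer constructors (specs) -------------------------------------------

#' Layer specifications for [nn_sequential()]
#'
#' Constructors describing one layer each: fully connected
#' (`layer_dense`), per-symbol learned embedding (`layer_embedding`), valid
#' 1D convolution along the sequence axis (`layer_conv1d`), average/max
#' pooling (`layer_avg_pool1d`, `layer_max_pool1d`), a single LSTM layer
#' (`layer_lstm`), and the shape utilities `layer_flatten`,
#' `layer_repeat` (tile a vector into a sequence) and `layer_resize1d`
#' (nearest-neighbour length change, used by convolutional decoders).
#'
#' @param units,filters Output width.
#' @param activation One of `"relu"`, `"sigmoid"`, `"tanh"`, `"linear"`.
#' @param vocab_size,dim Embedding table dimensions.
#' @param kernel,size Kernel / pooling window length along the sequence.
#' @param return_sequences Return the full hidden sequence instead of the
#'   last state.
#' @param n,length Target sequence lengths.
#' @return A layer specification list.
#' @name nn_layers
NULL

#' @rdname nn_layers
#' @export
layer_dense <- function(units, activation = "relu") {
  list(type = "dense", units = units, activation = activation)
}
#' @rdname nn_layers
#' @export
layer_embedding <- function(vocab_size, dim) {
  list(type = "embedding", vocab_size = vocab_size, dim = dim)
}
#' @rdname nn_layers
#' @export
layer_conv1d <- function(filters, kernel, activation = "relu") {
  list(type = "conv1d", filters = filters, kernel = kernel, activation = activation)
}
#' @rdname nn_layers
#' @export
layer_avg_pool1d <- function(size) list(type = "pool", size = size, mode = "avg")
#' @rdname nn_layers
#' @export
layer_max_pool1d <- function(size) list(type = "pool", size = size, mode = "max")
#' @rdname nn_layers
#' @export
layer_lstm <- function(units, return_sequences = FALSE) {
  list(type = "lstm", units = units, return_sequences = return_sequences)
}
#' @rdname nn_layers
#' @export
layer_flatten <- function() list(type = "flatten")
#' @rdname nn_layers
#' @export
layer_repeat <- function(n) list(type = "repeat", n = n)
#' @rdname nn_layers
#' @export
layer_resize1d <- function(length) list(type = "resize", target = length)
#' @rdname nn_layers
#' @param t,c Sequence length and channel count to reshape a flat vector to.
#' @export
layer_reshape <- function(t, c) list(type = "reshape", t = t, c = c)

# --- model construction ---------------------------------------------------

#' Build a sequential neural network
#'
#' Instantiates layer parameters (Glorot-uniform, seeded) for a stack of
#' layer specifications, tracking shapes from `input_shape` through the
#' stack. Shapes are `D` (a flat feature vector), `c(T, C)` (a sequence
#' with channels), or — when the first layer is an embedding — the token
#' sequence length `T`.
#'
#' @param input_shape Integer scalar (flat input or token length) or
#'   length-2 vector `c(T, C)`.
#' @param layers List of layer specs (see [nn_layers]).
#' @param loss `"bce"` (with sigmoid outputs) or `"mse"` (with linear
#'   outputs).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `eluent_nn`.
#' @export
nn_sequential <- function(input_shape, layers, loss = c("bce", "mse"), seed = 1L) {
  loss <- match.arg(loss)
  shape <- input_shape
  built <- vector("list", length(layers))
  withr::with_seed(seed, {
    for (i in seq_along(layers)) {
      sp <- layers[[i]]
      l <- sp
      if (sp$type == "dense") {
        if (length(shape) != 1) stop("dense layer needs a flat input; got shape ", paste(shape, collapse = "x"))
        l$params <- list(W = glorot(shape, sp$units, c(shape, sp$units)), b = rep(0, sp$units))
        shape <- sp$units
      } else if (sp$type == "embedding") {
        if (i != 1) stop("embedding must be the first layer")
        l$params <- list(E = glorot(sp$vocab_size, sp$dim, c(sp$vocab_size, sp$dim)))
        shape <- c(shape, sp$dim)
      } else if (sp$type == "conv1d") {
        if (length(shape) != 2) stop("conv1d needs a sequence input")
        if (sp$kernel > shape[1]) stop("conv1d kernel ", sp$kernel, " exceeds sequence length ", shape[1])
        cin <- shape[2]
        l$params <- list(
          W = glorot(sp$kernel * cin, sp$filters, c(sp$kernel * cin, sp$filters)),
          b = rep(0, sp$filters)
        )
        l$cin <- cin
        shape <- c(shape[1] - sp$kernel + 1L, sp$filters)
      } else if (sp$type == "pool") {
        if (length(shape) != 2) stop("pooling needs a sequence input")
        shape <- c(shape[1] %/% sp$size, shape[2])
        if (shape[1] < 1) stop("pooling window larger than sequence")
      } else if (sp$type == "lstm") {
        if (length(shape) != 2) stop("lstm needs a sequence input")
        cin <- shape[2]; H <- sp$units
        l$params <- list(
          Wx = glorot(cin, 4 * H, c(cin, 4 * H)),
          Wh = glorot(H, 4 * H, c(H, 4 * H)),
          b = c(rep(0, H), rep(1, H), rep(0, 2 * H)) # forget-gate bias 1
        )
        l$cin <- cin
        shape <- if (sp$return_sequences) c(shape[1], H) else H
      } else if (sp$type == "flatten") {
        shape <- prod(shape)
      } else if (sp$type == "repeat") {
        if (length(shape) != 1) stop("repeat needs a flat input")
        shape <- c(sp$n, shape)
      } else if (sp$type == "resize") {
        if (length(shape) != 2) stop("resize needs a sequence input")
        shape <- c(sp$target, shape[2])
      } else if (sp$type == "reshape") {
        if (length(shape) != 1 || shape != sp$t * sp$c) {
          stop("reshape expects a flat input of length t*c")
        }
        shape <- c(sp$t, sp$c)
      } else {
        stop("unknown layer type: ", sp$type)
      }
      l$out_shape <- shape
      built[[i]] <- l
    }
  })
  structure(
    list(
      layers = built, loss = loss, input_shape = input_shape,
      output_shape = shape, seed = seed, history = NULL
    ),
    class = "eluent_nn"
  )
}

#' @export
print.eluent_nn <- function(x, ...) {
  cat("Sequential network (", x$loss, " loss), ",
    format(nn_num_params(x), big.mark = ","), " parameters\n",
    sep = ""
  )
  cat("  input: ", paste(x$input_shape, collapse = " x "), "\n", sep = "")
  for (l in x$layers) {
    cat(sprintf(
      "  %-10s -> %s\n", l$type, paste(l$out_shape, collapse = " x ")
    ))
  }
  invisible(x)
}

#' Number of trainable parameters
#' @param net An `eluent_nn`.
#' @return Integer parameter count.
#' @export
nn_num_params <- function(net) {
  sum(vapply(net$layers, function(l) {
    if (is.null(l$params)) 0 else sum(vapply(l$params, length, numeric(1)))
  }, numeric(1)))
}

# --- forward / backward ---------------------------------------------------

layer_forward <- function(l, x) {
  B <- dim(x)[1] %||% length(x)
  switch(l$type,
    dense = {
      z <- x %*% l$params$W
      z <- sweep(z, 2, l$params$b, "+")
      a <- act_fun(z, l$activation)
      list(out = a, cache = list(x = x, a = a))
    },
    embedding = {
      idx <- as.vector(x) + 1L # 0-based tokens -> 1-based rows
      out2 <- l$params$E[idx, , drop = FALSE]
      out <- array(out2, dim = c(dim(x)[1], dim(x)[2], ncol(l$params$E)))
      list(out = out, cache = list(idx = idx, B = dim(x)[1], T = dim(x)[2]))
    },
    conv1d = {
      d <- dim(x); B <- d[1]; Tin <- d[2]; C <- d[3]
      k <- l$kernel; Tout <- Tin - k + 1L
      X2 <- matrix(0, B * Tout, k * C)
      for (j in seq_len(k)) {
        sl <- x[, j:(j + Tout - 1L), , drop = FALSE]
        dim(sl) <- c(B * Tout, C)
        X2[, ((j - 1L) * C + 1L):(j * C)] <- sl
      }
      z <- sweep(X2 %*% l$params$W, 2, l$params$b, "+")
      a2 <- act_fun(z, l$activation)
      out <- array(a2, dim = c(B, Tout, l$filters))
      list(out = out, cache = list(X2 = X2, a2 = a2, B = B, Tin = Tin, C = C, Tout = Tout))
    },
    pool = {
      d <- dim(x); B <- d[1]; Tin <- d[2]; C <- d[3]
      s <- l$size; Tout <- Tin %/% s
      xx <- x[, seq_len(Tout * s), , drop = FALSE]
      dim(xx) <- c(B, s, Tout, C)
      slice_j <- function(j) {
        sl <- xx[, j, , , drop = FALSE]
        dim(sl) <- c(B, Tout, C)
        sl
      }
      if (l$mode == "avg") {
        out <- array(0, dim = c(B, Tout, C))
        for (j in seq_len(s)) out <- out + slice_j(j)
        out <- out / s
        list(out = out, cache = list(B = B, Tin = Tin, C = C, Tout = Tout))
      } else {
        out <- array(-Inf, dim = c(B, Tout, C))
        for (j in seq_len(s)) out <- pmax(out, slice_j(j))
        masks <- vector("list", s)
        claimed <- array(FALSE, dim = c(B, Tout, C))
        for (j in seq_len(s)) {
          m <- (slice_j(j) == out) & !claimed
          claimed <- claimed | m
          masks[[j]] <- m
        }
        list(out = out, cache = list(masks = masks, B = B, Tin = Tin, C = C, Tout = Tout))
      }
    },
    lstm = {
      d <- dim(x); B <- d[1]; TT <- d[2]; C <- d[3]
      H <- l$units
      h <- matrix(0, B, H); cc <- matrix(0, B, H)
      steps <- vector("list", TT)
      hs <- if (l$return_sequences) array(0, dim = c(B, TT, H)) else NULL
      for (t in seq_len(TT)) {
        xt <- x[, t, , drop = TRUE]; dim(xt) <- c(B, C)
        z <- xt %*% l$params$Wx + h %*% l$params$Wh
        z <- sweep(z, 2, l$params$b, "+")
        i_g <- act_fun(z[, 1:H, drop = FALSE], "sigmoid")
        f_g <- act_fun(z[, (H + 1):(2 * H), drop = FALSE], "sigmoid")
        g_g <- act_fun(z[, (2 * H + 1):(3 * H), drop = FALSE], "tanh")
        o_g <- act_fun(z[, (3 * H + 1):(4 * H), drop = FALSE], "sigmoid")
        c_prev <- cc; h_prev <- h
        cc <- f_g * c_prev + i_g * g_g
        tc <- tanh(cc)
        h <- o_g * tc
        steps[[t]] <- list(
          xt = xt, i = i_g, f = f_g, g = g_g, o = o_g,
          c_prev = c_prev, h_prev = h_prev, tc = tc
        )
        if (l$return_sequences) hs[, t, ] <- h
      }
      out <- if (l$return_sequences) hs else h
      list(out = out, cache = list(steps = steps, B = B, T = TT, C = C))
    },
    flatten = {
      d <- dim(x)
      out <- x
      dim(out) <- c(d[1], prod(d[-1]))
      list(out = out, cache = list(d = d))
    },
    "repeat" = {
      B <- nrow(x); D <- ncol(x)
      out <- array(0, dim = c(B, l$n, D))
      for (t in seq_len(l$n)) out[, t, ] <- x
      list(out = out, cache = list(B = B, D = D))
    },
    resize = {
      d <- dim(x); B <- d[1]; Tin <- d[2]; C <- d[3]
      map <- pmin(pmax(round((seq_len(l$target) - 0.5) * Tin / l$target + 0.5), 1L), Tin)
      out <- x[, map, , drop = FALSE]
      list(out = out, cache = list(map = map, Tin = Tin, B = B, C = C))
    },
    reshape = {
      B <- nrow(x)
      out <- x
      dim(out) <- c(B, l$t, l$c)
      list(out = out, cache = list(B = B))
    },
    stop("unknown layer type: ", l$type)
  )
}

layer_backward <- function(l, cache, grad_out) {
  switch(l$type,
    dense = {
      dz <- grad_out * act_grad(cache$a, l$activation)
      list(
        grad_in = dz %*% t(l$params$W),
        grads = list(W = crossprod(cache$x, dz), b = colSums(dz))
      )
    },
    embedding = {
      d2 <- grad_out
      dim(d2) <- c(cache$B * cache$T, dim(l$params$E)[2])
      dE <- matrix(0, nrow(l$params$E), ncol(l$params$E))
      agg <- rowsum(d2, group = cache$idx)
      dE[as.integer(rownames(agg)), ] <- agg
      list(grad_in = NULL, grads = list(E = dE))
    },
    conv1d = {
      B <- cache$B; C <- cache$C; Tout <- cache$Tout; k <- l$kernel
      d2 <- grad_out
      dim(d2) <- c(B * Tout, l$filters)
      dz <- d2 * act_grad(cache$a2, l$activation)
      dX2 <- dz %*% t(l$params$W)
      dX <- array(0, dim = c(B, cache$Tin, C))
      for (j in seq_len(k)) {
        sl <- dX2[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
        dim(sl) <- c(B, Tout, C)
        dX[, j:(j + Tout - 1L), ] <- dX[, j:(j + Tout - 1L), , drop = FALSE] + sl
      }
      list(
        grad_in = dX,
        grads = list(W = crossprod(cache$X2, dz), b = colSums(dz))
      )
    },
    pool = {
      B <- cache$B; C <- cache$C; Tout <- cache$Tout; s <- l$size
      dX <- array(0, dim = c(B, cache$Tin, C))
      for (j in seq_len(s)) {
        idx <- (seq_len(Tout) - 1L) * s + j
        contrib <- if (l$mode == "avg") grad_out / s else grad_out * cache$masks[[j]]
        dX[, idx, ] <- contrib
      }
      list(grad_in = dX, grads = NULL)
    },
    lstm = {
      B <- cache$B; TT <- cache$T; C <- cache$C; H <- l$units
      dWx <- matrix(0, C, 4 * H); dWh <- matrix(0, H, 4 * H); db <- rep(0, 4 * H)
      dX <- array(0, dim = c(B, TT, C))
      dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
      for (t in rev(seq_len(TT))) {
        st <- cache$steps[[t]]
        dh <- dh_next
        if (l$return_sequences) {
          g <- grad_out[, t, , drop = TRUE]; dim(g) <- c(B, H)
          dh <- dh + g
        } else if (t == TT) {
          dh <- dh + grad_out
        }
        do_ <- dh * st$tc
        dc <- dc_next + dh * st$o * (1 - st$tc^2)
        di <- dc * st$g
        df <- dc * st$c_prev
        dg <- dc * st$i
        dz <- cbind(
          di * st$i * (1 - st$i),
          df * st$f * (1 - st$f),
          dg * (1 - st$g^2),
          do_ * st$o * (1 - st$o)
        )
        dWx <- dWx + crossprod(st$xt, dz)
        dWh <- dWh + crossprod(st$h_prev, dz)
        db <- db + colSums(dz)
        dh_next <- dz %*% t(l$params$Wh)
        dc_next <- dc * st$f
        dX[, t, ] <- dz %*% t(l$params$Wx)
      }
      list(grad_in = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
    },
    flatten = {
      g <- grad_out
      dim(g) <- cache$d
      list(grad_in = g, grads = NULL)
    },
    "repeat" = {
      B <- cache$B; D <- cache$D
      g <- matrix(0, B, D)
      for (t in seq_len(l$n)) {
        sl <- grad_out[, t, , drop = TRUE]; dim(sl) <- c(B, D)
        g <- g + sl
      }
      list(grad_in = g, grads = NULL)
    },
    resize = {
      dX <- array(0, dim = c(cache$B, cache$Tin, cache$C))
      for (j2 in seq_along(cache$map)) {
        j1 <- cache$map[j2]
        sl <- grad_out[, j2, , drop = FALSE]; dim(sl) <- c(cache$B, cache$C)
        old <- dX[, j1, , drop = FALSE]; dim(old) <- c(cache$B, cache$C)
        dX[, j1, ] <- old + sl
      }
      list(grad_in = dX, grads = NULL)
    },
    reshape = {
      g <- grad_out
      dim(g) <- c(cache$B, l$t * l$c)
      list(grad_in = g, grads = NULL)
    },
    stop("unknown layer type: ", l$type)
  )
}

nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  out <- x
  for (i in seq_along(net$layers)) {
    fw <- layer_forward(net$layers[[i]], out)
    out <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = out, caches = caches)
}

loss_value <- function(p, y, loss) {
  if (loss == "bce") {
    p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  } else {
    mean((p - y)^2)
  }
}

loss_grad <- function(p, y, loss) {
  n <- length(p)
  if (loss == "bce") {
    p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    g <- (p - y) / (p * (1 - p)) / n
  } else {
    g <- 2 * (p - y) / n
  }
  dim(g) <- dim(p) %||% NULL
  g
}

# one Adam step over all layer params; state kept inside net$layers[[i]]$opt
adam_step <- function(net, grads, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  net$t_step <- (net$t_step %||% 0) + 1
  t <- net$t_step
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    l <- net$layers[[i]]
    if (is.null(l$opt)) {
      l$opt <- list(
        m = lapply(l$params, function(p) array(0, dim = dim(p) %||% length(p))),
        v = lapply(l$params, function(p) array(0, dim = dim(p) %||% length(p)))
      )
    }
    for (nm in names(l$params)) {
      gv <- g[[nm]]
      l$opt$m[[nm]] <- beta1 * l$opt$m[[nm]] + (1 - beta1) * gv
      l$opt$v[[nm]] <- beta2 * l$opt$v[[nm]] + (1 - beta2) * gv^2
      mhat <- l$opt$m[[nm]] / (1 - beta1^t)
      vhat <- l$opt$v[[nm]] / (1 - beta2^t)
      upd <- lr * mhat / (sqrt(vhat) + eps)
      dim(upd) <- dim(l$params[[nm]]) %||% NULL
      l$params[[nm]] <- l$params[[nm]] - upd
    }
    net$layers[[i]] <- l
  }
  net
}

#' Train a network with Adam
#'
#' Mini-batch training with a 90/10 train/validation split of the provided
#' data (the validation slice is held out before shuffling, seeded), 40
#' epochs and batch size 256 by default. Per-epoch mean training loss and
#' validation loss are recorded in `net$history`. Training aborts with a
#' diagnostic if the loss diverges to NaN.
#'
#' @param net An `eluent_nn` from [nn_sequential()].
#' @param x Input: matrix or B x T x C array (integer token matrix for
#'   embedding-first networks).
#' @param y Target matrix (B x outputs).
#' @param epochs,batch_size,lr Training hyperparameters (defaults 40, 256,
#'   1e-3).
#' @param validation_split Fraction held out for validation (default 0.1;
#'   0 disables).
#' @param seed Integer seed for the split and batch shuffling.
#' @param verbose Print per-epoch losses.
#' @return The trained network, with `history` (tibble of epoch, loss,
#'   val_loss).
#' @export
nn_train <- function(net, x, y, epochs = 40L, batch_size = 256L, lr = 1e-3,
                     validation_split = 0.1, seed = 1L, verbose = FALSE) {
  n <- dim(x)[1]
  if (is.null(dim(y))) y <- matrix(y, ncol = 1)
  stopifnot(dim(y)[1] == n)
  take_rows <- function(a, idx) {
    if (length(dim(a)) == 3) a[idx, , , drop = FALSE] else a[idx, , drop = FALSE]
  }
  withr::with_seed(seed, {
    perm <- sample.int(n)
    n_val <- floor(validation_split * n)
    val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(perm, val_idx)
    x_tr <- take_rows(x, tr_idx); y_tr <- take_rows(y, tr_idx)
    x_val <- if (n_val > 0) take_rows(x, val_idx) else NULL
    y_val <- if (n_val > 0) take_rows(y, val_idx) else NULL
    n_tr <- length(tr_idx)
    hist <- vector("list", epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_tr)
      batch_losses <- c()
      for (bs in seq(1, n_tr, by = batch_size)) {
        idx <- ord[bs:min(bs + batch_size - 1, n_tr)]
        xb <- take_rows(x_tr, idx); yb <- take_rows(y_tr, idx)
        fw <- nn_forward(net, xb, training = TRUE)
        lo <- loss_value(fw$out, yb, net$loss)
        if (!is.finite(lo)) {
          stop(
            "training diverged (non-finite loss) at epoch ", ep,
            "; try a lower learning rate"
          )
        }
        batch_losses <- c(batch_losses, lo)
        g <- loss_grad(fw$out, yb, net$loss)
        grads <- vector("list", length(net$layers))
        for (i in rev(seq_along(net$layers))) {
          bw <- layer_backward(net$layers[[i]], fw$caches[[i]], g)
          grads[i] <- list(bw$grads)
          g <- bw$grad_in
          if (is.null(g) && i > 1) stop("gradient chain broke at layer ", i)
        }
        net <- adam_step(net, grads, lr)
      }
      val_loss <- if (!is.null(x_val)) {
        loss_value(nn_predict(net, x_val, batch_size), y_val, net$loss)
      } else {
        NA_real_
      }
      hist[[ep]] <- tibble::tibble(
        epoch = ep, loss = mean(batch_losses), val_loss = val_loss
      )
      if (verbose) {
        message(sprintf(
          "epoch %3d  loss %.5f  val_loss %.5f", ep, mean(batch_losses), val_loss
        ))
      }
    }
  })
  net$history <- dplyr::bind_rows(hist)
  net
}

#' Run a trained network forward
#'
#' @param net An `eluent_nn`.
#' @param x Input batch (same layout as in [nn_train()]).
#' @param batch_size Evaluation batch size.
#' @return Output matrix, B x outputs.
#' @export
nn_predict <- function(net, x, batch_size = 1024L) {
  n <- dim(x)[1]
  take_rows <- function(a, idx) {
    if (length(dim(a)) == 3) a[idx, , , drop = FALSE] else a[idx, , drop = FALSE]
  }
  outs <- list()
  for (bs in seq(1, n, by = batch_size)) {
    idx <- bs:min(bs + batch_size - 1, n)
    outs[[length(outs) + 1]] <- nn_forward(net, take_rows(x, idx))$out
  }
  if (length(dim(outs[[1]])) == 3) {
    d <- dim(outs[[1]])
    out <- array(0, dim = c(n, d[2], d[3]))
    at <- 1
    for (o in outs) {
      out[at:(at + dim(o)[1] - 1), , ] <- o
      at <- at + dim(o)[1]
    }
    out
  } else {
    do.call(rbind, outs)
  }
}

# Deterministic digest of all parameters of a network; used to verify that
# frozen encoder weights are untouched by downstream head training.
#' Weight digest of a network
#' @param net An `eluent_nn`.
#' @return A single numeric hash of all parameter values.
#' @export
nn_weight_hash <- function(net) {
  v <- unlist(lapply(net$layers, function(l) {
    if (is.null(l$params)) NULL else lapply(l$params, as.vector)
  }), use.names = FALSE)
  if (is.null(v)) return(0)
  sum(v * sin(seq_along(v))) + sum(abs(v))
}
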