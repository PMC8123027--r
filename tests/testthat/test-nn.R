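# Analytic gradients of every layer type are verified against central
# finite differences; this is the load-bearing correctness test for the
# whole training stack.

numgrad_worst <- function(net, x, y, n_probe = 8) {
  fw <- eluent:::nn_forward(net, x)
  g <- eluent:::loss_grad(fw$out, y, net$loss)
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    bw <- eluent:::layer_backward(net$layers[[i]], fw$caches[[i]], g)
    grads[i] <- list(bw$grads)
    g <- bw$grad_in
  }
  eps <- 1e-5
  worst <- 0
  for (i in seq_along(net$layers)) {
    if (is.null(net$layers[[i]]$params)) next
    for (nm in names(net$layers[[i]]$params)) {
      P <- net$layers[[i]]$params[[nm]]
      for (j in sample(length(P), min(n_probe, length(P)))) {
        net2 <- net
        net2$layers[[i]]$params[[nm]][j] <- P[j] + eps
        lp <- eluent:::loss_value(eluent:::nn_forward(net2, x)$out, y, net$loss)
        net2$layers[[i]]$params[[nm]][j] <- P[j] - eps
        lm <- eluent:::loss_value(eluent:::nn_forward(net2, x)$out, y, net$loss)
        num <- (lp - lm) / (2 * eps)
        ana <- grads[[i]][[nm]][j]
        worst <- max(worst, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
      }
    }
  }
  worst
}

test_that("backpropagation matches finite differences for every layer", {
  set.seed(42)
  cases <- list(
    list(
      net = nn_sequential(6, list(layer_dense(5), layer_dense(3, "sigmoid")),
        loss = "bce", seed = 2
      ),
      x = matrix(stats::runif(24), 4), y = matrix(stats::rbinom(12, 1, .5), 4)
    ),
    list(
      net = nn_sequential(
        c(12, 3),
        list(
          layer_conv1d(4, 3), layer_avg_pool1d(2), layer_conv1d(3, 2, "tanh"),
          layer_max_pool1d(2), layer_flatten(), layer_dense(2, "linear")
        ),
        loss = "mse", seed = 3
      ),
      x = array(stats::rnorm(180), c(5, 12, 3)), y = matrix(stats::rnorm(10), 5)
    ),
    list(
      net = nn_sequential(c(7, 4), list(layer_lstm(6), layer_dense(3, "sigmoid")),
        loss = "bce", seed = 4
      ),
      x = array(stats::rnorm(112), c(4, 7, 4)), y = matrix(stats::rbinom(12, 1, .5), 4)
    ),
    list(
      # sequence-to-sequence path used by the LSTM auto-encoder
      net = nn_sequential(
        c(5, 6),
        list(
          layer_lstm(4), layer_repeat(5), layer_lstm(4, return_sequences = TRUE),
          layer_conv1d(6, 1, "sigmoid")
        ),
        loss = "bce", seed = 5
      ),
      x = array(stats::rbinom(90, 1, .3), c(3, 5, 6)),
      y = array(stats::rbinom(90, 1, .3), c(3, 5, 6))
    ),
    list(
      net = nn_sequential(
        9, list(layer_embedding(7, 3), layer_flatten(), layer_dense(2, "sigmoid")),
        loss = "bce", seed = 6
      ),
      x = matrix(sample(0:6, 36, TRUE), 4), y = matrix(stats::rbinom(8, 1, .5), 4)
    ),
    list(
      # decoder path with reshape + resize + kernel-1 convolutions
      net = nn_sequential(
        c(6, 2),
        list(
          layer_conv1d(3, 2), layer_avg_pool1d(2), layer_flatten(),
          layer_dense(6, "relu"), layer_reshape(3, 2), layer_resize1d(6),
          layer_conv1d(2, 1, "sigmoid")
        ),
        loss = "bce", seed = 7
      ),
      x = array(stats::rnorm(48), c(4, 6, 2)),
      y = array(stats::rbinom(48, 1, .5), c(4, 6, 2))
    ),
    list(
      net = nn_sequential(
        8, list(layer_embedding(6, 4), layer_lstm(5), layer_dense(1, "linear")),
        loss = "mse", seed = 8
      ),
      x = matrix(sample(0:5, 24, TRUE), 3), y = matrix(stats::rnorm(3), 3)
    )
  )
  for (cs in cases) {
    expect_lt(numgrad_worst(cs$net, cs$x, cs$y), 1e-4)
  }
})

test_that("shape bookkeeping and parameter counts are consistent", {
  net <- nn_sequential(
    c(512, 8),
    list(
      layer_conv1d(64, 12), layer_avg_pool1d(3),
      layer_conv1d(64, 12), layer_avg_pool1d(3),
      layer_conv1d(64, 5), layer_avg_pool1d(3),
      layer_flatten(), layer_dense(10, "sigmoid")
    ),
    loss = "bce", seed = 1
  )
  # 512 -> 501 -> 167 -> 156 -> 52 -> 48 -> 16 -> 1024 -> 10
  expect_equal(net$layers[[1]]$out_shape, c(501, 64))
  expect_equal(net$layers[[6]]$out_shape, c(16, 64))
  expect_equal(net$output_shape, 10)
  x <- array(stats::rbinom(2 * 512 * 8, 1, .05), c(2, 512, 8))
  expect_equal(dim(eluent:::nn_forward(net, x)$out), c(2, 10))

  expect_error(nn_sequential(c(8, 512), list(layer_conv1d(4, 12))), "kernel")
  expect_error(nn_sequential(10, list(layer_conv1d(4, 2))), "sequence")
})

test_that("training reduces loss and is deterministic under one seed", {
  set.seed(99)
  x <- matrix(stats::runif(400 * 8), 400)
  w <- stats::rnorm(8)
  y <- matrix(as.numeric(stats::plogis(x %*% w) > 0.5))
  net <- nn_sequential(8, list(layer_dense(16), layer_dense(1, "sigmoid")),
    loss = "bce", seed = 1
  )
  tr1 <- nn_train(net, x, y, epochs = 12, batch_size = 64, seed = 5)
  expect_lt(utils::tail(tr1$history$loss, 1), tr1$history$loss[1])
  expect_lt(utils::tail(tr1$history$val_loss, 1), tr1$history$val_loss[1])

  tr2 <- nn_train(net, x, y, epochs = 12, batch_size = 64, seed = 5)
  expect_identical(tr1$history, tr2$history)
  expect_equal(nn_weight_hash(tr1), nn_weight_hash(tr2))

  tr3 <- nn_train(net, x, y, epochs = 12, batch_size = 64, seed = 6)
  expect_false(identical(tr1$history$loss, tr3$history$loss))

  p <- nn_predict(tr1, x)
  expect_equal(dim(p), c(400, 1))
  expect_identical(p, nn_predict(tr1, x))
})
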