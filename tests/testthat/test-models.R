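test_that("model builders wire the task-determined output layers", {
  v <- build_vocabulary("CCO.N")
  # solvents: 10 sigmoid outputs under BCE
  m <- build_model(model_config("solvents", "ecfp", "ffnn", seed = 1))
  expect_equal(m$output_shape, 10)
  expect_identical(m$layers[[length(m$layers)]]$activation, "sigmoid")
  expect_identical(m$loss, "bce")
  # ratio: 1 linear output under MSE
  r <- build_model(model_config("ratio", "ecfp", "ffnn", seed = 1))
  expect_equal(r$output_shape, 1)
  expect_identical(r$layers[[length(r$layers)]]$activation, "linear")
  expect_identical(r$loss, "mse")
  # learned embedding: 12-dimensional vectors over 200-length sequences
  le <- build_model(model_config("solvents", "le", "ffnn", seed = 1), vocab = v)
  expect_equal(le$layers[[1]]$out_shape, c(200, 12))
  expect_equal(le$layers[[2]]$out_shape, 2400)
  # ecfp_e always gets the FFNN head regardless of the net argument
  cfg <- model_config("solvents", "ecfp_e", "lstm", seed = 1)
  expect_identical(cfg$net, "ffnn")
  expect_error(build_model(cfg), "encoder")
  expect_error(build_model(model_config("solvents", "le", "ffnn")), "vocabulary")
})

test_that("label decisions follow threshold, top-2 clip and argmax fallback", {
  s <- rep(0.1, 10)
  s[1] <- 0.9; s[2] <- 0.8
  expect_identical(decide_labels(s)[[1]], c("ethyl acetate", "hexane"))

  # all below threshold: single argmax
  s2 <- rep(0.1, 10); s2[4] <- 0.45
  expect_identical(decide_labels(s2)[[1]], "methanol")

  # three above threshold: clipped to the top two by score
  s3 <- rep(0.1, 10); s3[3] <- 0.9; s3[5] <- 0.8; s3[7] <- 0.6
  expect_identical(decide_labels(s3)[[1]], c("dichloromethane", "chloroform"))

  # exact ties break by canonical priority
  s4 <- rep(0.6, 10)
  expect_identical(decide_labels(s4)[[1]], c("ethyl acetate", "hexane"))

  # output is always canonically ordered
  s5 <- rep(0, 10); s5[2] <- 0.99; s5[1] <- 0.6
  expect_identical(decide_labels(s5)[[1]], c("ethyl acetate", "hexane"))
})

test_that("training on planted-rule data learns and is seed-reproducible", {
  syn <- synth_small()
  ds1 <- split_dataset(syn$ds1, 0.10, seed = 21)
  cfg <- model_config("solvents", "ecfp", "ffnn",
    hidden = c(64L, 32L), epochs = 6, batch_size = 64, seed = 21
  )
  m <- train_model(cfg, ds1)
  expect_lt(utils::tail(m$history$val_loss, 1), m$history$val_loss[1])
  m2 <- train_model(cfg, ds1)
  expect_identical(m$history, m2$history)
  expect_equal(nn_weight_hash(m$net), nn_weight_hash(m2$net))

  test <- ds1[ds1$split == "test", ]
  rep <- classification_metrics(test$labels, decide_labels(predict(m, test)))
  b <- baselines(ds1)
  expect_gt(rep$subset_accuracy, b$majority_baseline)
})

test_that("hierarchical inference activates the regressor only for pairs", {
  syn <- synth_small()
  ds1 <- split_dataset(syn$ds1, 0.10, seed = 22)
  ds2 <- split_dataset(syn$ds2, 0.10, seed = 22)
  cls <- train_model(model_config("solvents", "ecfp", "ffnn",
    hidden = c(64L, 32L), epochs = 6, batch_size = 64, seed = 22
  ), ds1)
  reg <- train_model(model_config("ratio", "ecfp", "ffnn",
    hidden = c(64L, 32L), epochs = 6, batch_size = 64, seed = 22
  ), ds2)
  out <- predict_system(cls, reg, ds1[ds1$split == "test", ][1:30, ])
  expect_equal(nrow(out), 30)
  two <- lengths(out$labels) == 2
  expect_true(all(is.na(out$ratio[!two])))
  expect_true(all(!is.na(out$ratio[two])))
  expect_true(all(out$ratio[two] > 0 & out$ratio[two] < 1))
  # complements sum to exactly 1
  expect_equal(out$ratio[two] + out$complement[two], rep(1, sum(two)))
  # labels are canonically ordered
  for (l in out$labels[two]) expect_identical(l, canonical_order(l))

  # vectorization mismatch between the two models is a config error
  reg_le <- reg
  reg_le$config$vectorization <- "le"
  expect_error(predict_system(cls, reg_le, "CCO.CC"), "vectorization")
})

test_that("out-of-range regressor outputs are clipped into (0,1)", {
  # craft a linear regressor that always outputs 1.2
  cfg <- model_config("ratio", "ecfp", "ffnn", hidden = integer(0), seed = 1)
  net <- build_model(cfg)
  net$layers[[1]]$params$W[] <- 0
  net$layers[[1]]$params$b <- 1.2
  reg <- structure(
    list(config = cfg, net = net, vocab = NULL, encoder = NULL, history = NULL),
    class = "eluent_model"
  )
  syn <- synth_small()
  ds1 <- split_dataset(syn$ds1, 0.10, seed = 23)
  cls <- train_model(model_config("solvents", "ecfp", "ffnn",
    hidden = c(32L), epochs = 4, batch_size = 64, seed = 23
  ), ds1)
  expect_warning(
    out <- predict_system(cls, reg, ds1[1:20, ]),
    "clipped"
  )
  two <- lengths(out$labels) == 2
  expect_true(any(two))
  expect_true(all(out$ratio[two] < 1 & out$ratio[two] > 0))
})

test_that("model tidiers and plots expose config and history", {
  m <- structure(list(
    history = tibble::tibble(
      epoch = 1:3, loss = c(1, .6, .4), val_loss = c(1, .7, .5)
    ),
    config = model_config("solvents", "ecfp", "ffnn", seed = 1),
    net = build_model(model_config("solvents", "ecfp", "ffnn",
      hidden = c(8L), seed = 1
    ))
  ), class = "eluent_model")
  expect_identical(tidy(m), m$history)
  g <- glance(m)
  expect_identical(g$task, "solvents")
  expect_equal(g$final_val_loss, 0.5)
  expect_s3_class(autoplot(m), "ggplot")
})

test_that("augmented training buys robustness to molecule permutation", {
  syn <- generate_synthetic(synthetic_config(n_reactions = 700L, seed = 31L))
  ds1 <- split_dataset(syn$ds1, 0.10, seed = 31)
  aug <- augment_dataset(ds1, cap = 5, seed = 31)
  cfg <- model_config("solvents", "ecfp", "ffnn",
    hidden = c(64L, 32L), epochs = 8, batch_size = 64, seed = 31
  )
  m_plain <- train_model(cfg, ds1)
  m_aug <- train_model(cfg, aug)

  # 200+ test pairs: a reaction and a molecule-permuted twin
  test <- ds1[ds1$split == "test", ]
  reps <- ceiling(220 / nrow(test))
  test <- test[rep(seq_len(nrow(test)), reps)[1:220], ]
  withr::with_seed(31, {
    twin <- vapply(test$reaction_smiles, function(s) {
      mols <- split_reaction_smiles(s)
      paste(mols[sample.int(length(mols))], collapse = ".")
    }, character(1))
  })
  twin_ds <- tibble::tibble(reaction_smiles = unname(twin))
  agreement <- function(m) {
    a <- decide_labels(predict(m, test))
    b <- decide_labels(predict(m, twin_ds))
    mean(purrr::map2_lgl(a, b, setequal))
  }
  expect_gt(agreement(m_aug), agreement(m_plain))
})
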