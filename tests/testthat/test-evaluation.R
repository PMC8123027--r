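test_that("classification metrics match the hand-counted example", {
  # one instance: true {ethyl acetate, hexane}, predicted {ethyl acetate}
  rep <- classification_metrics(
    list(c("ethyl acetate", "hexane")), list("ethyl acetate")
  )
  # over the 10-label grid: TP=1, FN=1, TN=8, FP=0
  expect_equal(unname(rep$counts), c(1, 8, 0, 1))
  expect_equal(rep$label_accuracy, 0.9)
  expect_equal(rep$recall, 0.5)
  expect_equal(rep$precision, 1.0)
  expect_equal(rep$f1, 2 / 3)
  expect_equal(rep$subset_accuracy, 0)
})

test_that("perfect and degenerate predictions score as expected", {
  truth <- list(c("ethyl acetate", "hexane"), "methanol", c("methanol", "chloroform"))
  rep <- classification_metrics(truth, truth)
  expect_equal(rep$subset_accuracy, 1)
  expect_equal(rep$label_accuracy, 1)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  expect_equal(rep$f1, 1)

  # complement prediction: no true positives, precision 0
  rep0 <- classification_metrics(list("methanol"), list("toluene"))
  expect_equal(rep0$precision, 0)
  expect_equal(rep0$recall, 0)
  expect_error(classification_metrics(truth, truth[1:2]), "equal length")
})

test_that("pooled metrics agree with a brute-force confusion counter", {
  space <- solvent_labels()
  set.seed(7)
  for (trial in 1:30) {
    n <- sample(3:20, 1)
    rand_sets <- function() {
      purrr::map(seq_len(n), function(i) {
        canonical_order(sample(space, sample(1:2, 1)))
      })
    }
    truth <- rand_sets()
    pred <- rand_sets()
    rep <- classification_metrics(truth, pred)
    # oracle: loop over every instance x label decision
    tp <- tn <- fp <- fn <- 0
    for (i in seq_len(n)) {
      for (lab in space) {
        t <- lab %in% truth[[i]]
        p <- lab %in% pred[[i]]
        if (t && p) tp <- tp + 1
        if (!t && !p) tn <- tn + 1
        if (!t && p) fp <- fp + 1
        if (t && !p) fn <- fn + 1
      }
    }
    expect_equal(unname(rep$counts), c(tp, tn, fp, fn))
    expect_equal(rep$label_accuracy, (tp + tn) / (10 * n))
    expect_equal(
      rep$subset_accuracy,
      mean(vapply(seq_len(n), function(i) setequal(truth[[i]], pred[[i]]), logical(1)))
    )
    # permutation invariance
    ord <- sample(n)
    rep_p <- classification_metrics(truth[ord], pred[ord])
    expect_equal(rep_p$counts, rep$counts)
  }
})

test_that("regression metrics follow the printed formulas", {
  y <- c(0.1, 0.5, 0.9)
  expect_equal(regression_metrics(y, y)$r_squared, 1)
  expect_equal(regression_metrics(y, y)$pearson_r, 1)
  expect_equal(regression_metrics(y, y)$mse, 0)

  # predicting the mean gives R-squared exactly 0 (and, being constant,
  # an undefined correlation)
  expect_warning(
    rm <- regression_metrics(y, rep(mean(y), 3)),
    "undefined"
  )
  expect_equal(rm$r_squared, 0)

  r <- regression_metrics(y, c(0.2, 0.5, 0.8))
  expect_equal(r$mse, 0.02 / 3)
  expect_equal(r$r_squared, 1 - 0.02 / sum((y - mean(y))^2))

  expect_warning(
    rz <- regression_metrics(c(0.5, 0.5), c(0.4, 0.6)),
    "undefined"
  )
  expect_true(is.na(rz$pearson_r))
  expect_error(regression_metrics(0.5, 0.5), "at least 2")
})

test_that("R-squared of a least-squares fit equals squared correlation", {
  set.seed(11)
  for (trial in 1:10) {
    x <- stats::rnorm(20)
    y <- 0.5 * x + stats::rnorm(20, sd = 0.3)
    fit <- stats::lm(y ~ x)
    rep <- regression_metrics(y, unname(stats::fitted(fit)))
    expect_equal(rep$r_squared, stats::cor(x, y)^2)
    expect_equal(abs(rep$pearson_r), abs(stats::cor(x, y)))
  }
})

test_that("run summaries carry t-based confidence intervals", {
  mk <- function(acc) {
    structure(
      list(subset_accuracy = acc, n = 10L),
      class = "eluent_cls_report"
    )
  }
  s <- summarize_runs(list(mk(0.94), mk(0.95), mk(0.96)))
  row <- s[s$metric == "subset_accuracy", ]
  expect_equal(row$mean, 0.95)
  expect_equal(row$half_width, stats::qt(0.975, df = 2) * 0.01 / sqrt(3))

  # identical runs: zero-width interval
  s0 <- summarize_runs(list(mk(0.9), mk(0.9), mk(0.9)))
  expect_equal(s0$half_width[s0$metric == "subset_accuracy"], 0)

  # wider spread, same mean: wider interval
  s1 <- summarize_runs(list(mk(0.8), mk(0.9), mk(1.0)))
  expect_equal(s1$mean[1], s0$mean[1])
  expect_gt(s1$half_width[1], s0$half_width[1])

  # a single run has a mean but no interval
  s2 <- summarize_runs(list(mk(0.9)))
  expect_true(is.na(s2$half_width[1]))
})

test_that("broom-style tidiers return the documented shapes", {
  rep <- classification_metrics(
    list(c("ethyl acetate", "hexane"), "methanol"),
    list(c("ethyl acetate", "hexane"), "toluene")
  )
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(nrow(tidy(rep)), 10)
  expect_named(
    glance(rep),
    c("subset_accuracy", "label_accuracy", "precision", "recall", "f1", "n")
  )
  rr <- regression_metrics(c(.1, .5, .9), c(.2, .5, .8))
  expect_equal(nrow(tidy(rr)), 3)
  expect_equal(glance(rr)$mse, 0.02 / 3)
  expect_s3_class(autoplot(rep), "ggplot")
})
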