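#' Multilabel classification metrics
#'
#' Scores predicted label sets against true sets over the 10-label space.
#' Every (instance, label) pair is one binary decision; from the pooled
#' TP/TN/FP/FN counts come label accuracy `(TP+TN)/(TP+FP+TN+FN)` and the
#' micro-averaged precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and F1 (the
#' harmonic mean). Subset accuracy — the fraction of instances whose whole
#' predicted set matches the true set exactly — is reported alongside,
#' since "accuracy" of a multilabel model is quotable either way. A
#' per-class table (precision, recall, F1, support) covers the imbalanced
#' label distribution.
#'
#' @param truth,predicted Lists of character label vectors (1-2 canonical
#'   labels each), equal length.
#' @return Object of class `eluent_cls_report`: `subset_accuracy`,
#'   `label_accuracy`, `precision`, `recall`, `f1`, `counts`
#'   (TP/TN/FP/FN), `per_class` tibble.
#' @export
classification_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  yt <- labels_to_matrix(truth)
  yp <- labels_to_matrix(predicted)
  tp <- sum(yt == 1 & yp == 1)
  tn <- sum(yt == 0 & yp == 0)
  fp <- sum(yt == 0 & yp == 1)
  fn <- sum(yt == 1 & yp == 0)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  per_class <- purrr::map_dfr(seq_along(solvent_labels()), function(j) {
    tpj <- sum(yt[, j] == 1 & yp[, j] == 1)
    fpj <- sum(yt[, j] == 0 & yp[, j] == 1)
    fnj <- sum(yt[, j] == 1 & yp[, j] == 0)
    pj <- if (tpj + fpj == 0) 0 else tpj / (tpj + fpj)
    rj <- if (tpj + fnj == 0) 0 else tpj / (tpj + fnj)
    tibble::tibble(
      label = solvent_labels()[j],
      precision = pj, recall = rj,
      f1 = if (pj + rj == 0) 0 else 2 * pj * rj / (pj + rj),
      support = sum(yt[, j] == 1)
    )
  })
  structure(list(
    subset_accuracy = mean(purrr::map2_lgl(truth, predicted, setequal)),
    label_accuracy = (tp + tn) / (tp + tn + fp + fn),
    precision = precision, recall = recall, f1 = f1,
    counts = c(TP = tp, TN = tn, FP = fp, FN = fn),
    per_class = per_class,
    n = length(truth)
  ), class = "eluent_cls_report")
}

#' @export
print.eluent_cls_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Multilabel classification over %d instances:\n",
      "  subset accuracy : %.4f\n  label accuracy  : %.4f\n",
      "  precision       : %.4f\n  recall          : %.4f\n  F1              : %.4f\n"
    ),
    x$n, x$subset_accuracy, x$label_accuracy, x$precision, x$recall, x$f1
  ))
  invisible(x)
}

#' Regression metrics for ratio predictions
#'
#' R-squared (`1 - SS_res / SS_tot` against the truth mean), the Pearson
#' product-moment correlation, and mean squared error. With constant truth
#' the correlation is undefined and reported as `NA` with a warning.
#'
#' @param truth,predicted Numeric vectors of equal length (n >= 2).
#' @return Object of class `eluent_reg_report`: `r_squared`, `pearson_r`,
#'   `mse`, `n`.
#' @export
regression_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  if (length(truth) < 2) stop("need at least 2 instances")
  mse <- mean((truth - predicted)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum((truth - predicted)^2) / ss_tot
  pr <- if (stats::sd(truth) == 0 || stats::sd(predicted) == 0) {
    warning("zero variance: Pearson correlation undefined")
    NA_real_
  } else {
    stats::cor(truth, predicted)
  }
  structure(list(
    r_squared = r2, pearson_r = pr, mse = mse, n = length(truth)
  ), class = "eluent_reg_report")
}

#' @export
print.eluent_reg_report <- function(x, ...) {
  cat(sprintf(
    "Ratio regression over %d instances:\n  R-squared : %.4f\n  Pearson R : %.4f\n  MSE       : %.5f\n",
    x$n, x$r_squared, x$pearson_r, x$mse
  ))
  invisible(x)
}

#' Summarize metrics over repeated runs
#'
#' Mean and 95% (by default) Student-t confidence half-width per metric
#' over independent training runs. A single run yields means with `NA`
#' half-widths.
#'
#' @param reports List of report objects (all `eluent_cls_report` or all
#'   `eluent_reg_report`), or a data frame of per-run metric columns.
#' @param confidence Confidence level (default 0.95).
#' @return Tibble with `metric`, `mean`, `half_width`, `n_runs`.
#' @export
summarize_runs <- function(reports, confidence = 0.95) {
  df <- if (is.data.frame(reports)) {
    tibble::as_tibble(reports)
  } else {
    purrr::map_dfr(reports, function(r) {
      tibble::as_tibble(r[vapply(r, function(v) {
        is.numeric(v) && length(v) == 1
      }, logical(1))])
    })
  }
  df <- df[setdiff(names(df), "n")]
  n <- nrow(df)
  purrr::map_dfr(names(df), function(m) {
    v <- df[[m]]
    hw <- if (n < 2) {
      NA_real_
    } else {
      stats::qt(1 - (1 - confidence) / 2, df = n - 1) * stats::sd(v) / sqrt(n)
    }
    tibble::tibble(metric = m, mean = mean(v), half_width = hw, n_runs = n)
  })
}
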