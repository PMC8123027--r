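#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a classification report
#'
#' @param x An `eluent_cls_report`.
#' @param ... Unused.
#' @return The per-class tibble (precision, recall, F1, support per
#'   solvent label).
#' @export
tidy.eluent_cls_report <- function(x, ...) {
  x$per_class
}

#' @rdname tidy.eluent_cls_report
#' @return For `glance`, a one-row tibble of the pooled metrics.
#' @export
glance.eluent_cls_report <- function(x, ...) {
  tibble::tibble(
    subset_accuracy = x$subset_accuracy,
    label_accuracy = x$label_accuracy,
    precision = x$precision,
    recall = x$recall,
    f1 = x$f1,
    n = x$n
  )
}

#' Tidy a regression report
#'
#' @param x An `eluent_reg_report`.
#' @param ... Unused.
#' @return Long tibble of metric/value pairs; `glance` returns them as one
#'   row.
#' @export
tidy.eluent_reg_report <- function(x, ...) {
  tibble::tibble(
    metric = c("r_squared", "pearson_r", "mse"),
    value = c(x$r_squared, x$pearson_r, x$mse)
  )
}

#' @rdname tidy.eluent_reg_report
#' @export
glance.eluent_reg_report <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, pearson_r = x$pearson_r, mse = x$mse, n = x$n
  )
}

#' Tidy baselines
#'
#' @param x An `eluent_baselines`.
#' @param ... Unused.
#' @return For DS1 the label-set distribution tibble; for DS2 the two
#'   constant-predictor MSEs as metric/value rows. `glance` gives one row.
#' @export
tidy.eluent_baselines <- function(x, ...) {
  if (x$task == "DS1") {
    x$label_set_distribution
  } else {
    tibble::tibble(
      metric = c("mean_mse_baseline", "median_mse_baseline"),
      value = c(x$mean_mse_baseline, x$median_mse_baseline)
    )
  }
}

#' @rdname tidy.eluent_baselines
#' @export
glance.eluent_baselines <- function(x, ...) {
  if (x$task == "DS1") {
    tibble::tibble(
      random_baseline = x$random_baseline,
      majority_baseline = x$majority_baseline,
      n_label_sets = nrow(x$label_set_distribution)
    )
  } else {
    tibble::tibble(
      mean_mse_baseline = x$mean_mse_baseline,
      median_mse_baseline = x$median_mse_baseline,
      n = x$n
    )
  }
}

#' Tidy a trained model
#'
#' @param x An `eluent_model`.
#' @param ... Unused.
#' @return The per-epoch training history; `glance` returns configuration
#'   plus final losses as one row.
#' @export
tidy.eluent_model <- function(x, ...) {
  x$history
}

#' @rdname tidy.eluent_model
#' @export
glance.eluent_model <- function(x, ...) {
  tibble::tibble(
    task = x$config$task,
    vectorization = x$config$vectorization,
    net = x$config$net,
    epochs = x$config$epochs,
    parameters = nn_num_params(x$net),
    final_loss = utils::tail(x$history$loss, 1),
    final_val_loss = utils::tail(x$history$val_loss, 1)
  )
}

#' Plot a model's training history
#'
#' @param object An `eluent_model` (or `eluent_encoder`).
#' @param ... Unused.
#' @return A ggplot of training and validation loss per epoch.
#' @export
autoplot.eluent_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("loss", "val_loss"),
    names_to = "series", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$epoch, y = .data$value, colour = .data$series
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "epoch", y = "loss", colour = NULL,
      title = paste(object$config$task, "model training history")
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.eluent_model
#' @export
autoplot.eluent_encoder <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("loss", "val_loss"),
    names_to = "series", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$epoch, y = .data$value, colour = .data$series
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "epoch", y = "reconstruction BCE", colour = NULL,
      title = sprintf("%s auto-encoder training", object$spec$flavour)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-class classification metrics
#'
#' @param object An `eluent_cls_report`.
#' @param ... Unused.
#' @return A ggplot with per-solvent precision/recall/F1 bars.
#' @export
autoplot.eluent_cls_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_class, c("precision", "recall", "f1"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$label, -.data$support),
    y = .data$value, fill = .data$metric
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL, title = "Per-solvent metrics") +
    ggplot2::theme_minimal()
}

#' Plot the label-set distribution behind the baselines
#'
#' @param object An `eluent_baselines` (DS1 flavour).
#' @param top Show at most this many label sets.
#' @param ... Unused.
#' @return A ggplot bar chart of label-set probabilities.
#' @export
autoplot.eluent_baselines <- function(object, top = 15, ...) {
  if (object$task != "DS1") {
    stop("autoplot is defined for the label-set (DS1) baselines")
  }
  df <- utils::head(object$label_set_distribution, top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$label_set, .data$probability),
    y = .data$probability
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "probability",
      title = "Solvent-system distribution"
    ) +
    ggplot2::theme_minimal()
}
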