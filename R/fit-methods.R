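#' @export
print.fedherd_fit <- function(x, ...) {
  cat(sprintf("Federated herd stress classifier (%s arm)\n", x$arm))
  cat(sprintf("  model: %s%d-feature windows of %d -> LSTM(%d)%s -> sigmoid\n",
              if (x$model_cfg$cnn_enabled) {
                sprintf("conv(%d ch, k=%d) on ", x$model_cfg$cnn_channels,
                        x$model_cfg$cnn_kernel)
              } else "",
              x$model_cfg$n_features, x$model_cfg$window_len,
              x$model_cfg$lstm_hidden,
              if (x$model_cfg$dense_hidden > 0) {
                sprintf(" -> dense(%d)", x$model_cfg$dense_hidden)
              } else ""))
  cat(sprintf("  parameters: %d (%.2f MiB at 32-bit)\n",
              length(flatten_params(x$params)),
              param_size_bytes(x$params) / 2^20))
  if (x$arm == "federated") {
    tot <- comms_totals(x$ledger)
    cat(sprintf("  rounds: %d x %d local epochs over %d clients\n",
                x$fed_cfg$rounds, x$fed_cfg$local_epochs,
                length(x$client_sizes)))
    cat(sprintf("  traffic: %.1f MB uplink, %.1f MB downlink\n",
                tot$uplink_mb, tot$downlink_mb))
  } else {
    cat(sprintf("  epochs: %d on %d pooled windows\n",
                nrow(x$history), x$client_sizes[1]))
  }
  last <- x$history[nrow(x$history), ]
  if (nrow(x$history) && is.finite(last$global_accuracy)) {
    cat(sprintf("  held-out: loss %.4f, accuracy %.3f\n",
                last$global_loss, last$global_accuracy))
  }
  invisible(x)
}

#' @export
summary.fedherd_fit <- function(object, ...) {
  out <- list(arm = object$arm,
              history = object$history,
              totals = comms_totals(object$ledger),
              n_params = length(flatten_params(object$params)),
              fed_cfg = object$fed_cfg,
              model_cfg = object$model_cfg)
  class(out) <- "summary.fedherd_fit"
  out
}

#' @export
print.summary.fedherd_fit <- function(x, ...) {
  cat(sprintf("fedherd_fit summary (%s arm), %d parameters\n",
              x$arm, x$n_params))
  cat(sprintf("traffic: %.1f MB up / %.1f MB down\n",
              x$totals$uplink_mb, x$totals$downlink_mb))
  cat("training history (tail):\n")
  print(utils::tail(x$history, 5), row.names = FALSE)
  invisible(x)
}

#' @export
coef.fedherd_fit <- function(object, ...) {
  flatten_params(object$params)
}

#' Predict stress probabilities or classes for new windows
#'
#' @param object a `fedherd_fit`.
#' @param newdata a `windowed_dataset` built with the same feature set and
#'   window length as the training data (and the frozen training-time
#'   min-max bounds).
#' @param type `"prob"` for probabilities, `"class"` for 0/1 labels.
#' @param threshold decision threshold for `type = "class"` (strict `>`).
#' @param ... unused.
#' @export
predict.fedherd_fit <- function(object, newdata, type = c("prob", "class"),
                                threshold = 0.5, ...) {
  type <- match.arg(type)
  if (!inherits(newdata, "windowed_dataset")) {
    stop_data("'newdata' must be a windowed_dataset")
  }
  p <- nn_forward(object$params, newdata$x, object$model_cfg)
  if (type == "prob") p else as.integer(p > threshold)
}

#' Plot the training history of a fitted run
#'
#' Loss (and held-out accuracy, when tracked) against the communication
#' round (federated arm) or epoch (centralized arm).
#'
#' @param x a `fedherd_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fedherd_fit <- function(x, ...) {
  h <- x$history
  xlab <- if (x$arm == "federated") "communication round" else "epoch"
  has_acc <- any(is.finite(h$global_accuracy))
  old <- graphics::par(mfrow = c(1, if (has_acc) 2 else 1))
  on.exit(graphics::par(old))
  loss <- if (all(is.finite(h$global_loss))) h$global_loss else
    h$mean_client_loss
  graphics::plot(h$round, loss, type = "l", xlab = xlab,
                 ylab = "binary cross-entropy", ...)
  if (has_acc) {
    graphics::plot(h$round, h$global_accuracy, type = "l", xlab = xlab,
                   ylab = "held-out accuracy", ylim = c(0, 1), ...)
  }
  invisible(x)
}

#' Persist a fitted run as a directory of artifacts
#'
#' Writes the parameter container, `history.csv`, `ledger.csv` and a YAML
#' config snapshot.
#'
#' @param fit a `fedherd_fit`.
#' @param dir output directory (created if missing).
#' @export
save_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_params(fit$params, file.path(dir, "params.bin"), fit$model_cfg)
  utils::write.csv(fit$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$ledger, file.path(dir, "ledger.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(arm = fit$arm, seed = fit$seed,
                        federated = unclass(fit$fed_cfg),
                        model = unclass(fit$model_cfg)),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
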