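#' Confusion matrix at a probability threshold
#'
#' A window is predicted stressed iff its probability strictly exceeds the
#' threshold (a probability of exactly 0.5 at the default threshold is
#' predicted normal).
#'
#' @param probabilities numeric vector of predicted stress probabilities.
#' @param labels 0/1 vector of true labels, same length.
#' @param threshold decision threshold (default 0.5, strict `>`).
#' @return an object of class `confusion`: list with `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_matrix <- function(probabilities, labels, threshold = 0.5) {
  if (length(probabilities) != length(labels) || length(labels) == 0) {
    stop_data("probabilities and labels must be equal-length and non-empty")
  }
  if (!all(labels %in% c(0, 1))) stop_data("labels must be 0/1")
  pred <- probabilities > threshold
  structure(list(
    tp = sum(pred & labels == 1),
    fp = sum(pred & labels == 0),
    fn = sum(!pred & labels == 1),
    tn = sum(!pred & labels == 0)
  ), class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(predicted = c("normal", "stressed"),
                              actual = c("normal", "stressed")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(tp+tn)/n`, precision `tp/(tp+fp)`, recall `tp/(tp+fn)` and
#' F1 `2PR/(P+R)`. Ratios with a zero denominator are mapped to 0 with a
#' warning (a classifier that never predicts the positive class has
#' precision 0 here, not NA).
#'
#' @param conf a `confusion`.
#' @return list with `accuracy`, `precision`, `recall`, `f1`, all in
#'   `[0, 1]`.
#' @export
classification_metrics <- function(conf) {
  total <- conf$tp + conf$fp + conf$fn + conf$tn
  if (total == 0) stop_data("empty confusion matrix")
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (0/0); reporting 0", what))
      return(0)
    }
    num / den
  }
  precision <- safe_ratio(conf$tp, conf$tp + conf$fp, "precision")
  recall <- safe_ratio(conf$tp, conf$tp + conf$fn, "recall")
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(accuracy = (conf$tp + conf$tn) / total,
       precision = precision, recall = recall, f1 = f1)
}

#' Evaluate a parameter vector on a windowed dataset
#'
#' Forward pass over every window, then confusion matrix and metrics.
#' Deterministic given parameters and data.
#'
#' @param params a `param_vector`.
#' @param data a non-empty `windowed_dataset`.
#' @param model_cfg the [model_config()].
#' @param threshold decision threshold.
#' @return list with `confusion` and `metrics`.
#' @export
evaluate_model <- function(params, data, model_cfg, threshold = 0.5) {
  if (n_windows(data) == 0) stop_data("evaluation dataset is empty")
  p <- nn_forward(params, data$x, model_cfg)
  conf <- confusion_matrix(p, data$y, threshold)
  list(confusion = conf, metrics = classification_metrics(conf))
}

#' Compare fitted runs on a common test set
#'
#' One row per run: accuracy (as a percentage), F1, and the run's total
#' uplink and downlink traffic in MB (1 MB = 2^20 bytes). A centralized
#' run shows 0 MB — it ships no federated traffic.
#'
#' @param results named list of `fedherd_fit` objects.
#' @param test_data the common held-out `windowed_dataset`.
#' @param threshold decision threshold.
#' @return a data frame `model, accuracy_pct, f1, uplink_mb, downlink_mb`.
#' @export
compare_runs <- function(results, test_data, threshold = 0.5) {
  if (is.null(names(results))) {
    names(results) <- vapply(results, function(r) r$arm, character(1))
  }
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    ev <- evaluate_model(r$params, test_data, r$model_cfg, threshold)
    tot <- comms_totals(r$ledger)
    data.frame(model = nm,
               accuracy_pct = 100 * ev$metrics$accuracy,
               f1 = ev$metrics$f1,
               uplink_mb = tot$uplink_mb,
               downlink_mb = tot$downlink_mb)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
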