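#' Configuration for the edge preprocessing pipeline
#'
#' @param z_max z-score threshold beyond which a row is dropped as a sensor
#'   failure (default 3).
#' @param hr_threshold heart-rate proxy-stress threshold in bpm (default
#'   100; labels use strict `>`).
#' @param temp_threshold body-temperature threshold in degC (default 39.5).
#' @param rolling_window_minutes trailing window for rolling features
#'   (default 30).
#' @param outlier_features features screened by the z-score rule.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(z_max = 3,
                              hr_threshold = 100,
                              temp_threshold = 39.5,
                              rolling_window_minutes = 30,
                              outlier_features = PHYSIO_COLUMNS) {
  cfg <- list(
    z_max = check_positive(z_max, "z_max"),
    hr_threshold = check_positive(hr_threshold, "hr_threshold"),
    temp_threshold = check_positive(temp_threshold, "temp_threshold"),
    rolling_window_minutes =
      check_positive(rolling_window_minutes, "rolling_window_minutes"),
    outlier_features = outlier_features
  )
  class(cfg) <- "preprocess_config"
  cfg
}

order_herd <- function(table) {
  table[order(table$cattle_id, table$timestamp), , drop = FALSE]
}

#' Fill missing physiological values by forward then backward carry
#'
#' Per animal and per feature, gaps caused by transmission lags or sensor
#' dropouts are closed by carrying the last observation forward, then — for
#' leading gaps — the first observation backward. Values are carried
#' verbatim, never interpolated. Idempotent.
#'
#' @param table a sensor data frame sorted per animal by timestamp.
#' @param features columns to fill (default the physiological trio).
#' @return the filled data frame.
#' @export
fill_missing <- function(table, features = PHYSIO_COLUMNS) {
  if (nrow(table) == 0) return(table)
  features <- intersect(features, names(table))
  idx <- split(seq_len(nrow(table)), table$cattle_id)
  for (f in features) {
    col <- table[[f]]
    for (animal in names(idx)) {
      i <- idx[[animal]]
      v <- col[i]
      if (all(is.na(v))) {
        stop_data("animal '%s' has no observed values for feature '%s'",
                  animal, f)
      }
      v <- zoo::na.locf(v, na.rm = FALSE)
      v <- zoo::na.locf(v, fromLast = TRUE, na.rm = FALSE)
      col[i] <- v
    }
    table[[f]] <- col
  }
  table
}

#' Drop rows with implausible sensor values by z-score thresholding
#'
#' For each configured feature, the mean and (sample) standard deviation are
#' computed over the whole table; any row where `|x - mean| / sd` exceeds
#' `z_max` for at least one feature is dropped. Features with zero standard
#' deviation flag nothing. Intended to run after [fill_missing()].
#'
#' @param table a sensor data frame without missing values in the screened
#'   features.
#' @param cfg a [preprocess_config()].
#' @return list with `table` (surviving rows) and `dropped` (count).
#' @export
remove_outliers <- function(table, cfg = preprocess_config()) {
  if (nrow(table) == 0) return(list(table = table, dropped = 0L))
  feats <- intersect(cfg$outlier_features, names(table))
  bad <- rep(FALSE, nrow(table))
  for (f in feats) {
    x <- table[[f]]
    if (anyNA(x)) {
      stop_data("feature '%s' has missing values; run fill_missing first", f)
    }
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) next
    bad <- bad | (abs(x - mean(x)) / s > cfg$z_max)
  }
  out <- table[!bad, , drop = FALSE]
  rownames(out) <- NULL
  list(table = out, dropped = sum(bad))
}

#' Assign binary proxy stress labels by physiological thresholding
#'
#' `is_stressed` is set to 1 exactly where `heart_rate > hr_threshold` OR
#' `body_temp > temp_threshold` (strict inequalities), else 0. Thresholds
#' are in raw units (bpm, degC), so the operation must run before min-max
#' scaling; a table whose heart rates are all <= 1 is rejected as evidence
#' of pipeline-order misuse. Idempotent. These labels are proxies for
#' physiological stress, not clinical diagnoses.
#'
#' @param table a sensor data frame with raw-unit `heart_rate`/`body_temp`.
#' @param cfg a [preprocess_config()].
#' @return the labelled data frame.
#' @export
generate_labels <- function(table, cfg = preprocess_config()) {
  if (nrow(table) > 0 && all(table$heart_rate <= 1, na.rm = TRUE)) {
    stop_data(paste("heart_rate values are all <= 1; labels must be computed",
                    "on raw units before normalization"))
  }
  table$is_stressed <- as.integer(table$heart_rate > cfg$hr_threshold |
                                    table$body_temp > cfg$temp_threshold)
  table
}

#' Min-max scale features to the unit interval
#'
#' If `bounds` is absent, per-feature minima and maxima are learned from the
#' table (training mode) and returned for reuse; at inference the training
#' bounds are applied verbatim and out-of-bound values are clipped to
#' `[0, 1]`. Degenerate features (`max == min`) map to 0.
#'
#' @param table a sensor data frame without missing values in `features`.
#' @param bounds named list `feature -> c(min, max)`, or `NULL` to learn.
#' @param features columns to scale (default the model-input feature set
#'   present in the table).
#' @return list with `table` (scaled copy) and `bounds` (the bounds used).
#' @export
normalize_minmax <- function(table, bounds = NULL,
                             features = intersect(MODEL_FEATURES,
                                                  names(table))) {
  learn <- is.null(bounds)
  if (learn) bounds <- list()
  for (f in features) {
    if (learn) {
      bounds[[f]] <- c(min = min(table[[f]]), max = max(table[[f]]))
    }
    b <- bounds[[f]]
    if (is.null(b)) stop_config("no bounds supplied for feature '%s'", f)
    if (b[[2]] < b[[1]]) {
      stop_config("bounds for '%s' have max < min", f)
    }
    if (b[[2]] == b[[1]]) {
      table[[f]] <- rep(0, nrow(table))
    } else {
      table[[f]] <- pmin(pmax((table[[f]] - b[[1]]) / (b[[2]] - b[[1]]), 0), 1)
    }
  }
  list(table = table, bounds = bounds)
}

#' Save / load min-max feature bounds as JSON
#'
#' @param bounds named list `feature -> c(min, max)`.
#' @param path file path.
#' @export
write_bounds <- function(bounds, path) {
  obj <- lapply(bounds, function(b) list(min = b[[1]], max = b[[2]]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bounds
#' @export
read_bounds <- function(path) {
  obj <- jsonlite::read_json(path)
  lapply(obj, function(b) c(min = b$min, max = b$max))
}

#' Append trailing rolling features per animal
#'
#' Adds causal (trailing, current-sample-inclusive) time-based rolling
#' statistics per animal: `hr_roll_mean` and `temp_roll_mean` (rolling means
#' of heart rate and body temperature) and `activity_roll_var` (rolling
#' population variance of the activity index), over windows of
#' `rolling_window_minutes`. A window holding a single sample has variance
#' 0. The window is time-based, so irregular spacing is handled, but
#' timestamps must be sorted within each animal.
#'
#' @param table a per-animal time-sorted sensor data frame.
#' @param cfg a [preprocess_config()].
#' @return the data frame with the three rolling columns appended.
#' @export
add_rolling_features <- function(table, cfg = preprocess_config()) {
  if (nrow(table) == 0) {
    table$hr_roll_mean <- numeric(0)
    table$temp_roll_mean <- numeric(0)
    table$activity_roll_var <- numeric(0)
    return(table)
  }
  idx <- split(seq_len(nrow(table)), table$cattle_id)
  hr_m <- temp_m <- act_v <- rep(NA_real_, nrow(table))
  w_sec <- cfg$rolling_window_minutes * 60
  pop_var <- function(x) mean((x - mean(x))^2)
  for (i in idx) {
    ts <- as.numeric(table$timestamp[i])
    if (is.unsorted(ts, strictly = FALSE)) {
      stop_data("timestamps for animal '%s' are not sorted",
                table$cattle_id[i[1]])
    }
    lo <- 1L
    for (j in seq_along(i)) {
      while (ts[j] - ts[lo] > w_sec) lo <- lo + 1L
      win <- i[lo:j]
      hr_m[i[j]] <- mean(table$heart_rate[win])
      temp_m[i[j]] <- mean(table$body_temp[win])
      act_v[i[j]] <- pop_var(table$activity_level[win])
    }
  }
  table$hr_roll_mean <- hr_m
  table$temp_roll_mean <- temp_m
  table$activity_roll_var <- act_v
  table
}

#' Run the full edge preprocessing pipeline on a sensor table
#'
#' Applies, in order: per-animal forward/backward fill, z-score outlier row
#' removal, trailing rolling features, proxy stress labelling on raw units,
#' and min-max normalization of the model-input features. The raw-unit
#' labels are assigned before scaling, so the 100 bpm / 39.5 degC
#' thresholds keep their physical meaning.
#'
#' @param table a sensor data frame.
#' @param cfg a [preprocess_config()].
#' @param bounds training-time feature bounds, or `NULL` to learn them from
#'   this table.
#' @return list with `table` (clean, labelled, normalized), `bounds`, and
#'   `dropped` (outlier rows removed).
#' @export
preprocess_table <- function(table, cfg = preprocess_config(), bounds = NULL) {
  table <- order_herd(table)
  table <- fill_missing(table)
  ro <- remove_outliers(table, cfg)
  tab <- add_rolling_features(ro$table, cfg)
  tab <- generate_labels(tab, cfg)
  nm <- normalize_minmax(tab, bounds)
  list(table = nm$table, bounds = nm$bounds, dropped = ro$dropped)
}
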