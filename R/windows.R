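#' Slice a preprocessed table into fixed-length training windows
#'
#' Per animal, sliding windows of `window_len` consecutive samples are cut
#' at the given stride; each window's label is the `is_stressed` value of
#' its final row (detection at window end). An animal with fewer than
#' `window_len` samples yields zero windows. The number of windows per
#' animal is `floor((n - window_len) / stride) + 1`.
#'
#' @param table a preprocessed sensor data frame (normalized features,
#'   labels present), per-animal time-sorted.
#' @param window_len window length in samples (>= 1).
#' @param stride step between window starts in samples (>= 1). Stride 1 is
#'   the training default; `stride = window_len` tiles the series without
#'   overlap for reporting.
#' @param features feature columns, in model-input order.
#' @return an object of class `windowed_dataset`: a list with `x` (array
#'   `n_windows x window_len x n_features`), `y` (integer labels),
#'   `cattle_id`, `end_timestamp`, `feature_names`, `window_len`, `stride`.
#' @export
make_windows <- function(table, window_len = 8, stride = 1,
                         features = intersect(MODEL_FEATURES, names(table))) {
  window_len <- check_count(window_len, "window_len")
  stride <- check_count(stride, "stride")
  missing_feats <- setdiff(features, names(table))
  if (length(missing_feats)) {
    stop_data("table lacks feature column(s): %s",
              paste(missing_feats, collapse = ", "))
  }
  idx <- split(seq_len(nrow(table)), table$cattle_id)
  xs <- list(); ys <- list(); ids <- list(); ends <- list()
  for (animal in names(idx)) {
    i <- idx[[animal]]
    n <- length(i)
    if (n < window_len) next
    starts <- seq(1L, n - window_len + 1L, by = stride)
    mat <- as.matrix(table[i, features, drop = FALSE])
    x <- array(NA_real_, c(length(starts), window_len, length(features)))
    for (k in seq_along(starts)) {
      x[k, , ] <- mat[starts[k]:(starts[k] + window_len - 1L), , drop = FALSE]
    }
    last <- i[starts + window_len - 1L]
    xs[[animal]] <- x
    ys[[animal]] <- as.integer(table$is_stressed[last])
    ids[[animal]] <- rep(animal, length(starts))
    ends[[animal]] <- table$timestamp[last]
  }
  if (!length(xs)) {
    x <- array(numeric(0), c(0, window_len, length(features)))
    y <- integer(0); id <- character(0)
    end <- as.POSIXct(character(0), tz = "UTC")
  } else {
    n_tot <- sum(vapply(xs, function(a) dim(a)[1], numeric(1)))
    x <- array(NA_real_, c(n_tot, window_len, length(features)))
    at <- 1L
    for (a in xs) {
      x[at:(at + dim(a)[1] - 1L), , ] <- a
      at <- at + dim(a)[1]
    }
    y <- unlist(ys, use.names = FALSE)
    id <- unlist(ids, use.names = FALSE)
    end <- do.call(c, unname(ends))
  }
  structure(list(x = x, y = y, cattle_id = id, end_timestamp = end,
                 feature_names = features,
                 window_len = window_len, stride = stride),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf(
    "<windowed_dataset> %d windows of %d x %d (%d animals, %.1f%% stressed)\n",
    n_windows(x), x$window_len, length(x$feature_names),
    length(unique(x$cattle_id)),
    if (n_windows(x)) 100 * mean(x$y) else 0))
  invisible(x)
}

#' Number of windows in a windowed dataset
#' @param data a `windowed_dataset`.
#' @export
n_windows <- function(data) {
  dim(data$x)[1]
}

#' Subset a windowed dataset by window index
#' @param data a `windowed_dataset`.
#' @param i integer index vector.
#' @export
subset_windows <- function(data, i) {
  structure(list(x = data$x[i, , , drop = FALSE], y = data$y[i],
                 cattle_id = data$cattle_id[i],
                 end_timestamp = data$end_timestamp[i],
                 feature_names = data$feature_names,
                 window_len = data$window_len, stride = data$stride),
            class = "windowed_dataset")
}

#' Pool several windowed datasets into one
#' @param datasets list of `windowed_dataset`s with identical feature sets.
#' @export
combine_windows <- function(datasets) {
  datasets <- datasets[vapply(datasets, n_windows, numeric(1)) > 0]
  stopifnot(length(datasets) >= 1)
  f0 <- datasets[[1]]$feature_names
  for (d in datasets) {
    if (!identical(d$feature_names, f0) ||
        d$window_len != datasets[[1]]$window_len) {
      stop_data("windowed datasets are not schema-compatible")
    }
  }
  n_tot <- sum(vapply(datasets, n_windows, numeric(1)))
  x <- array(NA_real_, c(n_tot, datasets[[1]]$window_len, length(f0)))
  at <- 1L
  for (d in datasets) {
    x[at:(at + n_windows(d) - 1L), , ] <- d$x
    at <- at + n_windows(d)
  }
  structure(list(x = x,
                 y = unlist(lapply(datasets, `[[`, "y"), use.names = FALSE),
                 cattle_id = unlist(lapply(datasets, `[[`, "cattle_id"),
                                    use.names = FALSE),
                 end_timestamp = do.call(c, lapply(datasets, `[[`,
                                                   "end_timestamp")),
                 feature_names = f0,
                 window_len = datasets[[1]]$window_len,
                 stride = datasets[[1]]$stride),
            class = "windowed_dataset")
}
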