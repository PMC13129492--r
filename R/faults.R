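#' Configuration for sensor-fault injection
#'
#' Models the two defect classes the preprocessing pipeline must repair:
#' transmission dropouts (missing physiological cells, in runs whose length
#' is geometric with the configured mean) and sensor-failure spikes
#' (cells displaced by more than `outlier_magnitude_sd_multiplier` feature
#' standard deviations, so the z > 3 rule can remove them).
#'
#' @param missing_rate probability that a physiological cell is missing.
#' @param missing_run_length_mean mean dropout run length in samples
#'   (1 = independent per-cell dropout).
#' @param outlier_rate probability that a physiological cell is spiked.
#' @param outlier_magnitude_sd_multiplier spike displacement in feature
#'   standard deviations; must exceed 3 so spikes are removable by z-score
#'   thresholding.
#' @param seed integer seed for the fault stream.
#' @return an object of class `fault_config`.
#' @export
fault_config <- function(missing_rate = 0.02,
                         missing_run_length_mean = 1,
                         outlier_rate = 0.005,
                         outlier_magnitude_sd_multiplier = 6,
                         seed = 1) {
  cfg <- list(
    missing_rate = check_prob(missing_rate, "missing_rate"),
    missing_run_length_mean =
      check_positive(missing_run_length_mean, "missing_run_length_mean"),
    outlier_rate = check_prob(outlier_rate, "outlier_rate"),
    outlier_magnitude_sd_multiplier = outlier_magnitude_sd_multiplier,
    seed = as.integer(seed)
  )
  if (cfg$outlier_magnitude_sd_multiplier <= 3) {
    stop_config("'outlier_magnitude_sd_multiplier' must exceed 3")
  }
  class(cfg) <- "fault_config"
  cfg
}

#' Inject sensor faults into a clean sensor table
#'
#' Physiological cells (`heart_rate`, `body_temp`, `activity_level`) are set
#' missing in geometric-length runs at the configured rate, and spiked by at
#' least `outlier_magnitude_sd_multiplier` times the feature's standard
#' deviation at the configured outlier rate. Environmental and identity
#' columns are never touched. Fault positions are returned in a log.
#'
#' @param table a clean sensor data frame.
#' @param fault_cfg a [fault_config()].
#' @return list with `table` (faulted copy) and `log` (data frame
#'   `row, feature, kind` with kind in `missing`/`outlier`).
#' @export
inject_faults <- function(table, fault_cfg) {
  if (!inherits(fault_cfg, "fault_config")) {
    stop_config("'fault_cfg' must be a fault_config object")
  }
  out <- table
  log <- list()
  if (nrow(table) == 0 ||
      (fault_cfg$missing_rate == 0 && fault_cfg$outlier_rate == 0)) {
    return(list(table = out,
                log = data.frame(row = integer(0), feature = character(0),
                                 kind = character(0))))
  }
  with_seed(fault_cfg$seed, {
    feat_sd <- vapply(PHYSIO_COLUMNS,
                      function(f) stats::sd(table[[f]], na.rm = TRUE),
                      numeric(1))
    for (f in PHYSIO_COLUMNS) {
      n <- nrow(table)
      # dropout runs: starts are Bernoulli(rate / mean run length), lengths
      # 1 + Geometric, so the stationary missing fraction is ~missing_rate
      L <- fault_cfg$missing_run_length_mean
      miss <- rep(FALSE, n)
      if (fault_cfg$missing_rate > 0) {
        starts <- which(stats::runif(n) < fault_cfg$missing_rate / L)
        if (length(starts)) {
          lens <- 1 + stats::rgeom(length(starts), prob = min(1 / L, 1))
          for (j in seq_along(starts)) {
            idx <- starts[j]:min(starts[j] + lens[j] - 1, n)
            # keep runs within one animal's series
            idx <- idx[table$cattle_id[idx] == table$cattle_id[starts[j]]]
            miss[idx] <- TRUE
          }
        }
      }
      spike <- rep(FALSE, n)
      if (fault_cfg$outlier_rate > 0) {
        spike <- stats::runif(n) < fault_cfg$outlier_rate
        spike <- spike & !miss
        mult <- fault_cfg$outlier_magnitude_sd_multiplier
        disp <- sample(c(-1, 1), sum(spike), replace = TRUE) *
          feat_sd[[f]] * stats::runif(sum(spike), mult, mult * 1.5)
        out[[f]][spike] <- out[[f]][spike] + disp
      }
      out[[f]][miss] <- NA_real_
      if (any(miss)) {
        log[[length(log) + 1]] <- data.frame(row = which(miss), feature = f,
                                             kind = "missing")
      }
      if (any(spike)) {
        log[[length(log) + 1]] <- data.frame(row = which(spike), feature = f,
                                             kind = "outlier")
      }
    }
  })
  log <- if (length(log)) do.call(rbind, log) else {
    data.frame(row = integer(0), feature = character(0), kind = character(0))
  }
  rownames(log) <- NULL
  list(table = out, log = log)
}
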