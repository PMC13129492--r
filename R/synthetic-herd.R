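#' Configuration for the synthetic herd simulator
#'
#' Describes a herd of dairy cattle instrumented with wearable sensors.
#' Each animal gets its own baseline heart rate, body temperature and
#' activity level (drawn once from the configured between-animal
#' distributions, which is what makes a per-animal client partition
#' non-IID), a shared sinusoidal diurnal ambient-temperature cycle, and
#' Poisson-arrival stress episodes during which heart rate and body
#' temperature are boosted additively. Baselines default to the normal
#' bovine range (~70 bpm, ~38.5 degC) so that threshold crossings
#' (> 100 bpm, > 39.5 degC) are driven by episodes, not by baseline noise.
#'
#' @param n_animals number of animals (>= 0).
#' @param duration_hours length of the recording in hours.
#' @param sampling_interval_minutes spacing of sensor ticks in minutes.
#' @param hr_baseline_mean,hr_baseline_sd between-animal resting heart-rate
#'   distribution (bpm).
#' @param hr_noise_sd within-animal heart-rate measurement noise (bpm).
#' @param temp_baseline_mean,temp_baseline_sd between-animal body-temperature
#'   distribution (degC).
#' @param temp_noise_sd within-animal temperature noise (degC).
#' @param activity_baseline_mean,activity_baseline_sd between-animal activity
#'   index distribution (unitless, >= 0).
#' @param activity_noise_sd within-animal activity noise.
#' @param ambient_profile length-2 numeric: daily mean ambient temperature
#'   (degC) and diurnal amplitude (degC) of the sinusoidal cycle.
#' @param humidity_profile length-2 numeric: mean and sd of relative
#'   humidity (percent); values are clipped to `[0, 100]`.
#' @param stress_episode_rate expected stress episodes per animal per day.
#' @param stress_episode_duration_minutes episode length in minutes.
#' @param stress_hr_boost additive heart-rate elevation during an episode
#'   (bpm, > 0).
#' @param stress_temp_boost additive temperature elevation (degC, > 0).
#' @param stress_activity_shift additive activity change during an episode
#'   (restlessness; may be negative for lethargy).
#' @param gps_origin length-2 numeric (lat, long) of the paddock centre.
#' @param gps_step_sd random-walk step sd in degrees.
#' @param start_time POSIXct origin of the recording (UTC).
#' @param seed integer master seed for the simulator.
#' @return an object of class `herd_config`.
#' @export
herd_config <- function(n_animals = 20,
                        duration_hours = 168,
                        sampling_interval_minutes = 15,
                        hr_baseline_mean = 70, hr_baseline_sd = 5,
                        hr_noise_sd = 3,
                        temp_baseline_mean = 38.5, temp_baseline_sd = 0.2,
                        temp_noise_sd = 0.1,
                        activity_baseline_mean = 0.3,
                        activity_baseline_sd = 0.1,
                        activity_noise_sd = 0.05,
                        ambient_profile = c(mean = 22, amplitude = 6),
                        humidity_profile = c(mean = 60, sd = 10),
                        stress_episode_rate = 2,
                        stress_episode_duration_minutes = 60,
                        stress_hr_boost = 40,
                        stress_temp_boost = 1.5,
                        stress_activity_shift = 0.2,
                        gps_origin = c(lat = 42.0, long = -85.0),
                        gps_step_sd = 1e-4,
                        start_time = as.POSIXct("2024-06-01 00:00:00",
                                                tz = "UTC"),
                        seed = 1) {
  cfg <- list(
    n_animals = check_count(n_animals, "n_animals", min = 0),
    duration_hours = check_positive(duration_hours, "duration_hours"),
    sampling_interval_minutes =
      check_positive(sampling_interval_minutes, "sampling_interval_minutes"),
    hr_baseline_mean = check_positive(hr_baseline_mean, "hr_baseline_mean"),
    hr_baseline_sd = hr_baseline_sd,
    hr_noise_sd = hr_noise_sd,
    temp_baseline_mean = check_positive(temp_baseline_mean,
                                        "temp_baseline_mean"),
    temp_baseline_sd = temp_baseline_sd,
    temp_noise_sd = temp_noise_sd,
    activity_baseline_mean = activity_baseline_mean,
    activity_baseline_sd = activity_baseline_sd,
    activity_noise_sd = activity_noise_sd,
    ambient_profile = ambient_profile,
    humidity_profile = humidity_profile,
    stress_episode_rate = stress_episode_rate,
    stress_episode_duration_minutes =
      check_positive(stress_episode_duration_minutes,
                     "stress_episode_duration_minutes"),
    stress_hr_boost = check_positive(stress_hr_boost, "stress_hr_boost"),
    stress_temp_boost = check_positive(stress_temp_boost, "stress_temp_boost"),
    stress_activity_shift = stress_activity_shift,
    gps_origin = gps_origin,
    gps_step_sd = gps_step_sd,
    start_time = start_time,
    seed = as.integer(seed)
  )
  if (cfg$stress_episode_rate < 0) {
    stop_config("'stress_episode_rate' must be >= 0")
  }
  for (f in c("hr_baseline_sd", "hr_noise_sd", "temp_baseline_sd",
              "temp_noise_sd", "activity_baseline_sd", "activity_noise_sd",
              "gps_step_sd")) {
    if (cfg[[f]] < 0) stop_config("'%s' must be >= 0", f)
  }
  class(cfg) <- "herd_config"
  cfg
}

empty_herd_table <- function() {
  data.frame(
    timestamp = as.POSIXct(character(0), tz = "UTC"),
    cattle_id = character(0),
    heart_rate = numeric(0),
    body_temp = numeric(0),
    activity_level = numeric(0),
    ambient_temp = numeric(0),
    humidity = numeric(0),
    location_lat = numeric(0),
    location_long = numeric(0),
    is_stressed = integer(0),
    stringsAsFactors = FALSE
  )
}

# Draw Poisson-arrival rectangular stress episodes for one animal.
draw_episodes <- function(ticks, interval_min, rate_per_day, duration_min) {
  n_days <- length(ticks) * interval_min / 1440
  n_ep <- stats::rpois(1, rate_per_day * n_days)
  if (n_ep == 0) {
    return(data.frame(start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC")))
  }
  span <- as.numeric(difftime(ticks[length(ticks)], ticks[1], units = "mins"))
  starts <- sort(stats::runif(n_ep, 0, max(span - duration_min, 0)))
  data.frame(start = ticks[1] + starts * 60,
             end = ticks[1] + (starts + duration_min) * 60)
}

#' Simulate a multimodal sensor stream for a herd
#'
#' Produces one row per animal per sampling tick with the canonical
#' wearable-sensor schema (`timestamp`, `cattle_id`, `heart_rate`,
#' `body_temp`, `activity_level`, `ambient_temp`, `humidity`,
#' `location_lat`, `location_long`, `is_stressed`). During a stress episode
#' heart rate and body temperature are raised by the configured boosts (plus
#' noise) and the activity index is shifted; `is_stressed` is left `NA` —
#' proxy labels are assigned later by [generate_labels()] so that labelling
#' stays a property of the preprocessing pipeline, not of the generator.
#' Ground-truth episode intervals are returned alongside the table.
#'
#' Identical `(config, seed)` give bit-identical output. Independent
#' sub-streams are derived per animal, so the base signals do not change
#' when downstream stages (faults, partitioning) are toggled.
#'
#' @param config a [herd_config()].
#' @param episodes optional data frame `(cattle_id, start, end)` of fixed
#'   episode intervals overriding the Poisson draw (useful for controlled
#'   experiments).
#' @return a list with elements `table` (the sensor data frame, sorted by
#'   `(cattle_id, timestamp)`) and `episodes` (data frame
#'   `cattle_id, start, end`).
#' @export
#' @examples
#' sim <- simulate_herd(herd_config(n_animals = 2, duration_hours = 6))
#' head(sim$table)
simulate_herd <- function(config, episodes = NULL) {
  if (!inherits(config, "herd_config")) {
    stop_config("'config' must be a herd_config object")
  }
  n_ticks <- floor(config$duration_hours * 60 /
                     config$sampling_interval_minutes)
  if (config$n_animals == 0 || n_ticks == 0) {
    return(list(table = empty_herd_table(),
                episodes = data.frame(cattle_id = character(0),
                                      start = as.POSIXct(character(0), tz = "UTC"),
                                      end = as.POSIXct(character(0), tz = "UTC"))))
  }
  ticks <- config$start_time +
    (seq_len(n_ticks) - 1) * config$sampling_interval_minutes * 60
  ids <- sprintf("cow_%03d", seq_len(config$n_animals))

  # hour-of-day phase for the shared diurnal ambient cycle (min at ~04:00,
  # max at ~16:00)
  hod <- as.numeric(format(ticks, "%H", tz = "UTC")) +
    as.numeric(format(ticks, "%M", tz = "UTC")) / 60
  ambient_mean <- config$ambient_profile[[1]] +
    config$ambient_profile[[2]] * sin(2 * pi * (hod - 10) / 24)

  tabs <- vector("list", config$n_animals)
  eps <- vector("list", config$n_animals)
  for (a in seq_len(config$n_animals)) {
    tabs_a <- with_seed(sub_seed(config$seed, "animal", a), {
      hr0 <- stats::rnorm(1, config$hr_baseline_mean, config$hr_baseline_sd)
      temp0 <- stats::rnorm(1, config$temp_baseline_mean,
                            config$temp_baseline_sd)
      act0 <- max(stats::rnorm(1, config$activity_baseline_mean,
                               config$activity_baseline_sd), 0.01)
      if (is.null(episodes)) {
        ep <- draw_episodes(ticks, config$sampling_interval_minutes,
                            config$stress_episode_rate,
                            config$stress_episode_duration_minutes)
      } else {
        sel <- episodes$cattle_id == ids[a]
        ep <- data.frame(start = episodes$start[sel], end = episodes$end[sel])
      }
      in_ep <- rep(FALSE, n_ticks)
      for (k in seq_len(nrow(ep))) {
        in_ep <- in_ep | (ticks >= ep$start[k] & ticks < ep$end[k])
      }
      hr <- hr0 + stats::rnorm(n_ticks, 0, config$hr_noise_sd) +
        ifelse(in_ep, config$stress_hr_boost, 0)
      bt <- temp0 + stats::rnorm(n_ticks, 0, config$temp_noise_sd) +
        ifelse(in_ep, config$stress_temp_boost, 0)
      act <- pmax(act0 + stats::rnorm(n_ticks, 0, config$activity_noise_sd) +
                    ifelse(in_ep, config$stress_activity_shift, 0), 0)
      hum <- pmin(pmax(stats::rnorm(n_ticks, config$humidity_profile[[1]],
                                    config$humidity_profile[[2]]), 0), 100)
      lat <- config$gps_origin[[1]] +
        cumsum(stats::rnorm(n_ticks, 0, config$gps_step_sd))
      lon <- config$gps_origin[[2]] +
        cumsum(stats::rnorm(n_ticks, 0, config$gps_step_sd))
      list(
        table = data.frame(
          timestamp = ticks,
          cattle_id = ids[a],
          heart_rate = hr,
          body_temp = bt,
          activity_level = act,
          ambient_temp = ambient_mean + stats::rnorm(n_ticks, 0, 0.5),
          humidity = hum,
          location_lat = lat,
          location_long = lon,
          is_stressed = NA_integer_,
          stringsAsFactors = FALSE
        ),
        episodes = if (nrow(ep)) {
          data.frame(cattle_id = ids[a], start = ep$start, end = ep$end)
        } else {
          NULL
        }
      )
    })
    tabs[[a]] <- tabs_a$table
    eps[[a]] <- tabs_a$episodes
  }
  table <- do.call(rbind, tabs)
  rownames(table) <- NULL
  episodes_out <- do.call(rbind, eps[!vapply(eps, is.null, logical(1))])
  if (is.null(episodes_out)) {
    episodes_out <- data.frame(cattle_id = character(0),
                               start = as.POSIXct(character(0), tz = "UTC"),
                               end = as.POSIXct(character(0), tz = "UTC"))
  }
  rownames(episodes_out) <- NULL
  list(table = table, episodes = episodes_out)
}

#' Partition a sensor table into non-IID clients by animal
#'
#' Animals are shuffled under the given seed and split as evenly as possible
#' into `n_clients` disjoint groups (sizes differ by at most one). Because
#' each animal carries its own baselines, per-animal grouping yields
#' client-specific feature distributions — the non-IID regime a multi-farm
#' deployment exhibits. Row order within each client follows the input
#' table, and the union of the clients equals the input row-for-row.
#'
#' @param table a sensor data frame with a `cattle_id` column.
#' @param n_clients number of clients (>= 1, <= number of distinct animals).
#' @param seed shuffle seed.
#' @return a list of `n_clients` data frames.
#' @export
partition_by_animal <- function(table, n_clients, seed = 1) {
  n_clients <- check_count(n_clients, "n_clients")
  ids <- unique(table$cattle_id)
  if (n_clients > length(ids)) {
    stop_data("cannot partition %d animals into %d clients",
              length(ids), n_clients)
  }
  shuffled <- with_seed(seed, sample(ids))
  groups <- split(shuffled, rep_len(seq_len(n_clients), length(shuffled)))
  lapply(unname(groups), function(g) {
    out <- table[table$cattle_id %in% g, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Hold out a fraction of animals as a global test herd
#'
#' @param table a sensor data frame.
#' @param test_fraction fraction of animals held out (default 0.2).
#' @param seed shuffle seed.
#' @return list with `train` and `test` data frames (disjoint animal sets).
#' @export
split_animals <- function(table, test_fraction = 0.2, seed = 1) {
  check_prob(test_fraction, "test_fraction")
  ids <- unique(table$cattle_id)
  n_test <- round(length(ids) * test_fraction)
  test_ids <- with_seed(seed, sample(ids, n_test))
  list(train = {
    out <- table[!table$cattle_id %in% test_ids, , drop = FALSE]
    rownames(out) <- NULL
    out
  }, test = {
    out <- table[table$cattle_id %in% test_ids, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Write / read the sensor CSV dialect
#'
#' Emits exactly the canonical header
#' `timestamp,cattle_id,heart_rate,body_temp,activity_level,ambient_temp,humidity,location_lat,location_long,is_stressed`,
#' timestamps in ISO-8601 UTC, missing cells empty. Reading inverts writing.
#'
#' @param table a sensor data frame.
#' @param path file path.
#' @return `write_herd_csv` returns `path` invisibly; `read_herd_csv`
#'   returns the data frame.
#' @export
write_herd_csv <- function(table, path) {
  out <- table[, intersect(HERD_COLUMNS, names(table)), drop = FALSE]
  extra <- setdiff(names(table), HERD_COLUMNS)
  out <- cbind(out, table[, extra, drop = FALSE])
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_herd_csv
#' @export
read_herd_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(cattle_id = "character"))
  tab$timestamp <- as.POSIXct(tab$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC")
  if (!"is_stressed" %in% names(tab)) tab$is_stressed <- NA_integer_
  tab
}

#' Write episode ground truth as a sidecar CSV
#'
#' @param episodes data frame `(cattle_id, start, end)`.
#' @param path file path.
#' @export
write_episode_csv <- function(episodes, path) {
  out <- data.frame(
    cattle_id = episodes$cattle_id,
    start_timestamp = format(episodes$start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    end_timestamp = format(episodes$end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
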