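#' Derive a reproducible sub-seed from a master seed
#'
#' Every stochastic stage of the pipeline (simulation, fault injection,
#' partitioning, parameter initialization, per-round batching) draws its seed
#' from the experiment's master seed plus a stage tag, so stages can be rerun
#' independently and toggling one stage never perturbs another.
#'
#' @param master integer master seed.
#' @param ... stage tags (coerced to character) that identify the stream.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' sub_seed(42, "simulate")
#' sub_seed(42, "round", 3, "client", 7)
sub_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  tags <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  s <- abs(master) %% 2147483647
  for (code in utf8ToInt(tags)) {
    s <- (s * 31 + code) %% 2147483647
  }
  as.integer(s %% 2147483645L + 1L)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("fedherd_config_error", "fedherd_error")))
}

stop_data <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("fedherd_data_error", "fedherd_error")))
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min ||
      x != as.integer(x)) {
    stop_config("'%s' must be an integer >= %s (got %s)", name, min,
                deparse(substitute(x, parent.frame())))
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    stop_config("'%s' must be a positive number", name)
  }
  x
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
    stop_config("'%s' must lie in [0, 1]", name)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Columns of the sensor table, in the canonical emission order.
HERD_COLUMNS <- c("timestamp", "cattle_id", "heart_rate", "body_temp",
                  "activity_level", "ambient_temp", "humidity",
                  "location_lat", "location_long", "is_stressed")

# Physiological columns subject to faults / filling.
PHYSIO_COLUMNS <- c("heart_rate", "body_temp", "activity_level")

# Default model-input feature set: the five numeric sensor channels plus the
# three rolling features. GPS coordinates are deliberately excluded.
MODEL_FEATURES <- c("heart_rate", "body_temp", "activity_level",
                    "ambient_temp", "humidity",
                    "hr_roll_mean", "temp_roll_mean", "activity_roll_var")
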