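# Shared constants and small helpers.

# Canonical body-location order; every channel layout in the package follows it.
FOG_SENSORS <- c(
  "lumbar",
  "upper_leg_left", "upper_leg_right",
  "lower_leg_left", "lower_leg_right",
  "foot_left", "foot_right"
)

FOG_AXES <- c("x", "y", "z")

#' Named sensor configurations
#'
#' The five wearing configurations compared in the sensor ablation: all seven
#' sensors; the six leg/foot sensors; both lower legs; the lumbar sensor
#' alone; and the right foot alone.
#'
#' @return Named list of character vectors of sensor names (canonical order).
#' @export
#' @examples
#' sensor_configs()$lower_legs
sensor_configs <- function() {
  list(
    seven          = FOG_SENSORS,
    six_legs_feet  = setdiff(FOG_SENSORS, "lumbar"),
    lower_legs     = c("lower_leg_left", "lower_leg_right"),
    lumbar         = "lumbar",
    right_foot     = "foot_right"
  )
}

# Resolve a configuration name or an explicit sensor vector to sensor names.
resolve_sensors <- function(sensor_config) {
  if (length(sensor_config) == 1 && sensor_config %in% names(sensor_configs())) {
    return(sensor_configs()[[sensor_config]])
  }
  bad <- setdiff(sensor_config, FOG_SENSORS)
  if (length(bad) > 0) {
    abort(paste0("Unknown sensor name(s): ", paste(bad, collapse = ", ")),
          class = "gaitfog_validation_error")
  }
  FOG_SENSORS[FOG_SENSORS %in% sensor_config]
}

# Channel names for a sensor set: <sensor>_<axis>, axes x, y, z within sensor.
channel_names <- function(sensors) {
  as.vector(t(outer(sensors, FOG_AXES, paste, sep = "_")))
}

#' Derive a stage seed from a global seed
#'
#' Deterministically maps a global integer seed plus a label (stage name,
#' subject index, fold number, ...) to a new 31-bit seed so that pipeline
#' stages can be rerun in isolation with independent but reproducible
#' random streams.
#'
#' @param seed Integer global seed.
#' @param ... Labels (coerced to character) identifying the consumer.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "simulate", 3)
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(key)
  h <- as.double(seed %% 2147483647L)
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Run code with a temporary RNG state seeded at `seed`; restores the caller's
# RNG state afterwards so library calls do not perturb user reproducibility.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a finite number in [%s, %s]", name, lower, upper),
          class = "gaitfog_validation_error")
  }
  invisible(x)
}
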