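#' Remove reader-collision artifacts from an RFID stream
#'
#' Models the reader's dead time: on each antenna, a detection of a
#' *different* tag arriving within `refractory_ms` of the previously kept
#' detection is dropped, because the reader cannot resolve a second tag that
#' quickly. Repeats of the same tag are kept — they indicate continuous
#' presence of one head in the antenna loop, which the reader reports
#' reliably.
#'
#' @param rfid Data frame with columns `t_ms`, `antenna`, `tag_hex`, sorted
#'   by `t_ms`.
#' @param refractory_ms Dead time in ms (default 250). A different tag is
#'   kept only when it arrives strictly more than `refractory_ms` after the
#'   previously kept read.
#' @return The stream with collided reads removed.
#' @export
debounce_rfid <- function(rfid, refractory_ms = 250) {
  if (!nrow(rfid)) return(rfid)
  if (is.unsorted(rfid$t_ms)) stop("rfid stream must be sorted by t_ms")
  keep <- logical(nrow(rfid))
  for (ant in unique(rfid$antenna)) {
    idx <- which(rfid$antenna == ant)
    last_t <- -Inf
    last_tag <- NA_character_
    for (i in idx) {
      same <- !is.na(last_tag) && rfid$tag_hex[i] == last_tag
      if (same || rfid$t_ms[i] - last_t > refractory_ms) {
        keep[i] <- TRUE
        last_t <- rfid$t_ms[i]
        last_tag <- rfid$tag_hex[i]
      }
    }
  }
  out <- rfid[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attribute licks to animals via the RFID window rule
#'
#' Each lick on a spout is assigned to the animal of the latest RFID
#' detection on that spout's antenna at or before the lick, provided the gap
#' does not exceed the assignment window (default 3 s, inclusive). Licks with
#' no qualifying detection are attributed to [RAT_UNKNOWN]. The operation is
#' idempotent for a fixed log.
#'
#' @param log A [session_log()] whose `rfid` stream is already debounced;
#'   licks must be unassigned (all `NA`) unless `force = TRUE`.
#' @param force Re-assign even if `assigned_to` is already filled.
#' @return The log with `licks$assigned_to` filled.
#' @export
assign_licks <- function(log, force = FALSE) {
  log <- validate_session_log(log)
  if (!force && nrow(log$licks) && any(!is.na(log$licks$assigned_to)))
    stop("licks already assigned; use force = TRUE to re-assign")
  win <- log$config$assignment_window_ms
  licks <- log$licks
  licks$assigned_to <- rep(RAT_UNKNOWN, nrow(licks))
  for (sp in .SPOUTS) {
    det <- log$rfid[log$rfid$antenna == sp, , drop = FALSE]
    li <- which(licks$spout == sp)
    if (!length(li)) next
    if (!nrow(det)) next
    who <- canonicalize_tag(det$tag_hex, sp, log$animals)
    # latest detection with t <= lick time
    pos <- findInterval(licks$t_ms[li], det$t_ms)
    ok <- pos >= 1
    ok[ok] <- licks$t_ms[li][ok] - det$t_ms[pos[ok]] <= win
    licks$assigned_to[li[ok]] <- who[pos[ok]]
  }
  log$licks <- licks
  log
}

#' Run per-animal reinforcement schedules over an assigned lick stream
#'
#' Every registered animal carries an independent counter of its assigned
#' licks on the active spout. Under a fixed ratio (FR) a reward is emitted at
#' the timestamp of each `ratio`-th assigned active lick, so an animal with
#' `n` assigned active licks earns `floor(n / ratio)` rewards. Under a
#' variable ratio (VR) each successive requirement is drawn uniformly from
#' `{ratio - k, ..., ratio + k}` using the configured seed. Licks on the
#' inactive spout and licks attributed to [RAT_UNKNOWN] never advance any
#' counter. Each reward also schedules a cue-light flash of
#' `cue_duration_ms`; flashes may overlap when rewards are closer than the
#' flash length, and both are logged.
#'
#' @param log A [session_log()] with assigned licks.
#' @return The log with `rewards` filled and a `cues` data frame
#'   (`t_ms`, `duration_ms`) attached as `log$cues`. Cues are derivable
#'   from the reward stream, so [write_session_log()] does not persist
#'   them.
#' @export
run_schedule <- function(log) {
  log <- validate_session_log(log)
  if (nrow(log$licks) && any(is.na(log$licks$assigned_to)))
    stop("licks must be assigned before scheduling; run assign_licks()")
  cfg <- log$config
  active <- log$licks[log$licks$spout == "active", , drop = FALSE]
  if (nrow(log$licks) && nrow(active) &&
      all(active$assigned_to == RAT_UNKNOWN))
    warning("all active licks are unattributed (", RAT_UNKNOWN,
            "): no rewards delivered")
  rewards <- list()
  for (a in log$animals$animal_id) {
    t_a <- active$t_ms[active$assigned_to == a]
    n <- length(t_a)
    if (!n) next
    if (cfg$schedule_kind == "FR") {
      hit <- seq_len(n)[seq_len(n) %% cfg$ratio == 0]
    } else {
      reqs <- vr_requirements(cfg, animal_id = a, n_licks = n)
      hit <- cumsum(reqs)
      hit <- hit[hit <= n]
    }
    if (!length(hit)) next
    rewards[[a]] <- data.frame(
      t_ms = t_a[hit], animal_id = a,
      volume_ul = cfg$reward_volume_ul,
      licks_at_dispense = hit, stringsAsFactors = FALSE)
  }
  rw <- if (length(rewards)) do.call(rbind, rewards) else
    empty_reward_stream()
  rw <- sort_stream(rw)
  log$rewards <- rw
  log$cues <- data.frame(
    t_ms = rw$t_ms,
    duration_ms = rep(cfg$cue_duration_ms, nrow(rw)))
  validate_session_log(log)
}

# VR requirement draws: one independent, seeded sub-stream per animal so the
# sequence an animal faces does not depend on its cagemate's behavior.
vr_requirements <- function(cfg, animal_id, n_licks) {
  k <- cfg$vr_spread
  support <- (cfg$ratio - k):(cfg$ratio + k)
  n_max <- ceiling(n_licks / max(cfg$ratio - k, 1)) + 1
  seed <- (cfg$rng_seed + utf8_seed(animal_id)) %% .Machine$integer.max
  with_seed(seed, sample(support, n_max, replace = TRUE))
}

utf8_seed <- function(x) {
  sum(utf8ToInt(x) * seq_along(utf8ToInt(x))) %% 100000L
}

# evaluate code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

#' House-light state at a wall-clock time
#'
#' The house light is on between 21:00 and 09:00 (animals are housed on a
#' reversed light cycle) and off the rest of the day. The interval is
#' half-open, `[21:00, 09:00)`: 21:00 exactly is on, 09:00 exactly is off.
#'
#' @param clock_time Time of day as `"HH:MM"` / `"HH:MM:SS"` strings, or
#'   numeric hours in `[0, 24)`.
#' @return Character vector, `"on"` or `"off"`.
#' @examples
#' house_light_state(c("22:00", "12:00", "09:00"))  # on off off
#' @export
house_light_state <- function(clock_time) {
  mins <- if (is.character(clock_time)) {
    parts <- strsplit(clock_time, ":", fixed = TRUE)
    vapply(parts, function(p) {
      p <- suppressWarnings(as.numeric(p))
      if (length(p) < 2 || anyNA(p[1:2]) || p[1] < 0 || p[1] >= 24 ||
          p[2] < 0 || p[2] >= 60)
        stop("invalid clock time")
      p[1] * 60 + p[2]
    }, numeric(1))
  } else {
    if (any(clock_time < 0 | clock_time >= 24)) stop("invalid clock time")
    clock_time * 60
  }
  ifelse(mins >= 21 * 60 | mins < 9 * 60, "on", "off")
}

#' Stepper-motor model for the syringe pump
#'
#' @param step_angle_deg Step angle in degrees (default 1.8, i.e. 200 steps
#'   per revolution).
#' @param steps_per_ul Motor steps per microliter dispensed; `NULL` until
#'   calibrated.
#' @return A list of class `motor_model`.
#' @export
motor_model <- function(step_angle_deg = 1.8, steps_per_ul = NULL) {
  if (step_angle_deg <= 0) stop("step_angle_deg must be positive")
  if (!is.null(steps_per_ul) && steps_per_ul <= 0)
    stop("steps_per_ul must be positive")
  structure(list(step_angle_deg = step_angle_deg,
                 steps_per_ul = steps_per_ul),
            class = "motor_model")
}

#' Steps per full motor revolution
#'
#' @param motor A [motor_model()].
#' @return `round(360 / step_angle_deg)`.
#' @examples
#' steps_per_revolution(motor_model(1.8))  # 200
#' @export
steps_per_revolution <- function(motor) {
  round(360 / motor$step_angle_deg)
}

#' Motor steps needed to dispense a volume
#'
#' @param volume_ul Volume in microliters (positive).
#' @param motor A calibrated [motor_model()].
#' @return Integer number of steps, `round(volume_ul * steps_per_ul)`.
#' @export
steps_for_volume <- function(volume_ul, motor) {
  if (is.null(motor$steps_per_ul))
    stop("motor is uncalibrated: steps_per_ul is not set")
  if (any(volume_ul <= 0)) stop("volume_ul must be positive")
  round(volume_ul * motor$steps_per_ul)
}

#' Pump calibration from measured delivery volumes
#'
#' The calibration protocol commands `rewards_per_iteration` deliveries of
#' `per_reward_ul` each (default 5 x 60 ul = 300 ul per iteration), repeats
#' the iteration three times (900 ul cumulative), and weighs what actually
#' came out. The correction factor is commanded total over measured total;
#' multiplying the motor's `steps_per_ul` by it makes subsequent deliveries
#' hit the commanded volume.
#'
#' @param measured_totals_ul Measured volume per iteration, in ul
#'   (conventionally three positive values).
#' @param per_reward_ul Commanded volume per delivery (default 60).
#' @param rewards_per_iteration Deliveries per iteration (default 5).
#' @param motor Optional [motor_model()]; when supplied and calibrated, a
#'   corrected copy is returned in the result.
#' @return A list of class `pump_calibration` with `commanded_total_ul`,
#'   `measured_totals_ul`, `correction_factor`, `per_reward_commanded_ul`,
#'   and optionally `motor` (corrected).
#' @examples
#' calibrate_pump(c(300, 300, 300))$correction_factor   # 1
#' calibrate_pump(c(270, 270, 270))$correction_factor   # 900/810
#' @export
calibrate_pump <- function(measured_totals_ul, per_reward_ul = 60,
                           rewards_per_iteration = 5, motor = NULL) {
  if (!length(measured_totals_ul) || any(measured_totals_ul <= 0) ||
      anyNA(measured_totals_ul))
    stop("all measured volumes must be positive")
  commanded <- per_reward_ul * rewards_per_iteration *
    length(measured_totals_ul)
  factor <- commanded / sum(measured_totals_ul)
  out <- list(commanded_total_ul = commanded,
              measured_totals_ul = measured_totals_ul,
              correction_factor = factor,
              per_reward_commanded_ul = per_reward_ul)
  if (!is.null(motor)) {
    if (is.null(motor$steps_per_ul))
      stop("cannot correct an uncalibrated motor (steps_per_ul unset)")
    out$motor <- motor_model(motor$step_angle_deg,
                             motor$steps_per_ul * factor)
  }
  class(out) <- "pump_calibration"
  out
}

#' @export
print.pump_calibration <- function(x, ...) {
  cat(sprintf(
    "<pump_calibration> commanded %g ul, measured %g ul, factor %.4f\n",
    x$commanded_total_ul, sum(x$measured_totals_ul), x$correction_factor))
  invisible(x)
}

#' Run a complete session through the engine
#'
#' Deterministic event-ordered reduction of a raw session: debounce the RFID
#' stream, attribute licks, then run the reinforcement schedules. Identical
#' inputs (and seed, under VR) give an identical session log.
#'
#' @param config A [session_config()].
#' @param animals An [animal_registry()].
#' @param rfid Raw RFID stream (`t_ms`, `antenna`, `tag_hex`).
#' @param licks Raw lick stream (`t_ms`, `spout`), unassigned.
#' @param metadata Optional metadata list.
#' @return A complete [session_log()].
#' @export
run_session <- function(config, animals, rfid = empty_rfid_stream(),
                        licks = empty_lick_stream(), metadata = list()) {
  licks$assigned_to <- NULL
  log <- session_log(config, animals, rfid = rfid, licks = licks,
                     metadata = metadata)
  log$rfid <- debounce_rfid(log$rfid, config$rfid_refractory_ms)
  log <- assign_licks(log)
  run_schedule(log)
}
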