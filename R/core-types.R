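#' Sentinel label for licks that cannot be attributed to an animal
#'
#' When no RFID detection precedes a lick within the assignment window the
#' lick is attributed to this sentinel rather than to any registered animal.
#' Unattributed licks never advance a reinforcement schedule.
#'
#' @format A length-one character vector.
#' @export
RAT_UNKNOWN <- "RatUnknown"

.SPOUTS <- c("active", "inactive")
.SEXES <- c("male", "female")
.GROUPS <- c("single", "duo")

#' Build an animal registry
#'
#' The registry maps each animal to its RFID tag under both reader dialects.
#' The reader guarding the active spout reports tags as 8-digit hexadecimal
#' strings while the inactive-spout reader reports 10-digit strings; how the
#' two encodings of one chip relate is reader firmware detail, so the mapping
#' is declared explicitly here, never inferred from string arithmetic.
#'
#' @param animal_id Character vector of short animal labels (unique).
#' @param rfid_active 8-digit hexadecimal tag strings, one per animal, as
#'   reported by the active-spout antenna.
#' @param rfid_inactive 10-digit hexadecimal tag strings, as reported by the
#'   inactive-spout antenna.
#' @param sex `"male"` or `"female"` per animal.
#' @param group Housing/testing condition, `"single"` or `"duo"`.
#' @param body_weight_g Body weight in grams (positive), recorded before the
#'   session.
#' @return A `data.frame` of class `animal_registry`.
#' @examples
#' animal_registry(
#'   animal_id = c("r1", "r2"),
#'   rfid_active = c("0A1B2C3D", "11223344"),
#'   rfid_inactive = c("000A1B2C3D", "0011223344"),
#'   sex = c("male", "male"), group = "duo", body_weight_g = c(410, 395)
#' )
#' @export
animal_registry <- function(animal_id, rfid_active, rfid_inactive,
                            sex = "male", group = "single",
                            body_weight_g = NA_real_) {
  n <- length(animal_id)
  reg <- data.frame(
    animal_id = as.character(animal_id),
    rfid_active = toupper(as.character(rfid_active)),
    rfid_inactive = toupper(as.character(rfid_inactive)),
    sex = rep_len(as.character(sex), n),
    group = rep_len(as.character(group), n),
    body_weight_g = rep_len(as.numeric(body_weight_g), n),
    stringsAsFactors = FALSE
  )
  validate_registry(reg)
}

validate_registry <- function(reg) {
  stopifnot(is.data.frame(reg))
  need <- c("animal_id", "rfid_active", "rfid_inactive", "sex", "group",
            "body_weight_g")
  missing <- setdiff(need, names(reg))
  if (length(missing))
    stop("registry is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(reg$animal_id))
    stop("duplicate animal_id in registry")
  if (any(reg$animal_id == RAT_UNKNOWN))
    stop("animal_id may not equal the sentinel ", RAT_UNKNOWN)
  if (any(!nzchar(reg$rfid_active)) || any(!nzchar(reg$rfid_inactive)))
    stop("rfid tags must be non-empty")
  if (any(!grepl("^[0-9A-F]{8}$", reg$rfid_active)))
    stop("rfid_active tags must be 8 hexadecimal digits")
  if (any(!grepl("^[0-9A-F]{10}$", reg$rfid_inactive)))
    stop("rfid_inactive tags must be 10 hexadecimal digits")
  if (anyDuplicated(reg$rfid_active) || anyDuplicated(reg$rfid_inactive))
    stop("two animals share a tag: registry tags must be unique per antenna")
  if (any(!is.na(reg$body_weight_g) & reg$body_weight_g <= 0))
    stop("body_weight_g must be positive")
  if (any(!reg$sex %in% .SEXES))
    stop("sex must be one of: ", paste(.SEXES, collapse = ", "))
  if (any(!reg$group %in% .GROUPS))
    stop("group must be one of: ", paste(.GROUPS, collapse = ", "))
  class(reg) <- c("animal_registry", "data.frame")
  reg
}

#' Session configuration
#'
#' Collects the schedule and every timing constant the engine uses. Defaults
#' reproduce the reference deployment: 1 h sessions, fixed-ratio 5, 60 ul
#' rewards, 3 s lick-attribution window, 0.5 s reward cue, 250 ms RFID reader
#' refractory, and 16 ms touch-sensor sampling.
#'
#' @param session_length_ms Session duration in ms (default 3,600,000 = 1 h).
#' @param schedule_kind `"FR"` (fixed ratio) or `"VR"` (variable ratio).
#' @param ratio Response requirement (default 5). Under VR this is the mean
#'   of the drawn requirements.
#' @param vr_spread Half-width `k` of the VR support `{ratio-k, ..., ratio+k}`
#'   (default 2); ignored under FR.
#' @param reward_volume_ul Reward drop volume in microliters (default 60).
#' @param assignment_window_ms Maximal delay between an RFID detection and a
#'   lick for the lick to be attributed to that animal (default 3,000;
#'   inclusive boundary).
#' @param cue_duration_ms Cue-light flash duration on reward (default 500).
#' @param rfid_refractory_ms Reader dead time before a different tag can be
#'   read on the same antenna (default 250).
#' @param touch_sample_ms Touch-sensor electrode sampling interval (default
#'   16); the simulator quantizes lick times to this grid, the engine does
#'   not.
#' @param rng_seed Integer seed; required for VR schedules so requirement
#'   draws are reproducible.
#' @return A list of class `session_config`.
#' @export
session_config <- function(session_length_ms = 3600000,
                           schedule_kind = c("FR", "VR"),
                           ratio = 5,
                           vr_spread = 2,
                           reward_volume_ul = 60,
                           assignment_window_ms = 3000,
                           cue_duration_ms = 500,
                           rfid_refractory_ms = 250,
                           touch_sample_ms = 16,
                           rng_seed = NULL) {
  schedule_kind <- match.arg(schedule_kind)
  cfg <- list(
    session_length_ms = as.numeric(session_length_ms),
    schedule_kind = schedule_kind,
    ratio = as.integer(ratio),
    vr_spread = as.integer(vr_spread),
    reward_volume_ul = as.numeric(reward_volume_ul),
    assignment_window_ms = as.numeric(assignment_window_ms),
    cue_duration_ms = as.numeric(cue_duration_ms),
    rfid_refractory_ms = as.numeric(rfid_refractory_ms),
    touch_sample_ms = as.numeric(touch_sample_ms),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  durs <- c("session_length_ms", "reward_volume_ul", "assignment_window_ms",
            "cue_duration_ms", "rfid_refractory_ms", "touch_sample_ms")
  for (f in durs)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      stop(f, " must be a positive scalar")
  if (!cfg$schedule_kind %in% c("FR", "VR"))
    stop("schedule_kind must be FR or VR")
  if (is.na(cfg$ratio) || cfg$ratio < 1)
    stop("ratio must be a positive integer")
  if (cfg$schedule_kind == "VR") {
    if (is.null(cfg$rng_seed))
      stop("VR schedules require rng_seed for reproducibility")
    if (cfg$vr_spread < 0 || cfg$vr_spread >= cfg$ratio)
      stop("vr_spread must be in [0, ratio)")
  }
  class(cfg) <- "session_config"
  cfg
}

empty_rfid_stream <- function() {
  data.frame(t_ms = numeric(0), antenna = character(0),
             tag_hex = character(0), stringsAsFactors = FALSE)
}

empty_lick_stream <- function() {
  data.frame(t_ms = numeric(0), spout = character(0),
             assigned_to = character(0), stringsAsFactors = FALSE)
}

empty_reward_stream <- function() {
  data.frame(t_ms = numeric(0), animal_id = character(0),
             volume_ul = numeric(0), licks_at_dispense = numeric(0),
             stringsAsFactors = FALSE)
}

#' Assemble a session log
#'
#' The session log is the interchange object between the engine, the
#' analytics and the simulator: a configuration, an animal registry and the
#' three timestamped event streams (RFID detections, licks, rewards). Streams
#' are sorted by time on construction; ties keep input order, so an RFID
#' detection logged at the same millisecond as a lick still precedes it.
#'
#' @param config A [session_config()].
#' @param animals An [animal_registry()].
#' @param rfid Data frame with columns `t_ms`, `antenna`
#'   (`"active"`/`"inactive"`), `tag_hex`.
#' @param licks Data frame with columns `t_ms`, `spout`, and optionally
#'   `assigned_to` (`NA` until [assign_licks()] runs).
#' @param rewards Data frame with columns `t_ms`, `animal_id`, `volume_ul`,
#'   `licks_at_dispense`; usually filled by [run_schedule()].
#' @param metadata Free-form list (session index, date, chamber label, ...).
#' @return A list of class `session_log`.
#' @export
session_log <- function(config, animals,
                        rfid = empty_rfid_stream(),
                        licks = empty_lick_stream(),
                        rewards = empty_reward_stream(),
                        metadata = list()) {
  config <- validate_config(unclass(config))
  animals <- validate_registry(animals)
  rfid <- as.data.frame(rfid, stringsAsFactors = FALSE)
  licks <- as.data.frame(licks, stringsAsFactors = FALSE)
  rewards <- as.data.frame(rewards, stringsAsFactors = FALSE)
  if (!"assigned_to" %in% names(licks))
    licks$assigned_to <- rep(NA_character_, nrow(licks))
  log <- structure(
    list(config = config, animals = animals,
         rfid = sort_stream(rfid), licks = sort_stream(licks),
         rewards = sort_stream(rewards), metadata = metadata),
    class = "session_log")
  validate_session_log(log)
}

sort_stream <- function(df) {
  if (nrow(df) && is.unsorted(df$t_ms))
    df <- df[order(df$t_ms), , drop = FALSE]
  rownames(df) <- NULL
  df
}

validate_session_log <- function(log) {
  stopifnot(inherits(log, "session_log"))
  check_stream(log$rfid, c("t_ms", "antenna", "tag_hex"), "rfid")
  check_stream(log$licks, c("t_ms", "spout", "assigned_to"), "licks")
  check_stream(log$rewards,
               c("t_ms", "animal_id", "volume_ul", "licks_at_dispense"),
               "rewards")
  if (nrow(log$rfid) && any(!log$rfid$antenna %in% .SPOUTS))
    stop("rfid antenna must be 'active' or 'inactive'")
  if (nrow(log$licks)) {
    if (any(!log$licks$spout %in% .SPOUTS))
      stop("lick spout must be 'active' or 'inactive'")
    if (any(log$licks$t_ms > log$config$session_length_ms))
      stop("lick timestamps exceed session_length_ms")
    assigned <- log$licks$assigned_to
    known <- is.na(assigned) | assigned == RAT_UNKNOWN |
      assigned %in% log$animals$animal_id
    if (!all(known))
      stop("assigned_to labels absent from registry: ",
           paste(unique(assigned[!known]), collapse = ", "))
  }
  if (nrow(log$rewards)) {
    if (any(log$rewards$volume_ul <= 0))
      stop("reward volume_ul must be positive")
    if (any(!log$rewards$animal_id %in% log$animals$animal_id))
      stop("reward animal_id absent from registry")
  }
  log
}

check_stream <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " stream missing columns: ", paste(missing, collapse = ", "))
  if (nrow(df)) {
    bad <- which(!is.finite(df$t_ms) | df$t_ms < 0)
    if (length(bad))
      stop(what, " stream row ", bad[1], ": invalid timestamp ",
           df$t_ms[bad[1]])
  }
  invisible(df)
}

#' Resolve a raw RFID tag to an animal identity
#'
#' Pure lookup: the tag string (in the dialect of the antenna that read it)
#' is matched against the registry column for that antenna. Unregistered tags
#' resolve to [RAT_UNKNOWN]; registry construction already rejects duplicate
#' tags, so a match is unique.
#'
#' @param tag_hex Character vector of raw tag strings.
#' @param antenna `"active"` (8-digit dialect) or `"inactive"` (10-digit).
#' @param registry An [animal_registry()].
#' @return Character vector of animal ids, `RAT_UNKNOWN` where unmatched.
#' @examples
#' reg <- animal_registry("r1", "0A1B2C3D", "000A1B2C3D", body_weight_g = 400)
#' canonicalize_tag("0a1b2c3d", "active", reg)    # "r1"
#' canonicalize_tag("DEADBEEF", "active", reg)    # "RatUnknown"
#' @export
canonicalize_tag <- function(tag_hex, antenna, registry) {
  registry <- validate_registry(registry)
  antenna <- match.arg(antenna, .SPOUTS)
  col <- if (antenna == "active") registry$rfid_active else
    registry$rfid_inactive
  idx <- match(toupper(as.character(tag_hex)), col)
  out <- registry$animal_id[idx]
  out[is.na(idx)] <- RAT_UNKNOWN
  out
}

#' @export
print.session_log <- function(x, ...) {
  cat("<session_log>\n")
  cat(sprintf("  schedule: %s%d, reward %g ul, length %g min\n",
              x$config$schedule_kind, x$config$ratio,
              x$config$reward_volume_ul,
              x$config$session_length_ms / 60000))
  cat(sprintf("  animals: %s\n", paste(x$animals$animal_id, collapse = ", ")))
  cat(sprintf("  events: %d rfid, %d licks, %d rewards\n",
              nrow(x$rfid), nrow(x$licks), nrow(x$rewards)))
  invisible(x)
}
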