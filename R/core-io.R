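#' Write a session log to a directory of delimited-text tables
#'
#' Serializes a [session_log()] as four comma-delimited UTF-8 tables with
#' header rows — `rfid.csv` (`t_ms,antenna,tag_hex`), `licks.csv`
#' (`t_ms,spout,assigned_to`), `rewards.csv`
#' (`t_ms,animal_id,volume_ul,licks_at_dispense`), `animals.csv` — plus a
#' `config.yaml` sidecar holding the configuration and metadata. Output is
#' byte-stable for a fixed input, so logs diff cleanly under version control.
#'
#' @param log A valid [session_log()].
#' @param path Directory to write into (created if absent).
#' @return `path`, invisibly.
#' @seealso [read_session_log()]
#' @export
write_session_log <- function(log, path) {
  log <- validate_session_log(log)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_table <- function(df, file) {
    if ("t_ms" %in% names(df)) df$t_ms <- fmt_num(df$t_ms)
    if ("volume_ul" %in% names(df)) df$volume_ul <- fmt_num(df$volume_ul)
    utils::write.csv(df, file.path(path, file), row.names = FALSE,
                     quote = FALSE, na = "", fileEncoding = "UTF-8",
                     eol = "\n")
  }
  write_table(log$rfid, "rfid.csv")
  write_table(log$licks, "licks.csv")
  write_table(log$rewards, "rewards.csv")
  write_table(as.data.frame(log$animals), "animals.csv")
  sidecar <- list(config = unclass(log$config), metadata = log$metadata)
  yaml::write_yaml(sidecar, file.path(path, "config.yaml"))
  invisible(path)
}

fmt_num <- function(x) {
  # fixed notation, no trailing zeros: stable across locales and re-reads
  trimws(formatC(x, format = "fg", digits = 15))
}

#' Read a session log written by [write_session_log()]
#'
#' Validates every row; a malformed row (negative or non-numeric timestamp,
#' unknown antenna or spout label) raises an error naming the file and row.
#' Streams found out of time order are re-sorted with a warning.
#'
#' @param path Directory containing `rfid.csv`, `licks.csv`, `rewards.csv`,
#'   `animals.csv` and `config.yaml`.
#' @return A [session_log()].
#' @export
read_session_log <- function(path) {
  need <- c("rfid.csv", "licks.csv", "rewards.csv", "animals.csv",
            "config.yaml")
  for (f in need)
    if (!file.exists(file.path(path, f)))
      stop("session log at '", path, "' is missing ", f)
  sidecar <- yaml::read_yaml(file.path(path, "config.yaml"))
  cfg <- validate_config(sidecar$config)
  animals <- validate_registry(
    utils::read.csv(file.path(path, "animals.csv"),
                    colClasses = c(rfid_active = "character",
                                   rfid_inactive = "character"),
                    stringsAsFactors = FALSE))
  rfid <- read_stream(file.path(path, "rfid.csv"),
                      c("t_ms", "antenna", "tag_hex"))
  licks <- read_stream(file.path(path, "licks.csv"),
                       c("t_ms", "spout", "assigned_to"),
                       optional = "assigned_to")
  rewards <- read_stream(file.path(path, "rewards.csv"),
                         c("t_ms", "animal_id", "volume_ul",
                           "licks_at_dispense"))
  for (nm in c("rfid", "licks", "rewards")) {
    df <- get(nm)
    if (nrow(df) && is.unsorted(df$t_ms))
      warning(nm, " stream was out of order; re-sorted by t_ms")
  }
  if ("assigned_to" %in% names(licks))
    licks$assigned_to[!is.na(licks$assigned_to) &
                        licks$assigned_to == ""] <- NA_character_
  session_log(cfg, animals, rfid = rfid, licks = licks, rewards = rewards,
              metadata = if (is.null(sidecar$metadata)) list() else
                sidecar$metadata)
}

read_stream <- function(file, cols, optional = character(0)) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = if ("tag_hex" %in% cols)
                          c(tag_hex = "character") else NA)
  missing <- setdiff(setdiff(cols, optional), names(df))
  if (length(missing))
    stop(basename(file), " is missing columns: ",
         paste(missing, collapse = ", "))
  if (nrow(df)) {
    t_num <- suppressWarnings(as.numeric(df$t_ms))
    bad <- which(is.na(t_num) | t_num < 0)
    if (length(bad))
      stop(basename(file), " row ", bad[1], ": malformed timestamp '",
           df$t_ms[bad[1]], "'")
    df$t_ms <- t_num
  }
  for (ch in intersect(c("antenna", "tag_hex", "spout", "assigned_to",
                         "animal_id"), names(df)))
    df[[ch]] <- as.character(df[[ch]])
  df
}

#' Read a camera object-detection table
#'
#' Reads the per-frame bounding-box CSV emitted by an upstream object
#' detector: one row per detected object with columns
#' `frame_index,obj_class,cx,cy,w,h,confidence`. Object classes cover the
#' animal body parts and spouts (`rat`, `head`, `nose`, `tail_base`, `tail`,
#' `active_spout`, `inactive_spout`, `head_in_spout`). Frame timestamps are
#' derived as `frame_index * frame_period_s`.
#'
#' @param path CSV file path.
#' @param frame_period_s Capture period in seconds (default 2, one picture
#'   every 2 s).
#' @return A `data.frame` of detection records with an added `t_s` column.
#' @export
read_detections <- function(path, frame_period_s = 2) {
  if (!file.exists(path)) stop("detection table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_detections(df, frame_period_s)
}

validate_detections <- function(df, frame_period_s = 2) {
  need <- c("frame_index", "obj_class", "cx", "cy", "w", "h", "confidence")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("detection table missing columns: ",
         paste(missing, collapse = ", "))
  if (nrow(df)) {
    bad <- which(df$confidence < 0 | df$confidence > 1)
    if (length(bad))
      stop("detection row ", bad[1], ": confidence outside [0,1]")
    bad <- which(df$w <= 0 | df$h <= 0)
    if (length(bad))
      stop("detection row ", bad[1], ": non-positive box extent")
  }
  df$t_s <- df$frame_index * frame_period_s
  df
}

#' Write a detection table
#'
#' @param df Detection records as from [read_detections()] or
#'   [simulate_trajectories()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(df, path) {
  keep <- intersect(c("frame_index", "obj_class", "cx", "cy", "w", "h",
                      "confidence", "session"), names(df))
  out <- df[, keep, drop = FALSE]
  for (num in intersect(c("cx", "cy", "w", "h", "confidence"), names(out)))
    out[[num]] <- trimws(formatC(out[[num]], format = "fg", digits = 10))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
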