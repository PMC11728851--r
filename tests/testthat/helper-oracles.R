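# Shared fixtures and independent brute-force oracles.

test_registry <- function(n = 2) {
  animal_registry(
    animal_id = paste0("r", seq_len(n)),
    rfid_active = sprintf("%08X", seq_len(n) * 1111L),
    rfid_inactive = sprintf("%010X", seq_len(n) * 1111L),
    sex = rep(c("male", "female"), length.out = n),
    group = if (n == 2) "duo" else "single",
    body_weight_g = 400 + seq_len(n)
  )
}

short_config <- function(...) {
  session_config(session_length_ms = 60000, ...)
}

# A random small session: detections drawn from registered tags (plus the
# occasional stray unregistered tag), licks scattered over both spouts.
random_stream_log <- function(seed, config = short_config(),
                              n_animals = 2) {
  set.seed(seed)
  reg <- test_registry(n_animals)
  n_det <- sample(0:25, 1)
  n_licks <- sample(0:40, 1)
  horizon <- config$session_length_ms
  antenna <- sample(c("active", "inactive"), n_det, replace = TRUE)
  tag <- vapply(antenna, function(a) {
    pool <- if (a == "active") c(reg$rfid_active, "DEADBEEF") else
      c(reg$rfid_inactive, "00DEADBEEF")
    sample(pool, 1, prob = c(rep(4, n_animals), 1))
  }, character(1))
  rfid <- data.frame(t_ms = sort(sample(0:horizon, n_det, replace = TRUE)),
                     antenna = antenna, tag_hex = tag,
                     stringsAsFactors = FALSE)
  licks <- data.frame(
    t_ms = sort(sample(0:horizon, n_licks, replace = TRUE)),
    spout = sample(c("active", "inactive"), n_licks, replace = TRUE),
    stringsAsFactors = FALSE)
  session_log(config, reg, rfid = rfid, licks = licks)
}

# O(n * m) assignment oracle: for every lick scan ALL detections on its
# spout's antenna and take the latest one within the window.
oracle_assign <- function(log) {
  licks <- log$licks
  win <- log$config$assignment_window_ms
  for (i in seq_len(nrow(licks))) {
    sp <- licks$spout[i]
    t <- licks$t_ms[i]
    ok <- which(log$rfid$antenna == sp & log$rfid$t_ms <= t &
                  t - log$rfid$t_ms <= win)
    licks$assigned_to[i] <- if (length(ok)) {
      j <- max(ok)  # stream is time-sorted: max index = latest detection
      canonicalize_tag(log$rfid$tag_hex[j], sp, log$animals)
    } else RAT_UNKNOWN
  }
  licks
}

# Per-animal FR counter simulation, lick by lick.
oracle_fr_rewards <- function(log) {
  counters <- stats::setNames(rep(0L, nrow(log$animals)),
                              log$animals$animal_id)
  out <- list()
  licks <- log$licks[order(log$licks$t_ms), , drop = FALSE]
  for (i in seq_len(nrow(licks))) {
    a <- licks$assigned_to[i]
    if (licks$spout[i] != "active" || is.na(a) || a == RAT_UNKNOWN ||
        !a %in% names(counters)) next
    counters[a] <- counters[a] + 1L
    if (counters[a] %% log$config$ratio == 0)
      out[[length(out) + 1L]] <- data.frame(
        t_ms = licks$t_ms[i], animal_id = a,
        licks_at_dispense = counters[a])
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(t_ms = numeric(0), animal_id = character(0),
               licks_at_dispense = numeric(0))
}

# Detection-table rows, one call per object, for hand-built spatial cases.
det_row <- function(frame, cls, cx, cy, conf = 0.9, w = 8, h = 8) {
  data.frame(frame_index = frame, obj_class = cls, cx = cx, cy = cy,
             w = w, h = h, confidence = conf, stringsAsFactors = FALSE)
}

dir_digest <- function(path) {
  files <- sort(list.files(path, recursive = TRUE, full.names = TRUE))
  md5 <- tools::md5sum(files)
  names(md5) <- substring(files, nchar(path) + 2)
  md5
}
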