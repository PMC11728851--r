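#' Segment a lick train into clusters
#'
#' A lick cluster (bout) is a run of licks in rapid succession; the run is
#' sustained until a pause longer than `pause_ms`. A gap strictly greater
#' than the threshold ends the cluster — a gap of exactly `pause_ms` is still
#' tolerated within a cluster. Isolated licks form size-1 clusters.
#'
#' @param t_ms Sorted lick timestamps (ms) of one animal on one spout.
#' @param pause_ms Pause threshold in ms (default 1000).
#' @return A `data.frame` with one row per cluster: `cluster`, `start_ms`,
#'   `end_ms`, `n_licks`, and a list-column `within_ilis_ms` holding the
#'   `n_licks - 1` successive within-cluster gaps.
#' @examples
#' segment_clusters(c(0, 150, 300, 2000, 2200))  # two clusters, sizes 3 and 2
#' @export
segment_clusters <- function(t_ms, pause_ms = 1000) {
  if (!length(t_ms)) {
    return(data.frame(cluster = integer(0), start_ms = numeric(0),
                      end_ms = numeric(0), n_licks = integer(0),
                      within_ilis_ms = I(list())))
  }
  if (is.unsorted(t_ms)) stop("lick timestamps must be sorted")
  gaps <- diff(t_ms)
  cl <- cumsum(c(1L, as.integer(gaps > pause_ms)))
  idx <- split(seq_along(t_ms), cl)
  out <- data.frame(
    cluster = seq_along(idx),
    start_ms = vapply(idx, function(i) t_ms[i[1]], numeric(1)),
    end_ms = vapply(idx, function(i) t_ms[i[length(i)]], numeric(1)),
    n_licks = lengths(idx)
  )
  out$within_ilis_ms <- I(lapply(idx, function(i)
    if (length(i) > 1) diff(t_ms[i]) else numeric(0)))
  rownames(out) <- NULL
  out
}

#' Mean interlick interval
#'
#' The interlick interval (ILI) is the time between successive licks.
#' By default only within-cluster gaps are pooled: gaps longer than the
#' pause threshold are pauses between bouts, not part of the lick rhythm.
#' `mode = "pooled"` averages all successive gaps regardless of cluster
#' structure, for comparison.
#'
#' @param clusters Output of [segment_clusters()].
#' @param mode `"within"` (default) or `"pooled"`.
#' @return Mean ILI in ms, or `NA_real_` when no cluster has two licks.
#' @export
mean_ili <- function(clusters, mode = c("within", "pooled")) {
  mode <- match.arg(mode)
  gaps <- unlist(clusters$within_ilis_ms, use.names = FALSE)
  if (mode == "pooled" && nrow(clusters) > 1) {
    between <- clusters$start_ms[-1] -
      clusters$end_ms[-nrow(clusters)]
    gaps <- c(gaps, between)
  }
  if (!length(gaps)) return(NA_real_)
  mean(gaps)
}

#' Latency to the first lick on a spout
#'
#' @param log An assigned [session_log()].
#' @param animal_id Registered animal label.
#' @param spout `"active"` (default) or `"inactive"`.
#' @return Time of the first assigned lick in ms, or `NA_real_` if the
#'   animal never licked that spout.
#' @export
latency_to_first_lick <- function(log, animal_id, spout = "active") {
  log <- validate_session_log(log)
  spout <- match.arg(spout, .SPOUTS)
  if (!animal_id %in% log$animals$animal_id)
    stop("unknown animal: ", animal_id)
  t <- log$licks$t_ms[log$licks$spout == spout &
                        !is.na(log$licks$assigned_to) &
                        log$licks$assigned_to == animal_id]
  if (!length(t)) NA_real_ else min(t)
}

#' Per-animal per-session microstructure summary
#'
#' Computes the standard microstructure and intake measures for one animal
#' in one session: number of clusters and mean cluster size on the active
#' spout, mean within-cluster ILI, latency to the first active lick, lick
#' counts per spout (plus `log10(licks + 1)`, the scale used for group
#' statistics since inactive counts may be zero), rewards earned, and intake.
#' Intake is reported volumetrically as ml of solution per kg body weight
#' (`rewards x reward_volume_ul / body_weight_g`, since ul/g = ml/kg); when
#' `solute_mg_per_ml` is supplied the solute dose in mg/kg is added.
#'
#' @param log An assigned [session_log()] with rewards filled.
#' @param animal_id Registered animal label.
#' @param body_weight_g Body weight in grams; defaults to the registry value.
#' @param pause_ms Cluster pause threshold in ms (default 1000).
#' @param solute_mg_per_ml Optional solute concentration (mg solute per ml
#'   of solution) to convert volumetric intake to a dose.
#' @return A one-row `data.frame` (class `microstructure_summary`).
#' @export
summarize_session <- function(log, animal_id, body_weight_g = NULL,
                              pause_ms = 1000, solute_mg_per_ml = NULL) {
  log <- validate_session_log(log)
  if (!animal_id %in% log$animals$animal_id)
    stop("unknown animal: ", animal_id)
  if (is.null(body_weight_g))
    body_weight_g <-
      log$animals$body_weight_g[log$animals$animal_id == animal_id]
  if (is.na(body_weight_g) || body_weight_g <= 0)
    stop("body_weight_g must be positive")
  mine <- !is.na(log$licks$assigned_to) & log$licks$assigned_to == animal_id
  act <- sort(log$licks$t_ms[mine & log$licks$spout == "active"])
  inact <- sort(log$licks$t_ms[mine & log$licks$spout == "inactive"])
  cl <- segment_clusters(act, pause_ms)
  n_rewards <- sum(log$rewards$animal_id == animal_id)
  vol_ul <- n_rewards * log$config$reward_volume_ul
  out <- data.frame(
    animal_id = animal_id,
    session_index = metadata_or(log, "session_index", NA_integer_),
    n_clusters = nrow(cl),
    mean_cluster_size = if (nrow(cl)) length(act) / nrow(cl) else NA_real_,
    mean_ili_ms = mean_ili(cl),
    latency_ms = latency_to_first_lick(log, animal_id, "active"),
    active_licks = length(act),
    inactive_licks = length(inact),
    log10_active_licks = log10(length(act) + 1),
    log10_inactive_licks = log10(length(inact) + 1),
    rewards = n_rewards,
    intake_ul = vol_ul,
    intake_ml_per_kg = vol_ul / body_weight_g,
    stringsAsFactors = FALSE
  )
  if (!is.null(solute_mg_per_ml))
    out$intake_mg_per_kg <- out$intake_ml_per_kg * solute_mg_per_ml
  class(out) <- c("microstructure_summary", "data.frame")
  out
}

metadata_or <- function(log, field, default) {
  v <- log$metadata[[field]]
  if (is.null(v)) default else v
}

#' Microstructure summaries for every animal in a session
#'
#' @inheritParams summarize_session
#' @return A `data.frame`, one row per registered animal.
#' @export
summarize_all <- function(log, pause_ms = 1000, solute_mg_per_ml = NULL) {
  rows <- lapply(log$animals$animal_id, function(a)
    summarize_session(log, a, pause_ms = pause_ms,
                      solute_mg_per_ml = solute_mg_per_ml))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
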