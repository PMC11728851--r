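# Minimum enforced gap between consecutive bouts of one rat, ms. Strictly
# above the 1 s cluster pause plus one 16 ms quantization step on each side,
# so that generated bouts are recoverable as clusters even after lick times
# snap to the sensor grid. Gaps between bouts on one ANTENNA must instead
# exceed the lick-assignment window, or a bout whose RFID read was missed
# would inherit the previous bout's detection and be silently attributed to
# the wrong animal; see min_spout_gap() below.
.MIN_BOUT_GAP_MS <- 1048

min_spout_gap <- function(config) {
  config$assignment_window_ms + 4 * config$touch_sample_ms
}

#' Parameters of the session and trajectory simulator
#'
#' Defaults emulate a palatable-solution session as measured in adult rats:
#' bout onsets at about 1.8 per minute per rat with roughly 16 licks per
#' bout (about 100 bouts and 1,600-1,800 active licks per 1 h session), a
#' 6-7 Hz lick rhythm (gamma within-bout interlick intervals, mean 150 ms,
#' floored at the 16 ms sensor sampling interval), a 1.9% chance that a head
#' entry produces no RFID read, and a strong preference for the active
#' spout. Trajectory parameters drive a two-state (drinking vs roaming)
#' head-movement model in which the second rat joins its partner's spout
#' visits with probability `coupling`; see [simulate_trajectories()].
#'
#' @param n_rats 1 or 2 animals in the chamber.
#' @param bout_rate_per_min Mean bout onsets per minute per rat.
#' @param within_bout_ili_mean_ms,within_bout_ili_sd_ms Mean and spread of
#'   intra-bout interlick intervals (gamma), truncated at 16 ms.
#' @param licks_per_bout_mean Mean licks per bout (shifted-geometric).
#' @param rfid_miss_prob Probability a bout's head entry yields no RFID
#'   detection (its licks then become unattributable).
#' @param active_preference Probability a bout targets the active spout.
#' @param coupling Follower attraction in [0, 1] for duo trajectories: the
#'   per-frame probability that rat 2 adopts rat 1's behavioral state
#'   (drinking at the spout vs roaming) instead of its own.
#' @param spout_attraction Fraction of the remaining distance to the spout
#'   covered per frame while in the drinking state, in (0, 1].
#' @param step_sd Roaming random-walk step standard deviation, chamber
#'   units per frame.
#' @param head_dropout_prob Probability a head goes undetected in a frame.
#' @param sex Sex label(s) for the simulated animals.
#' @param seed Integer seed; every draw the simulator makes flows from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_rats = 2,
                       bout_rate_per_min = 1.8,
                       within_bout_ili_mean_ms = 150,
                       within_bout_ili_sd_ms = 50,
                       licks_per_bout_mean = 16,
                       rfid_miss_prob = 0.019,
                       active_preference = 0.9,
                       coupling = 0.5,
                       spout_attraction = 0.25,
                       step_sd = 4,
                       head_dropout_prob = 0.05,
                       sex = "male",
                       seed = 1L) {
  p <- list(n_rats = as.integer(n_rats),
            bout_rate_per_min = bout_rate_per_min,
            within_bout_ili_mean_ms = within_bout_ili_mean_ms,
            within_bout_ili_sd_ms = within_bout_ili_sd_ms,
            licks_per_bout_mean = licks_per_bout_mean,
            rfid_miss_prob = rfid_miss_prob,
            active_preference = active_preference,
            coupling = coupling,
            spout_attraction = spout_attraction,
            step_sd = step_sd,
            head_dropout_prob = head_dropout_prob,
            sex = sex,
            seed = as.integer(seed))
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  if (!p$n_rats %in% 1:2) stop("n_rats must be 1 or 2")
  probs <- c("rfid_miss_prob", "active_preference", "coupling",
             "head_dropout_prob")
  for (f in probs)
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must be in [0, 1]")
  if (p$within_bout_ili_mean_ms < 16)
    stop("within_bout_ili_mean_ms must be at least the 16 ms sensor floor")
  for (f in c("bout_rate_per_min", "within_bout_ili_sd_ms",
              "licks_per_bout_mean", "step_sd"))
    if (p[[f]] <= 0) stop(f, " must be positive")
  if (p$spout_attraction <= 0 || p$spout_attraction > 1)
    stop("spout_attraction must be in (0, 1]")
  class(p) <- "sim_params"
  p
}

default_registry <- function(params) {
  n <- params$n_rats
  tags8 <- paste0("A000", sprintf("%04X", seq_len(n) * 4369L))
  animal_registry(
    animal_id = paste0("rat", seq_len(n)),
    rfid_active = tags8,
    rfid_inactive = paste0("00", tags8),
    sex = rep_len(params$sex, n),
    group = if (n == 2) "duo" else "single",
    body_weight_g = 400 - 5 * (seq_len(n) - 1)
  )
}

#' Simulate one operant session with ground truth
#'
#' Licking is bout-structured: bout onsets follow a Poisson process per rat,
#' shifted where necessary so that consecutive bouts of one rat are
#' separated by more than the 1 s cluster pause (each generated bout is then
#' a recoverable lick cluster) and bouts on one antenna are separated by
#' more than the lick-assignment window (one head fits the spout opening at
#' a time, and a bout can then never inherit the preceding bout's RFID
#' read). Each bout targets the active
#' spout with probability `active_preference`, contains a shifted-geometric
#' number of licks with gamma interlick intervals floored at 16 ms, and its
#' lick times are quantized to the touch-sensor sampling grid. A head entry
#' emits an RFID detection just before the first lick — suppressed for the
#' whole bout with probability `rfid_miss_prob` — and, while the bout runs
#' on, repeated reads of the same tag every 2 s (the head stays in the
#' antenna loop, and same-tag repeats survive debouncing), so every lick of
#' a detected bout falls within the 3 s assignment window.
#'
#' @param params A [sim_params()].
#' @param config A [session_config()].
#' @return A list: `log`, a [session_log()] with unassigned licks and raw
#'   RFID stream, and `truth`, ground truth with per-bout (`bouts`) and
#'   per-lick (`licks`) tables.
#' @export
simulate_session <- function(params, config = session_config()) {
  params <- validate_sim_params(unclass(params))
  animals <- default_registry(params)
  with_seed(params$seed, {
    cand <- list()
    for (r in seq_len(params$n_rats)) {
      t <- 0
      rate_ms <- params$bout_rate_per_min / 60000
      repeat {
        t <- t + stats::rexp(1, rate_ms)
        if (t > config$session_length_ms) break
        n_licks <- 1L + stats::rgeom(1, 1 / params$licks_per_bout_mean)
        mu <- params$within_bout_ili_mean_ms
        sg <- params$within_bout_ili_sd_ms
        ilis <- pmax(stats::rgamma(n_licks - 1, shape = (mu / sg)^2,
                                   rate = mu / sg^2), 16)
        cand[[length(cand) + 1L]] <- list(
          rat = animals$animal_id[r],
          onset = t,
          spout = if (stats::runif(1) < params$active_preference)
            "active" else "inactive",
          ilis = ilis,
          detected = stats::runif(1) > params$rfid_miss_prob)
        t <- t + sum(ilis) + .MIN_BOUT_GAP_MS
      }
    }
    cand <- cand[order(vapply(cand, `[[`, numeric(1), "onset"))]

    last_end_spout <- c(active = -Inf, inactive = -Inf)
    last_end_rat <- stats::setNames(rep(-Inf, params$n_rats),
                                    animals$animal_id)
    grid <- config$touch_sample_ms
    bouts <- list(); licks <- list(); rfid <- list()
    for (b in cand) {
      start <- max(b$onset,
                   last_end_spout[[b$spout]] + min_spout_gap(config),
                   last_end_rat[[b$rat]] + .MIN_BOUT_GAP_MS)
      t_lick <- floor((start + c(0, cumsum(b$ilis))) / grid) * grid
      if (t_lick[length(t_lick)] > config$session_length_ms) next
      last_end_spout[[b$spout]] <- t_lick[length(t_lick)]
      last_end_rat[[b$rat]] <- t_lick[length(t_lick)]
      id <- length(bouts) + 1L
      bouts[[id]] <- data.frame(
        bout_id = id, rat = b$rat, spout = b$spout,
        start_ms = t_lick[1], end_ms = t_lick[length(t_lick)],
        n_licks = length(t_lick), detected = b$detected,
        stringsAsFactors = FALSE)
      licks[[id]] <- data.frame(
        t_ms = t_lick, spout = b$spout, true_animal = b$rat,
        bout_id = id, stringsAsFactors = FALSE)
      if (b$detected) {
        t_read <- seq(max(0, t_lick[1] - 120), t_lick[length(t_lick)],
                      by = 2000)
        tag <- if (b$spout == "active")
          animals$rfid_active[animals$animal_id == b$rat]
        else animals$rfid_inactive[animals$animal_id == b$rat]
        rfid[[id]] <- data.frame(
          t_ms = t_read, antenna = b$spout, tag_hex = tag,
          stringsAsFactors = FALSE)
      }
    }
    truth_bouts <- if (length(bouts)) do.call(rbind, bouts) else
      data.frame(bout_id = integer(0), rat = character(0),
                 spout = character(0), start_ms = numeric(0),
                 end_ms = numeric(0), n_licks = integer(0),
                 detected = logical(0))
    truth_licks <- if (length(licks)) do.call(rbind, licks) else
      data.frame(t_ms = numeric(0), spout = character(0),
                 true_animal = character(0), bout_id = integer(0))
    rfid_df <- if (length(rfid)) do.call(rbind, rfid) else
      empty_rfid_stream()
    log <- session_log(
      config, animals,
      rfid = rfid_df,
      licks = data.frame(t_ms = truth_licks$t_ms,
                         spout = truth_licks$spout,
                         assigned_to = NA_character_,
                         stringsAsFactors = FALSE),
      metadata = list(simulated = TRUE, seed = params$seed))
    truth_licks <- truth_licks[order(truth_licks$t_ms), , drop = FALSE]
    rownames(truth_licks) <- NULL
    list(log = log,
         truth = list(bouts = truth_bouts, licks = truth_licks,
                      params = params))
  })
}

# Markov rates of the latent behavioral state (per 2 s frame): probability
# of starting a spout visit while roaming, and of leaving one. Visits last
# about 8 frames (~16 s) and the stationary time share at the spout (~0.45)
# matches the strong preference for the active-spout region seen in
# palatable-solution sessions.
.P_ENTER_SPOUT <- 0.10
.P_EXIT_SPOUT <- 0.12
# Propensity of a loosely coupled pair to huddle (follow the partner's
# position) during the partner's roaming episodes; scaled by 1 - coupling.
.P_HUDDLE <- 0.7

#' Simulate coupled two-rat head trajectories as detection records
#'
#' Each rat alternates between two latent behavioral states: *drinking*
#' (the head is drawn toward the active spout, moving a fraction
#' `spout_attraction` of the remaining distance per frame with reduced
#' jitter) and *roaming* (an unbiased random walk with step scale
#' `step_sd`, kept inside the chamber by clamping). State switches follow a
#' two-state Markov chain. `coupling` sets where the pair's social
#' proximity is anchored. At each episode boundary of rat 1's chain, rat 2
#' decides how to coordinate: when rat 1 starts a spout visit, rat 2 joins
#' it with probability `coupling`; when rat 1 starts roaming, rat 2 huddles
#' with it — tracking its partner's position wherever it goes — with
#' probability `0.7 * (1 - coupling)`; otherwise rat 2 runs its own
#' independent chain. A loosely coupled pair is therefore often close
#' together *away* from the spout (small head-pair distance at large
#' spout distance), which washes out the relation between the two
#' distances, while a strongly coupled pair is co-located specifically at
#' the spout and dispersed elsewhere — so the correlation between
#' head-pair distance and mean head-to-spout distance grows with
#' `coupling`. Each frame emits both spout boxes and the surviving head
#' boxes (heads drop out with `head_dropout_prob`) in the detection-table
#' format.
#'
#' @param params A [sim_params()] (trajectory fields and `seed` are used).
#' @param n_frames Number of frames (one per 2 s of session by default).
#' @param geometry A [chamber_geometry()].
#' @param frame_period_s Seconds between frames (default 2).
#' @return A list: `detections` (a detection `data.frame`) and `truth`
#'   (true per-frame positions, latent states, and the coupling used).
#' @export
simulate_trajectories <- function(params, n_frames,
                                  geometry = chamber_geometry(100, 100),
                                  frame_period_s = 2) {
  params <- validate_sim_params(unclass(params))
  n_r <- params$n_rats
  with_seed(params$seed + 1L, {
    spout <- geometry$active_spout_pos
    pos <- matrix(rep(c(geometry$width / 2, geometry$height / 2), n_r),
                  ncol = 2, byrow = TRUE)
    pos <- pos + matrix(stats::rnorm(2 * n_r, 0, params$step_sd),
                        ncol = 2)
    a <- params$spout_attraction
    drinking <- rep(FALSE, 2)   # own-chain state per rat
    mode2 <- "own"              # rat 2 coordination: own / join / huddle
    traj <- array(NA_real_, dim = c(n_frames, n_r, 2))
    states <- matrix(FALSE, n_frames, n_r)
    rows <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      flip <- stats::runif(2)
      prev1 <- drinking[1]
      drinking <- ifelse(drinking, flip >= .P_EXIT_SPOUT,
                         flip < .P_ENTER_SPOUT)
      # coordination is re-decided at the leader's episode boundaries, so
      # it is sustained over whole spout visits or roaming excursions
      if (drinking[1] != prev1) {
        u <- stats::runif(1)
        mode2 <- if (drinking[1]) {
          if (u < params$coupling) "join" else "own"
        } else {
          if (u < .P_HUDDLE * (1 - params$coupling)) "huddle" else "own"
        }
      }
      eff <- drinking
      if (n_r == 2 && mode2 == "join") eff[2] <- drinking[1]
      for (r in seq_len(n_r)) {
        if (r == 2 && mode2 == "huddle" && !drinking[1]) {
          pos[2, ] <- pos[2, ] + a * (pos[1, ] - pos[2, ]) +
            stats::rnorm(2, 0, params$step_sd / 2)
        } else if (eff[r]) {
          pos[r, ] <- pos[r, ] + a * (spout - pos[r, ]) +
            stats::rnorm(2, 0, params$step_sd / 2)
        } else {
          pos[r, ] <- pos[r, ] + stats::rnorm(2, 0, params$step_sd)
        }
      }
      pos[, 1] <- pmin(pmax(pos[, 1], 0), geometry$width)
      pos[, 2] <- pmin(pmax(pos[, 2], 0), geometry$height)
      traj[f, , ] <- pos
      states[f, ] <- eff[seq_len(n_r)]
      seen <- stats::runif(n_r) >= params$head_dropout_prob
      k <- sum(seen)
      rows[[f]] <- data.frame(
        frame_index = f,
        obj_class = c(rep("head", k), "active_spout", "inactive_spout"),
        cx = c(pos[seen, 1], spout[1], geometry$inactive_spout_pos[1]),
        cy = c(pos[seen, 2], spout[2], geometry$inactive_spout_pos[2]),
        w = 8, h = 8,
        confidence = c(stats::runif(k, 0.6, 0.99),
                       stats::runif(2, 0.85, 0.99)),
        stringsAsFactors = FALSE)
    }
    det <- do.call(rbind, rows)
    rownames(det) <- NULL
    list(detections = validate_detections(det, frame_period_s),
         truth = list(positions = traj, states = states,
                      coupling = params$coupling, params = params))
  })
}

#' Generate a reproducible synthetic cohort on disk
#'
#' Lays out a fixture tree mirroring a multi-group design: for each housing
#' unit (a single rat or a duo cage) and each session, a simulated session
#' log is written with [write_session_log()], plus a per-unit detection
#' table for duo units, and a `manifest.json` listing every seed and the
#' per-session ground-truth bout counts. Re-running with the same arguments
#' reproduces the identical tree.
#'
#' @param design A `data.frame` with columns `group` (`"single"`/`"duo"`),
#'   `sex`, `n_units` (housing units per cell) and `n_sessions`.
#' @param out_dir Output directory; must not already contain a manifest
#'   unless `force = TRUE`.
#' @param params Baseline [sim_params()]; `n_rats`, `sex` and `seed` are
#'   overridden per unit.
#' @param config A [session_config()].
#' @param base_seed Integer seed from which per-session seeds are derived.
#' @param n_frames Frames of trajectory data per duo session (0 to skip).
#' @param force Overwrite an existing cohort.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
generate_cohort <- function(design, out_dir, params = sim_params(),
                            config = session_config(), base_seed = 1L,
                            n_frames = 0L, force = FALSE) {
  stopifnot(all(c("group", "sex", "n_units", "n_sessions") %in%
                  names(design)))
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !force)
    stop("cohort already exists at ", out_dir, "; use force = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  counter <- 0L
  for (d in seq_len(nrow(design))) {
    n_rats <- if (design$group[d] == "duo") 2L else 1L
    for (u in seq_len(design$n_units[d])) {
      for (s in seq_len(design$n_sessions[d])) {
        counter <- counter + 1L
        seed <- derive_seed(base_seed, counter)
        p <- params
        p$n_rats <- n_rats
        p$sex <- design$sex[d]
        p$seed <- seed
        p <- validate_sim_params(unclass(p))
        sim <- simulate_session(p, config)
        sim$log$metadata$session_index <- s
        sim$log$metadata$unit <- u
        sim$log$metadata$group <- design$group[d]
        rel <- file.path(paste0(design$group[d], "_", design$sex[d],
                                "_u", u), paste0("session", s))
        write_session_log(sim$log, file.path(out_dir, rel))
        if (n_frames > 0 && n_rats == 2) {
          tr <- simulate_trajectories(p, n_frames)
          write_detections(tr$detections,
                           file.path(out_dir, rel, "detections.csv"))
        }
        entries[[counter]] <- list(
          path = rel, group = design$group[d], sex = design$sex[d],
          unit = u, session = s, seed = seed,
          true_bouts = nrow(sim$truth$bouts),
          true_licks = nrow(sim$truth$licks))
      }
    }
  }
  manifest <- list(base_seed = base_seed, design = design,
                   sessions = entries)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

derive_seed <- function(base_seed, counter) {
  as.integer((as.numeric(base_seed) * 7919 + counter) %% 2147483647)
}
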