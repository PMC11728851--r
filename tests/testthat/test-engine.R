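reg <- test_registry(2)

test_that("debouncing drops a different tag inside the refractory window", {
  rfid <- data.frame(t_ms = c(0, 200), antenna = "active",
                     tag_hex = reg$rfid_active[1:2])
  out <- debounce_rfid(rfid)
  expect_equal(out$tag_hex, reg$rfid_active[1])

  rfid$t_ms <- c(0, 300)  # boundary: strictly more than 250 ms is kept
  expect_equal(nrow(debounce_rfid(rfid)), 2L)

  same <- data.frame(t_ms = c(0, 100), antenna = "active",
                     tag_hex = reg$rfid_active[1])
  expect_equal(nrow(debounce_rfid(same)), 2L)  # continuous presence

  # antennas are independent readers
  both <- data.frame(t_ms = c(0, 100),
                     antenna = c("active", "inactive"),
                     tag_hex = c(reg$rfid_active[1], reg$rfid_inactive[2]))
  expect_equal(nrow(debounce_rfid(both)), 2L)
})

test_that("the refractory applies to the previously *kept* detection", {
  # A@0 kept, B@200 dropped, C@400 is 400 ms after A (the kept one): kept
  tags <- sprintf("%08X", 1:3 * 1111L)
  r3 <- animal_registry(c("a", "b", "c"), tags,
                        sprintf("%010X", 1:3 * 1111L), body_weight_g = 400)
  rfid <- data.frame(t_ms = c(0, 200, 400), antenna = "active",
                     tag_hex = r3$rfid_active)
  expect_equal(debounce_rfid(rfid)$t_ms, c(0, 400))
})

test_that("lick assignment honors the 3 s window boundary inclusively", {
  rfid <- data.frame(t_ms = 1000, antenna = "active",
                     tag_hex = reg$rfid_active[1])
  licks <- data.frame(t_ms = c(3999, 4001), spout = "active")
  log <- assign_licks(session_log(short_config(), reg, rfid = rfid,
                                  licks = licks))
  expect_equal(log$licks$assigned_to, c("r1", RAT_UNKNOWN))
})

test_that("the latest prior detection wins", {
  rfid <- data.frame(t_ms = c(0, 500), antenna = "active",
                     tag_hex = reg$rfid_active[1:2])
  licks <- data.frame(t_ms = 600, spout = "active")
  log <- assign_licks(session_log(short_config(), reg, rfid = rfid,
                                  licks = licks))
  expect_equal(log$licks$assigned_to, "r2")
})

test_that("assignment requires force to overwrite and is idempotent", {
  log <- random_stream_log(99)
  a1 <- assign_licks(log)
  expect_error(assign_licks(a1), "force")
  a2 <- assign_licks(a1, force = TRUE)
  expect_equal(a1$licks, a2$licks)
})

test_that("assignment matches the brute-force scan on random streams", {
  for (seed in 1:60) {
    log <- random_stream_log(seed)
    got <- assign_licks(log)$licks
    expect_equal(got, oracle_assign(log), info = paste("seed", seed))
  }
})

test_that("FR5 emits a reward at every fifth assigned active lick", {
  t <- seq(0, by = 200, length.out = 23)
  licks <- data.frame(t_ms = t, spout = "active", assigned_to = "r1")
  log <- session_log(short_config(), reg, licks = licks)
  out <- run_schedule(log)
  expect_equal(nrow(out$rewards), 4L)  # floor(23 / 5)
  expect_equal(out$rewards$t_ms, t[c(5, 10, 15, 20)])
  expect_equal(out$rewards$licks_at_dispense, c(5, 10, 15, 20))
  expect_equal(out$rewards$volume_ul, rep(60, 4))
  expect_equal(out$cues$duration_ms, rep(500, 4))
})

test_that("schedule counters are independent across animals", {
  t <- seq(0, by = 100, length.out = 10)
  licks <- data.frame(t_ms = t, spout = "active",
                      assigned_to = rep(c("r1", "r2"), 5))
  log <- run_schedule(session_log(short_config(), reg, licks = licks))
  expect_equal(sort(log$rewards$animal_id), c("r1", "r2"))
  expect_equal(oracle_fr_rewards(log)$animal_id, log$rewards$animal_id)
})

test_that("inactive and unattributed licks never earn rewards", {
  licks <- data.frame(t_ms = seq(0, by = 10, length.out = 100),
                      spout = "inactive", assigned_to = "r1")
  log <- run_schedule(session_log(short_config(), reg, licks = licks))
  expect_equal(nrow(log$rewards), 0L)

  licks2 <- data.frame(t_ms = seq(0, by = 10, length.out = 50),
                       spout = "active", assigned_to = RAT_UNKNOWN)
  expect_warning(
    log2 <- run_schedule(session_log(short_config(), reg, licks = licks2)),
    "unattributed")
  expect_equal(nrow(log2$rewards), 0L)
})

test_that("reward emission matches the per-lick counter oracle", {
  for (seed in 61:100) {
    log <- suppressWarnings(
      run_schedule(assign_licks(random_stream_log(seed))))
    orc <- oracle_fr_rewards(log)
    expect_equal(log$rewards$t_ms, orc$t_ms, info = paste("seed", seed))
    expect_equal(log$rewards$animal_id, orc$animal_id,
                 info = paste("seed", seed))
    # FR conservation per animal
    for (a in log$animals$animal_id) {
      n_act <- sum(log$licks$spout == "active" &
                     log$licks$assigned_to == a)
      expect_equal(sum(log$rewards$animal_id == a),
                   n_act %/% log$config$ratio)
    }
  }
})

test_that("adding licks for one animal never affects the other", {
  base <- data.frame(t_ms = seq(1000, by = 100, length.out = 12),
                     spout = "active", assigned_to = "r2")
  log0 <- run_schedule(session_log(short_config(), reg, licks = base))
  extra <- rbind(base, data.frame(t_ms = seq(100, by = 50, length.out = 7),
                                  spout = "active", assigned_to = "r1"))
  log1 <- run_schedule(session_log(short_config(), reg, licks = extra))
  r2_rewards <- function(l) {
    out <- l$rewards[l$rewards$animal_id == "r2",
                     c("t_ms", "licks_at_dispense")]
    rownames(out) <- NULL
    out
  }
  expect_equal(r2_rewards(log1), r2_rewards(log0))
  expect_gte(sum(log1$rewards$animal_id == "r1"), 0)
})

test_that("deleting unattributed licks leaves the reward stream unchanged", {
  for (seed in 101:115) {
    log <- assign_licks(random_stream_log(seed))
    full <- suppressWarnings(run_schedule(log))
    pruned <- log
    pruned$licks <- log$licks[log$licks$assigned_to != RAT_UNKNOWN, ,
                              drop = FALSE]
    rownames(pruned$licks) <- NULL
    out <- suppressWarnings(run_schedule(pruned))
    expect_equal(out$rewards, full$rewards, info = paste("seed", seed))
  }
})

test_that("VR schedules are reproducible and draw from the stated support", {
  cfg <- short_config(schedule_kind = "VR", ratio = 5, vr_spread = 2,
                      rng_seed = 11)
  licks <- data.frame(t_ms = seq(0, by = 50, length.out = 200),
                      spout = "active", assigned_to = "r1")
  l1 <- run_schedule(session_log(cfg, reg, licks = licks))
  l2 <- run_schedule(session_log(cfg, reg, licks = licks))
  expect_equal(l1$rewards, l2$rewards)
  reqs <- diff(c(0, l1$rewards$licks_at_dispense))
  expect_true(all(reqs >= 3 & reqs <= 7))
  expect_gt(length(unique(reqs)), 1)
})

test_that("house light follows the reversed light cycle, half-open", {
  expect_equal(house_light_state(c("22:00", "12:00", "09:00", "21:00",
                                   "08:59", "20:59")),
               c("on", "off", "off", "on", "on", "off"))
  expect_error(house_light_state("25:00"), "invalid")
})

test_that("pump calibration reproduces the commanded-volume arithmetic", {
  cal <- calibrate_pump(c(300, 300, 300))
  expect_equal(cal$commanded_total_ul, 900)
  expect_equal(cal$correction_factor, 1)
  expect_equal(calibrate_pump(c(270, 270, 270))$correction_factor,
               900 / 810)
  expect_error(calibrate_pump(c(0, 300, 300)), "positive")
})

test_that("a miscalibrated pump is corrected to within 0.1%", {
  # pump truly delivers 8% short of what its steps_per_ul claims
  claimed <- 12
  true_ul_per_step <- 0.92 / claimed
  dispense <- function(spu) {
    steps <- steps_for_volume(60, motor_model(1.8, spu))
    steps * true_ul_per_step * 5  # one iteration = five rewards
  }
  measured <- rep(dispense(claimed), 3)
  cal <- calibrate_pump(measured, motor = motor_model(1.8, claimed))
  re_measured <- dispense(cal$motor$steps_per_ul) * 3
  expect_lt(abs(re_measured - 900) / 900, 0.001)
})

test_that("motor step arithmetic follows the step angle", {
  expect_equal(steps_per_revolution(motor_model(1.8)), 200)
  expect_equal(steps_per_revolution(motor_model(0.9)), 400)
  expect_equal(steps_for_volume(60, motor_model(1.8, 10)), 600)
  expect_error(steps_for_volume(60, motor_model(1.8)), "uncalibrated")
})

test_that("run_session equals the hand-composed pipeline", {
  expect_equal(nrow(run_session(short_config(), reg)$licks), 0L)

  for (seed in 116:125) {
    raw <- random_stream_log(seed)
    got <- suppressWarnings(
      run_session(raw$config, raw$animals, rfid = raw$rfid,
                  licks = raw$licks[c("t_ms", "spout")]))
    manual <- raw
    manual$rfid <- debounce_rfid(manual$rfid,
                                 raw$config$rfid_refractory_ms)
    manual <- suppressWarnings(run_schedule(assign_licks(manual)))
    expect_equal(got$licks, manual$licks, info = paste("seed", seed))
    expect_equal(got$rewards, manual$rewards, info = paste("seed", seed))
  }
})

test_that("a fully RFID-covered FR5 session rewards every fifth lick", {
  t_det <- seq(0, by = 2000, length.out = 13)
  rfid <- data.frame(t_ms = t_det, antenna = "active",
                     tag_hex = reg$rfid_active[1])
  t_lick <- seq(100, by = 1000, length.out = 25)
  licks <- data.frame(t_ms = t_lick, spout = "active")
  out <- run_session(short_config(), reg, rfid = rfid, licks = licks)
  expect_equal(nrow(out$rewards), 5L)
  expect_equal(unique(out$rewards$animal_id), "r1")
})
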