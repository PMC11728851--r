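geom <- chamber_geometry(100, 100)

test_that("frame building applies the confidence floor and max rules", {
  det <- rbind(
    det_row(0, "head", 10, 10, conf = 0.9),
    det_row(0, "head", 40, 40, conf = 0.4),      # below the 50% floor
    det_row(0, "active_spout", 5, 5, conf = 0.9),
    det_row(0, "active_spout", 6, 6, conf = 0.6),
    det_row(0, "inactive_spout", 95, 95, conf = 0.8))
  fr <- frames_from_detections(det)
  expect_equal(sum(fr$obj_class == "head"), 1L)
  sp <- fr[fr$obj_class == "active_spout", ]
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$cx, 5)
  det3 <- rbind(det_row(1, "head", 1, 1, conf = 0.9),
                det_row(1, "head", 2, 2, conf = 0.8),
                det_row(1, "head", 3, 3, conf = 0.7))
  expect_warning(fr3 <- frames_from_detections(det3), ">2 head")
  expect_equal(fr3$cy, c(1, 2))
})

test_that("normalization pins the spout and preserves geometry", {
  det <- rbind(
    det_row(0, "active_spout", 8, 10), det_row(0, "head", 20, 30),
    det_row(0, "head", 40, 50),
    det_row(1, "active_spout", 12, 10), det_row(1, "head", 25, 35))
  fr <- frames_from_detections(det)
  nf <- normalize_frames(fr)
  expect_equal(attr(nf, "mean_spout"), c(10, 10))
  expect_equal(unique(nf$shift_x), c(2, -2))
  sp <- nf[nf$obj_class == "active_spout", ]
  expect_equal(stats::var(sp$cx), 0)
  expect_equal(stats::var(sp$cy), 0)
  # translation invariance of within-frame distances
  d0 <- function(df, f) {
    h <- df[df$obj_class == "head" & df$frame_index == f, ]
    sqrt(diff(h$cx)^2 + diff(h$cy)^2)
  }
  expect_equal(d0(nf, 0), d0(fr, 0))
  # identical spout position in all frames is a no-op
  same <- rbind(det_row(0, "active_spout", 10, 10),
                det_row(1, "active_spout", 10, 10),
                det_row(1, "head", 3, 4))
  nsame <- normalize_frames(frames_from_detections(same))
  expect_equal(unique(nsame$shift_x), 0)
  expect_error(normalize_frames(frames_from_detections(
    det_row(0, "head", 1, 1))), "active spout")
})

test_that("frames lacking the spout inherit the session mean translation", {
  det <- rbind(
    det_row(0, "active_spout", 8, 10),
    det_row(1, "active_spout", 12, 10),
    det_row(2, "head", 50, 50))   # no spout detected in frame 2
  nf <- normalize_frames(frames_from_detections(det))
  expect_equal(nf$shift_x[nf$frame_index == 2], 0)  # mean of +2 and -2
})

test_that("quadrants follow the active-spout convention with low ties", {
  expect_equal(quadrant_of(5, 5, geom), 1L)        # active-spout corner
  expect_equal(quadrant_of(95, 5, geom), 2L)
  expect_equal(quadrant_of(95, 95, geom), 3L)      # inactive-spout corner
  expect_equal(quadrant_of(5, 95, geom), 4L)
  expect_equal(quadrant_of(50, 50, geom), 1L)      # midpoint tie -> Q1
  expect_warning(q <- quadrant_of(150, 5, geom), "clamped")
  expect_equal(q, 2L)
  expect_error(chamber_geometry(0, 100), "degenerate")
})

test_that("head-pair distance normalizes and skips incomplete frames", {
  g10 <- chamber_geometry(10, 10, norm_constant = 10)
  det <- rbind(det_row(0, "head", 0, 0), det_row(0, "head", 3, 4),
               det_row(1, "head", 5, 5),
               det_row(2, "head", 2, 2), det_row(2, "head", 2, 2))
  pd <- head_pair_distance(frames_from_detections(det), g10)
  expect_equal(pd$pair_distance[pd$frame_index == 0], 0.5)  # 5 / 10
  expect_true(is.na(pd$pair_distance[pd$frame_index == 1]))
  expect_equal(pd$pair_distance[pd$frame_index == 2], 0)
  expect_equal(pd$mid_x[pd$frame_index == 0], 1.5)
})

test_that("mean head-to-spout distance averages the visible heads", {
  g10 <- chamber_geometry(10, 10, norm_constant = 10)
  det <- rbind(
    det_row(0, "active_spout", 0, 0),
    det_row(0, "head", 5, 0), det_row(0, "head", 0, 15),
    det_row(1, "active_spout", 0, 0), det_row(1, "head", 3, 4),
    det_row(2, "active_spout", 0, 0), det_row(2, "head", 0, 0))
  ms <- mean_head_to_spout(frames_from_detections(det, 0.4), g10)
  expect_equal(ms$mean_spout_distance[ms$frame_index == 0], 1.0)
  expect_equal(ms$mean_spout_distance[ms$frame_index == 1], 0.5)
  expect_equal(ms$mean_spout_distance[ms$frame_index == 2], 0)
})

test_that("pearson_r matches the closed form and stats::cor", {
  x <- c(1, 2, 4, 7, 11)
  expect_equal(pearson_r(x, 1.5 * x), 1)
  expect_equal(pearson_r(x, -x), -1)
  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(20)
    b <- rnorm(20)
    expect_equal(pearson_r(a, b), stats::cor(a, b))
    # invariance under positive affine maps; sign flip under negation
    expect_equal(pearson_r(3 * a + 2, b), pearson_r(a, b))
    expect_equal(pearson_r(-a, b), -pearson_r(a, b))
  }
  expect_warning(r0 <- pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(r0))
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("quadrant summary aggregates by midpoint quadrant", {
  det <- rbind(det_row(0, "head", 4, 4), det_row(0, "head", 8, 8),
               det_row(1, "head", 90, 90), det_row(1, "head", 96, 96),
               det_row(2, "head", 10, 10), det_row(2, "head", 12, 12))
  qs <- quadrant_distance_summary(frames_from_detections(det), geom)
  expect_equal(qs$n_frames[qs$quadrant == 1], 2L)
  expect_equal(qs$n_frames[qs$quadrant == 3], 1L)
  expect_false(any(qs$quadrant %in% c(2L, 4L)))  # empty cells absent
  expect_equal(nrow(quadrant_distance_summary(
    frames_from_detections(det_row(0, "head", 1, 1)), geom)), 0L)
})

test_that("uniform scatter spreads frames roughly evenly over quadrants", {
  set.seed(4)
  n <- 400
  det <- do.call(rbind, lapply(seq_len(n), function(f) {
    c1 <- runif(2, 0, 100)
    rbind(det_row(f, "head", c1[1], c1[2]),
          det_row(f, "head", c1[1] + runif(1, -3, 3),
                  c1[2] + runif(1, -3, 3)))
  }))
  det$cx <- pmin(pmax(det$cx, 0), 100)
  det$cy <- pmin(pmax(det$cy, 0), 100)
  qs <- suppressWarnings(
    quadrant_distance_summary(frames_from_detections(det), geom))
  expect_equal(sum(qs$n_frames), n)
  expect_true(all(qs$n_frames > n / 4 - 4 * sqrt(n * 0.25 * 0.75)))
})

test_that("density maps conserve counts", {
  det <- do.call(rbind, lapply(1:7, function(f)
    det_row(f, "head", 10.5, 10.5)))
  m <- density_map(frames_from_detections(det), geom)
  expect_equal(sum(m), 7L)
  expect_equal(m[6, 6], 7L)  # all mass in one cell
  set.seed(5)
  det2 <- do.call(rbind, lapply(1:500, function(f)
    det_row(f, "head", runif(1, 0, 100), runif(1, 0, 100))))
  m2 <- density_map(frames_from_detections(det2), geom, bins = c(5, 5))
  expect_equal(sum(m2), 500L)
  expect_true(max(m2) / max(min(m2), 1) < 6)  # uniform input, loose bound
})
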