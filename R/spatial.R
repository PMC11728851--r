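#' Chamber geometry for quadrant and distance analysis
#'
#' Coordinates follow the image convention: origin at the top-left corner,
#' x increasing rightward, y increasing downward. The chamber is divided
#' into four quadrants at `quadrant_origin` (default the chamber midpoint):
#' Quadrant 1 is the low-x/low-y corner holding the active spout, Quadrant 2
#' is adjacent along x, Quadrant 3 is diagonal (holding the inactive spout)
#' and Quadrant 4 is the remaining corner. Distances are divided by
#' `norm_constant`, by default the chamber diagonal so that any within-
#' chamber distance lies in [0, 1].
#'
#' @param width,height Chamber extents in image units (positive).
#' @param quadrant_origin Numeric `c(x, y)` splitting point (default
#'   midpoint).
#' @param norm_constant Length used to normalize distances (default
#'   diagonal).
#' @param active_spout_pos,inactive_spout_pos Nominal spout positions, used
#'   by the trajectory simulator (defaults: near the Quadrant-1 and
#'   Quadrant-3 corners).
#' @return A list of class `chamber_geometry`.
#' @export
chamber_geometry <- function(width, height,
                             quadrant_origin = c(width / 2, height / 2),
                             norm_constant = sqrt(width^2 + height^2),
                             active_spout_pos = c(0.06 * width,
                                                  0.06 * height),
                             inactive_spout_pos = c(0.94 * width,
                                                    0.94 * height)) {
  if (width <= 0 || height <= 0)
    stop("degenerate geometry: width and height must be positive")
  if (norm_constant <= 0) stop("norm_constant must be positive")
  structure(list(width = width, height = height,
                 quadrant_origin = quadrant_origin,
                 norm_constant = norm_constant,
                 active_spout_pos = active_spout_pos,
                 inactive_spout_pos = inactive_spout_pos,
                 quadrant_of_active_spout = 1L),
            class = "chamber_geometry")
}

#' Group detection records into usable frame observations
#'
#' Applies the detector's correctness floor (detections below
#' `min_confidence` are discarded; 0.5 mirrors the 50% criterion used when
#' validating the detector), then resolves duplicates: for each spout class
#' at most one box per frame is kept (highest confidence), and frames
#' reporting more than two heads keep the two most confident with a warning.
#'
#' @param records Detection records (see [read_detections()]).
#' @param min_confidence Confidence floor in [0, 1] (default 0.5).
#' @return The retained records, class `frame_observations`; an optional
#'   `session` column is carried through.
#' @export
frames_from_detections <- function(records, min_confidence = 0.5) {
  records <- validate_detections(records,
                                 frame_period_s = infer_period(records))
  df <- records[records$confidence >= min_confidence, , drop = FALSE]
  if (!"session" %in% names(df)) df$session <- 1L
  keep <- rep(TRUE, nrow(df))
  key <- interaction(df$session, df$frame_index, drop = TRUE)
  for (cls in c("active_spout", "inactive_spout")) {
    i <- which(df$obj_class == cls)
    if (!length(i)) next
    drop <- unlist(lapply(split(i, droplevels(key[i])), function(j)
      j[-which.max(df$confidence[j])]))
    keep[drop] <- FALSE
  }
  hi <- which(df$obj_class == "head")
  if (length(hi)) {
    over <- FALSE
    for (j in split(hi, droplevels(key[hi]))) {
      if (length(j) > 2) {
        over <- TRUE
        keep[j[-order(df$confidence[j], decreasing = TRUE)[1:2]]] <- FALSE
      }
    }
    if (over)
      warning("frames with >2 head detections: kept the 2 most confident")
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("frame_observations", "data.frame")
  out
}

infer_period <- function(records) {
  if ("t_s" %in% names(records) && nrow(records) &&
      any(records$frame_index > 0)) {
    i <- which(records$frame_index > 0)[1]
    records$t_s[i] / records$frame_index[i]
  } else 2
}

#' Normalize frames to a common active-spout position
#'
#' Camera placement differs across chambers and sessions, so raw
#' coordinates are not comparable. Every frame is translated so its active
#' spout lands on the mean active-spout position over all frames; the
#' translation moves every object in the frame, so within-frame distances
#' are untouched. Frames in which the spout was not detected are shifted by
#' their session's mean translation.
#'
#' @param frames A `frame_observations` table (see
#'   [frames_from_detections()]).
#' @return The translated table, class `normalized_frames`, with columns
#'   `shift_x`, `shift_y` recording the applied translation and an attribute
#'   `mean_spout` giving the common spout position.
#' @export
normalize_frames <- function(frames) {
  sp <- frames[frames$obj_class == "active_spout", , drop = FALSE]
  if (!nrow(sp))
    stop("no frame contains the active spout: cannot normalize")
  mean_spout <- c(mean(sp$cx), mean(sp$cy))
  key <- paste(frames$session, frames$frame_index)
  sp_key <- paste(sp$session, sp$frame_index)
  idx <- match(key, sp_key)
  shift_x <- mean_spout[1] - sp$cx[idx]
  shift_y <- mean_spout[2] - sp$cy[idx]
  for (s in unique(frames$session)) {
    in_s <- frames$session == s
    miss <- in_s & is.na(shift_x)
    if (any(miss)) {
      have <- in_s & !is.na(shift_x)
      if (any(have)) {
        shift_x[miss] <- mean(shift_x[have])
        shift_y[miss] <- mean(shift_y[have])
      } else {
        shift_x[miss] <- 0
        shift_y[miss] <- 0
      }
    }
  }
  out <- frames
  out$cx <- out$cx + shift_x
  out$cy <- out$cy + shift_y
  # pin translated spouts to the mean exactly (a + (m - a) can be one ulp
  # off in floating point; the post-condition is exact equality)
  is_sp <- out$obj_class == "active_spout"
  out$cx[is_sp] <- mean_spout[1]
  out$cy[is_sp] <- mean_spout[2]
  out$shift_x <- shift_x
  out$shift_y <- shift_y
  attr(out, "mean_spout") <- mean_spout
  class(out) <- c("normalized_frames", class(frames))
  out
}

#' Quadrant of a point
#'
#' Quadrants are defined by the chamber's quadrant origin: Q1 low-x/low-y
#' (active-spout corner), Q2 high-x/low-y, Q3 high-x/high-y (inactive
#' spout), Q4 low-x/high-y. Points exactly on a boundary are assigned to the
#' lower quadrant index; points outside the chamber are clamped to its
#' bounds with a warning.
#'
#' @param x,y Point coordinates (vectors).
#' @param geometry A [chamber_geometry()].
#' @return Integer vector of quadrant indices in 1..4.
#' @export
quadrant_of <- function(x, y, geometry) {
  if (any(x < 0 | x > geometry$width | y < 0 | y > geometry$height)) {
    warning("points outside chamber bounds were clamped")
    x <- pmin(pmax(x, 0), geometry$width)
    y <- pmin(pmax(y, 0), geometry$height)
  }
  ox <- geometry$quadrant_origin[1]
  oy <- geometry$quadrant_origin[2]
  low_x <- x <= ox
  low_y <- y <= oy
  out <- integer(length(x))
  out[low_x & low_y] <- 1L
  out[!low_x & low_y] <- 2L
  out[!low_x & !low_y] <- 3L
  out[low_x & !low_y] <- 4L
  out
}

#' Per-frame head-pair distance
#'
#' Euclidean distance between the two detected head centers, divided by the
#' geometry's normalization constant. Frames without exactly two heads give
#' `NA` and are excluded from aggregates — detector dropouts are not
#' imputed. Head identity is not tracked, so the measure is symmetric.
#'
#' @param frames A (normalized) frame table.
#' @param geometry A [chamber_geometry()].
#' @return A `data.frame` with `session`, `frame_index`, `n_heads`,
#'   `pair_distance`, `mid_x`, `mid_y` (head-pair midpoint).
#' @export
head_pair_distance <- function(frames, geometry) {
  heads <- frames[frames$obj_class == "head", , drop = FALSE]
  key <- paste(heads$session, heads$frame_index, sep = "\r")
  grp <- split(seq_len(nrow(heads)), key)
  res <- lapply(grp, function(i) {
    n <- length(i)
    if (n == 2) {
      d <- sqrt(diff(heads$cx[i])^2 + diff(heads$cy[i])^2) /
        geometry$norm_constant
      c(n, d, mean(heads$cx[i]), mean(heads$cy[i]))
    } else c(n, NA_real_, NA_real_, NA_real_)
  })
  m <- do.call(rbind, res)
  first <- vapply(grp, `[`, numeric(1), 1)
  out <- data.frame(session = heads$session[first],
                    frame_index = heads$frame_index[first],
                    n_heads = as.integer(m[, 1]),
                    pair_distance = m[, 2],
                    mid_x = m[, 3], mid_y = m[, 4])
  out <- out[order(out$session, out$frame_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-frame mean head-to-spout distance
#'
#' Mean, over the heads visible in the frame, of the Euclidean distance from
#' head center to the given spout, divided by the normalization constant.
#' `NA` when the frame has no head or the spout was not detected.
#'
#' @param frames A (normalized) frame table.
#' @param geometry A [chamber_geometry()].
#' @param spout `"active"` (default) or `"inactive"`.
#' @return A `data.frame` with `session`, `frame_index`, `mean_spout_distance`.
#' @export
mean_head_to_spout <- function(frames, geometry, spout = "active") {
  spout <- match.arg(spout, .SPOUTS)
  cls <- paste0(spout, "_spout")
  sp <- frames[frames$obj_class == cls, , drop = FALSE]
  heads <- frames[frames$obj_class == "head", , drop = FALSE]
  key_h <- paste(heads$session, heads$frame_index, sep = "\r")
  key_s <- paste(sp$session, sp$frame_index, sep = "\r")
  grp <- split(seq_len(nrow(heads)), key_h)
  vals <- vapply(names(grp), function(k) {
    j <- match(k, key_s)
    if (is.na(j)) return(NA_real_)
    i <- grp[[k]]
    mean(sqrt((heads$cx[i] - sp$cx[j])^2 + (heads$cy[i] - sp$cy[j])^2)) /
      geometry$norm_constant
  }, numeric(1))
  first <- vapply(grp, `[`, numeric(1), 1)
  out <- data.frame(session = heads$session[first],
                    frame_index = heads$frame_index[first],
                    mean_spout_distance = unname(vals))
  out <- out[order(out$session, out$frame_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson product-moment correlation
#'
#' Direct implementation of the product-moment coefficient; pairs with a
#' missing value in either series are dropped first.
#'
#' @param x,y Paired numeric series (at least 3 complete pairs).
#' @return The coefficient in [-1, 1]; `NA_real_` with a warning when
#'   either series has zero variance.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  dx <- x - mean(x)
  dy <- y - mean(y)
  denom <- sqrt(sum(dx^2) * sum(dy^2))
  if (denom == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  sum(dx * dy) / denom
}

#' Head-pair distance by quadrant
#'
#' Aggregates the per-frame head-pair distance by session and quadrant; a
#' frame's quadrant is the quadrant of its head-pair midpoint. Frames
#' without exactly two heads are excluded. Session-by-quadrant cells with no
#' frames are absent from the table, not zero.
#'
#' @param frames A normalized frame table.
#' @param geometry A [chamber_geometry()].
#' @return A `data.frame`: `session`, `quadrant`, `n_frames`,
#'   `mean_distance`, `se_distance`.
#' @export
quadrant_distance_summary <- function(frames, geometry) {
  pd <- head_pair_distance(frames, geometry)
  pd <- pd[!is.na(pd$pair_distance), , drop = FALSE]
  if (!nrow(pd)) {
    return(data.frame(session = integer(0), quadrant = integer(0),
                      n_frames = integer(0), mean_distance = numeric(0),
                      se_distance = numeric(0)))
  }
  suppressWarnings(
    pd$quadrant <- quadrant_of(pd$mid_x, pd$mid_y, geometry))
  key <- paste(pd$session, pd$quadrant, sep = "\r")
  agg <- split(pd$pair_distance, key)
  first <- match(names(agg), key)
  out <- data.frame(
    session = pd$session[first],
    quadrant = pd$quadrant[first],
    n_frames = lengths(agg),
    mean_distance = vapply(agg, mean, numeric(1)),
    se_distance = vapply(agg, function(v)
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
      numeric(1))
  )
  out <- out[order(out$session, out$quadrant), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binned density map of head positions
#'
#' Counts head detections in a regular grid over the chamber. The grid is
#' exact (no smoothing): cell counts always sum to the number of head
#' points.
#'
#' @param frames A (normalized) frame table.
#' @param geometry A [chamber_geometry()].
#' @param bins Grid size `c(nx, ny)` (default 50 x 50).
#' @return An `nx` by `ny` integer matrix of counts; rows index x-bins.
#' @export
density_map <- function(frames, geometry, bins = c(50, 50)) {
  heads <- frames[frames$obj_class == "head", , drop = FALSE]
  nx <- bins[1]; ny <- bins[if (length(bins) > 1) 2 else 1]
  bx <- pmin(pmax(ceiling(heads$cx / geometry$width * nx), 1L), nx)
  by <- pmin(pmax(ceiling(heads$cy / geometry$height * ny), 1L), ny)
  m <- matrix(0L, nrow = nx, ncol = ny)
  if (nrow(heads)) {
    tab <- table(factor(bx, levels = seq_len(nx)),
                 factor(by, levels = seq_len(ny)))
    m <- matrix(as.integer(tab), nrow = nx, ncol = ny)
  }
  m
}
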