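#' Arena and zone configuration
#'
#' Rectangular open-field arena (default 50 x 50 cm) with named zones:
#' discs (`list(type = "disc", center = c(x, y), radius = r)`),
#' rectangles (`list(type = "rect", xmin, xmax, ymin, ymax)`), or
#' polygons (`list(type = "polygon", x = ..., y = ...)`). Zone
#' boundaries count as inside. All zones must lie within the arena.
#'
#' @param width_cm,height_cm arena extent.
#' @param zones named list of zone definitions.
#' @param fps video frame rate, > 0.
#' @return an `ArenaConfig` object.
#' @export
arena_config <- function(width_cm = 50, height_cm = 50, zones = list(),
                         fps = 30) {
  if (fps <= 0) stop("`fps` must be > 0")
  if (length(zones) && is.null(names(zones))) stop("zones must be named")
  cfg <- structure(list(width_cm = width_cm, height_cm = height_cm,
                        zones = zones, fps = fps),
                   class = "ArenaConfig")
  for (nm in names(zones)) {
    z <- zones[[nm]]
    pts <- switch(z$type,
      disc = cbind(z$center[1L] + c(-1, 1, 0, 0) * z$radius,
                   z$center[2L] + c(0, 0, -1, 1) * z$radius),
      rect = cbind(c(z$xmin, z$xmax), c(z$ymin, z$ymax)),
      polygon = cbind(z$x, z$y),
      stop("unknown zone type: ", z$type))
    if (any(pts[, 1L] < 0 | pts[, 1L] > width_cm |
            pts[, 2L] < 0 | pts[, 2L] > height_cm)) {
      stop("zone '", nm, "' extends outside the arena")
    }
  }
  cfg
}

#' Read an arena configuration from YAML
#'
#' @param path YAML file with `width_cm`, `height_cm`, `fps` and a
#'   `zones` mapping.
#' @return an `ArenaConfig`.
#' @export
read_arena_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  zones <- lapply(y$zones, function(z) {
    if (!is.null(z$center)) z$center <- as.numeric(unlist(z$center))
    z
  })
  arena_config(width_cm = y$width_cm, height_cm = y$height_cm,
               zones = zones, fps = y$fps)
}

# Point-in-zone with closed (boundary-inside) semantics.
.in_zone <- function(x, y, zone) {
  switch(zone$type,
    disc = (x - zone$center[1L])^2 + (y - zone$center[2L])^2 <=
      zone$radius^2,
    rect = x >= zone$xmin & x <= zone$xmax & y >= zone$ymin & y <= zone$ymax,
    polygon = .in_polygon(x, y, zone$x, zone$y),
    stop("unknown zone type"))
}

# Ray-casting point-in-polygon; points on an edge count as inside.
.in_polygon <- function(x, y, px, py) {
  n <- length(px)
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    # edge membership (within numerical tolerance)
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    within <- x >= pmin(xi, xj) - 1e-9 & x <= pmax(xi, xj) + 1e-9 &
      y >= pmin(yi, yj) - 1e-9 & y <= pmax(yi, yj) + 1e-9
    on_edge <- on_edge | (abs(cross) < 1e-9 & within)
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Which zone contains each trajectory point
#'
#' @param traj a `Trajectory` or data.frame with `x`, `y`.
#' @param arena an `ArenaConfig`.
#' @return character vector of zone names (`NA` outside every zone).
#' @export
zone_of <- function(traj, arena) {
  out <- rep(NA_character_, nrow(traj))
  for (nm in names(arena$zones)) {
    hit <- .in_zone(traj$x, traj$y, arena$zones[[nm]])
    out[hit & is.na(out)] <- nm
  }
  out
}

#' Trajectory container
#'
#' Time-stamped centroid path. Time must be strictly increasing;
#' positions outside the arena are reported (not dropped).
#'
#' @param t_s,x_cm,y_cm numeric vectors of equal length.
#' @param arena optional `ArenaConfig` for the bounds check.
#' @return a `Trajectory` data.frame with columns `frame`, `t`, `x`, `y`.
#' @export
trajectory <- function(t_s, x_cm, y_cm, arena = NULL) {
  if (any(diff(t_s) <= 0)) stop("time must be strictly increasing")
  df <- data.frame(frame = seq_along(t_s) - 1L, t = t_s, x = x_cm, y = y_cm)
  if (!is.null(arena)) {
    out <- sum(x_cm < 0 | x_cm > arena$width_cm |
                 y_cm < 0 | y_cm > arena$height_cm)
    if (out > 0) message(out, " position(s) outside the arena")
  }
  class(df) <- c("Trajectory", class(df))
  df
}

#' Read / write trajectory CSV (frame, t, x, y)
#' @param path CSV path.
#' @param traj a `Trajectory`.
#' @return `read_trajectory_csv`: a `Trajectory`; `write_trajectory_csv`:
#'   the path, invisibly.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  trajectory(df$t, df$x, df$y)
}

#' @rdname read_trajectory_csv
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("frame", "t", "x", "y")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Per-zone occupancy time and proportion
#'
#' Each frame contributes one frame-interval of dwell time to the zone
#' containing the centroid (boundary inside; overlapping zones are a
#' configuration error).
#'
#' @param traj a `Trajectory`.
#' @param arena an `ArenaConfig` with at least one zone.
#' @return data.frame: `zone`, `time_s`, `proportion` (of session
#'   duration; the out-of-zone remainder is reported as zone `"none"`).
#' @export
zone_occupancy <- function(traj, arena) {
  if (!length(arena$zones)) stop("no zones defined")
  hits <- sapply(names(arena$zones), function(nm)
    .in_zone(traj$x, traj$y, arena$zones[[nm]]))
  if (is.null(dim(hits))) hits <- matrix(hits, nrow = 1L)
  if (any(rowSums(hits) > 1L)) stop("zones overlap")
  dt <- 1 / arena$fps
  dur <- nrow(traj) * dt
  time_s <- colSums(hits) * dt
  data.frame(zone = c(colnames(hits), "none"),
             time_s = c(time_s, dur - sum(time_s)),
             proportion = c(time_s, dur - sum(time_s)) / dur)
}

#' Discrimination index
#'
#' `DI = (t_target - t_other) / (t_target + t_other)`, bounded in
#' \[-1, 1\]: the novel-object and sociability preference metric.
#' Undefined (NA, with a warning) when both times are zero; invariant to
#' rescaling both times; antisymmetric under argument swap.
#'
#' @param t_target_s,t_other_s dwell times (s).
#' @return the DI.
#' @export
discrimination_index <- function(t_target_s, t_other_s) {
  tot <- t_target_s + t_other_s
  if (tot <= 0) {
    warning("both dwell times are zero: DI undefined")
    return(NA_real_)
  }
  (t_target_s - t_other_s) / tot
}

#' Zone approach latency and first choice
#'
#' Latency is the time of the first frame inside each zone of interest;
#' the first choice is the zone reached earliest. The animal must start
#' outside all zones of interest.
#'
#' @param traj a `Trajectory`.
#' @param arena an `ArenaConfig`.
#' @param zones_of_interest zone names (default: all).
#' @return list with `latency_s` (named, NA when never entered) and
#'   `first_choice` (NA when no zone entered).
#' @export
approach_metrics <- function(traj, arena,
                             zones_of_interest = names(arena$zones)) {
  start_in <- vapply(zones_of_interest, function(nm)
    .in_zone(traj$x[1L], traj$y[1L], arena$zones[[nm]]), logical(1))
  if (any(start_in)) stop("animal starts inside a zone of interest")
  lat <- vapply(zones_of_interest, function(nm) {
    hit <- which(.in_zone(traj$x, traj$y, arena$zones[[nm]]))
    if (!length(hit)) NA_real_ else traj$t[hit[1L]]
  }, numeric(1))
  fc <- if (all(is.na(lat))) NA_character_
        else zones_of_interest[which.min(lat)]
  list(latency_s = lat, first_choice = fc)
}

#' Path kinematics
#'
#' Velocities from centered finite differences on the boxcar-smoothed
#' path (smoothing suppresses tracking jitter that would otherwise
#' inflate the maximum); total distance is the summed segment length of
#' the smoothed path.
#'
#' @param traj a `Trajectory` (>= 2 frames).
#' @param smooth_window_frames boxcar length (default 5; 1 disables).
#' @return list with `max_velocity`, `mean_velocity` (units/s) and
#'   `total_distance` (trajectory units).
#' @export
kinematics <- function(traj, smooth_window_frames = 5L) {
  n <- nrow(traj)
  if (n < 2L) stop("need at least 2 frames")
  w <- max(1L, as.integer(smooth_window_frames))
  sm <- function(v) {
    if (w == 1L || n <= w) return(v)
    f <- as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
    f[is.na(f)] <- v[is.na(f)]
    f
  }
  x <- sm(traj$x); y <- sm(traj$y)
  # centered differences in the interior, one-sided at the ends
  ix <- 2:(n - 1L)
  vx <- (x[ix + 1L] - x[ix - 1L]) / (traj$t[ix + 1L] - traj$t[ix - 1L])
  vy <- (y[ix + 1L] - y[ix - 1L]) / (traj$t[ix + 1L] - traj$t[ix - 1L])
  speed <- sqrt(vx^2 + vy^2)
  list(max_velocity = max(speed), mean_velocity = mean(speed),
       total_distance = sum(sqrt(diff(x)^2 + diff(y)^2)))
}

#' Grooming bout summary
#'
#' @param intervals data.frame or matrix with columns `start_s`, `end_s`;
#'   bouts must be sorted and non-overlapping.
#' @return list with `occurrences`, `mean_duration_s` (NA when empty),
#'   `total_time_s`.
#' @export
grooming_summary <- function(intervals) {
  if (is.null(dim(intervals)) || nrow(intervals) == 0L) {
    return(list(occurrences = 0L, mean_duration_s = NA_real_,
                total_time_s = 0))
  }
  s <- intervals[, 1L]; e <- intervals[, 2L]
  if (any(e < s)) stop("interval ends before it starts")
  if (nrow(intervals) > 1L && any(s[-1L] < e[-length(e)])) {
    stop("intervals overlap")
  }
  d <- e - s
  list(occurrences = nrow(intervals), mean_duration_s = mean(d),
       total_time_s = sum(d))
}

#' Bregma-interpolated transfected-cell totals
#'
#' Cells are counted in every other section; counts for skipped sections
#' are linearly interpolated against their Bregma coordinate between the
#' flanking counted sections, and the total is the sum of counted plus
#' interpolated values. Sections outside the counted Bregma range are
#' not extrapolated (error unless `drop_outside = TRUE`, which flags
#' and drops them).
#'
#' @param sections data.frame with `bregma_mm` (strictly decreasing,
#'   rostral to caudal) and `count` (NA for uncounted sections).
#' @param drop_outside drop (rather than refuse) uncounted sections
#'   outside the counted range.
#' @return list with `sections` (the completed table, plus an
#'   `interpolated` flag) and `total`.
#' @export
interpolate_cell_counts <- function(sections, drop_outside = FALSE) {
  b <- sections$bregma_mm
  if (any(diff(b) >= 0)) stop("bregma must be strictly decreasing")
  counted <- !is.na(sections$count)
  if (sum(counted) < 2L) stop("need at least 2 counted sections")
  missing <- which(!counted)
  rng <- range(b[counted])
  outside <- !counted & (b < rng[1L] | b > rng[2L])
  if (any(outside)) {
    if (!drop_outside) {
      stop("uncounted section(s) outside the counted Bregma range; ",
           "extrapolation refused")
    }
    message(sum(outside), " uncounted section(s) outside range dropped")
    sections <- sections[!outside, , drop = FALSE]
    b <- sections$bregma_mm
    counted <- !is.na(sections$count)
  }
  est <- sections$count
  if (any(!counted)) {
    est[!counted] <- stats::approx(b[counted], sections$count[counted],
                                   xout = b[!counted])$y
  }
  out <- data.frame(bregma_mm = b, count = est,
                    interpolated = !counted)
  list(sections = out, total = sum(est))
}
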