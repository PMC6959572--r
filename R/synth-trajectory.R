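#' Generate a biased random-walk trajectory in an arena
#'
#' Metropolis random walk: Gaussian step proposals are reflected at the
#' arena walls and accepted with probability `w(new)/w(current)`, where
#' `w` is the preference weight of the zone containing a point (1
#' outside all zones). With uniform weights the stationary distribution
#' is uniform over the arena, so equal-area zones are visited equally in
#' the long run. `lock_zone` emulates a hard preference: once the animal
#' first enters that zone, proposals leaving it are rejected.
#'
#' @param arena an `ArenaConfig`.
#' @param zone_preference named numeric weights (>= 0) per zone;
#'   unnamed zones get weight 1.
#' @param duration_s session length.
#' @param fps frames per second (defaults to the arena's).
#' @param step_sd proposal SD per frame (cm).
#' @param start `(x, y)` start position (default arena center).
#' @param lock_zone zone name to lock into after first entry, or NULL.
#' @param seed RNG seed.
#' @return list with `traj` (a `Trajectory`) and `truth` (the occupancy
#'   table computed directly from the generated positions).
#' @export
generate_trajectory <- function(arena, zone_preference = NULL,
                                duration_s = 300, fps = arena$fps,
                                step_sd = 2, start = NULL,
                                lock_zone = NULL, seed = NULL) {
  stopifnot(inherits(arena, "ArenaConfig"))
  w <- stats::setNames(rep(1, length(arena$zones)), names(arena$zones))
  if (!is.null(zone_preference)) {
    if (any(zone_preference < 0)) stop("weights must be >= 0")
    w[names(zone_preference)] <- zone_preference
  }
  weight_at <- function(x, y) {
    for (nm in names(arena$zones)) {
      if (.in_zone(x, y, arena$zones[[nm]])) return(w[[nm]])
    }
    1
  }
  reflect <- function(v, lim) {
    v <- v %% (2 * lim)
    ifelse(v > lim, 2 * lim - v, v)
  }
  n <- as.integer(round(duration_s * fps))
  xs <- numeric(n); ys <- numeric(n)
  if (is.null(start)) start <- c(arena$width_cm / 2, arena$height_cm / 2)
  with_seed(seed, {
    x <- start[1L]; y <- start[2L]
    wc <- weight_at(x, y)
    locked <- FALSE
    for (i in seq_len(n)) {
      xs[i] <- x; ys[i] <- y
      if (!is.null(lock_zone) && !locked &&
          .in_zone(x, y, arena$zones[[lock_zone]])) locked <- TRUE
      nx <- reflect(x + stats::rnorm(1, 0, step_sd), arena$width_cm)
      ny <- reflect(y + stats::rnorm(1, 0, step_sd), arena$height_cm)
      if (locked && !.in_zone(nx, ny, arena$zones[[lock_zone]])) next
      wn <- weight_at(nx, ny)
      if (wn >= wc || stats::runif(1) < wn / wc) {
        x <- nx; y <- ny; wc <- wn
      }
    }
  })
  traj <- trajectory((seq_len(n) - 1L) / fps, xs, ys, arena)
  list(traj = traj,
       truth = if (length(arena$zones)) zone_occupancy(traj, arena)
               else NULL)
}
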