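#' Eight-arm radial maze geometry
#'
#' Describes the maze used to label positions with sections: a central
#' platform from which eight arms radiate, each ending in a reward-field
#' recess. Sections partition the maze into \code{reward_RF} (end-field of
#' the target arm), \code{target_arm} (the target arm shaft), \code{other_RF}
#' (end-fields of the other arms) and \code{other} (center and remaining
#' arm shafts).
#'
#' @param n_arms number of arms (default 8).
#' @param center_radius central platform radius in cm (default 26).
#' @param arm_length arm length in cm (default 55).
#' @param rf_length length of the end-field recess in cm (default 10).
#' @param target_arm index of the rewarded arm (default 1).
#' @return object of class \code{maze_geometry}.
#' @export
maze_geometry <- function(n_arms = 8, center_radius = 26, arm_length = 55,
                          rf_length = 10, target_arm = 1) {
  if (rf_length >= arm_length)
    stop("maze_geometry: reward field overlaps the whole arm (invalid geometry)")
  if (center_radius <= 0 || arm_length <= 0 || n_arms < 3)
    stop("maze_geometry: invalid geometry")
  structure(list(n_arms = n_arms, center_radius = center_radius,
                 arm_length = arm_length, rf_length = rf_length,
                 target_arm = target_arm,
                 angles = 2 * pi * (seq_len(n_arms) - 1) / n_arms),
            class = "maze_geometry")
}

#' Section label for maze positions
#'
#' @param x,y position coordinates in cm (maze center at the origin).
#' @param maze a [maze_geometry()].
#' @return character vector of section labels; every position receives
#'   exactly one label.
#' @export
maze_section <- function(x, y, maze) {
  r <- sqrt(x^2 + y^2)
  ang <- atan2(y, x) %% (2 * pi)
  arm <- round(ang / (2 * pi / maze$n_arms)) %% maze$n_arms + 1
  rf_start <- maze$center_radius + maze$arm_length - maze$rf_length
  out <- rep("other", length(x))
  on_arm <- r >= maze$center_radius
  in_rf <- r >= rf_start
  out[on_arm & arm == maze$target_arm] <- "target_arm"
  out[in_rf & arm == maze$target_arm] <- "reward_RF"
  out[in_rf & arm != maze$target_arm] <- "other_RF"
  out
}

#' Generate a synthetic behavior track on the radial maze
#'
#' Produces a 20 Hz position/speed track with section labels emulating an
#' arm-to-arm reference-memory task: each trial departs from a pseudo-random
#' arm, visits a number of wrong arms that decreases across days (the
#' learning schedule), then runs to the target arm and dwells at the reward.
#' Latency to reward therefore decreases with training by construction.
#' Speed is computed from positions by central differences followed by a
#' 0.5 s moving average, and is capped by the waypoint stepper.
#'
#' @param maze a [maze_geometry()].
#' @param n_trials trials per day (default 4).
#' @param n_days training days (default 10).
#' @param seed integer seed driving all randomness.
#' @param fs track sampling rate in Hz (default 20).
#' @param speed_cap maximum speed in cm/s (default 90).
#' @param mean_speed average running speed in cm/s (default 25).
#' @param reward_dwell_s dwell time at the reward in seconds (default 5).
#' @param wrong_visit_schedule numeric length-2: mean number of wrong-arm
#'   visits on the first and last day (default \code{c(4, 0)}).
#' @return data.frame of class \code{behavior_track} with columns
#'   \code{time}, \code{x}, \code{y}, \code{speed}, \code{section},
#'   \code{trial_index}, \code{day_index}.
#' @export
generate_behavior <- function(maze = maze_geometry(), n_trials = 4, n_days = 10,
                              seed = 0, fs = 20, speed_cap = 90,
                              mean_speed = 25, reward_dwell_s = 5,
                              wrong_visit_schedule = c(4, 0)) {
  stopifnot(n_trials >= 1, n_days >= 1)
  set.seed(child_seed(seed, 1))
  dt <- 1 / fs
  visits_by_day <- round(seq(wrong_visit_schedule[1], wrong_visit_schedule[2],
                             length.out = n_days))
  arm_tip <- maze$center_radius + maze$arm_length - maze$rf_length / 2
  departures <- setdiff(seq_len(maze$n_arms), maze$target_arm)

  pieces <- list()
  t_offset <- 0
  trial_no <- 0
  for (day in seq_len(n_days)) {
    for (tr in seq_len(n_trials)) {
      trial_no <- trial_no + 1
      dep <- sample(departures, 1)
      wrong_arms <- sample(setdiff(departures, dep),
                           min(visits_by_day[day], maze$n_arms - 2))
      # waypoints: depart -> center -> (wrong arm -> center)* -> target tip
      way <- list(c(arm_tip, dep), c(0, NA))
      for (w in wrong_arms) { way <- c(way, list(c(arm_tip, w), c(0, NA))) }
      way <- c(way, list(c(arm_tip, maze$target_arm)))
      pts <- do.call(rbind, lapply(way, function(p) {
        if (is.na(p[2])) c(0, 0) else p[1] * c(cos(maze$angles[p[2]]),
                                               sin(maze$angles[p[2]]))
      }))
      xy <- walk_waypoints(pts, dt, mean_speed, speed_cap)
      # dwell at reward with small jitter
      nd <- round(reward_dwell_s * fs)
      dwell <- cbind(xy[nrow(xy), 1] + rnorm(nd, 0, 0.3),
                     xy[nrow(xy), 2] + rnorm(nd, 0, 0.3))
      xy <- rbind(xy, dwell)
      n <- nrow(xy)
      pieces[[trial_no]] <- data.frame(
        time = t_offset + seq_len(n) * dt,
        x = xy[, 1], y = xy[, 2],
        trial_index = trial_no, day_index = day)
      t_offset <- t_offset + n * dt
    }
  }
  out <- do.call(rbind, pieces)
  # speed is computed within each trial: trials are separate episodes and
  # the inter-trial repositioning is not locomotion
  out$speed <- unlist(lapply(split(seq_len(nrow(out)), out$trial_index),
                             function(i) track_speed(out$x[i], out$y[i], fs)),
                      use.names = FALSE)
  out$section <- maze_section(out$x, out$y, maze)
  out <- out[, c("time", "x", "y", "speed", "section",
                 "trial_index", "day_index")]
  class(out) <- c("behavior_track", "data.frame")
  attr(out, "maze") <- maze
  attr(out, "fs") <- fs
  out
}

# advance along a waypoint polyline with an Ornstein-Uhlenbeck speed process
walk_waypoints <- function(pts, dt, mean_speed, speed_cap) {
  xy <- matrix(numeric(0), ncol = 2)
  pos <- pts[1, ]
  v <- mean_speed
  for (k in 2:nrow(pts)) {
    target <- pts[k, ]
    repeat {
      d <- target - pos
      dist <- sqrt(sum(d^2))
      if (dist < mean_speed * dt) break
      v <- v + 0.5 * (mean_speed - v) * dt + 6 * sqrt(dt) * rnorm(1)
      v <- min(max(v, 2), 0.95 * speed_cap)
      pos <- pos + d / dist * v * dt
      xy <- rbind(xy, pos)
    }
    pos <- target
  }
  rbind(xy, pos)
}

# central-difference speed with 0.5 s moving average
track_speed <- function(x, y, fs) {
  n <- length(x)
  vx <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) * fs
  vy <- c(y[2] - y[1], (y[3:n] - y[1:(n - 2)]) / 2, y[n] - y[n - 1]) * fs
  v <- sqrt(vx^2 + vy^2)
  w <- max(1, round(0.5 * fs))
  as.numeric(stats::filter(v, rep(1 / w, w), sides = 2, circular = TRUE))
}

#' Mean latency to reward per day
#'
#' Latency is the time from trial start to the first sample labeled
#' \code{reward_RF}.
#'
#' @param behavior a behavior track from [generate_behavior()].
#' @return data.frame with \code{day_index} and \code{latency} (s).
#' @export
latency_by_day <- function(behavior) {
  per_trial <- lapply(split(behavior, behavior$trial_index), function(b) {
    hit <- which(b$section == "reward_RF")[1]
    data.frame(day_index = b$day_index[1],
               latency = if (is.na(hit)) max(b$time) - b$time[1]
                         else b$time[hit] - b$time[1])
  })
  lt <- do.call(rbind, per_trial)
  aggregate(latency ~ day_index, lt, mean)
}
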