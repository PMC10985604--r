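# Synthetic obstacle-course trajectory generator.
#
# Foot motion is modelled as alternating stance (strictly stationary) and
# swing.  A swing is a smooth parameterised arc: the horizontal coordinates
# follow a minimum-jerk profile sigma(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5
# (zero velocity and acceleration at lift-off and touchdown in the plane),
# while the vertical coordinate follows z(tau) = apex * sin(pi * tau), whose
# apex is analytically known and whose non-zero vertical velocity at the
# swing boundaries gives foot strike and foot off a crisp kinematic
# signature, as heel impact does in real gait.  Every Fig-3-style parameter
# of a generated trial therefore has a closed-form (or exhaustively
# computable) ground truth that is returned with the trial.

MARKER_Z_FOOT <- 0.020   # toe/heel marker height above the sole (m)
ANKLE_OFFSET <- c(0.06, 0, 0.08)

#' @noRd
min_jerk <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)

# Invert the minimum-jerk profile: tau such that min_jerk(tau) = s, s in [0,1].
#' @noRd
min_jerk_inv <- function(s) {
  if (s <= 0) return(0)
  if (s >= 1) return(1)
  stats::uniroot(function(tau) min_jerk(tau) - s, c(0, 1), tol = 1e-12)$root
}

# Physical-setup default levels per task (internal units: m, s, percent).
#' @noRd
task_level_defaults <- function(task, profile) {
  base <- list(step_length = profile$step_length,
               step_width = profile$step_width,
               gait_speed = profile$gait_speed,
               double_stance_pct = profile$double_stance_fraction * 100,
               swing_apex_height = profile$swing_apex_height)
  obstacle_speed <- 0.90 * profile$gait_speed / 1.10
  extra <- switch(task,
    normal_walking = list(),
    overstepping = list(gait_speed = obstacle_speed,
                        max_step_height_L = 0.2753, max_step_height_T = 0.2830,
                        preobstacle_distance_T = 0.1645,
                        postobstacle_distance_L = 0.1960,
                        single_stance_pre_T = 0.70, single_stance_post_L = 0.62),
    crossing = list(gait_speed = obstacle_speed,
                    preobstacle_distance_T = 0.0636,
                    postobstacle_distance_L = 0.0329,
                    single_stance_pre_T = 0.61, single_stance_post_L = 0.54),
    balancing = list(gait_speed = obstacle_speed,
                     step_width = 0.0536, step_length = 0.5273,
                     double_stance_pct = 28.58),
    circumventing = list(gait_speed = obstacle_speed,
                         min_shoulder_obstacle_distance = 0.1066))
  utils::modifyList(base, extra)
}

#' @noRd
allowed_overrides <- function(task) {
  base <- c("step_length", "step_width", "gait_speed", "double_stance_pct",
            "swing_apex_height")
  switch(task,
    normal_walking = base,
    overstepping = c(base, "max_step_height_L", "max_step_height_T",
                     "preobstacle_distance_T", "postobstacle_distance_L",
                     "single_stance_pre_T", "single_stance_post_L"),
    crossing = c(base, "step_length_over_gap", "preobstacle_distance_T",
                 "postobstacle_distance_L", "single_stance_pre_T",
                 "single_stance_post_L"),
    balancing = base,
    circumventing = c("gait_speed", "swing_apex_height", "step_width",
                      "min_shoulder_obstacle_distance"))
}

# Build the placement schedule for one trial: a data.frame with one row per
# foot placement (foot, x = heel ground position, y, strike time, duration
# and vertical apex of the swing *into* the placement), plus derived timing.
#' @noRd
build_schedule <- function(task, profile, lv, geometry, leading_foot) {
  s <- lv$step_length
  v <- lv$gait_speed
  dsf <- lv$double_stance_pct / 100
  fl <- profile$foot_length
  L <- geometry$walkway_length
  st <- s / v                      # step (half-stride) time
  t_swing <- (1 - dsf) * st * 2 / 2 # default swing duration = (1-ds)*stride/2
  apex_ref <- max(lv$swing_apex_height - MARKER_Z_FOOT, 0.005)
  lead <- if (identical(leading_foot, "right")) "R" else "L"
  trail <- if (lead == "L") "R" else "L"

  x_first <- 0.30
  tail_limit <- L - 0.25
  special <- list()

  if (task %in% c("overstepping", "crossing")) {
    pre <- lv$preobstacle_distance_T
    post <- lv$postobstacle_distance_L
    edge_in <- if (task == "overstepping") geometry$bar_position else geometry$gap_start
    edge_out <- if (task == "overstepping") geometry$bar_position else
      geometry$gap_start + geometry$gap_width
    x_tp <- edge_in - pre - fl          # trailing foot before the obstacle
    x_lc <- edge_out + post             # leading foot lands after it
    x_lp <- x_tp - s
    if (x_lp < 0.35) {
      stopf("geometry incompatible with profile: no room for the approach (%s)", task)
    }
    if (x_lc - x_tp < 0.03) {
      stopf("geometry incompatible with profile: obstacle span %.2f m is not achievable (spanning placement would move backwards)",
            x_lc - x_tp)
    }
    # the crossing swing must actually carry the toe past the obstacle plane
    if (x_lc + fl < (edge_in + edge_out) / 2 + 0.02) {
      stopf("geometry incompatible with profile: spanning step is not achievable (toe lands short of the obstacle plane)")
    }
    n_app <- floor((x_lp - 0.25) / s)
    if (n_app < 1) stopf("geometry incompatible with profile: approach too short")
    xs <- c(x_lp - (n_app:1) * s, x_lp, x_tp, x_lc)
    i_lc <- length(xs)
    tail <- seq(x_lc + s, tail_limit, by = s)
    if (length(tail) < 1) stopf("geometry incompatible with profile: no room after obstacle")
    xs <- c(xs, tail)
    n <- length(xs)
    # alternate feet so that the crossing placement belongs to the leading foot
    first <- if (i_lc %% 2 == 1) lead else trail
    second <- if (first == lead) trail else lead
    foot <- rep(c(first, second), length.out = n)
    stopifnot(foot[i_lc] == lead, foot[i_lc - 1] == trail)
    # strike-time gaps: uniform st, widened around the crossing so the
    # prescribed single-stance (= crossing swing) durations fit
    ss_pre <- lv$single_stance_pre_T
    ss_post <- lv$single_stance_post_L
    gaps <- rep(st, n)
    gaps[i_lc] <- max(st, ss_pre + 0.15 * st)
    gaps[i_lc + 1] <- max(st, ss_post + 0.15 * st)
    dur <- rep(t_swing, n)
    dur[i_lc] <- ss_pre
    dur[i_lc + 1] <- ss_post
    apex <- rep(apex_ref, n)
    if (task == "overstepping") {
      apex[i_lc] <- max(lv$max_step_height_L - MARKER_Z_FOOT, 0.01)
      apex[i_lc + 1] <- max(lv$max_step_height_T - MARKER_Z_FOOT, 0.01)
    }
    y <- ifelse(foot == "L", lv$step_width / 2, -lv$step_width / 2)
    special <- list(i_lp = i_lc - 2L, i_tp = i_lc - 1L, i_lc = i_lc,
                    i_tc = i_lc + 1L, edge_in = edge_in, edge_out = edge_out)
  } else {
    xs <- seq(x_first, tail_limit, by = s)
    n <- length(xs)
    if (n < 4) stopf("geometry incompatible with profile: step length too long for walkway")
    foot <- rep(c(lead, trail), length.out = n)
    gaps <- rep(st, n)
    dur <- rep(t_swing, n)
    apex <- rep(apex_ref, n)
    if (task == "balancing") {
      zone <- c(geometry$beam_start, geometry$beam_start + geometry$beam_length)
      in_zone <- xs >= zone[1] & xs <= zone[2]
      halfw <- ifelse(in_zone, lv$step_width / 2, profile$step_width / 2)
      y <- geometry$beam_center_y + ifelse(foot == "L", halfw, -halfw)
    } else {
      y <- ifelse(foot == "L", lv$step_width / 2, -lv$step_width / 2)
    }
  }

  strike_t <- cumsum(c(0, gaps[3:n]))          # placements 1..2 stand at t = 0
  strike_t <- c(0, 0, strike_t[-1])
  dur[1:2] <- NA_real_                         # no swing into the initial stance
  # swing into k must start after the contralateral strike k-1
  for (k in 3:n) dur[k] <- min(dur[k], strike_t[k] - strike_t[k - 1] - 0.02)
  if (any(dur[-(1:2)] <= 0.05)) stopf("geometry incompatible with profile: swing durations degenerate")

  pl <- data.frame(foot = foot, x = xs, y = y, strike_t = strike_t,
                   dur = dur, apex = apex)
  sh_x0 <- mean(xs[1:2])
  zone <- task_zone(geometry, task)
  t_end <- max(strike_t[n] + 0.4, (zone[2] + 0.15 - sh_x0) / v)
  list(placements = pl, st = st, t_swing = t_swing, sh_x0 = sh_x0,
       t_end = t_end, special = special, v = v, lead = lead, trail = trail)
}

# Evaluate one foot's marker-reference trajectory (heel ground point) on the
# frame grid.  Stance is exactly stationary; swings interpolate between
# consecutive placements of the same foot.
#' @noRd
foot_track <- function(pl_f, t, t_end) {
  m <- nrow(pl_f)
  n <- length(t)
  out <- matrix(NA_real_, n, 3)
  off <- c(if (m > 1) pl_f$strike_t[-1] - pl_f$dur[-1] else numeric(0), t_end + 1)
  for (k in seq_len(m)) {
    idx <- t >= pl_f$strike_t[k] - 1e-9 & t <= off[k] + 1e-9
    out[idx, 1] <- pl_f$x[k]
    out[idx, 2] <- pl_f$y[k]
    out[idx, 3] <- 0
    if (k < m) {
      sw <- t > off[k] + 1e-9 & t < pl_f$strike_t[k + 1] - 1e-9
      if (any(sw)) {
        tau <- (t[sw] - off[k]) / pl_f$dur[k + 1]
        sg <- min_jerk(tau)
        out[sw, 1] <- pl_f$x[k] + (pl_f$x[k + 1] - pl_f$x[k]) * sg
        out[sw, 2] <- pl_f$y[k] + (pl_f$y[k + 1] - pl_f$y[k]) * sg
        out[sw, 3] <- pl_f$apex[k + 1] * sin(pi * tau)
      }
    }
  }
  out
}

# Lateral weave of the shoulder centroid through the slalom poles:
# amplitude * cos(pi (x - x_p1) / spacing), tapered to zero with raised-cosine
# ramps outside the pole block.
#' @noRd
weave_y <- function(x, geometry, amplitude, ramp = 0.5) {
  px <- sort(geometry$pole_positions[, 1])
  p1 <- px[1]; p4 <- px[length(px)]
  base <- amplitude * cos(pi * (x - p1) / geometry$pole_spacing)
  env <- numeric(length(x))
  env[x >= p1 & x <= p4] <- 1
  lo <- x > p1 - ramp & x < p1
  env[lo] <- 0.5 * (1 - cos(pi * (x[lo] - (p1 - ramp)) / ramp))
  hi <- x > p4 & x < p4 + ramp
  env[hi] <- 0.5 * (1 + cos(pi * (x[hi] - p4) / ramp))
  base * env
}

# Minimal shoulder-pole clearance of the analytic path over the frame grid
# restricted to the pole zone; used both to calibrate the weave amplitude and
# as the trial's ground truth.
#' @noRd
weave_min_clearance <- function(amplitude, sh_x, geometry, sw) {
  zone <- task_zone(geometry, "circumventing")
  keep <- sh_x >= zone[1] & sh_x <= zone[2]
  x <- sh_x[keep]
  yc <- weave_y(x, geometry, amplitude)
  best <- Inf
  for (i in seq_len(nrow(geometry$pole_positions))) {
    px <- geometry$pole_positions[i, 1]; py <- geometry$pole_positions[i, 2]
    for (s in c(1, -1)) {
      d <- sqrt((x - px)^2 + (yc + s * sw / 2 - py)^2)
      best <- min(best, min(d))
    }
  }
  best - geometry$pole_radius
}

# Solve for the weave amplitude that realises a target minimal clearance:
# bracket the root on a coarse amplitude grid (clearance is increasing in
# the amplitude over the usable range), then polish with uniroot.
#' @noRd
calibrate_weave <- function(target, sh_x, geometry, sw) {
  f <- function(a) weave_min_clearance(a, sh_x, geometry, sw) - target
  grid <- seq(0.02, sw / 2 + 1.0, by = 0.04)
  fg <- vapply(grid, f, numeric(1))
  i <- which(fg[-1] >= 0 & fg[-length(fg)] < 0)[1]
  if (is.na(i)) {
    if (all(fg < 0)) {
      stopf("geometry incompatible with profile: clearance %.1f cm not achievable with pole spacing %.2f m",
            target * 100, geometry$pole_spacing)
    }
    return(grid[which.min(abs(fg))])
  }
  stats::uniroot(f, grid[c(i, i + 1)], f.lower = fg[i], f.upper = fg[i + 1],
                 tol = 1e-10)$root
}

# Closed-form toe height when the toe crosses a forward plane during the
# swing into placement k (which starts from the same foot's previous
# placement, two back in the alternating sequence).
#' @noRd
clearance_at <- function(pl, k, plane_x, foot_length) {
  x0 <- pl$x[k - 2] + foot_length
  x1 <- pl$x[k] + foot_length
  sgm <- (plane_x - x0) / (x1 - x0)
  if (sgm <= 0 || sgm >= 1) return(NA_real_)
  tau <- min_jerk_inv(sgm)
  pl$apex[k] * sin(pi * tau) + MARKER_Z_FOOT
}

#' Simulate one obstacle-course trial
#'
#' Generates the nine-marker trajectory of a single trial of one of the five
#' walking tasks, together with the analytic ground truth of every
#' spatiotemporal parameter the extraction stage computes.  Stance feet are
#' exactly stationary (up to the requested marker noise); swing arcs have
#' analytically known apexes, so override values such as a prescribed maximum
#' step height are realised exactly.
#'
#' @param profile A [gait_profile()].
#' @param task One of [gait_tasks()].
#' @param geometry A [course_geometry()].
#' @param overrides Named list of ground-truth parameter values for this
#'   trial, in internal units (m, s, percentage points).  Only parameters
#'   defined for the task may be named (see Details); unknown names raise an
#'   error.  For the crossing task `step_length_over_gap` prescribes the
#'   spanning step directly and re-derives the post-obstacle landing.
#' @param sampling_rate Frames per second.
#' @param noise_sd Isotropic Gaussian jitter SD (m) added per coordinate and
#'   frame; drawn from the current RNG state.
#' @param dropout_probability Per-frame, per-marker probability of losing the
#'   marker (coordinates set to missing).
#' @param leading_foot `"left"` or `"right"`: the foot instructed to cross
#'   first (used by overstepping and crossing).
#' @param participant_id,condition,trial_index Metadata carried on the
#'   recording.
#' @details Allowed override names per task: the base gait parameters
#'   (`step_length`, `step_width`, `gait_speed`, `double_stance_pct`,
#'   `swing_apex_height`) for all footfall tasks, plus
#'   `max_step_height_L/_T`, `preobstacle_distance_T`,
#'   `postobstacle_distance_L`, `single_stance_pre_T`,
#'   `single_stance_post_L` for overstepping (the latter four also for
#'   crossing, together with `step_length_over_gap`), and
#'   `min_shoulder_obstacle_distance` for circumventing.  Task total time is
#'   derived from gait speed and cannot be overridden directly.
#' @return A `trial_recording` whose `ground_truth` element holds the true
#'   parameter values (reporting units: cm, s, percent, m/s), the true
#'   failure flag, and the full foot strike / foot off event schedule.
#' @export
simulate_trial <- function(profile, task, geometry = course_geometry(),
                           overrides = list(), sampling_rate = 100,
                           noise_sd = 0, dropout_probability = 0,
                           leading_foot = "left",
                           participant_id = "P01", condition = "physical",
                           trial_index = 1L) {
  check_task(task)
  if (!inherits(profile, "gait_profile")) stopf("profile must be a gait_profile")
  if (!inherits(geometry, "course_geometry")) stopf("geometry must be a course_geometry")
  bad <- setdiff(names(overrides), allowed_overrides(task))
  if (length(bad)) {
    stopf("overrides not defined for task '%s': %s", task, paste(bad, collapse = ", "))
  }
  lv <- task_level_defaults(task, profile)
  if (!is.null(overrides$step_length_over_gap)) {
    pre <- overrides$preobstacle_distance_T %||% lv$preobstacle_distance_T
    overrides$postobstacle_distance_L <-
      overrides$step_length_over_gap - geometry$gap_width - pre
    overrides$step_length_over_gap <- NULL
  }
  lv <- utils::modifyList(lv, overrides)

  fs <- sampling_rate
  fl <- profile$foot_length
  sw <- profile$shoulder_width

  if (task == "circumventing") {
    sch <- build_schedule(task, profile, lv, geometry, leading_foot)
    t <- seq(0, sch$t_end, by = 1 / fs)
    sh_x <- sch$sh_x0 + sch$v * t
    amp <- calibrate_weave(lv$min_shoulder_obstacle_distance, sh_x, geometry, sw)
    # feet follow a damped version of the weave so the whole body slaloms
    sch$placements$y <- sch$placements$y +
      0.8 * weave_y(sch$placements$x, geometry, amp)
  } else {
    sch <- build_schedule(task, profile, lv, geometry, leading_foot)
    t <- seq(0, sch$t_end, by = 1 / fs)
    sh_x <- sch$sh_x0 + sch$v * t
    amp <- 0
  }
  n <- length(t)
  pl <- sch$placements

  ref_L <- foot_track(pl[pl$foot == "L", , drop = FALSE], t, sch$t_end)
  ref_R <- foot_track(pl[pl$foot == "R", , drop = FALSE], t, sch$t_end)
  yc <- if (task == "circumventing") weave_y(sh_x, geometry, amp) else rep(0, n)
  zsh <- profile$shoulder_height

  markers <- list(
    L_TOE = ref_L + matrix(c(fl, 0, MARKER_Z_FOOT), n, 3, byrow = TRUE),
    L_HEEL = ref_L + matrix(c(0, 0, MARKER_Z_FOOT), n, 3, byrow = TRUE),
    L_ANK = ref_L + matrix(ANKLE_OFFSET, n, 3, byrow = TRUE),
    R_TOE = ref_R + matrix(c(fl, 0, MARKER_Z_FOOT), n, 3, byrow = TRUE),
    R_HEEL = ref_R + matrix(c(0, 0, MARKER_Z_FOOT), n, 3, byrow = TRUE),
    R_ANK = ref_R + matrix(ANKLE_OFFSET, n, 3, byrow = TRUE),
    L_SHO = cbind(sh_x, yc + sw / 2, rep(zsh, n)),
    R_SHO = cbind(sh_x, yc - sw / 2, rep(zsh, n)),
    C7 = cbind(sh_x - 0.05, yc, rep(zsh + 0.03, n))
  )
  markers <- lapply(markers, function(m) {
    dimnames(m) <- list(NULL, c("X", "Y", "Z")); m
  })

  gt <- ground_truth_params(task, pl, sch, geometry, fl, sh_x, amp, sw, lv)
  gt$events <- schedule_events(pl, sch$t_end)
  gt$leading_foot <- leading_foot

  if (noise_sd > 0) {
    for (nm in names(markers)) {
      markers[[nm]] <- markers[[nm]] + matrix(stats::rnorm(3L * n, 0, noise_sd), n, 3)
    }
  }
  if (dropout_probability > 0) {
    for (nm in names(markers)) {
      drop <- stats::runif(n) < dropout_probability
      markers[[nm]][drop, ] <- NA_real_
    }
  }

  structure(list(
    participant_id = participant_id, condition = condition, task = task,
    trial_index = as.integer(trial_index), sampling_rate = fs,
    markers = markers, leading_foot = leading_foot,
    instruction_violation = FALSE,
    ground_truth = gt
  ), class = "trial_recording")
}

# Ground-truth event schedule implied by the placements.
#' @noRd
schedule_events <- function(pl, t_end) {
  ev <- list()
  for (f in c("L", "R")) {
    p <- pl[pl$foot == f, , drop = FALSE]
    m <- nrow(p)
    strikes <- p$strike_t
    offs <- if (m > 1) p$strike_t[-1] - p$dur[-1] else numeric(0)
    ev[[f]] <- rbind(
      data.frame(foot = f, kind = "strike", time = strikes),
      data.frame(foot = f, kind = "off", time = offs)
    )
  }
  out <- rbind(ev$L, ev$R)
  out <- out[out$time <= t_end, ]
  out <- out[order(out$time, out$foot, out$kind), ]
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

#' @noRd
ground_truth_params <- function(task, pl, sch, geometry, fl, sh_x, amp, sw, lv) {
  zone <- task_zone(geometry, task)
  total_time <- (zone[2] - zone[1]) / sch$v
  sp <- sch$special
  p <- switch(task,
    normal_walking = c(step_length = lv$step_length * 100,
                       step_width = lv$step_width * 100,
                       gait_speed = lv$gait_speed,
                       double_stance_pct = lv$double_stance_pct),
    overstepping = c(
      max_step_height_L = pl$apex[sp$i_lc] + MARKER_Z_FOOT,
      max_step_height_T = pl$apex[sp$i_tc] + MARKER_Z_FOOT,
      step_height_over_obstacle_L = clearance_at(pl, sp$i_lc, geometry$bar_position, fl),
      step_height_over_obstacle_T = clearance_at(pl, sp$i_tc, geometry$bar_position, fl),
      preobstacle_distance_T = geometry$bar_position - (pl$x[sp$i_tp] + fl),
      postobstacle_distance_L = pl$x[sp$i_lc] - geometry$bar_position
    ) * 100,
    crossing = c(
      step_length = pl$x[sp$i_lc] - (pl$x[sp$i_tp] + fl),
      preobstacle_distance_T = geometry$gap_start - (pl$x[sp$i_tp] + fl),
      postobstacle_distance_L = pl$x[sp$i_lc] - sp$edge_out
    ) * 100,
    balancing = c(step_length = lv$step_length * 100,
                  step_width = lv$step_width * 100,
                  double_stance_pct = lv$double_stance_pct),
    circumventing = c(
      min_shoulder_obstacle_distance =
        weave_min_clearance(amp, sh_x, geometry, sw) * 100
    )
  )
  if (task %in% c("overstepping", "crossing")) {
    p <- c(p, single_stance_pre_T = pl$dur[sp$i_lc],
           single_stance_post_L = pl$dur[sp$i_tc])
  }
  if (task != "normal_walking") p <- c(p, total_time = total_time)
  fail <- gt_failure(task, p)
  list(task = task, params = p, failure = fail)
}

#' @noRd
gt_failure <- function(task, p) {
  switch(task,
    overstepping = isTRUE(p[["max_step_height_L"]] < 16) ||
      isTRUE(p[["max_step_height_T"]] < 16),
    crossing = isTRUE(p[["step_length"]] < 51),
    balancing = isTRUE(p[["step_width"]] > 19),
    circumventing = isTRUE(p[["min_shoulder_obstacle_distance"]] < 2),
    FALSE)
}

#' @export
print.trial_recording <- function(x, ...) {
  n <- nrow(x$markers[[1]])
  cat(sprintf("<trial_recording> %s %s %s #%d: %d frames @ %g Hz, %d markers\n",
              x$participant_id, x$condition, x$task, x$trial_index,
              n, x$sampling_rate, length(x$markers)))
  invisible(x)
}
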