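# Task-specific spatiotemporal parameter extraction.
#
# Conventions (matching how clearance and landing distance are measured in
# obstacle-crossing gait analysis): the toe marker defines pre-obstacle foot
# position and clearance, the heel marker defines landings; step height is
# measured above the floor (z = 0); pre-obstacle distances are signed,
# negative when the toe is already past the obstacle's near edge.  Lengths
# are reported in cm, times in s, double stance in percent of stride time,
# gait speed in m/s.

#' Default failure rules
#'
#' The a-priori failure thresholds of the obstacle course: an obstacle
#' negotiation counts as failed when the maximum step height of either foot
#' stays below 16 cm (1 cm above the 15 cm bar, absorbing marker height),
#' the gap-crossing step is shorter than 51 cm (1 cm beyond the 50 cm gap),
#' any step on the beam is wider than 19 cm (the 20 cm beam minus margin),
#' or a shoulder passes a pole closer than 2 cm.
#'
#' @return A tibble (task, parameter, comparator, threshold) with thresholds
#'   in reporting units (cm).
#' @export
failure_rules <- function() {
  tibble::tribble(
    ~task, ~parameter, ~comparator, ~threshold,
    "overstepping", "max_step_height_L", "lt", 16,
    "overstepping", "max_step_height_T", "lt", 16,
    "crossing", "step_length", "lt", 51,
    "balancing", "step_width", "gt", 19,
    "circumventing", "min_shoulder_obstacle_distance", "lt", 2
  )
}

#' @noRd
rule_violated <- function(value, comparator, threshold) {
  !is.na(value) & ((comparator == "lt" & value < threshold) |
                     (comparator == "gt" & value > threshold))
}

#' @noRd
shoulder_centroid <- function(trial) {
  (trial$markers$L_SHO + trial$markers$R_SHO) / 2
}

# Per-stance summary: one row per foot strike with the marker positions
# averaged over the stationary frames of that stance (boundary frames are
# trimmed, so a plain mean is both exact on clean data and optimal under
# isotropic jitter).
#' @noRd
stance_table <- function(trial, events) {
  fs <- trial$sampling_rate
  n <- nrow(trial$markers[[1]])
  foot_v <- character(0); t0_v <- t1_v <- numeric(0)
  hx <- hy <- tx <- ty <- numeric(0)
  for (f in c("L", "R")) {
    ev <- events[events$foot == f, ]
    strikes <- ev$time[ev$kind == "strike"]
    offs <- ev$time[ev$kind == "off"]
    heel <- trial$markers[[paste0(f, "_HEEL")]]
    toe <- trial$markers[[paste0(f, "_TOE")]]
    for (i in seq_along(strikes)) {
      t0 <- strikes[i]
      t1 <- if (i <= length(offs)) offs[i] else (n - 1) / fs
      i0 <- min(max(ceiling(t0 * fs) + 2L, 1L), n)
      i1 <- max(min(floor(t1 * fs), n), 1L)
      if (i1 < i0) { i0 <- max(round(t0 * fs), 1L); i1 <- i0 }
      idx <- i0:i1
      foot_v <- c(foot_v, f); t0_v <- c(t0_v, t0)
      t1_v <- c(t1_v, if (i <= length(offs)) offs[i] else NA_real_)
      hx <- c(hx, mean(heel[idx, 1])); hy <- c(hy, mean(heel[idx, 2]))
      tx <- c(tx, mean(toe[idx, 1])); ty <- c(ty, mean(toe[idx, 2]))
    }
  }
  st <- data.frame(foot = foot_v, strike_time = t0_v, off_time = t1_v,
                   heel_x = hx, heel_y = hy, toe_x = tx, toe_y = ty)
  st <- st[order(st$strike_time, st$foot), ]
  rownames(st) <- NULL
  st
}

# Mean step length/width (m) over successive contralateral stances,
# optionally restricted to stances whose heels fall inside an x-range.
#' @noRd
step_geometry <- function(st, zone = NULL) {
  if (!is.null(zone)) st <- st[st$heel_x >= zone[1] & st$heel_x <= zone[2], , drop = FALSE]
  if (nrow(st) < 2) stopf("fewer than 2 steps available")
  lens <- widths <- numeric(0)
  for (i in 2:nrow(st)) {
    if (st$foot[i] != st$foot[i - 1]) {
      lens <- c(lens, abs(st$heel_x[i] - st$heel_x[i - 1]))
      widths <- c(widths, abs(st$heel_y[i] - st$heel_y[i - 1]))
    }
  }
  if (length(lens) < 1) stopf("no alternating step pairs found")
  list(step_length = mean(lens), step_width = mean(widths),
       max_step_width = max(widths), n_steps = length(lens))
}

# Double stance as percent of stride time, over strides that start inside
# `zone` (heel of the opening strike) when given; a stride may end past the
# zone so that long strides on a short beam still contribute.
#' @noRd
double_stance_pct <- function(st, events, zone = NULL) {
  vals <- numeric(0)
  for (f in c("L", "R")) {
    own <- st[st$foot == f, , drop = FALSE]
    other <- events[events$foot != f, ]
    own_off <- events$time[events$foot == f & events$kind == "off"]
    if (nrow(own) < 2) next
    for (i in 1:(nrow(own) - 1)) {
      t0 <- own$strike_time[i]; t1 <- own$strike_time[i + 1]
      if (!is.null(zone) &&
          !(own$heel_x[i] >= zone[1] && own$heel_x[i] <= zone[2])) next
      oc <- other$time[other$kind == "off" & other$time > t0 & other$time < t1]
      cs <- other$time[other$kind == "strike" & other$time > t0 & other$time < t1]
      oo <- own_off[own_off > t0 & own_off < t1]
      if (!length(oc) || !length(cs) || !length(oo)) next
      ds <- (oc[1] - t0) + (oo[1] - cs[1])
      vals <- c(vals, 100 * ds / (t1 - t0))
    }
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

# Time at which a monotone forward coordinate crosses a plane, by linear
# interpolation between the bracketing frames (exact for constant speed).
#' @noRd
crossing_time <- function(x, t, plane) {
  i <- which(x >= plane)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(t[1])
  t[i - 1] + (plane - x[i - 1]) / (x[i] - x[i - 1]) * (t[i] - t[i - 1])
}

#' @noRd
total_task_time <- function(trial, zone) {
  sh <- shoulder_centroid(trial)
  t <- (seq_len(nrow(sh)) - 1) / trial$sampling_rate
  ok <- !is.na(sh[, 1])
  t_in <- crossing_time(sh[ok, 1], t[ok], zone[1])
  t_out <- crossing_time(sh[ok, 1], t[ok], zone[2])
  if (is.na(t_in) || is.na(t_out)) stopf("shoulder centroid never traverses the task zone")
  t_out - t_in
}

# The swing of each foot that crosses a forward plane: consecutive stances of
# one foot whose toe positions straddle the plane.  Returns per-foot rows
# with the swing interval, ordered so the leading (earlier) foot comes first.
#' @noRd
crossing_swings <- function(st, plane) {
  out <- list()
  for (f in c("L", "R")) {
    own <- st[st$foot == f, , drop = FALSE]
    if (nrow(own) < 2) next
    for (i in 1:(nrow(own) - 1)) {
      if (own$toe_x[i] < plane && own$toe_x[i + 1] > plane) {
        out[[length(out) + 1L]] <- data.frame(
          foot = f, off_time = own$off_time[i], strike_time = own$strike_time[i + 1],
          from_toe_x = own$toe_x[i], to_heel_x = own$heel_x[i + 1],
          from_idx = i, stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (length(out) < 2) stopf("no crossing detected: fewer than two swings span the obstacle plane")
  sw <- do.call(rbind, out)
  sw[order(sw$off_time), ]
}

# Smooth (cubic-spline) maximisation / plane-crossing evaluation of the toe
# trajectory during one swing.
#' @noRd
swing_toe_curves <- function(trial, foot, t0, t1) {
  fs <- trial$sampling_rate
  n <- nrow(trial$markers[[1]])
  toe <- trial$markers[[paste0(foot, "_TOE")]]
  i0 <- max(floor(t0 * fs) - 1L, 0L) + 1L
  i1 <- min(ceiling(t1 * fs) + 1L, n - 1L) + 1L
  idx <- i0:i1
  t <- (idx - 1) / fs
  list(x = stats::splinefun(t, toe[idx, 1]),
       z = stats::splinefun(t, toe[idx, 3]),
       t0 = t0, t1 = t1)
}

#' @noRd
swing_max_height <- function(curves) {
  opt <- stats::optimize(curves$z, c(curves$t0, curves$t1), maximum = TRUE,
                         tol = 1e-10)
  max(opt$objective, curves$z(curves$t0), curves$z(curves$t1))
}

#' @noRd
swing_height_at_plane <- function(curves, plane) {
  g <- function(t) curves$x(t) - plane
  if (g(curves$t0) > 0 || g(curves$t1) < 0) return(NA_real_)
  ts <- stats::uniroot(g, c(curves$t0, curves$t1), tol = 1e-12)$root
  curves$z(ts)
}

#' Extract the spatiotemporal parameters of one trial
#'
#' Computes, for a single trial, every task parameter of the obstacle-course
#' protocol from the marker trajectories and detected gait events, together
#' with the trial's failure verdict under the supplied rules.
#'
#' @param trial A `trial_recording`.
#' @param events Result of [detect_events()]; computed on the fly when
#'   omitted.
#' @param geometry A [course_geometry()].
#' @param rules Failure rules, see [failure_rules()].
#' @param stance Optional precomputed internal stance table (reused by the
#'   pipeline to avoid recomputation).
#' @return A `task_parameters` list: `task`, `leading_foot` (detected, for
#'   obstacle tasks), `values` (named numeric, reporting units),
#'   `rule_values` (quantities the failure rules are evaluated on),
#'   `failure` (logical) and `failure_reasons`.
#' @export
task_parameters <- function(trial, events = NULL, geometry = course_geometry(),
                            rules = failure_rules(), stance = NULL) {
  if (is.null(events)) events <- detect_events(trial)
  if (is.null(stance) && trial$task != "circumventing") {
    stance <- stance_table(trial, events)
  }
  fn <- switch(trial$task,
    normal_walking = normal_walking_params,
    overstepping = overstepping_params,
    crossing = crossing_params,
    balancing = balancing_params,
    circumventing = circumventing_params)
  res <- fn(trial, events, geometry, stance)
  rl <- rules[rules$task == trial$task, , drop = FALSE]
  reasons <- character(0)
  if (nrow(rl)) {
    for (i in seq_len(nrow(rl))) {
      v <- res$rule_values[[rl$parameter[i]]]
      if (!is.null(v) && isTRUE(rule_violated(v, rl$comparator[i], rl$threshold[i]))) {
        reasons <- c(reasons, sprintf("%s %s %g", rl$parameter[i],
                                      rl$comparator[i], rl$threshold[i]))
      }
    }
  }
  res$failure <- length(reasons) > 0
  res$failure_reasons <- reasons
  structure(res, class = "task_parameters")
}

#' @noRd
normal_walking_params <- function(trial, events, geometry, st) {
  if (sum(events$kind == "strike") < 3) stopf("fewer than 3 foot strikes detected")
  sg <- step_geometry(st)
  sh <- shoulder_centroid(trial)
  t <- (seq_len(nrow(sh)) - 1) / trial$sampling_rate
  tw <- range(st$strike_time)
  if (diff(tw) <= 0) stopf("degenerate analysis window")
  x_at <- stats::approx(t, sh[, 1], xout = tw)$y
  speed <- diff(x_at) / diff(tw)
  ds <- double_stance_pct(st, events)
  list(task = "normal_walking", leading_foot = "unknown",
       values = c(step_length = sg$step_length * 100,
                  step_width = sg$step_width * 100,
                  gait_speed = speed,
                  double_stance_pct = ds),
       rule_values = list())
}

#' @noRd
obstacle_negotiation_params <- function(trial, events, geometry, st, task) {
  edge_in <- if (task == "overstepping") geometry$bar_position else geometry$gap_start
  edge_out <- if (task == "overstepping") geometry$bar_position else
    geometry$gap_start + geometry$gap_width
  plane <- (edge_in + edge_out) / 2
  sw <- crossing_swings(st, plane)
  lead <- sw[1, ]; trailf <- sw[2, ]
  # trailing stance before the obstacle = the stance the trailing crossing
  # swing starts from
  trail_pre_toe <- trailf$from_toe_x
  pre <- edge_in - trail_pre_toe
  post <- lead$to_heel_x - edge_out
  ss_pre <- lead$strike_time - lead$off_time
  ss_post <- trailf$strike_time - trailf$off_time
  zone <- task_zone(geometry, task)
  tot <- total_task_time(trial, zone)
  vals <- c(preobstacle_distance_T = pre * 100,
            postobstacle_distance_L = post * 100,
            single_stance_pre_T = ss_pre,
            single_stance_post_L = ss_post,
            total_time = tot)
  rule_values <- list()
  if (task == "overstepping") {
    hL <- swing_toe_curves(trial, lead$foot, lead$off_time, lead$strike_time)
    hT <- swing_toe_curves(trial, trailf$foot, trailf$off_time, trailf$strike_time)
    vals <- c(max_step_height_L = swing_max_height(hL) * 100,
              max_step_height_T = swing_max_height(hT) * 100,
              step_height_over_obstacle_L =
                swing_height_at_plane(hL, geometry$bar_position) * 100,
              step_height_over_obstacle_T =
                swing_height_at_plane(hT, geometry$bar_position) * 100,
              vals)
    rule_values <- list(max_step_height_L = vals[["max_step_height_L"]],
                        max_step_height_T = vals[["max_step_height_T"]])
  } else {
    step_len <- lead$to_heel_x - trail_pre_toe
    vals <- c(step_length = step_len * 100, vals)
    rule_values <- list(step_length = vals[["step_length"]])
  }
  list(task = task,
       leading_foot = if (lead$foot == "L") "left" else "right",
       values = vals, rule_values = rule_values)
}

#' @noRd
overstepping_params <- function(trial, events, geometry, st) {
  obstacle_negotiation_params(trial, events, geometry, st, "overstepping")
}

#' @noRd
crossing_params <- function(trial, events, geometry, st) {
  obstacle_negotiation_params(trial, events, geometry, st, "crossing")
}

#' @noRd
balancing_params <- function(trial, events, geometry, st) {
  zone <- obstacle_extent(geometry, "balancing")
  sg <- step_geometry(st, zone = zone)
  ds <- double_stance_pct(st, events, zone = zone)
  tot <- total_task_time(trial, task_zone(geometry, "balancing"))
  list(task = "balancing", leading_foot = "unknown",
       values = c(step_width = sg$step_width * 100,
                  step_length = sg$step_length * 100,
                  double_stance_pct = ds,
                  total_time = tot),
       rule_values = list(step_width = sg$max_step_width * 100))
}

#' Minimal shoulder-obstacle clearance by exhaustive scan
#'
#' Minimum over every frame in the pole zone, both acromion markers and all
#' poles of the horizontal distance from marker to pole centre minus the
#' pole radius.
#'
#' @param trial A `trial_recording`.
#' @param geometry A [course_geometry()].
#' @return Clearance in metres (negative means overlap with the pole).
#' @export
min_shoulder_clearance <- function(trial, geometry = course_geometry()) {
  sh <- shoulder_centroid(trial)
  zone <- task_zone(geometry, "circumventing")
  keep <- !is.na(sh[, 1]) & sh[, 1] >= zone[1] & sh[, 1] <= zone[2]
  if (!any(keep)) stopf("shoulder markers missing throughout the pole zone")
  best <- Inf
  for (nm in c("L_SHO", "R_SHO")) {
    m <- trial$markers[[nm]][keep, , drop = FALSE]
    ok <- !is.na(m[, 1])
    for (i in seq_len(nrow(geometry$pole_positions))) {
      d <- sqrt((m[ok, 1] - geometry$pole_positions[i, 1])^2 +
                  (m[ok, 2] - geometry$pole_positions[i, 2])^2)
      if (length(d)) best <- min(best, min(d))
    }
  }
  best - geometry$pole_radius
}

#' @noRd
circumventing_params <- function(trial, events, geometry, st = NULL) {
  d <- min_shoulder_clearance(trial, geometry)
  tot <- total_task_time(trial, task_zone(geometry, "circumventing"))
  list(task = "circumventing", leading_foot = "unknown",
       values = c(min_shoulder_obstacle_distance = d * 100, total_time = tot),
       rule_values = list(min_shoulder_obstacle_distance = d * 100))
}

#' Failure totals across trials
#'
#' Tallies rule violations across the trials of one task, per condition:
#' total failures and the number of distinct participants with at least one
#' failure, mirroring the "n (number of children)" accounting of the study
#' protocol.
#'
#' @param rule_table Tibble with one row per (trial, rule parameter):
#'   columns `participant_id`, `condition`, `task`, `trial_index`,
#'   `parameter`, `value`.
#' @param rules Failure rules, see [failure_rules()].
#' @return Tibble (task, parameter, condition, failures, children).
#' @export
count_failures <- function(rule_table, rules = failure_rules()) {
  if (length(unique(rule_table$task)) > 1) {
    stopf("count_failures expects trials of a single task")
  }
  tsk <- unique(rule_table$task)
  rl <- rules[rules$task == tsk, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(rl))) {
    sub <- rule_table[rule_table$parameter == rl$parameter[i], , drop = FALSE]
    if (!nrow(sub)) next
    sub$fail <- rule_violated(sub$value, rl$comparator[i], rl$threshold[i])
    for (cond in unique(sub$condition)) {
      sc <- sub[sub$condition == cond, ]
      out[[length(out) + 1L]] <- tibble::tibble(
        task = tsk, parameter = rl$parameter[i], condition = cond,
        failures = sum(sc$fail),
        children = length(unique(sc$participant_id[sc$fail])))
    }
  }
  if (!length(out)) {
    return(tibble::tibble(task = character(0), parameter = character(0),
                          condition = character(0), failures = integer(0),
                          children = integer(0)))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$parameter, .data$condition)
}
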