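#' Gait profile of a simulated participant
#'
#' Baseline (physical-setup) gait characteristics used by the synthetic
#' trajectory generator.  Defaults equal the physical-setup group means of
#' the validation cohort during unobstructed walking; body dimensions
#' default to a typical 12-year-old (1.46 m tall, 33 cm shoulder width).
#'
#' @param step_length Anteroposterior distance between successive
#'   contralateral foot placements (m).
#' @param step_width Mediolateral distance between successive contralateral
#'   foot placements (m).
#' @param gait_speed Forward walking speed (m/s).
#' @param double_stance_fraction Fraction of stride time spent with both feet
#'   on the ground, in `[0, 0.6]`.
#' @param swing_apex_height Apex height of the toe marker during an
#'   unobstructed swing (m).
#' @param shoulder_width Distance between the acromion markers (m).
#' @param shoulder_height Height of the acromion markers above the floor (m).
#' @param foot_length Forward offset of the toe marker from the heel
#'   marker (m).
#' @return A `gait_profile` list; `stride_time` (s) is derived as
#'   `2 * step_length / gait_speed`.
#' @export
gait_profile <- function(step_length = 0.6044,
                         step_width = 0.0929,
                         gait_speed = 1.10,
                         double_stance_fraction = 0.2475,
                         swing_apex_height = 0.05,
                         shoulder_width = 0.33,
                         shoulder_height = 1.19,
                         foot_length = 0.15) {
  for (f in c("step_length", "step_width", "gait_speed", "swing_apex_height",
              "shoulder_width", "shoulder_height", "foot_length")) {
    v <- get(f)
    if (!is_number(v) || v <= 0) stopf("gait_profile field '%s' must be a positive number", f)
  }
  if (!is_number(double_stance_fraction) ||
      double_stance_fraction < 0 || double_stance_fraction > 0.6) {
    stopf("double_stance_fraction must lie in [0, 0.6]")
  }
  structure(list(
    step_length = step_length, step_width = step_width,
    gait_speed = gait_speed,
    double_stance_fraction = double_stance_fraction,
    swing_apex_height = swing_apex_height,
    shoulder_width = shoulder_width, shoulder_height = shoulder_height,
    foot_length = foot_length,
    stride_time = 2 * step_length / gait_speed
  ), class = "gait_profile")
}

#' Condition effect on one task parameter
#'
#' Describes how a spatiotemporal parameter shifts in the VR condition
#' relative to the physical condition: a mean shift, a between-participant SD
#' of the shift, and a within-participant (trial-to-trial) SD.  Units follow
#' the parameter (m for lengths, s for times, percentage points for double
#' stance, m/s for speed): effects are stored in the generator's internal
#' units, not the cm reporting units.
#'
#' @param task Task identifier (see [gait_tasks()]).
#' @param parameter Parameter name the shift applies to.
#' @param condition_shift Mean VR-minus-physical shift.
#' @param between_sd Between-participant SD of the shift (>= 0).
#' @param within_sd Trial-to-trial SD of the parameter (>= 0), applied in
#'   both conditions.
#' @param level_correlation Correlation in `[-1, 1]` between a participant's
#'   baseline level and their shift (participants with high baselines tend
#'   to show smaller VR increases; this is what makes the VR-condition SD
#'   differ from `sqrt(physical_sd^2 + diff_sd^2)`).
#' @return A `task_effect` list.
#' @export
task_effect <- function(task, parameter, condition_shift,
                        between_sd = 0, within_sd = 0,
                        level_correlation = 0) {
  check_task(task)
  if (!is_number(condition_shift)) stopf("condition_shift must be a number")
  if (!is_number(between_sd) || between_sd < 0) stopf("between_sd must be >= 0")
  if (!is_number(within_sd) || within_sd < 0) stopf("within_sd must be >= 0")
  if (!is_number(level_correlation) || abs(level_correlation) > 1) {
    stopf("level_correlation must lie in [-1, 1]")
  }
  structure(list(task = task, parameter = parameter,
                 condition_shift = condition_shift,
                 between_sd = between_sd, within_sd = within_sd,
                 level_correlation = level_correlation),
            class = "task_effect")
}

# Trial-to-trial SDs (internal units) used by reference_effects(); chosen as
# typical repeat-trial variability in paediatric obstacle gait and kept well
# below the between-participant SDs so the printed difference SDs dominate.
#' @noRd
default_within_sd <- function(parameter) {
  switch(parameter,
    gait_speed = 0.04,
    double_stance_pct = 1.5,
    single_stance_pre_T = 0.03,
    single_stance_post_L = 0.03,
    min_shoulder_obstacle_distance = 0.010,
    0.015) # lengths/heights (m)
  }

#' Condition effects emulating the validation cohort
#'
#' Builds the list of [task_effect()]s whose mean shifts and
#' between-participant SDs equal the published VR-minus-physical difference
#' column of [reference_summary()] (converted to internal units).  Total-time
#' and derived-clearance differences are not injected: total time follows
#' from the simulated speed, and clearance over the obstacle follows
#' geometrically from the swing apex.
#'
#' The level-shift correlation of each effect is back-derived from the
#' printed SDs: since `VR = level + shift`,
#' `vr_sd^2 = physical_sd^2 + diff_sd^2 + 2 rho physical_sd diff_sd`, which
#' pins down `rho`.  The published VR columns are all less dispersed than
#' independence would imply, i.e. shifts regress toward the mean.
#'
#' @return A list of `task_effect` objects.
#' @export
reference_effects <- function() {
  ref <- reference_summary()
  injectable <- !(ref$parameter %in% c("total_time",
                                       "step_height_over_obstacle_L",
                                       "step_height_over_obstacle_T"))
  ref <- ref[injectable, ]
  lapply(seq_len(nrow(ref)), function(i) {
    r <- ref[i, ]
    scale <- if (r$unit == "cm") 0.01 else 1
    rho <- if (r$physical_sd > 0 && r$diff_sd > 0) {
      (r$vr_sd^2 - r$physical_sd^2 - r$diff_sd^2) / (2 * r$physical_sd * r$diff_sd)
    } else 0
    task_effect(r$task, r$parameter,
                condition_shift = r$diff_mean * scale,
                between_sd = r$diff_sd * scale,
                within_sd = default_within_sd(r$parameter),
                level_correlation = max(min(rho, 0.95), -0.95))
  })
}

#' Configuration of a synthetic study
#'
#' Bundles everything needed to simulate a two-condition obstacle-course
#' study: cohort size, the eight-trials-per-task recording protocol,
#' sampling rate, marker noise and dropout, the course geometry, and the
#' VR condition effects.
#'
#' @param n_participants Number of participants (default 20, the validation
#'   cohort size).
#' @param trials_per_task Trials recorded per task and condition (default 8:
#'   six analysed plus two spares).
#' @param sampling_rate Motion-capture sampling rate in Hz (default 100).
#' @param noise_sd Isotropic Gaussian marker jitter SD per coordinate and
#'   frame (m); default 1 mm, typical for optical capture.
#' @param dropout_probability Per-frame, per-marker probability that a marker
#'   is lost (all three coordinates missing); in `[0, 1)`.
#' @param rng_seed Integer seed making the whole dataset reproducible.
#' @param effects List of [task_effect()]s applied in the VR condition
#'   (default [reference_effects()]).
#' @param geometry A [course_geometry()].
#' @param profile_mean Population-mean [gait_profile()].
#' @param profile_sd Named numeric vector of between-participant SDs for
#'   profile fields (see Details).
#' @details Participant baseline profiles are drawn from normals truncated to
#'   physiologic ranges; default SDs follow the physical-setup column of
#'   [reference_summary()] where available (step length 10.22 cm, step width
#'   3.92 cm, speed 0.23 m/s, double stance 4.41 points) and 10 percent of
#'   the mean for body dimensions.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_participants = 20,
                             trials_per_task = 8,
                             sampling_rate = 100,
                             noise_sd = 0.001,
                             dropout_probability = 0,
                             rng_seed = 1L,
                             effects = reference_effects(),
                             geometry = course_geometry(),
                             profile_mean = gait_profile(),
                             profile_sd = NULL) {
  if (!is_count(n_participants)) stopf("n_participants must be a count >= 1")
  if (!is_count(trials_per_task)) stopf("trials_per_task must be a count >= 1")
  if (!is_number(sampling_rate) || sampling_rate <= 0) stopf("sampling_rate must be > 0")
  if (!is_number(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!is_number(dropout_probability) || dropout_probability < 0 ||
      dropout_probability >= 1) {
    stopf("dropout_probability must lie in [0, 1)")
  }
  if (!inherits(geometry, "course_geometry")) stopf("geometry must be a course_geometry")
  if (!inherits(profile_mean, "gait_profile")) stopf("profile_mean must be a gait_profile")
  if (!all(vapply(effects, inherits, logical(1), "task_effect"))) {
    stopf("effects must be a list of task_effect objects")
  }
  sd_default <- c(step_length = 0.1022, step_width = 0.0392, gait_speed = 0.23,
                  double_stance_fraction = 0.0441, swing_apex_height = 0.01,
                  shoulder_width = 0.033, shoulder_height = 0.12,
                  foot_length = 0.015)
  if (!is.null(profile_sd)) {
    bad <- setdiff(names(profile_sd), names(sd_default))
    if (length(bad)) stopf("unknown profile_sd fields: %s", paste(bad, collapse = ", "))
    sd_default[names(profile_sd)] <- profile_sd
  }
  structure(list(
    n_participants = as.integer(n_participants),
    trials_per_task = as.integer(trials_per_task),
    sampling_rate = sampling_rate, noise_sd = noise_sd,
    dropout_probability = dropout_probability,
    rng_seed = as.integer(rng_seed),
    effects = effects, geometry = geometry,
    profile_mean = profile_mean, profile_sd = sd_default
  ), class = "synthetic_config")
}
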