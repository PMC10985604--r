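#' Published spatiotemporal reference summary
#'
#' Group-level summary statistics (n = 20 children with gait disorders)
#' reported by the validation study that compared obstacle negotiation in an
#' immersive virtual-reality (VR) setup against the physical course: per task
#' and parameter, the physical-setup mean (SD), the VR-setup mean (SD), and
#' the paired VR-minus-physical difference mean (SD).  Lengths are in cm,
#' times in seconds, gait speed in m/s and double stance in percent of stride
#' time.
#'
#' These printed values are the inputs to the statistical layer when the raw
#' motion-capture recordings are unavailable: [difference_ci()] on the
#' difference column reproduces the study's confidence intervals, and
#' [classify_noninferiority()] with [default_margins()] reproduces its
#' noninferiority verdicts.  They also parameterise the synthetic-trajectory
#' generator (see [reference_effects()]).
#'
#' @return A tibble with columns `task`, `parameter`, `unit`, `primary`
#'   (logical: primary outcome), `physical_mean`, `physical_sd`, `vr_mean`,
#'   `vr_sd`, `diff_mean`, `diff_sd`, `n`.
#' @seealso [reference_failures()], [reference_decisions()]
#' @export
reference_summary <- function() {
  tb <- tibble::tribble(
    ~task, ~parameter, ~unit, ~primary,
    ~physical_mean, ~physical_sd, ~vr_mean, ~vr_sd, ~diff_mean, ~diff_sd,
    "normal_walking", "step_length", "cm", FALSE, 60.44, 10.22, 54.91, 7.11, -5.53, 7.14,
    "normal_walking", "step_width", "cm", FALSE, 9.29, 3.92, 9.48, 3.07, 0.19, 2.07,
    "normal_walking", "gait_speed", "m/s", FALSE, 1.10, 0.23, 0.95, 0.20, -0.15, 0.24,
    "normal_walking", "double_stance_pct", "%", FALSE, 24.75, 4.41, 27.48, 3.82, 2.72, 4.21,
    "overstepping", "max_step_height_L", "cm", TRUE, 27.53, 4.74, 31.31, 7.21, 3.77, 5.69,
    "overstepping", "max_step_height_T", "cm", TRUE, 28.30, 6.27, 26.55, 8.47, -1.75, 7.07,
    "overstepping", "step_height_over_obstacle_L", "cm", FALSE, 24.77, 5.18, 25.30, 8.29, 0.53, 5.64,
    "overstepping", "step_height_over_obstacle_T", "cm", FALSE, 25.32, 5.61, 18.80, 9.06, -6.52, 8.28,
    "overstepping", "preobstacle_distance_T", "cm", FALSE, 16.45, 7.66, 10.17, 9.01, -6.28, 5.60,
    "overstepping", "postobstacle_distance_L", "cm", FALSE, 19.60, 5.67, 24.45, 6.97, 4.85, 5.58,
    "overstepping", "single_stance_pre_T", "s", FALSE, 0.70, 0.17, 0.75, 0.16, 0.05, 0.10,
    "overstepping", "single_stance_post_L", "s", FALSE, 0.62, 0.14, 0.60, 0.10, -0.01, 0.12,
    "overstepping", "total_time", "s", FALSE, 3.64, 1.49, 4.03, 1.16, 0.39, 0.84,
    "crossing", "step_length", "cm", TRUE, 83.81, 7.11, 82.06, 9.32, -1.75, 7.22,
    "crossing", "preobstacle_distance_T", "cm", FALSE, 6.36, 4.55, -5.91, 8.27, -12.27, 8.87,
    "crossing", "postobstacle_distance_L", "cm", FALSE, 3.29, 5.99, 13.82, 7.50, 10.53, 6.96,
    "crossing", "single_stance_pre_T", "s", FALSE, 0.61, 0.14, 0.69, 0.17, 0.08, 0.15,
    "crossing", "single_stance_post_L", "s", FALSE, 0.54, 0.08, 0.54, 0.09, 0.00, 0.07,
    "crossing", "total_time", "s", FALSE, 4.05, 1.26, 4.69, 1.11, 0.64, 0.79,
    "balancing", "step_width", "cm", TRUE, 5.36, 2.92, 6.41, 2.69, 1.05, 1.93,
    "balancing", "step_length", "cm", FALSE, 52.73, 8.51, 47.31, 11.56, -5.41, 8.45,
    "balancing", "double_stance_pct", "%", FALSE, 28.58, 5.35, 32.55, 6.05, 3.97, 6.39,
    "balancing", "total_time", "s", FALSE, 4.44, 1.43, 5.31, 1.72, 0.87, 1.88,
    "circumventing", "min_shoulder_obstacle_distance", "cm", TRUE, 10.66, 3.36, 10.41, 3.77, 0.25, 4.44,
    "circumventing", "total_time", "s", FALSE, 5.25, 2.48, 5.76, 1.98, 0.50, 1.51
  )
  tb$n <- 20L
  tb
}

#' Published failure counts per task and condition
#'
#' Failure totals (and number of distinct children who failed at least once)
#' reported by the validation study, under its a-priori failure rules:
#' maximum step height below 16 cm (per foot), crossing step length below
#' 51 cm, balancing step width above 19 cm, and minimal shoulder-obstacle
#' distance below 2 cm.
#'
#' @return A tibble with columns `task`, `parameter`, `condition`,
#'   `failures`, `children`.
#' @export
reference_failures <- function() {
  tibble::tribble(
    ~task, ~parameter, ~condition, ~failures, ~children,
    "overstepping", "max_step_height_L", "physical", 1L, 1L,
    "overstepping", "max_step_height_L", "vr", 4L, 2L,
    "overstepping", "max_step_height_T", "physical", 1L, 1L,
    "overstepping", "max_step_height_T", "vr", 15L, 3L,
    "crossing", "step_length", "physical", 14L, 7L,
    "crossing", "step_length", "vr", 31L, 10L,
    "balancing", "step_width", "physical", 6L, 3L,
    "balancing", "step_width", "vr", 5L, 3L,
    "circumventing", "min_shoulder_obstacle_distance", "physical", 3L, 3L,
    "circumventing", "min_shoulder_obstacle_distance", "vr", 13L, 7L
  )
}

#' Published noninferiority verdicts for the five primary outcomes
#'
#' @return A tibble with columns `task`, `parameter`, `decision`.
#' @export
reference_decisions <- function() {
  tibble::tribble(
    ~task, ~parameter, ~decision,
    "overstepping", "max_step_height_L", "noninferior",
    "overstepping", "max_step_height_T", "inconclusive",
    "crossing", "step_length", "noninferior",
    "balancing", "step_width", "noninferior",
    "circumventing", "min_shoulder_obstacle_distance", "noninferior"
  )
}
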