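# Whole-study simulation: a two-condition (physical / immersive VR) cohort
# with participant heterogeneity, condition-order minimization, and injected
# VR condition effects.

# Clamping ranges keeping drawn participant levels physiologically plausible
# and generator-feasible (internal units).
PROFILE_CLAMPS <- list(
  step_length = c(0.35, 0.90), step_width = c(0.03, 0.20),
  gait_speed = c(0.55, 1.80), double_stance_fraction = c(0.10, 0.45),
  swing_apex_height = c(0.03, 0.10), shoulder_width = c(0.24, 0.45),
  shoulder_height = c(0.90, 1.55), foot_length = c(0.10, 0.20)
)

LEVEL_CLAMPS <- list(
  max_step_height_L = c(0.05, 0.55), max_step_height_T = c(0.05, 0.55),
  "overstepping.preobstacle_distance_T" = c(0.01, 0.45),
  "overstepping.postobstacle_distance_L" = c(0.02, 0.45),
  "crossing.preobstacle_distance_T" = c(-0.20, 0.30),
  "crossing.postobstacle_distance_L" = c(-0.20, 0.40),
  single_stance_pre_T = c(0.25, 1.10), single_stance_post_L = c(0.25, 1.10),
  "balancing.step_width" = c(0.005, 0.30),
  "balancing.step_length" = c(0.35, 0.85),
  "balancing.double_stance_pct" = c(8, 50),
  # upper bound: the widest clearance the slalom path can realise between
  # 0.56 m poles with child shoulder widths, minus a safety margin
  min_shoulder_obstacle_distance = c(0.005, 0.16),
  step_length = c(0.35, 0.90), step_width = c(0.03, 0.20),
  gait_speed = c(0.55, 1.80), double_stance_pct = c(8, 50)
)

#' @noRd
level_clamp <- function(task, parameter) {
  key <- paste(task, parameter, sep = ".")
  LEVEL_CLAMPS[[key]] %||% LEVEL_CLAMPS[[parameter]] %||% c(-Inf, Inf)
}

# Per-task parameters whose participant-level baselines are drawn from the
# physical-setup column of reference_summary() (everything not already a
# gait_profile field).
#' @noRd
task_drawn_params <- function(task) {
  switch(task,
    normal_walking = character(0),
    overstepping = c("max_step_height_L", "max_step_height_T",
                     "preobstacle_distance_T", "postobstacle_distance_L",
                     "single_stance_pre_T", "single_stance_post_L"),
    crossing = c("preobstacle_distance_T", "postobstacle_distance_L",
                 "single_stance_pre_T", "single_stance_post_L"),
    balancing = c("step_width", "step_length", "double_stance_pct"),
    circumventing = "min_shoulder_obstacle_distance")
}

#' @noRd
internal_scale <- function(unit) if (unit == "cm") 0.01 else 1

#' Simulate a complete two-condition study
#'
#' Generates the full dataset the analysis pipeline expects: for each
#' participant, both conditions times the requested tasks times
#' `trials_per_task` trial recordings, in recording order (condition order
#' assigned by covariate-adaptive minimization over gender, age group and
#' functional-walking-ability group).  Participant baselines are drawn from
#' truncated normals around the physical-setup reference means; in the VR
#' condition every configured [task_effect()] adds a participant-specific
#' shift.  The whole dataset is deterministic given `config$rng_seed`.
#'
#' @param config A [synthetic_config()].
#' @param tasks Subset of [gait_tasks()] to simulate (default all five).
#' @return A `study_dataset`: list with `trials` (list of
#'   `trial_recording`s), `participants` (tibble of covariates, condition
#'   order, declared leading foot and true VR shifts) and `config`.
#' @export
simulate_study <- function(config, tasks = gait_tasks()) {
  if (!inherits(config, "synthetic_config")) stopf("config must be a synthetic_config")
  tasks <- vapply(tasks, check_task, character(1))
  set.seed(config$rng_seed)
  np <- config$n_participants
  k <- config$trials_per_task
  ref <- reference_summary()

  gender <- sample(c("female", "male"), np, replace = TRUE, prob = c(0.35, 0.65))
  age <- stats::runif(np, 6.6, 17.8)
  faq <- sample(6:10, np, replace = TRUE)
  lead <- sample(c("left", "right"), np, replace = TRUE)

  # condition order by minimization (randomization factor 1)
  enrolled <- NULL
  orders <- character(np)
  for (i in seq_len(np)) {
    fac <- participant_factors(gender[i], age[i], faq[i])
    orders[i] <- minimization_assign(fac, enrolled,
                                     arms = c("physical_first", "vr_first"))
    enrolled <- rbind(enrolled, cbind(fac, arm = orders[i]))
  }

  # participant baseline profiles
  profiles <- vector("list", np)
  pm <- config$profile_mean
  for (i in seq_len(np)) {
    args <- lapply(names(PROFILE_CLAMPS), function(f) {
      cl <- PROFILE_CLAMPS[[f]]
      rnorm_clamped(1, pm[[f]], config$profile_sd[[f]], cl[1], cl[2])
    })
    names(args) <- names(PROFILE_CLAMPS)
    profiles[[i]] <- do.call(gait_profile, args)
  }

  # participant task-parameter baselines (physical condition), with their
  # standard scores kept so VR shifts can correlate with the level
  levels_i <- vector("list", np)
  z_levels <- list()
  for (task in tasks) {
    for (par in task_drawn_params(task)) {
      z_levels[[paste(task, par, sep = ".")]] <- stats::rnorm(np)
    }
  }
  for (i in seq_len(np)) {
    lv <- list()
    for (task in tasks) {
      for (par in task_drawn_params(task)) {
        key <- paste(task, par, sep = ".")
        r <- ref[ref$task == task & ref$parameter == par, ]
        cl <- level_clamp(task, par)
        sc <- internal_scale(r$unit)
        lv[[key]] <- min(max(r$physical_mean * sc +
                               r$physical_sd * sc * z_levels[[key]][i],
                             cl[1]), cl[2])
      }
    }
    levels_i[[i]] <- lv
  }
  # standard scores of the profile fields behind the normal-walking levels
  if ("normal_walking" %in% tasks) {
    prof_field <- c(step_length = "step_length", step_width = "step_width",
                    gait_speed = "gait_speed",
                    double_stance_pct = "double_stance_fraction")
    for (par in names(prof_field)) {
      f <- prof_field[[par]]
      z_levels[[paste("normal_walking", par, sep = ".")]] <-
        vapply(profiles, function(p) (p[[f]] - pm[[f]]) / config$profile_sd[[f]],
               numeric(1))
    }
  }

  shifts <- draw_participant_shifts(config$effects, np, z_levels)

  trials <- vector("list", np * 2L * length(tasks) * k)
  ti <- 0L
  for (i in seq_len(np)) {
    conds <- if (orders[i] == "physical_first") c("physical", "vr") else c("vr", "physical")
    pid <- sprintf("P%02d", i)
    for (cond in conds) {
      for (task in tasks) {
        for (tr in seq_len(k)) {
          ov <- trial_overrides(task, profiles[[i]], levels_i[[i]],
                                shifts, i, cond, config$effects)
          ti <- ti + 1L
          trials[[ti]] <- simulate_trial(
            profiles[[i]], task, config$geometry, overrides = ov,
            sampling_rate = config$sampling_rate, noise_sd = config$noise_sd,
            dropout_probability = config$dropout_probability,
            leading_foot = lead[i], participant_id = pid,
            condition = cond, trial_index = tr)
        }
      }
    }
  }

  participants <- tibble::tibble(
    participant_id = sprintf("P%02d", seq_len(np)),
    gender = gender, age = age, faq = faq,
    condition_order = orders, leading_foot = lead
  )
  structure(list(trials = trials, participants = participants,
                 shifts = shifts, config = config, tasks = tasks),
            class = "study_dataset")
}

# Participant-specific VR shifts for every configured effect.  Each shift
# correlates with the participant's baseline level through the effect's
# level_correlation (so the simulated VR-condition dispersion matches the
# printed VR column, not the wider independent-sum value).  The crossing
# pre/post shifts are additionally drawn jointly: their mutual correlation
# is back-derived from the configured step-length difference SD (the three
# quantities are linearly dependent, step_length = pre + gap + post), so the
# implied step-length shift distribution matches the configured one.
#' @noRd
draw_participant_shifts <- function(effects, np, z_levels = list()) {
  key <- vapply(effects, function(e) paste(e$task, e$parameter, sep = "."), character(1))
  names(effects) <- key
  shift_with_level <- function(e, nm, u) {
    rho <- e$level_correlation %||% 0
    zl <- z_levels[[nm]]
    if (is.null(zl) || rho == 0) {
      z <- u
    } else {
      z <- rho * zl + sqrt(1 - rho^2) * u
    }
    e$condition_shift + e$between_sd * z
  }
  out <- list()
  cross_pre <- effects[["crossing.preobstacle_distance_T"]]
  cross_post <- effects[["crossing.postobstacle_distance_L"]]
  cross_sl <- effects[["crossing.step_length"]]
  joint <- !is.null(cross_pre) && !is.null(cross_post) && !is.null(cross_sl)
  for (nm in key) {
    e <- effects[[nm]]
    if (joint && nm %in% c("crossing.preobstacle_distance_T",
                           "crossing.postobstacle_distance_L",
                           "crossing.step_length")) next
    out[[nm]] <- shift_with_level(e, nm, stats::rnorm(np))
  }
  if (joint) {
    s1 <- cross_pre$between_sd; s2 <- cross_post$between_sd
    sl <- cross_sl$between_sd
    rho_pp <- if (s1 > 0 && s2 > 0) (sl^2 - s1^2 - s2^2) / (2 * s1 * s2) else 0
    r1 <- cross_pre$level_correlation %||% 0
    r2 <- cross_post$level_correlation %||% 0
    # residual correlation after the level components
    denom <- sqrt(1 - r1^2) * sqrt(1 - r2^2)
    rho_u <- if (denom > 0) rho_pp / denom else 0
    rho_u <- max(min(rho_u, 0.98), -0.98)
    u1 <- stats::rnorm(np); u2 <- stats::rnorm(np)
    u2 <- rho_u * u1 + sqrt(1 - rho_u^2) * u2
    out[["crossing.preobstacle_distance_T"]] <-
      shift_with_level(cross_pre, "crossing.preobstacle_distance_T", u1)
    out[["crossing.postobstacle_distance_L"]] <-
      shift_with_level(cross_post, "crossing.postobstacle_distance_L", u2)
  }
  out
}

# Trial-to-trial SD for a parameter: the configured effect's within_sd, or
# zero when the parameter has no configured effect (so an effect-free
# configuration is exactly condition-symmetric).
#' @noRd
effect_within_sd <- function(effects, task, parameter) {
  for (e in effects) {
    if (e$task == task && e$parameter == parameter) return(e$within_sd)
  }
  0
}

# Assemble the per-trial override list: participant level (+ VR shift)
# + trial-to-trial noise, clamped to feasible ranges.
#' @noRd
trial_overrides <- function(task, profile, levels, shifts, i, cond, effects) {
  ov <- list()
  vr <- identical(cond, "vr")
  value_of <- function(par, base) {
    key <- paste(task, par, sep = ".")
    val <- base
    if (vr && !is.null(shifts[[key]])) val <- val + shifts[[key]][i]
    wsd <- effect_within_sd(effects, task, par)
    if (wsd > 0) val <- val + stats::rnorm(1, 0, wsd)
    cl <- level_clamp(task, par)
    min(max(val, cl[1]), cl[2])
  }
  if (task == "normal_walking") {
    ov$step_length <- value_of("step_length", profile$step_length)
    ov$step_width <- value_of("step_width", profile$step_width)
    ov$gait_speed <- value_of("gait_speed", profile$gait_speed)
    ov$double_stance_pct <- value_of("double_stance_pct",
                                     profile$double_stance_fraction * 100)
    return(ov)
  }
  for (par in task_drawn_params(task)) {
    ov[[par]] <- value_of(par, levels[[paste(task, par, sep = ".")]])
  }
  ov
}

#' Inject invalid trials into a simulated study
#'
#' Perturbs a chosen fraction of trials so they fail the validity screening:
#' obstacle trials get their foot-marker series swapped (the participant
#' crossed with the wrong leading foot), other selections lose a required
#' marker for a stretch longer than any interpolation limit, and every third
#' selection is flagged as an instruction violation (an externally recorded
#' reason).  Used to exercise the first-k-valid selection logic.
#'
#' @param dataset A `study_dataset` from [simulate_study()].
#' @param fraction Fraction of trials to invalidate, in `[0, 1)`.
#' @param gap_frames Length of the marker gap used for the
#'   `marker_failure` mode (default 45 frames, beyond any sensible
#'   interpolation limit).
#' @return A list with `dataset` (perturbed copy) and `injected`, a tibble of
#'   the affected trials and the perturbation mode.
#' @export
inject_invalid_trials <- function(dataset, fraction, gap_frames = 45L) {
  if (!inherits(dataset, "study_dataset")) stopf("dataset must be a study_dataset")
  if (!is_number(fraction) || fraction < 0 || fraction >= 1) {
    stopf("fraction must lie in [0, 1)")
  }
  n <- length(dataset$trials)
  n_inj <- floor(fraction * n)
  if (n_inj == 0) {
    return(list(dataset = dataset,
                injected = tibble::tibble(index = integer(0), mode = character(0))))
  }
  idx <- sort(sample.int(n, n_inj))
  modes <- character(n_inj)
  for (j in seq_along(idx)) {
    trial <- dataset$trials[[idx[j]]]
    mode <- if (j %% 3L == 0L) "instruction_violation"
      else if (trial$task %in% c("overstepping", "crossing") && j %% 2L == 1L)
        "wrong_leading_foot"
      else "marker_failure"
    dataset$trials[[idx[j]]] <- invalidate_trial(trial, mode, gap_frames)
    modes[j] <- mode
  }
  list(dataset = dataset, injected = tibble::tibble(index = idx, mode = modes))
}

#' @noRd
invalidate_trial <- function(trial, mode, gap_frames) {
  if (mode == "instruction_violation") {
    trial$instruction_violation <- TRUE
  } else if (mode == "wrong_leading_foot") {
    mk <- trial$markers
    swap <- c(L_TOE = "R_TOE", L_HEEL = "R_HEEL", L_ANK = "R_ANK",
              R_TOE = "L_TOE", R_HEEL = "L_HEEL", R_ANK = "L_ANK")
    for (nm in names(swap)) trial$markers[[nm]] <- mk[[swap[nm]]]
    ev <- trial$ground_truth$events
    ev$foot <- ifelse(ev$foot == "L", "R", "L")
    trial$ground_truth$events <- ev
  } else { # marker_failure: long gap on the leading toe inside the task zone
    foot <- if (identical(trial$leading_foot, "right")) "R_TOE" else "L_TOE"
    m <- trial$markers[[foot]]
    start <- max(2L, floor(nrow(m) * 0.45))
    end <- min(nrow(m) - 1L, start + gap_frames - 1L)
    trial$markers[[foot]][start:end, ] <- NA_real_
  }
  attr(trial, "injected_invalid") <- mode
  trial
}
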