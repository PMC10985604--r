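# Study-level processing: trial validity, first-k-valid selection,
# per-participant aggregation, paired condition differences, and
# covariate-adaptive condition-order randomization.

#' Assess the validity of a trial
#'
#' A trial is invalid when (a) the participant crossed the obstacle with a
#' different foot than the one declared for them (overstepping and crossing
#' tasks), (b) required markers are missing beyond the interpolation limit
#' while inside the task zone, or (c) an instruction violation was recorded
#' externally on the trial.  Verdicts, not exceptions: detection problems
#' surface as `marker_failure`.
#'
#' @param trial A `trial_recording`.
#' @param events Result of [detect_events()], or `NULL` to compute (a failed
#'   detection yields a `marker_failure` verdict).
#' @param geometry A [course_geometry()].
#' @param declared_leading_foot `"left"`/`"right"`; defaults to the trial's
#'   metadata.
#' @param max_gap Interpolation limit in frames.
#' @param stance Optional precomputed internal stance table.
#' @return List with `valid` (logical) and `reasons` (character vector among
#'   `wrong_leading_foot`, `instruction_violation`, `marker_failure`).
#' @export
assess_validity <- function(trial, events = NULL, geometry = course_geometry(),
                            declared_leading_foot = trial$leading_foot,
                            max_gap = 10L, stance = NULL) {
  reasons <- character(0)
  if (isTRUE(trial$instruction_violation)) reasons <- c(reasons, "instruction_violation")

  required <- c("L_TOE", "L_HEEL", "R_TOE", "R_HEEL")
  if (trial$task == "circumventing") required <- c(required, "L_SHO", "R_SHO")
  filled <- interpolate_gaps(trial, max_gap)
  gaps <- attr(filled, "gap_report")
  zone <- task_zone(geometry, trial$task)
  sh <- shoulder_centroid(trial)
  in_zone <- which(!is.na(sh[, 1]) & sh[, 1] >= zone[1] & sh[, 1] <= zone[2])
  if (nrow(gaps)) {
    bad <- gaps[!gaps$filled & gaps$marker %in% required, , drop = FALSE]
    if (nrow(bad)) {
      overlaps <- length(in_zone) == 0 ||
        any(bad$start <= max(in_zone) & bad$end >= min(in_zone))
      if (overlaps) reasons <- c(reasons, "marker_failure")
    }
  }

  if (trial$task %in% c("overstepping", "crossing") &&
      declared_leading_foot %in% c("left", "right") &&
      !"marker_failure" %in% reasons) {
    detected <- tryCatch({
      if (is.null(events)) events <- detect_events(filled)
      st <- stance %||% stance_table(filled, events)
      ext <- obstacle_extent(geometry, trial$task)
      sw <- crossing_swings(st, mean(ext))
      if (sw$foot[1] == "L") "left" else "right"
    }, error = function(e) NA_character_)
    if (is.na(detected)) {
      reasons <- c(reasons, "marker_failure")
    } else if (detected != declared_leading_foot) {
      reasons <- c(reasons, "wrong_leading_foot")
    }
  }
  list(valid = length(reasons) == 0, reasons = unique(reasons))
}

#' Select the first k valid trials
#'
#' Follows the analysis protocol of keeping the first six valid trials per
#' participant, condition and task, in recording order.  When fewer than `k`
#' trials are valid, all valid trials are kept and a shortfall warning is
#' emitted; zero valid trials is an error.
#'
#' @param trials List of trials in recording order.
#' @param verdicts List of [assess_validity()] results, parallel to `trials`.
#' @param k Number of trials to keep (default 6).
#' @return The selected trials (list), with attribute `shortfall` when fewer
#'   than `k` were available.
#' @export
select_valid_trials <- function(trials, verdicts, k = 6L) {
  if (k < 1) stopf("k must be >= 1")
  stopifnot(length(trials) == length(verdicts))
  valid <- which(vapply(verdicts, function(v) isTRUE(v$valid), logical(1)))
  if (!length(valid)) stopf("zero valid trials")
  sel <- utils::head(valid, k)
  out <- trials[sel]
  if (length(sel) < k) {
    warnf("only %d valid trials available (requested %d)", length(sel), k)
    attr(out, "shortfall") <- TRUE
  }
  attr(out, "selected_indices") <- sel
  out
}

#' Aggregate trial parameters to a participant summary
#'
#' Arithmetic mean of each parameter over the selected trials of one
#' participant, condition and task.
#'
#' @param param_list List of `task_parameters` (or plain named numeric
#'   vectors) from the selected trials.
#' @return List with `means` (named numeric) and `n_trials_used`.
#' @export
aggregate_trials <- function(param_list) {
  if (!length(param_list)) stopf("at least one trial is required")
  vals <- lapply(param_list, function(p) if (is.list(p)) p$values else p)
  nm <- names(vals[[1]])
  m <- vapply(nm, function(k) mean(vapply(vals, `[[`, numeric(1), k)), numeric(1))
  list(means = m, n_trials_used = length(vals))
}

#' Paired VR-minus-physical differences
#'
#' The study's difference convention: the physical-setup value is subtracted
#' from the VR value, so negative differences mean a smaller value under VR.
#'
#' @param summaries Tibble with columns `participant_id`, `condition`
#'   (`"physical"`/`"vr"`), `task`, `parameter`, `mean`.
#' @param on_missing `"error"` (default) or `"drop"`: what to do with
#'   participant/task/parameter cells observed in only one condition.
#'   Dropped cells are never silent: they are attached as attribute
#'   `missing_cells` and reported with a warning.
#' @return Tibble (participant_id, task, parameter, physical, vr,
#'   difference).
#' @export
paired_differences <- function(summaries, on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  wide <- tidyr::pivot_wider(summaries, names_from = "condition",
                             values_from = "mean")
  if (!all(c("physical", "vr") %in% names(wide))) {
    stopf("both conditions are required to form paired differences")
  }
  bad <- is.na(wide$physical) | is.na(wide$vr)
  if (any(bad)) {
    miss <- wide[bad, , drop = FALSE]
    if (on_missing == "error") {
      stopf("missing condition for %d participant/task/parameter cells (first: %s %s %s)",
            nrow(miss), miss$participant_id[1], miss$task[1], miss$parameter[1])
    }
    warnf("dropping %d participant/task/parameter cells missing in one condition",
          nrow(miss))
    wide <- wide[!bad, , drop = FALSE]
    wide$difference <- wide$vr - wide$physical
    attr(wide, "missing_cells") <- miss
    return(wide)
  }
  wide$difference <- wide$vr - wide$physical
  wide
}

#' Stratification factors for condition-order minimization
#'
#' @param gender `"female"`/`"male"`.
#' @param age Age in years; grouped by `age_breaks` (default `<10`, `10-14`,
#'   `>=14`).
#' @param faq Functional walking-ability score (1-10); dichotomized at
#'   `faq_break`.
#' @param age_breaks,faq_break Grouping cut points.
#' @return One-row data.frame with columns `gender`, `age_group`,
#'   `faq_group`.
#' @export
participant_factors <- function(gender, age, faq,
                                age_breaks = c(10, 14), faq_break = 9) {
  age_group <- if (age < age_breaks[1]) sprintf("<%g", age_breaks[1])
    else if (age < age_breaks[2]) sprintf("%g-%g", age_breaks[1], age_breaks[2])
    else sprintf(">=%g", age_breaks[2])
  faq_group <- if (faq < faq_break) sprintf("<%g", faq_break) else sprintf(">=%g", faq_break)
  data.frame(gender = gender, age_group = age_group, faq_group = faq_group,
             stringsAsFactors = FALSE)
}

#' Covariate-adaptive (minimization) assignment
#'
#' Assigns a new participant to the arm that minimizes the summed marginal
#' imbalance over the stratification factors, deterministically
#' (randomization factor 1); exact ties are broken by a fair coin from the
#' current RNG stream.
#'
#' @param new One-row data.frame of factor levels (see
#'   [participant_factors()]).
#' @param enrolled Data.frame of previously enrolled participants: the same
#'   factor columns plus `arm`; `NULL` when none.
#' @param arms Character vector of the two arms.
#' @return The assigned arm (character scalar).
#' @export
minimization_assign <- function(new, enrolled = NULL,
                                arms = c("physical_first", "vr_first")) {
  stopifnot(length(arms) == 2)
  facs <- names(new)
  imb <- vapply(arms, function(cand) {
    tot <- 0
    for (f in facs) {
      n1 <- n2 <- 0
      if (!is.null(enrolled) && nrow(enrolled)) {
        sub <- enrolled[enrolled[[f]] == new[[f]][1], , drop = FALSE]
        n1 <- sum(sub$arm == arms[1])
        n2 <- sum(sub$arm == arms[2])
      }
      if (cand == arms[1]) n1 <- n1 + 1 else n2 <- n2 + 1
      tot <- tot + abs(n1 - n2)
    }
    tot
  }, numeric(1))
  if (imb[1] == imb[2]) sample(arms, 1) else arms[which.min(imb)]
}
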