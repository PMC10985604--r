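# End-to-end orchestration: events -> validity -> first-k-valid selection ->
# parameter extraction -> aggregation -> paired differences -> CIs and
# noninferiority decisions -> failure accounting, plus report rendering.

#' Run the full analysis pipeline on a study dataset
#'
#' Executes the complete computation chain on a loaded or simulated dataset
#' and returns every intermediate and final table: per-trial parameters,
#' validity verdicts, participant summaries (mean of the selected trials),
#' paired VR-minus-physical differences, per-parameter difference statistics
#' with 95% CIs, noninferiority decisions against the supplied margins, and
#' failure totals.
#'
#' @param dataset A `study_dataset` from [simulate_study()] or
#'   [load_study()].
#' @param geometry A [course_geometry()]; defaults to the dataset's own.
#' @param margins Tibble (task, parameter, margin) of noninferiority margins
#'   (default [default_margins()]).
#' @param k Number of valid trials analysed per cell (default 6).
#' @param ci_method `"z"` (default) or `"t"`.
#' @param det_params [detection_params()] for event detection.
#' @param rules [failure_rules()] for failure accounting.
#' @return A `pipeline_result` list of tibbles: `trial_parameters`,
#'   `rule_values`, `validity`, `summaries`, `differences`, `stats`,
#'   `decisions`, `failures`, `condition_stats`, `log`.
#' @export
run_pipeline <- function(dataset, geometry = NULL, margins = default_margins(),
                         k = 6L, ci_method = "z",
                         det_params = detection_params(),
                         rules = failure_rules()) {
  if (!inherits(dataset, "study_dataset")) stopf("dataset must be a study_dataset")
  if (!length(dataset$trials)) stopf("empty dataset: nothing to analyse")
  geometry <- geometry %||% (if (!is.null(dataset$config)) dataset$config$geometry) %||%
    course_geometry()

  keyv <- vapply(dataset$trials, function(tr)
    paste(tr$participant_id, tr$condition, tr$task, sep = "\r"), character(1))
  cells <- split(seq_along(dataset$trials), keyv)

  par_rows <- list(); rule_rows <- list(); val_rows <- list()
  sum_rows <- list(); log_rows <- list()
  log_add <- function(code, msg) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(code = code, message = msg)
  }

  for (cell in cells) {
    cell <- cell[order(vapply(dataset$trials[cell], `[[`, integer(1), "trial_index"))]
    trials <- dataset$trials[cell]
    first <- trials[[1]]
    events <- vector("list", length(trials))
    verdicts <- vector("list", length(trials))
    filled <- vector("list", length(trials))
    stances <- vector("list", length(trials))
    for (j in seq_along(trials)) {
      filled[[j]] <- interpolate_gaps(trials[[j]], det_params$max_gap)
      events[[j]] <- tryCatch(
        suppressWarnings(detect_events(filled[[j]], det_params)),
        error = function(e) e)
      ev <- if (inherits(events[[j]], "error")) NULL else events[[j]]
      if (!is.null(ev) && first$task != "circumventing") {
        stances[[j]] <- tryCatch(stance_table(filled[[j]], ev),
                                 error = function(e) NULL)
      }
      verdicts[[j]] <- assess_validity(trials[[j]], ev, geometry,
                                       max_gap = det_params$max_gap,
                                       stance = stances[[j]])
      if (inherits(events[[j]], "error") && verdicts[[j]]$valid) {
        verdicts[[j]] <- list(valid = FALSE, reasons = "marker_failure")
      }
      val_rows[[length(val_rows) + 1L]] <- data.frame(
        participant_id = first$participant_id, condition = first$condition,
        task = first$task, trial_index = trials[[j]]$trial_index,
        valid = verdicts[[j]]$valid,
        reasons = paste(verdicts[[j]]$reasons, collapse = ";"))
      if (!verdicts[[j]]$valid) {
        log_add("invalid_trial", sprintf("%s %s %s trial %d invalid: %s",
                first$participant_id, first$condition, first$task,
                trials[[j]]$trial_index,
                paste(verdicts[[j]]$reasons, collapse = ", ")))
      }
    }
    sel_idx <- tryCatch({
      sel <- select_valid_trials(trials, verdicts, k)
      if (isTRUE(attr(sel, "shortfall"))) {
        log_add("shortfall", sprintf("%s %s %s: only %d valid trials",
                first$participant_id, first$condition, first$task,
                length(attr(sel, "selected_indices"))))
      }
      attr(sel, "selected_indices")
    }, warning = function(w) {
      sel <- suppressWarnings(select_valid_trials(trials, verdicts, k))
      log_add("shortfall", sprintf("%s %s %s: only %d valid trials",
              first$participant_id, first$condition, first$task,
              length(attr(sel, "selected_indices"))))
      attr(sel, "selected_indices")
    }, error = function(e) {
      log_add("no_valid_trials", conditionMessage(e))
      integer(0)
    })
    if (!length(sel_idx)) next

    plist <- vector("list", length(sel_idx))
    for (jj in seq_along(sel_idx)) {
      j <- sel_idx[jj]
      tp <- task_parameters(filled[[j]], events[[j]], geometry, rules,
                            stance = stances[[j]])
      plist[[jj]] <- tp
      par_rows[[length(par_rows) + 1L]] <- data.frame(
        participant_id = first$participant_id, condition = first$condition,
        task = first$task, trial_index = trials[[j]]$trial_index,
        parameter = names(tp$values), value = unname(tp$values))
      if (length(tp$rule_values)) {
        rule_rows[[length(rule_rows) + 1L]] <- data.frame(
          participant_id = first$participant_id, condition = first$condition,
          task = first$task, trial_index = trials[[j]]$trial_index,
          parameter = names(tp$rule_values),
          value = unlist(tp$rule_values, use.names = FALSE))
      }
    }
    agg <- aggregate_trials(plist)
    sum_rows[[length(sum_rows) + 1L]] <- data.frame(
      participant_id = first$participant_id, condition = first$condition,
      task = first$task, parameter = names(agg$means),
      mean = unname(agg$means), n_trials_used = agg$n_trials_used)
  }

  trial_parameters <- tibble::as_tibble(do.call(rbind, par_rows))
  rule_values <- tibble::as_tibble(do.call(rbind, rule_rows))
  validity <- tibble::as_tibble(do.call(rbind, val_rows))
  summaries <- tibble::as_tibble(do.call(rbind, sum_rows))

  differences <- suppressWarnings(paired_differences(
    summaries[, c("participant_id", "condition", "task", "parameter", "mean")],
    on_missing = "drop"))
  miss <- attr(differences, "missing_cells")
  if (!is.null(miss)) {
    for (i in seq_len(nrow(miss))) {
      log_add("missing_cell", sprintf("%s %s %s present in one condition only",
              miss$participant_id[i], miss$task[i], miss$parameter[i]))
    }
  }

  stat_rows <- list(); dec_rows <- list()
  for (grp in split(differences,
                    paste(differences$task, differences$parameter, sep = "\r"))) {
    if (nrow(grp) < 2) {
      log_add("insufficient_n", sprintf(
        "%s %s: only %d paired difference(s); CI and decision skipped",
        grp$task[1], grp$parameter[1], nrow(grp)))
      next
    }
    ds <- difference_stats(grp$difference, method = ci_method)
    stat_rows[[length(stat_rows) + 1L]] <- data.frame(
      task = grp$task[1], parameter = grp$parameter[1], n = ds$n,
      mean_diff = ds$mean_diff, sd_diff = ds$sd_diff,
      ci_low = ds$ci_low, ci_high = ds$ci_high, normality_p = ds$normality_p)
    mg <- margins[margins$task == grp$task[1] &
                    margins$parameter == grp$parameter[1], ]
    if (nrow(mg) == 1) {
      dec <- classify_noninferiority(ds, mg$margin)
      dec_rows[[length(dec_rows) + 1L]] <- data.frame(
        task = grp$task[1], parameter = grp$parameter[1],
        mean_diff = ds$mean_diff, ci_low = ds$ci_low, ci_high = ds$ci_high,
        margin = mg$margin, decision = dec$decision)
    }
  }
  stats_tb <- tibble::as_tibble(do.call(rbind, stat_rows))
  decisions <- tibble::as_tibble(do.call(rbind, dec_rows))

  failures <- dplyr::bind_rows(lapply(
    split(rule_values, rule_values$task), count_failures, rules = rules))

  # condition-level descriptive table (mean and SD across participant means)
  condition_stats <- dplyr::summarise(
    dplyr::group_by(summaries, .data$task, .data$parameter, .data$condition),
    sd = stats::sd(.data$mean), mean = mean(.data$mean), .groups = "drop")
  condition_stats <- condition_stats[, c("task", "parameter", "condition",
                                         "mean", "sd")]

  log_tb <- if (length(log_rows)) tibble::as_tibble(do.call(rbind, log_rows))
    else tibble::tibble(code = character(0), message = character(0))

  structure(list(trial_parameters = trial_parameters, rule_values = rule_values,
                 validity = validity, summaries = summaries,
                 differences = differences, stats = stats_tb,
                 decisions = decisions, failures = failures,
                 condition_stats = condition_stats, log = log_tb),
            class = "pipeline_result")
}

#' Noninferiority analysis from a printed summary table
#'
#' Runs the statistical layer alone on published condition means/SDs and
#' difference means/SDs (the shape of [reference_summary()]): z-based CIs
#' from the difference column and three-way decisions against the margins.
#'
#' @param ref Tibble in the shape of [reference_summary()].
#' @param margins Tibble (task, parameter, margin).
#' @param method CI method, `"z"` (default) or `"t"`.
#' @return Tibble (task, parameter, n, mean_diff, sd_diff, ci_low, ci_high,
#'   margin, decision) with decisions only where a margin is defined.
#' @export
analyze_reference <- function(ref = reference_summary(),
                              margins = default_margins(), method = "z") {
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    r <- ref[i, ]
    ci <- ci_from_summary(r$diff_mean, r$diff_sd, r$n, method = method)
    mg <- margins[margins$task == r$task & margins$parameter == r$parameter, ]
    dec <- if (nrow(mg) == 1) {
      classify_noninferiority(list(ci_low = ci[1], ci_high = ci[2]), mg$margin)$decision
    } else NA_character_
    data.frame(task = r$task, parameter = r$parameter, n = r$n,
               mean_diff = r$diff_mean, sd_diff = r$diff_sd,
               ci_low = ci[1], ci_high = ci[2],
               margin = if (nrow(mg) == 1) mg$margin else NA_real_,
               decision = dec)
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Render a summary table of conditions, differences and failures
#'
#' A fixed-width text table with one block per task: parameter rows showing
#' "physical mean (SD)", "VR mean (SD)" and "difference (SD)" across
#' participants (2-decimal, half-up rounding), followed by failure rows
#' "n (children)" per condition.
#'
#' @param results A `pipeline_result` from [run_pipeline()].
#' @param tasks Tasks to include (default: all present).
#' @return Character vector of table lines (also printed invisibly-friendly;
#'   write with [writeLines()]).
#' @export
render_summary_table <- function(results, tasks = NULL) {
  cs <- results$condition_stats
  st <- results$stats
  tasks <- tasks %||% intersect(gait_tasks(), unique(cs$task))
  fmt <- function(m, s) sprintf("%.2f (%.2f)", round_half_up(m), round_half_up(s))
  lines <- sprintf("%-34s %18s %18s %18s", "Task and parameter",
                   "Physical", "VR", "Difference")
  for (tk in tasks) {
    lines <- c(lines, sprintf("-- %s --", tk))
    sub <- st[st$task == tk, ]
    for (i in seq_len(nrow(sub))) {
      p <- sub$parameter[i]
      ph <- cs[cs$task == tk & cs$parameter == p & cs$condition == "physical", ]
      vr <- cs[cs$task == tk & cs$parameter == p & cs$condition == "vr", ]
      lines <- c(lines, sprintf("%-34s %18s %18s %18s", p,
                                fmt(ph$mean, ph$sd), fmt(vr$mean, vr$sd),
                                fmt(sub$mean_diff[i], sub$sd_diff[i])))
    }
    fl <- results$failures[results$failures$task == tk, ]
    for (i in seq_len(nrow(fl))) {
      lines <- c(lines, sprintf("%-34s %18s", sprintf("failures %s [%s]",
                                                      fl$parameter[i], fl$condition[i]),
                                sprintf("%d (%d)", fl$failures[i], fl$children[i])))
    }
  }
  lines
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d trials analysed, %d participants, %d decisions\n",
              nrow(unique(x$trial_parameters[, c("participant_id", "condition",
                                                 "task", "trial_index")])),
              length(unique(x$summaries$participant_id)), nrow(x$decisions)))
  if (nrow(x$decisions)) {
    for (i in seq_len(nrow(x$decisions))) {
      d <- x$decisions[i, ]
      cat(sprintf("  %s / %s: %.2f [%.2f, %.2f] vs %+g -> %s\n",
                  d$task, d$parameter, d$mean_diff, d$ci_low, d$ci_high,
                  d$margin, d$decision))
    }
  }
  invisible(x)
}
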