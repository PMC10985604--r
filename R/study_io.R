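# Study manifests: a delimited-text index of per-trial TRC files plus the
# metadata the TRC format cannot carry (participant, condition, task, trial
# number, declared leading foot, externally recorded instruction
# violations), with optional ground-truth sidecars for synthetic trials.

#' Write a study dataset to TRC files plus a manifest
#'
#' One TRC file per trial, a tab-separated manifest indexing them, and (for
#' synthetic trials) a ground-truth sidecar per trial holding the true
#' parameter values and event schedule.
#'
#' @param dataset A `study_dataset`.
#' @param dir Output directory (created if needed).
#' @param sidecars Write ground-truth sidecars (default TRUE when present).
#' @return Path of the manifest file, invisibly.
#' @export
write_study <- function(dataset, dir, sidecars = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(dataset$trials, function(tr) {
    stem <- sprintf("%s_%s_%s_%02d", tr$participant_id, tr$condition,
                    tr$task, tr$trial_index)
    trc <- file.path(dir, paste0(stem, ".trc"))
    write_trc(tr, trc)
    gt_file <- ""
    if (sidecars && !is.null(tr$ground_truth)) {
      gt_file <- file.path(dir, paste0(stem, ".gt.tsv"))
      write_gt_sidecar(tr$ground_truth, gt_file)
    }
    data.frame(participant_id = tr$participant_id, condition = tr$condition,
               task = tr$task, trial_index = tr$trial_index,
               leading_foot = tr$leading_foot,
               instruction_violation = tr$instruction_violation,
               file = basename(trc),
               gt_file = if (nzchar(gt_file)) basename(gt_file) else "",
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mpath)
}

#' @noRd
write_gt_sidecar <- function(gt, path) {
  p <- data.frame(type = "param", name = names(gt$params),
                  value = unname(gt$params), stringsAsFactors = FALSE)
  e <- data.frame(type = "event",
                  name = paste(gt$events$foot, gt$events$kind, sep = ":"),
                  value = gt$events$time, stringsAsFactors = FALSE)
  f <- data.frame(type = "meta", name = "failure", value = as.numeric(gt$failure))
  utils::write.table(rbind(p, e, f), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @noRd
read_gt_sidecar <- function(path, task) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  pars <- d[d$type == "param", ]
  evs <- d[d$type == "event", ]
  fk <- strsplit(evs$name, ":", fixed = TRUE)
  params <- stats::setNames(pars$value, pars$name)
  list(task = task, params = params,
       failure = as.logical(d$value[d$type == "meta" & d$name == "failure"]),
       events = tibble::tibble(foot = vapply(fk, `[[`, "", 1),
                               kind = vapply(fk, `[[`, "", 2),
                               time = evs$value))
}

#' Load a study dataset from a manifest
#'
#' Reads every trial referenced by the manifest, attaches its metadata and
#' any ground-truth sidecar, and orders trials by participant, condition,
#' task and trial index.  Missing files and duplicate
#' (participant, condition, task, trial) keys are errors naming the
#' offending row; an empty manifest yields an empty dataset with a warning.
#'
#' @param manifest_path Path to a manifest written by [write_study()].
#' @return A `study_dataset` (without simulation internals).
#' @export
load_study <- function(manifest_path) {
  if (!file.exists(manifest_path)) stopf("no such manifest: %s", manifest_path)
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("participant_id", "condition", "task", "trial_index", "file")
  miss <- setdiff(need, names(man))
  if (length(miss)) stopf("manifest lacks columns: %s", paste(miss, collapse = ", "))
  if (!nrow(man)) {
    warnf("empty manifest: returning an empty dataset")
    return(structure(list(trials = list(), participants = tibble::tibble(),
                          config = NULL, tasks = character(0)),
                     class = "study_dataset"))
  }
  key <- with(man, paste(participant_id, condition, task, trial_index))
  dup <- which(duplicated(key))
  if (length(dup)) {
    stopf("duplicate trial key in manifest row %d: %s", dup[1], key[dup[1]])
  }
  dir <- dirname(manifest_path)
  man <- man[order(man$participant_id, man$condition, man$task, man$trial_index), ]
  trials <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- file.path(dir, man$file[i])
    if (!file.exists(f)) {
      stopf("manifest row %d: trial file does not exist: %s", i, man$file[i])
    }
    tr <- read_trc(f)
    tr$participant_id <- man$participant_id[i]
    tr$condition <- man$condition[i]
    tr$task <- check_task(man$task[i])
    tr$trial_index <- as.integer(man$trial_index[i])
    tr$leading_foot <- if ("leading_foot" %in% names(man)) man$leading_foot[i] else "unknown"
    tr$instruction_violation <- if ("instruction_violation" %in% names(man))
      isTRUE(as.logical(man$instruction_violation[i])) else FALSE
    if ("gt_file" %in% names(man) && nzchar(man$gt_file[i])) {
      gt_path <- file.path(dir, man$gt_file[i])
      if (file.exists(gt_path)) tr$ground_truth <- read_gt_sidecar(gt_path, tr$task)
    }
    trials[[i]] <- tr
  }
  participants <- tibble::tibble(participant_id = unique(man$participant_id))
  structure(list(trials = trials, participants = participants,
                 config = NULL, tasks = unique(man$task)),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d trials, %d participants, tasks: %s\n",
              length(x$trials), nrow(x$participants),
              paste(x$tasks, collapse = ", ")))
  invisible(x)
}
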