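# Trial-log and subject-table schema. The study's raw logs came from lab
# scripts; this artifact defines its own auditable long format: one row per
# stimulus/response event.

.trial_cols <- c("subject_id", "task", "trial_index", "condition", "digit",
                 "direction", "distance_index", "onset_time_s", "rt_s",
                 "responded", "correct")
.subject_cols <- c("subject_id", "group", "age", "gender", "fsiq",
                   "srs_total_t", "panss_pos", "panss_neg")

#' Bundle a subject table and a trial table into a dataset
#'
#' @param subjects Tibble with columns `subject_id, group, age, gender, fsiq,
#'   srs_total_t, panss_pos, panss_neg`; empty/NA = missing.
#' @param trials Tibble in the trial-log schema (see [read_trials()]).
#' @param meta List of provenance metadata (generator seed and config, or
#'   source files; `truth` holds true per-subject generative parameters for
#'   recovery checks when simulated).
#' @return A `pps_dataset` object.
#' @export
pps_dataset <- function(subjects, trials, meta = list()) {
  subjects <- as_tibble(subjects)
  trials <- as_tibble(trials)
  missing_s <- setdiff(.subject_cols, names(subjects))
  if (length(missing_s))
    stop("schema error: subject table missing column(s): ",
         paste(missing_s, collapse = ", "))
  missing_t <- setdiff(.trial_cols, names(trials))
  if (length(missing_t))
    stop("schema error: trial table missing column(s): ",
         paste(missing_t, collapse = ", "))
  orphan <- setdiff(unique(trials$subject_id), subjects$subject_id)
  if (length(orphan))
    stop("validation error: trials reference unknown subject(s): ",
         paste(head(orphan, 5), collapse = ", "))
  validate_trials(trials)
  structure(list(subjects = subjects, trials = trials, meta = meta),
            class = "pps_dataset")
}

#' @export
print.pps_dataset <- function(x, ...) {
  cat("<pps_dataset>", nrow(x$subjects), "subjects,",
      nrow(x$trials), "trials\n")
  cat("  groups:", paste(sprintf("%s=%d", names(table(x$subjects$group)),
                                 table(x$subjects$group)), collapse = " "), "\n")
  invisible(x)
}

validate_trials <- function(trials) {
  bad_task <- which(!trials$task %in% .tasks)
  if (length(bad_task))
    stop("validation error: unknown task at row(s) ",
         paste(head(bad_task, 5), collapse = ", "))
  ok_cond <- (trials$task == "CCE" & trials$condition %in% .cce_conditions) |
    (trials$task == "PPS" & trials$condition %in% .pps_conditions)
  if (any(!ok_cond))
    stop("validation error: unknown condition label at row(s) ",
         paste(head(which(!ok_cond), 5), collapse = ", "),
         " (first offending label: '",
         trials$condition[which(!ok_cond)[1]], "')")
  di <- trials$distance_index
  is_exp <- trials$task == "PPS" & trials$condition == "experimental"
  if (any(is.na(di[is_exp])) || any(!di[is_exp] %in% 1:11))
    stop("validation error: PPS experimental trials need distance_index in 1..11, row(s) ",
         paste(head(which(is_exp & (is.na(di) | !di %in% 1:11)), 5), collapse = ", "))
  if (any(!is.na(di) & !is_exp))
    stop("validation error: distance_index set on non-experimental trial, row(s) ",
         paste(head(which(!is.na(di) & !is_exp), 5), collapse = ", "))
  bad_rt <- which(!is.na(trials$rt_s) & trials$rt_s <= 0)
  if (length(bad_rt))
    stop("validation error: non-positive rt_s at row(s) ",
         paste(head(bad_rt, 5), collapse = ", "))
  is_catch <- trials$task == "PPS" & trials$condition == "catch"
  if (any(!is.na(trials$onset_time_s[is_catch])))
    stop("validation error: catch trials must not carry a tactile onset, row(s) ",
         paste(head(which(is_catch & !is.na(trials$onset_time_s)), 5), collapse = ", "))
  invisible(trials)
}

#' Write a dataset to delimited text
#'
#' Writes `trials.csv` and `subjects.csv` (plus `truth.csv` when the dataset
#' carries simulated ground truth) under `dir`. Comma-delimited, UTF-8,
#' header row; empty cells are missing values. The round trip through
#' [read_trials()] reproduces every field.
#'
#' @param dataset A `pps_dataset`.
#' @param dir Output directory, created if absent.
#' @return Invisibly, the paths written.
#' @export
write_trials <- function(dataset, dir) {
  stopifnot(inherits(dataset, "pps_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(trials = file.path(dir, "trials.csv"),
             subjects = file.path(dir, "subjects.csv"))
  write.csv(dataset$trials, paths["trials"], row.names = FALSE, na = "")
  write.csv(dataset$subjects, paths["subjects"], row.names = FALSE, na = "")
  if (!is.null(dataset$meta$truth)) {
    paths["truth"] <- file.path(dir, "truth.csv")
    write.csv(dataset$meta$truth, paths["truth"], row.names = FALSE, na = "")
  }
  invisible(paths)
}

#' Read a dataset from delimited text
#'
#' Expects the files written by [write_trials()]: a trial log with columns
#' `subject_id, task, trial_index, condition, digit, direction,
#' distance_index, onset_time_s, rt_s, responded, correct` and a subject
#' table with `subject_id, group, age, gender, fsiq, srs_total_t, panss_pos,
#' panss_neg`. Missing required columns raise a schema error naming them;
#' malformed rows (unknown condition labels, non-positive RTs, catch trials
#' with onsets) raise a validation error with row numbers.
#'
#' @param trials_path Path to the trial log CSV.
#' @param subjects_path Path to the subject table CSV.
#' @param truth_path Optional path to a simulated-truth CSV.
#' @return A `pps_dataset`.
#' @export
read_trials <- function(trials_path, subjects_path, truth_path = NULL) {
  trials <- read.csv(trials_path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  subjects <- read.csv(subjects_path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing_t <- setdiff(.trial_cols, names(trials))
  if (length(missing_t))
    stop("schema error: trial file missing column(s): ",
         paste(missing_t, collapse = ", "))
  missing_s <- setdiff(.subject_cols, names(subjects))
  if (length(missing_s))
    stop("schema error: subject file missing column(s): ",
         paste(missing_s, collapse = ", "))
  trials$subject_id <- as.character(trials$subject_id)
  subjects$subject_id <- as.character(subjects$subject_id)
  for (col in c("responded", "correct"))
    trials[[col]] <- as.logical(trials[[col]])
  trials$distance_index <- as.integer(trials$distance_index)
  meta <- list(source = c(trials = trials_path, subjects = subjects_path))
  if (!is.null(truth_path) && file.exists(truth_path))
    meta$truth <- as_tibble(read.csv(truth_path, stringsAsFactors = FALSE))
  pps_dataset(as_tibble(subjects), as_tibble(trials), meta)
}
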