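#' Write a cohort and its trajectories to CSV
#'
#' Writes `participants.csv` (wide, one row per participant) and
#' `trajectories.csv` (long: `participant_id,timepoint,pnt`) under `dir`.
#' Missing cells are encoded as empty fields; numeric values round-trip
#' exactly through [read_cohort()].
#'
#' @param cohort participant table from [generate_cohort()].
#' @param trajectories long trajectory table from [generate_trajectories()].
#' @param dir output directory (created if absent).
#' @return invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, trajectories, dir) {
  validate_cohort_tables(cohort, trajectories)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pf <- file.path(dir, "participants.csv")
  tf <- file.path(dir, "trajectories.csv")
  readr::write_csv(cohort, pf, na = "")
  readr::write_csv(trajectories, tf, na = "")
  invisible(c(participants = pf, trajectories = tf))
}

#' Read a cohort and trajectories written by [write_cohort()]
#'
#' @param dir directory holding `participants.csv` and `trajectories.csv`.
#' @return `list(cohort = data.frame, trajectories = data.frame)`.
#' @export
read_cohort <- function(dir) {
  pf <- file.path(dir, "participants.csv")
  tf <- file.path(dir, "trajectories.csv")
  for (f in c(pf, tf)) {
    if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
  }
  cohort <- as.data.frame(
    readr::read_csv(pf, na = "", show_col_types = FALSE, progress = FALSE),
    stringsAsFactors = FALSE
  )
  trajectories <- as.data.frame(
    readr::read_csv(tf, na = "", show_col_types = FALSE, progress = FALSE),
    stringsAsFactors = FALSE
  )
  if (nrow(trajectories) == 0L) {
    stop("trajectory file has no timepoints", call. = FALSE)
  }
  trajectories$timepoint <- as.integer(trajectories$timepoint)
  validate_cohort_tables(cohort, trajectories)
  list(cohort = cohort, trajectories = trajectories)
}

validate_cohort_tables <- function(cohort, trajectories) {
  need <- c("participant_id", "age", "sex", "education", "days_poststroke",
            "diabetes", "hypertension", "bmi")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("participant table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dup <- unique(cohort$participant_id[duplicated(cohort$participant_id)])
  if (length(dup)) {
    stop("duplicate participant_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  for (b in c("diabetes", "hypertension")) {
    if (!all(cohort[[b]] %in% c(0L, 1L))) {
      stop("column `", b, "` must be 0/1", call. = FALSE)
    }
  }
  tneed <- c("participant_id", "timepoint", "pnt")
  if (!all(tneed %in% names(trajectories))) {
    stop("trajectory table must have columns ",
         paste(tneed, collapse = ", "), call. = FALSE)
  }
  orphan <- setdiff(trajectories$participant_id, cohort$participant_id)
  if (length(orphan)) {
    stop("trajectory references unknown participant(s): ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
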