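#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   distinct pull left_join bind_rows n across all_of
#' @importFrom tibble tibble as_tibble
NULL

# fixed visit vocabulary; downstream early/final labels depend on it
VISIT_DAYS <- c(0L, 4L, 7L, 14L, 28L)
PATIENT_ARMS <- c("yueju", "escitalopram")
ALL_ARMS <- c(PATIENT_ARMS, "healthy_control")
SCALE_MAX <- c(hamd24 = 76, qids_sr16 = 27, phq9 = 27)
MEASURE_VARS <- c("hamd24", "qids_sr16", "phq9", "bdnf")

#' Enrollment criteria for a depression trial
#'
#' Thresholds applied at the baseline (day-0) visit. Subjects failing any
#' criterion are excluded in full (all their rows). The defaults reflect a
#' moderate-to-severe MDD trial: clinician-rated HAMD-24 of at least 20 and
#' self-rated QIDS-SR16 of at least 5.
#'
#' @param min_hamd24 Minimum day-0 HAMD-24 score (inclusive). Default 20.
#' @param min_qids Minimum day-0 QIDS-SR16 score (inclusive). Default 5.
#' @param min_age,max_age Age window in years; only checked when an `age`
#'   column is present. Defaults 18 and 65.
#' @return A list with class `"enrollment_criteria"`.
#' @export
#' @examples
#' enrollment_criteria()
#' enrollment_criteria(min_hamd24 = 17)
enrollment_criteria <- function(min_hamd24 = 20L, min_qids = 5L,
                                min_age = 18L, max_age = 65L) {
  stopifnot(min_hamd24 > 0, min_qids >= 0, min_age <= max_age)
  structure(list(min_hamd24 = min_hamd24, min_qids = min_qids,
                 min_age = min_age, max_age = max_age),
            class = "enrollment_criteria")
}

parse_measure <- function(x) {
  # empty cells and NA/NaN tokens (any case) are missing; anything else that
  # fails to parse as a number is also missing, but counted by the caller
  x <- trimws(as.character(x))
  x[x == "" | toupper(x) %in% c("NA", "NAN")] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Read and validate a long-format trial table
#'
#' Reads a UTF-8 CSV with one row per subject x visit-day and columns
#' `subject_id, trial, arm, day, hamd24, qids_sr16, phq9, bdnf_pg_ml`
#' (optionally `age`, `sex`). Unparseable numeric cells become missing values
#' and are tallied in the attached load report; blank cells and the tokens
#' `"NA"`/`"NaN"` (case-insensitive) are the missing-value convention.
#'
#' @param path Path to the CSV file.
#' @param expected_trial Optional `"trial1"` or `"trial2"`; if given, the
#'   file's `trial` column must match.
#' @return A tibble of validated measurement records (columns `subject_id`,
#'   `trial`, `arm`, `day`, `hamd24`, `qids_sr16`, `phq9`, `bdnf`, plus any
#'   optional columns), with a `load_report` attribute; retrieve it with
#'   [load_report()]. Row order is preserved.
#' @details Validation errors (not warnings): a missing mandatory column,
#'   duplicated `(subject_id, day)` pairs, visit days outside
#'   \{0, 4, 7, 14, 28\}, scale scores above the instrument maximum or
#'   negative, non-positive BDNF, or a non-control subject without a day-0
#'   HAMD-24 record.
#' @seealso [apply_enrollment()], [complete_cases()], [write_trial_table()]
#' @export
read_trial_table <- function(path, expected_trial = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("subject_id", "trial", "arm", "day", "hamd24", "qids_sr16",
              "phq9", "bdnf_pg_ml")
  miss <- setdiff(needed, names(raw))
  if (length(miss) > 0) {
    abort(paste0("missing mandatory column(s): ", paste(miss, collapse = ", ")))
  }
  numcols <- c("day", "hamd24", "qids_sr16", "phq9", "bdnf_pg_ml")
  n_unparseable <- integer(0)
  dat <- raw
  for (cc in numcols) {
    parsed <- parse_measure(raw[[cc]])
    blank <- trimws(raw[[cc]]) %in% c("", "NA", "NaN", "na", "nan", "Na", "NAN") |
      is.na(raw[[cc]])
    n_unparseable[cc] <- sum(is.na(parsed) & !blank)
    dat[[cc]] <- parsed
  }
  dat <- dplyr::rename(dat, bdnf = "bdnf_pg_ml")
  dat$day <- as.integer(dat$day)
  validate_trial_data(dat)
  if (!is.null(expected_trial)) {
    expected_trial <- match.arg(expected_trial, c("trial1", "trial2"))
    bad <- setdiff(unique(dat$trial), expected_trial)
    if (length(bad) > 0) {
      abort(paste0("expected trial '", expected_trial, "' but file contains: ",
                   paste(bad, collapse = ", ")))
    }
  }
  report <- tibble(
    field = c("rows", paste0("unparseable_", numcols),
              paste0("missing_", c("hamd24", "qids_sr16", "phq9", "bdnf"))),
    value = c(nrow(dat), unname(n_unparseable),
              sum(is.na(dat$hamd24)), sum(is.na(dat$qids_sr16)),
              sum(is.na(dat$phq9)), sum(is.na(dat$bdnf)))
  )
  attr(dat, "load_report") <- report
  dat
}

#' Validate a long-format trial tibble in memory
#'
#' Enforces the record invariants used throughout the package; called by
#' [read_trial_table()] and by the simulator. Errors on the first violation.
#'
#' @param data A tibble with columns `subject_id`, `trial`, `arm`, `day`,
#'   `hamd24`, `qids_sr16`, `phq9`, `bdnf`.
#' @return `data`, invisibly.
#' @export
validate_trial_data <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("subject_id", "trial", "arm", "day", MEASURE_VARS)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  if (any(!data$arm %in% ALL_ARMS)) {
    abort(paste0("unknown arm value(s): ",
                 paste(setdiff(unique(data$arm), ALL_ARMS), collapse = ", ")))
  }
  bad_day <- stats::na.omit(setdiff(unique(data$day), VISIT_DAYS))
  if (length(bad_day) > 0) {
    abort(paste0("visit day(s) outside the {0,4,7,14,28} schedule: ",
                 paste(bad_day, collapse = ", ")))
  }
  dup <- duplicated(data[, c("subject_id", "day")])
  if (any(dup)) {
    abort(paste0("duplicate (subject_id, day) pair(s): ",
                 paste(unique(data$subject_id[dup]), collapse = ", ")))
  }
  for (sc in names(SCALE_MAX)) {
    v <- data[[sc]]
    if (any(v < 0 | v > SCALE_MAX[[sc]], na.rm = TRUE)) {
      abort(paste0(sc, " outside [0, ", SCALE_MAX[[sc]], "]"))
    }
  }
  if (any(data$bdnf <= 0, na.rm = TRUE)) abort("bdnf must be positive (pg/ml)")
  pat <- data[data$arm != "healthy_control", ]
  if (nrow(pat) > 0) {
    has_base <- tapply(pat$day == 0 & !is.na(pat$hamd24), pat$subject_id, any)
    if (any(!has_base)) {
      abort(paste0("subject(s) without a day-0 HAMD-24 record: ",
                   paste(names(has_base)[!has_base], collapse = ", ")))
    }
  }
  invisible(data)
}

#' Read a healthy-control BDNF table
#'
#' Controls contribute serum BDNF only (no symptom scales, no visit
#' schedule); the expected header is `subject_id, arm, bdnf_pg_ml` with
#' `arm = "healthy_control"`.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `subject_id`, `arm`, `bdnf`.
#' @export
read_control_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  miss <- setdiff(c("subject_id", "arm", "bdnf_pg_ml"), names(raw))
  if (length(miss) > 0) {
    abort(paste0("missing mandatory column(s): ", paste(miss, collapse = ", ")))
  }
  out <- tibble(subject_id = raw$subject_id,
                arm = raw$arm,
                bdnf = parse_measure(raw$bdnf_pg_ml))
  if (any(out$arm != "healthy_control")) abort("control table must have arm = healthy_control")
  if (any(out$bdnf <= 0, na.rm = TRUE)) abort("bdnf must be positive (pg/ml)")
  out
}

#' Write a trial table (round-trip safe)
#'
#' Writes the on-disk CSV schema read by [read_trial_table()]. Numeric values
#' are written at full precision so a write-then-read round trip reproduces
#' every value and every missing cell exactly.
#'
#' @param data A validated trial tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(data, path) {
  out <- data
  out <- dplyr::rename(out, bdnf_pg_ml = "bdnf")
  readr::write_csv(out, path, na = "NA")
  invisible(path)
}

#' Write a healthy-control table
#' @param data A control tibble from [read_control_table()] or the simulator.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_control_table <- function(data, path) {
  out <- dplyr::rename(data, bdnf_pg_ml = "bdnf")
  readr::write_csv(out, path, na = "NA")
  invisible(path)
}

#' Retrieve the load report attached by [read_trial_table()]
#' @param data A tibble returned by [read_trial_table()].
#' @return A tibble of per-field counts, or `NULL` if absent.
#' @export
load_report <- function(data) attr(data, "load_report")

#' Retrieve the exclusion report attached by [apply_enrollment()]
#' @param data A tibble returned by [apply_enrollment()].
#' @return A tibble with columns `subject_id`, `reason`, or `NULL` if absent.
#' @export
exclusion_report <- function(data) attr(data, "exclusions")

#' Apply enrollment criteria at baseline
#'
#' Removes, in full, every subject whose day-0 record fails a criterion
#' (HAMD-24 below `min_hamd24`, QIDS-SR16 below `min_qids`, or age outside
#' the window when an `age` column exists). Thresholds are inclusive: a day-0
#' HAMD-24 equal to the minimum is retained. Healthy-control rows are never
#' touched. Idempotent.
#'
#' @param data A validated trial tibble.
#' @param criteria An [enrollment_criteria()] object.
#' @return The filtered tibble, with an `exclusions` attribute listing
#'   `subject_id` and the violated criterion; retrieve it with
#'   [exclusion_report()].
#' @export
apply_enrollment <- function(data, criteria = enrollment_criteria()) {
  stopifnot(inherits(criteria, "enrollment_criteria"))
  base <- data[data$day %in% 0L & data$arm != "healthy_control", ]
  reasons <- character(0)
  ids <- character(0)
  for (i in seq_len(nrow(base))) {
    r <- base[i, ]
    why <- NULL
    if (is.na(r$hamd24) || r$hamd24 < criteria$min_hamd24) {
      why <- paste0("hamd24 < ", criteria$min_hamd24)
    } else if (!is.na(r$qids_sr16) && r$qids_sr16 < criteria$min_qids) {
      why <- paste0("qids_sr16 < ", criteria$min_qids)
    } else if ("age" %in% names(r) && !is.na(r$age) &&
               (r$age < criteria$min_age || r$age > criteria$max_age)) {
      why <- paste0("age outside [", criteria$min_age, ", ", criteria$max_age, "]")
    }
    if (!is.null(why)) {
      ids <- c(ids, r$subject_id)
      reasons <- c(reasons, why)
    }
  }
  keep <- data$arm == "healthy_control" | !(data$subject_id %in% ids)
  out <- data[keep, , drop = FALSE]
  attr(out, "exclusions") <- tibble(subject_id = ids, reason = reasons)
  out
}

#' Complete-case subjects for a given set of variables and days
#'
#' Retains only the subjects having every requested variable present on every
#' requested day. Subsetting is per analysis: each downstream analysis calls
#' this with its own variables/days, so the effective n can differ between
#' analyses (e.g. the symptom time course may use more subjects than the
#' BDNF time course). Healthy-control rows are dropped. Idempotent and
#' deterministic.
#'
#' @param data A validated trial tibble.
#' @param variables Character vector of measurement columns
#'   (`"hamd24"`, `"qids_sr16"`, `"phq9"`, `"bdnf"`).
#' @param days Integer vector of visit days.
#' @return The filtered tibble (all rows of the retained subjects).
#' @export
complete_cases <- function(data, variables, days) {
  stopifnot(length(variables) > 0, length(days) > 0)
  bad <- setdiff(variables, MEASURE_VARS)
  if (length(bad) > 0) {
    abort(paste0("unknown variable(s): ", paste(bad, collapse = ", ")))
  }
  days <- as.integer(days)
  pat <- data[data$arm != "healthy_control", , drop = FALSE]
  ok_subject <- function(sub) {
    rows <- pat[pat$subject_id == sub, , drop = FALSE]
    for (d in days) {
      r <- rows[rows$day == d, , drop = FALSE]
      if (nrow(r) != 1) return(FALSE)
      for (v in variables) if (is.na(r[[v]])) return(FALSE)
    }
    TRUE
  }
  subs <- unique(pat$subject_id)
  keep <- subs[vapply(subs, ok_subject, logical(1))]
  pat[pat$subject_id %in% keep, , drop = FALSE]
}

# subjects x days matrix of one variable; rows named by subject, cols by day
pivot_measure_matrix <- function(data, variable, days) {
  cc <- complete_cases(data, variable, days)
  wide <- tidyr::pivot_wider(
    cc[, c("subject_id", "day", variable)],
    names_from = "day", values_from = all_of(variable)
  )
  wide <- wide[, c("subject_id", as.character(sort(unique(days)))), drop = FALSE]
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$subject_id
  m
}
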