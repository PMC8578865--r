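#' Neuroplasticity index
#'
#' The neuroplasticity index (NI) is the ratio of the serum BDNF
#' concentration to the same-visit HAMD-24 score, in pg/ml per HAMD-24
#' point. It expresses how much circulating neurotrophic signal stands
#' behind each point of rated depression severity.
#'
#' A HAMD-24 of 0 (full remission) makes the ratio undefined; the function
#' returns `NA` for those elements rather than imputing a floor, since any
#' floor would be arbitrary and remitted subjects no longer need outcome
#' prediction. Negative inputs are a domain error.
#'
#' @param bdnf Serum BDNF in pg/ml (positive).
#' @param hamd24 HAMD-24 score (non-negative integer-valued).
#' @return `bdnf / hamd24`, vectorised; `NA` where either input is missing or
#'   `hamd24` is 0.
#' @export
#' @examples
#' neuroplasticity_index(4000, 20) # 200
neuroplasticity_index <- function(bdnf, hamd24) {
  if (any(bdnf <= 0, na.rm = TRUE)) rlang::abort("bdnf must be positive")
  if (any(hamd24 < 0, na.rm = TRUE)) rlang::abort("hamd24 must be non-negative")
  out <- ifelse(!is.na(hamd24) & hamd24 == 0, NA_real_, bdnf / hamd24)
  as.numeric(out)
}

#' NI enhancement between two visits
#'
#' NI enhancement is the signed difference in NI following a period of
#' treatment: later value minus earlier value. It may be negative (the index
#' can fall early under some drugs).
#'
#' @param ni_from NI at the earlier visit.
#' @param ni_to NI at the later visit.
#' @return `ni_to - ni_from`; `NA` if either is undefined.
#' @export
ni_enhancement <- function(ni_from, ni_to) ni_to - ni_from

#' Per-subject NI values for a whole dataset
#'
#' Computes NI at every visit where both BDNF and a positive HAMD-24 are
#' present (same-day pairs only; no interpolation across visits). Visits
#' where HAMD-24 is 0 are excluded and counted in the `undefined_ni`
#' attribute.
#'
#' @param data A validated trial tibble.
#' @return A tibble `subject_id, trial, arm, day, ni`, one row per defined
#'   NI value.
#' @seealso [ni_enhancement_table()], [ni_series()]
#' @export
ni_table <- function(data) {
  pat <- data[data$arm != "healthy_control", , drop = FALSE]
  ok <- !is.na(pat$bdnf) & !is.na(pat$hamd24) & pat$hamd24 > 0
  zero <- !is.na(pat$bdnf) & !is.na(pat$hamd24) & pat$hamd24 == 0
  out <- pat[ok, c("subject_id", "trial", "arm", "day"), drop = FALSE]
  out$ni <- neuroplasticity_index(pat$bdnf[ok], pat$hamd24[ok])
  out <- as_tibble(out)
  attr(out, "undefined_ni") <- pat[zero, c("subject_id", "day")]
  out
}

#' All pairwise NI enhancements per subject
#'
#' For every subject and every ordered pair of visits (`day_from <
#' day_to`) at which NI is defined, the enhancement `ni(day_to) -
#' ni(day_from)`.
#'
#' @param data A validated trial tibble.
#' @return A tibble `subject_id, trial, arm, day_from, day_to, enhancement`.
#' @export
ni_enhancement_table <- function(data) {
  nit <- ni_table(data)
  one <- function(df) {
    days <- sort(df$day)
    if (length(days) < 2) {
      return(tibble(day_from = integer(0), day_to = integer(0),
                    enhancement = numeric(0)))
    }
    pr <- utils::combn(days, 2)
    ni_of <- stats::setNames(df$ni, df$day)
    tibble(day_from = as.integer(pr[1, ]), day_to = as.integer(pr[2, ]),
           enhancement = ni_of[as.character(pr[2, ])] - ni_of[as.character(pr[1, ])])
  }
  nit |>
    dplyr::group_by(.data$subject_id, .data$trial, .data$arm) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

#' NI series for one subject
#'
#' @param data A validated trial tibble.
#' @param subject_id Subject identifier present in `data`.
#' @return A list with `subject_id`, `ni_by_day` (tibble `day, ni`) and
#'   `enhancements` (tibble `day_from, day_to, enhancement`, all pairs of
#'   days at which NI is defined).
#' @export
ni_series <- function(data, subject_id) {
  if (!subject_id %in% data$subject_id) {
    rlang::abort(paste0("unknown subject: ", subject_id))
  }
  sid <- subject_id
  nit <- dplyr::filter(ni_table(data), .data$subject_id == sid)
  enh <- dplyr::filter(ni_enhancement_table(data), .data$subject_id == sid)
  list(subject_id = sid,
       ni_by_day = nit[, c("day", "ni")],
       enhancements = enh[, c("day_from", "day_to", "enhancement")])
}

#' HAMD-24 reduction rate
#'
#' Fractional improvement from baseline: `(baseline - final) / baseline`.
#' Negative values indicate worsening. Invariant under rescaling both scores
#' by a common positive factor.
#'
#' @param hamd_baseline Baseline HAMD-24 (positive).
#' @param hamd_final Final HAMD-24 (non-negative).
#' @return Fraction in (-Inf, 1], vectorised.
#' @export
#' @examples
#' hamd_reduction_rate(30, 12) # 0.6
hamd_reduction_rate <- function(hamd_baseline, hamd_final) {
  if (any(hamd_baseline <= 0, na.rm = TRUE)) {
    rlang::abort("hamd_baseline must be positive")
  }
  (hamd_baseline - hamd_final) / hamd_baseline
}

#' Classify treatment responders by HAMD-24 reduction rate
#'
#' A subject is a responder ("quasi-effective" outcome) when the HAMD-24
#' reduction rate from `baseline_day` to `final_day` meets the threshold.
#' The comparison is inclusive: a reduction of exactly 60% counts as
#' response at the default threshold. Subjects missing either score receive
#' no label and are listed in the `unlabelled` attribute.
#'
#' @param data A validated trial tibble.
#' @param baseline_day,final_day Visit days; defaults 0 and 28 (the
#'   four-week endpoint).
#' @param threshold Response threshold as a fraction in (0, 1]; default 0.60.
#' @return A tibble `subject_id, trial, arm, reduction_rate, responder`.
#' @export
classify_responders <- function(data, baseline_day = 0L, final_day = 28L,
                                threshold = 0.60) {
  stopifnot(threshold > 0, threshold <= 1,
            baseline_day %in% VISIT_DAYS, final_day %in% VISIT_DAYS)
  pat <- data[data$arm != "healthy_control", , drop = FALSE]
  b <- pat[pat$day == baseline_day, c("subject_id", "trial", "arm", "hamd24")]
  f <- pat[pat$day == final_day, c("subject_id", "hamd24")]
  names(b)[names(b) == "hamd24"] <- "hamd_baseline"
  names(f)[names(f) == "hamd24"] <- "hamd_final"
  m <- dplyr::inner_join(b, f, by = "subject_id")
  ok <- !is.na(m$hamd_baseline) & !is.na(m$hamd_final) & m$hamd_baseline > 0
  lab <- m[ok, , drop = FALSE]
  out <- tibble(
    subject_id = lab$subject_id, trial = lab$trial, arm = lab$arm,
    reduction_rate = hamd_reduction_rate(lab$hamd_baseline, lab$hamd_final)
  )
  out$responder <- out$reduction_rate >= threshold
  attr(out, "unlabelled") <- setdiff(unique(pat$subject_id), out$subject_id)
  attr(out, "threshold") <- threshold
  out
}
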