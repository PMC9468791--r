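#' Calculated annualized bleeding rate
#'
#' `ABR = n_bleeds / exposure_days * 365.25`, the direct per-participant
#' rate. Vectorized.
#'
#' @param n_bleeds Nonnegative bleed counts.
#' @param exposure_days Positive follow-up lengths in days.
#' @return Bleeds per participant-year.
#' @examples
#' calculated_abr(13, 182.625)  # 26
#' @export
calculated_abr <- function(n_bleeds, exposure_days) {
  if (any(exposure_days <= 0)) {
    stop("exposure_days must be positive", call. = FALSE)
  }
  if (any(n_bleeds < 0)) stop("n_bleeds must be nonnegative", call. = FALSE)
  n_bleeds / exposure_days * 365.25
}

#' Median and interquartile range of individual ABRs
#'
#' Summarizes per-participant calculated ABRs the way descriptive cohort
#' tables report them. Quartiles use the linear-interpolation convention
#' (`stats::quantile` type 7).
#'
#' @param rates Numeric vector of individual ABRs (length >= 1).
#' @return Named vector `median`, `q1`, `q3`.
#' @export
median_iqr_abr <- function(rates) {
  if (!length(rates)) stop("no rates supplied", call. = FALSE)
  q <- stats::quantile(rates, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Per-participant exposure counts
#'
#' Tallies adjudicated bleeds per participant and pairs them with the
#' participant's efficacy-period length in days (the half-open period
#' `[efficacy_start, efficacy_end)`, so length = end - start). Participants
#' with no bleeds contribute zero counts — dropping them would bias every
#' rate upward.
#'
#' @param adjudicated Output of [adjudicate()].
#' @param roster Participant roster (the diary's `participants` table),
#'   optionally pre-filtered to the analysis population.
#' @param bleeds Which bleeds to count: `"all"`, `"treated"`, `"untreated"`.
#' @param use_collapse Count distinct collapse groups instead of raw bleeds.
#' @return Tibble: `participant_id`, `cohort`, `regimen`, `n_bleeds`,
#'   `exposure_days`, `period_label`.
#' @export
exposure_counts <- function(adjudicated, roster,
                            bleeds = c("all", "treated", "untreated"),
                            use_collapse = FALSE) {
  bleeds <- match.arg(bleeds)
  sel <- switch(bleeds, all = rep(TRUE, nrow(adjudicated)),
                treated = adjudicated$treated,
                untreated = !adjudicated$treated)
  adj <- adjudicated[sel, , drop = FALSE]
  counts <- if (use_collapse && "collapse_group_id" %in% names(adj)) {
    dplyr::summarise(dplyr::group_by(adj, .data$participant_id),
                     n_bleeds = dplyr::n_distinct(.data$collapse_group_id),
                     .groups = "drop")
  } else {
    dplyr::count(adj, .data$participant_id, name = "n_bleeds")
  }
  out <- dplyr::left_join(
    roster[c("participant_id", "cohort", "regimen", "study_phase",
             "efficacy_start", "efficacy_end")],
    counts, by = "participant_id")
  out$n_bleeds[is.na(out$n_bleeds)] <- 0L
  out$exposure_days <- as.numeric(out$efficacy_end - out$efficacy_start)
  out$period_label <- out$study_phase
  tibble::as_tibble(out[c("participant_id", "cohort", "regimen", "n_bleeds",
                          "exposure_days", "period_label")])
}
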