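#' Assemble and validate a diary
#'
#' A diary bundles a participant roster with the two independent event
#' streams the BMQ captures: perceived bleeds and medication administrations.
#' Recording the streams separately is what makes untreated bleeds visible at
#' all — a bleed is only "treated" once a later dose with a treat-bleed
#' purpose is linked to it by [adjudicate()].
#'
#' Validation is total: every row is either accepted or contributes a
#' diagnostic naming its table and row number, and the whole set of problems
#' is reported in one error. Events timestamped outside the owner's efficacy
#' period are retained but flagged (`in_efficacy_period = FALSE`) and are
#' excluded from analyses by default.
#'
#' @param participants Roster tibble: `participant_id`, `cohort` (A/B/C),
#'   `age_group`, `inhibitor_status` (logical), `regimen`, `study_phase`,
#'   `efficacy_start`, `efficacy_end` (Dates; the period is half-open
#'   `[start, end)` so its length in days is `end - start`), optional
#'   `prior_iti` (logical).
#' @param bleeds Bleed tibble: `participant_id`, `onset` (POSIXct UTC, day
#'   resolution or finer), `location` (cohort vocabulary), `cause`,
#'   `symptoms` (semicolon-joined subset of the symptom vocabulary, may be
#'   empty), `reported_joint_location` (logical).
#' @param medications Medication tibble: `participant_id`, `time` (POSIXct
#'   UTC), `agent`, `dose` (>= 0), `dose_unit`, `purpose`.
#' @return A validated `bmq_diary` object (list of the three tibbles, with
#'   `in_efficacy_period` computed on both event tables).
#' @seealso [read_diary()], [write_diary()], [adjudicate()]
#' @export
diary <- function(participants, bleeds = NULL, medications = NULL) {
  participants <- tibble::as_tibble(participants)
  bleeds <- if (is.null(bleeds)) empty_bleeds() else tibble::as_tibble(bleeds)
  medications <- if (is.null(medications)) empty_medications() else
    tibble::as_tibble(medications)

  problems <- character(0)
  note <- function(tab, rows, msg) {
    if (length(rows)) {
      problems <<- c(problems, sprintf("%s row %d: %s", tab, rows, msg))
    }
  }

  ## roster ----
  req <- c("participant_id", "cohort", "age_group", "inhibitor_status",
           "regimen", "study_phase", "efficacy_start", "efficacy_end")
  miss <- setdiff(req, names(participants))
  if (length(miss)) {
    stop("roster is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"prior_iti" %in% names(participants)) {
    participants$prior_iti <- NA
  }
  participants$prior_iti <- as.logical(participants$prior_iti)
  participants$inhibitor_status <- as.logical(participants$inhibitor_status)
  participants$efficacy_start <- as.Date(participants$efficacy_start)
  participants$efficacy_end <- as.Date(participants$efficacy_end)

  note("roster", which(duplicated(participants$participant_id)),
       "duplicated participant_id")
  note("roster", which(!participants$cohort %in% COHORTS), "unknown cohort")
  note("roster", which(!participants$age_group %in% AGE_GROUPS),
       "unknown age_group")
  note("roster", which(!participants$regimen %in% REGIMENS), "unknown regimen")
  note("roster", which(!participants$study_phase %in% STUDY_PHASES),
       "unknown study_phase")
  note("roster",
       which(!(participants$efficacy_start < participants$efficacy_end)),
       "efficacy_start must precede efficacy_end")
  bad_age <- (participants$cohort %in% c("A", "C") &
                participants$age_group != "adult_adolescent") |
    (participants$cohort == "B" & participants$age_group != "pediatric")
  note("roster", which(participants$cohort %in% COHORTS &
                         participants$age_group %in% AGE_GROUPS & bad_age),
       "cohorts A/C are adult_adolescent and cohort B pediatric")
  bad_inh <- (participants$cohort %in% c("A", "B") &
                !participants$inhibitor_status) |
    (participants$cohort == "C" & participants$inhibitor_status)
  note("roster", which(participants$cohort %in% COHORTS &
                         !is.na(participants$inhibitor_status) & bad_inh),
       "cohorts A/B require inhibitor_status TRUE, cohort C FALSE")

  roster_idx <- stats::setNames(seq_len(nrow(participants)),
                                participants$participant_id)

  ## bleeds ----
  reqb <- c("participant_id", "onset", "location", "cause")
  miss <- setdiff(reqb, names(bleeds))
  if (length(miss)) {
    stop("bleeds table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"symptoms" %in% names(bleeds)) bleeds$symptoms <- ""
  if (!"reported_joint_location" %in% names(bleeds)) {
    bleeds$reported_joint_location <- FALSE
  }
  bleeds$onset <- as_utc_time(bleeds$onset)
  bleeds$symptoms <- canonical_symptoms(bleeds$symptoms)
  bleeds$reported_joint_location <-
    as.logical(bleeds$reported_joint_location)
  bleeds$reported_joint_location[is.na(bleeds$reported_joint_location)] <- FALSE

  known <- bleeds$participant_id %in% participants$participant_id
  note("bleeds", which(!known), "participant_id not in roster")
  note("bleeds", which(is.na(bleeds$onset)), "unparseable onset")
  note("bleeds", which(!bleeds$cause %in% CAUSES), "unknown cause")
  if (nrow(bleeds)) {
    coh <- participants$cohort[roster_idx[bleeds$participant_id]]
    for (cc in COHORTS) {
      sel <- which(known & coh == cc &
                     !bleeds$location %in% cohort_locations(cc))
      note("bleeds", sel, sprintf(
        "location not in cohort %s vocabulary (valid: %s)", cc,
        paste(cohort_locations(cc), collapse = ", ")))
    }
    bad_sym <- vapply(symptom_list(bleeds$symptoms),
                      function(s) any(!s %in% SYMPTOMS), logical(1))
    note("bleeds", which(bad_sym), "unknown symptom token")
  }

  ## medications ----
  reqm <- c("participant_id", "time", "agent", "dose", "purpose")
  miss <- setdiff(reqm, names(medications))
  if (length(miss)) {
    stop("medications table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"dose_unit" %in% names(medications)) medications$dose_unit <- ""
  medications$time <- as_utc_time(medications$time)
  medications$dose <- as.numeric(medications$dose)

  note("medications",
       which(!medications$participant_id %in% participants$participant_id),
       "participant_id not in roster")
  note("medications", which(is.na(medications$time)), "unparseable time")
  note("medications", which(!medications$agent %in% AGENTS), "unknown agent")
  note("medications", which(!medications$purpose %in% PURPOSES),
       "unknown purpose")
  note("medications", which(is.na(medications$dose) | medications$dose < 0),
       "dose must be a nonnegative number")

  if (length(problems)) {
    stop("invalid diary:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }

  bleeds$in_efficacy_period <- in_period(bleeds$participant_id, bleeds$onset,
                                         participants, roster_idx)
  medications$in_efficacy_period <- in_period(medications$participant_id,
                                              medications$time,
                                              participants, roster_idx)

  structure(list(participants = participants, bleeds = bleeds,
                 medications = medications),
            class = "bmq_diary")
}

in_period <- function(ids, times, participants, roster_idx) {
  if (!length(ids)) return(logical(0))
  i <- roster_idx[ids]
  start <- as_utc_time(participants$efficacy_start[i])
  end <- as_utc_time(participants$efficacy_end[i])
  times >= start & times < end
}

# Parse timestamps: Date, POSIXct, or ISO-8601 strings at day, minute or
# second resolution. Everything is carried as POSIXct in UTC; day-resolution
# values sit at midnight.
as_utc_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) {
    return(as.POSIXct(as.character(x), tz = "UTC"))
  }
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC",
                    origin = "1970-01-01")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(out) & !is.na(x) & nzchar(x)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(x[todo], tz = "UTC", format = fmt)
  }
  out
}

empty_bleeds <- function() {
  tibble::tibble(participant_id = character(0),
                 onset = as.POSIXct(character(0), tz = "UTC"),
                 location = character(0), cause = character(0),
                 symptoms = character(0),
                 reported_joint_location = logical(0))
}

empty_medications <- function() {
  tibble::tibble(participant_id = character(0),
                 time = as.POSIXct(character(0), tz = "UTC"),
                 agent = character(0), dose = numeric(0),
                 dose_unit = character(0), purpose = character(0))
}

#' @export
print.bmq_diary <- function(x, ...) {
  cat(sprintf(
    "<bmq_diary> %d participants (cohorts: %s), %d bleeds, %d medications\n",
    nrow(x$participants),
    paste(sort(unique(x$participants$cohort)), collapse = "/"),
    nrow(x$bleeds), nrow(x$medications)))
  invisible(x)
}

#' Drop a participant from a diary
#'
#' Removes one roster entry together with all of its bleed and medication
#' records; used by the single-participant sensitivity analysis.
#'
#' @param d A `bmq_diary`.
#' @param participant_id Id present in the roster.
#' @return A `bmq_diary` without that participant.
#' @export
exclude_participant <- function(d, participant_id) {
  stopifnot(inherits(d, "bmq_diary"))
  if (!participant_id %in% d$participants$participant_id) {
    stop("unknown participant_id: ", participant_id, call. = FALSE)
  }
  diary(d$participants[d$participants$participant_id != participant_id, ],
        d$bleeds[d$bleeds$participant_id != participant_id, ],
        d$medications[d$medications$participant_id != participant_id, ])
}
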