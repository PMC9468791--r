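#' Cohort profile for the diary simulator
#'
#' Describes one simulated cohort: its size, regimen mix, gamma-Poisson
#' bleeding process, location/cause mixes over the cohort's vocabulary,
#' treatment-decision behavior and prophylaxis schedule. The gamma-Poisson
#' construction (participant rate drawn from a Gamma with mean
#' `bleed_rate_per_year` and squared coefficient of variation `dispersion`,
#' counts Poisson given the rate and follow-up) is exactly the NB2 model the
#' estimators assume, so parameter recovery is well-posed.
#'
#' @param cohort `"A"`, `"B"` or `"C"` (fixes vocabulary, age group and
#'   inhibitor status).
#' @param n_participants Cohort size.
#' @param prop_prophylactic Probability a participant is on a prophylactic
#'   rather than episodic regimen.
#' @param bleed_rate_per_year Mean bleeds per participant-year (all bleeds).
#' @param dispersion NB2 overdispersion `alpha` (0 = Poisson).
#' @param location_mix Named probability vector over the cohort's location
#'   vocabulary; default mixes approximate adult joint-dominated bleeding
#'   (or the pediatric "other"-dominated pattern for cohort B).
#' @param cause_mix Named probabilities over spontaneous / traumatic /
#'   surgery_procedure.
#' @param treat_probability Probability a bleed is treated; scalar or named
#'   by regimen (`c(episodic = , prophylactic = )`).
#' @param prophylaxis_interval_days Days between scheduled prophylaxis doses
#'   (1-3).
#' @param followup_weeks Length-2 range; follow-up is drawn uniformly.
#' @param study_phase `"NIS"` or `"HAVEN"`.
#' @param start First efficacy day (Date).
#' @return A `cohort_profile` list.
#' @export
cohort_profile <- function(cohort,
                           n_participants = 50,
                           prop_prophylactic = 0.5,
                           bleed_rate_per_year = 30,
                           dispersion = 1,
                           location_mix = NULL,
                           cause_mix = c(spontaneous = 0.55, traumatic = 0.42,
                                         surgery_procedure = 0.03),
                           treat_probability = 0.6,
                           prophylaxis_interval_days = 2,
                           followup_weeks = c(12, 48),
                           study_phase = "NIS",
                           start = as.Date("2015-06-01")) {
  cohort <- match.arg(cohort, COHORTS)
  if (is.null(location_mix)) {
    location_mix <- if (cohort == "A") {
      c(knee = 0.20, elbow = 0.15, ankle = 0.13, wrist = 0.02,
        fingers_thumb = 0.02, shoulder = 0.02, hip = 0.02, toes = 0.01,
        muscle = 0.14, soft_tissue = 0.09, bruise_hematoma = 0.14,
        miscellaneous = 0.06)
    } else if (cohort == "B") {
      c(knee = 0.07, elbow = 0.06, ankle = 0.05, wrist = 0.01,
        fingers_thumb = 0.01, shoulder = 0.01, hip = 0.01, toes = 0.01,
        muscle = 0.11, other = 0.66)
    } else {
      c(knee = 0.15, elbow = 0.20, ankle = 0.18, wrist = 0.02,
        fingers_thumb = 0.02, shoulder = 0.02, hip = 0.02, toes = 0.01,
        muscle = 0.25, other = 0.13)
    }
  }
  stopifnot(abs(sum(location_mix) - 1) < 1e-6,
            all(names(location_mix) %in% cohort_locations(cohort)),
            abs(sum(cause_mix) - 1) < 1e-6,
            setequal(names(cause_mix), CAUSES),
            bleed_rate_per_year > 0, dispersion >= 0,
            prop_prophylactic >= 0, prop_prophylactic <= 1,
            prophylaxis_interval_days >= 1, prophylaxis_interval_days <= 3,
            length(followup_weeks) == 2, followup_weeks[1] > 0,
            followup_weeks[1] <= followup_weeks[2])
  if (length(treat_probability) == 1 && is.null(names(treat_probability))) {
    treat_probability <- c(episodic = unname(treat_probability),
                           prophylactic = unname(treat_probability))
  }
  stopifnot(all(REGIMENS %in% names(treat_probability)),
            all(treat_probability >= 0 & treat_probability <= 1))
  structure(list(cohort = cohort, n_participants = n_participants,
                 prop_prophylactic = prop_prophylactic,
                 bleed_rate_per_year = bleed_rate_per_year,
                 dispersion = dispersion, location_mix = location_mix,
                 cause_mix = cause_mix, treat_probability = treat_probability,
                 prophylaxis_interval_days = prophylaxis_interval_days,
                 followup_weeks = followup_weeks, study_phase = study_phase,
                 start = as.Date(start)),
            class = "cohort_profile")
}

#' Default profiles at the study's operating points
#'
#' Three cohorts sized and followed like the observational study they
#' emulate: 103 adults/adolescents with inhibitors followed 4.1-69.6 weeks,
#' 24 children with inhibitors (8.7-44.1 weeks), 94 adults/adolescents
#' without inhibitors (12.4-47.7 weeks). All-bleed rates and
#' treat-probabilities are set so pooled cohorts bleed ~25-33 times/year
#' with roughly 40%/40%/26% of bleeds left untreated.
#'
#' @return Named list of three [cohort_profile()]s.
#' @export
default_cohort_profiles <- function() {
  list(
    A = cohort_profile("A", n_participants = 103, bleed_rate_per_year = 32,
                       treat_probability = 0.60,
                       followup_weeks = c(4.1, 69.6)),
    B = cohort_profile("B", n_participants = 24, bleed_rate_per_year = 33,
                       treat_probability = 0.60,
                       followup_weeks = c(8.7, 44.1)),
    C = cohort_profile("C", n_participants = 94, bleed_rate_per_year = 29,
                       treat_probability = 0.74,
                       followup_weeks = c(12.4, 47.7)))
}

# Deterministic per-participant stream: adding participants or cohorts never
# perturbs the draws of existing ones.
participant_seed <- function(seed, pid) {
  h <- 0
  for (ch in utf8ToInt(pid)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (seed %% 2147483647) * 48271) %% 2147483647)
}

#' Simulate a BMQ-style diary
#'
#' Per participant: follow-up uniform in the profile's range; a latent rate
#' from the gamma-Poisson (NB2) process; bleed onsets uniform over the
#' efficacy period at day resolution; locations, causes and symptoms from
#' the profile mixes; a treat-purpose dose 0-2 days after each bleed with
#' the regimen's treat probability; scheduled prophylaxis doses for
#' prophylactic participants. Each participant draws from an RNG stream
#' derived from `(seed, participant_id)`, so output is fully reproducible
#' and stable under cohort growth.
#'
#' @param profiles A [cohort_profile()] or list of them.
#' @param seed Integer seed.
#' @return A validated `bmq_diary`.
#' @export
simulate_diary <- function(profiles, seed) {
  if (inherits(profiles, "cohort_profile")) profiles <- list(profiles)
  stopifnot(length(seed) == 1, is.finite(seed))
  roster <- list(); bleeds <- list(); meds <- list()

  for (pr in profiles) {
    stopifnot(inherits(pr, "cohort_profile"))
    for (i in seq_len(pr$n_participants)) {
      pid <- sprintf("%s%04d", pr$cohort, i)
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      set.seed(participant_seed(seed, pid))

      regimen <- if (stats::runif(1) < pr$prop_prophylactic) {
        "prophylactic"
      } else "episodic"
      days <- max(7L, round(stats::runif(1, pr$followup_weeks[1],
                                         pr$followup_weeks[2]) * 7))
      rate <- if (pr$dispersion > 0) {
        stats::rgamma(1, shape = 1 / pr$dispersion,
                      scale = pr$bleed_rate_per_year * pr$dispersion)
      } else pr$bleed_rate_per_year
      n_b <- stats::rpois(1, rate * days / 365.25)

      inhib <- pr$cohort %in% c("A", "B")
      roster[[pid]] <- tibble::tibble(
        participant_id = pid, cohort = pr$cohort,
        age_group = if (pr$cohort == "B") "pediatric" else "adult_adolescent",
        inhibitor_status = inhib, regimen = regimen,
        study_phase = pr$study_phase,
        efficacy_start = pr$start, efficacy_end = pr$start + days,
        prior_iti = NA)

      agent <- if (pr$study_phase == "HAVEN") {
        "emicizumab"
      } else if (inhib) "bypassing_agent" else "FVIII"
      dose_amt <- if (agent == "emicizumab") 1.5 else 50
      dose_unit <- if (agent == "emicizumab") "mg_per_kg" else "IU_per_kg"

      if (n_b > 0) {
        onset_day <- sort(floor(stats::runif(n_b, 0, days)))
        loc <- sample(names(pr$location_mix), n_b, replace = TRUE,
                      prob = pr$location_mix)
        cause <- sample(names(pr$cause_mix), n_b, replace = TRUE,
                        prob = pr$cause_mix)
        symp <- vapply(loc, function(l) {
          if (!l %in% JOINT_SITES) return("")
          keep <- stats::runif(5) < c(0.5, 0.65, 0.5, 0.3, 0.2)
          paste(SYMPTOMS[keep], collapse = ";")
        }, character(1), USE.NAMES = FALSE)
        bleeds[[pid]] <- tibble::tibble(
          participant_id = pid,
          onset = pr$start + onset_day,
          location = loc, cause = cause, symptoms = symp,
          reported_joint_location = loc %in% JOINT_SITES)
        p_treat <- pr$treat_probability[[regimen]]
        treat_sel <- stats::runif(n_b) < p_treat
        if (any(treat_sel)) {
          delay <- sample(0:2, sum(treat_sel), replace = TRUE)
          dose_day <- pmin(onset_day[treat_sel] + delay, days - 1L)
          meds[[paste0(pid, ".t")]] <- tibble::tibble(
            participant_id = pid, time = pr$start + dose_day,
            agent = agent, dose = dose_amt, dose_unit = dose_unit,
            purpose = "treat_bleed")
        }
      }
      if (regimen == "prophylactic") {
        sched <- seq(0L, days - 1L, by = pr$prophylaxis_interval_days)
        meds[[paste0(pid, ".p")]] <- tibble::tibble(
          participant_id = pid, time = pr$start + sched,
          agent = agent, dose = dose_amt, dose_unit = dose_unit,
          purpose = "prophylaxis")
      }
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    }
  }
  diary(dplyr::bind_rows(roster),
        if (length(bleeds)) dplyr::bind_rows(bleeds) else NULL,
        if (length(meds)) dplyr::bind_rows(meds) else NULL)
}

#' Specification of an exact-count fixture
#'
#' Describes a deterministic diary whose adjudication reproduces stated
#' per-stratum counts exactly — the mechanism for validating the pipeline
#' against printed tables when patient-level data are inaccessible.
#'
#' @param cohort `"A"`, `"B"` or `"C"`.
#' @param n_participants Roster size (zero-bleed participants included, so
#'   reporter denominators are honest).
#' @param treated,untreated Data frames with a count column `n` and optional
#'   `location`, `cause`, `reported_joint_location`, `symptoms`,
#'   `participant` (explicit 1-based participant index); each row expands to
#'   `n` identical bleeds. Defaults: location `"muscle"`, cause
#'   `"spontaneous"`.
#' @param n_untreated_reporters Exact number of distinct participants that
#'   carry untreated bleeds (default: `min(total untreated, n_participants)`).
#' @param regimen Regimen recorded for every participant.
#' @param n_untreated_prophylaxis_followed How many untreated bleeds get a
#'   same-day prophylaxis dose (sets the 24-h follow flag).
#' @param study_phase `"NIS"` or `"HAVEN"`.
#' @param start First efficacy day.
#' @return A `count_fixture_spec` list for [build_count_fixture()].
#' @export
count_fixture_spec <- function(cohort, n_participants,
                               treated = NULL, untreated = NULL,
                               n_untreated_reporters = NULL,
                               regimen = "episodic",
                               n_untreated_prophylaxis_followed = 0,
                               study_phase = "NIS",
                               start = as.Date("2015-06-01")) {
  cohort <- match.arg(cohort, COHORTS)
  regimen <- match.arg(regimen, REGIMENS)
  norm <- function(df) {
    if (is.null(df)) return(NULL)
    df <- tibble::as_tibble(df)
    stopifnot("n" %in% names(df))
    if (any(df$n < 0 | df$n != round(df$n))) {
      stop("fixture counts must be nonnegative integers", call. = FALSE)
    }
    if (!"location" %in% names(df)) df$location <- "muscle"
    if (!"cause" %in% names(df)) df$cause <- "spontaneous"
    if (!"participant" %in% names(df)) df$participant <- NA_integer_
    if (!"reported_joint_location" %in% names(df)) {
      df$reported_joint_location <- df$location %in% JOINT_SITES
    }
    if (!"symptoms" %in% names(df)) {
      df$symptoms <- ifelse(df$location %in% JOINT_SITES, "aura;pain", "")
    }
    bad <- !df$location %in% cohort_locations(cohort)
    if (any(bad)) {
      stop("fixture location(s) outside cohort ", cohort, " vocabulary: ",
           paste(unique(df$location[bad]), collapse = ", "), call. = FALSE)
    }
    df
  }
  treated <- norm(treated); untreated <- norm(untreated)
  n_untr <- if (is.null(untreated)) 0L else sum(untreated$n)
  if (is.null(n_untreated_reporters)) {
    n_untreated_reporters <- min(n_untr, n_participants)
  }
  if (n_untreated_reporters > n_participants) {
    stop("more untreated reporters than participants", call. = FALSE)
  }
  if (n_untr < n_untreated_reporters) {
    stop("fewer untreated bleeds than requested reporters", call. = FALSE)
  }
  if (!is.null(untreated) &&
      any(!is.na(untreated$participant) &
            untreated$participant > max(n_untreated_reporters, 1))) {
    stop("explicit participant index exceeds n_untreated_reporters",
         call. = FALSE)
  }
  if (n_untreated_prophylaxis_followed > n_untr) {
    stop("cannot flag more untreated bleeds than exist", call. = FALSE)
  }
  structure(list(cohort = cohort, n_participants = n_participants,
                 treated = treated, untreated = untreated,
                 n_untreated_reporters = n_untreated_reporters,
                 regimen = regimen,
                 n_untreated_prophylaxis_followed =
                   n_untreated_prophylaxis_followed,
                 study_phase = study_phase, start = as.Date(start)),
            class = "count_fixture_spec")
}

#' Build a deterministic diary realizing exact counts
#'
#' Expands one or more [count_fixture_spec()]s into a minimal diary whose
#' adjudication reproduces the spec exactly: every treated bleed gets a
#' same-calendar-day treat-purpose dose on a day of its own, and untreated
#' bleeds are placed strictly after the participant's last dose so no
#' later treatment can capture them. Untreated bleeds are dealt round-robin
#' over exactly `n_untreated_reporters` participants.
#'
#' @param specs A `count_fixture_spec` or list of them (an empty list gives
#'   an empty diary).
#' @return A validated `bmq_diary`.
#' @examples
#' fx <- build_count_fixture(count_fixture_spec(
#'   "A", n_participants = 10,
#'   treated = data.frame(n = 20), untreated = data.frame(n = 13)))
#' classify_treated_untreated(adjudicate(fx))
#' @export
build_count_fixture <- function(specs) {
  if (inherits(specs, "count_fixture_spec")) specs <- list(specs)
  roster <- list(); bleeds <- list(); meds <- list()

  for (sp in specs) {
    stopifnot(inherits(sp, "count_fixture_spec"))
    proto <- tibble::tibble(n = integer(0), location = character(0),
                            cause = character(0),
                            participant = integer(0),
                            reported_joint_location = logical(0),
                            symptoms = character(0))
    expand <- function(df) {
      if (is.null(df) || !nrow(df)) return(proto)
      tibble::as_tibble(df)[rep(seq_len(nrow(df)), df$n), ]
    }
    tr <- expand(sp$treated); un <- expand(sp$untreated)

    # deal bleeds to participants
    tr_p <- if (nrow(tr)) {
      rep_len(seq_len(sp$n_participants), nrow(tr))
    } else integer(0)
    un_p <- if (nrow(un)) un$participant else integer(0)
    if (nrow(un)) {
      open <- which(is.na(un_p))
      pool <- setdiff(seq_len(sp$n_untreated_reporters), unique(un_p))
      # cover every reporter first, then cycle
      fill <- c(pool, rep_len(seq_len(max(sp$n_untreated_reporters, 1)),
                              max(0, length(open) - length(pool))))
      if (length(open) < length(pool)) {
        stop("not enough unassigned untreated bleeds to cover all reporters",
             call. = FALSE)
      }
      un_p[open] <- fill[seq_along(open)]
    }

    next_day <- integer(sp$n_participants)       # per-participant day cursor
    tr_day <- integer(length(tr_p))
    for (j in seq_along(tr_p)) {
      tr_day[j] <- next_day[tr_p[j]]
      next_day[tr_p[j]] <- next_day[tr_p[j]] + 1L
    }
    un_cursor <- next_day + 1L                   # 1-day gap after last dose
    un_day <- integer(length(un_p))
    for (j in seq_along(un_p)) {
      un_day[j] <- un_cursor[un_p[j]]
      un_cursor[un_p[j]] <- un_cursor[un_p[j]] + 1L
    }

    period_days <- max(30L, next_day, un_cursor) + 10L
    pid <- sprintf("%s%04d", sp$cohort, seq_len(sp$n_participants))
    roster[[length(roster) + 1]] <- tibble::tibble(
      participant_id = pid, cohort = sp$cohort,
      age_group = if (sp$cohort == "B") "pediatric" else "adult_adolescent",
      inhibitor_status = sp$cohort %in% c("A", "B"), regimen = sp$regimen,
      study_phase = sp$study_phase,
      efficacy_start = sp$start, efficacy_end = sp$start + period_days,
      prior_iti = NA)

    agent <- if (sp$study_phase == "HAVEN") {
      "emicizumab"
    } else if (sp$cohort %in% c("A", "B")) "bypassing_agent" else "FVIII"

    mk_bleeds <- function(df, p_idx, day) {
      tibble::tibble(participant_id = pid[p_idx], onset = sp$start + day,
                     location = df$location, cause = df$cause,
                     symptoms = df$symptoms,
                     reported_joint_location = df$reported_joint_location)
    }
    if (nrow(tr)) {
      bleeds[[length(bleeds) + 1]] <- mk_bleeds(tr, tr_p, tr_day)
      meds[[length(meds) + 1]] <- tibble::tibble(
        participant_id = pid[tr_p], time = sp$start + tr_day, agent = agent,
        dose = 50, dose_unit = "IU_per_kg", purpose = "treat_bleed")
    }
    if (nrow(un)) {
      bleeds[[length(bleeds) + 1]] <- mk_bleeds(un, un_p, un_day)
      m <- sp$n_untreated_prophylaxis_followed
      if (m > 0) {
        meds[[length(meds) + 1]] <- tibble::tibble(
          participant_id = pid[un_p[seq_len(m)]],
          time = sp$start + un_day[seq_len(m)], agent = agent,
          dose = 50, dose_unit = "IU_per_kg", purpose = "prophylaxis")
      }
    }
  }
  empty_roster <- tibble::tibble(
    participant_id = character(0), cohort = character(0),
    age_group = character(0), inhibitor_status = logical(0),
    regimen = character(0), study_phase = character(0),
    efficacy_start = as.Date(character(0)),
    efficacy_end = as.Date(character(0)), prior_iti = logical(0))
  diary(if (length(roster)) dplyr::bind_rows(roster) else empty_roster,
        if (length(bleeds)) dplyr::bind_rows(bleeds) else NULL,
        if (length(meds)) dplyr::bind_rows(meds) else NULL)
}

#' Count-fixture specs for the motivating study's headline tables
#'
#' Returns [count_fixture_spec()]s that realize the treated/untreated,
#' location and reporter count patterns published for the three cohorts of
#' the motivating observational study of bleeds in hemophilia A (adults/
#' adolescents with FVIII inhibitors, children with inhibitors, adults/
#' adolescents without inhibitors), plus the untreated-bleed pattern of the
#' non-inhibitor prophylaxis group after switching to emicizumab, in which
#' one participant's repeated percutaneous drainage procedures dominate the
#' surgery/procedural category. These diaries are synthetic reconstructions
#' from printed counts, not patient-level data: within each stratum the
#' unreported attributes (exact dates, per-participant allocation) are
#' assigned deterministically by [build_count_fixture()].
#'
#' @return Named list of specs: `A`, `B`, `C` (observational cohorts) and
#'   `haven3` (post-switch untreated pattern; its dominant procedural
#'   bleeder is participant `C0001`).
#' @export
nis_count_fixtures <- function() {
  list(
    A = count_fixture_spec(
      "A", n_participants = 103,
      treated = data.frame(n = 997),
      untreated = data.frame(
        location = c("knee", "elbow", "ankle", "wrist", "muscle",
                     "soft_tissue", "bruise_hematoma", "miscellaneous"),
        n = c(104, 76, 57, 125, 89, 72, 104, 32)),
      n_untreated_reporters = 74),
    B = count_fixture_spec(
      "B", n_participants = 24,
      treated = data.frame(n = 233),
      untreated = data.frame(
        location = c("knee", "elbow", "ankle", "wrist", "hip",
                     "muscle", "other"),
        n = c(7, 1, 1, 1, 1, 12, 133)),
      n_untreated_reporters = 13),
    C = count_fixture_spec(
      "C", n_participants = 94,
      treated = data.frame(n = 1220),
      untreated = data.frame(location = c("knee", "elbow", "ankle", "wrist",
                                          "muscle", "other"),
                             n = c(43, 65, 72, 54, 141, 58)),
      n_untreated_reporters = 45),
    haven3 = count_fixture_spec(
      "C", n_participants = 48, regimen = "prophylactic",
      study_phase = "HAVEN",
      treated = data.frame(n = 47),
      untreated = data.frame(
        location = c("muscle", "muscle", "muscle", "other", "knee", "other"),
        cause = c("surgery_procedure", "spontaneous", "traumatic",
                  "surgery_procedure", "spontaneous", "traumatic"),
        n = c(65, 1, 1, 2, 18, 63),
        participant = c(1, 1, 1, NA, NA, NA)))
  )
}
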