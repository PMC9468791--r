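#' Round half away from zero, as descriptive tables print
#'
#' Reports percentages to one decimal using the "round half up" convention
#' of clinical tables (26.25 -> 26.3), unlike base R's banker's rounding.
#'
#' @param x Numeric.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

pct <- function(num, den, digits = 1) {
  out <- rep(NA_real_, length(num))
  ok <- !is.na(den) & den > 0
  out[ok] <- round_half_up(100 * num[ok] / den[ok], digits)
  out
}

#' Proportion of untreated bleeds by stratum
#'
#' Per stratum (cohort by default), untreated bleeds over all bleeds. A
#' stratum with no bleeds has an undefined (NA) percentage, never 0.
#'
#' @param adjudicated Output of [adjudicate()].
#' @param by Grouping columns present in `adjudicated` (e.g. `"cohort"`,
#'   `c("cohort", "regimen")`).
#' @return Tibble with grouping columns, `n_untreated`, `n_total`,
#'   `pct_untreated`, and the raw `fraction`.
#' @export
proportion_untreated <- function(adjudicated, by = "cohort") {
  out <- adjudicated |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(n_untreated = sum(!.data$treated),
                     n_total = dplyr::n(), .groups = "drop")
  out$pct_untreated <- pct(out$n_untreated, out$n_total)
  out$fraction <- out$n_untreated / out$n_total
  out
}

#' Percentage of participants reporting at least one untreated bleed
#'
#' Denominator is every analyzed participant in the cohort, including those
#' who reported no bleeds at all — which is why the roster, not the bleed
#' table, supplies it.
#'
#' @param adjudicated Output of [adjudicate()].
#' @param roster The diary's `participants` table.
#' @return Tibble: `cohort`, `n_reporting`, `n_participants`, `pct_reporting`.
#' @export
reporter_percentages <- function(adjudicated, roster) {
  reporters <- unique(adjudicated$participant_id[!adjudicated$treated])
  out <- roster |>
    dplyr::group_by(.data$cohort) |>
    dplyr::summarise(
      n_reporting = sum(.data$participant_id %in% reporters),
      n_participants = dplyr::n(), .groups = "drop")
  out$pct_reporting <- pct(out$n_reporting, out$n_participants)
  out
}

#' Bleed-location table
#'
#' Reproduces the layout of descriptive location tables: per cohort and
#' treated status, a `joint` row (a bleed counts as joint when its location
#' token is a joint site or its joint checkbox is set) with
#' knee/elbow/ankle/other sub-rows expressed as percentages *of joint
#' bleeds*, then `muscle` and the cohort-dialect extra categories as
#' percentages of the stratum's total bleeds. Joint-site names recorded
#' under the type "other" (e.g. a bruise around a joint) stay out of the
#' joint row unless the checkbox says otherwise.
#'
#' @param adjudicated Output of [adjudicate()].
#' @param by Stratifying columns, default `c("cohort", "treated")`.
#' @return Tidy tibble: strata, `row` (location group), `n`, `denominator`,
#'   `pct`, `share_of` (`"total"` or `"joint"`).
#' @export
location_table <- function(adjudicated, by = c("cohort", "treated")) {
  adj <- adjudicated
  adj$.joint <- adj$location %in% JOINT_SITES | adj$reported_joint_location
  adj$.site <- dplyr::case_when(
    !adj$.joint & adj$location == "muscle" ~ "muscle",
    !adj$.joint ~ adj$location,
    adj$location %in% c("knee", "elbow", "ankle") ~ adj$location,
    TRUE ~ "other_joint")

  strata <- dplyr::distinct(adj, dplyr::across(dplyr::all_of(by)))
  purrr::pmap_dfr(strata, function(...) {
    key <- list(...)
    sel <- rep(TRUE, nrow(adj))
    for (nm in names(key)) sel <- sel & adj[[nm]] == key[[nm]]
    s <- adj[sel, ]
    total <- nrow(s)
    n_joint <- sum(s$.joint)
    joint_rows <- tibble::tibble(
      row = c("joint", "knee", "elbow", "ankle", "other_joint"),
      n = c(n_joint, sum(s$.site == "knee" & s$.joint),
            sum(s$.site == "elbow" & s$.joint),
            sum(s$.site == "ankle" & s$.joint),
            sum(s$.site == "other_joint")),
      denominator = c(total, rep(n_joint, 4)),
      share_of = c("total", rep("joint", 4)))
    extras <- setdiff(unique(c("muscle", s$.site[!s$.joint])), JOINT_SITES)
    extra_rows <- tibble::tibble(
      row = extras,
      n = vapply(extras, function(e) sum(s$.site == e & !s$.joint),
                 integer(1), USE.NAMES = FALSE),
      denominator = total, share_of = "total")
    rows <- dplyr::bind_rows(joint_rows, extra_rows)
    rows$pct <- pct(rows$n, rows$denominator)
    dplyr::bind_cols(tibble::as_tibble(key)[rep(1, nrow(rows)), ], rows)
  })
}

#' Bleed-cause table
#'
#' Spontaneous / traumatic / surgery-procedural percentages per stratum.
#' Surgery/procedural bleeds are part of the denominator by default — the
#' aim is a comprehensive description of bleeding, not a trial endpoint.
#'
#' @param adjudicated Output of [adjudicate()].
#' @param by Stratifying columns, default `c("cohort", "treated")`; add
#'   `"regimen"` for the episodic/prophylaxis split.
#' @return Tidy tibble: strata, `cause`, `n`, `denominator`, `pct`.
#' @export
cause_table <- function(adjudicated, by = c("cohort", "treated")) {
  if (!nrow(adjudicated)) {
    empty <- adjudicated[0, by, drop = FALSE]
    empty$cause <- character(0)
    empty$n <- integer(0)
    empty$denominator <- integer(0)
    empty$pct <- numeric(0)
    return(tibble::as_tibble(empty))
  }
  out <- adjudicated |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::reframe(
      n = vapply(CAUSES, function(cc) sum(.data$cause == cc), integer(1),
                 USE.NAMES = FALSE),
      denominator = dplyr::n(),
      cause = CAUSES) |>
    dplyr::relocate("cause", .before = "n")
  out$pct <- pct(out$n, out$denominator)
  out
}

#' Untreated bleeds followed by prophylaxis within the window
#'
#' Among untreated bleeds belonging to prophylaxis-regimen participants,
#' the share followed within the configured window (default 24 h) by a dose
#' the participant recorded as prophylaxis. Cohorts with no such bleeds are
#' reported with an undefined percentage.
#'
#' @param adjudicated Output of [adjudicate()] (the flag must be present).
#' @param roster The diary's `participants` table.
#' @return Tibble: `cohort`, `n_followed`, `n_untreated_prophylaxis`, `pct_followed`.
#' @export
prophylaxis_follow_summary <- function(adjudicated, roster) {
  proph_ids <- roster$participant_id[roster$regimen == "prophylactic"]
  un <- adjudicated[!adjudicated$treated &
                      adjudicated$participant_id %in% proph_ids, ]
  out <- roster |>
    dplyr::distinct(.data$cohort) |>
    dplyr::arrange(.data$cohort)
  out$n_followed <- vapply(out$cohort, function(cc) {
    sum(un$prophylaxis_followup_within_24h[un$cohort == cc])
  }, integer(1), USE.NAMES = FALSE)
  out$n_untreated_prophylaxis <- vapply(out$cohort, function(cc) {
    sum(un$cohort == cc)
  }, integer(1), USE.NAMES = FALSE)
  out$pct_followed <- pct(out$n_followed, out$n_untreated_prophylaxis)
  out
}

#' All descriptive tables for a diary
#'
#' Runs adjudication and builds every summary surface in one call; the unit
#' other functions diff against in the sensitivity analysis.
#'
#' @param d A `bmq_diary`.
#' @param config An [adjudication_config()].
#' @return Named list: `counts`, `proportion_untreated`,
#'   `reporter_percentages`, `location_table`, `cause_table`,
#'   `cause_table_by_regimen`, `prophylaxis_follow`, and the `adjudicated`
#'   tibble itself.
#' @export
summarize_diary <- function(d, config = adjudication_config()) {
  adj <- adjudicate(d, config)
  list(
    counts = classify_treated_untreated(adj),
    proportion_untreated = proportion_untreated(adj),
    reporter_percentages = reporter_percentages(adj, d$participants),
    location_table = location_table(adj),
    cause_table = cause_table(adj),
    cause_table_by_regimen = cause_table(adj,
                                         by = c("cohort", "treated", "regimen")),
    prophylaxis_follow = prophylaxis_follow_summary(adj, d$participants),
    adjudicated = adj)
}

#' Single-participant sensitivity analysis
#'
#' Recomputes every summary table with one participant removed, to show
#' whether a headline proportion is carried by a single individual (e.g. one
#' person's repeated procedural bleeds inflating a surgery share). The
#' excluded run is the full pipeline on the filtered diary, so it composes
#' exactly with [summarize_diary()].
#'
#' @param d A `bmq_diary`.
#' @param participant_id Participant to drop.
#' @param config An [adjudication_config()].
#' @return List with `full` and `excluded` [summarize_diary()] bundles and a
#'   `diff` tibble comparing cause-table percentages.
#' @export
sensitivity_exclude <- function(d, participant_id,
                                config = adjudication_config()) {
  full <- summarize_diary(d, config)
  excluded <- summarize_diary(exclude_participant(d, participant_id), config)
  diff <- dplyr::full_join(
    full$cause_table, excluded$cause_table,
    by = c("cohort", "treated", "cause"), suffix = c("_full", "_excluded"))
  diff$pct_change <- diff$pct_excluded - diff$pct_full
  list(full = full, excluded = excluded, diff = diff)
}
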