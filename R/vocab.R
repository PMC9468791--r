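#' Controlled vocabularies for BMQ-style diaries
#'
#' The diary instrument records a closed set of bleed locations, causes,
#' symptoms, medication agents and dose purposes. Location vocabularies are
#' cohort dialects: adults/adolescents with FVIII inhibitors (Cohort A)
#' recorded soft-tissue, bruise/hematoma and miscellaneous bleeds as distinct
#' types, while the pediatric (B) and non-inhibitor (C) cohorts used a single
#' "other" category instead.
#'
#' @name vocabularies
#' @keywords internal
NULL

# Joint sites shared by every cohort dialect; knee/elbow/ankle are reported
# separately in summary tables, the rest collapse into an "other joint" row.
JOINT_SITES <- c("knee", "elbow", "ankle", "wrist", "fingers_thumb",
                 "shoulder", "hip", "toes")
JOINT_SITES_OTHER <- setdiff(JOINT_SITES, c("knee", "elbow", "ankle"))

COHORTS <- c("A", "B", "C")
CAUSES <- c("spontaneous", "traumatic", "surgery_procedure")
SYMPTOMS <- c("aura", "pain", "swelling", "reduced_motion", "warmth")
AGENTS <- c("FVIII", "bypassing_agent", "emicizumab")
PURPOSES <- c("treat_bleed", "prophylaxis", "procedure", "other")
AGE_GROUPS <- c("adult_adolescent", "pediatric")
REGIMENS <- c("episodic", "prophylactic")
STUDY_PHASES <- c("NIS", "HAVEN")

#' Location vocabulary for a cohort
#'
#' @param cohort One of `"A"`, `"B"`, `"C"`.
#' @return Character vector of valid `location` tokens for that cohort.
#' @examples
#' cohort_locations("A")
#' @export
cohort_locations <- function(cohort) {
  cohort <- match.arg(cohort, COHORTS)
  extras <- if (cohort == "A") {
    c("soft_tissue", "bruise_hematoma", "miscellaneous")
  } else {
    "other"
  }
  c(JOINT_SITES, "muscle", extras)
}

#' Map locations onto the shared coarse taxonomy
#'
#' Collapses the cohort dialects onto `{joint, muscle, other_nonjoint}` so
#' that cross-cohort summaries compare like with like. A bleed whose location
#' token is not a joint site but whose `reported_joint_location` flag is set
#' (the pediatric instrument's joint checkbox) is counted as `joint`.
#'
#' @param location Character vector of location tokens.
#' @param reported_joint_location Logical vector, recycled; defaults to FALSE.
#' @return Character vector over `{joint, muscle, other_nonjoint}`.
#' @export
normalize_location <- function(location, reported_joint_location = FALSE) {
  rj <- rep_len(as.logical(reported_joint_location), length(location))
  out <- rep("other_nonjoint", length(location))
  out[location %in% JOINT_SITES | rj] <- "joint"
  out[location == "muscle" & !rj] <- "muscle"
  out
}

# Canonical form for the symptom set: sorted, semicolon-joined, "" if empty.
canonical_symptoms <- function(x) {
  if (!length(x)) return(character(0))
  vapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE), function(s) {
    s <- sort(unique(trimws(s[nzchar(trimws(s))])))
    paste(s, collapse = ";")
  }, character(1))
}

symptom_list <- function(x) {
  if (!length(x)) return(list())
  strsplit(ifelse(is.na(x) | !nzchar(x), "", x), ";", fixed = TRUE)
}
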