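# Builders and independent oracles shared across test files.

# One-participant diary from day offsets (numeric days, fractions allowed
# for time-of-day) relative to 2015-06-01.
make_test_diary <- function(bleed_days = numeric(0), locations = "knee",
                            causes = "spontaneous", symptoms = "",
                            dose_days = numeric(0),
                            dose_purposes = "treat_bleed",
                            cohort = "A", regimen = "episodic",
                            period_days = 400, n_participants = 1) {
  start <- as.POSIXct("2015-06-01", tz = "UTC")
  pid <- sprintf("%s%04d", cohort, seq_len(n_participants))
  age <- if (cohort == "B") "pediatric" else "adult_adolescent"
  inhib <- cohort %in% c("A", "B")
  roster <- tibble::tibble(
    participant_id = pid, cohort = cohort,
    age_group = age,
    inhibitor_status = inhib, regimen = regimen,
    study_phase = "NIS", efficacy_start = as.Date("2015-06-01"),
    efficacy_end = as.Date("2015-06-01") + period_days, prior_iti = NA)
  nb <- length(bleed_days)
  bleeds <- if (nb) tibble::tibble(
    participant_id = pid[1], onset = start + bleed_days * 86400,
    location = rep_len(locations, nb), cause = rep_len(causes, nb),
    symptoms = rep_len(symptoms, nb),
    reported_joint_location = rep_len(locations, nb) %in%
      bleedabr::cohort_locations(cohort)[1:8])
  nd <- length(dose_days)
  meds <- if (nd) tibble::tibble(
    participant_id = pid[1], time = start + dose_days * 86400,
    agent = if (cohort == "C") "FVIII" else "bypassing_agent",
    dose = 50, dose_unit = "IU_per_kg",
    purpose = rep_len(dose_purposes, nd))
  diary(roster, bleeds, meds)
}

# Random one-participant diary with <= max_events events for property tests.
rand_small_diary <- function(max_events = 8) {
  n <- sample.int(max_events, 1)
  nb <- sample.int(n, 1)
  nd <- n - nb
  frac <- function(k) sample(c(0, 0.25, 0.5), k, replace = TRUE)
  make_test_diary(
    bleed_days = sample(0:9, nb, replace = TRUE) + frac(nb),
    locations = sample(c("knee", "elbow", "muscle"), nb, replace = TRUE),
    causes = sample(c("spontaneous", "traumatic"), nb, replace = TRUE),
    dose_days = if (nd) sample(0:9, nd, replace = TRUE) + frac(nd) else
      numeric(0),
    dose_purposes = if (nd) sample(c("treat_bleed", "prophylaxis"), nd,
                                   replace = TRUE, prob = c(0.8, 0.2)) else
      character(0))
}

# Exhaustive linkage oracle: enumerate every feasible bleed->dose
# assignment (dose at/after onset; a dose shared only within one calendar
# day) and return the lexicographically smallest one scanning bleeds in
# onset order with "unlinked" ranked last. Independent of the greedy code.
exhaustive_linkage <- function(d) {
  stopifnot(length(unique(d$participants$participant_id)) == 1)
  b <- d$bleeds[order(d$bleeds$onset), ]
  doses <- d$medications[d$medications$purpose == "treat_bleed", ]
  doses <- doses[order(doses$time), ]
  nb <- nrow(b); nd <- nrow(doses)
  if (nb == 0) return(logical(0))
  if (nd == 0) return(rep(FALSE, nb))
  choices <- rep(list(0:nd), nb)
  grid <- as.matrix(expand.grid(choices))
  bday <- floor(as.numeric(b$onset) / 86400)
  ok <- apply(grid, 1, function(a) {
    for (i in seq_len(nb)) {
      if (a[i] > 0 && doses$time[a[i]] < b$onset[i]) return(FALSE)
    }
    for (k in seq_len(nd)) {
      users <- which(a == k)
      if (length(users) > 1 && length(unique(bday[users])) > 1) return(FALSE)
    }
    TRUE
  })
  feas <- grid[ok, , drop = FALSE]
  key <- feas
  key[key == 0] <- nd + 1L   # unlinked sorts last
  ord <- do.call(order, as.data.frame(key))
  best <- feas[ord[1], ]
  treated <- best > 0
  names(treated) <- NULL
  # return in the adjudicated ordering (participant, onset)
  treated
}

# Dense grid-search NB2 MLE oracle on (log lambda, log alpha), with
# staged refinement; independent of the analytic-gradient fit.
grid_nb_mle <- function(n_bleeds, exposure_days) {
  y <- n_bleeds; Tyr <- exposure_days / 365.25
  ll <- function(loglam, logalp) {
    mu <- exp(loglam) * Tyr
    r <- exp(-logalp)
    sum(lgamma(y + r) - lgamma(r) - lfactorial(y) +
          r * (log(r) - log(r + mu)) + y * (log(mu) - log(r + mu)))
  }
  cl <- log(sum(y) / sum(Tyr)); ca <- 0
  wl <- 4; wa <- 10
  for (stage in 1:5) {
    gl <- seq(cl - wl, cl + wl, length.out = 41)
    ga <- seq(ca - wa, ca + wa, length.out = 41)
    vals <- outer(gl, ga, Vectorize(ll))
    ix <- arrayInd(which.max(vals), dim(vals))
    cl <- gl[ix[1]]; ca <- ga[ix[2]]
    wl <- wl / 10; wa <- wa / 10
  }
  list(rate_per_year = exp(cl), dispersion = exp(ca), loglik = ll(cl, ca))
}
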