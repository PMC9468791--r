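# Fixtures realizing the printed count patterns of the three cohorts.
fixture_A <- function() build_count_fixture(count_fixture_spec(
  "A", n_participants = 103,
  treated = data.frame(n = 997),
  untreated = data.frame(
    location = c("knee", "elbow", "ankle", "wrist", "muscle",
                 "soft_tissue", "bruise_hematoma", "miscellaneous"),
    n = c(104, 76, 57, 125, 89, 72, 104, 32)),
  n_untreated_reporters = 74))

fixture_B <- function() build_count_fixture(count_fixture_spec(
  "B", n_participants = 24,
  treated = data.frame(n = 233),
  untreated = data.frame(
    location = c("knee", "elbow", "ankle", "wrist", "hip", "muscle", "other"),
    n = c(7, 1, 1, 1, 1, 12, 133)),
  n_untreated_reporters = 13))

fixture_C <- function() build_count_fixture(count_fixture_spec(
  "C", n_participants = 94,
  treated = data.frame(n = 1220),
  untreated = data.frame(location = c("knee", "muscle", "other"),
                         n = c(234, 141, 58)),
  n_untreated_reporters = 45))

test_that("untreated proportions come out at the fixture design points", {
  sA <- summarize_diary(fixture_A())
  expect_equal(sA$counts$all, 1656)
  expect_equal(sA$proportion_untreated$pct_untreated, 39.8)
  sC <- summarize_diary(fixture_C())
  expect_equal(sC$proportion_untreated$pct_untreated, 26.2)
  # degenerate: everything treated
  d <- make_test_diary(bleed_days = c(1, 2), dose_days = c(1, 2))
  expect_equal(proportion_untreated(adjudicate(d))$pct_untreated, 0)
})

test_that("reporter percentages use the full roster as denominator", {
  sA <- summarize_diary(fixture_A())
  expect_equal(sA$reporter_percentages$n_reporting, 74)
  expect_equal(sA$reporter_percentages$pct_reporting, 71.8)
  sB <- summarize_diary(fixture_B())
  expect_equal(sB$reporter_percentages$pct_reporting, 54.2)
  d <- make_test_diary(bleed_days = 1, dose_days = 1, n_participants = 5)
  rp <- reporter_percentages(adjudicate(d), d$participants)
  expect_equal(rp$pct_reporting, 0)
  expect_equal(rp$n_participants, 5)
})

test_that("the location table reproduces joint shares and sub-shares", {
  sB <- summarize_diary(fixture_B())
  lt <- sB$location_table[!sB$location_table$treated, ]
  joint <- lt[lt$row == "joint", ]
  expect_equal(joint$n, 11)
  expect_equal(joint$denominator, 156)
  expect_equal(joint$pct, 7.1)
  knee <- lt[lt$row == "knee", ]
  expect_equal(knee$n, 7)
  expect_equal(knee$denominator, 11)  # sub-rows are shares of joint bleeds
  expect_equal(knee$pct, 63.6)
})

test_that("a single joint bleed is 100% joint and 100% its site", {
  d <- make_test_diary(bleed_days = 1, locations = "elbow")
  lt <- location_table(adjudicate(d))
  expect_equal(lt$pct[lt$row == "joint"], 100)
  expect_equal(lt$pct[lt$row == "elbow"], 100)
})

test_that("location rows partition the stratum count exactly", {
  for (fx in list(fixture_A(), fixture_B(), fixture_C())) {
    s <- summarize_diary(fx)
    lt <- s$location_table
    for (tr in unique(lt$treated)) {
      sub <- lt[lt$treated == tr, ]
      top <- sub[sub$share_of == "total", ]
      expect_equal(sum(top$n), top$denominator[1])
      expect_equal(sum(top$pct), 100, tolerance = 0.2)
      jo <- sub[sub$share_of == "joint", ]
      expect_equal(sum(jo$n), sub$n[sub$row == "joint"])
    }
  }
})

test_that("untreated muscle shares match the fixture design points", {
  get_muscle <- function(s) {
    lt <- s$location_table
    lt$pct[lt$row == "muscle" & !lt$treated]
  }
  expect_equal(get_muscle(summarize_diary(fixture_A())), 13.5)
  expect_equal(get_muscle(summarize_diary(fixture_B())), 7.7)
  expect_equal(get_muscle(summarize_diary(fixture_C())), 32.6)
})

test_that("cause percentages include surgery bleeds in the denominator", {
  fx <- build_count_fixture(count_fixture_spec(
    "C", n_participants = 48, regimen = "prophylactic",
    untreated = data.frame(cause = c("spontaneous", "surgery_procedure"),
                           n = c(72, 2))))
  ct <- cause_table(adjudicate(fx))
  expect_equal(ct$pct[ct$cause == "surgery_procedure"], 2.7)
  expect_equal(sum(ct$pct), 100, tolerance = 0.2)
  d <- make_test_diary(bleed_days = 1:3)
  ct2 <- cause_table(adjudicate(d))
  expect_equal(ct2$pct[ct2$cause == "spontaneous"], 100)
  expect_equal(ct2$pct[ct2$cause != "spontaneous"], c(0, 0))
})

test_that("the prophylaxis-follow summary counts only prophylaxis
           participants' untreated bleeds", {
  fx <- build_count_fixture(count_fixture_spec(
    "A", n_participants = 20, regimen = "prophylactic",
    untreated = data.frame(n = 100),
    n_untreated_prophylaxis_followed = 50))
  s <- summarize_diary(fx)
  expect_equal(s$prophylaxis_follow$n_followed, 50)
  expect_equal(s$prophylaxis_follow$n_untreated_prophylaxis, 100)
  expect_equal(s$prophylaxis_follow$pct_followed, 50)
})

test_that("empty strata report undefined percentages, not zero", {
  # episodic-only cohort: no prophylaxis participants at all
  fx <- build_count_fixture(count_fixture_spec(
    "A", n_participants = 5, untreated = data.frame(n = 10)))
  s <- summarize_diary(fx)
  expect_true(is.na(s$prophylaxis_follow$pct_followed))
  # prophylactic cohort with zero untreated bleeds
  fx2 <- build_count_fixture(count_fixture_spec(
    "A", n_participants = 5, regimen = "prophylactic",
    treated = data.frame(n = 10)))
  s2 <- summarize_diary(fx2)
  expect_equal(s2$prophylaxis_follow$n_untreated_prophylaxis, 0)
  expect_true(is.na(s2$prophylaxis_follow$pct_followed))
})

test_that("excluding a participant equals running the filtered diary", {
  fx <- build_count_fixture(count_fixture_spec(
    "C", n_participants = 10, treated = data.frame(n = 30),
    untreated = data.frame(n = 12), n_untreated_reporters = 6))
  res <- sensitivity_exclude(fx, "C0001")
  direct <- summarize_diary(exclude_participant(fx, "C0001"))
  expect_equal(res$excluded$counts, direct$counts)
  expect_equal(res$excluded$cause_table, direct$cause_table)
  expect_equal(res$excluded$reporter_percentages,
               direct$reporter_percentages)
})

test_that("excluding a zero-bleed participant only shrinks denominators", {
  fx <- build_count_fixture(count_fixture_spec(
    "C", n_participants = 10, untreated = data.frame(n = 5),
    n_untreated_reporters = 5))
  res <- sensitivity_exclude(fx, "C0010")  # holds no bleeds
  expect_equal(res$excluded$counts, res$full$counts)
  expect_equal(res$excluded$reporter_percentages$n_participants, 9)
  expect_equal(res$full$reporter_percentages$n_participants, 10)
})

test_that("excluding the only participant gives empty-diary outputs", {
  fx <- build_count_fixture(count_fixture_spec(
    "C", n_participants = 1, untreated = data.frame(n = 3)))
  res <- sensitivity_exclude(fx, "C0001")
  expect_equal(res$excluded$counts$all, 0)
  expect_error(sensitivity_exclude(fx, "nobody"), "unknown participant")
})

test_that("percentages round half away from zero to one decimal", {
  expect_equal(round_half_up(26.25), 26.3)
  expect_equal(round_half_up(26.24), 26.2)
  expect_equal(round_half_up(0.05), 0.1)
  expect_equal(round_half_up(2.5, 0), 3)
})
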