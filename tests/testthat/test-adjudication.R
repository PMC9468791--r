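# Linkage rule: one treatment, one bleed; first treatment thereafter;
# unlimited gap; same-calendar-day sharing; location never merges bleeds.

test_that("a bleed links to the first treat dose regardless of the gap", {
  d <- make_test_diary(bleed_days = 5, dose_days = 9)
  adj <- link_treatments(d)
  expect_true(adj$treated)
  expect_equal(adj$linked_medication_row, 1L)
})

test_that("same-calendar-day bleeds share the single subsequent dose", {
  d <- make_test_diary(bleed_days = c(3, 3), locations = c("knee", "elbow"),
                       dose_days = 3)
  adj <- link_treatments(d)
  expect_equal(adj$treated, c(TRUE, TRUE))
  expect_equal(adj$linked_medication_row, c(1L, 1L))
})

test_that("bleeds on different days never share one dose", {
  d <- make_test_diary(bleed_days = c(1, 2), locations = c("knee", "knee"),
                       dose_days = 3)
  adj <- link_treatments(d)
  expect_equal(adj$treated, c(TRUE, FALSE))
})

test_that("a dose at the bleed's exact timestamp counts as thereafter", {
  d <- make_test_diary(bleed_days = 4, dose_days = 4)
  expect_true(link_treatments(d)$treated)
})

test_that("doses before every bleed stay orphans and are reported", {
  d <- make_test_diary(bleed_days = 10, dose_days = c(2, 11))
  adj <- link_treatments(d)
  expect_true(adj$treated)
  expect_equal(adj$linked_medication_row, 2L)
  expect_equal(nrow(attr(adj, "orphan_doses")), 1)
})

test_that("prophylaxis doses never make a bleed treated", {
  d <- make_test_diary(bleed_days = 5, dose_days = 6,
                       dose_purposes = "prophylaxis")
  expect_false(link_treatments(d)$treated)
})

test_that("partition and one-to-one hold on random diaries", {
  set.seed(101)
  for (rep in 1:60) {
    d <- rand_small_diary()
    adj <- link_treatments(d)
    counts <- classify_treated_untreated(adj)
    expect_equal(counts$all, counts$treated + counts$untreated)
    expect_equal(counts$all, nrow(adj))
    links <- adj[adj$treated, c("onset", "linked_medication_row")]
    if (nrow(links) > 1) {
      day <- floor(as.numeric(links$onset) / 86400)
      shared <- split(day, links$linked_medication_row)
      for (s in shared) expect_length(unique(s), 1)
    }
  }
})

test_that("linkage ignores location and cause (metamorphic)", {
  set.seed(202)
  for (rep in 1:25) {
    d <- rand_small_diary()
    adj1 <- link_treatments(d)
    d2 <- d
    if (nrow(d2$bleeds)) {
      d2$bleeds$location <- rev(d2$bleeds$location)
      d2$bleeds$cause <- sample(d2$bleeds$cause)
    }
    adj2 <- link_treatments(d2)
    expect_equal(adj2$treated, adj1$treated)
    expect_equal(adj2$linked_medication_row, adj1$linked_medication_row)
  }
})

test_that("greedy linkage equals the exhaustive-search oracle", {
  set.seed(303)
  for (rep in 1:80) {
    d <- rand_small_diary()
    adj <- link_treatments(d)
    expect_equal(unname(adj$treated), unname(exhaustive_linkage(d)),
                 info = paste("replicate", rep))
  }
})

# 72-hour collapsing rule

test_that("with the rule off every bleed is its own group", {
  d <- make_test_diary(bleed_days = c(1, 2, 3), dose_days = c(1, 2, 3))
  adj <- collapse_72h(link_treatments(d), d)
  expect_equal(counted_bleeds(adj), 3)
  expect_false(any(duplicated(adj$collapse_group_id)))
})

test_that("same type and location within 72h of treatment stop merge", {
  cfg <- adjudication_config(apply_72h_rule = TRUE,
                             collapse_reference = "after_treatment_stop")
  d <- make_test_diary(bleed_days = c(1, 3), locations = c("knee", "knee"),
                       causes = "spontaneous", dose_days = 1)
  adj <- collapse_72h(link_treatments(d, cfg), d, cfg)
  expect_equal(counted_bleeds(adj), 1)
})

test_that("a different location splits the pair into two groups", {
  cfg <- adjudication_config(apply_72h_rule = TRUE)
  d <- make_test_diary(bleed_days = c(1, 3), locations = c("knee", "elbow"),
                       dose_days = 1)
  adj <- collapse_72h(link_treatments(d, cfg), d, cfg)
  expect_equal(counted_bleeds(adj), 2)
})

test_that("a different cause splits the pair unless type is not required", {
  d <- make_test_diary(bleed_days = c(1, 3), locations = "knee",
                       causes = c("spontaneous", "traumatic"), dose_days = 1)
  cfg <- adjudication_config(apply_72h_rule = TRUE)
  expect_equal(counted_bleeds(collapse_72h(link_treatments(d, cfg), d, cfg)), 2)
  cfg2 <- adjudication_config(apply_72h_rule = TRUE, same_type_required = FALSE)
  expect_equal(counted_bleeds(collapse_72h(link_treatments(d, cfg2), d, cfg2)), 1)
})

test_that("transitive chains merge in treatment-relative mode", {
  cfg <- adjudication_config(apply_72h_rule = TRUE,
                             collapse_reference = "after_treatment_stop")
  # b1 treated day 2; b2 day 4 within 72h of day-2 dose, untreated, so the
  # chain reference moves to b2's onset; b3 day 6 within 72h of day 4.
  d <- make_test_diary(bleed_days = c(1, 4, 6), locations = "knee",
                       dose_days = 2)
  adj <- collapse_72h(link_treatments(d, cfg), d, cfg)
  expect_equal(counted_bleeds(adj), 1)
  expect_length(unique(adj$collapse_group_id), 1)
})

test_that("transitive chains merge in bleed-relative mode for untreated runs", {
  cfg <- adjudication_config(apply_72h_rule = TRUE,
                             collapse_reference = "after_previous_bleed")
  d <- make_test_diary(bleed_days = c(0, 3, 6, 12), locations = "knee")
  adj <- collapse_72h(link_treatments(d, cfg), d, cfg)
  # 0-3 and 3-6 chain; 12 is 6 days after 6 -> new group
  expect_equal(counted_bleeds(adj), 2)
  expect_equal(adj$collapse_group_id[1:3], rep(adj$collapse_group_id[1], 3))
})

test_that("enabling the rule never increases counted bleeds (property)", {
  set.seed(404)
  for (rep in 1:30) {
    d <- rand_small_diary()
    off <- adjudication_config()
    raw <- collapse_72h(link_treatments(d, off), d, off)
    expect_equal(counted_bleeds(raw), nrow(raw))
    for (mode in c("after_treatment_stop", "after_previous_bleed")) {
      cfg <- adjudication_config(apply_72h_rule = TRUE,
                                 collapse_reference = mode)
      on <- collapse_72h(link_treatments(d, cfg), d, cfg)
      expect_lte(counted_bleeds(on), counted_bleeds(raw))
    }
  }
})

# Joint-bleed definitions

test_that("cohort A requires aura plus another joint symptom at a joint site", {
  expect_true(classify_joint("knee", "aura;swelling", "A"))
  expect_false(classify_joint("knee", "swelling", "A"))
  expect_false(classify_joint("knee", "aura", "A"))
  expect_false(classify_joint("muscle", "aura;swelling", "A"))
})

test_that("cohort C drops the aura requirement", {
  expect_true(classify_joint("ankle", "pain", "C"))
  expect_true(classify_joint("ankle", "aura", "C"))
  expect_false(classify_joint("ankle", "", "C"))
  expect_false(classify_joint("other", "pain", "C"))
})

test_that("cohort B uses the reported joint location", {
  expect_true(classify_joint("knee", "", "B"))
  expect_true(classify_joint("other", "", "B", reported_joint_location = TRUE))
  expect_false(classify_joint("other", "", "B"))
})

# 24-hour prophylaxis-follow flag

test_that("untreated bleeds followed by prophylaxis within 24h are flagged", {
  d <- make_test_diary(bleed_days = 10, dose_days = 10.5,
                       dose_purposes = "prophylaxis")
  adj <- flag_prophylaxis_followup(link_treatments(d), d)
  expect_true(adj$prophylaxis_followup_within_24h)
})

test_that("a prophylaxis dose outside the window does not flag", {
  d <- make_test_diary(bleed_days = 10, dose_days = 12,
                       dose_purposes = "prophylaxis")
  adj <- flag_prophylaxis_followup(link_treatments(d), d)
  expect_false(adj$prophylaxis_followup_within_24h)
})

test_that("exactly 24h later still flags; treated bleeds never flag", {
  d <- make_test_diary(bleed_days = 10, dose_days = 11,
                       dose_purposes = "prophylaxis")
  expect_true(flag_prophylaxis_followup(
    link_treatments(d), d)$prophylaxis_followup_within_24h)
  d2 <- make_test_diary(bleed_days = 10, dose_days = c(10, 10),
                        dose_purposes = c("treat_bleed", "prophylaxis"))
  adj2 <- flag_prophylaxis_followup(link_treatments(d2), d2)
  expect_true(adj2$treated)
  expect_false(adj2$prophylaxis_followup_within_24h)
})

test_that("surgery bleeds can be excluded from adjudication on request", {
  d <- make_test_diary(bleed_days = c(1, 2),
                       causes = c("spontaneous", "surgery_procedure"))
  expect_equal(nrow(adjudicate(d)), 2)
  cfg <- adjudication_config(include_surgery_bleeds = FALSE)
  expect_equal(nrow(adjudicate(d, cfg)), 1)
})
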