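test_that("item completeness recomputes from a routine stratum's counts", {
  doc <- fixture_from_counts(207, c(3, 0, 24), 180, "routine")
  rep <- item_completeness(doc$forms)
  rt <- rep[rep$stratum == "routine", ]
  expect_equal(rt$cases, rep(207L, 4))
  expect_equal(rt$available[rt$item == "therapy_start_date"], 204L)
  expect_equal(rt$available[rt$item == "followup_status"], 207L)
  expect_equal(rt$available[rt$item == "followup_date"], 183L)
  expect_equal(rt$available[rt$item == "all_three"], 180L)
  expect_equal(rt$percentage[rt$item == "followup_status"], 100)
  expect_equal(rt$percentage[rt$item == "followup_date"], 88.4)
  # percentages always recompute from their own numerator/denominator
  expect_equal(rt$percentage,
               round(100 * rt$available / rt$cases + 1e-9, 1))
})

test_that("whole-cohort completeness matches the printed study counts", {
  doc <- fixture_from_counts(965, c(23, 15, 55), 881, "retrospective")
  rep <- item_completeness(doc$forms)
  tot <- rep[rep$stratum == "total", ]
  expect_equal(tot$available, c(942L, 950L, 910L, 881L))
  expect_equal(tot$percentage[tot$item == "therapy_start_date"], 97.6)
  expect_equal(tot$percentage[tot$item == "followup_date"], 94.3)
  expect_equal(tot$percentage[tot$item == "all_three"], 91.3)
})

test_that("strata are additive and the empty input yields an empty report", {
  d1 <- fixture_from_counts(50, c(2, 1, 5), 44, "routine")$forms
  d2 <- fixture_from_counts(70, c(3, 0, 7), 62, "retrospective")$forms
  d2$patient_pseudonym <- paste0("R", d2$patient_pseudonym)
  d2$form_id <- paste0("R", d2$form_id)
  rep <- item_completeness(rbind(d1, d2))
  for (it in unique(rep$item)) {
    expect_equal(rep$available[rep$stratum == "total" & rep$item == it],
                 rep$available[rep$stratum == "routine" & rep$item == it] +
                   rep$available[rep$stratum == "retrospective" & rep$item == it])
  }
  emp <- item_completeness(form_document()$forms)
  expect_s3_class(emp, "completeness_report")
  expect_true(all(is.na(emp$percentage)))
  full <- item_completeness(fixture_from_counts(10, c(0, 0, 0), 10)$forms)
  expect_true(all(full$percentage[full$cases > 0] == 100))
})

test_that("form completeness counts eligible patients with survival info", {
  doc <- fixture_from_counts(115, c(0, 0, 0), 115, "routine")
  eligible <- sprintf("P%05d", 1:191)
  fc <- form_completeness(eligible, doc$forms)
  expect_equal(fc$with_form, 115L)
  expect_equal(fc$eligible, 191L)
  expect_equal(fc$percentage, 60.2)
  # forms outside the eligible set are ignored
  fc2 <- form_completeness(sprintf("P%05d", 1:100), doc$forms)
  expect_equal(fc2$with_form, 100L)
  expect_equal(fc2$percentage, 100)
  # a form without survival information does not count
  noinfo <- fixture_from_counts(10, c(0, 0, 10), 0, "routine")
  expect_equal(form_completeness(sprintf("P%05d", 1:10), noinfo$forms)$with_form,
               0L)
  expect_error(form_completeness(character(0), doc$forms), "empty")
})

test_that("person-time completeness follows the Clark convention", {
  # both patients have 2922 days potential; one observed exactly half
  rec <- data.frame(origin_date = as.Date(c("2000-01-01", "2000-01-01")),
                    last_contact_date = as.Date(c("2004-01-01", "2008-01-01")),
                    os_event = c(0L, 0L))
  expect_equal(clark_completeness(rec, "2008-01-01"), 75)
  # complete follow-up everywhere -> 100%
  full <- rec; full$last_contact_date <- as.Date("2008-01-01")
  expect_equal(clark_completeness(full, "2008-01-01"), 100)
  # death closes follow-up: a patient dead at last contact is complete
  dead <- data.frame(origin_date = as.Date("2000-01-01"),
                     last_contact_date = as.Date("2002-01-01"),
                     os_event = 1L)
  expect_equal(clark_completeness(dead, "2008-01-01"), 100)
  expect_equal(clark_completeness(rbind(rec, dead), "2008-01-01"),
               100 * (1461 + 2922 + 731) / (2922 + 2922 + 731))
  # last contact beyond study end clamps potential with a warning
  late <- data.frame(origin_date = as.Date("2000-01-01"),
                     last_contact_date = as.Date("2011-01-01"),
                     os_event = 0L)
  expect_warning(c1 <- clark_completeness(late, "2010-01-01"), "clamp")
  expect_equal(c1, 100)
  expect_error(clark_completeness(rec, "1999-01-01"), "precede")
})

test_that("completeness bounds and reconstruction invariants hold", {
  doc <- simulate_cohort(cohort_spec(n_patients = 120, seed = 31))
  rec <- build_records(doc)
  C <- clark_completeness(rec, "2010-05-31")
  expect_gte(C, 0); expect_lte(C, 100)
  rep <- item_completeness(deduplicate_forms(doc)$current)
  expect_true(all(rep$available <= rep$cases))
  a3 <- rep$available[rep$item == "all_three"]
  for (s in unique(rep$stratum)) {
    sub <- rep[rep$stratum == s, ]
    expect_lte(sub$available[sub$item == "all_three"],
               min(sub$available[sub$item != "all_three"]))
  }
})
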