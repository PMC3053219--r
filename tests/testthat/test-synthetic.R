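test_that("simulation is reproducible and respects patient counts", {
  spec <- cohort_spec(n_patients = 100, seed = 11)
  d1 <- simulate_cohort(spec)
  d2 <- simulate_cohort(spec)
  expect_identical(write_odm(d1), write_odm(d2))    # byte-identical rerun
  expect_equal(length(unique(d1$forms$patient_pseudonym)), 100L)
  expect_gte(nrow(d1$forms), 100L)
  # a different seed changes the cohort
  expect_false(identical(write_odm(d1),
                         write_odm(simulate_cohort(cohort_spec(
                           n_patients = 100, seed = 12)))))
})

test_that("zero death hazard generates no death statuses", {
  spec <- cohort_spec(n_patients = 80, hazard_death = 0, seed = 8)
  doc <- simulate_cohort(spec)
  expect_false(any(grepl("^Death", doc$forms$status_label)))
  lat <- attr(doc, "latent")
  expect_false(any(lat$died))
})

test_that("generated statuses are consistent with the latent history", {
  spec <- cohort_spec(n_patients = 120, seed = 19, imprecise_date_rate = 0,
                      missing_rates = c(therapy_date = 0, status = 0,
                                        followup_date = 0))
  doc <- simulate_cohort(spec)
  lat <- attr(doc, "latent")
  forms <- doc$forms
  fu <- resolve_date(forms$followup_date)
  origin <- lat$origin_date[match(forms$patient_pseudonym,
                                  lat$patient_pseudonym)]
  t_form <- as.numeric(fu - origin) / 365.25
  relapse_t <- lat$relapse_years[match(forms$patient_pseudonym,
                                       lat$patient_pseudonym)]
  is_death <- grepl("^Death", forms$status_label)
  is_relapse <- forms$status_label %in% c("Relapse (PSA)", "Relapse")
  # a death form is the patient's chronologically last form
  for (p in unique(forms$patient_pseudonym[is_death])) {
    rows <- which(forms$patient_pseudonym == p)
    expect_true(is_death[rows[which.max(fu[rows])]])
    expect_equal(sum(is_death[rows]), 1L)
  }
  # relapse statuses never precede the latent relapse time
  # (form dates are rounded to whole days)
  expect_true(all(t_form[is_relapse] >= relapse_t[is_relapse] - 1/365.25))
})

test_that("a fully observed cohort reports 100% item completeness", {
  spec <- cohort_spec(n_patients = 150, seed = 23,
                      missing_rates = c(therapy_date = 0, status = 0,
                                        followup_date = 0))
  doc <- simulate_cohort(spec)
  rep <- item_completeness(deduplicate_forms(doc)$current)
  expect_true(all(rep$percentage[rep$cases > 0] == 100))
})

test_that("event fractions converge to the exponential closed form", {
  spec <- cohort_spec(n_patients = 5000, seed = 29, imprecise_date_rate = 0,
                      missing_rates = c(therapy_date = 0, status = 0,
                                        followup_date = 0))
  doc <- simulate_cohort(spec)
  lat <- attr(doc, "latent")
  # conditional on each origin, P(death by study end) = 1 - exp(-lambda * fu_max)
  fu_max <- as.numeric(as.Date("2010-05-31") - lat$origin_date) / 365.25
  p <- 1 - exp(-spec$hazard_death * fu_max)
  mc_se <- sqrt(sum(p * (1 - p))) / length(p)
  expect_lt(abs(mean(lat$died) - mean(p)), 3 * mc_se)
  # and the pipeline recovers the latent observation times exactly
  rec <- build_records(doc)
  m <- match(rec$patient_id, lat$patient_pseudonym)
  expect_equal(rec$time_years, lat$exit_years[m], tolerance = 2 / 365.25)
})

test_that("median survival from the full pipeline matches the closed form", {
  spec <- cohort_spec(n_patients = 5000, hazard_death = 0.05,
                      missing_rates = c(therapy_date = 0, status = 0,
                                        followup_date = 0),
                      imprecise_date_rate = 0, seed = 1)
  rec <- build_records(simulate_cohort(spec))
  med <- median_survival(km_fit(rec, endpoint = "os"))
  expect_lt(abs(med - log(2) / 0.05) / (log(2) / 0.05), 0.05)
})

test_that("count fixtures respect feasibility and greedy overlap", {
  doc <- fixture_from_counts(965, c(23, 15, 55), 881, "retrospective")
  miss <- is.na(doc$forms$therapy_date) + is.na(doc$forms$status_label) +
    is.na(doc$forms$followup_date)
  expect_equal(sum(miss == 0), 881L)
  expect_equal(sum(miss >= 2), 9L)      # inclusion-exclusion: 93 slots, 84 patients
  expect_error(fixture_from_counts(10, c(8, 0, 0), 5), "max\\(missing")
  expect_error(fixture_from_counts(10, c(1, 1, 1), 2),
               "exceeds sum")
  # deterministic
  expect_identical(write_odm(fixture_from_counts(50, c(2, 1, 5), 44)),
                   write_odm(fixture_from_counts(50, c(2, 1, 5), 44)))
})

test_that("invalid specifications are rejected up front", {
  expect_error(cohort_spec(n_patients = 0), "positive")
  expect_error(cohort_spec(department_mix = c(urology = 0.5)), "summing")
  expect_error(cohort_spec(hazard_death = -1), "non-negative")
  expect_error(cohort_spec(routine_fraction = 1.5), "fraction")
  expect_error(cohort_spec(accrual_start = "2011-01-01"), "accrual")
})
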