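test_that("the most current form wins deduplication", {
  # single form: identity
  one <- make_form()
  dd <- deduplicate_forms(one)
  expect_equal(dd$current$form_id, "F001")

  # later follow-up date wins regardless of row order
  f <- rbind(make_form("F1", followup_date = "2009-01-01",
                       status_label = "Relapse (PSA)"),
             make_form("F2", followup_date = "2010-01-01",
                       status_label = "Death of prostate cancer"))
  expect_equal(deduplicate_forms(f)$current$status_label,
               "Death of prostate cancer")
  expect_equal(deduplicate_forms(f[2:1, ])$current$status_label,
               "Death of prostate cancer")

  # equal dates: later entry timestamp; equal timestamps: larger form_id
  g <- rbind(make_form("F1", entry_timestamp = "2010-01-01T08:00:00"),
             make_form("F2", entry_timestamp = "2010-01-01T09:00:00"))
  expect_equal(deduplicate_forms(g)$current$form_id, "F2")
  h <- rbind(make_form("F1"), make_form("F2"))
  expect_equal(deduplicate_forms(h)$current$form_id, "F2")

  # a dated form always outranks an undated one
  u <- rbind(make_form("F9", followup_date = NA,
                       entry_timestamp = "2011-01-01T00:00:00"),
             make_form("F1", followup_date = "2005-01-01"))
  expect_equal(deduplicate_forms(u)$current$form_id, "F1")
})

test_that("deduplication is idempotent, order-invariant and conserving", {
  doc <- simulate_cohort(cohort_spec(n_patients = 40, seed = 12))
  dd <- deduplicate_forms(doc$forms)
  expect_equal(nrow(dd$current),
               length(unique(doc$forms$patient_pseudonym)))
  expect_identical(deduplicate_forms(dd$current)$current, dd$current)
  set.seed(1)
  shuffled <- doc$forms[sample(nrow(doc$forms)), ]
  dd2 <- deduplicate_forms(shuffled)
  expect_identical(dd2$current, dd$current)
  expect_identical(dd2$history, dd$history)
})

test_that("observation time and events follow the current status", {
  f <- make_form(therapy_date = "2000-01-01", followup_date = "2005-01-01",
                 status_label = "Death of prostate cancer")
  rec <- build_records(f)
  days <- as.numeric(as.Date("2005-01-01") - as.Date("2000-01-01"))
  expect_equal(rec$time_years, days / 365.25)   # 5.00 years
  expect_equal(rec$os_event, 1L)
  expect_equal(rec$efs_event, 1L)
  expect_equal(rec$efs_time_years, rec$time_years)

  # zero-duration boundary
  z <- make_form(therapy_date = "2000-01-01", followup_date = "2000-01-01",
                 status_label = "Initial diagnosis")
  recz <- build_records(z)
  expect_equal(recz$time_years, 0)
  expect_equal(recz$os_event, 0L)
})

test_that("EFS time runs to the first event-positive form", {
  f <- rbind(make_form("F1", followup_date = "2003-06-10",
                       status_label = "Relapse (PSA)"),
             make_form("F2", followup_date = "2008-02-01",
                       status_label = "Relapse free"))
  rec <- build_records(f)
  expect_equal(rec$os_event, 0L)
  expect_equal(rec$time_years,
               as.numeric(as.Date("2008-02-01") - as.Date("2000-01-01")) / 365.25)
  expect_equal(rec$efs_event, 1L)
  expect_equal(rec$efs_time_years,
               as.numeric(as.Date("2003-06-10") - as.Date("2000-01-01")) / 365.25)
  # origin is the earliest therapy date across forms
  g <- rbind(make_form("F1", therapy_date = "2001-05-01"),
             make_form("F2", therapy_date = "2000-03-01",
                       followup_date = "2006-01-01"))
  expect_equal(build_records(g)$origin_date, as.Date("2000-03-01"))
})

test_that("unanalyzable patients are excluded and reported, never silently", {
  f <- rbind(make_form("F1", patient = "A", therapy_date = NA),
             make_form("F2", patient = "B", status_label = NA),
             make_form("F3", patient = "C", followup_date = NA),
             make_form("F4", patient = "D"))
  rec <- build_records(f)
  excl <- attr(rec, "excluded")
  expect_equal(rec$patient_id, "D")
  expect_setequal(excl$patient_id, c("A", "B", "C"))
  expect_setequal(excl$reason, c("missing_therapy_date", "missing_status",
                                 "missing_followup_date"))
  # follow-up before origin is a data error, excluded with a warning
  neg <- make_form(therapy_date = "2005-01-01", followup_date = "2000-01-01")
  expect_warning(recn <- build_records(neg), "before origin")
  expect_equal(nrow(recn), 0L)
  expect_equal(attr(recn, "excluded")$reason, "followup_before_origin")
  # diagnosis origin as alternative time axis
  d <- build_records(make_form(therapy_date = NA), origin = "diagnosis")
  expect_equal(d$origin_date, as.Date("1999-12-01"))
})

test_that("record invariants hold on simulated cohorts", {
  doc <- simulate_cohort(cohort_spec(n_patients = 150, seed = 9))
  rec <- build_records(doc)
  expect_true(all(rec$time_years >= 0))
  expect_true(all(rec$efs_time_years <= rec$time_years + 1e-12))
  expect_true(all(rec$efs_event[rec$os_event == 1] == 1))
  # conservation: every patient is analyzed or excluded
  expect_equal(nrow(rec) + nrow(attr(rec, "excluded")),
               length(unique(doc$forms$patient_pseudonym)))
})

test_that("CSV export round-trips records and handles the empty case", {
  doc <- simulate_cohort(cohort_spec(n_patients = 25, seed = 4))
  rec <- build_records(doc,
                       group = setNames(rep(c("G1", "G2"), length.out = 25),
                                        sprintf("P%05d", 1:25)))
  csv <- export_csv(rec)
  back <- read_records_csv(text = csv)
  cols <- c("patient_id", "department", "followup_date", "status_label",
            "os_event", "efs_event", "entry_mode", "group")
  expect_equal(back[, cols], rec[, cols], ignore_attr = TRUE)
  expect_equal(back$time_years, rec$time_years, tolerance = 1e-10)
  expect_equal(back$origin_date, rec$origin_date)
  expect_true(any(!is.na(back$group)))

  empty <- build_records(form_document()$forms)
  expect_equal(length(strsplit(export_csv(empty), "\n")[[1]]), 1L)

  # keyed pseudonymization is stable and hides source ids
  p1 <- export_csv(rec, pseudonymize_key = "k1")
  expect_identical(p1, export_csv(rec, pseudonymize_key = "k1"))
  expect_false(grepl("P00001", p1))
})
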