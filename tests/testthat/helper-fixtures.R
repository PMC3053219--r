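# builders for small follow-up documents used across tests

make_form <- function(form_id = "F001", patient = "P001",
                      department = "urology",
                      diagnosis_date = "1999-12-01",
                      therapy_date = "2000-01-01",
                      followup_date = "2005-01-01",
                      status_label = "Relapse free",
                      entry_mode = "routine",
                      entry_timestamp = "2010-03-01T10:00:00", ...) {
  extra <- list(...)
  row <- data.frame(form_id = form_id, patient_pseudonym = patient,
                    department = department,
                    diagnosis_date = diagnosis_date,
                    therapy_date = therapy_date,
                    followup_date = followup_date,
                    status_label = status_label,
                    entry_mode = entry_mode,
                    entry_timestamp = entry_timestamp,
                    stringsAsFactors = FALSE)
  for (nm in names(extra)) row[[nm]] <- extra[[nm]]
  row
}

make_doc <- function(...) {
  form_document(do.call(rbind.fill_forms, list(...)))
}

# rbind allowing different column subsets (missing -> NA)
rbind.fill_forms <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (c in setdiff(cols, names(d))) d[[c]] <- NA_character_
    d[, cols]
  }))
}

# the four-observation worked example: event at 1, censor at 2,
# event at 3, censor at 4
worked_fit <- function(...) km_fit(c(1, 2, 3, 4), c(1, 0, 1, 0), ...)

# empirical survivor function: direct counting, independent of km_fit
empirical_survivor <- function(times, at) {
  vapply(at, function(t) mean(times > t), 0)
}
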